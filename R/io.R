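trait_table_cols <- c("genotype", "experiment", "replicate", "treatment",
                      "dat", "trait", "value")

#' Read and write the long-format trait table
#'
#' The single interchange format of the pipeline: one row per measurement
#' with header `genotype,experiment,replicate,treatment,dat,trait,value`.
#' Missing values are preserved; DATs are validated against the timeline.
#'
#' @param path CSV file path.
#' @param timeline A `pd_timeline` used to validate DATs (`NULL` skips).
#' @return A typed tibble of trait records.
#' @export
read_trait_table <- function(path, timeline = default_timeline()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trait_table_cols, names(raw))
  if (length(miss)) {
    stop("trait table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw$dat <- suppressWarnings(as.integer(raw$dat))
  raw$value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(raw$dat))
  if (length(bad)) {
    stop("malformed dat values on line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  }
  if (!is.null(timeline)) {
    out_of_range <- which(raw$dat < timeline$first_dat |
                            raw$dat > timeline$last_dat)
    if (length(out_of_range)) {
      stop("dat outside timeline on line(s): ",
           paste(utils::head(out_of_range + 1L, 10), collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::as_tibble(raw[, trait_table_cols])
}

#' @rdname read_trait_table
#' @param records Trait-record tibble to write.
#' @export
write_trait_table <- function(records, path) {
  utils::write.csv(records[, trait_table_cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and write watering-record tables
#'
#' The minimal interchange header is `plant_id,dat,weight_before,
#' weight_after,water_added`; plant ids of the form
#' `genotype_experiment_replicate_treatment` are parsed back into their
#' components on read (extra metadata columns, if present, are kept).
#'
#' @param path CSV file path.
#' @return A validated watering tibble.
#' @export
read_watering_table <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_watering(raw)
  if (!all(c("genotype", "experiment", "replicate", "treatment") %in%
             names(raw))) {
    parts <- strsplit(raw$plant_id, "_", fixed = TRUE)
    if (all(lengths(parts) == 4L)) {
      m <- do.call(rbind, parts)
      raw$genotype <- m[, 1]; raw$experiment <- m[, 2]
      raw$replicate <- m[, 3]; raw$treatment <- m[, 4]
    }
  }
  raw
}

#' @rdname read_watering_table
#' @param watering Watering tibble to write.
#' @export
write_watering_table <- function(watering, path) {
  validate_watering(watering)
  keep <- intersect(c("plant_id", "dat", "weight_before", "weight_after",
                      "water_added"), names(watering))
  utils::write.csv(watering[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotype metadata
#'
#' @param path CSV with columns `genotype`, `chickpea_type`,
#'   `biological_status` and optionally `origin_country`.
#' @return A validated [genotype_meta()] tibble.
#' @export
read_genotype_meta <- function(path) {
  genotype_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default pipeline configuration
#'
#' All tunable conventions in one list: timeline and pot calibration,
#' segmentation and hue-class settings, the outlier threshold, the BLUE
#' estimation method, the colour-ratio mode, the selection criteria and
#' the master seed.
#'
#' @return A list of class `pd_config`.
#' @export
default_config <- function() {
  structure(list(
    timeline = default_timeline(),
    calibration = default_pot_calibration(),
    segmentation = list(sat_max = 0.25, value_min = 0.05,
                        keep_largest = FALSE),
    hue_classes = hue_classes(),
    ratio_mode = "to_green",
    mcv_method = "pixel",
    outlier_threshold = 3,
    blue_method = "auto",
    key_dats = c(28L, 42L),
    wue_phases = c("DT", "DR", "DA"),
    eb_report_scale = 1e-5,
    seed = 1L
  ), class = "pd_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; absent keys keep their defaults. The file
#' round-trips through [write_pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pd_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    cfg[[k]] <- switch(
      k,
      timeline = do.call(default_timeline, user$timeline),
      calibration = do.call(pot_calibration, user$calibration),
      hue_classes = do.call(hue_classes, lapply(user$hue_classes, function(m)
        matrix(unlist(m), ncol = 2, byrow = TRUE))),
      key_dats = as.integer(user[[k]]),
      seed = as.integer(user[[k]]),
      user[[k]]
    )
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pd_config` to serialise.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pd_config"))
  tl <- config$timeline
  cal <- config$calibration
  hc <- config$hue_classes
  yaml::write_yaml(list(
    timeline = list(first_dat = tl$first_dat, last_dat = tl$last_dat,
                    drought_start = tl$drought_start,
                    rewater_step1 = tl$rewater_step1,
                    rewater_step2 = tl$rewater_step2,
                    fluorcam_dats = tl$fluorcam_dats,
                    excluded_dats = tl$excluded_dats),
    calibration = list(
      weight_at_field_capacity = cal$weight_at_field_capacity,
      weight_at_wilting_point = cal$weight_at_wilting_point,
      dry_system_weight = cal$dry_system_weight),
    segmentation = config$segmentation,
    hue_classes = lapply(hc, function(m) apply(m, 1, as.list)),
    ratio_mode = config$ratio_mode,
    mcv_method = config$mcv_method,
    outlier_threshold = config$outlier_threshold,
    blue_method = config$blue_method,
    key_dats = config$key_dats,
    wue_phases = config$wue_phases,
    eb_report_scale = config$eb_report_scale,
    seed = config$seed
  ), path)
  invisible(path)
}
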
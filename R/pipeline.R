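#' Run the full analysis pipeline on a trait table
#'
#' Executes the table-to-table stages in order: outlier screening,
#' variance components and heritability, genotype BLUEs, derived traits
#' (relative growth rate, drought loss, phase water-use efficiency,
#' coefficient of variation), and the panel analysis (deviations from the
#' panel mean and two-tier superiority selection). EB is rescaled to
#' reporting units (1e-5 voxels) exactly once, when the BLUE table is
#' built. Identical inputs and configuration give identical outputs.
#'
#' @param traits Long trait table (see [read_trait_table()]).
#' @param watering Watering table with genotype metadata columns (see
#'   [read_watering_table()]).
#' @param meta Optional [genotype_meta()] table for group comparisons.
#' @param config A [default_config()] list.
#' @param heritability_traits Traits for which the per-DAT heritability
#'   trace is computed (REML per slice; the costly stage). Default EB.
#' @param out_dir Optional directory; when given, every stage writes its
#'   CSV output there.
#' @return A list of class `pd_pipeline_result` with elements `flags`,
#'   `traits_clean`, `heritability`, `blues`, `rgr`, `loss`, `wue`, `cv`,
#'   `deviations`, `selection`, `group_stats`, `log`.
#' @export
run_pipeline <- function(traits, watering, meta = NULL,
                         config = default_config(),
                         heritability_traits = "EB",
                         out_dir = NULL) {
  stopifnot(inherits(config, "pd_config"))
  tl <- config$timeline
  log <- list()
  note <- function(stage, msg) {
    log[[stage]] <<- msg
    invisible(NULL)
  }
  if (!all(c("control", "drought") %in% unique(traits$treatment))) {
    stop("pipeline stage 'derived traits' requires both treatments; found: ",
         paste(unique(traits$treatment), collapse = ", "), call. = FALSE)
  }

  # 1. outlier screening --------------------------------------------------
  flags <- detect_outliers(traits, threshold = config$outlier_threshold)
  clean <- remove_outliers(traits, flags)
  note("outliers", sprintf("%d of %d observations flagged",
                           sum(flags$flagged), nrow(flags)))

  # 2. heritability trace --------------------------------------------------
  h2 <- heritability_table(
    clean[clean$trait %in% heritability_traits, , drop = FALSE])
  note("heritability", sprintf("%d slices", nrow(h2)))

  # 3. BLUEs ---------------------------------------------------------------
  blues <- compute_blues(clean, method = config$blue_method)
  # EB to reporting units (1e-5 voxels), applied exactly once
  eb_rows <- blues$trait == "EB"
  blues$blue[eb_rows] <- blues$blue[eb_rows] * config$eb_report_scale
  blues$se[eb_rows] <- blues$se[eb_rows] * config$eb_report_scale
  note("blues", sprintf("%d genotype x DAT x treatment estimates",
                        nrow(blues)))

  # 4. derived traits ------------------------------------------------------
  eb_blues <- blues[blues$trait == "EB", , drop = FALSE]
  panel_series <- dplyr::summarise(
    dplyr::group_by(eb_blues, .data$treatment, .data$dat),
    value = mean(.data$blue, na.rm = TRUE), .groups = "drop")
  rgr_tab <- dplyr::bind_rows(lapply(split(panel_series,
                                           panel_series$treatment),
                                     function(s) {
    s <- s[order(s$dat), ]
    filled <- interpolate_missing(
      tibble::tibble(dat = s$dat, value = s$value),
      setdiff(seq(min(s$dat), max(s$dat)), s$dat))
    r <- rgr(filled)
    r$treatment <- s$treatment[1]
    r
  }))

  key_eb <- eb_blues[eb_blues$dat %in% config$key_dats, , drop = FALSE]
  panel_key <- dplyr::summarise(
    dplyr::group_by(key_eb, .data$treatment, .data$dat),
    value = mean(.data$blue, na.rm = TRUE), .groups = "drop")
  wide_key <- tidyr::pivot_wider(panel_key, names_from = "treatment",
                                 values_from = "value")
  loss_tab <- tibble::tibble(
    trait = "EB", dat = wide_key$dat,
    loss = loss_percent(wide_key$drought, wide_key$control))

  wue_tab <- dplyr::bind_rows(lapply(config$wue_phases, function(ph) {
    phase_wue(eb_blues, watering, ph, timeline = tl, flags = flags)
  }))

  cv_tab <- dplyr::summarise(
    dplyr::group_by(blues, .data$trait, .data$treatment, .data$dat),
    cv = cv_percent(.data$blue), .groups = "drop")
  note("derived", sprintf("%d RGR intervals, %d WUE rows",
                          nrow(rgr_tab), nrow(wue_tab)))

  # 5. panel analysis ------------------------------------------------------
  eb_dev <- panel_deviation(key_eb, "blue")
  wue_dev <- panel_deviation(
    dplyr::rename(wue_tab, value = "wue"), "value")
  selection <- select_superior(eb_dev, wue_dev,
                               key_dats = config$key_dats,
                               phases = config$wue_phases)
  note("selection", sprintf("%d better than mean, %d superior",
                            length(selection$tier1),
                            length(selection$tier2)))
  group_stats <- NULL
  if (!is.null(meta)) {
    meta <- genotype_meta(meta)
    dev28 <- eb_dev[eb_dev$dat == config$key_dats[1] &
                      eb_dev$treatment == "drought", , drop = FALSE]
    m <- dplyr::left_join(dev28, meta, by = "genotype")
    group_stats <- list(
      chickpea_type = group_compare(m$deviation, m$chickpea_type),
      biological_status = group_compare(m$deviation, m$biological_status))
  }

  result <- structure(
    list(flags = flags, traits_clean = clean, heritability = h2,
         blues = blues, rgr = rgr_tab, loss = loss_tab, wue = wue_tab,
         cv = cv_tab, deviations = list(eb = eb_dev, wue = wue_dev),
         selection = selection, group_stats = group_stats, log = log),
    class = "pd_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(flags, file.path(out_dir, "outliers.csv"),
                     row.names = FALSE)
    utils::write.csv(h2, file.path(out_dir, "heritability.csv"),
                     row.names = FALSE)
    utils::write.csv(blues, file.path(out_dir, "blues.csv"),
                     row.names = FALSE)
    utils::write.csv(rgr_tab, file.path(out_dir, "rgr.csv"),
                     row.names = FALSE)
    utils::write.csv(loss_tab, file.path(out_dir, "loss.csv"),
                     row.names = FALSE)
    utils::write.csv(wue_tab, file.path(out_dir, "wue.csv"),
                     row.names = FALSE)
    utils::write.csv(cv_tab, file.path(out_dir, "cv.csv"),
                     row.names = FALSE)
    rank <- data.frame(genotype = rownames(selection$matrix),
                       selection$matrix,
                       tier1 = rownames(selection$matrix) %in%
                         selection$tier1,
                       tier2 = rownames(selection$matrix) %in%
                         selection$tier2)
    utils::write.csv(rank, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
print.pd_pipeline_result <- function(x, ...) {
  cat("<pd_pipeline_result>\n")
  for (stage in names(x$log)) cat(" ", stage, ":", x$log[[stage]], "\n")
  invisible(x)
}

#' Extract traits from a directory of multi-view PNG image sets
#'
#' Runs segmentation and trait extraction on every
#' `<plant_id>_dat<NN>_*.png` quadruple found in `dir` and returns the
#' long-format trait table rows (EB, PH, MCV, r2g, y2g). Plant ids of the
#' form `genotype_experiment_replicate_treatment` are parsed into the
#' design columns.
#'
#' @param dir Image directory.
#' @param config A [default_config()] list.
#' @param mm_per_pixel Side-camera scale.
#' @return A long trait tibble.
#' @export
extract_image_dir <- function(dir, config = default_config(),
                              mm_per_pixel = 1) {
  files <- list.files(dir, pattern = "_top\\.png$")
  if (!length(files)) stop("no *_top.png images in ", dir, call. = FALSE)
  bg <- background_model(config$segmentation$sat_max,
                         config$segmentation$value_min)
  rows <- lapply(files, function(f) {
    stem <- sub("_top\\.png$", "", f)
    dat <- as.integer(sub(".*_dat(\\d+)$", "\\1", stem))
    plant_id <- sub("_dat\\d+$", "", stem)
    imgset <- read_image_set(dir, plant_id, dat,
                             mm_per_pixel_side = mm_per_pixel,
                             mm_per_pixel_top = mm_per_pixel)
    tr <- extract_image_traits(imgset, background = bg,
                               classes = config$hue_classes,
                               ratio_mode = config$ratio_mode,
                               mcv_method = config$mcv_method)
    parts <- strsplit(plant_id, "_", fixed = TRUE)[[1]]
    meta <- if (length(parts) == 4) parts else rep(NA_character_, 4)
    tibble::tibble(
      genotype = meta[1], experiment = meta[2], replicate = meta[3],
      treatment = meta[4], dat = dat,
      trait = c("EB", "PH", "MCV", "r2g", "y2g"),
      value = c(tr$eb, tr$ph, tr$mcv, tr$r2g, tr$y2g))
  })
  dplyr::bind_rows(rows)
}
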
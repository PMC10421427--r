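#' Linearly interpolate missing DATs in a BLUE series
#'
#' Fills the requested DATs by linear interpolation on the value scale
#' between the nearest present neighbours; filled points are flagged.
#' A requested DAT without both flanking neighbours is an error.
#'
#' @param series Tibble with columns `dat` (strictly increasing) and
#'   `value` (additional columns are carried through).
#' @param dats_to_fill Integer DATs to fill. Already-present DATs are left
#'   unchanged (idempotence).
#' @return The series with filled rows inserted and a logical
#'   `interpolated` column.
#' @export
#' @examples
#' s <- tibble::tibble(dat = c(13, 15), value = c(2, 4))
#' interpolate_missing(s, 14)$value # 2 3 4
interpolate_missing <- function(series, dats_to_fill) {
  stopifnot(all(diff(series$dat) > 0), all(is.finite(series$value)))
  if (!"interpolated" %in% names(series)) series$interpolated <- FALSE
  fill <- setdiff(as.integer(dats_to_fill), series$dat)
  for (d in fill) {
    lo <- max(series$dat[series$dat < d], -Inf)
    hi <- min(series$dat[series$dat > d], Inf)
    if (!is.finite(lo) || !is.finite(hi)) {
      stop("cannot interpolate DAT ", d, ": missing flanking value",
           call. = FALSE)
    }
    v <- stats::approx(series$dat, series$value, xout = d)$y
    row <- series[1, ]
    row$dat <- d; row$value <- v; row$interpolated <- TRUE
    series <- dplyr::bind_rows(series, row)
  }
  series[order(series$dat), , drop = FALSE]
}

#' Relative growth rate of a biovolume series
#'
#' `RGR_i = (ln v_i - ln v_(i-1)) / (dat_i - dat_(i-1))` for consecutive
#' points; an interval with a non-positive value yields a missing RGR with
#' a warning. RGR can be negative under shrinkage.
#'
#' @param series Tibble with `dat` (strictly increasing) and positive
#'   `value`.
#' @return Tibble with `dat` (the interval's right endpoint) and `rgr`
#'   (per day).
#' @export
#' @examples
#' s <- tibble::tibble(dat = 1:4, value = c(1, 2, 4, 8))
#' rgr(s)$rgr # ln 2 at every step
rgr <- function(series) {
  stopifnot(all(diff(series$dat) > 0))
  v <- series$value
  ok <- v > 0 & is.finite(v)
  if (any(!ok)) {
    warning("non-positive values: RGR missing for affected intervals",
            call. = FALSE)
  }
  lv <- ifelse(ok, log(v), NA_real_)
  tibble::tibble(
    dat = series$dat[-1],
    rgr = diff(lv) / diff(series$dat)
  )
}

#' Percent loss of a trait under drought
#'
#' `(1 - drought / control) * 100`; negative when the stressed value
#' exceeds the control (as for stress-indicator colour ratios).
#'
#' @param trait_drought,trait_control Trait values (vectorised).
#' @return Loss in percent; `NA` with a warning where the control is 0.
#' @export
#' @examples
#' loss_percent(18.5, 85.1) # ~78% biovolume loss
#' loss_percent(0.013, 0.005) # -160%
loss_percent <- function(trait_drought, trait_control) {
  out <- (1 - trait_drought / trait_control) * 100
  bad <- trait_control == 0
  if (any(bad, na.rm = TRUE)) {
    warning("control value 0: loss undefined", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Water-use efficiency over a drought phase
#'
#' The biovolume gained between the first and last DAT of the phase
#' (BLUE scale) divided by the irrigation water summed over the phase.
#' Water is first cleaned of outlier-linked rows, averaged per genotype
#' and DAT across replicate plants, then summed; a phase sum of zero
#' milliliters is replaced by 1 mL. Endpoint BLUEs missing from the series
#' are linearly interpolated when flanked, otherwise the genotype is
#' returned as missing with a flag.
#'
#' @param eb_blues BLUE series of EB: tibble with `genotype`, `treatment`,
#'   `dat`, `blue` (one trait, possibly many genotypes).
#' @param watering Watering table with `genotype`, `treatment`, `dat`,
#'   `water_added` (plant-level rows; replicate plants are averaged).
#' @param phase Phase name (`"DT"`, `"DR"`, `"DA"`) or a one-row window
#'   from [phase_windows()].
#' @param timeline A `pd_timeline`.
#' @param flags Optional [detect_outliers()] table; watering rows of
#'   flagged EB observations (matched by genotype/experiment/replicate/
#'   treatment/DAT) are dropped before averaging.
#' @return Tibble with one row per genotype x treatment: `delta_eb`,
#'   `water_sum`, `wue`, and a `complete` flag.
#' @export
phase_wue <- function(eb_blues, watering, phase,
                      timeline = default_timeline(), flags = NULL) {
  pw <- phase_windows(timeline)
  if (is.character(phase)) {
    stopifnot(phase %in% pw$phase)
    win <- pw[pw$phase == phase, ]
  } else {
    win <- phase
  }
  start <- win$start_dat[1]; end <- win$end_dat[1]
  phase_name <- if (is.character(phase)) phase else win$phase[1]

  if (!is.null(flags)) {
    bad <- flags[flags$flagged & flags$trait == "EB", , drop = FALSE]
    if (nrow(bad)) {
      key <- function(d) paste(d$genotype, d$experiment, d$replicate,
                               d$treatment, d$dat)
      watering <- watering[!(key(watering) %in% key(bad)), , drop = FALSE]
    }
  }
  water <- dplyr::summarise(
    dplyr::group_by(watering, .data$genotype, .data$treatment, .data$dat),
    water_added = mean(.data$water_added), .groups = "drop")
  water <- water[water$dat >= start & water$dat <= end, , drop = FALSE]
  wsum <- dplyr::summarise(
    dplyr::group_by(water, .data$genotype, .data$treatment),
    water_sum = sum(.data$water_added), .groups = "drop")

  ends <- lapply(
    split(eb_blues, list(eb_blues$genotype, eb_blues$treatment),
          drop = TRUE),
    function(s) {
      s <- s[order(s$dat), c("genotype", "treatment", "dat", "blue")]
      series <- tibble::tibble(dat = s$dat, value = s$blue)
      filled <- try(interpolate_missing(series, c(start, end)),
                    silent = TRUE)
      if (inherits(filled, "try-error")) {
        return(tibble::tibble(genotype = s$genotype[1],
                              treatment = s$treatment[1],
                              delta_eb = NA_real_, complete = FALSE))
      }
      tibble::tibble(
        genotype = s$genotype[1], treatment = s$treatment[1],
        delta_eb = filled$value[filled$dat == end] -
          filled$value[filled$dat == start],
        complete = TRUE)
    })
  delta <- dplyr::bind_rows(ends)
  out <- dplyr::left_join(delta, wsum, by = c("genotype", "treatment"))
  out$water_sum[is.na(out$water_sum)] <- 0
  out$water_sum_used <- ifelse(out$water_sum == 0, 1, out$water_sum)
  out$wue <- out$delta_eb / out$water_sum_used
  out$phase <- phase_name
  out[, c("genotype", "treatment", "phase", "delta_eb", "water_sum",
          "water_sum_used", "wue", "complete")]
}

#' Coefficient of variation, in percent
#'
#' Sample standard deviation over the mean, times 100. Uses the n-1
#' denominator.
#'
#' @param values Numeric vector (n >= 2; missing values dropped).
#' @return CV in percent; `NA` when the mean is 0.
#' @export
#' @examples
#' cv_percent(c(2, 4)) # 47.14%
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Photosystem-II plasticity ratio
#'
#' The operating efficiency under low light divided by the operating
#' efficiency under high light; a measure of PSII plasticity to
#' fluctuating light.
#'
#' @param phi_l,phi_h Operating efficiencies (vectorised).
#' @return `phi_l / phi_h`; `NA` where `phi_h` is 0.
#' @export
phi_psii_ratio <- function(phi_l, phi_h) {
  out <- phi_l / phi_h
  out[!is.na(phi_h) & phi_h == 0] <- NA_real_
  out
}
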
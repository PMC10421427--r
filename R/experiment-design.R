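#' Experiment timeline for a drought/recovery phenotyping trial
#'
#' Encodes the day-after-transfer (DAT) schedule shared by the simulator and
#' the analysis: when drought starts, when the two-step re-watering happens,
#' on which days chlorophyll-fluorescence imaging took place, and which DATs
#' are excluded per experiment because of incomplete imaging.
#'
#' @param first_dat First imaging day (DAT).
#' @param last_dat Last imaging day (DAT).
#' @param drought_start First DAT of the 10% PAW drought regime.
#' @param rewater_step1 DAT of the fixed-volume first re-watering step.
#' @param rewater_step2 DAT from which drought pots return to the control
#'   PAW target.
#' @param fluorcam_dats Integer DATs with photosystem-II measurements.
#' @param excluded_dats Named list mapping experiment id (e.g. `"E1"`) to the
#'   integer DATs excluded from analysis for that experiment.
#'
#' @return An object of class `pd_timeline`.
#' @export
#' @examples
#' tl <- default_timeline()
#' tl$drought_start
default_timeline <- function(first_dat = 1L,
                             last_dat = 42L,
                             drought_start = 8L,
                             rewater_step1 = 29L,
                             rewater_step2 = 30L,
                             fluorcam_dats = c(6L, 13L, 20L, 27L, 34L),
                             excluded_dats = list(E1 = 1L, E2 = 14L)) {
  tl <- structure(
    list(
      first_dat = as.integer(first_dat),
      last_dat = as.integer(last_dat),
      drought_start = as.integer(drought_start),
      rewater_step1 = as.integer(rewater_step1),
      rewater_step2 = as.integer(rewater_step2),
      fluorcam_dats = sort(as.integer(fluorcam_dats)),
      excluded_dats = lapply(excluded_dats, as.integer)
    ),
    class = "pd_timeline"
  )
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  stopifnot(inherits(tl, "pd_timeline"))
  with(tl, {
    if (!(drought_start < rewater_step1 && rewater_step1 < rewater_step2 &&
          rewater_step2 <= last_dat)) {
      stop("timeline must satisfy drought_start < rewater_step1 < ",
           "rewater_step2 <= last_dat", call. = FALSE)
    }
    if (any(fluorcam_dats < first_dat | fluorcam_dats > last_dat)) {
      stop("fluorcam_dats must lie within [first_dat, last_dat]", call. = FALSE)
    }
  })
  invisible(tl)
}

#' @export
print.pd_timeline <- function(x, ...) {
  cat("<pd_timeline> DAT", x$first_dat, "-", x$last_dat,
      "| drought from DAT", x$drought_start,
      "| re-watering DAT", x$rewater_step1, "(+300 mL) /", x$rewater_step2,
      "\n  fluorcam DATs:", paste(x$fluorcam_dats, collapse = ", "), "\n")
  invisible(x)
}

#' Phase windows of the drought experiment
#'
#' The analysis divides the timeline into an establishment window and three
#' drought phases: drought tolerance (DT, the stress period), drought
#' recovery (DR, after re-watering) and drought adaptability (DA, stress and
#' recovery combined). DT and DR partition DA.
#'
#' @param timeline A `pd_timeline`.
#' @return A tibble with columns `phase`, `start_dat`, `end_dat`.
#' @export
#' @examples
#' phase_windows()
phase_windows <- function(timeline = default_timeline()) {
  validate_timeline(timeline)
  tibble::tibble(
    phase = c("establishment", "DT", "DR", "DA"),
    start_dat = c(2L, timeline$drought_start, timeline$rewater_step1,
                  timeline$drought_start),
    end_dat = c(timeline$drought_start - 1L, timeline$rewater_step1 - 1L,
                timeline$last_dat, timeline$last_dat)
  )
}

#' Phases containing a DAT
#'
#' @param dat Integer vector of DATs in `[2, last_dat]` (DAT 1 belongs to no
#'   phase and returns an empty set).
#' @param timeline A `pd_timeline`.
#' @return A list (one element per `dat`) of character vectors of phase names;
#'   unlisted to a single character vector when `length(dat) == 1`.
#' @export
#' @examples
#' phase_of(20) # DT and DA overlap
phase_of <- function(dat, timeline = default_timeline()) {
  pw <- phase_windows(timeline)
  if (any(dat < 1 | dat > timeline$last_dat)) {
    stop("dat outside timeline [", timeline$first_dat, ", ",
         timeline$last_dat, "]", call. = FALSE)
  }
  out <- lapply(as.integer(dat), function(d) {
    pw$phase[pw$start_dat <= d & d <= pw$end_dat]
  })
  if (length(dat) == 1L) out[[1]] else out
}

#' Pot calibration for the plant-available-water scale
#'
#' A two-point linear calibration: the pot weight at substrate field capacity
#' maps to 100% PAW, the weight at the permanent wilting point to 0% PAW.
#'
#' @param weight_at_field_capacity Pot weight (g) at field capacity.
#' @param weight_at_wilting_point Pot weight (g) at wilting point.
#' @param dry_system_weight Weight (g) of pot + dry substrate + support.
#' @return An object of class `pd_pot_calibration`.
#' @export
pot_calibration <- function(weight_at_field_capacity,
                            weight_at_wilting_point,
                            dry_system_weight = weight_at_wilting_point) {
  w <- c(weight_at_field_capacity, weight_at_wilting_point, dry_system_weight)
  if (any(!is.finite(w))) {
    stop("calibration weights must be finite", call. = FALSE)
  }
  if (!(weight_at_wilting_point < weight_at_field_capacity)) {
    stop("weight_at_wilting_point must be below weight_at_field_capacity",
         call. = FALSE)
  }
  structure(
    list(
      weight_at_field_capacity = weight_at_field_capacity,
      weight_at_wilting_point = weight_at_wilting_point,
      dry_system_weight = dry_system_weight
    ),
    class = "pd_pot_calibration"
  )
}

#' Default pot calibration used by the simulator
#'
#' 1 mL of irrigation equals 1 g of pot weight; the usable water range
#' (field capacity minus wilting point) defaults to 1000 g for a ~3 L pot.
#'
#' @return A `pd_pot_calibration`.
#' @export
default_pot_calibration <- function() {
  pot_calibration(
    weight_at_field_capacity = 2500,
    weight_at_wilting_point = 1500,
    dry_system_weight = 1400
  )
}

#' Plant-available water from pot weight
#'
#' Linear two-point scale: 100 * (weight - wilting) / (field capacity -
#' wilting), clamped to `[0, 100]`.
#'
#' @param weight_before Pot weight (g) before watering; vectorised.
#' @param cal A [pot_calibration()].
#' @return PAW percentages in `[0, 100]`.
#' @export
#' @examples
#' cal <- default_pot_calibration()
#' paw_from_weight(cal$weight_at_field_capacity, cal) # 100
paw_from_weight <- function(weight_before, cal) {
  stopifnot(inherits(cal, "pd_pot_calibration"))
  if (any(!is.finite(weight_before))) {
    stop("weight_before must be finite", call. = FALSE)
  }
  paw <- 100 * (weight_before - cal$weight_at_wilting_point) /
    (cal$weight_at_field_capacity - cal$weight_at_wilting_point)
  pmin(100, pmax(0, paw))
}

#' Irrigation target for a DAT and treatment
#'
#' Control pots are held at 70% PAW throughout. Drought pots are held at
#' 70% until the day before drought initiation, at 10% during the stress
#' period, receive a fixed 300 mL on the first re-watering day, and return to
#' 70% afterwards.
#'
#' @param dat Integer DAT (scalar).
#' @param treatment `"control"` or `"drought"`.
#' @param timeline A `pd_timeline`.
#' @return A list with `type` (`"paw"` or `"volume"`) and `value`
#'   (percent PAW, or mL for the fixed-volume step).
#' @export
#' @examples
#' target_paw(15, "drought") # 10% PAW
#' target_paw(29, "drought") # fixed 300 mL
target_paw <- function(dat, treatment = c("control", "drought"),
                       timeline = default_timeline()) {
  treatment <- match.arg(treatment)
  validate_timeline(timeline)
  stopifnot(length(dat) == 1L)
  dat <- as.integer(dat)
  if (dat < timeline$first_dat || dat > timeline$last_dat) {
    stop("dat ", dat, " outside timeline", call. = FALSE)
  }
  if (treatment == "control") {
    return(list(type = "paw", value = 70))
  }
  if (dat < timeline$drought_start) {
    list(type = "paw", value = 70)
  } else if (dat < timeline$rewater_step1) {
    list(type = "paw", value = 10)
  } else if (dat == timeline$rewater_step1) {
    list(type = "volume", value = 300)
  } else {
    list(type = "paw", value = 70)
  }
}

#' Watering amount implied by a target and the current pot weight
#'
#' Water is only ever added (a balance-watering station cannot remove it):
#' for a PAW target the amount raises the pot exactly to the target weight,
#' or zero if the pot already is at or above it; for a fixed-volume step the
#' amount is the volume itself. 1 mL is treated as 1 g.
#'
#' @param weight_before Pot weight (g) before watering.
#' @param target A target as returned by [target_paw()].
#' @param cal A [pot_calibration()].
#' @return Water to add, in mL (>= 0).
#' @export
water_to_target <- function(weight_before, target, cal) {
  stopifnot(inherits(cal, "pd_pot_calibration"))
  if (identical(target$type, "volume")) {
    return(rep(target$value, length(weight_before)))
  }
  target_weight <- cal$weight_at_wilting_point +
    target$value / 100 *
      (cal$weight_at_field_capacity - cal$weight_at_wilting_point)
  pmax(0, target_weight - weight_before)
}

#' Validate a watering-record table
#'
#' Checks the long-format irrigation log: non-negative additions, weight
#' after watering at least the weight before, and the 1 mL = 1 g consistency
#' between the two weights and the logged volume.
#'
#' @param watering A data frame with columns `plant_id`, `dat`,
#'   `weight_before`, `weight_after`, `water_added`.
#' @param tol Tolerance (g) for the weight/volume consistency check.
#' @return The table, invisibly; errors on violation.
#' @export
validate_watering <- function(watering, tol = 1e-6) {
  need <- c("plant_id", "dat", "weight_before", "weight_after", "water_added")
  miss <- setdiff(need, names(watering))
  if (length(miss)) {
    stop("watering table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(watering$water_added < 0)) {
    stop("water_added must be non-negative", call. = FALSE)
  }
  if (any(watering$weight_after < watering$weight_before - tol)) {
    stop("weight_after must be >= weight_before", call. = FALSE)
  }
  dev <- abs(watering$weight_after - watering$weight_before -
               watering$water_added)
  if (any(dev > pmax(tol, 0.01 * pmax(1, watering$water_added)))) {
    stop("water_added inconsistent with weight change (1 mL = 1 g)",
         call. = FALSE)
  }
  invisible(watering)
}
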
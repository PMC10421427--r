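#' Multi-view image set for one plant on one imaging day
#'
#' One top view and exactly three side views, as RGB arrays (height x width
#' x 3, values in `[0, 1]` as returned by [png::readPNG()]), plus the
#' mm-per-pixel scale of each camera.
#'
#' @param top RGB array for the top view.
#' @param sides List of exactly three RGB arrays (side views).
#' @param mm_per_pixel_side,mm_per_pixel_top Physical scale of the cameras.
#' @param plant_id,dat Identity of the imaged plant and the imaging day.
#' @return An object of class `pd_image_set`.
#' @export
image_set <- function(top, sides, mm_per_pixel_side = 1, mm_per_pixel_top = 1,
                      plant_id = NA_character_, dat = NA_integer_) {
  check_rgb <- function(x, what) {
    if (!(is.array(x) && length(dim(x)) == 3 && dim(x)[3] >= 3 &&
          all(dim(x)[1:2] > 0))) {
      stop(what, " must be a non-empty height x width x 3 RGB array",
           call. = FALSE)
    }
    if (min(x) < 0 || max(x) > 1) {
      stop(what, " channel values must lie in [0, 1]", call. = FALSE)
    }
  }
  check_rgb(top, "top view")
  if (!(is.list(sides) && length(sides) == 3L)) {
    stop("exactly three side views are required", call. = FALSE)
  }
  for (i in 1:3) check_rgb(sides[[i]], paste0("side view ", i))
  structure(
    list(top = top, sides = sides,
         mm_per_pixel_side = mm_per_pixel_side,
         mm_per_pixel_top = mm_per_pixel_top,
         plant_id = plant_id, dat = as.integer(dat)),
    class = "pd_image_set"
  )
}

#' @export
print.pd_image_set <- function(x, ...) {
  cat("<pd_image_set>", x$plant_id, "DAT", x$dat,
      "| top", paste(dim(x$top)[1:2], collapse = "x"),
      "| 3 side views", paste(dim(x$sides[[1]])[1:2], collapse = "x"), "\n")
  invisible(x)
}

#' Background model for HSV segmentation
#'
#' The synthetic renders (and typical imaging chambers) use a low-saturation
#' backdrop; plant pixels are saturated and bright. A pixel is foreground
#' when its saturation exceeds `sat_max` and its value exceeds `value_min`.
#'
#' @param sat_max Maximum background saturation (plant pixels exceed it).
#' @param value_min Minimum plant brightness (darker pixels are background).
#' @return An object of class `pd_background_model`.
#' @export
background_model <- function(sat_max = 0.25, value_min = 0.05) {
  structure(list(sat_max = sat_max, value_min = value_min),
            class = "pd_background_model")
}

#' HSV channels of an RGB array
#'
#' @param image RGB array with values in `[0, 1]`.
#' @return List of matrices `h`, `s`, `v` (hue, saturation, value in
#'   `[0, 1]`), each with the image's height x width dimensions.
#' @keywords internal
image_hsv <- function(image) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Segment the plant from one view
#'
#' HSV thresholding against a uniform low-saturation background; a fully
#' background image yields an empty mask (not an error). Optionally only the
#' largest connected foreground component is retained (requires EBImage).
#'
#' @param image RGB array with values in `[0, 1]`.
#' @param background A [background_model()].
#' @param keep_largest Retain only the largest 8-connected component.
#' @return An object of class `pd_plant_mask`: a logical matrix with
#'   attribute `pixel_count`.
#' @export
segment_plant <- function(image, background = background_model(),
                          keep_largest = FALSE) {
  stopifnot(inherits(background, "pd_background_model"))
  hsv <- image_hsv(image)
  mask <- hsv$s > background$sat_max & hsv$v > background$value_min
  if (keep_largest && any(mask)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("keep_largest = TRUE requires the EBImage package", call. = FALSE)
    }
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  plant_mask(mask)
}

plant_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(mask, pixel_count = sum(mask), class = c("pd_plant_mask", "matrix"))
}

#' Foreground pixel count of a mask
#' @param mask A `pd_plant_mask` (or logical matrix).
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) {
  pc <- attr(mask, "pixel_count")
  if (is.null(pc)) sum(mask) else pc
}

#' Estimated biovolume from one top and three side silhouettes
#'
#' With `s` the mean of the three side-view silhouette areas and `t` the
#' top-view area (both in pixels), the biovolume proxy is
#' `EB = sqrt(s^2 * t) = s * sqrt(t)` voxels. Reporting conventionally
#' rescales EB by 1e-5 once, at the reporting layer (see [scale_eb()]).
#'
#' @param top_mask Top-view `pd_plant_mask`.
#' @param side_masks List of three side-view masks.
#' @return EB in voxels; 0 (with a warning) if any silhouette is empty.
#' @export
#' @examples
#' m <- function(n) structure(matrix(TRUE, 1, n), pixel_count = n,
#'                            class = c("pd_plant_mask", "matrix"))
#' compute_eb(m(100), list(m(100), m(100), m(100))) # 1000
compute_eb <- function(top_mask, side_masks) {
  stopifnot(length(side_masks) == 3L)
  t_area <- mask_area(top_mask)
  s_areas <- vapply(side_masks, mask_area, numeric(1))
  if (t_area == 0 || any(s_areas == 0)) {
    warning("empty silhouette: EB set to 0", call. = FALSE)
    return(0)
  }
  mean(s_areas) * sqrt(t_area)
}

#' Plant height from the side-view silhouettes
#'
#' The vertical foreground extent (`max_row - min_row + 1`) of each side
#' view, converted to mm; across the three views the maximum is returned
#' (a plant's height is its tallest silhouette). Empty masks give 0.
#'
#' @param side_masks List of side-view masks (a single mask is accepted).
#' @param mm_per_pixel Side-camera scale in mm/pixel.
#' @return Height in mm.
#' @export
compute_ph <- function(side_masks, mm_per_pixel = 1) {
  if (inherits(side_masks, "pd_plant_mask")) side_masks <- list(side_masks)
  extent <- vapply(side_masks, function(m) {
    rows <- which(rowSums(m) > 0)
    if (!length(rows)) 0 else diff(range(rows)) + 1
  }, numeric(1))
  max(extent) * mm_per_pixel
}

#' Hue class boundaries for colour-ratio traits
#'
#' Hue intervals (degrees on the 0--360 circle) defining the red, yellow and
#' green pixel classes. Red wraps around 0.
#'
#' @param red,yellow,green Two-column matrices or numeric vectors of
#'   `[lower, upper)` bounds in degrees; `red` may contain two rows for the
#'   wrap-around.
#' @return An object of class `pd_hue_classes`.
#' @export
hue_classes <- function(red = rbind(c(0, 30), c(330, 360)),
                        yellow = c(30, 75),
                        green = c(75, 165)) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 2)
  structure(list(red = as_mat(red), yellow = as_mat(yellow),
                 green = as_mat(green)),
            class = "pd_hue_classes")
}

classify_hue <- function(hue_deg, classes) {
  in_ranges <- function(ranges) {
    hit <- rep(FALSE, length(hue_deg))
    for (i in seq_len(nrow(ranges))) {
      hit <- hit | (hue_deg >= ranges[i, 1] & hue_deg < ranges[i, 2])
    }
    hit
  }
  out <- rep(NA_character_, length(hue_deg))
  out[in_ranges(classes$red)] <- "red"
  out[in_ranges(classes$yellow)] <- "yellow"
  out[in_ranges(classes$green)] <- "green"
  out
}

#' Colour traits of the top-view plant pixels
#'
#' Converts the masked plant pixels to HSV hue in `[0, 1]`, excluding
#' grayscale pixels whose hue is undefined (saturation 0). Returns the mean
#' hue (MCV; ~0.23 for a healthy green canopy), a 20-bin hue histogram, the
#' red/yellow/green pixel counts under [hue_classes()], and the
#' red-to-green and yellow-to-green ratios.
#'
#' @param top_image RGB array of the top view.
#' @param top_mask `pd_plant_mask` for the same view.
#' @param classes A [hue_classes()] specification.
#' @param ratio_mode `"to_green"` (counts divided by the green count, the
#'   default) or `"of_total"` (fractions of all plant pixels).
#' @param mcv_method `"pixel"` (mean hue over plant pixels, the default) or
#'   `"histogram"` (bin centres weighted by bin counts).
#' @param n_bins Number of histogram bins over hue `[0, 1]`.
#' @return A list with `mcv`, `hue_histogram`, `n_red`, `n_yellow`,
#'   `n_green`, `r2g`, `y2g`. Ratios are `NA` (with a warning) when the
#'   green count is zero in `"to_green"` mode.
#' @export
compute_color_traits <- function(top_image, top_mask,
                                 classes = hue_classes(),
                                 ratio_mode = c("to_green", "of_total"),
                                 mcv_method = c("pixel", "histogram"),
                                 n_bins = 20L) {
  ratio_mode <- match.arg(ratio_mode)
  mcv_method <- match.arg(mcv_method)
  hsv <- image_hsv(top_image)
  sel <- as.logical(top_mask) & hsv$s > 0
  hue <- hsv$h[sel]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  if (!length(hue)) {
    return(list(mcv = NA_real_, hue_histogram = rep(0, n_bins),
                n_red = 0L, n_yellow = 0L, n_green = 0L,
                r2g = NA_real_, y2g = NA_real_))
  }
  counts <- hist(hue, breaks = breaks, plot = FALSE, right = FALSE)$counts
  hist_frac <- counts / length(hue)
  mcv <- if (mcv_method == "pixel") {
    mean(hue)
  } else {
    centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
    sum(centres * hist_frac)
  }
  cls <- classify_hue(hue * 360, classes)
  n_red <- sum(cls == "red", na.rm = TRUE)
  n_yellow <- sum(cls == "yellow", na.rm = TRUE)
  n_green <- sum(cls == "green", na.rm = TRUE)
  if (ratio_mode == "to_green") {
    if (n_green == 0) {
      warning("no green pixels: r2g/y2g undefined", call. = FALSE)
      r2g <- y2g <- NA_real_
    } else {
      r2g <- n_red / n_green
      y2g <- n_yellow / n_green
    }
  } else {
    r2g <- n_red / length(hue)
    y2g <- n_yellow / length(hue)
  }
  list(mcv = mcv, hue_histogram = hist_frac,
       n_red = n_red, n_yellow = n_yellow, n_green = n_green,
       r2g = r2g, y2g = y2g)
}

#' Extract all image-derived traits from a multi-view image set
#'
#' Segments each view and computes EB (voxels), PH (mm), MCV, r2g and y2g.
#'
#' @param imgset A [image_set()].
#' @param background A [background_model()].
#' @param classes A [hue_classes()] specification.
#' @param ... Passed to [compute_color_traits()].
#' @return A one-row tibble with the five traits plus per-view areas.
#' @export
extract_image_traits <- function(imgset, background = background_model(),
                                 classes = hue_classes(), ...) {
  stopifnot(inherits(imgset, "pd_image_set"))
  top_mask <- segment_plant(imgset$top, background)
  side_masks <- lapply(imgset$sides, segment_plant, background = background)
  eb <- compute_eb(top_mask, side_masks)
  ph <- compute_ph(side_masks, imgset$mm_per_pixel_side)
  col <- compute_color_traits(imgset$top, top_mask, classes = classes, ...)
  tibble::tibble(
    plant_id = imgset$plant_id, dat = imgset$dat,
    eb = eb, ph = ph, mcv = col$mcv, r2g = col$r2g, y2g = col$y2g,
    top_area = mask_area(top_mask),
    side_area_1 = mask_area(side_masks[[1]]),
    side_area_2 = mask_area(side_masks[[2]]),
    side_area_3 = mask_area(side_masks[[3]])
  )
}

#' Rescale estimated biovolume to reporting units
#'
#' EB is reported on a 1e-5 voxel scale (e.g. a raw biovolume of 8.51e6
#' voxels prints as 85.1). Apply exactly once, at the reporting layer.
#'
#' @param eb Raw EB in voxels.
#' @return EB in 1e-5 voxel units.
#' @export
scale_eb <- function(eb) eb * 1e-5

#' Read or write a multi-view image set as PNG files
#'
#' Files follow the naming convention `<plant_id>_dat<NN>_{top|side1|side2|
#' side3}.png` (8-bit RGB).
#'
#' @param dir Directory holding (or receiving) the PNG files.
#' @param plant_id,dat Plant identity and imaging day.
#' @param mm_per_pixel_side,mm_per_pixel_top Camera scales for the returned
#'   [image_set()].
#' @return `read_image_set()` returns a `pd_image_set`; `write_image_set()`
#'   returns the written file paths invisibly.
#' @export
read_image_set <- function(dir, plant_id, dat,
                           mm_per_pixel_side = 1, mm_per_pixel_top = 1) {
  stem <- file.path(dir, sprintf("%s_dat%02d", plant_id, as.integer(dat)))
  read_one <- function(suffix) {
    path <- paste0(stem, "_", suffix, ".png")
    if (!file.exists(path)) stop("missing image: ", path, call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  }
  image_set(read_one("top"),
            lapply(paste0("side", 1:3), read_one),
            mm_per_pixel_side = mm_per_pixel_side,
            mm_per_pixel_top = mm_per_pixel_top,
            plant_id = plant_id, dat = dat)
}

#' @rdname read_image_set
#' @param imgset A `pd_image_set` to write.
#' @export
write_image_set <- function(imgset, dir) {
  stopifnot(inherits(imgset, "pd_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_dat%02d", imgset$plant_id, imgset$dat))
  paths <- paste0(stem, "_", c("top", paste0("side", 1:3)), ".png")
  png::writePNG(imgset$top, paths[1])
  for (i in 1:3) png::writePNG(imgset$sides[[i]], paths[i + 1])
  invisible(paths)
}
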
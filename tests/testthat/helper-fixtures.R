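# shared fixtures: tiny balanced slices and toy BLUE/watering tables

make_slice <- function(values,
                       n_exp = 2, n_rep = 2,
                       genotypes = NULL, dat = 1L,
                       treatment = "control", trait = "EB") {
  n_geno <- length(values) / (n_exp * n_rep)
  stopifnot(n_geno == round(n_geno))
  if (is.null(genotypes)) genotypes <- sprintf("G%03d", seq_len(n_geno))
  grid <- expand.grid(genotype = genotypes,
                      experiment = sprintf("E%d", seq_len(n_exp)),
                      replicate = sprintf("R%d", seq_len(n_rep)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(
    genotype = grid$genotype, experiment = grid$experiment,
    replicate = grid$replicate, treatment = treatment,
    dat = as.integer(dat), trait = trait, value = values
  )
}

# a plant mask of known pixel count, for EB/PH arithmetic tests
make_mask <- function(nrow, ncol, rows = seq_len(nrow),
                      cols = seq_len(ncol)) {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  structure(m, pixel_count = sum(m), class = c("pd_plant_mask", "matrix"))
}

# uniform-colour RGB array from an HSV triple (8-bit quantized like a PNG)
make_rgb <- function(nrow, ncol, h, s = 1, v = 0.9) {
  rgb <- grDevices::col2rgb(grDevices::hsv(h, s, v)) / 255
  arr <- array(0, c(nrow, ncol, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}
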
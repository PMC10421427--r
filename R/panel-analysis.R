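#' Genotype metadata table
#'
#' Validates the panel metadata: chickpea market type and biological
#' status come from closed vocabularies.
#'
#' @param meta Data frame with `genotype`, `chickpea_type` (`desi` or
#'   `kabuli`), `biological_status` (`landrace`, `cultivar`,
#'   `breeding material`, `domesticated material`) and optionally
#'   `origin_country`.
#' @return The validated tibble.
#' @export
genotype_meta <- function(meta) {
  need <- c("genotype", "chickpea_type", "biological_status")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta$chickpea_type %in% c("desi", "kabuli"))) {
    stop("chickpea_type must be 'desi' or 'kabuli'", call. = FALSE)
  }
  ok_status <- c("landrace", "cultivar", "breeding material",
                 "domesticated material")
  if (!all(meta$biological_status %in% ok_status)) {
    stop("biological_status outside the closed vocabulary", call. = FALSE)
  }
  tibble::as_tibble(meta)
}

#' Simulated metadata for a synthetic panel
#'
#' A panel balanced for desi and kabuli types with a landrace-dominated
#' biological status mix, deterministic given the genotype ids.
#'
#' @param genotypes Character vector of genotype ids.
#' @return A [genotype_meta()] tibble.
#' @export
simulate_genotype_meta <- function(genotypes) {
  n <- length(genotypes)
  type <- rep(c("desi", "kabuli"), length.out = n)
  status <- rep("landrace", n)
  status[seq_len(n) %% 5 == 0] <- "cultivar"
  status[seq_len(n) %% 17 == 0] <- "breeding material"
  status[seq_len(n) %% 29 == 0] <- "domesticated material"
  genotype_meta(tibble::tibble(
    genotype = genotypes, chickpea_type = type, biological_status = status,
    origin_country = rep(c("TUR", "IND", "ETH", "MEX", "PRT", "TJK"),
                         length.out = n)
  ))
}

#' Deviation of each genotype from the panel mean
#'
#' `deviation = value - mean(value over the panel)`, per treatment (and
#' per any other grouping columns present, e.g. `dat` or `phase`).
#' Deviations sum to zero within each group.
#'
#' @param values Tibble with `genotype`, `treatment`, a `value` column
#'   named by `value_col`, and optional `dat`/`phase`/`trait` columns used
#'   as additional grouping keys.
#' @param value_col Name of the value column.
#' @return The input with a `deviation` column appended.
#' @export
panel_deviation <- function(values, value_col = "blue") {
  keys <- intersect(c("trait", "treatment", "dat", "phase"), names(values))
  grouped <- dplyr::group_by(values,
                             dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::mutate(grouped,
                       deviation = .data[[value_col]] -
                         mean(.data[[value_col]], na.rm = TRUE))
  dplyr::ungroup(out)
}

#' Two-tier superiority selection against the panel mean
#'
#' Builds the criterion set of the panel screen -- biovolume at the last
#' drought day and the last experiment day, and phase water-use efficiency
#' in the tolerance (DT), recovery (DR) and adaptability (DA) windows, in
#' both treatments -- and classifies genotypes into: tier 1 ("better than
#' mean"), strictly positive deviation on every criterion of the focal
#' `tier1_treatment`; and tier 2 ("superior"), strictly positive on every
#' criterion in both treatments. Ties (deviation exactly 0) fail. The full
#' pass/fail matrix is returned for audit.
#'
#' @param eb_dev [panel_deviation()] table of EB BLUEs containing the key
#'   DATs (columns `genotype`, `treatment`, `dat`, `deviation`).
#' @param wue_dev [panel_deviation()] table of phase WUE (columns
#'   `genotype`, `treatment`, `phase`, `deviation`).
#' @param key_dats The two decision DATs (last drought day, last day).
#' @param phases The WUE phases entering the criteria.
#' @param tier1_treatment Treatments whose criteria define tier 1
#'   (default both, making tier 1 the both-treatment relaxation of tier 2
#'   applied per criterion; genotypes missing any criterion are excluded
#'   and flagged).
#' @return A list of class `pd_selection`: `matrix` (logical genotypes x
#'   criteria), `tier1`, `tier2` (character vectors), `excluded`
#'   (genotypes with missing criteria).
#' @export
select_superior <- function(eb_dev, wue_dev, key_dats = c(28L, 42L),
                            phases = c("DT", "DR", "DA"),
                            tier1_treatment = c("control", "drought")) {
  eb <- eb_dev[eb_dev$dat %in% key_dats, , drop = FALSE]
  eb$criterion <- paste0("EB_dat", eb$dat, "_", eb$treatment)
  wue <- wue_dev[wue_dev$phase %in% phases, , drop = FALSE]
  wue$criterion <- paste0("WUE_", wue$phase, "_", wue$treatment)
  crit <- dplyr::bind_rows(
    eb[, c("genotype", "treatment", "criterion", "deviation")],
    wue[, c("genotype", "treatment", "criterion", "deviation")]
  )
  wide <- tidyr::pivot_wider(crit[, c("genotype", "criterion", "deviation")],
                             names_from = "criterion",
                             values_from = "deviation")
  mat <- as.matrix(wide[, -1, drop = FALSE]) > 0
  rownames(mat) <- wide$genotype
  excluded <- rownames(mat)[!stats::complete.cases(mat)]
  crit_names <- colnames(mat)
  t1_cols <- crit_names[sub(".*_", "", crit_names) %in% tier1_treatment]
  ok <- !rownames(mat) %in% excluded
  tier1 <- rownames(mat)[ok & rowSums(!mat[, t1_cols, drop = FALSE]) == 0]
  tier2 <- rownames(mat)[ok & rowSums(!mat) == 0]
  structure(list(matrix = mat, tier1 = tier1, tier2 = tier2,
                 excluded = excluded, criteria = crit_names),
            class = "pd_selection")
}

#' @export
print.pd_selection <- function(x, ...) {
  cat("<pd_selection>", nrow(x$matrix), "genotypes x", ncol(x$matrix),
      "criteria |", length(x$tier1), "better than mean,",
      length(x$tier2), "superior\n")
  invisible(x)
}

#' Group comparison by one-way ANOVA with Tukey's HSD
#'
#' Compares per-genotype values across metadata groups (e.g. desi vs
#' kabuli, or biological status): one-way ANOVA, Tukey honest significant
#' differences for all pairs, and group means with 95 percent confidence
#' intervals. With exactly two groups the ANOVA reduces to a two-sample
#' comparison and is run through the same path.
#'
#' @param values Numeric vector, one value per genotype.
#' @param groups Factor or character vector of group labels, same length.
#' @param conf_level Confidence level for the group-mean intervals.
#' @return A list of class `pd_group_compare`: `anova_p`, `group_stats`
#'   (mean, n, ci_lower, ci_upper per group), `tukey` (pairwise table).
#'   Degenerate groupings (fewer than 2 groups with >= 2 members) return
#'   `NA` with a warning.
#' @export
group_compare <- function(values, groups, conf_level = 0.95) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2 || sum(sizes >= 2) < 2) {
    warning("degenerate grouping: ANOVA skipped", call. = FALSE)
    return(structure(list(anova_p = NA_real_, group_stats = NULL,
                          tukey = NULL), class = "pd_group_compare"))
  }
  fit <- stats::aov(values ~ groups)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  tukey <- tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"])
  stats_tab <- dplyr::bind_rows(lapply(levels(groups), function(g) {
    v <- values[groups == g]
    se <- stats::sd(v) / sqrt(length(v))
    half <- stats::qt(1 - (1 - conf_level) / 2, length(v) - 1) * se
    tibble::tibble(group = g, n = length(v), mean = mean(v),
                   ci_lower = mean(v) - half, ci_upper = mean(v) + half)
  }))
  structure(list(anova_p = p, group_stats = stats_tab, tukey = tukey),
            class = "pd_group_compare")
}

#' @export
print.pd_group_compare <- function(x, ...) {
  cat("<pd_group_compare> ANOVA p =", format(x$anova_p, digits = 3), "\n")
  if (!is.null(x$group_stats)) print(x$group_stats)
  invisible(x)
}

#' Pearson correlations between trait BLUE series
#'
#' Pairwise Pearson r and two-sided p-values over genotype BLUEs, per
#' treatment, within a DAT window (values are first averaged per genotype
#' over the window).
#'
#' @param blues BLUE table (`genotype`, `trait`, `treatment`, `dat`,
#'   `blue`).
#' @param traits Traits to correlate (default: all present).
#' @param dat_range Optional `c(start, end)` DAT window.
#' @return A tibble: `treatment`, `trait_x`, `trait_y`, `r`, `p`, `n`.
#'   Pairs with fewer than 3 complete genotypes or zero variance yield
#'   `NA`.
#' @export
trait_correlations <- function(blues, traits = unique(blues$trait),
                               dat_range = NULL) {
  b <- blues[blues$trait %in% traits, , drop = FALSE]
  if (!is.null(dat_range)) {
    b <- b[b$dat >= dat_range[1] & b$dat <= dat_range[2], , drop = FALSE]
  }
  means <- dplyr::summarise(
    dplyr::group_by(b, .data$genotype, .data$treatment, .data$trait),
    value = mean(.data$blue, na.rm = TRUE), .groups = "drop")
  out <- list()
  for (trt in unique(means$treatment)) {
    wide <- tidyr::pivot_wider(means[means$treatment == trt, ],
                               names_from = "trait",
                               values_from = "value")
    present <- intersect(traits, names(wide))
    for (i in seq_along(present)) {
      for (j in seq_len(i)) {
        x <- wide[[present[i]]]; y <- wide[[present[j]]]
        ok <- stats::complete.cases(x, y)
        if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        out[[length(out) + 1]] <- tibble::tibble(
          treatment = trt, trait_x = present[i], trait_y = present[j],
          r = r, p = p, n = sum(ok))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Principal component analysis of per-genotype phase means
#'
#' Averages each trait's BLUEs per genotype over a DAT window, standardizes
#' traits to unit variance (they carry incommensurate units) and runs a
#' PCA per treatment. Constant traits are dropped with a warning.
#'
#' @param blues BLUE table.
#' @param traits Traits to include.
#' @param dat_range DAT window, default the drought-tolerance phase 8--28.
#' @param treatment Single treatment to analyse.
#' @return A list of class `pd_pca`: `loadings`, `scores`,
#'   `explained_variance` (fractions summing to 1), `traits_used`.
#' @export
panel_pca <- function(blues, traits = c("EB", "PH", "MCV", "r2g", "y2g"),
                      dat_range = c(8, 28), treatment = "control") {
  b <- blues[blues$trait %in% traits & blues$treatment == treatment &
               blues$dat >= dat_range[1] & blues$dat <= dat_range[2], ,
             drop = FALSE]
  means <- dplyr::summarise(
    dplyr::group_by(b, .data$genotype, .data$trait),
    value = mean(.data$blue, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "trait",
                             values_from = "value")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$genotype
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3 || ncol(mat) < 2) {
    stop("PCA needs >= 3 genotypes and >= 2 traits", call. = FALSE)
  }
  constant <- apply(mat, 2, stats::sd) == 0
  if (any(constant)) {
    warning("dropping constant trait(s): ",
            paste(colnames(mat)[constant], collapse = ", "), call. = FALSE)
    mat <- mat[, !constant, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained_variance = ev, traits_used = colnames(mat)),
            class = "pd_pca")
}

#' @export
print.pd_pca <- function(x, ...) {
  cat("<pd_pca>", length(x$traits_used), "traits; PC1 explains",
      sprintf("%.1f%%", 100 * x$explained_variance[1]), "\n")
  invisible(x)
}
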
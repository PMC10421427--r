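test_that("panel deviations are centred and translation-equivariant", {
  v <- tibble::tibble(genotype = c("A", "B"), treatment = "control",
                      dat = 28L, blue = c(4, 6))
  d <- panel_deviation(v)
  expect_equal(d$deviation, c(-1, 1))
  set.seed(91)
  v2 <- tibble::tibble(genotype = sprintf("G%02d", 1:30),
                       treatment = rep(c("control", "drought"), 15),
                       dat = 28L, blue = stats::rnorm(30))
  d2 <- panel_deviation(v2)
  agg <- tapply(d2$deviation, d2$treatment, sum)
  expect_equal(as.numeric(agg), c(0, 0), tolerance = 1e-12)
  v3 <- v2; v3$blue <- v3$blue + 100
  expect_equal(panel_deviation(v3)$deviation, d2$deviation)
})

make_dev_tables <- function(eb28, eb42, wue, genotypes) {
  trts <- c("control", "drought")
  eb <- dplyr::bind_rows(lapply(trts, function(trt) {
    tibble::tibble(genotype = rep(genotypes, 2), treatment = trt,
                   dat = rep(c(28L, 42L), each = length(genotypes)),
                   blue = c(eb28[[trt]], eb42[[trt]]))
  }))
  wue_tab <- dplyr::bind_rows(lapply(trts, function(trt) {
    dplyr::bind_rows(lapply(c("DT", "DR", "DA"), function(ph) {
      tibble::tibble(genotype = genotypes, treatment = trt, phase = ph,
                     value = wue[[trt]][[ph]])
    }))
  }))
  list(eb = panel_deviation(eb, "blue"),
       wue = panel_deviation(wue_tab, "value"))
}

test_that("an identical panel selects nobody (strict inequality)", {
  g <- sprintf("G%02d", 1:6)
  same <- list(control = rep(5, 6), drought = rep(2, 6))
  wue <- list(control = list(DT = rep(1, 6), DR = rep(1, 6), DA = rep(1, 6)),
              drought = list(DT = rep(9, 6), DR = rep(1, 6), DA = rep(2, 6)))
  dev <- make_dev_tables(same, same, wue, g)
  sel <- select_superior(dev$eb, dev$wue)
  expect_length(sel$tier1, 0)
  expect_length(sel$tier2, 0)
})

test_that("a genotype below the mean on one criterion fails with an audit trail", {
  g <- c("G01", "G02", "G03")
  up <- c(3, 2, 1) # G01 best on EB everywhere
  eb <- list(control = up, drought = up)
  wue_good <- list(DT = up, DR = up, DA = up)
  wue_bad <- list(DT = c(1, 2, 3), DR = up, DA = up) # G01 worst on DT
  dev <- make_dev_tables(eb, eb, list(control = wue_bad,
                                      drought = wue_good), g)
  sel <- select_superior(dev$eb, dev$wue)
  expect_false("G01" %in% sel$tier2)
  expect_false(sel$matrix["G01", "WUE_DT_control"])
  expect_true(sel$matrix["G01", "EB_dat28_control"])
})

test_that("selection is monotone in a genotype's criterion values", {
  g <- c("G01", "G02", "G03", "G04")
  base <- c(2, 1, -1, -2)
  eb <- list(control = base, drought = base)
  wue <- list(control = list(DT = base, DR = base, DA = base),
              drought = list(DT = base, DR = base, DA = base))
  dev <- make_dev_tables(eb, eb, wue, g)
  sel <- select_superior(dev$eb, dev$wue)
  expect_true("G01" %in% sel$tier2)
  # improving G01 further cannot remove it
  eb_up <- list(control = base + c(5, 0, 0, 0), drought = base)
  dev2 <- make_dev_tables(eb_up, eb, wue, g)
  sel2 <- select_superior(dev2$eb, dev$wue)
  expect_true("G01" %in% sel2$tier2)
})

test_that("genotypes missing a criterion are excluded and flagged", {
  g <- c("G01", "G02", "G03")
  base <- c(1, 0, -1)
  eb <- list(control = base, drought = base)
  wue <- list(control = list(DT = base, DR = base, DA = base),
              drought = list(DT = base, DR = c(NA, 0, 1), DA = base))
  dev <- make_dev_tables(eb, eb, wue, g)
  sel <- select_superior(dev$eb, dev$wue)
  expect_true("G01" %in% sel$excluded)
  expect_false("G01" %in% sel$tier2)
})

test_that("group comparison flags a strong group offset and not a null", {
  set.seed(101)
  null_vals <- stats::rnorm(60)
  grp <- rep(c("desi", "kabuli"), each = 30)
  null_cmp <- group_compare(null_vals, grp)
  expect_gt(null_cmp$anova_p, 0.001)
  off_vals <- null_vals + ifelse(grp == "desi", 5, 0)
  off_cmp <- group_compare(off_vals, grp)
  expect_lt(off_cmp$anova_p, 1e-10)
  expect_lt(off_cmp$tukey$p_adj[1], 1e-6)
  expect_equal(nrow(off_cmp$group_stats), 2)
  expect_true(all(off_cmp$group_stats$ci_lower <
                    off_cmp$group_stats$ci_upper))
})

test_that("group means fall inside their own confidence intervals", {
  set.seed(103)
  vals <- stats::rnorm(40, mean = 10)
  grp <- rep(c("a", "b"), 20)
  cmp <- group_compare(vals, grp)
  with(cmp$group_stats, {
    expect_true(all(ci_lower <= mean & mean <= ci_upper))
  })
})

test_that("degenerate groupings are skipped with a warning", {
  expect_warning(cmp <- group_compare(c(1, 2, 3), c("a", "a", "a")),
                 "degenerate")
  expect_true(is.na(cmp$anova_p))
})

test_that("four-level biological-status groupings run through Tukey", {
  set.seed(105)
  status <- rep(c("landrace", "cultivar", "breeding material",
                  "domesticated material"), each = 8)
  cmp <- group_compare(stats::rnorm(32), status)
  expect_equal(nrow(cmp$tukey), choose(4, 2))
})

test_that("trait correlations recover exact and degenerate cases", {
  set.seed(107)
  g <- sprintf("G%02d", 1:20)
  x <- stats::rnorm(20)
  blues <- dplyr::bind_rows(
    tibble::tibble(genotype = g, trait = "EB", treatment = "control",
                   dat = 10L, blue = x),
    tibble::tibble(genotype = g, trait = "PH", treatment = "control",
                   dat = 10L, blue = -x),
    tibble::tibble(genotype = g, trait = "MCV", treatment = "control",
                   dat = 10L, blue = rep(1, 20)))
  ct <- trait_correlations(blues, traits = c("EB", "PH", "MCV"))
  get <- function(a, b) ct$r[ct$trait_x == a & ct$trait_y == b |
                               ct$trait_x == b & ct$trait_y == a]
  expect_equal(get("EB", "EB"), 1)
  expect_equal(get("PH", "EB"), -1)
  expect_true(is.na(get("MCV", "EB"))) # zero variance
})

test_that("correlated genetic factors appear in the BLUE correlations", {
  sim <- simulate_traits(sim_design(n_genotypes = 40, seed = 19),
                         traits = c("EB", "PH"))
  blues <- compute_blues(sim$traits)
  ct <- trait_correlations(blues, traits = c("EB", "PH"),
                           dat_range = c(8, 28))
  r <- ct$r[ct$trait_x == "PH" & ct$trait_y == "EB" &
              ct$treatment == "control"]
  expect_gt(r, 0.5) # PH is allometric in EB with shared genetics
  expect_lt(ct$p[ct$trait_x == "PH" & ct$trait_y == "EB" &
                   ct$treatment == "control"], 0.01)
})

test_that("PCA explained-variance fractions are normalised", {
  set.seed(109)
  g <- sprintf("G%02d", 1:25)
  x <- stats::rnorm(25)
  blues <- dplyr::bind_rows(
    tibble::tibble(genotype = g, trait = "EB", treatment = "control",
                   dat = 10L, blue = x),
    tibble::tibble(genotype = g, trait = "PH", treatment = "control",
                   dat = 10L, blue = 2 * x + 3), # perfectly correlated
    tibble::tibble(genotype = g, trait = "r2g", treatment = "control",
                   dat = 10L, blue = stats::rnorm(25)))
  pc <- panel_pca(blues, traits = c("EB", "PH"), dat_range = c(8, 28))
  expect_equal(pc$explained_variance[1], 1)
  pc3 <- panel_pca(blues, traits = c("EB", "PH", "r2g"),
                   dat_range = c(8, 28))
  expect_equal(sum(pc3$explained_variance), 1)
})

test_that("constant traits are dropped from the PCA with a warning", {
  g <- sprintf("G%02d", 1:10)
  blues <- dplyr::bind_rows(
    tibble::tibble(genotype = g, trait = "EB", treatment = "control",
                   dat = 10L, blue = stats::rnorm(10)),
    tibble::tibble(genotype = g, trait = "PH", treatment = "control",
                   dat = 10L, blue = stats::rnorm(10)),
    tibble::tibble(genotype = g, trait = "MCV", treatment = "control",
                   dat = 10L, blue = rep(0.23, 10)))
  expect_warning(pc <- panel_pca(blues, traits = c("EB", "PH", "MCV"),
                                 dat_range = c(8, 28)), "constant")
  expect_equal(pc$traits_used, c("EB", "PH"))
})

test_that("metadata vocabularies are enforced", {
  meta <- simulate_genotype_meta(sprintf("G%03d", 1:60))
  expect_equal(sum(meta$chickpea_type == "desi"), 30)
  bad <- meta; bad$chickpea_type[1] <- "pea"
  expect_error(genotype_meta(bad), "desi")
  bad2 <- meta; bad2$biological_status[1] <- "wild"
  expect_error(genotype_meta(bad2), "vocabulary")
})
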
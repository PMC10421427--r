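test_that("the heritability formula matches direct arithmetic", {
  expect_equal(heritability(variance_components(1, 0, 0, 2, 2)), 1)
  expect_equal(heritability(variance_components(0, 0, 2, 2, 2)), 0)
  expect_equal(heritability(variance_components(2, 1, 2, 2, 2)),
               2 / (2 + 0.5 + 0.5))
  expect_true(is.na(heritability(variance_components(0, 0, 0, 2, 2))))
})

test_that("heritability is monotone in its variance components", {
  base <- c(v_g = 2, v_gxe = 1, v_e = 2)
  h <- function(v) heritability(variance_components(v[1], v[2], v[3], 2, 2))
  expect_gt(h(base + c(1, 0, 0)), h(base))
  expect_lt(h(base + c(0, 1, 0)), h(base))
  expect_lt(h(base + c(0, 0, 1)), h(base))
})

test_that("negative variance components are truncated and flagged", {
  vc <- variance_components(-0.3, 1, 2, 2, 2)
  expect_equal(vc$v_g, 0)
  expect_equal(attr(vc, "clipped"), "v_g")
})

test_that("REML equals the balanced closed form to numerical identity", {
  for (i in 1:8) {
    s <- simulate_trait_slice(n_genotypes = 30, sd_g = 2, sd_exp = 1,
                              sd_gxe = 1, sd_resid = 1, seed = 300 + i)
    a <- fit_variance_components(s, "reml")
    b <- fit_variance_components(s, "ems")
    expect_equal(a$v_g, b$v_g, tolerance = 1e-8)
    expect_equal(a$v_gxe, b$v_gxe, tolerance = 1e-8)
    expect_equal(a$v_e, b$v_e, tolerance = 1e-8)
  }
})

test_that("variance components are recovered on a large balanced slice", {
  s <- simulate_trait_slice(n_genotypes = 500, sd_g = 2, sd_exp = 0.5,
                            sd_gxe = 1, sd_resid = 1, seed = 17)
  vc <- fit_variance_components(s, "ems")
  expect_equal(vc$v_g, 4, tolerance = 0.35)
  expect_equal(vc$v_gxe, 1, tolerance = 0.35)
  expect_equal(vc$v_e, 1, tolerance = 0.15)
})

test_that("a pure-noise slice yields a near-zero genotype variance", {
  s <- simulate_trait_slice(n_genotypes = 300, sd_g = 0, sd_exp = 0.5,
                            sd_gxe = 0, sd_resid = 1, seed = 21)
  vc <- fit_variance_components(s, "reml")
  expect_lt(vc$v_g, 0.1)
})

test_that("a zero-noise slice loads all variance on the genotype", {
  s <- simulate_trait_slice(n_genotypes = 30, sd_g = 2, sd_exp = 0,
                            sd_gxe = 0, sd_resid = 0, seed = 23)
  vc <- fit_variance_components(s, "reml")
  expect_gt(vc$v_g, 0)
  expect_equal(vc$v_gxe, 0, tolerance = 1e-6)
  expect_equal(vc$v_e, 0, tolerance = 1e-6)
})

test_that("a single-experiment slice flags the undefined interaction", {
  s <- simulate_trait_slice(n_experiments = 1, seed = 3)
  expect_warning(vc <- fit_variance_components(s), "single experiment")
  expect_equal(vc$v_gxe, 0)
})

test_that("identical observations produce zero outlier flags", {
  s <- make_slice(rep(5, 24), n_exp = 2, n_rep = 2)
  fl <- suppressWarnings(detect_outliers(s))
  expect_equal(sum(fl$flagged), 0)
})

test_that("an infinite threshold flags nothing", {
  s <- simulate_trait_slice(seed = 31)
  fl <- detect_outliers(s, threshold = Inf)
  expect_equal(sum(fl$flagged), 0)
})

test_that("a planted 10-SD contaminant is flagged, touching only its cell", {
  s <- simulate_trait_slice(n_genotypes = 60, sd_g = 2, sd_exp = 0.5,
                            sd_gxe = 1, sd_resid = 1, seed = 33)
  s$value[100] <- s$value[100] + 10
  fl <- detect_outliers(s, threshold = 3)
  expect_true(fl$flagged[100])
  # any further flag can only be the contaminant's replicate partner,
  # swamped through the shared genotype-by-experiment cell
  cell <- paste(s$genotype, s$experiment)
  expect_true(all(cell[fl$row[fl$flagged]] == cell[100]))
  clean <- remove_outliers(s, fl)
  expect_equal(nrow(clean), nrow(s) - sum(fl$flagged))
})

test_that("outlier screening treats each DAT/treatment slice separately", {
  s1 <- simulate_trait_slice(seed = 41, dat = 10, treatment = "control")
  s2 <- simulate_trait_slice(seed = 42, dat = 10, treatment = "drought")
  s2$value[5] <- s2$value[5] + 12
  fl <- detect_outliers(dplyr::bind_rows(s1, s2))
  flagged <- fl[fl$flagged, ]
  # all flags stay inside the contaminated treatment slice
  expect_gte(nrow(flagged), 1)
  expect_true(all(flagged$treatment == "drought"))
  expect_true((nrow(s1) + 5) %in% fl$row[fl$flagged]) # the planted row
})

test_that("balanced BLUEs equal plain genotype means", {
  s <- make_slice(c(3, 5, 4, 8, 1, 2, 3, 4), n_exp = 2, n_rep = 2)
  b_auto <- compute_blues(s, method = "auto")
  expect_equal(b_auto$blue[b_auto$genotype == "G001"], mean(c(3, 4, 1, 3)))
  expect_equal(b_auto$blue[b_auto$genotype == "G002"], mean(c(5, 8, 2, 4)))
  # the REML path agrees on balanced data
  s2 <- simulate_trait_slice(n_genotypes = 12, seed = 51)
  b1 <- compute_blues(s2, method = "auto")
  b2 <- compute_blues(s2, method = "reml")
  expect_equal(b1$blue, b2$blue, tolerance = 1e-6)
})

test_that("BLUEs are equivariant under a genotype-wide shift", {
  s <- simulate_trait_slice(n_genotypes = 10, seed = 55)
  shifted <- s
  shifted$value[shifted$genotype == "G003"] <-
    shifted$value[shifted$genotype == "G003"] + 7
  b0 <- compute_blues(s, method = "reml")
  b1 <- compute_blues(shifted, method = "reml")
  expect_equal(b1$blue[b1$genotype == "G003"],
               b0$blue[b0$genotype == "G003"] + 7, tolerance = 1e-6)
})

test_that("BLUEs are invariant to relabeling of the experiments", {
  s <- simulate_trait_slice(n_genotypes = 10, seed = 57)
  swapped <- s
  swapped$experiment <- ifelse(s$experiment == "E1", "E2", "E1")
  expect_equal(compute_blues(s, method = "reml")$blue,
               compute_blues(swapped, method = "reml")$blue,
               tolerance = 1e-6)
})

test_that("unbalanced BLUEs match a direct generalized-least-squares oracle", {
  s <- simulate_trait_slice(n_genotypes = 8, seed = 61)
  s <- s[-c(3, 17), ] # drop two observations -> unbalanced
  b <- compute_blues(s, method = "auto")
  # oracle: GLS with the covariance implied by the fitted components,
  # assembled by direct matrix algebra
  fit <- phenodrought:::fit_blue_model(s)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_ge <- vc$vcov[vc$grp == "genotype:experiment"]
  v_e <- vc$vcov[vc$grp == "experiment"]
  v_r <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(~ 0 + factor(s$genotype))
  Ze <- stats::model.matrix(~ 0 + factor(s$experiment))
  Zge <- stats::model.matrix(~ 0 + factor(s$genotype):factor(s$experiment))
  V <- v_e * tcrossprod(Ze) + v_ge * tcrossprod(Zge) + v_r * diag(nrow(s))
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, s$value)))
  expect_equal(unname(b$blue), unname(drop(beta)), tolerance = 1e-6)
})

test_that("the per-DAT heritability table covers every slice", {
  sim <- simulate_traits(sim_design(n_genotypes = 15, seed = 2),
                         traits = "EB")
  tr <- sim$traits[sim$traits$dat %in% c(10, 25), ]
  h2 <- heritability_table(tr)
  expect_equal(nrow(h2), 4) # 2 DATs x 2 treatments
  expect_true(all(h2$h2 >= 0 & h2$h2 <= 1))
  expect_true(all(h2$v_g >= 0))
})
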
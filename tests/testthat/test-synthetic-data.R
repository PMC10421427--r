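small_design <- function(seed = 1L, n_genotypes = 8L) {
  sim_design(n_genotypes = n_genotypes, seed = seed)
}

test_that("the simulator is deterministic given the seed", {
  a <- simulate_traits(small_design(seed = 3), traits = c("EB", "r2g"))
  b <- simulate_traits(small_design(seed = 3), traits = c("EB", "r2g"))
  expect_identical(a$traits, b$traits)
  expect_identical(a$watering, b$watering)
  c <- simulate_traits(small_design(seed = 4), traits = "EB")
  expect_false(identical(a$traits$value[a$traits$trait == "EB"],
                         c$traits$value))
})

test_that("per-genotype substreams survive subsetting of the panel", {
  a <- simulate_traits(small_design(n_genotypes = 6), traits = "EB")
  b <- simulate_traits(small_design(n_genotypes = 12), traits = "EB")
  ga <- a$traits[a$traits$genotype == "G005", ]
  gb <- b$traits[b$traits$genotype == "G005", ]
  expect_equal(ga$value, gb$value)
})

test_that("excluded DATs are emitted as missing values", {
  sim <- simulate_traits(small_design(), traits = "EB")
  tr <- sim$traits
  expect_true(all(is.na(tr$value[tr$experiment == "E1" & tr$dat == 1])))
  expect_true(all(is.na(tr$value[tr$experiment == "E2" & tr$dat == 14])))
  expect_true(all(!is.na(tr$value[tr$experiment == "E1" & tr$dat == 14])))
})

test_that("control pots are restored to exactly 70% PAW at every watering", {
  sim <- simulate_traits(small_design(), traits = "EB")
  cal <- default_pot_calibration()
  ctrl <- sim$watering[sim$watering$treatment == "control", ]
  expect_equal(paw_from_weight(ctrl$weight_after, cal),
               rep(70, nrow(ctrl)), tolerance = 1e-10)
})

test_that("drought pots follow the stress regime and the 300 mL step", {
  sim <- simulate_traits(small_design(), traits = "EB")
  drt <- sim$watering[sim$watering$treatment == "drought", ]
  step <- drt[drt$dat == 29, ]
  expect_true(all(step$water_added == 300))
  stress <- drt[drt$dat >= 8 & drt$dat <= 28, ]
  # during stress the pots stay above the 10% target, so almost no water
  expect_lt(sum(stress$water_added), 0.01 * sum(drt$water_added))
  validate_watering(sim$watering)
})

test_that("drought suppresses the biovolume trajectory from the stress start", {
  p <- sim_params()
  bc <- eb_trajectory(p, "control")
  bd <- eb_trajectory(p, "drought")
  expect_equal(bc[as.character(1:8)], bd[as.character(1:8)])
  expect_true(all(bd[as.character(15:42)] < bc[as.character(15:42)]))
  # senescence makes the drought RGR slightly negative under advanced stress
  expect_lt(min(diff(log(bd))[as.character(20:28)]), 0)
  # and growth resumes after re-watering
  expect_gt(diff(log(bd))[["34"]], 0)
})

test_that("a null treatment penalty gives identical expected trajectories", {
  p <- sim_params(drought = list(suppression = 1, tau = 6, sen_max = 0,
                                 sen_delay = 12, sen_tau = 2,
                                 recovery_rate = 0.35))
  expect_equal(eb_trajectory(p, "control"), eb_trajectory(p, "drought"))
})

test_that("the exact-model slice generator matches its stated heritability", {
  s <- simulate_trait_slice(n_genotypes = 40, sd_g = 2, sd_gxe = 1,
                            sd_resid = 1, seed = 5)
  expect_equal(attr(s, "true_h2"), 4 / (4 + 1 / 2 + 1 / 4))
  expect_identical(s, simulate_trait_slice(n_genotypes = 40, sd_g = 2,
                                           sd_gxe = 1, sd_resid = 1,
                                           seed = 5))
  expect_equal(nrow(s), 40 * 2 * 2)
})

test_that("a noiseless large slice has empirical heritability one", {
  s <- simulate_trait_slice(n_genotypes = 200, sd_g = 2, sd_exp = 0,
                            sd_gxe = 0, sd_resid = 0, seed = 2)
  vc <- fit_variance_components(s, method = "ems")
  expect_equal(heritability(vc), 1)
})

test_that("planted outliers are recorded with their row indices", {
  s <- simulate_trait_slice(seed = 9)
  pl <- plant_outliers(s, rate = 0.01, size = 10, sd_resid = 1, seed = 10)
  expect_equal(nrow(pl$records), nrow(s))
  moved <- which(pl$records$value != s$value)
  expect_equal(moved, pl$planted)
  expect_equal(abs(pl$records$value[moved] - s$value[moved]),
               rep(10, length(moved)))
})

test_that("rendered images satisfy the biovolume identity and colour request", {
  rp <- render_plant_images(eb = 5000, ph_mm = 80, mcv = 0.23,
                            r2g = 0.01, y2g = 0.04)
  with(rp$truth, {
    expect_equal(eb, side_area * sqrt(top_area))
    expect_equal(r2g, n_red / n_green)
    expect_equal(y2g, n_yellow / n_green)
  })
  expect_equal(rp$truth$eb, 5000, tolerance = 0.05)
  expect_equal(rp$truth$ph, 80)
  # r2g = 0 renders no red pixels
  rp0 <- render_plant_images(eb = 1000, ph_mm = 40, r2g = 0)
  expect_equal(rp0$truth$n_red, 0)
  # a single-hue canopy carries the requested mean hue exactly
  rp1 <- render_plant_images(eb = 1000, ph_mm = 40, mcv = 0.23)
  expect_equal(rp1$truth$mcv, 0.23)
  expect_error(render_plant_images(eb = 1000, ph_mm = 4000), "height")
})

test_that("simulated panel means reproduce the expected stress contrasts", {
  sim <- simulate_traits(sim_design(n_genotypes = 20, seed = 11),
                         traits = c("EB", "r2g", "PhiPSIIh"))
  tr <- sim$traits
  m <- function(trait, trt, d) {
    mean(tr$value[tr$trait == trait & tr$treatment == trt & tr$dat == d],
         na.rm = TRUE)
  }
  expect_lt(m("EB", "drought", 28) / m("EB", "control", 28), 0.35)
  expect_gt(m("r2g", "drought", 28), 1.8 * m("r2g", "control", 28))
  expect_lt(m("PhiPSIIh", "drought", 27), 0.9 * m("PhiPSIIh", "control", 27))
  expect_gt(m("PhiPSIIh", "drought", 34), 0.95 * m("PhiPSIIh", "control", 34))
})

test_that("a simulation bundle round-trips through its CSV files", {
  sim <- simulate_traits(small_design(n_genotypes = 4), traits = "EB")
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tr <- read_trait_table(file.path(dir, "traits.csv"))
  expect_equal(nrow(tr), nrow(sim$traits))
  expect_equal(tr$value, sim$traits$value, tolerance = 1e-12)
  w <- read_watering_table(file.path(dir, "watering.csv"))
  expect_equal(nrow(w), nrow(sim$watering))
  expect_true(all(c("genotype", "treatment") %in% names(w)))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$design$n_genotypes, 4)
})
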
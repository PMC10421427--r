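#' Design of a simulated phenotyping trial
#'
#' The default reproduces the study layout the package targets: 60
#' genotypes, two experiments, two biological replicates per genotype,
#' treatment and experiment, control and drought treatments, DAT 1--42.
#'
#' @param n_genotypes,n_experiments,n_reps Design counts (all >= 1).
#' @param treatments Treatment labels.
#' @param timeline A [default_timeline()].
#' @param seed Master seed; all simulator randomness derives from it.
#' @return An object of class `pd_sim_design`.
#' @export
sim_design <- function(n_genotypes = 60L, n_experiments = 2L, n_reps = 2L,
                       treatments = c("control", "drought"),
                       timeline = default_timeline(), seed = 1L) {
  stopifnot(n_genotypes >= 1, n_experiments >= 1, n_reps >= 1)
  validate_timeline(timeline)
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         n_experiments = as.integer(n_experiments),
         n_reps = as.integer(n_reps),
         treatments = treatments, timeline = timeline,
         seed = as.integer(seed)),
    class = "pd_sim_design"
  )
}

#' Parameters of the trait simulator
#'
#' Logistic growth in biovolume with a treatment-dependent rate, a
#' multiplicative drought penalty that deepens over the stress period, a
#' senescence term that can push the relative growth rate slightly negative
#' under sustained stress, and an exponential return towards the control
#' growth rate after re-watering. Colour and photosystem-II traits follow
#' piecewise-linear stress-response anchors. Genotype effects are
#' phase- and treatment-specific log-scale multipliers of the growth rate
#' and of daily water use, plus a shared vigour term; experiment, genotype x
#' experiment and residual noise are added at the observation level
#' (multiplicative on EB, PH and the colour ratios; additive on MCV and
#' PhiPSII, clipped to valid ranges).
#'
#' @param growth Named list: `b0` initial biovolume (voxels), `k` carrying
#'   capacity (voxels), `r` relative growth rate per day.
#' @param drought Named list: `suppression` asymptotic growth-rate
#'   multiplier under stress (in `[0, 1]`), `tau` days over which the
#'   penalty deepens, `sen_max` maximal senescence rate (1/day),
#'   `sen_delay` days of stress before senescence starts, `sen_tau` its
#'   ramp time constant, `recovery_rate` per-day return towards control
#'   growth after the second re-watering step.
#' @param genetics Named list of genotype-effect standard deviations:
#'   `vigor` (log initial size), `growth` (log growth-rate multiplier,
#'   per treatment x phase), `water` (log water-use multiplier, per
#'   treatment x phase), `ph`, `r2g`, `y2g` (log multipliers), `mcv`,
#'   `psii` (additive).
#' @param noise Named list of observation-noise standard deviations:
#'   `exp_*`, `gxe_*`, `resid_*` per trait family (`eb`, `ph`, `ratio`,
#'   `mcv`, `psii`) and `water` (log daily water-use noise).
#' @param watering Named list: `evap` daily evaporation (g), `transp`
#'   transpiration per reported-EB unit (g/day), `paw_close` PAW (percent)
#'   below which stomata progressively close, `beta` closure exponent.
#' @param ph Named list: allometry `scale` and `exponent` mapping
#'   biovolume to height in mm.
#' @param color Named list of piecewise-linear anchors (`dat`, `value`)
#'   per trait and treatment for MCV, r2g, y2g, PhiPSIIh, PhiPSIIl.
#' @return An object of class `pd_sim_params`.
#' @export
sim_params <- function(growth = list(b0 = 2e5, k = 5e8, r = 0.139),
                       drought = list(suppression = 0.58, tau = 6,
                                      sen_max = 0.10, sen_delay = 12,
                                      sen_tau = 2, recovery_rate = 0.35),
                       genetics = list(vigor = 0.05, growth = 0.10,
                                       water = 0.12, ph = 0.05,
                                       r2g = 0.12, y2g = 0.12,
                                       mcv = 0.004, psii = 0.010),
                       noise = list(exp_eb = 0.04, gxe_eb = 0.05,
                                    resid_eb = 0.10,
                                    exp_ph = 0.02, gxe_ph = 0.03,
                                    resid_ph = 0.05,
                                    exp_ratio = 0.05, gxe_ratio = 0.08,
                                    resid_ratio = 0.15,
                                    exp_mcv = 0.002, gxe_mcv = 0.002,
                                    resid_mcv = 0.003,
                                    exp_psii = 0.005, gxe_psii = 0.006,
                                    resid_psii = 0.010,
                                    water = 0.10),
                       watering = list(evap = 15, transp = 0.6,
                                       paw_close = 30, beta = 1),
                       ph = list(scale = 3.5, exponent = 0.25),
                       color = default_color_anchors()) {
  p <- structure(list(growth = growth, drought = drought,
                      genetics = genetics, noise = noise,
                      watering = watering, ph = ph, color = color),
                 class = "pd_sim_params")
  stopifnot(p$growth$k > 0, p$growth$b0 > 0,
            p$drought$suppression >= 0, p$drought$suppression <= 1,
            all(unlist(p$genetics) >= 0), all(unlist(p$noise) >= 0))
  p
}

#' Default stress-response anchors for colour and PhiPSII traits
#'
#' Piecewise-linear (DAT, value) anchors per trait and treatment. The
#' drought anchors emulate the canonical stress pattern: colour ratios rise
#' over the stress period (red-to-green roughly 0.005 control vs 0.013
#' drought, yellow-to-green 0.029 vs 0.069 at the last drought day), mean
#' hue rises ~6% under advanced stress, and PhiPSII under high light dips
#' by ~7% after 13 days and ~20% after 19 days of stress, all relaxing
#' back after re-watering.
#'
#' @return Nested list `color[[trait]][[treatment]]` of anchor data frames.
#' @export
default_color_anchors <- function() {
  a <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(dat = m[, 1], value = m[, 2])
  }
  list(
    MCV = list(
      control = a(1, 0.230, 42, 0.230),
      drought = a(1, 0.230, 15, 0.230, 20, 0.2420, 24, 0.2447, 28, 0.2447,
                  32, 0.2380, 36, 0.2300, 42, 0.2300)
    ),
    r2g = list(
      control = a(1, 0.0040, 28, 0.0050, 42, 0.0060),
      drought = a(1, 0.0040, 14, 0.0050, 28, 0.0130, 34, 0.0070, 42, 0.0040)
    ),
    y2g = list(
      control = a(1, 0.0240, 28, 0.0290, 42, 0.0320),
      drought = a(1, 0.0240, 14, 0.0320, 28, 0.0690, 36, 0.0400, 42, 0.0350)
    ),
    PhiPSIIh = list(
      control = a(1, 0.550, 42, 0.550),
      drought = a(1, 0.550, 8, 0.550, 13, 0.538, 20, 0.512, 27, 0.440,
                  34, 0.545, 42, 0.550)
    ),
    PhiPSIIl = list(
      control = a(1, 0.460, 42, 0.460),
      drought = a(1, 0.460, 8, 0.460, 13, 0.452, 20, 0.437, 27, 0.390,
                  34, 0.455, 42, 0.460)
    )
  )
}

#' Deterministic substream seed from a master seed and a string key
#'
#' Stable string hash so that every genotype and plant owns its own random
#' substream: subsetting genotypes never reshuffles the draws of others.
#'
#' @param master Integer master seed.
#' @param key Character key.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(master, key) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_substream <- function(master, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, key))
  force(expr)
}

anchor_value <- function(anchors, dat) {
  stats::approx(anchors$dat, anchors$value, xout = dat, rule = 2)$y
}

#' Deterministic biovolume trajectory for one treatment
#'
#' Daily logistic growth with the drought penalty, senescence and recovery
#' dynamics of [sim_params()]; genotype growth multipliers act on the rate.
#'
#' @param params A `pd_sim_params`.
#' @param treatment `"control"` or `"drought"`.
#' @param timeline A `pd_timeline`.
#' @param vigor Log initial-size effect (scalar).
#' @param g_early,g_late Log growth-rate multipliers for the window up to
#'   the last drought day and for the recovery window.
#' @return Numeric vector of biovolumes (voxels) indexed by DAT.
#' @export
eb_trajectory <- function(params, treatment, timeline = default_timeline(),
                          vigor = 0, g_early = 0, g_late = 0) {
  dats <- timeline$first_dat:timeline$last_dat
  dt_end <- timeline$rewater_step1 - 1L
  b <- numeric(length(dats))
  b[1] <- params$growth$b0 * exp(vigor)
  drt <- params$drought
  for (i in seq_along(dats)[-1]) {
    t <- dats[i]
    axis <- if (t <= dt_end) g_early else g_late
    rate <- params$growth$r * (1 - b[i - 1] / params$growth$k) * exp(axis)
    sen <- 0
    if (treatment == "drought" && t >= timeline$drought_start) {
      if (t <= dt_end) {
        d <- t - timeline$drought_start
        m <- drt$suppression + (1 - drt$suppression) * exp(-d / drt$tau)
        sen <- drt$sen_max *
          (1 - exp(-max(0, d - drt$sen_delay) / drt$sen_tau))
      } else {
        d_end <- dt_end - timeline$drought_start
        m_end <- drt$suppression +
          (1 - drt$suppression) * exp(-d_end / drt$tau)
        sen_end <- drt$sen_max *
          (1 - exp(-max(0, d_end - drt$sen_delay) / drt$sen_tau))
        rec <- exp(-drt$recovery_rate * (t - timeline$rewater_step1))
        m <- 1 - (1 - m_end) * rec
        sen <- sen_end * rec
      }
      rate <- rate * m
    }
    b[i] <- b[i - 1] * exp(rate - sen)
  }
  names(b) <- dats
  b
}

draw_genotype_effects <- function(design, params, superior = character()) {
  g <- params$genetics
  ids <- sprintf("G%03d", seq_len(design$n_genotypes))
  eff <- lapply(ids, function(id) {
    with_substream(design$seed, paste0("geno_", id), {
      z <- stats::rnorm(14)
      list(vigor = z[1] * g$vigor,
           g_ctrl_early = z[2] * g$growth, g_ctrl_late = z[3] * g$growth,
           g_drt_early = z[4] * g$growth, g_drt_late = z[5] * g$growth,
           w_ctrl_dt = z[6] * g$water, w_ctrl_dr = z[7] * g$water,
           w_drt_dt = z[8] * g$water, w_drt_dr = z[9] * g$water,
           ph = z[10] * g$ph, mcv = z[11] * g$mcv,
           r2g = z[12] * g$r2g, y2g = z[13] * g$y2g, psii = z[14] * g$psii)
    })
  })
  eff <- do.call(rbind, lapply(eff, function(e) tibble::as_tibble(e)))
  eff <- dplyr::bind_cols(tibble::tibble(genotype = ids), eff)
  # planted superior genotypes: +2 SD on every growth axis, -2 SD on every
  # water-use axis (less water for the same biovolume), deterministically
  sup <- intersect(superior, ids)
  if (length(superior) && !setequal(sup, superior)) {
    stop("unknown superior genotype ids", call. = FALSE)
  }
  i <- eff$genotype %in% sup
  if (any(i)) {
    eff$vigor[i] <- 2 * g$vigor
    for (cc in c("g_ctrl_early", "g_ctrl_late", "g_drt_early", "g_drt_late")) {
      eff[[cc]][i] <- 2 * g$growth
    }
    for (cc in c("w_ctrl_dt", "w_ctrl_dr", "w_drt_dt", "w_drt_dr")) {
      eff[[cc]][i] <- -2 * g$water
    }
  }
  eff
}

#' Simulate trait tables, watering records and ground truth for a panel
#'
#' For each plant and DAT the observed value is a deterministic genotype x
#' treatment trajectory plus experiment, genotype-x-experiment and residual
#' noise. Drought trajectories suppress growth from the drought start,
#' allow a slightly negative relative growth rate under advanced stress,
#' and recover after the second re-watering step; colour ratios rise under
#' stress and relax afterwards; PhiPSII declines and returns. Watering is
#' simulated closed-loop against [target_paw()] with biomass-dependent
#' transpiration. The DATs excluded per experiment are emitted as missing
#' values.
#'
#' @param design A [sim_design()].
#' @param params A [sim_params()].
#' @param traits Traits to simulate (subset of `"EB"`, `"PH"`, `"MCV"`,
#'   `"r2g"`, `"y2g"`, `"PhiPSIIh"`, `"PhiPSIIl"`).
#' @param superior Character vector of genotype ids planted as uniformly
#'   superior (+2 SD on every growth axis, -2 SD on every water-use axis).
#' @param calibration A [pot_calibration()] for the watering loop.
#' @return A list of class `pd_simulation` with elements `traits` (long
#'   tibble: genotype, experiment, replicate, treatment, dat, trait,
#'   value), `watering` (plant-level irrigation log with plant metadata),
#'   and `truth` (genotype effects, deterministic trajectories, true
#'   heritability of EB per DAT and treatment, design and parameters).
#' @export
simulate_traits <- function(design = sim_design(), params = sim_params(),
                            traits = c("EB", "PH", "MCV", "r2g", "y2g",
                                       "PhiPSIIh", "PhiPSIIl"),
                            superior = character(),
                            calibration = default_pot_calibration()) {
  stopifnot(inherits(design, "pd_sim_design"),
            inherits(params, "pd_sim_params"))
  traits <- match.arg(traits, several.ok = TRUE)
  tl <- design$timeline
  dats <- tl$first_dat:tl$last_dat
  nd <- length(dats)
  exps <- sprintf("E%d", seq_len(design$n_experiments))
  reps <- sprintf("R%d", seq_len(design$n_reps))

  eff <- draw_genotype_effects(design, params, superior)
  ids <- eff$genotype

  # deterministic per-genotype trajectories -------------------------------
  traj <- list()
  for (trt in design$treatments) {
    traj[[trt]] <- t(vapply(seq_along(ids), function(i) {
      e <- eff[i, ]
      if (trt == "control") {
        eb_trajectory(params, "control", tl, e$vigor,
                      e$g_ctrl_early, e$g_ctrl_late)
      } else {
        eb_trajectory(params, "drought", tl, e$vigor,
                      e$g_drt_early, e$g_drt_late)
      }
    }, numeric(nd)))
    rownames(traj[[trt]]) <- ids
  }

  # experiment effects per trait family ----------------------------------
  fam <- c(EB = "eb", PH = "ph", MCV = "mcv", r2g = "ratio", y2g = "ratio",
           PhiPSIIh = "psii", PhiPSIIl = "psii")
  exp_eff <- sapply(names(fam), function(tr) {
    with_substream(design$seed, paste0("expeff_", tr),
                   stats::rnorm(length(exps),
                                sd = params$noise[[paste0("exp_", fam[tr])]]))
  })
  rownames(exp_eff) <- exps

  # g x e effects per genotype, experiment, treatment, trait --------------
  gxe <- lapply(names(fam), function(tr) {
    sd_gxe <- params$noise[[paste0("gxe_", fam[tr])]]
    arr <- array(0, c(length(ids), length(exps), length(design$treatments)),
                 dimnames = list(ids, exps, design$treatments))
    for (i in seq_along(ids)) {
      arr[i, , ] <- with_substream(
        design$seed, paste0("gxe_", tr, "_", ids[i]),
        stats::rnorm(length(exps) * length(design$treatments), sd = sd_gxe))
    }
    arr
  })
  names(gxe) <- names(fam)

  # plant grid ------------------------------------------------------------
  plants <- expand.grid(genotype = ids, experiment = exps, replicate = reps,
                        treatment = design$treatments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plants$plant_id <- paste(plants$genotype, plants$experiment,
                           plants$replicate, plants$treatment, sep = "_")
  np <- nrow(plants)

  # trait observations ----------------------------------------------------
  psii_dats <- tl$fluorcam_dats
  rows <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    tr <- traits[k]
    use_dats <- if (tr %in% c("PhiPSIIh", "PhiPSIIl")) psii_dats else dats
    nu <- length(use_dats)
    resid <- matrix(0, np, nu)
    sd_res <- params$noise[[paste0("resid_", fam[tr])]]
    for (j in seq_len(np)) {
      resid[j, ] <- with_substream(
        design$seed, paste0("resid_", tr, "_", plants$plant_id[j]),
        stats::rnorm(nu, sd = sd_res))
    }
    det <- matrix(0, np, nu)
    for (j in seq_len(np)) {
      g <- plants$genotype[j]; trt <- plants$treatment[j]
      b <- traj[[trt]][g, match(use_dats, dats)]
      gi <- match(g, ids)
      det[j, ] <- switch(
        tr,
        EB = b,
        PH = params$ph$scale * b^params$ph$exponent * exp(eff$ph[gi]),
        MCV = anchor_value(params$color$MCV[[trt]], use_dats) + eff$mcv[gi],
        r2g = anchor_value(params$color$r2g[[trt]], use_dats) *
          exp(eff$r2g[gi]),
        y2g = anchor_value(params$color$y2g[[trt]], use_dats) *
          exp(eff$y2g[gi]),
        PhiPSIIh = anchor_value(params$color$PhiPSIIh[[trt]], use_dats) +
          eff$psii[gi],
        PhiPSIIl = anchor_value(params$color$PhiPSIIl[[trt]], use_dats) +
          eff$psii[gi]
      )
    }
    ee <- exp_eff[plants$experiment, tr]
    ge <- gxe[[tr]][cbind(match(plants$genotype, ids),
                          match(plants$experiment, exps),
                          match(plants$treatment, design$treatments))]
    shift <- matrix(ee + ge, np, nu)
    value <- if (tr %in% c("EB", "PH", "r2g", "y2g")) {
      det * exp(shift + resid) # multiplicative, stays positive
    } else {
      pmin(1, pmax(0, det + shift + resid))
    }
    long <- tibble::tibble(
      genotype = rep(plants$genotype, nu),
      experiment = rep(plants$experiment, nu),
      replicate = rep(plants$replicate, nu),
      treatment = rep(plants$treatment, nu),
      dat = rep(use_dats, each = np),
      trait = tr,
      value = as.vector(value)
    )
    rows[[k]] <- long
  }
  trait_tab <- dplyr::bind_rows(rows)

  # excluded DATs are emitted as missing ----------------------------------
  for (e in names(tl$excluded_dats)) {
    bad <- trait_tab$experiment == e & trait_tab$dat %in% tl$excluded_dats[[e]]
    trait_tab$value[bad] <- NA_real_
  }

  watering <- simulate_watering(design, params, eff, traj, plants,
                                calibration)

  truth <- list(effects = eff, trajectories = traj,
                h2_eb = true_h2_eb(design, params, traj),
                superior = superior, design = design, params = params)
  structure(list(traits = trait_tab, watering = watering, truth = truth),
            class = "pd_simulation")
}

#' @export
print.pd_simulation <- function(x, ...) {
  cat("<pd_simulation>", nrow(x$traits), "trait records,",
      nrow(x$watering), "watering records,",
      nrow(x$truth$effects), "genotypes\n")
  invisible(x)
}

# closed-loop daily watering for every plant
simulate_watering <- function(design, params, eff, traj, plants,
                              calibration) {
  tl <- design$timeline
  dats <- tl$first_dat:tl$last_dat
  range_g <- calibration$weight_at_field_capacity -
    calibration$weight_at_wilting_point
  wp <- calibration$weight_at_wilting_point
  np <- nrow(plants)
  gi <- match(plants$genotype, eff$genotype)
  dt_end <- tl$rewater_step1 - 1L
  w_axis_dt <- ifelse(plants$treatment == "control",
                      eff$w_ctrl_dt[gi], eff$w_drt_dt[gi])
  w_axis_dr <- ifelse(plants$treatment == "control",
                      eff$w_ctrl_dr[gi], eff$w_drt_dr[gi])
  noise <- matrix(0, np, length(dats))
  for (j in seq_len(np)) {
    noise[j, ] <- with_substream(
      design$seed, paste0("water_", plants$plant_id[j]),
      stats::rnorm(length(dats), sd = params$noise$water))
  }
  targets <- lapply(design$treatments, function(trt) {
    lapply(dats, target_paw, treatment = trt, timeline = tl)
  })
  names(targets) <- design$treatments

  W <- rep(0.70 * range_g, np)
  out <- vector("list", length(dats))
  for (i in seq_along(dats)) {
    t <- dats[i]
    weight_before <- wp + W
    water <- numeric(np)
    for (trt in design$treatments) {
      sel <- plants$treatment == trt
      water[sel] <- water_to_target(weight_before[sel],
                                    targets[[trt]][[i]], calibration)
    }
    W <- W + water
    paw_after <- 100 * W / range_g
    b_det <- numeric(np)
    for (trt in design$treatments) {
      sel <- plants$treatment == trt
      b_det[sel] <- traj[[trt]][cbind(gi[sel], i)]
    }
    axis <- if (t <= dt_end) w_axis_dt else w_axis_dr
    loss <- exp(axis + noise[, i]) *
      (params$watering$evap + params$watering$transp * scale_eb(b_det)) *
      pmin(1, paw_after / params$watering$paw_close)^params$watering$beta
    out[[i]] <- tibble::tibble(
      plant_id = plants$plant_id, genotype = plants$genotype,
      experiment = plants$experiment, replicate = plants$replicate,
      treatment = plants$treatment, dat = t,
      weight_before = weight_before, weight_after = weight_before + water,
      water_added = water, paw_before = paw_from_weight(weight_before,
                                                        calibration)
    )
    W <- pmax(0, W - loss)
  }
  dplyr::bind_rows(out)
}

# true broad-sense heritability of EB per DAT/treatment on the log scale,
# from the deterministic genotype trajectories and the noise parameters
true_h2_eb <- function(design, params, traj) {
  v_gxe <- params$noise$gxe_eb^2
  v_e <- params$noise$resid_eb^2
  out <- list()
  for (trt in names(traj)) {
    v_g <- apply(log(traj[[trt]]), 2, stats::var)
    h2 <- vapply(v_g, function(vg) {
      heritability(variance_components(vg, v_gxe, v_e,
                                       design$n_experiments, design$n_reps))
    }, numeric(1))
    out[[trt]] <- tibble::tibble(treatment = trt,
                                 dat = as.integer(names(v_g)),
                                 v_g = v_g, v_gxe = v_gxe, v_e = v_e,
                                 h2 = h2)
  }
  dplyr::bind_rows(out)
}

#' Simulate one DAT slice under the exact variance-component model
#'
#' Draws `value = mean + g + e + ge + resid` with independent Gaussian
#' genotype, experiment, interaction and residual effects: the linear model
#' whose variance components [fit_variance_components()] estimates. Used
#' for parameter-recovery and outlier-screening checks where the true
#' heritability must be known exactly.
#'
#' @param n_genotypes,n_experiments,n_reps Design counts.
#' @param mean Grand mean.
#' @param sd_g,sd_exp,sd_gxe,sd_resid Standard deviations of the effects.
#' @param dat,treatment,trait Labels for the emitted records.
#' @param seed Seed for this slice.
#' @return A tibble in the long trait-record format, with attribute
#'   `true_h2`.
#' @export
simulate_trait_slice <- function(n_genotypes = 60L, n_experiments = 2L,
                                 n_reps = 2L, mean = 10,
                                 sd_g = 2, sd_exp = 0.5, sd_gxe = 1,
                                 sd_resid = 1, dat = 1L,
                                 treatment = "control", trait = "EB",
                                 seed = 1L) {
  set.seed(seed)
  ids <- sprintf("G%03d", seq_len(n_genotypes))
  exps <- sprintf("E%d", seq_len(n_experiments))
  reps <- sprintf("R%d", seq_len(n_reps))
  g <- stats::rnorm(n_genotypes, sd = sd_g)
  e <- stats::rnorm(n_experiments, sd = sd_exp)
  ge <- matrix(stats::rnorm(n_genotypes * n_experiments, sd = sd_gxe),
               n_genotypes, n_experiments)
  grid <- expand.grid(genotype = seq_len(n_genotypes),
                      experiment = seq_len(n_experiments),
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE)
  value <- mean + g[grid$genotype] + e[grid$experiment] +
    ge[cbind(grid$genotype, grid$experiment)] +
    stats::rnorm(nrow(grid), sd = sd_resid)
  out <- tibble::tibble(
    genotype = ids[grid$genotype], experiment = exps[grid$experiment],
    replicate = reps[grid$replicate], treatment = treatment,
    dat = as.integer(dat), trait = trait, value = value
  )
  vc <- variance_components(sd_g^2, sd_gxe^2, sd_resid^2,
                            n_experiments, n_reps)
  attr(out, "true_h2") <- heritability(vc)
  out
}

#' Plant gross outliers into a trait slice
#'
#' Displaces a random subset of observations by a fixed multiple of the
#' residual standard deviation (random sign), returning the contaminated
#' records and the planted row indices -- the oracle for outlier-screening
#' sensitivity checks.
#'
#' @param records A long trait-record tibble.
#' @param rate Contamination rate (fraction of rows).
#' @param size Displacement in residual standard deviations.
#' @param sd_resid Residual standard deviation of the clean data.
#' @param seed Seed for the contamination draw.
#' @return A list with `records` and integer `planted` row indices.
#' @export
plant_outliers <- function(records, rate = 0.01, size = 10, sd_resid = 1,
                           seed = 1L) {
  set.seed(seed)
  n <- nrow(records)
  n_bad <- max(1L, round(rate * n))
  planted <- sort(sample.int(n, n_bad))
  sign <- sample(c(-1, 1), n_bad, replace = TRUE)
  records$value[planted] <- records$value[planted] + sign * size * sd_resid
  list(records = records, planted = planted)
}

#' Render a multi-view plant image set with known ground truth
#'
#' Draws a rectangular canopy in the top view and three identical
#' rectangular silhouettes in the side views on a uniform gray background,
#' such that the silhouette areas reproduce the requested biovolume under
#' the `mean side area * sqrt(top area)` rule up to pixel quantization, the
#' side extent reproduces the requested height, and the top-view pixel hue
#' classes reproduce the requested colour ratios and mean hue. The exact
#' achieved values (from the integer pixel counts actually rendered) are
#' returned as ground truth.
#'
#' @param eb Requested biovolume (pixel-voxel units).
#' @param ph_mm Requested plant height in mm.
#' @param mcv Requested mean hue in `[0, 1]` (achievable exactly only when
#'   the implied green hue stays inside the green class).
#' @param r2g,y2g Requested red-to-green and yellow-to-green count ratios.
#' @param canvas Height and width of each view in pixels.
#' @param mm_per_pixel Side-camera scale.
#' @param background_gray Background intensity in `[0, 1]` (saturation 0).
#' @param plant_id,dat Labels for the returned [image_set()].
#' @return A list with `images` (a `pd_image_set`) and `truth` (one-row
#'   tibble of achieved eb, ph, mcv, r2g, y2g and the exact pixel counts).
#' @export
render_plant_images <- function(eb, ph_mm, mcv = 0.23, r2g = 0, y2g = 0,
                                canvas = c(200L, 200L), mm_per_pixel = 1,
                                background_gray = 0.5,
                                plant_id = "plant", dat = 1L) {
  stopifnot(eb > 0, ph_mm > 0, r2g >= 0, y2g >= 0)
  h_can <- canvas[1]; w_can <- canvas[2]
  ph_px <- max(1L, round(ph_mm / mm_per_pixel))
  if (ph_px > h_can) {
    stop("requested height exceeds the canvas", call. = FALSE)
  }
  # split the biovolume into a top area t and side area s with s = e/sqrt(t);
  # a near-cubic split keeps both areas of similar magnitude, and the top
  # rectangle is re-solved after the side width is quantized so the achieved
  # biovolume stays within ~1% of the request
  t_target <- max(4, round(eb^(2 / 3)))
  s_target <- eb / sqrt(t_target)
  w_side <- max(1L, round(s_target / ph_px))
  if (w_side > w_can) stop("side silhouette exceeds the canvas",
                           call. = FALSE)
  s_area <- w_side * ph_px
  t_target <- max(4, round((eb / s_area)^2))
  a <- max(2L, floor(sqrt(t_target)))
  b <- max(2L, round(t_target / a))
  if (a > h_can || b > w_can) stop("top canopy exceeds the canvas",
                                   call. = FALSE)
  t_area <- a * b

  # integer pixel counts for the colour classes
  n_green <- max(1L, round(t_area / (1 + r2g + y2g)))
  n_red <- round(r2g * n_green)
  n_yellow <- round(y2g * n_green)
  n_green <- t_area - n_red - n_yellow
  if (n_green < 1) stop("colour ratios leave no green pixels", call. = FALSE)

  hue_red <- 10 / 360; hue_yellow <- 50 / 360
  hue_green <- (mcv * t_area - n_red * hue_red - n_yellow * hue_yellow) /
    n_green
  hue_green <- min(164 / 360, max(76 / 360, hue_green))
  mcv_true <- (n_red * hue_red + n_yellow * hue_yellow +
                 n_green * hue_green) / t_area

  blank <- function() {
    arr <- array(background_gray, c(h_can, w_can, 3))
    arr
  }
  paint <- function(arr, rows, cols, hue) {
    rgb <- grDevices::col2rgb(grDevices::hsv(hue, 1, 0.9)) / 255
    for (ch in 1:3) arr[rows, cols, ch] <- rgb[ch]
    arr
  }
  # top view: rectangle a x b, red then yellow pixels first in column order
  top <- blank()
  r0 <- floor((h_can - a) / 2); c0 <- floor((w_can - b) / 2)
  top <- paint(top, r0 + seq_len(a), c0 + seq_len(b), hue_green)
  idx <- cbind(rep(r0 + seq_len(a), b), rep(c0 + seq_len(b), each = a))
  recolor <- function(arr, which_idx, hue) {
    rgb <- grDevices::col2rgb(grDevices::hsv(hue, 1, 0.9)) / 255
    for (ch in 1:3) {
      arr[cbind(which_idx, ch)] <- rgb[ch]
    }
    arr
  }
  if (n_red > 0) top <- recolor(top, idx[seq_len(n_red), , drop = FALSE],
                                hue_red)
  if (n_yellow > 0) {
    top <- recolor(top, idx[n_red + seq_len(n_yellow), , drop = FALSE],
                   hue_yellow)
  }
  # side views: w_side x ph_px green rectangle sitting on the bottom edge
  side <- blank()
  rows <- (h_can - ph_px + 1):h_can
  cols <- floor((w_can - w_side) / 2) + seq_len(w_side)
  side <- paint(side, rows, cols, hue_green)

  imgs <- image_set(top, list(side, side, side),
                    mm_per_pixel_side = mm_per_pixel,
                    mm_per_pixel_top = mm_per_pixel,
                    plant_id = plant_id, dat = dat)
  truth <- tibble::tibble(
    plant_id = plant_id, dat = as.integer(dat),
    eb = s_area * sqrt(t_area), ph = ph_px * mm_per_pixel,
    mcv = mcv_true,
    r2g = n_red / n_green, y2g = n_yellow / n_green,
    top_area = t_area, side_area = s_area,
    n_red = n_red, n_yellow = n_yellow, n_green = n_green
  )
  list(images = imgs, truth = truth)
}

#' Write a simulation bundle to disk
#'
#' Emits `traits.csv`, `watering.csv`, `ground_truth.csv` (genotype
#' effects) and a `manifest.yaml` recording design counts and the seed.
#'
#' @param sim A `pd_simulation` from [simulate_traits()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pd_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trait_table(sim$traits, file.path(dir, "traits.csv"))
  write_watering_table(sim$watering, file.path(dir, "watering.csv"))
  utils::write.csv(sim$truth$effects, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  d <- sim$truth$design
  yaml::write_yaml(list(
    design = list(n_genotypes = d$n_genotypes,
                  n_experiments = d$n_experiments, n_reps = d$n_reps,
                  treatments = d$treatments, seed = d$seed),
    superior = as.list(sim$truth$superior)
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
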
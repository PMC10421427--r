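#' Variance components of a genotype x experiment design
#'
#' Container for the genotype, genotype-x-experiment and residual variance
#' components plus the design counts entering the heritability formula.
#' Negative inputs are truncated at zero and flagged.
#'
#' @param v_g,v_gxe,v_e Variance components (genotype, interaction,
#'   residual).
#' @param num_exp,num_rep Number of experiments and of biological
#'   replicates per experiment.
#' @return An object of class `pd_variance_components` with a `clipped`
#'   attribute naming any truncated component.
#' @export
variance_components <- function(v_g, v_gxe, v_e, num_exp, num_rep) {
  raw <- c(v_g = unname(v_g), v_gxe = unname(v_gxe), v_e = unname(v_e))
  clipped <- names(raw)[raw < 0]
  raw[raw < 0] <- 0
  structure(
    list(v_g = raw[["v_g"]], v_gxe = raw[["v_gxe"]], v_e = raw[["v_e"]],
         num_exp = as.integer(num_exp), num_rep = as.integer(num_rep)),
    clipped = clipped,
    class = "pd_variance_components"
  )
}

#' @export
print.pd_variance_components <- function(x, ...) {
  cat(sprintf("<variance components> v_g=%.4g v_gxe=%.4g v_e=%.4g (%d exp, %d rep)\n",
              x$v_g, x$v_gxe, x$v_e, x$num_exp, x$num_rep))
  invisible(x)
}

#' Broad-sense heritability
#'
#' `H2 = v_g / (v_g + v_gxe / numExp + v_e / (numRep * numExp))`, the
#' entry-mean heritability of a genotype tested in `numExp` experiments
#' with `numRep` replicates each.
#'
#' @param vc A [variance_components()] object.
#' @return H2 in `[0, 1]`, or `NA` when all components are zero.
#' @export
#' @examples
#' heritability(variance_components(2, 1, 2, 2, 2)) # 2/3
heritability <- function(vc) {
  stopifnot(inherits(vc, "pd_variance_components"))
  denom <- vc$v_g + vc$v_gxe / vc$num_exp + vc$v_e / (vc$num_rep * vc$num_exp)
  if (denom == 0) return(NA_real_)
  vc$v_g / denom
}

# single-DAT slice sanity checks shared by the model fitters
check_slice <- function(records) {
  need <- c("genotype", "experiment", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("slice missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records[!is.na(records$value), , drop = FALSE]
}

is_balanced_slice <- function(records) {
  tab <- table(records$genotype, records$experiment)
  length(tab) > 0 && min(tab) == max(tab) && min(tab) >= 1
}

#' Variance components of one DAT/treatment slice
#'
#' Estimates the genotype, genotype-x-experiment and residual variances of
#' a replicated two-experiment slice with genotype, experiment and their
#' interaction as random effects: by REML (lme4) or by the balanced-design
#' expected-mean-squares closed form (the two agree on balanced data).
#' Negative estimates are truncated at zero and flagged.
#'
#' @param records One DAT/treatment slice of the long trait table.
#' @param method `"reml"` (default) or `"ems"` (balanced closed form; the
#'   independent cross-check).
#' @return A [variance_components()] object.
#' @export
fit_variance_components <- function(records, method = c("reml", "ems")) {
  method <- match.arg(method)
  records <- check_slice(records)
  num_exp <- length(unique(records$experiment))
  tab <- table(records$genotype, records$experiment)
  num_rep <- round(stats::median(tab))
  if (num_exp < 2) {
    warning("single experiment: v_gxe undefined, returned 0", call. = FALSE)
    agg <- stats::aggregate(value ~ genotype, records, mean)
    v_e <- mean(tapply(records$value, records$genotype, stats::var),
                na.rm = TRUE)
    v_g <- stats::var(agg$value) - v_e / max(1, num_rep)
    return(variance_components(v_g, 0, max(0, v_e), 1, num_rep))
  }
  if (method == "ems") {
    return(ems_variance_components(records))
  }
  # a (near-)zero residual stratum breaks the profiled REML optimisation;
  # the closed form is exact there for balanced slices
  cell <- interaction(records$genotype, records$experiment, drop = TRUE)
  within_var <- stats::ave(records$value, cell,
                           FUN = function(v) v - mean(v))
  if (is_balanced_slice(records) &&
      sum(within_var^2) <= 1e-12 * max(1, stats::var(records$value))) {
    return(ems_variance_components(records))
  }
  records$genotype <- factor(records$genotype)
  records$experiment <- factor(records$experiment)
  fit <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | genotype) + (1 | experiment) + (1 | genotype:experiment),
    data = records, REML = TRUE,
    control = lme4::lmerControl(
      check.conv.singular = "ignore",
      optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(name) vc$vcov[vc$grp == name]
  est <- c(g = pick("genotype"), e = pick("experiment"),
           ge = pick("genotype:experiment"), resid = pick("Residual"))
  # polish the derivative-free optimum with analytic-gradient AI-REML
  # iterations (Fisher scoring); lmer localises the optimum, the polish
  # sharpens it to ~1e-10 so the balanced case matches the closed form
  if (nrow(records) <= 1200) {
    est <- tryCatch(
      ai_reml_polish(records$value, records$genotype, records$experiment,
                     est),
      error = function(e) est)
  }
  variance_components(est[["g"]], est[["ge"]], est[["resid"]],
                      num_exp, num_rep)
}

# Average-information REML refinement for the model
# y = mu + genotype + experiment + genotype:experiment + resid.
# Newton-type iterations on the REML log-likelihood with the average-
# information approximation to the Hessian; components proposed negative
# are pinned to zero (active-set handling).
ai_reml_polish <- function(y, g, e, start, max_iter = 40, tol = 1e-10) {
  n <- length(y)
  sc <- stats::var(y)
  if (sc == 0) return(start)
  y <- y / sqrt(sc)
  theta <- pmax(unlist(start) / sc, 0)
  Zg <- stats::model.matrix(~ 0 + g)
  Ze <- stats::model.matrix(~ 0 + e)
  Zge <- stats::model.matrix(~ 0 + g:e)
  A <- list(g = tcrossprod(Zg), e = tcrossprod(Ze), ge = tcrossprod(Zge),
            resid = diag(n))
  X <- matrix(1, n, 1)
  pinned <- theta <= 1e-12
  for (iter in seq_len(max_iter)) {
    V <- theta[1] * A$g + theta[2] * A$e + theta[3] * A$ge +
      max(theta[4], 1e-10) * A$resid
    Vi <- tryCatch(chol2inv(chol(V)), error = function(err) NULL)
    if (is.null(Vi)) break
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    Py <- P %*% y
    grad <- vapply(A, function(Ai) {
      -0.5 * (sum(P * Ai) - drop(crossprod(Py, Ai %*% Py)))
    }, numeric(1))
    free <- !pinned | grad > 0
    if (!any(free)) break
    PAy <- lapply(A, function(Ai) P %*% (Ai %*% Py))
    ai <- matrix(0, 4, 4)
    for (i in 1:4) {
      for (j in i:4) {
        ai[i, j] <- ai[j, i] <- 0.5 * drop(crossprod(PAy[[i]],
                                                     A[[j]] %*% Py))
      }
    }
    step <- rep(0, 4)
    sol <- tryCatch(solve(ai[free, free, drop = FALSE], grad[free]),
                    error = function(err) NULL)
    if (is.null(sol)) break
    step[free] <- sol
    new_theta <- theta + step
    # damp steps that overshoot the boundary
    fac <- 1
    while (any(new_theta < -1e-12) && fac > 1e-4) {
      fac <- fac / 2
      new_theta <- theta + fac * step
    }
    new_theta <- pmax(new_theta, 0)
    pinned <- new_theta <= 1e-12
    moved <- max(abs(new_theta - theta))
    theta <- new_theta
    if (moved < tol && max(abs(grad[free])) < 1e-8) break
  }
  out <- theta * sc
  names(out) <- names(start)
  out
}

#' Balanced-design ANOVA (expected mean squares) variance components
#'
#' Closed-form method-of-moments estimators for the two-way random model
#' with replication: `sigma2_e = MSE`, `sigma2_gxe = (MS_GxE - MSE) / r`,
#' `sigma2_g = (MS_G - MS_GxE) / (r * e)`, with the experiment main
#' variance estimated alongside. Because REML constrains every component
#' to be non-negative, a negative unconstrained estimator is handled by
#' re-solving the reduced model with that component removed (experiment
#' and interaction sums of squares pool into the next stratum), which is
#' the exact constrained solution for a balanced layout. Requires a
#' balanced slice.
#'
#' @param records A balanced single-DAT slice.
#' @return A [variance_components()] object.
#' @export
ems_variance_components <- function(records) {
  records <- check_slice(records)
  if (!is_balanced_slice(records)) {
    stop("EMS closed form requires a balanced slice", call. = FALSE)
  }
  g <- factor(records$genotype)
  e <- factor(records$experiment)
  n_g <- nlevels(g); n_e <- nlevels(e)
  r <- nrow(records) / (n_g * n_e)
  y <- records$value
  grand <- mean(y)
  mg <- tapply(y, g, mean)
  me <- tapply(y, e, mean)
  mge <- tapply(y, list(g, e), mean)
  ss_g <- r * n_e * sum((mg - grand)^2)
  ss_e <- r * n_g * sum((me - grand)^2)
  ss_ge <- r * sum((mge - outer(mg, rep(1, n_e)) -
                      outer(rep(1, n_g), me) + grand)^2)
  ss_resid <- sum((y - mge[cbind(g, e)])^2)
  df_g <- n_g - 1
  df_e <- n_e - 1
  df_ge <- (n_g - 1) * (n_e - 1)
  df_resid <- n_g * n_e * (r - 1)
  ms_g <- ss_g / df_g
  ms_e <- ss_e / df_e
  ms_ge <- ss_ge / df_ge
  mse <- if (df_resid > 0) ss_resid / df_resid else 0

  v_e_hat <- mse
  v_ge_hat <- (ms_ge - mse) / r
  v_g_hat <- (ms_g - ms_ge) / (r * n_e)
  v_exp_hat <- (ms_e - ms_ge) / (r * n_g)

  if (v_exp_hat < 0) {
    # experiment variance on the boundary: its stratum pools with the
    # interaction (cells within genotype), a balanced nested layout
    ms_cell <- (ss_e + ss_ge) / (df_e + df_ge)
    v_ge_hat <- (ms_cell - mse) / r
    v_g_hat <- (ms_g - ms_cell) / (r * n_e)
    if (v_ge_hat < 0) {
      # interaction also on the boundary: cells pool into the residual
      v_e_hat <- (ss_e + ss_ge + ss_resid) / (df_e + df_ge + df_resid)
      v_ge_hat <- 0
      v_g_hat <- (ms_g - v_e_hat) / (r * n_e)
    }
  } else if (v_ge_hat < 0) {
    # interaction on the boundary with experiment retained
    v_e_hat <- (ss_ge + ss_resid) / (df_ge + df_resid)
    v_ge_hat <- 0
    v_g_hat <- (ms_g - v_e_hat) / (r * n_e)
    v_exp_hat <- (ms_e - v_e_hat) / (r * n_g)
    if (v_exp_hat < 0) {
      v_e_hat <- (ss_e + ss_ge + ss_resid) / (df_e + df_ge + df_resid)
      v_g_hat <- (ms_g - v_e_hat) / (r * n_e)
    }
  }
  variance_components(v_g_hat, v_ge_hat, v_e_hat, n_e, r)
}

# the outlier/BLUE mixed model: genotype fixed, experiment and genotype x
# experiment random
fit_blue_model <- function(records) {
  records$genotype <- factor(records$genotype)
  records$experiment <- factor(records$experiment)
  suppressMessages(lme4::lmer(
    value ~ 0 + genotype + (1 | experiment) + (1 | genotype:experiment),
    data = records, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.conv.grad = "ignore",
                                check.conv.hess = "ignore",
                                calc.derivs = FALSE)))
}

#' Mixed-model outlier screening
#'
#' For every DAT x treatment x trait slice, fits the model with genotype as
#' a fixed effect and experiment and genotype-x-experiment as random
#' effects, and flags observations whose absolute standardized conditional
#' residual exceeds `threshold`. Applied once, without iterative
#' re-fitting. A slice with no residual degrees of freedom yields no flags
#' (with a warning).
#'
#' @param records Long trait table (`genotype`, `experiment`, `replicate`,
#'   `treatment`, `dat`, `trait`, `value`).
#' @param threshold Absolute standardized-residual cut-off (default 3).
#' @return A tibble of flags: one row per non-missing observation with its
#'   `standardized_residual` and logical `flagged`.
#' @export
detect_outliers <- function(records, threshold = 3) {
  keep <- !is.na(records$value)
  rec <- records[keep, , drop = FALSE]
  rec$.row <- which(keep)
  groups <- split(rec,
                  interaction(rec$trait, rec$treatment, rec$dat, drop = TRUE))
  out <- lapply(groups, function(slice) {
    res <- rep(NA_real_, nrow(slice))
    n_geno <- length(unique(slice$genotype))
    if (nrow(slice) > n_geno + 1 && is.finite(threshold)) {
      fit <- try(fit_blue_model(slice), silent = TRUE)
      if (!inherits(fit, "try-error") && stats::sigma(fit) > 0) {
        res <- stats::resid(fit) / stats::sigma(fit)
      } else {
        warning("singular fit in slice: no outlier flags", call. = FALSE)
      }
    } else if (nrow(slice) <= n_geno + 1) {
      warning("no residual degrees of freedom in slice: no flags",
              call. = FALSE)
    }
    if (all(is.na(res))) res[] <- 0
    if (stats::sd(slice$value) == 0) res[] <- 0 # constant slice: no flags
    tibble::tibble(
      row = slice$.row,
      plant_id = paste(slice$genotype, slice$experiment, slice$replicate,
                       slice$treatment, sep = "_"),
      genotype = slice$genotype, experiment = slice$experiment,
      replicate = slice$replicate, treatment = slice$treatment,
      dat = slice$dat, trait = slice$trait,
      standardized_residual = as.numeric(res),
      flagged = abs(as.numeric(res)) > threshold
    )
  })
  res <- dplyr::bind_rows(out)
  res[order(res$row), , drop = FALSE]
}

#' Remove flagged observations from a trait table
#'
#' @param records Long trait table.
#' @param flags Output of [detect_outliers()].
#' @return `records` with flagged rows removed.
#' @export
remove_outliers <- function(records, flags) {
  bad <- flags$row[flags$flagged]
  if (length(bad)) records[-bad, , drop = FALSE] else records
}

#' Genotype BLUEs for one or more DAT/treatment slices
#'
#' Per-genotype fixed-effect estimates under the model with genotype fixed
#' and experiment and genotype-x-experiment random. For a fully balanced
#' slice the generalized-least-squares solution equals the plain genotype
#' mean whatever the variance components, and that exact shortcut is used;
#' unbalanced slices (e.g. after outlier removal) are fitted by REML.
#'
#' @param records Long trait table (one or several traits/DATs).
#' @param method `"auto"` (balanced shortcut where exact, REML otherwise),
#'   `"reml"` (always fit), or `"means"` (always plain means).
#' @return A tibble with one row per genotype x DAT x treatment x trait:
#'   `blue`, `se`, `n_obs`.
#' @export
compute_blues <- function(records, method = c("auto", "reml", "means")) {
  method <- match.arg(method)
  rec <- records[!is.na(records$value), , drop = FALSE]
  groups <- split(rec,
                  interaction(rec$trait, rec$treatment, rec$dat, drop = TRUE))
  out <- lapply(groups, function(slice) {
    balanced <- is_balanced_slice(slice)
    use_means <- switch(method,
                        auto = balanced || length(unique(slice$experiment)) < 2,
                        reml = FALSE,
                        means = TRUE)
    if (use_means) {
      agg <- dplyr::summarise(
        dplyr::group_by(slice, .data$genotype),
        blue = mean(.data$value),
        se = stats::sd(.data$value) / sqrt(dplyr::n()),
        n_obs = dplyr::n(), .groups = "drop")
    } else {
      fit <- fit_blue_model(slice)
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      geno <- sub("^genotype", "", names(cf))
      n_obs <- table(slice$genotype)[geno]
      agg <- tibble::tibble(genotype = geno, blue = as.numeric(cf),
                            se = as.numeric(se),
                            n_obs = as.integer(n_obs))
    }
    agg$dat <- slice$dat[1]
    agg$treatment <- slice$treatment[1]
    agg$trait <- slice$trait[1]
    agg
  })
  res <- dplyr::bind_rows(out)
  res <- res[, c("genotype", "trait", "treatment", "dat", "blue", "se",
                 "n_obs")]
  res[order(res$trait, res$treatment, res$dat, res$genotype), ]
}

#' Per-DAT heritability table
#'
#' Variance components and broad-sense heritability for every trait x
#' treatment x DAT slice of a long trait table.
#'
#' @param records Long trait table.
#' @param method Passed to [fit_variance_components()].
#' @return A tibble: `trait`, `treatment`, `dat`, `v_g`, `v_gxe`, `v_e`,
#'   `h2`.
#' @export
heritability_table <- function(records, method = "reml") {
  rec <- records[!is.na(records$value), , drop = FALSE]
  groups <- split(rec,
                  interaction(rec$trait, rec$treatment, rec$dat, drop = TRUE))
  out <- lapply(groups, function(slice) {
    vc <- fit_variance_components(slice, method = method)
    tibble::tibble(trait = slice$trait[1], treatment = slice$treatment[1],
                   dat = slice$dat[1], v_g = vc$v_g, v_gxe = vc$v_gxe,
                   v_e = vc$v_e, h2 = heritability(vc))
  })
  res <- dplyr::bind_rows(out)
  res[order(res$trait, res$treatment, res$dat), ]
}
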
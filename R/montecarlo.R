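# Monte Carlo propagation of measurement and fit uncertainty to tie-line
# endpoints and volume ratios. Each iteration perturbs the selected inputs
# (balance noise on the top-phase mass, pipetting noise on the average
# composition, and/or parameter draws from the binodal / conjugate fit
# covariances), re-runs the deterministic solver, and aggregates.

#' Noise model for Monte Carlo resampling
#'
#' @param sigma_top_mass Gaussian sd of the top-phase mass, mg.
#' @param sigma_avg_comp Gaussian sd applied independently to the average
#'   PEG and dextran concentrations, wt\%.
#' @param resample_binodal Draw binodal parameters from the fit's
#'   multivariate-normal covariance each iteration?
#' @param resample_conjugate Draw conjugate-curve coefficients from their
#'   fit covariance (only used by [mc_interpolated()])?
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(sigma_top_mass = 2, sigma_avg_comp = 0.05,
                        resample_binodal = TRUE, resample_conjugate = TRUE) {
  stopifnot(sigma_top_mass >= 0, sigma_avg_comp >= 0)
  structure(list(sigma_top_mass = sigma_top_mass,
                 sigma_avg_comp = sigma_avg_comp,
                 resample_binodal = isTRUE(resample_binodal),
                 resample_conjugate = isTRUE(resample_conjugate)),
            class = "noise_model")
}

draw_binodal <- function(binodal_fit, resample) {
  base <- binodal_fit$params
  vc <- binodal_fit$vcov
  if (!resample || is.null(vc) || !all(is.finite(vc)))
    return(function() base)
  mu <- base$par
  spec <- binodal_forms[[base$form]]
  function() {
    p <- MASS::mvrnorm(1, mu = mu, Sigma = vc)
    p <- pmin(pmax(p, spec$lower + 1e-10), spec$upper)
    out <- base
    out$par <- p
    out
  }
}

draw_conjugate <- function(conj, resample) {
  if (!resample || is.null(conj$model)) return(function() conj)
  mu <- c(conj$q0, conj$q1, conj$q2)
  vc <- tryCatch(stats::vcov(conj$model), error = function(e) NULL)
  if (is.null(vc) || nrow(vc) != 3L || !all(is.finite(vc)))
    return(function() conj)
  function() {
    q <- MASS::mvrnorm(1, mu = mu, Sigma = vc)
    out <- conj
    out$q0 <- q[1]; out$q1 <- q[2]; out$q2 <- q[3]
    out
  }
}

mc_quantities <- function(tl, rho) {
  c(top_peg = tl$top$peg, top_dex = tl$top$dex,
    bottom_peg = tl$bottom$peg, bottom_dex = tl$bottom$dex,
    f_top = {
      f <- attr(tl, "f_top"); if (is.null(f)) lever_fraction(tl) else f
    },
    volume_ratio = volume_ratio(tl, rho))
}

summarize_mc <- function(draws, n_iter, n_failed) {
  m <- do.call(rbind, draws)
  summ <- data.frame(
    quantity = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    lo95 = apply(m, 2, stats::quantile, probs = 0.025, names = FALSE),
    hi95 = apply(m, 2, stats::quantile, probs = 0.975, names = FALSE),
    row.names = NULL)
  structure(list(summary = summ, n_iter = n_iter, n_failed = n_failed,
                 draws = m),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<Monte Carlo summary> %d iterations (%d failed and dropped)\n",
              x$n_iter, x$n_failed))
  print(x$summary, digits = 5)
  invisible(x)
}

run_mc <- function(n_iter, seed, iterate, max_fail_frac = 0.2) {
  stopifnot(n_iter >= 1)
  draws <- withr_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      tryCatch(iterate(), error = function(e) NULL)
    })
  })
  failed <- vapply(draws, is.null, logical(1))
  if (mean(failed) > max_fail_frac)
    stop(sprintf(paste0("%.0f%% of Monte Carlo iterations failed to solve; ",
                        "the noise model is inconsistent with the phase ",
                        "diagram"), 100 * mean(failed)), call. = FALSE)
  if (all(failed)) stop("all Monte Carlo iterations failed", call. = FALSE)
  summarize_mc(draws[!failed], n_iter, sum(failed))
}

#' Monte Carlo uncertainty of a solved tie-line
#'
#' Perturbs the gravimetric inputs (and optionally the binodal parameters)
#' per the noise model, re-runs [solve_tieline()] and [volume_ratio()] each
#' iteration, and summarizes endpoint compositions, the top-phase mass
#' fraction and the volume ratio. Iterations whose solve fails are dropped
#' and counted; more than 20\% failures is an error. Deterministic for a
#' fixed seed.
#'
#' @param exp A [gravimetric_experiment()].
#' @param binodal_fit A [fit_binodal()] result (its covariance feeds the
#'   binodal resampling), or bare [binodal_params()] (no resampling).
#' @param noise A [noise_model()].
#' @param n_iter Number of iterations (default 10000).
#' @param seed RNG seed.
#' @param rho [phase_densities()] for the volume ratio.
#' @return An object of class `"mc_summary"`: a `summary` data.frame with
#'   per-quantity mean, sd and central 95\% interval, plus `n_iter`,
#'   `n_failed` and the raw `draws` matrix.
#' @export
mc_tielines <- function(exp, binodal_fit, noise = noise_model(),
                        n_iter = 10000L, seed = 1L,
                        rho = phase_densities()) {
  stopifnot(inherits(exp, "gravimetric_experiment"),
            inherits(noise, "noise_model"))
  if (inherits(binodal_fit, "binodal_params"))
    binodal_fit <- list(params = binodal_fit, vcov = NULL)
  # the unperturbed solve must work before we propagate noise through it
  solve_tieline(exp, binodal_fit$params)
  next_binodal <- draw_binodal(binodal_fit, noise$resample_binodal)
  run_mc(n_iter, seed, function() {
    tm <- exp$top_mass + stats::rnorm(1, 0, noise$sigma_top_mass)
    avg <- composition(
      max(exp$avg$dex + stats::rnorm(1, 0, noise$sigma_avg_comp), 1e-6),
      max(exp$avg$peg + stats::rnorm(1, 0, noise$sigma_avg_comp), 0))
    e <- gravimetric_experiment(exp$total_mass, avg, tm)
    tl <- solve_tieline(e, next_binodal())
    mc_quantities(tl, rho)
  })
}

#' Monte Carlo uncertainty of an interpolated tie-line
#'
#' As [mc_tielines()], but perturbing the binodal and conjugate-curve fits
#' (multivariate-normal draws from their covariances) and the target
#' composition, then re-running [interpolate_tieline()].
#'
#' @param target Target average composition.
#' @param binodal_fit A [fit_binodal()] result or [binodal_params()].
#' @param conj_fit A [fit_conjugate()] result.
#' @inheritParams mc_tielines
#' @return An `"mc_summary"` object.
#' @export
mc_interpolated <- function(target, binodal_fit, conj_fit,
                            noise = noise_model(), n_iter = 1000L,
                            seed = 1L, rho = phase_densities()) {
  stopifnot(inherits(conj_fit, "conjugate_curve"),
            inherits(noise, "noise_model"))
  if (inherits(binodal_fit, "binodal_params"))
    binodal_fit <- list(params = binodal_fit, vcov = NULL)
  target <- as_composition(target)
  suppressWarnings(
    interpolate_tieline(target, binodal_fit$params, conj_fit))
  next_binodal <- draw_binodal(binodal_fit, noise$resample_binodal)
  next_conj <- draw_conjugate(conj_fit, noise$resample_conjugate)
  run_mc(n_iter, seed, function() {
    tgt <- composition(
      max(target$dex + stats::rnorm(1, 0, noise$sigma_avg_comp), 1e-6),
      max(target$peg + stats::rnorm(1, 0, noise$sigma_avg_comp), 0))
    tl <- suppressWarnings(
      interpolate_tieline(tgt, next_binodal(), next_conj()))
    mc_quantities(tl, rho)
  })
}
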
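#' Construct a phase-diagram composition
#'
#' A composition is a point in the PEG-dextran phase diagram, expressed as
#' mass fractions of the two polymers in weight percent of the whole system
#' (polymers + buffer).
#'
#' @param dex Dextran concentration, wt\% (x-axis of the phase diagram).
#' @param peg PEG concentration, wt\% (y-axis).
#' @return An object of class `"atps_composition"`: a named list with
#'   elements `dex` and `peg`.
#' @examples
#' composition(dex = 6, peg = 5)
#' @export
composition <- function(dex, peg) {
  stopifnot(is.numeric(dex), is.numeric(peg), length(dex) == 1L,
            length(peg) == 1L)
  if (!is.finite(dex) || !is.finite(peg))
    stop("composition must be finite", call. = FALSE)
  if (dex < 0 || peg < 0)
    stop("polymer concentrations cannot be negative", call. = FALSE)
  if (dex + peg >= 100)
    stop("dex + peg must be < 100 wt% (the balance is buffer)", call. = FALSE)
  structure(list(dex = dex, peg = peg), class = "atps_composition")
}

#' @export
print.atps_composition <- function(x, ...) {
  cat(sprintf("<composition> dextran %.4g wt%%, PEG %.4g wt%%\n", x$dex, x$peg))
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "atps_composition")) return(x)
  if (is.numeric(x) && length(x) == 2L && !is.null(names(x)) &&
      all(c("dex", "peg") %in% names(x)))
    return(composition(x[["dex"]], x[["peg"]]))
  if (is.list(x) && all(c("dex", "peg") %in% names(x)))
    return(composition(x$dex, x$peg))
  stop("cannot interpret input as a composition; supply composition() or ",
       "a named vector c(dex = , peg = )", call. = FALSE)
}

# ---- binodal model forms ----------------------------------------------------
#
# The binodal is parametrized as y = f(x; theta) with x = dextran wt% and
# y = PEG wt%. The default form is the classic three-parameter exponential
# curve for polymer-polymer ATPS binodals augmented by an additive inverse
# term D/x so that the curve is asymptotic with the ordinate and never
# predicts negative polymer concentrations:
#
#   f(x) = A * exp(B * sqrt(x) - C * x^3) + D / x
#
# Alternate readings of the model can be registered through
# `binodal_custom()` without touching the downstream tie-line machinery.

binodal_forms <- list(
  exp_inverse = list(
    par_names = c("A", "B", "C", "D"),
    fn = function(x, p) p[["A"]] * exp(p[["B"]] * sqrt(x) - p[["C"]] * x^3) +
      p[["D"]] / x,
    lower = c(A = 1e-8, B = -Inf, C = 0, D = 0),
    upper = c(A = Inf, B = Inf, C = Inf, D = Inf)
  ),
  exp = list(
    par_names = c("A", "B", "C"),
    fn = function(x, p) p[["A"]] * exp(p[["B"]] * sqrt(x) - p[["C"]] * x^3),
    lower = c(A = 1e-8, B = -Inf, C = 0),
    upper = c(A = Inf, B = Inf, C = Inf)
  )
)

#' Binodal curve parameters
#'
#' Creates a parametrized binodal curve `y = f(x)` mapping dextran wt\% to
#' PEG wt\%. Two built-in forms are available:
#' \describe{
#'   \item{`"exp_inverse"` (default)}{`A*exp(B*sqrt(x) - C*x^3) + D/x`. The
#'     inverse term makes the curve asymptotic with the y-axis, so no
#'     negative PEG concentration is ever predicted at small dextran.}
#'   \item{`"exp"`}{the un-augmented three-parameter curve
#'     `A*exp(B*sqrt(x) - C*x^3)` (equivalent to `D = 0`).}
#' }
#'
#' @param A,B,C Coefficients of the exponential part. `A` has units of wt\%;
#'   `B` and `C` are in the reciprocal powers of wt\% implied by the form.
#' @param D Coefficient of the inverse term (wt\%^2); `0` disables it.
#' @param form `"exp_inverse"` or `"exp"`.
#' @return An object of class `"binodal_params"`.
#' @seealso [binodal_custom()], [eval_binodal()], [fit_binodal()]
#' @examples
#' b <- binodal_params(A = 10.7, B = -0.45, C = 2.6e-4, D = 0.5)
#' eval_binodal(b, c(1, 5, 15))
#' @export
binodal_params <- function(A, B, C, D = 0, form = "exp_inverse") {
  form <- match.arg(form, names(binodal_forms))
  p <- c(A = A, B = B, C = C)
  if (form == "exp_inverse") p <- c(p, D = D)
  if (!all(is.finite(p)))
    stop("binodal parameters must be finite", call. = FALSE)
  if (p[["A"]] <= 0)
    stop("A must be > 0 (the curve must stay positive)", call. = FALSE)
  structure(list(form = form, par = p, fn = NULL), class = "binodal_params")
}

#' Binodal curve from a user-supplied function
#'
#' Wraps an arbitrary decreasing positive function `y = fn(x)` as a binodal
#' so it can be used with the tie-line solver and interpolation machinery,
#' e.g. for toy diagrams in tests or alternate published models.
#'
#' @param fn Function of one vector argument, dextran wt\% -> PEG wt\%.
#' @return An object of class `"binodal_params"` with `form = "custom"`.
#' @examples
#' toy <- binodal_custom(function(x) 10 / x)
#' eval_binodal(toy, 2)
#' @export
binodal_custom <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(form = "custom", par = numeric(0), fn = fn),
            class = "binodal_params")
}

#' @export
print.binodal_params <- function(x, ...) {
  if (x$form == "custom") {
    cat("<binodal> custom function form\n")
  } else {
    cat(sprintf("<binodal> form '%s': %s\n", x$form,
                paste(sprintf("%s=%.6g", names(x$par), x$par), collapse = ", ")))
  }
  invisible(x)
}

#' Evaluate the binodal curve
#'
#' @param params A [binodal_params()] or [binodal_custom()] object.
#' @param x Dextran concentration(s), wt\%; must be strictly positive (the
#'   default form diverges at `x = 0`).
#' @return PEG concentration(s) on the binodal, wt\%.
#' @export
eval_binodal <- function(params, x) {
  stopifnot(inherits(params, "binodal_params"), is.numeric(x))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("binodal is defined for dextran wt% > 0 only", call. = FALSE)
  if (params$form == "custom") return(params$fn(x))
  binodal_forms[[params$form]]$fn(x, params$par)
}

#' Classify a composition as single- or two-phase
#'
#' A composition above the binodal (`peg > f(dex)`) demixes into a PEG-rich
#' and a dextran-rich phase; a composition on or below it stays single
#' phase. Clouding is the positive signal in titration, so boundary points
#' classify as single phase (strict inequality).
#'
#' @param params A binodal.
#' @param c An [composition()] (or named vector `c(dex=, peg=)`).
#' @return `TRUE` if the composition phase-separates.
#' @examples
#' b <- binodal_params(10.7, -0.45, 2.6e-4, 0.5)
#' is_two_phase(b, composition(6, 5))
#' @export
is_two_phase <- function(params, c) {
  c <- as_composition(c)
  if (c$dex == 0) {
    # the inverse term makes f(0+) infinite: nothing at dex = 0 can sit above
    has_inverse <- params$form == "custom" ||
      (params$form == "exp_inverse" && params$par[["D"]] > 0)
    if (has_inverse)
      stop("composition with dex = 0 is on the asymptote; classification ",
           "is undefined", call. = FALSE)
    return(c$peg > params$par[["A"]])
  }
  c$peg > eval_binodal(params, c$dex)
}

# ---- cloud-point series -----------------------------------------------------

#' Cloud-point titration series
#'
#' Bundles compositions recorded at clouding transitions during a titration,
#' i.e. points that lie on the binodal.
#'
#' @param dex,peg Numeric vectors of equal length, wt\%.
#' @param protocol Character scalar or vector tagging which titration arm
#'   produced each point (`"peg_into_dex"` or `"dex_into_peg"`).
#' @return A `data.frame` of class `"cloud_points"` with columns
#'   `dex`, `peg`, `protocol`.
#' @export
cloud_points <- function(dex, peg, protocol = "peg_into_dex") {
  stopifnot(is.numeric(dex), is.numeric(peg), length(dex) == length(peg))
  if (length(dex) < 6L)
    stop("at least 6 cloud points are required for a binodal fit",
         call. = FALSE)
  if (any(!is.finite(dex)) || any(!is.finite(peg)) || any(dex <= 0) ||
      any(peg < 0))
    stop("cloud points must be finite with dex > 0 and peg >= 0",
         call. = FALSE)
  protocol <- rep_len(as.character(protocol), length(dex))
  if (max(dex) / min(dex) < 5)
    warning("cloud points cover a narrow dextran range; the fitted binodal ",
            "may be poorly constrained at one end", call. = FALSE)
  structure(data.frame(dex = dex, peg = peg, protocol = protocol,
                       stringsAsFactors = FALSE),
            class = c("cloud_points", "data.frame"))
}

as_cloud_points <- function(x) {
  if (inherits(x, "cloud_points")) return(x)
  if (is.data.frame(x) && all(c("dex", "peg") %in% names(x)))
    return(cloud_points(x$dex, x$peg,
                        if ("protocol" %in% names(x)) x$protocol else "unknown"))
  stop("expected a cloud_points object or data.frame with dex/peg columns",
       call. = FALSE)
}

# ---- fitting ----------------------------------------------------------------

rss_of <- function(form, par, dex, peg) {
  yhat <- binodal_forms[[form]]$fn(dex, as.list(par))
  sum((peg - yhat)^2)
}

#' Fit the binodal to cloud-point data
#'
#' Unweighted ordinary least squares in y (PEG wt\%) by Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]), with a deterministic multistart (the supplied
#' init plus jittered restarts under a fixed seed) to reduce the risk of a
#' local minimum; the restart with the lowest residual sum of squares wins.
#'
#' @param series A [cloud_points()] object or data.frame with `dex`, `peg`
#'   columns (wt\%). Points from both titration arms are pooled.
#' @param init Optional [binodal_params()] initial guess. Default:
#'   `A = max(peg)`, `B = -0.3`, `C = 1e-4`, `D = 0.1`.
#' @param form Model form, see [binodal_params()].
#' @param lower,upper Optional named bound overrides for the parameters.
#'   Defaults keep `A > 0`, `C >= 0`, `D >= 0`.
#' @param n_starts Number of multistart inits (>= 1).
#' @param seed Seed for the jittered restarts (fit is deterministic given
#'   `init`, bounds and this seed).
#' @param weights Optional nonnegative case weights.
#' @return An object of class `"binodal_fit"`: list with `params`
#'   ([binodal_params()]), `rss`, `n_points`, `convergence` (`TRUE` if the
#'   optimizer reported convergence), `vcov` (parameter covariance from the
#'   best fit, for Monte Carlo resampling), `sigma` (residual sd), `data`.
#' @examples
#' truth <- binodal_params(10.7, -0.45, 2.6e-4, 0.5)
#' x <- seq(0.5, 25, length.out = 12)
#' cp <- cloud_points(x, eval_binodal(truth, x))
#' fit <- fit_binodal(cp)
#' fit$params
#' @export
fit_binodal <- function(series, init = NULL, form = "exp_inverse",
                        lower = NULL, upper = NULL, n_starts = 5L,
                        seed = 1L, weights = NULL) {
  form <- match.arg(form, names(binodal_forms))
  series <- as_cloud_points(series)
  spec <- binodal_forms[[form]]
  npar <- length(spec$par_names)
  if (nrow(series) < npar)
    stop(sprintf("need at least %d points to fit %d parameters", npar, npar),
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(series))
  stopifnot(length(weights) == nrow(series), all(weights >= 0))

  start0 <- if (is.null(init)) {
    s <- c(A = max(series$peg), B = -0.3, C = 1e-4)
    if (form == "exp_inverse") s <- c(s, D = 0.1)
    s
  } else {
    if (init$form != form)
      stop("init parameters are for form '", init$form, "', not '", form, "'",
           call. = FALSE)
    init$par
  }
  if (!all(is.finite(start0))) stop("initial guess must be finite", call. = FALSE)

  lo <- spec$lower; hi <- spec$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  start0 <- pmin(pmax(start0, lo + 1e-10), hi)

  # deterministic multistart: init + jittered copies
  starts <- list(start0)
  if (n_starts > 1L) {
    jit <- withr_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        s <- start0 * exp(stats::rnorm(npar, 0, 0.3))
        s["B"] <- start0[["B"]] + stats::rnorm(1, 0, 0.15)
        pmin(pmax(s, lo + 1e-10), hi)
      })
    })
    starts <- c(starts, jit)
  }

  dat <- data.frame(x = series$dex, y = series$peg)
  model_formula <- if (form == "exp_inverse") {
    y ~ A * exp(B * sqrt(x) - C * x^3) + D / x
  } else {
    y ~ A * exp(B * sqrt(x) - C * x^3)
  }

  best <- NULL
  best_rss <- Inf
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(model_formula, data = dat, start = as.list(s),
                        lower = lo, upper = hi, weights = weights,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- sum(weights * stats::residuals(fit)^2)
    if (r < best_rss) {
      best_rss <- r
      best <- fit
      converged <- fit$convInfo$isConv
    }
  }
  if (is.null(best))
    stop("binodal fit failed to converge from any start; check the data or ",
         "supply an initial guess", call. = FALSE)

  par <- stats::coef(best)
  params <- if (form == "exp_inverse") {
    binodal_params(par[["A"]], par[["B"]], par[["C"]], par[["D"]], form = form)
  } else {
    binodal_params(par[["A"]], par[["B"]], par[["C"]], form = form)
  }
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  structure(list(params = params, rss = best_rss,
                 n_points = nrow(series), convergence = isTRUE(converged),
                 vcov = vc, sigma = stats::sigma(best),
                 form = form, data = series),
            class = "binodal_fit")
}

#' @export
print.binodal_fit <- function(x, ...) {
  cat(sprintf("<binodal fit> form '%s', n = %d, rss = %.6g wt%%^2, %s\n",
              x$form, x$n_points, x$rss,
              if (x$convergence) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

# run code under a temporary RNG state so callers' streams are untouched
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Check binodal shape invariants on a grid
#'
#' Asserts numerically that the curve is strictly decreasing and positive
#' over `(0, x_max]`, the physical requirements for a polymer-polymer
#' binodal in this parametrization.
#'
#' @param params A binodal.
#' @param x_range Domain to check, wt\%.
#' @param n Grid size.
#' @return Invisibly `TRUE`; errors describing the violation otherwise.
#' @export
check_binodal_shape <- function(params, x_range = c(0.05, 45), n = 1000L) {
  g <- seq(x_range[1], x_range[2], length.out = n)
  y <- eval_binodal(params, g)
  if (any(!is.finite(y)))
    stop("binodal is non-finite inside the domain", call. = FALSE)
  if (any(y <= 0))
    stop("binodal predicts non-positive PEG concentration at dex = ",
         signif(g[which(y <= 0)[1]], 4), " wt%", call. = FALSE)
  if (any(diff(y) >= 0))
    stop("binodal is not strictly decreasing near dex = ",
         signif(g[which(diff(y) >= 0)[1]], 4), " wt%", call. = FALSE)
  invisible(TRUE)
}
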
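# Tie-line interpolation through a conjugate curve.
#
# The conjugate curve is an auxiliary quadratic fitted through the
# midpoints of the empirically solved tie-lines. Any candidate tie-line is
# then required to (i) have both endpoints on the binodal and (ii) have its
# midpoint on the conjugate curve; marching along the conjugate curve (a
# one-parameter family indexed by midpoint dextran, monotonically related
# to arc length) and refining the member that passes through the target
# average composition yields the interpolated tie-line.

#' Fit the conjugate curve to tie-line anchors
#'
#' Ordinary least squares of a quadratic `y = q0 + q1*x + q2*x^2` through
#' the tie-line midpoints `((x_t + x_b)/2, (y_t + y_b)/2)` in phase-diagram
#' coordinates.
#'
#' @param tielines List of [tie_line()] objects (>= 3), or a data.frame
#'   with columns `top_dex`, `top_peg`, `bottom_dex`, `bottom_peg`.
#' @param anchor Anchor construction: `"midpoint"` (default and only
#'   built-in), or a function `tie_line -> c(x, y)` for alternative
#'   constructions.
#' @return An object of class `"conjugate_curve"`: coefficients `q0`, `q1`,
#'   `q2`, the underlying `lm` fit (`model`), anchor coordinates
#'   (`anchors`), and the anchored x-range (`range`).
#' @export
fit_conjugate <- function(tielines, anchor = "midpoint") {
  anchors <- conjugate_anchors(tielines, anchor)
  if (nrow(anchors) < 3L)
    stop("at least 3 tie-lines are required to fit the conjugate quadratic",
         call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2), data = anchors)
  co <- stats::coef(fit)
  if (any(!is.finite(co))) {
    warning("anchors do not determine a quadratic (collinear in x^2); ",
            "falling back to a straight conjugate line (q2 = 0)",
            call. = FALSE)
    fit <- stats::lm(y ~ x, data = anchors)
    co <- c(stats::coef(fit), 0)
  }
  structure(list(q0 = unname(co[1]), q1 = unname(co[2]), q2 = unname(co[3]),
                 model = fit, anchors = anchors,
                 range = range(anchors$x)),
            class = "conjugate_curve")
}

conjugate_anchors <- function(tielines, anchor = "midpoint") {
  if (inherits(tielines, "tie_line")) tielines <- list(tielines)
  if (is.data.frame(tielines)) {
    stopifnot(all(c("top_dex", "top_peg", "bottom_dex", "bottom_peg") %in%
                    names(tielines)))
    df <- tielines
  } else {
    df <- do.call(rbind, lapply(tielines, function(tl) {
      data.frame(top_dex = tl$top$dex, top_peg = tl$top$peg,
                 bottom_dex = tl$bottom$dex, bottom_peg = tl$bottom$peg)
    }))
  }
  if (is.function(anchor)) {
    xy <- t(apply(df, 1, function(r) {
      tl <- tie_line(composition(r[["top_dex"]], r[["top_peg"]]),
                     composition(r[["bottom_dex"]], r[["bottom_peg"]]),
                     composition((r[["top_dex"]] + r[["bottom_dex"]]) / 2,
                                 (r[["top_peg"]] + r[["bottom_peg"]]) / 2))
      anchor(tl)
    }))
    return(data.frame(x = xy[, 1], y = xy[, 2]))
  }
  anchor <- match.arg(anchor, "midpoint")
  data.frame(x = (df$top_dex + df$bottom_dex) / 2,
             y = (df$top_peg + df$bottom_peg) / 2)
}

#' Evaluate the conjugate curve
#' @param conj A [fit_conjugate()] result.
#' @param x Dextran wt\%.
#' @return PEG wt\% on the conjugate curve.
#' @export
eval_conjugate <- function(conj, x) {
  stopifnot(inherits(conj, "conjugate_curve"))
  conj$q0 + conj$q1 * x + conj$q2 * x^2
}

#' @export
print.conjugate_curve <- function(x, ...) {
  cat(sprintf(
    "<conjugate curve> y = %.5g + %.5g x + %.5g x^2, anchored on x in [%.3g, %.3g]\n",
    x$q0, x$q1, x$q2, x$range[1], x$range[2]))
  invisible(x)
}

# Tie-line whose midpoint sits at conjugate abscissa xm: solve
# f(xt) + f(2*xm - xt) = 2*q(xm) for xt in (0, xm). Returns NA if no root.
tieline_at_midpoint <- function(xm, binodal, conj, tol = 1e-12) {
  ym2 <- 2 * eval_conjugate(conj, xm)
  r <- function(xt) eval_binodal(binodal, xt) +
    eval_binodal(binodal, 2 * xm - xt) - ym2
  lo <- xm * 1e-6
  hi <- xm * (1 - 1e-9)
  rl <- r(lo); rh <- r(hi)
  if (!is.finite(rl) || !is.finite(rh) || rl * rh > 0) return(NA_real_)
  stats::uniroot(r, lower = lo, upper = hi, tol = tol, maxiter = 2000L)$root
}

# signed collinearity residual of target with the candidate endpoints
interp_resid <- function(xm, target, binodal, conj) {
  xt <- tieline_at_midpoint(xm, binodal, conj)
  if (!is.finite(xt)) return(NA_real_)
  xb <- 2 * xm - xt
  yt <- eval_binodal(binodal, xt)
  yb <- eval_binodal(binodal, xb)
  (yt - target$peg) * (xb - target$dex) - (yb - target$peg) * (xt - target$dex)
}

#' Interpolate a tie-line at an arbitrary two-phase composition
#'
#' Finds the tie-line through `target` whose endpoints lie on the binodal
#' and whose midpoint lies on the conjugate curve. The solver marches along
#' the conjugate curve, building candidate tie-lines at a grid of midpoint
#' abscissae, brackets the candidate collinear with the target, and
#' polishes it by Brent root refinement in two nested one-dimensional
#' solves.
#'
#' @param target Target average composition ([composition()] or named
#'   vector); must be strictly two-phase.
#' @param binodal A [binodal_params()] (or [fit_binodal()] result).
#' @param conj A [fit_conjugate()] result.
#' @param xm_range Midpoint search range (dextran wt\%). Default: the
#'   anchored conjugate range extended by 60\% on each side (extrapolation
#'   beyond the anchors is allowed but flagged with a warning).
#' @param n_grid March resolution.
#' @return A [tie_line()] with attribute `extrapolated` (logical).
#' @export
interpolate_tieline <- function(target, binodal, conj, xm_range = NULL,
                                n_grid = 120L) {
  if (inherits(binodal, "binodal_fit")) binodal <- binodal$params
  stopifnot(inherits(binodal, "binodal_params"),
            inherits(conj, "conjugate_curve"))
  target <- as_composition(target)
  if (!is_two_phase(binodal, target))
    stop("target composition is single-phase under this binodal", call. = FALSE)
  if (is.null(xm_range)) {
    w <- diff(conj$range)
    xm_range <- c(max(conj$range[1] - 0.6 * w, target$dex / 2 * 0 + 1e-3),
                  conj$range[2] + 0.6 * w)
    xm_range[1] <- max(xm_range[1], 0.2)
  }
  grid <- seq(xm_range[1], xm_range[2], length.out = n_grid)
  rg <- vapply(grid, interp_resid, numeric(1),
               target = target, binodal = binodal, conj = conj)
  ok <- which(is.finite(rg))
  if (length(ok) < 2L)
    stop("no candidate tie-lines exist along the conjugate curve in the ",
         "searched range; the target may be outside the anchored region",
         call. = FALSE)
  flips <- ok[which(rg[ok][-1] * rg[ok][-length(ok)] < 0)]
  sol <- NULL
  for (i in flips) {
    j <- ok[which(ok > i)[1]]
    xm <- stats::uniroot(function(m) interp_resid(m, target, binodal, conj),
                         lower = grid[i], upper = grid[j],
                         tol = 1e-12, maxiter = 2000L)$root
    xt <- tieline_at_midpoint(xm, binodal, conj)
    xb <- 2 * xm - xt
    if (xt < target$dex && target$dex < xb) {
      sol <- c(xm = xm, xt = xt, xb = xb)
      break
    }
  }
  if (is.null(sol)) {
    exact <- ok[which(rg[ok] == 0)]
    if (length(exact)) {
      xm <- grid[exact[1]]
      xt <- tieline_at_midpoint(xm, binodal, conj)
      sol <- c(xm = xm, xt = xt, xb = 2 * xm - xt)
    } else {
      stop("no admissible tie-line through the target was found; it likely ",
           "lies outside the region anchored by the conjugate curve ",
           sprintf("(searched midpoints in [%.3g, %.3g])",
                   xm_range[1], xm_range[2]), call. = FALSE)
    }
  }
  extrap <- sol[["xm"]] < conj$range[1] || sol[["xm"]] > conj$range[2]
  if (extrap)
    warning(sprintf(paste0("interpolated tie-line midpoint (dex = %.3g wt%%) ",
                           "lies outside the anchored conjugate range ",
                           "[%.3g, %.3g]; extrapolating"),
                    sol[["xm"]], conj$range[1], conj$range[2]), call. = FALSE)
  tl <- tie_line(composition(sol[["xt"]], eval_binodal(binodal, sol[["xt"]])),
                 composition(sol[["xb"]], eval_binodal(binodal, sol[["xb"]])),
                 target, tol = 1e-6)
  attr(tl, "f_top") <- lever_fraction(tl)
  attr(tl, "extrapolated") <- extrap
  tl
}
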
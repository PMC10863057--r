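# Tie-line solving from gravimetric phase-separation data.
#
# A 500 mg-scale ATPS of known average composition is allowed to separate;
# the PEG-rich top phase is decanted and weighed. With f_top = M_top/M the
# endpoint compositions follow from the closed system: two mass balances
# (PEG and dextran), both endpoints on the binodal, and mass closure
# M_bottom = M - M_top. Substituting the binodal reduces the system to one
# root-finding problem in the top-phase dextran concentration.

#' Phase densities for volume-ratio correction
#'
#' @param rho_top Density of the PEG-rich (top) phase, g/mL. Default 1.0.
#' @param rho_bottom Density of the dextran-rich (bottom) phase, g/mL.
#'   Default 1.1.
#' @return A list of class `"phase_densities"`.
#' @export
phase_densities <- function(rho_top = 1.0, rho_bottom = 1.1) {
  stopifnot(is.numeric(rho_top), is.numeric(rho_bottom),
            rho_top > 0, rho_bottom > 0)
  structure(list(rho_top = rho_top, rho_bottom = rho_bottom),
            class = "phase_densities")
}

#' One gravimetric phase-separation record
#'
#' @param total_mass Total ATPS mass, mg.
#' @param avg Average composition of the whole system ([composition()] or
#'   named vector).
#' @param top_mass Measured mass of the decanted PEG-rich top phase, mg.
#' @return An object of class `"gravimetric_experiment"`.
#' @examples
#' gravimetric_experiment(500, composition(dex = 6, peg = 5), 333.6)
#' @export
gravimetric_experiment <- function(total_mass, avg, top_mass) {
  avg <- as_composition(avg)
  stopifnot(is.numeric(total_mass), is.numeric(top_mass))
  if (!(total_mass > 0) || !(top_mass > 0) || !(top_mass < total_mass))
    stop("need 0 < top_mass < total_mass", call. = FALSE)
  structure(list(total_mass = total_mass, avg = avg, top_mass = top_mass),
            class = "gravimetric_experiment")
}

#' Tie-line between coexisting phase compositions
#'
#' The tie-line joins the equilibrium compositions of the PEG-rich (top)
#' and dextran-rich (bottom) phases; every average composition on the
#' segment separates into these same two endpoints.
#'
#' @param top,bottom,avg Compositions ([composition()] or named vectors).
#' @param tol Collinearity tolerance (wt\%): a warning is raised when `avg`
#'   deviates from the top-bottom segment by more than this (printed table
#'   values carry rounding error; solver output is collinear to machine
#'   precision).
#' @return An object of class `"tie_line"`.
#' @export
tie_line <- function(top, bottom, avg, tol = 0.05) {
  top <- as_composition(top); bottom <- as_composition(bottom)
  avg <- as_composition(avg)
  if (!(top$peg > bottom$peg))
    stop("top (PEG-rich) phase must have higher PEG than bottom", call. = FALSE)
  if (!(bottom$dex > top$dex))
    stop("bottom (dextran-rich) phase must have higher dextran than top",
         call. = FALSE)
  res <- collinearity_residual(top, bottom, avg)
  if (res > tol)
    warning(sprintf("average composition is %.3g wt%% off the tie-line segment",
                    res), call. = FALSE)
  structure(list(top = top, bottom = bottom, avg = avg), class = "tie_line")
}

# perpendicular distance (wt%) of avg from the top-bottom segment line
collinearity_residual <- function(top, bottom, avg) {
  dx <- bottom$dex - top$dex
  dy <- bottom$peg - top$peg
  abs(dy * (avg$dex - top$dex) - dx * (avg$peg - top$peg)) / sqrt(dx^2 + dy^2)
}

#' @export
print.tie_line <- function(x, ...) {
  cat(sprintf(paste0("<tie-line> top (%.4g, %.4g) -- avg (%.4g, %.4g) -- ",
                     "bottom (%.4g, %.4g)  [dex, peg wt%%]\n"),
              x$top$dex, x$top$peg, x$avg$dex, x$avg$peg,
              x$bottom$dex, x$bottom$peg))
  invisible(x)
}

#' Solve tie-line endpoints from a gravimetric experiment
#'
#' With the top-phase mass fraction `f_top = top_mass/total_mass` known, the
#' endpoints must satisfy the PEG and dextran mass balances
#' `avg = f_top * top + (1 - f_top) * bottom` with both endpoints on the
#' binodal. Eliminating `bottom.dex` through the dextran balance and both
#' PEG concentrations through the binodal leaves a single equation in
#' `top.dex`, solved by a grid-bracketed Brent search (bisection-refined
#' with interpolation polish).
#'
#' @param exp A [gravimetric_experiment()].
#' @param binodal A [binodal_params()] (or the `params` of a
#'   [fit_binodal()]).
#' @param x_max Upper bound for the bottom-phase dextran search, wt\%.
#' @param n_grid Grid size used to bracket the root.
#' @param tol Root tolerance on top.dex.
#' @return A [tie_line()] with attributes `f_top` (top-phase mass fraction)
#'   and `residual` (PEG-balance residual at the solution, wt\%).
#' @examples
#' b <- binodal_params(10.7, -0.45, 2.6e-4, 0.5)
#' e <- gravimetric_experiment(500, composition(6, 5), 320)
#' solve_tieline(e, b)
#' @export
solve_tieline <- function(exp, binodal, x_max = 60, n_grid = 200L,
                          tol = 1e-12) {
  stopifnot(inherits(exp, "gravimetric_experiment"))
  if (inherits(binodal, "binodal_fit")) binodal <- binodal$params
  stopifnot(inherits(binodal, "binodal_params"))
  avg <- exp$avg
  if (!is_two_phase(binodal, avg))
    stop("average composition is single-phase under this binodal; no ",
         "tie-line exists", call. = FALSE)
  f_top <- exp$top_mass / exp$total_mass

  # bottom.dex implied by the dextran balance
  xb_of <- function(xt) (avg$dex - f_top * xt) / (1 - f_top)
  resid <- function(xt) {
    f_top * eval_binodal(binodal, xt) +
      (1 - f_top) * eval_binodal(binodal, xb_of(xt)) - avg$peg
  }

  eps <- 1e-9
  hi <- avg$dex - eps
  # keep bottom.dex inside (avg.dex, x_max]
  lo_bound <- max(eps, (avg$dex - (1 - f_top) * x_max) / f_top + eps)
  if (lo_bound >= hi)
    stop("no admissible bracket for top.dex; x_max too small?", call. = FALSE)
  grid <- seq(lo_bound, hi, length.out = n_grid)
  rg <- vapply(grid, resid, numeric(1))
  sgn <- sign(rg)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (any(rg == 0)) {
    xt <- grid[which(rg == 0)[1]]
  } else if (length(flips) == 0L) {
    stop("tie-line solver found no root in the admissible branch ",
         sprintf("(residual range [%.3g, %.3g]); the average composition ",
                 min(rg), max(rg)),
         "may be inconsistent with the measured top-phase mass", call. = FALSE)
  } else {
    roots <- vapply(flips, function(i) {
      stats::uniroot(resid, lower = grid[i], upper = grid[i + 1],
                     tol = tol, maxiter = 2000L)$root
    }, numeric(1))
    # admissible root: PEG-rich top above the average, dextran-rich bottom below
    ok <- vapply(roots, function(r) {
      eval_binodal(binodal, r) > avg$peg &&
        eval_binodal(binodal, xb_of(r)) < avg$peg
    }, logical(1))
    if (!any(ok))
      stop("tie-line solver roots violate phase-enrichment ordering; ",
           "diagnostics: roots at top.dex = ",
           paste(signif(roots, 6), collapse = ", "), call. = FALSE)
    if (sum(ok) > 1L)
      warning("multiple admissible tie-line roots; taking the one with the ",
              "smallest top.dex", call. = FALSE)
    xt <- min(roots[ok])
  }

  xb <- xb_of(xt)
  tl <- tie_line(composition(xt, eval_binodal(binodal, xt)),
                 composition(xb, eval_binodal(binodal, xb)),
                 avg, tol = 1e-6)
  attr(tl, "f_top") <- f_top
  attr(tl, "residual") <- abs(resid(xt))
  tl
}

#' Lever-rule top-phase mass fraction
#'
#' The fraction of total mass in the PEG-rich phase, from the relative
#' position of the average composition between the endpoints:
#' `(avg.peg - bottom.peg) / (top.peg - bottom.peg)` on the PEG axis
#' (equivalently on the dextran axis for a mass-balance-consistent
#' tie-line).
#'
#' @param tl A [tie_line()].
#' @param basis `"peg"` (default) or `"dex"`: which concentration axis to
#'   use. The two agree to solver tolerance for solved tie-lines and to
#'   printed rounding for transcribed table values.
#' @return Top-phase mass fraction in `[0, 1]`.
#' @examples
#' tl <- tie_line(top = c(dex = 0.91, peg = 7.34),
#'                bottom = c(dex = 16.21, peg = 0.31),
#'                avg = c(dex = 6.0, peg = 5.0))
#' lever_fraction(tl)  # 0.667
#' @export
lever_fraction <- function(tl, basis = c("peg", "dex")) {
  stopifnot(inherits(tl, "tie_line"))
  basis <- match.arg(basis)
  num_den <- if (basis == "peg") {
    c(tl$avg$peg - tl$bottom$peg, tl$top$peg - tl$bottom$peg)
  } else {
    c(tl$avg$dex - tl$bottom$dex, tl$top$dex - tl$bottom$dex)
  }
  if (abs(num_den[2]) < 1e-12)
    stop("degenerate tie-line: endpoints coincide on the ", basis, " axis",
         call. = FALSE)
  num_den[1] / num_den[2]
}

#' Density-corrected dextran:PEG volume ratio
#'
#' The ratio of dextran-rich (continuous) to PEG-rich (disperse) phase
#' volume. By the lever rule the bottom:top mass ratio is `(1 - f)/f` with
#' `f` the top-phase mass fraction; dividing each phase mass by its density
#' gives `vr = ((1 - f)/f) * (rho_top/rho_bottom)`. This equals the
#' segment-length construction on the phase diagram (distance from the
#' average composition to the PEG-rich intersection over the distance to
#' the dextran-rich intersection), density-corrected.
#'
#' @param tl A [tie_line()].
#' @param rho A [phase_densities()]; defaults to 1.0 (PEG-rich) and 1.1
#'   (dextran-rich) g/mL.
#' @param basis Lever-rule axis passed to [lever_fraction()].
#' @return Volume ratio, mL/mL.
#' @examples
#' tl <- tie_line(top = c(dex = 0.08, peg = 18.10),
#'                bottom = c(dex = 26.82, peg = 3.01e-4),
#'                avg = c(dex = 21.65, peg = 3.5))
#' volume_ratio(tl)  # 3.79
#' @export
volume_ratio <- function(tl, rho = phase_densities(), basis = "peg") {
  stopifnot(inherits(rho, "phase_densities"))
  f <- lever_fraction(tl, basis = basis)
  if (f <= 0 || f >= 1)
    stop("lever fraction is ", signif(f, 4),
         "; volume ratio undefined when a phase vanishes", call. = FALSE)
  ((1 - f) / f) * (rho$rho_top / rho$rho_bottom)
}

#' Tie-lines as a data frame
#'
#' @param tielines A list of [tie_line()] objects.
#' @param rho Optional [phase_densities()] to add a `volume_ratio` column.
#' @return A data.frame with columns `avg_peg`, `avg_dex`, `top_peg`,
#'   `top_dex`, `bottom_peg`, `bottom_dex`, `f_top`, `volume_ratio`.
#' @export
tielines_table <- function(tielines, rho = phase_densities()) {
  if (inherits(tielines, "tie_line")) tielines <- list(tielines)
  rows <- lapply(tielines, function(tl) {
    f <- attr(tl, "f_top")
    if (is.null(f)) f <- lever_fraction(tl)
    data.frame(avg_peg = tl$avg$peg, avg_dex = tl$avg$dex,
               top_peg = tl$top$peg, top_dex = tl$top$dex,
               bottom_peg = tl$bottom$peg, bottom_dex = tl$bottom$dex,
               f_top = f, volume_ratio = volume_ratio(tl, rho))
  })
  do.call(rbind, rows)
}
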
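# Synthetic-experiment generator. Produces cloud-point titrations,
# gravimetric separations and property measurements with the statistical
# structure the analysis assumes, from a fully known ground truth, so
# every pipeline stage can be validated by parameter recovery.

#' Ground truth for synthetic ATPS experiments
#'
#' Defines a complete synthetic "laboratory": a true binodal, a tie-line
#' slope field (slope as a quadratic function of the bottom-endpoint
#' dextran concentration, steepening with dextran as observed empirically),
#' a true property surface and pellet-polymer line, and a lognormal
#' microgel size model whose median diameter decreases with the volume
#' ratio (higher continuous:disperse volume ratios give smaller microgels).
#'
#' Defaults emulate a 4-arm PEG 20 kDa / dextran 40 kDa system in PBS:
#' the default binodal crosses 9.3 wt\% PEG near 0.4 wt\% dextran and
#' 0.9 wt\% PEG near 14.5 wt\% dextran, and the slope field reproduces the
#' range of empirically observed tie-line slopes (about -0.46 to -0.93).
#' They are representative, not a transcription of any measured system.
#'
#' Two constructions of the tie-line field are available. The default,
#' `tie_field = "conjugate"`, defines tie-lines as the chords of the
#' binodal whose midpoints lie on an exact quadratic conjugate curve
#' (`conjugate` coefficients); this field is exactly recoverable by the
#' conjugate-interpolation machinery, so zero-noise round trips close to
#' solver precision. `tie_field = "slope"` instead prescribes the
#' tie-line slope as a quadratic function of the bottom-endpoint dextran
#' concentration; its midpoint curve is only approximately quadratic
#' (within about 0.05 wt\% over the default sampling region — the default
#' `conjugate` coefficients were frozen from exactly this construction).
#'
#' @param binodal True binodal ([binodal_params()]).
#' @param tie_field `"conjugate"` (default) or `"slope"`.
#' @param conjugate Coefficients `c(q0, q1, q2)` of the true conjugate
#'   quadratic (midpoint PEG as a function of midpoint dextran, wt\%).
#' @param tie_slope Coefficients `c(s0, s1, s2)` of
#'   `slope(x_b) = s0 + s1*x_b + s2*x_b^2`, or a function of `x_b`.
#' @param stiffness True AFM stiffness surface `c(a, b, c)` (kPa):
#'   `a*peg + b/vr + c`.
#' @param rheology True shear storage modulus surface `c(a, b, c)` (Pa).
#' @param tga_line True pellet-polymer line `c(slope, intercept)` (wt\% per
#'   wt\%, wt\%).
#' @param size_model `c(d0, k, sdlog)`: diameters ~ lognormal with
#'   `meanlog = log(d0) - k*log(vr)` (µm) and sd `sdlog` on the log scale.
#' @return A list of class `"atps_truth"`.
#' @export
atps_ground_truth <- function(
    binodal = binodal_params(A = 10.7, B = -0.45, C = 2.6e-4, D = 0.5),
    tie_field = c("conjugate", "slope"),
    conjugate = c(q0 = 4.446, q1 = -0.605, q2 = 0.0693),
    tie_slope = c(s0 = -0.37, s1 = 0, s2 = -4.0e-4),
    stiffness = c(a = 2.0, b = 30, c = 5),
    rheology = c(a = 150, b = 2000, c = 300),
    tga_line = c(slope = 0.24, intercept = 0.47),
    size_model = c(d0 = 60, k = 0.5, sdlog = 0.3)) {
  stopifnot(inherits(binodal, "binodal_params"))
  tie_field <- match.arg(tie_field)
  slope_fn <- if (is.function(tie_slope)) tie_slope else {
    function(xb) tie_slope[[1]] + tie_slope[[2]] * xb + tie_slope[[3]] * xb^2
  }
  structure(list(binodal = binodal, tie_field = tie_field,
                 conjugate = conjugate, tie_slope = slope_fn,
                 stiffness = stiffness, rheology = rheology,
                 tga_line = tga_line, size_model = size_model),
            class = "atps_truth")
}

# the truth conjugate as a conjugate_curve object (no fit model attached)
truth_conjugate <- function(truth) {
  structure(list(q0 = truth$conjugate[[1]], q1 = truth$conjugate[[2]],
                 q2 = truth$conjugate[[3]], model = NULL, anchors = NULL,
                 range = c(5, 25)),
            class = "conjugate_curve")
}

#' True tie-line through an average composition
#'
#' Solves, under the ground-truth diagram, for the tie-line through `avg`.
#' With the default conjugate field this is the binodal chord through
#' `avg` whose midpoint lies on the truth conjugate quadratic. With the
#' slope field, the bottom endpoint `x_b` satisfies
#' `f(x_b) = avg.peg + slope(x_b) * (x_b - avg.dex)` and the top endpoint
#' lies on the same straight line where it re-crosses the binodal.
#'
#' @param truth An [atps_ground_truth()].
#' @param avg Average composition (two-phase).
#' @param x_max Search bound for the bottom endpoint (slope field), wt\%.
#' @return A [tie_line()] with attribute `f_top` (lever-rule top mass
#'   fraction).
#' @export
truth_tieline <- function(truth, avg, x_max = 60) {
  stopifnot(inherits(truth, "atps_truth"))
  avg <- as_composition(avg)
  if (!is_two_phase(truth$binodal, avg))
    stop("average composition is single-phase under the truth binodal",
         call. = FALSE)
  if (truth$tie_field == "conjugate") {
    tl <- suppressWarnings(
      interpolate_tieline(avg, truth$binodal, truth_conjugate(truth),
                          xm_range = c(0.3, x_max / 2), n_grid = 200L))
    attr(tl, "extrapolated") <- NULL
    return(tl)
  }
  f <- function(x) eval_binodal(truth$binodal, x)
  g <- function(xb) f(xb) - (avg$peg + truth$tie_slope(xb) * (xb - avg$dex))
  xb <- stats::uniroot(g, lower = avg$dex + 1e-9, upper = x_max,
                       tol = 1e-13, maxiter = 2000L)$root
  m <- truth$tie_slope(xb)
  h <- function(xt) f(xt) - (avg$peg + m * (xt - avg$dex))
  xt <- stats::uniroot(h, lower = 1e-8, upper = avg$dex - 1e-9,
                       tol = 1e-13, maxiter = 2000L)$root
  tl <- tie_line(composition(xt, f(xt)), composition(xb, f(xb)), avg,
                 tol = 1e-6)
  attr(tl, "f_top") <- lever_fraction(tl)
  tl
}

#' Simulate a cloud-point titration
#'
#' Walks the titration arithmetic: titrant is added to the analyte in
#' quantized volume increments; after each addition the mixture
#' composition is updated by mass balance and checked against the true
#' binodal. At each clouding transition the composition is recorded, then
#' buffer is added in its own increments until clouding subsides, and the
#' cycle repeats until the prescribed total titrant volume has been
#' delivered. Recorded points therefore straddle the true binodal within
#' one increment step; optional Gaussian noise emulates reading error.
#'
#' @param truth An [atps_ground_truth()].
#' @param protocol `"peg_into_dex"` (PEG titrant into dextran analyte,
#'   default: 20 wt\% PEG into 550 mg of 42.86 wt\% dextran) or
#'   `"dex_into_peg"` (30 wt\% dextran into 300 mg of 20 wt\% PEG).
#' @param increment_mg Titrant increment range, mg (volumes in µL are
#'   numerically equal at density ~1 g/mL). Default `c(5, 30)`.
#' @param pbs_increment_mg Buffer increment range for de-clouding, mg.
#'   Default `c(10, 150)`.
#' @param total_titrant_mg Stop after this much titrant (default 850).
#' @param noise_sigma Gaussian sd added to recorded compositions, wt\%.
#' @param seed RNG seed (increment sizes are drawn uniformly within their
#'   ranges).
#' @return A [cloud_points()] series (with a warning and fewer points if
#'   the titration path rarely crosses the binodal).
#' @export
simulate_cloud_titration <- function(truth,
                                     protocol = c("peg_into_dex",
                                                  "dex_into_peg"),
                                     increment_mg = c(5, 30),
                                     pbs_increment_mg = c(10, 150),
                                     total_titrant_mg = 850,
                                     noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(truth, "atps_truth"))
  protocol <- match.arg(protocol)
  if (protocol == "peg_into_dex") {
    m_dex <- 550 * 0.4286; m_peg <- 0; m_tot <- 550
    titrant <- c(dex = 0, peg = 0.20)
  } else {
    m_dex <- 0; m_peg <- 300 * 0.20; m_tot <- 300
    titrant <- c(dex = 0.30, peg = 0)
  }
  pts <- withr_seed(seed, {
    out <- list()
    added <- 0
    clouded <- FALSE
    guard <- 0L
    while (added < total_titrant_mg && (guard <- guard + 1L) < 50000L) {
      dm <- stats::runif(1, increment_mg[1], increment_mg[2])
      m_dex <- m_dex + dm * titrant[["dex"]]
      m_peg <- m_peg + dm * titrant[["peg"]]
      m_tot <- m_tot + dm
      added <- added + dm
      comp <- c(dex = 100 * m_dex / m_tot, peg = 100 * m_peg / m_tot)
      if (comp[["dex"]] > 0 &&
          comp[["peg"]] > eval_binodal(truth$binodal, comp[["dex"]])) {
        # clouding observed: record, then dilute with buffer until it clears
        rec <- comp + stats::rnorm(2, 0, noise_sigma)
        out[[length(out) + 1L]] <- pmax(rec, c(1e-6, 0))
        clear_guard <- 0L
        repeat {
          dpbs <- stats::runif(1, pbs_increment_mg[1], pbs_increment_mg[2])
          m_tot <- m_tot + dpbs
          comp <- c(dex = 100 * m_dex / m_tot, peg = 100 * m_peg / m_tot)
          if (comp[["peg"]] <= eval_binodal(truth$binodal, comp[["dex"]]))
            break
          if ((clear_guard <- clear_guard + 1L) > 5000L)
            stop("buffer additions never cleared the clouding; the truth ",
                 "binodal and protocol are inconsistent", call. = FALSE)
        }
      }
    }
    out
  })
  if (length(pts) == 0L) {
    warning("titrant path never crossed the binodal; returning an empty ",
            "series", call. = FALSE)
    return(data.frame(dex = numeric(0), peg = numeric(0),
                      protocol = character(0)))
  }
  m <- do.call(rbind, pts)
  if (nrow(m) >= 6L) {
    cloud_points(m[, 1], m[, 2], protocol)
  } else {
    data.frame(dex = m[, 1], peg = m[, 2], protocol = protocol,
               stringsAsFactors = FALSE)
  }
}

#' Simulate gravimetric phase-separation experiments
#'
#' For each requested average composition, the true top-phase mass follows
#' from the ground-truth tie-line through it (lever rule); Gaussian
#' weighing noise is added and replicates emitted.
#'
#' @param truth An [atps_ground_truth()].
#' @param avg_compositions A data.frame with columns `dex`, `peg` (wt\%).
#' @param total_mass Total ATPS mass per sample, mg (default 500).
#' @param sigma_top_mass Weighing noise sd, mg (default 2).
#' @param n_reps Replicates per composition (default 3).
#' @param seed RNG seed.
#' @return A data.frame with one row per replicate: `total_mass_mg`,
#'   `avg_peg_wtpct`, `avg_dex_wtpct`, `top_mass_mg`, `replicate_id`, and
#'   the true endpoint compositions (`true_top_peg`, ...) for recovery
#'   checks.
#' @export
simulate_gravimetric <- function(truth, avg_compositions, total_mass = 500,
                                 sigma_top_mass = 2, n_reps = 3L,
                                 seed = 1L) {
  stopifnot(inherits(truth, "atps_truth"),
            is.data.frame(avg_compositions),
            all(c("dex", "peg") %in% names(avg_compositions)))
  rows <- withr_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(avg_compositions))) {
      avg <- composition(avg_compositions$dex[i], avg_compositions$peg[i])
      tl <- truth_tieline(truth, avg)
      f_top <- attr(tl, "f_top")
      for (r in seq_len(n_reps)) {
        tm <- f_top * total_mass + stats::rnorm(1, 0, sigma_top_mass)
        out[[length(out) + 1L]] <- data.frame(
          total_mass_mg = total_mass,
          avg_peg_wtpct = avg$peg, avg_dex_wtpct = avg$dex,
          top_mass_mg = tm, replicate_id = r,
          true_top_peg = tl$top$peg, true_top_dex = tl$top$dex,
          true_bottom_peg = tl$bottom$peg, true_bottom_dex = tl$bottom$dex)
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Simulate microgel property measurements
#'
#' Draws AFM-like stiffnesses (kPa) and rheology-like moduli (Pa) from the
#' ground-truth property surfaces with heteroscedastic noise (sd
#' proportional to the true value), TGA-like pellet polymer contents from
#' the true line with additive noise, and microgel diameters from the
#' lognormal size model.
#'
#' @param truth An [atps_ground_truth()].
#' @param formulations A data.frame with columns `formulation_id`,
#'   `peg_avg` (wt\%) and `vr` (mL/mL).
#' @param n_afm,n_rheo,n_tga,n_size Observations per formulation
#'   (defaults mirror a realistic design: 10 microgels by AFM, 3 scaffolds
#'   by rheology, 3 TGA samples, 300 sized microgels).
#' @param cv_afm,cv_rheo Coefficient of variation of the multiplicative
#'   noise (default 0.30 and 0.15).
#' @param sigma_tga Additive TGA noise sd, wt\% (default 0.1).
#' @param sdlog_override Optional named numeric vector mapping
#'   `formulation_id` to a replacement lognormal `sdlog` (e.g. to emulate
#'   the elevated polydispersity of a fast-coarsening formulation).
#' @param seed RNG seed.
#' @return A list with data.frames `measurements` (columns
#'   `formulation_id`, `peg_avg`, `vr`, `property_kind`
#'   in `afm_stiffness_kPa` / `rheology_modulus_Pa` / `pellet_polymer_wtpct`,
#'   `value`) and `diameters` (`formulation_id`, `diameter_um`).
#' @export
simulate_property_measurements <- function(truth, formulations,
                                           n_afm = 10L, n_rheo = 3L,
                                           n_tga = 3L, n_size = 300L,
                                           cv_afm = 0.30, cv_rheo = 0.15,
                                           sigma_tga = 0.1,
                                           sdlog_override = NULL,
                                           seed = 1L) {
  stopifnot(inherits(truth, "atps_truth"), is.data.frame(formulations),
            all(c("formulation_id", "peg_avg", "vr") %in%
                  names(formulations)))
  surf <- function(p, peg, vr) p[[1]] * peg + p[[2]] / vr + p[[3]]
  withr_seed(seed, {
    meas <- list(); dia <- list()
    for (i in seq_len(nrow(formulations))) {
      id <- formulations$formulation_id[i]
      peg <- formulations$peg_avg[i]; vr <- formulations$vr[i]
      mu_afm <- surf(truth$stiffness, peg, vr)
      mu_rhe <- surf(truth$rheology, peg, vr)
      mu_tga <- truth$tga_line[[1]] * peg + truth$tga_line[[2]]
      add <- function(kind, vals) {
        if (length(vals) == 0L) return(NULL)
        data.frame(formulation_id = id, peg_avg = peg, vr = vr,
                   property_kind = kind, value = vals)
      }
      meas[[length(meas) + 1L]] <- add(
        "afm_stiffness_kPa",
        pmax(mu_afm + stats::rnorm(n_afm, 0, cv_afm * mu_afm), 1e-3))
      meas[[length(meas) + 1L]] <- add(
        "rheology_modulus_Pa",
        pmax(mu_rhe + stats::rnorm(n_rheo, 0, cv_rheo * mu_rhe), 1e-3))
      meas[[length(meas) + 1L]] <- add(
        "pellet_polymer_wtpct",
        pmax(mu_tga + stats::rnorm(n_tga, 0, sigma_tga), 1e-3))
      sdl <- truth$size_model[["sdlog"]]
      if (!is.null(sdlog_override) && id %in% names(sdlog_override))
        sdl <- sdlog_override[[id]]
      if (n_size > 0L)
        dia[[length(dia) + 1L]] <- data.frame(
          formulation_id = id,
          diameter_um = stats::rlnorm(
            n_size,
            meanlog = log(truth$size_model[["d0"]]) -
              truth$size_model[["k"]] * log(vr),
            sdlog = sdl))
    }
    list(measurements = do.call(rbind, meas),
         diameters = do.call(rbind, dia))
  })
}
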
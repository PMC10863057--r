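# End-to-end pipeline: binodal fit -> tie-line solves -> conjugate fit ->
# tie-line interpolation -> volume ratios -> property fits -> Monte Carlo.

#' Run the full phase-diagram pipeline
#'
#' Executes every stage on the tables named in the configuration and
#' writes a machine-readable JSON report plus per-stage outputs to the
#' output directory. Reruns with identical inputs and seed produce a
#' byte-identical report (no timestamps are recorded; inputs are
#' identified by md5 hash).
#'
#' @param config A named list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{`cloudpoints`}{path to the cloud-point CSV (required); see
#'       [read_cloudpoints()].}
#'     \item{`gravimetric`}{path to the gravimetric CSV (required); see
#'       [read_gravimetric()].}
#'     \item{`measurements`}{path to the property CSV (optional); see
#'       [read_measurements()].}
#'     \item{`targets`}{optional data.frame (or list of lists) of target
#'       average compositions `dex`, `peg` to interpolate.}
#'     \item{`binodal_form`}{`"exp_inverse"` (default) or `"exp"`.}
#'     \item{`rho_top`, `rho_bottom`}{phase densities, g/mL (defaults 1.0,
#'       1.1).}
#'     \item{`seed`}{integer seed used for every stochastic stage
#'       (default 1).}
#'     \item{`n_mc`}{Monte Carlo iterations per solved tie-line (0 =
#'       skip, the default).}
#'     \item{`outdir`}{output directory (required).}
#'   }
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("cloudpoints", "gravimetric", "outdir"))
    if (is.null(config[[key]]))
      stop("pipeline config is missing required entry '", key, "'",
           call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  rho <- phase_densities(config$rho_top %||% 1.0, config$rho_bottom %||% 1.1)
  form <- config$binodal_form %||% "exp_inverse"
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  report <- list(seed = seed,
                 densities = list(rho_top = rho$rho_top,
                                  rho_bottom = rho$rho_bottom),
                 inputs = list())
  for (key in c("cloudpoints", "gravimetric", "measurements"))
    if (!is.null(config[[key]]))
      report$inputs[[key]] <- list(
        path = config[[key]], md5 = unname(tools::md5sum(config[[key]])))

  # -- binodal ---------------------------------------------------------------
  cp <- stage("read-cloudpoints", read_cloudpoints(config$cloudpoints))
  bfit <- stage("fit-binodal", fit_binodal(cp, form = form, seed = seed))
  check_binodal_shape(bfit$params,
                      x_range = c(max(min(cp$dex) / 2, 0.05), max(cp$dex)))
  write_binodal_json(bfit, file.path(outdir, "binodal.json"),
                     data_file = config$cloudpoints)
  report$binodal <- list(form = bfit$form,
                         params = as.list(bfit$params$par),
                         rss = bfit$rss, n_points = bfit$n_points,
                         convergence = bfit$convergence)

  # -- tie-lines -------------------------------------------------------------
  grav <- stage("read-gravimetric", read_gravimetric(config$gravimetric))
  solved <- stage("solve-tielines", lapply(seq_len(nrow(grav)), function(i) {
    e <- gravimetric_experiment(
      grav$total_mass_mg[i],
      composition(grav$avg_dex_wtpct[i], grav$avg_peg_wtpct[i]),
      grav$top_mass_mg[i])
    solve_tieline(e, bfit$params)
  }))
  tl_df <- tielines_table(solved, rho)
  tl_df$replicate_id <- grav$replicate_id
  write_tielines(tl_df, file.path(outdir, "tielines.csv"))
  report$tielines <- tl_df

  # replicate means per distinct average composition anchor the conjugate
  key <- paste(grav$avg_dex_wtpct, grav$avg_peg_wtpct)
  mean_df <- do.call(rbind, lapply(split(tl_df, key)[unique(key)],
                                   function(d) {
    data.frame(avg_peg = d$avg_peg[1], avg_dex = d$avg_dex[1],
               top_peg = mean(d$top_peg), top_dex = mean(d$top_dex),
               bottom_peg = mean(d$bottom_peg),
               bottom_dex = mean(d$bottom_dex))
  }))
  conj <- stage("fit-conjugate", fit_conjugate(mean_df))
  report$conjugate <- list(q0 = conj$q0, q1 = conj$q1, q2 = conj$q2,
                           anchor_range = conj$range)

  # -- interpolation ---------------------------------------------------------
  if (!is.null(config$targets)) {
    tgt <- config$targets
    if (!is.data.frame(tgt))
      tgt <- do.call(rbind, lapply(tgt, as.data.frame))
    interp <- stage("interpolate", lapply(seq_len(nrow(tgt)), function(i) {
      interpolate_tieline(composition(tgt$dex[i], tgt$peg[i]),
                          bfit$params, conj)
    }))
    int_df <- tielines_table(interp, rho)
    int_df$extrapolated <- vapply(interp, function(tl)
      isTRUE(attr(tl, "extrapolated")), logical(1))
    write_tielines(int_df, file.path(outdir, "interpolated.csv"))
    report$interpolated <- int_df
  }

  # -- property models -------------------------------------------------------
  if (!is.null(config$measurements)) {
    meas <- stage("read-measurements", read_measurements(config$measurements))
    fits <- list()
    for (kind in unique(meas$property_kind)) {
      d <- meas[meas$property_kind == kind, ]
      d2 <- data.frame(peg_avg = d$peg_avg_wtpct, vr = d$volume_ratio,
                       value = d$value)
      lin <- stage(paste0("fit-linear-", kind), fit_linear_peg(d2))
      surf <- tryCatch(fit_property_surface(d2), error = function(e) NULL)
      fits[[kind]] <- list(
        linear = list(slope = lin$slope, intercept = lin$intercept,
                      r2 = lin$r2, adj_r2 = lin$adj_r2,
                      pred_r2 = lin$pred_r2),
        surface = if (!is.null(surf)) list(
          a = surf$a, b = surf$b, c = surf$c, form = surf$form,
          r2 = surf$r2, adj_r2 = surf$adj_r2, pred_r2 = surf$pred_r2,
          vcov = unclass(surf$vcov)) else NULL)
    }
    report$properties <- fits
  }

  # -- Monte Carlo -----------------------------------------------------------
  n_mc <- as.integer(config$n_mc %||% 0L)
  if (n_mc > 0L) {
    noise <- noise_model(
      sigma_top_mass = config$sigma_top_mass %||% 2,
      sigma_avg_comp = config$sigma_avg_comp %||% 0.05)
    first <- !duplicated(key)
    mc <- stage("mc", lapply(which(first), function(i) {
      e <- gravimetric_experiment(
        grav$total_mass_mg[i],
        composition(grav$avg_dex_wtpct[i], grav$avg_peg_wtpct[i]),
        grav$top_mass_mg[i])
      s <- mc_tielines(e, bfit, noise, n_iter = n_mc, seed = seed, rho = rho)
      list(avg_dex = grav$avg_dex_wtpct[i], avg_peg = grav$avg_peg_wtpct[i],
           n_iter = s$n_iter, n_failed = s$n_failed, summary = s$summary)
    }))
    report$mc <- mc
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(report)
}
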
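# CSV schemas, JSON model files and validation for the pipeline stages.
# All numeric parsing is locale-independent (decimal point, UTF-8).

check_schema <- function(df, path, required, numeric_cols) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: column '%s' is not numeric at line %d (value '%s')",
                     path, col, bad[1] + 1L, v[bad[1]]), call. = FALSE)
      df[[col]] <- parsed
    }
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: column '%s' has a missing/non-finite value at line %d",
                   path, col, bad[1] + 1L), call. = FALSE)
  }
  df
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a cloud-point table
#'
#' Expected columns: `dex_wtpct`, `peg_wtpct`, `protocol` (header required).
#'
#' @param path CSV path.
#' @return A [cloud_points()] object.
#' @export
read_cloudpoints <- function(path) {
  df <- check_schema(read_csv_strict(path), path,
                     c("dex_wtpct", "peg_wtpct", "protocol"),
                     c("dex_wtpct", "peg_wtpct"))
  cloud_points(df$dex_wtpct, df$peg_wtpct, df$protocol)
}

#' Read a gravimetric-experiment table
#'
#' Expected columns: `total_mass_mg`, `avg_peg_wtpct`, `avg_dex_wtpct`,
#' `top_mass_mg`, `replicate_id`.
#'
#' @param path CSV path.
#' @return A data.frame (validated).
#' @export
read_gravimetric <- function(path) {
  check_schema(read_csv_strict(path), path,
               c("total_mass_mg", "avg_peg_wtpct", "avg_dex_wtpct",
                 "top_mass_mg", "replicate_id"),
               c("total_mass_mg", "avg_peg_wtpct", "avg_dex_wtpct",
                 "top_mass_mg"))
}

#' Read a property-measurement table
#'
#' Expected columns: `formulation_id`, `peg_avg_wtpct`, `volume_ratio`,
#' `property_kind`, `value`, `units`.
#'
#' @param path CSV path.
#' @return A data.frame (validated).
#' @export
read_measurements <- function(path) {
  check_schema(read_csv_strict(path), path,
               c("formulation_id", "peg_avg_wtpct", "volume_ratio",
                 "property_kind", "value", "units"),
               c("peg_avg_wtpct", "volume_ratio", "value"))
}

#' Write a fitted binodal to JSON
#'
#' Stores the form name, parameters, rss, point count, residual sd,
#' covariance and (when the source file is given) an md5 hash of the input
#' data for provenance.
#'
#' @param fit A [fit_binodal()] result.
#' @param path Output JSON path.
#' @param data_file Optional path of the CSV the fit came from (hashed).
#' @return `path`, invisibly.
#' @export
write_binodal_json <- function(fit, path, data_file = NULL) {
  stopifnot(inherits(fit, "binodal_fit"))
  obj <- list(form = fit$form, params = as.list(fit$params$par),
              rss = fit$rss, n_points = fit$n_points,
              sigma = fit$sigma, convergence = fit$convergence,
              vcov = if (!is.null(fit$vcov)) unclass(fit$vcov) else NULL,
              data_md5 = if (!is.null(data_file))
                unname(tools::md5sum(data_file)) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted binodal from JSON
#' @param path JSON path written by [write_binodal_json()].
#' @return A list mimicking a [fit_binodal()] result (class
#'   `"binodal_fit"`).
#' @export
read_binodal_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  params <- if (obj$form == "exp_inverse") {
    binodal_params(p$A, p$B, p$C, p$D, form = "exp_inverse")
  } else {
    binodal_params(p$A, p$B, p$C, form = "exp")
  }
  vc <- if (!is.null(obj$vcov)) as.matrix(obj$vcov) else NULL
  if (!is.null(vc)) dimnames(vc) <- list(names(params$par), names(params$par))
  structure(list(params = params, rss = obj$rss, n_points = obj$n_points,
                 convergence = obj$convergence, vcov = vc,
                 sigma = obj$sigma, form = obj$form, data = NULL),
            class = "binodal_fit")
}

#' Write a tie-line table to CSV
#'
#' @param tielines A list of [tie_line()] objects or the data.frame from
#'   [tielines_table()].
#' @param path Output CSV path.
#' @param rho [phase_densities()] used for the volume-ratio column.
#' @return `path`, invisibly.
#' @export
write_tielines <- function(tielines, path, rho = phase_densities()) {
  df <- if (is.data.frame(tielines)) tielines else
    tielines_table(tielines, rho)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled reference tie-line compositions
#'
#' Gravimetrically determined tie-lines for a 4-arm PEG 20 kDa / dextran
#' 40 kDa ATPS in PBS: six average compositions with the equilibrium
#' compositions of their separated phases (replicate means; entries below
#' reporting precision are stored as 0).
#'
#' @return A data.frame with columns `avg_peg`, `avg_dex`, `top_peg`,
#'   `top_dex`, `bottom_peg`, `bottom_dex` (all wt\%).
#' @export
reference_tielines <- function() {
  path <- system.file("extdata", "empirical_tielines.csv",
                      package = "atpsdiagram", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled reference microgel formulations
#'
#' The five ATPS formulations used for microgel synthesis in the same
#' reference system: average compositions, interpolated phase
#' compositions, and the reported density-corrected dextran:PEG volume
#' ratio.
#'
#' @return A data.frame with columns `formulation`, `avg_peg`, `avg_dex`,
#'   `top_peg`, `top_dex`, `bottom_peg`, `bottom_dex`, `volume_ratio`.
#' @export
reference_formulations <- function() {
  path <- system.file("extdata", "microgel_formulations.csv",
                      package = "atpsdiagram", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
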
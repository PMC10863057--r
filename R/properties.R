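# Phenomenological models linking ATPS formulation variables to microgel
# material properties, plus small derived statistics (PDI of diameters,
# Bartlett-gated group-comparison routing).

press_statistic <- function(fit) {
  # PRESS via the hat-matrix shortcut: sum((e_i / (1 - h_ii))^2)
  r <- stats::residuals(fit)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  sum((r / (1 - h))^2)
}

fit_diagnostics <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  n <- length(y)
  p <- length(stats::coef(fit))
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  pred <- 1 - press_statistic(fit) / sst
  list(r2 = r2, adj_r2 = adj, pred_r2 = pred)
}

property_surface_forms <- c("inverse_vr", "linear_vr")

#' Fit the formulation-to-property surface
#'
#' Fits the phenomenological model relating a microgel property to the
#' average PEG concentration of the ATPS and the dextran:PEG volume ratio.
#' The default form is linear in PEG and inverse in the volume ratio,
#'
#'   `value = a * peg_avg + b / vr + c`,
#'
#' chosen because pellet polymer content tracks average PEG linearly while
#' stiffness falls with increasing volume ratio. The alternative
#' `"linear_vr"` form replaces `b / vr` with `b * vr`. Both are linear in
#' the parameters and fitted by [stats::lm()]; diagnostics include the
#' PRESS-based predicted R-squared used to flag overfitting.
#'
#' @param data A data.frame with columns `peg_avg` (wt\%), `vr` (mL/mL) and
#'   `value` (property units: kPa for AFM stiffness, Pa for shear storage
#'   modulus, wt\% for pellet polymer content). Replicates enter
#'   individually, unweighted.
#' @param form `"inverse_vr"` (default) or `"linear_vr"`.
#' @return An object of class `"property_fit"`: coefficients `a`, `b`, `c`,
#'   diagnostics `r2`/`adj_r2`/`pred_r2`, standard errors `se`, covariance
#'   matrix `vcov`, the `form` name, and the underlying `model`.
#' @examples
#' d <- data.frame(peg_avg = c(3.5, 3.5, 2.2, 5.3, 4.0),
#'                 vr = c(3.79, 6.88, 11.48, 4.24, 9.26))
#' d$value <- 2 * d$peg_avg + 30 / d$vr + 5
#' fit_property_surface(d)
#' @export
fit_property_surface <- function(data, form = "inverse_vr") {
  form <- match.arg(form, property_surface_forms)
  stopifnot(is.data.frame(data),
            all(c("peg_avg", "vr", "value") %in% names(data)))
  if (nrow(data) < 4L)
    stop("need at least 4 measurements for the 3-parameter surface",
         call. = FALSE)
  if (length(unique(data$vr)) < 2L)
    stop("design is rank-deficient: all measurements share one volume ",
         "ratio, so the vr term is not identifiable", call. = FALSE)
  if (length(unique(data$peg_avg)) < 2L)
    stop("design is rank-deficient: all measurements share one average ",
         "PEG concentration, so the PEG term is not identifiable",
         call. = FALSE)
  d <- data.frame(value = data$value, peg_avg = data$peg_avg,
                  vterm = if (form == "inverse_vr") 1 / data$vr else data$vr)
  fit <- stats::lm(value ~ peg_avg + vterm, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("design is rank-deficient: the PEG and volume-ratio regressors ",
         "are collinear", call. = FALSE)
  co <- stats::coef(fit)
  diag <- fit_diagnostics(fit, d$value)
  structure(list(a = unname(co[["peg_avg"]]), b = unname(co[["vterm"]]),
                 c = unname(co[["(Intercept)"]]),
                 r2 = diag$r2, adj_r2 = diag$adj_r2, pred_r2 = diag$pred_r2,
                 se = sqrt(diag(stats::vcov(fit)))[c("peg_avg", "vterm",
                                                     "(Intercept)")],
                 vcov = stats::vcov(fit), form = form, model = fit,
                 n = nrow(d)),
            class = "property_fit")
}

#' Predict from a fitted property surface
#' @param object A `"property_fit"`.
#' @param peg_avg,vr Formulation variables.
#' @param ... Unused.
#' @return Predicted property values.
#' @export
predict_property <- function(object, peg_avg, vr, ...) {
  stopifnot(inherits(object, "property_fit"))
  vt <- if (object$form == "inverse_vr") 1 / vr else vr
  object$a * peg_avg + object$b * vt + object$c
}

#' @export
print.property_fit <- function(x, ...) {
  op <- if (x$form == "inverse_vr") "/" else "*"
  cat(sprintf(
    "<property fit> value = %.5g * peg_avg + %.5g %s vr + %.5g  (n = %d)\n",
    x$a, x$b, op, x$c, x$n))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f\n",
              x$r2, x$adj_r2, x$pred_r2))
  invisible(x)
}

#' Simple linear model of a property on average PEG concentration
#'
#' OLS regression `value ~ peg_avg`, the model that suffices for pellet
#' polymer content (which tracks the average PEG concentration of the
#' ATPS, not the phase-diagram-predicted PEG-rich phase concentration).
#'
#' @param data A data.frame with columns `peg_avg` and `value`.
#' @return A list of class `"property_fit_linear"` with `slope`,
#'   `intercept`, `r2`, `adj_r2`, `pred_r2`, `se`, `vcov` and `model`.
#' @export
fit_linear_peg <- function(data) {
  stopifnot(is.data.frame(data), all(c("peg_avg", "value") %in% names(data)))
  if (nrow(data) < 3L)
    stop("need at least 3 points for the linear fit", call. = FALSE)
  if (length(unique(data$peg_avg)) < 2L)
    stop("peg_avg is constant; slope is not identifiable", call. = FALSE)
  fit <- stats::lm(value ~ peg_avg, data = data)
  diag <- fit_diagnostics(fit, data$value)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[["peg_avg"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r2 = diag$r2, adj_r2 = diag$adj_r2, pred_r2 = diag$pred_r2,
                 se = sqrt(diag(stats::vcov(fit))),
                 vcov = stats::vcov(fit), model = fit, n = nrow(data)),
            class = "property_fit_linear")
}

#' @export
print.property_fit_linear <- function(x, ...) {
  cat(sprintf("<linear fit> value = %.5g * peg_avg + %.5g  (n = %d)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f\n",
              x$r2, x$adj_r2, x$pred_r2))
  invisible(x)
}

#' Polydispersity index of particle diameters
#'
#' Ratio of the variance of the diameters to the square of their number
#' average. The population variance (denominator `n`) is used; the choice
#' of variance convention is not standardized across labs, so it is stated
#' here explicitly.
#'
#' @param diameters Numeric vector of diameters (any consistent length
#'   unit; the PDI is dimensionless and scale-invariant).
#' @return The PDI.
#' @examples
#' pdi(c(1, 2, 3))  # (2/3) / 2^2 = 0.1667
#' @export
pdi <- function(diameters) {
  stopifnot(is.numeric(diameters))
  if (length(diameters) < 2L)
    stop("PDI requires at least 2 diameters", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be finite and positive", call. = FALSE)
  m <- mean(diameters)
  v <- mean((diameters - m)^2)
  v / m^2
}

#' Bartlett-gated routing of group comparisons
#'
#' Groups are first screened with Bartlett's test for homoscedasticity. If
#' its null is not rejected (p >= `alpha`), the parametric route is taken:
#' one-way ANOVA with Tukey HSD multiple comparisons. If it is rejected,
#' the nonparametric route is taken: Kruskal-Wallis (pairwise post hoc left
#' to the caller's preferred procedure). A group with zero variance makes
#' Bartlett's statistic undefined and routes nonparametric with a warning.
#'
#' @param groups A named list of numeric vectors (each group n >= 2), or a
#'   data.frame with columns `group` and `value`.
#' @param alpha Critical p-value for the Bartlett gate (default 0.05).
#' @return A list of class `"comparison_route"`: `route`
#'   (`"anova_tukey"` or `"kruskal_dunn"`), `bartlett` (the htest, or NULL
#'   if undefined), `omnibus` (the routed test's result), and `posthoc`
#'   (TukeyHSD for the parametric route, NULL otherwise).
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
#' route_comparison(g)$route
#' @export
route_comparison <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups),
                       vapply(groups, length, 1L)))
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars == 0)) {
    warning("a group has zero variance; Bartlett's test is undefined, ",
            "routing to the nonparametric comparison", call. = FALSE)
    return(structure(list(route = "kruskal_dunn", bartlett = NULL,
                          omnibus = stats::kruskal.test(values, labels),
                          posthoc = NULL),
                     class = "comparison_route"))
  }
  bt <- stats::bartlett.test(values, labels)
  if (bt$p.value >= alpha) {
    fit <- stats::aov(values ~ labels)
    structure(list(route = "anova_tukey", bartlett = bt,
                   omnibus = fit, posthoc = stats::TukeyHSD(fit)),
              class = "comparison_route")
  } else {
    structure(list(route = "kruskal_dunn", bartlett = bt,
                   omnibus = stats::kruskal.test(values, labels),
                   posthoc = NULL),
              class = "comparison_route")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_route <- function(x, ...) {
  cat("<group comparison> route:", x$route, "\n")
  if (!is.null(x$bartlett))
    cat(sprintf("  Bartlett p = %.4g\n", x$bartlett$p.value))
  invisible(x)
}
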
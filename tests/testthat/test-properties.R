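formulation_design <- function() {
  data.frame(formulation_id = c("soft", "i1", "i2", "i3", "stiff"),
             peg_avg = c(3.5, 3.5, 2.2, 5.3, 4.0),
             vr = c(3.79, 6.88, 11.48, 4.24, 9.26))
}

loo_pred_r2 <- function(df, fit_fun, predict_fun) {
  # brute-force leave-one-out PRESS
  press <- sum(vapply(seq_len(nrow(df)), function(i) {
    f <- fit_fun(df[-i, ])
    (df$value[i] - predict_fun(f, df[i, ]))^2
  }, numeric(1)))
  1 - press / sum((df$value - mean(df$value))^2)
}

test_that("noiseless data identifies the surface exactly with R2 = 1", {
  d <- formulation_design()
  d <- d[rep(1:5, 2), ]
  d$value <- 2 * d$peg_avg + 30 / d$vr + 5
  fit <- suppressWarnings(fit_property_surface(d))
  expect_equal(c(fit$a, fit$b, fit$c), c(2, 30, 5), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(predict_property(fit, 4, 6), 2 * 4 + 30 / 6 + 5,
               tolerance = 1e-10)
  # rank-deficient designs are named, not silently dropped
  d1 <- d; d1$vr <- 5
  expect_error(fit_property_surface(d1), "volume")
  d2 <- d; d2$peg_avg <- 3
  expect_error(fit_property_surface(d2), "PEG")
})

test_that("predicted R2 by the hat-matrix shortcut equals brute-force leave-one-out", {
  set.seed(14)
  d <- formulation_design()[rep(1:5, 4), ]
  d$value <- 2 * d$peg_avg + 30 / d$vr + 5 + rnorm(nrow(d), 0, 2)
  fit <- fit_property_surface(d)
  expect_equal(fit$pred_r2,
               loo_pred_r2(d, fit_property_surface,
                           function(f, row) predict_property(f, row$peg_avg,
                                                             row$vr)),
               tolerance = 1e-10)
  dl <- data.frame(peg_avg = d$peg_avg, value = d$value)
  lin <- fit_linear_peg(dl)
  expect_equal(lin$pred_r2,
               loo_pred_r2(dl, fit_linear_peg,
                           function(f, row) f$slope * row$peg_avg +
                             f$intercept),
               tolerance = 1e-10)
  # diagnostics are ordered for OLS on the same data
  expect_lte(fit$adj_r2, fit$r2)
  expect_lte(fit$pred_r2, fit$r2)
})

test_that("surface parameters are recovered within 3 se at the design size", {
  truth <- fix_truth()
  sim <- simulate_property_measurements(truth, formulation_design(),
                                        n_afm = 10L, seed = 18)
  afm <- sim$measurements[sim$measurements$property_kind ==
                            "afm_stiffness_kPa", ]
  fit <- fit_property_surface(afm[, c("peg_avg", "vr", "value")])
  expect_lt(abs(fit$a - truth$stiffness[["a"]]), 3 * fit$se[["peg_avg"]])
  expect_lt(abs(fit$b - truth$stiffness[["b"]]), 3 * fit$se[["vterm"]])
  expect_lt(abs(fit$c - truth$stiffness[["c"]]),
            3 * fit$se[["(Intercept)"]])
})

test_that("the pellet-polymer line is recovered and the surface adds little to it", {
  truth <- fix_truth()
  sim <- simulate_property_measurements(truth, formulation_design(),
                                        n_tga = 6L, seed = 25)
  tga <- sim$measurements[sim$measurements$property_kind ==
                            "pellet_polymer_wtpct", ]
  lin <- fit_linear_peg(tga[, c("peg_avg", "value")])
  expect_lt(abs(lin$slope - truth$tga_line[["slope"]]), 3 * lin$se[[2]])
  # collinear points give a perfect line
  d <- data.frame(peg_avg = 1:5, value = 2 * (1:5) + 1)
  expect_equal(suppressWarnings(fit_linear_peg(d))$r2, 1, tolerance = 1e-12)
  expect_error(fit_linear_peg(data.frame(peg_avg = rep(3, 5),
                                         value = 1:5)), "constant")
  # data generated without any vr dependence: the surface does not
  # substantially improve on the line
  surf <- fit_property_surface(tga[, c("peg_avg", "vr", "value")])
  expect_lt(surf$adj_r2 - lin$adj_r2, 0.05)
})

test_that("surface is increasing in PEG and decreasing in vr when a, b > 0", {
  d <- formulation_design()[rep(1:5, 2), ]
  d$value <- 2 * d$peg_avg + 30 / d$vr + 5
  fit <- suppressWarnings(fit_property_surface(d))
  expect_gt(fit$a, 0); expect_gt(fit$b, 0)
  pegs <- seq(2.2, 5.3, length.out = 8)
  vrs <- seq(3.79, 11.48, length.out = 8)
  for (v in vrs)
    expect_true(all(diff(predict_property(fit, pegs, v)) > 0))
  for (p in pegs)
    expect_true(all(diff(predict_property(fit, p, vrs)) < 0))
})

test_that("repeated-design recovery of the PEG coefficient is calibrated", {
  truth <- fix_truth()
  res <- vapply(1:100, function(r) {
    sim <- simulate_property_measurements(truth, formulation_design(),
                                          n_afm = 9L, n_rheo = 0L,
                                          n_tga = 0L, n_size = 0L,
                                          seed = 1000 + r)
    afm <- sim$measurements
    fit <- fit_property_surface(afm[, c("peg_avg", "vr", "value")])
    c(rel = abs(fit$a - truth$stiffness[["a"]]) / truth$stiffness[["a"]],
      std = abs(fit$a - truth$stiffness[["a"]]) / fit$se[["peg_avg"]])
  }, numeric(2))
  # the reported standard error is calibrated: the median standardized
  # error of a well-specified fit is ~0.67 (half-normal median)
  expect_lt(median(res["std", ]), 1.5)
  # at 9 measurements/group and 30% CV noise the design carries
  # se(a)/a ~ 0.4, so the median absolute relative error sits near 0.45
  expect_lt(median(res["rel", ]), 0.6)
})

test_that("PDI matches hand arithmetic and is scale invariant", {
  expect_equal(pdi(c(1, 2, 3)), (2 / 3) / 4, tolerance = 1e-12)
  expect_identical(pdi(rep(4.2, 10)), 0)
  set.seed(2)
  d <- rlnorm(50, log(60), 0.3)
  for (k in c(0.01, 1, 250)) expect_equal(pdi(k * d), pdi(d))
  expect_error(pdi(5), "at least 2")
  expect_error(pdi(numeric(0)), "at least 2")
  expect_error(pdi(c(1, -2, 3)), "positive")
})

test_that("Bartlett gate routes homoscedastic groups to ANOVA and unequal to Kruskal", {
  base <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.4, 0.7, 1.3)
  same <- list(a = base, b = base + 2, c = base - 1)
  r1 <- route_comparison(same)
  expect_identical(r1$route, "anova_tukey")
  expect_equal(unname(r1$bartlett$statistic), 0, tolerance = 1e-10)
  expect_s3_class(r1$posthoc, "TukeyHSD")
  set.seed(31)
  uneq <- list(a = rnorm(20, 0, 1), b = rnorm(20, 0, 10))
  r2 <- route_comparison(uneq)
  expect_identical(r2$route, "kruskal_dunn")
  expect_lt(r2$bartlett$p.value, 0.05)
  expect_identical(r2$omnibus$method, "Kruskal-Wallis rank sum test")
  # zero-variance group: gate undefined, nonparametric with a warning
  expect_warning(r3 <- route_comparison(list(a = c(1, 1, 1),
                                             b = c(1, 2, 3))),
                 "zero variance")
  expect_identical(r3$route, "kruskal_dunn")
  expect_error(route_comparison(list(a = 1, b = c(1, 2))), "at least 2")
})
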
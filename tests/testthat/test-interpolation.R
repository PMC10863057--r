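make_tieline_with_midpoint <- function(xm, ym, half_dx, half_dy) {
  tie_line(top = c(dex = xm - half_dx, peg = ym + half_dy),
           bottom = c(dex = xm + half_dx, peg = ym - half_dy),
           avg = c(dex = xm, peg = ym), tol = Inf)
}

test_that("three anchors on a known quadratic are recovered exactly", {
  q <- c(5, -0.35, 0.03)
  xs <- c(6, 10, 16)
  tls <- lapply(xs, function(x)
    make_tieline_with_midpoint(x, q[1] + q[2] * x + q[3] * x^2, 3, 2))
  conj <- fit_conjugate(tls)
  expect_equal(c(conj$q0, conj$q1, conj$q2), q, tolerance = 1e-10)
  expect_equal(eval_conjugate(conj, 8), q[1] + q[2] * 8 + q[3] * 64,
               tolerance = 1e-10)
  expect_error(fit_conjugate(tls[1:2]), "at least 3")
})

test_that("noisy anchors recover the generator's conjugate within 3 se", {
  truth <- fix_truth()
  set.seed(11)
  avgs <- fix_avgs()
  tls <- lapply(seq_len(nrow(avgs)), function(i)
    truth_tieline(truth, composition(avgs$dex[i], avgs$peg[i])))
  df <- tielines_table(tls)
  # jitter each endpoint by sigma = 0.05 wt%
  for (col in c("top_peg", "top_dex", "bottom_peg", "bottom_dex"))
    df[[col]] <- pmax(df[[col]] + rnorm(nrow(df), 0, 0.05), 1e-4)
  conj <- fit_conjugate(df)
  se <- summary(conj$model)$coefficients[, "Std. Error"]
  expect_lt(abs(conj$q0 - truth$conjugate[[1]]), 3 * se[1])
  expect_lt(abs(conj$q1 - truth$conjugate[[2]]), 3 * se[2])
  expect_lt(abs(conj$q2 - truth$conjugate[[3]]), 3 * se[3])
})

test_that("the empirical tie-line midpoints follow a smooth quadratic conjugate", {
  conj <- fit_conjugate(reference_tielines())
  expect_lt(max(abs(residuals(conj$model))), 1.5)
  expect_gt(summary(conj$model)$r.squared, 0.97)
})

test_that("interpolating at an anchor's average returns that tie-line", {
  truth <- fix_truth()
  anchors <- lapply(list(c(6, 5), c(10, 7), c(18, 11)), function(a)
    truth_tieline(truth, composition(a[1], a[2])))
  conj <- fit_conjugate(anchors)
  tl <- interpolate_tieline(anchors[[2]]$avg, truth$binodal, conj)
  expect_lt(max_endpoint_err(tl, anchors[[2]]), 1e-8)
})

test_that("interpolation recovers the generator's field at random targets", {
  truth <- fix_truth()
  bfit <- fix_binodal_fit()
  avgs <- fix_avgs()
  conj <- fit_conjugate(tielines_table(lapply(seq_len(nrow(avgs)), function(i)
    truth_tieline(truth, composition(avgs$dex[i], avgs$peg[i])))))
  set.seed(9)
  n_ok <- 0L
  while (n_ok < 10L) {
    dex <- runif(1, 6, 22)
    peg <- eval_binodal(truth$binodal, dex) + runif(1, 1.5, 6)
    tgt <- composition(dex, peg)
    ref <- truth_tieline(truth, tgt)
    tl <- suppressWarnings(interpolate_tieline(tgt, bfit$params, conj))
    expect_lt(max_endpoint_err(tl, ref), 1e-4)
    n_ok <- n_ok + 1L
  }
})

test_that("formulations sharing a tie-line interpolate to near-identical endpoints", {
  bfit <- fix_reference_binodal()
  conj <- fit_conjugate(reference_tielines())
  targets <- list(c(30.97, 3.5), c(32.48, 2.2), c(28.88, 5.3))
  tls <- lapply(targets, function(a)
    suppressWarnings(
      interpolate_tieline(composition(a[1], a[2]), bfit$params, conj)))
  top_pegs <- vapply(tls, function(tl) tl$top$peg, numeric(1))
  # all three land on one tie-line at the PEG-rich end near 30 wt%
  expect_lt(max(top_pegs) - min(top_pegs), 0.1)
  for (tp in top_pegs) expect_equal(tp, 30.0, tolerance = 0.5 / 30.0)
})

test_that("interpolation beyond the anchored range warns but still solves", {
  bfit <- fix_reference_binodal()
  conj <- fit_conjugate(reference_tielines())
  expect_warning(
    tl <- interpolate_tieline(composition(39.36, 4.0), bfit$params, conj),
    "extrapolat")
  expect_true(isTRUE(attr(tl, "extrapolated")))
  expect_gt(tl$top$peg, tl$bottom$peg)
})

test_that("endpoints vary continuously as the target moves through the region", {
  truth <- fix_truth()
  conj <- fit_conjugate(tielines_table(lapply(
    list(c(6, 5), c(10, 7), c(14, 9), c(18, 11)), function(a)
      truth_tieline(truth, composition(a[1], a[2])))))
  path <- seq(0, 1, length.out = 100)
  from <- c(7, 6); to <- c(20, 11.5)
  tops <- vapply(path, function(t) {
    tgt <- composition(from[1] + t * (to[1] - from[1]),
                       from[2] + t * (to[2] - from[2]))
    suppressWarnings(
      interpolate_tieline(tgt, truth$binodal, conj))$top$peg
  }, numeric(1))
  expect_true(all(is.finite(tops)))
  expect_lt(max(abs(diff(tops))), 0.5)  # no branch jumps along the path
})

test_that("volume ratio grows monotonically toward the dextran-rich endpoint", {
  truth <- fix_truth()
  conj <- fit_conjugate(tielines_table(lapply(
    list(c(6, 5), c(10, 7), c(18, 11)), function(a)
      truth_tieline(truth, composition(a[1], a[2])))))
  ref <- truth_tieline(truth, composition(10, 7))
  ts <- seq(0.15, 0.85, length.out = 9)
  vrs <- vapply(ts, function(t) {
    tgt <- composition(
      (1 - t) * ref$top$dex + t * ref$bottom$dex,
      (1 - t) * ref$top$peg + t * ref$bottom$peg)
    volume_ratio(suppressWarnings(
      interpolate_tieline(tgt, truth$binodal, conj)))
  }, numeric(1))
  expect_true(all(diff(vrs) > 0))
})
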
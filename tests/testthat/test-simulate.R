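test_that("infinitesimal increments put cloud points on the true binodal", {
  truth <- fix_truth()
  cp <- suppressWarnings(
    simulate_cloud_titration(truth, "peg_into_dex",
                             increment_mg = c(0.05, 0.1),
                             pbs_increment_mg = c(0.5, 1),
                             total_titrant_mg = 40, seed = 1))
  dev <- abs(cp$peg - eval_binodal(truth$binodal, cp$dex))
  expect_gt(nrow(cp), 50)
  expect_lt(max(dev), 0.05)
})

test_that("the two titration arms trace complementary descending clouds", {
  truth <- fix_truth()
  cp1 <- simulate_cloud_titration(truth, "peg_into_dex", seed = 11)
  cp2 <- suppressWarnings(
    simulate_cloud_titration(truth, "dex_into_peg", seed = 12))
  expect_gte(nrow(cp1), 6)
  expect_gte(nrow(cp2), 6)
  # PEG-into-dextran explores the dextran-rich end, the reverse arm the
  # PEG-rich end
  expect_gt(max(cp1$dex), 14)
  expect_lt(min(cp2$dex), 1)
  expect_gt(max(cp2$peg), 8)
  pooled <- rbind(cp1, cp2)
  expect_lt(cor(pooled$dex, pooled$peg, method = "spearman"), -0.8)
})

test_that("a fit on protocol-increment titration data tracks the truth curve", {
  truth <- fix_truth()
  cp1 <- simulate_cloud_titration(truth, "peg_into_dex", seed = 11)
  cp2 <- suppressWarnings(
    simulate_cloud_titration(truth, "dex_into_peg", seed = 12))
  pooled <- rbind(cp1, cp2)
  fit <- suppressWarnings(
    fit_binodal(cloud_points(pooled$dex, pooled$peg, pooled$protocol),
                upper = c(B = 0)))
  g <- seq(3, 30, length.out = 150)
  # quantization-driven tolerance: recorded points overshoot one-sidedly
  expect_lt(max(abs(eval_binodal(fit$params, g) -
                      eval_binodal(truth$binodal, g))), 1)
})

test_that("gravimetric simulation round-trips and its spread tracks the noise", {
  truth <- fix_truth()
  avgs <- fix_avgs()
  g0 <- simulate_gravimetric(truth, avgs, sigma_top_mass = 0, n_reps = 1,
                             seed = 3)
  for (i in seq_len(nrow(g0))) {
    tl <- solve_tieline(
      gravimetric_experiment(g0$total_mass_mg[i],
                             composition(g0$avg_dex_wtpct[i],
                                         g0$avg_peg_wtpct[i]),
                             g0$top_mass_mg[i]),
      truth$binodal)
    ref <- tie_line(c(dex = g0$true_top_dex[i], peg = g0$true_top_peg[i]),
                    c(dex = g0$true_bottom_dex[i],
                      peg = g0$true_bottom_peg[i]),
                    composition(g0$avg_dex_wtpct[i], g0$avg_peg_wtpct[i]))
    expect_lt(max_endpoint_err(tl, ref), 1e-6)
  }
  one <- avgs[2, , drop = FALSE]
  s_small <- sd(simulate_gravimetric(truth, one, sigma_top_mass = 1,
                                     n_reps = 30, seed = 4)$top_mass_mg)
  s_big <- sd(simulate_gravimetric(truth, one, sigma_top_mass = 5,
                                   n_reps = 30, seed = 4)$top_mass_mg)
  expect_lt(s_small, s_big)
  expect_error(simulate_gravimetric(truth, data.frame(dex = 1, peg = 1)),
               "single-phase")
})

test_that("zero-noise property measurements identify the truth surfaces exactly", {
  truth <- fix_truth()
  fl <- data.frame(formulation_id = c("a", "b", "c", "d", "e"),
                   peg_avg = c(3.5, 3.5, 2.2, 5.3, 4.0),
                   vr = c(3.79, 6.88, 11.48, 4.24, 9.26))
  sim <- simulate_property_measurements(truth, fl, cv_afm = 0, cv_rheo = 0,
                                        sigma_tga = 0, n_size = 10L,
                                        seed = 6)
  afm <- sim$measurements[sim$measurements$property_kind ==
                            "afm_stiffness_kPa", ]
  fit <- suppressWarnings(
    fit_property_surface(afm[, c("peg_avg", "vr", "value")]))
  expect_equal(c(fit$a, fit$b, fit$c),
               unname(truth$stiffness), tolerance = 1e-8)
  tga <- sim$measurements[sim$measurements$property_kind ==
                            "pellet_polymer_wtpct", ]
  lin <- suppressWarnings(fit_linear_peg(tga[, c("peg_avg", "value")]))
  expect_equal(c(lin$slope, lin$intercept), unname(truth$tga_line),
               tolerance = 1e-8)
})

test_that("diameters shrink with volume ratio and PDI responds to the size spread", {
  truth <- fix_truth()
  fl <- data.frame(formulation_id = c("lowvr", "highvr", "stiff"),
                   peg_avg = c(3.5, 2.2, 4.0), vr = c(3.79, 11.48, 9.26))
  sim <- simulate_property_measurements(
    truth, fl, n_afm = 0L, n_rheo = 0L, n_tga = 0L, n_size = 300L,
    sdlog_override = c(stiff = 0.6), seed = 8)
  med <- tapply(sim$diameters$diameter_um, sim$diameters$formulation_id,
                median)
  expect_gt(med[["lowvr"]], med[["highvr"]])
  pdis <- tapply(sim$diameters$diameter_um, sim$diameters$formulation_id,
                 pdi)
  expect_gt(pdis[["stiff"]], max(pdis[["lowvr"]], pdis[["highvr"]]))
})

test_that("generated tables conform to the pipeline CSV schemas", {
  truth <- fix_truth()
  tmp <- withr::local_tempdir()
  grav <- simulate_gravimetric(truth, fix_avgs(), seed = 9)
  gpath <- file.path(tmp, "gravimetric.csv")
  write.csv(grav[, c("total_mass_mg", "avg_peg_wtpct", "avg_dex_wtpct",
                     "top_mass_mg", "replicate_id")],
            gpath, row.names = FALSE)
  expect_silent(gr <- read_gravimetric(gpath))
  expect_identical(nrow(gr), nrow(grav))
  cp <- simulate_cloud_titration(truth, "peg_into_dex", seed = 10)
  cpath <- file.path(tmp, "cloudpoints.csv")
  write.csv(data.frame(dex_wtpct = cp$dex, peg_wtpct = cp$peg,
                       protocol = cp$protocol),
            cpath, row.names = FALSE)
  expect_s3_class(read_cloudpoints(cpath), "cloud_points")
})
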
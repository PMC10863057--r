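# Shared fixtures. Heavy objects are memoized so the suite builds them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

fix_truth <- function() memo("truth", atps_ground_truth())

# the six empirical average compositions used throughout
fix_avgs <- function() data.frame(dex = c(6, 8, 10, 12, 18, 24),
                                  peg = c(5, 6, 7, 8, 11, 13))

# exact on-curve cloud points: the infinitesimal-increment limit
fix_exact_cloud <- function() {
  truth <- fix_truth()
  x <- c(seq(0.4, 2, length.out = 8), seq(3, 30, length.out = 14))
  cloud_points(x, eval_binodal(truth$binodal, x))
}

fix_binodal_fit <- function() memo("bfit", fit_binodal(fix_exact_cloud()))

# binodal constrained to the empirical tie-line endpoints (decreasing branch)
fix_reference_binodal <- function() memo("ref_bfit", {
  t1 <- reference_tielines()
  suppressWarnings(fit_binodal(
    cloud_points(c(t1$top_dex, t1$bottom_dex),
                 c(t1$top_peg, pmax(t1$bottom_peg, 1e-3))),
    upper = c(B = 0)))
})

ref_tieline_row <- function(t1, i) {
  tie_line(top = c(dex = t1$top_dex[i], peg = t1$top_peg[i]),
           bottom = c(dex = t1$bottom_dex[i], peg = t1$bottom_peg[i]),
           avg = c(dex = t1$avg_dex[i], peg = t1$avg_peg[i]))
}

max_endpoint_err <- function(tl, ref) {
  max(abs(c(tl$top$dex - ref$top$dex, tl$top$peg - ref$top$peg,
            tl$bottom$dex - ref$bottom$dex, tl$bottom$peg - ref$bottom$peg)))
}
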
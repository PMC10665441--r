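test_that("generate_truth is deterministic and honors sparsity", {
  cfg <- synthetic_config(n_promoters = 200, metals = c("zinc", "copper"),
                          shape_assignment = data.frame(
                            metal = c("zinc", "zinc", "copper"),
                            shape = c("fast", "steady", "late")),
                          weight_sparsity = 0.05, seed = 11)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  sizes <- lengths(t1$member_sets)
  # binomial(200 - used, 0.05) supports: about 10 promoters each
  expect_true(all(sizes >= 2 & sizes <= 25))
  # member sets are disjoint and coincide with the large-weight promoters
  expect_equal(anyDuplicated(unlist(t1$member_sets)), 0L)
  for (j in 1:3) {
    big <- rownames(t1$M_true)[abs(t1$M_true[, j]) >= cfg$weight_scale / 2]
    expect_setequal(big, t1$member_sets[[j]])
  }
  # activity rows live only in their assigned metal window
  for (j in 1:3) {
    win <- dynomodulon:::metal_window_columns(cfg$design, t1$metals[j],
                                              "induction")
    expect_true(all(t1$A_true[j, -win] == 0))
    expect_equal(max(t1$A_true[j, win]), 1)
  }
})

test_that("zero-component truth yields empty matrices", {
  cfg <- synthetic_config(n_promoters = 30, metals = c("zinc", "copper"),
                          shape_assignment = data.frame(metal = character(),
                                                        shape = character()),
                          seed = 1)
  truth <- generate_truth(cfg)
  expect_equal(ncol(truth$M_true), 0L)
  expect_equal(nrow(truth$A_true), 0L)
  X <- generate_fold_change(truth, noise_sd = 0)
  expect_true(all(X == 0))
})

test_that("more components than promoters is rejected", {
  expect_error(
    synthetic_config(n_promoters = 2, metals = c("zinc", "copper"),
                     shape_assignment = data.frame(
                       metal = rep("zinc", 3), shape = rep("steady", 3))),
    "more planted components")
})

test_that("fold-change realization adds calibrated noise", {
  cfg <- recovery_config(seed = 5)
  truth <- generate_truth(cfg)
  X0 <- generate_fold_change(truth, noise_sd = 0)
  expect_equal(X0, truth$M_true %*% truth$A_true, ignore_attr = TRUE)
  # one member of one steady component traces weight * ramp in its window
  j <- which(truth$shape_labels == "steady")[1]
  p <- truth$member_sets[[j]][1]
  win <- dynomodulon:::metal_window_columns(cfg$design, truth$metals[j],
                                            "induction")
  expect_equal(X0[p, win],
               truth$M_true[p, j] * make_shape_template("steady", 6) +
                 (truth$M_true[p, -j, drop = FALSE] %*%
                    truth$A_true[-j, win, drop = FALSE])[1, ],
               ignore_attr = TRUE)
  # Monte-Carlo: empirical residual sd within 5% of nominal at 300 x 36
  X <- generate_fold_change(truth, noise_sd = 0.25, seed = 99)
  expect_equal(sd(X - X0), 0.25, tolerance = 0.05)
  # determinism
  expect_identical(X, generate_fold_change(truth, noise_sd = 0.25, seed = 99))
})

test_that("raw fluorescence round-trips through preprocessing", {
  cfg <- monotone_config()
  truth <- generate_truth(cfg)
  raw <- generate_raw_fluorescence(truth)
  expect_identical(raw, generate_raw_fluorescence(truth))
  norm <- preprocess_series(raw$series, raw$control)
  X <- build_fold_change_matrix(norm, cfg$design, "induction")
  planted <- generate_fold_change(truth, noise_sd = 0)
  expect_lt(max(abs(X - planted[rownames(X), colnames(X)])), 1e-9)
})

test_that("zero-weight truth gives flat fold changes from raw data", {
  cfg <- synthetic_config(n_promoters = 15, metals = c("zinc", "copper"),
                          shape_assignment = data.frame(metal = character(),
                                                        shape = character()),
                          noise_sd = 0, spike_prob = 0,
                          control_drift_per_min = 0, seed = 2)
  truth <- generate_truth(cfg)
  raw <- generate_raw_fluorescence(truth)
  X <- build_fold_change_matrix(preprocess_series(raw$series, raw$control),
                                cfg$design, "induction")
  expect_lt(max(abs(X)), 1e-9)
})

test_that("an impulse artifact is removed by the kernel-11 filter", {
  cfg <- monotone_config()
  truth <- generate_truth(cfg)
  raw <- generate_raw_fluorescence(truth)
  m <- cfg$metals[1]
  p <- truth$member_sets[[1]][1]
  X_clean <- build_fold_change_matrix(
    preprocess_series(raw$series, raw$control), cfg$design, "induction")
  spike_at <- function(t) {
    spiked <- data.table::copy(raw$series)
    spiked[spiked$promoter_id == p & spiked$time_min == t,
           fluorescence := fluorescence + 20 * cfg$baseline_level]
    build_fold_change_matrix(preprocess_series(spiked, raw$control),
                             cfg$design, "induction")
  }
  # spike on locally flat signal (before the window): removed exactly
  X_flat <- spike_at(cfg$design$induction_start_min[[m]] - 70)
  expect_equal(X_flat, X_clean)
  # spike at a sampled point on the rising ramp: the median shifts by at
  # most one rank, i.e. one 10-min step of the underlying ramp
  X_ramp <- spike_at(cfg$design$induction_start_min[[m]] + 120)
  dev <- abs(X_ramp[p, ] - X_clean[p, ])
  step <- max(abs(diff(X_clean[p, 1:6]))) / 4  # one grid step in log2 units
  expect_lt(max(dev), step + 1e-9)
  expect_gt(max(dev), 0)  # the rank shift is real
  # all other promoters are untouched
  others <- setdiff(rownames(X_clean), p)
  expect_equal(X_ramp[others, ], X_clean[others, ])
})

test_that("isolated activity peaks are attenuated by the median filter", {
  # a known property of median filtering: a peak at a sampled point is
  # replaced by its larger flank; the fast shape's first sample is halved
  metals <- c("zinc", "copper")
  cfg <- synthetic_config(n_promoters = 40, metals = metals,
                          shape_assignment = data.frame(
                            metal = metals, shape = c("fast", "steady")),
                          weight_sparsity = 0.1, noise_sd = 0,
                          spike_prob = 0, control_drift_per_min = 0,
                          seed = 3)
  truth <- generate_truth(cfg)
  raw <- generate_raw_fluorescence(truth)
  X <- build_fold_change_matrix(preprocess_series(raw$series, raw$control),
                                cfg$design, "induction")
  planted <- generate_fold_change(truth, noise_sd = 0)
  p <- truth$member_sets[[1]][1]
  w <- truth$M_true[p, 1]
  # peak column: planted w * 1, observed ~ w * 0.5 (larger flank)
  expect_equal(X[p, "zinc:1"], w * 0.5, tolerance = 0.05)
  # the monotone remainder of the window is exact
  expect_equal(X[p, paste0("zinc:", 3:6)],
               planted[p, paste0("zinc:", 3:6)], tolerance = 1e-9)
})

test_that("series files round-trip through write/read", {
  cfg <- monotone_config(n_promoters = 5)
  raw <- generate_raw_fluorescence(generate_truth(cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(raw$series, path)
  back <- read_series(path)
  expect_equal(as.data.frame(back), as.data.frame(raw$series))
})
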
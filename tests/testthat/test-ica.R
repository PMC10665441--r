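test_that("dimension selection matches the eigen-spectrum oracle", {
  # rank-1 matrix
  X1 <- outer(rnorm(30), rnorm(8))
  expect_equal(select_dimension(X1), 1L)
  # planted variance shares (0.60, 0.30, 0.09, 0.01): k = 3 at 99%
  # (gene-space basis built mean-zero so centering preserves the shares)
  set.seed(10)
  U <- qr.Q(qr(scale(matrix(rnorm(200 * 4), 200, 4), scale = FALSE)))
  V <- qr.Q(qr(matrix(rnorm(6 * 4), 6, 4)))
  X <- U %*% diag(sqrt(c(0.60, 0.30, 0.09, 0.01))) %*% t(V)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(which(cumsum(ev) / sum(ev) >= 0.99)[1], 3)  # oracle
  expect_equal(select_dimension(X, 0.99), 3L)
  # full variance on a tall full-rank matrix
  set.seed(11)
  Xf <- matrix(rnorm(40 * 4), 40, 4)
  expect_equal(select_dimension(Xf, 1.0), 4L)
  expect_error(select_dimension(matrix(1, 5, 5)), "zero variance")
})

test_that("single ICA runs recover strongly non-Gaussian planted components", {
  cfg <- recovery_config(seed = 8)
  truth <- generate_truth(cfg)
  X <- generate_fold_change(truth, noise_sd = 0)
  k <- select_dimension(X)
  expect_equal(k, 5L)
  conf <- ica_config(fast_test = TRUE, base_seed = 8)
  ens <- run_ica_ensemble(X, k, conf)
  expect_identical(ens, run_ica_ensemble(X, k, conf))  # determinism
  for (run in ens) {
    expect_equal(unname(colSums(run$M^2)), rep(1, k), tolerance = 1e-8)
    # sign convention: largest-magnitude entry positive
    expect_true(all(apply(run$M, 2, function(m) m[which.max(abs(m))] > 0)))
    r <- match_planted(run$M, truth$M_true)
    expect_true(all(r > 0.95))
  }
})

test_that("rank-1 data yields the planted vector up to scale and sign", {
  set.seed(3)
  m <- rnorm(60)^3  # heavy-tailed
  a <- runif(10, 0.5, 2)
  X <- outer(m, a)
  ens <- run_ica_ensemble(X, 1, ica_config(fast_test = TRUE, base_seed = 1))
  expect_gt(abs(cor(ens[[1]]$M[, 1], m)), 0.999)
})

test_that("component clustering matches a brute-force distance grouping", {
  # build a synthetic ensemble: 10 runs x (3 planted near-copies + 2 noise)
  set.seed(14)
  planted <- matrix(rnorm(80 * 3)^3, 80, 3)
  planted <- sweep(planted, 2, sqrt(colSums(planted^2)), "/")
  ens <- lapply(1:10, function(r) {
    Mp <- planted + matrix(rnorm(80 * 3, 0, 0.002), 80, 3)
    Mn <- matrix(rnorm(80 * 2), 80, 2)
    M <- cbind(Mp, Mn)
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    M <- M * rep(sample(c(-1, 1), 5, replace = TRUE), each = 80)
    list(M = M, A = matrix(0, 5, 4))
  })
  ens <- structure(ens, class = "ica_ensemble", n_runs_requested = 10L)
  cl <- cluster_components(ens, cluster_distance = 0.1, min_frac = 0.5)
  expect_length(cl, 3)
  expect_setequal(sapply(cl, function(x) length(x$idx)), c(10, 10, 10))
  # brute-force oracle: graph components of the pairwise |r| > 0.9 relation
  P <- do.call(cbind, lapply(ens, `[[`, "M"))
  D <- 1 - abs(cor(P))
  adj <- D <= 0.1
  oracle_labels <- rep(0L, ncol(P))
  lab <- 0L
  for (i in seq_len(ncol(P))) {
    if (oracle_labels[i] > 0) next
    lab <- lab + 1L
    comp <- i
    repeat {
      nxt <- which(rowSums(adj[, comp, drop = FALSE]) > 0 & oracle_labels == 0)
      if (!length(setdiff(nxt, comp))) break
      comp <- union(comp, nxt)
    }
    oracle_labels[comp] <- lab
  }
  big <- which(table(oracle_labels)[as.character(oracle_labels)] >= 5)
  for (x in cl) expect_length(unique(oracle_labels[x$idx]), 1)
  expect_setequal(unlist(lapply(cl, `[[`, "idx")), big)
})

test_that("a component and its negation cluster together; orthogonal ones never do", {
  v <- rnorm(50); v <- v / sqrt(sum(v^2))
  w <- rnorm(50); w <- w - v * sum(v * w); w <- w / sqrt(sum(w^2))
  M <- cbind(v, -v, w)
  D <- 1 - abs(cor(M))
  expect_lt(D[1, 2], 1e-12)
  expect_gt(D[1, 3], 0.1)
  labels <- dynomodulon:::dbscan_distance(D, eps = 0.1, min_pts = 2)
  expect_equal(labels[1], labels[2])
  expect_true(labels[3] == 0 || labels[3] != labels[1])
})

test_that("robust extraction recovers planted components on noiseless data", {
  cfg <- recovery_config(seed = 12)
  truth <- generate_truth(cfg)
  X <- generate_fold_change(truth, noise_sd = 0)
  dec <- robust_ica(X, ica_config(fast_test = TRUE, base_seed = 12))
  expect_equal(dec$n_robust, 5L)
  r <- match_planted(dec$M, truth$M_true)
  expect_true(all(r > 0.99))
  # reconstruction of the rank-5 matrix is essentially exact
  expect_lt(norm(X - reconstruct(dec), "F") / norm(X, "F"), 0.05)
  expect_true(all(dec$run_freq == 1))
})

test_that("identical runs give centroids equal to the run components", {
  cfg <- recovery_config(seed = 30)
  truth <- generate_truth(cfg)
  X <- generate_fold_change(truth, noise_sd = 0)
  ens <- run_ica_ensemble(X, 5, ica_config(fast_test = TRUE, base_seed = 2))
  # replicate run 1 ten times: centroids must equal run 1 exactly
  ens_dup <- structure(rep(ens[1], 10), class = "ica_ensemble",
                       n_runs_requested = 10L)
  cl <- cluster_components(ens_dup, 0.1, 0.5)
  expect_length(cl, 5)
  for (x in cl) {
    cent <- dynomodulon:::cluster_centroid(ens_dup, x)
    j <- x$comp[1]
    expect_equal(cent$m, ens[[1]]$M[, j], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(cent$a, ens[[1]]$A[j, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the consistency filter prunes most directions of pure noise", {
  # A fixed noise matrix has finite-sample heavy-tailed directions that are
  # genuine attractors of the contrast and can reproduce across restarts
  # (the component class flagged downstream as single-promoter artifacts);
  # the filter must still discard the bulk of the whitened dimensions.
  counts <- sapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rnorm(120 * 12), 120, 12)
    dec <- suppressMessages(
      robust_ica(X, ica_config(fast_test = TRUE, base_seed = s)))
    c(k = dec$k_pca, robust = dec$n_robust)
  })
  expect_true(all(counts["robust", ] < counts["k", ]))
})

test_that("row permutation permutes M rows; column scaling scales A", {
  cfg <- recovery_config(seed = 17, n_promoters = 120)
  truth <- generate_truth(cfg)
  X <- generate_fold_change(truth, noise_sd = 0)
  conf <- ica_config(fast_test = TRUE, base_seed = 17)
  dec <- robust_ica(X, conf)

  perm <- sample(nrow(X))
  dec_p <- robust_ica(X[perm, ], conf)
  expect_equal(dec_p$n_robust, dec$n_robust)
  # match components by |r| and compare permuted weights entrywise
  R <- abs(cor(dec$M[perm, ], dec_p$M))
  for (i in seq_len(dec$n_robust)) {
    j <- which.max(R[i, ])
    expect_gt(R[i, j], 0.9999)
    s <- sign(cor(dec$M[perm, i], dec_p$M[, j]))
    expect_equal(s * dec_p$M[, j], dec$M[perm, i], tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(s * dec_p$A[j, ], dec$A[i, ], tolerance = 1e-4,
                 ignore_attr = TRUE)
  }

  dec_s <- robust_ica(3 * X, conf)
  R2 <- abs(cor(dec$M, dec_s$M))
  for (i in seq_len(dec$n_robust)) {
    j <- which.max(R2[i, ])
    s <- sign(cor(dec$M[, i], dec_s$M[, j]))
    expect_equal(s * dec_s$M[, j], dec$M[, i], tolerance = 1e-4,
                 ignore_attr = TRUE)
    expect_equal(s * dec_s$A[j, ], 3 * dec$A[i, ], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("our FastICA core agrees with an independent implementation", {
  skip_if_not_installed("ica")
  cfg <- recovery_config(seed = 23, n_promoters = 150)
  truth <- generate_truth(cfg)
  X <- generate_fold_change(truth, noise_sd = 0)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  set.seed(1)
  fit <- ica::icafast(Xc, nc = 5, center = FALSE, maxit = 400, tol = 1e-6)
  ours <- run_ica_ensemble(X, 5, ica_config(fast_test = TRUE, base_seed = 3))
  r_ref <- match_planted(fit$S, truth$M_true)
  r_ours <- match_planted(ours[[1]]$M, truth$M_true)
  expect_true(all(r_ref > 0.99))
  expect_true(all(r_ours > 0.99))
})

test_that("decomposition matrices round-trip through delimited text", {
  cfg <- recovery_config(seed = 31, n_promoters = 80)
  X <- generate_fold_change(generate_truth(cfg), noise_sd = 0)
  dec <- robust_ica(X, ica_config(fast_test = TRUE, base_seed = 1))
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_decomposition(dec, mp, ap, header_lines = "seed=1")
  M <- read_fold_change_matrix(mp)
  expect_equal(M, dec$M, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(colnames(M), sprintf("im_%d", 0:(dec$n_robust - 1)))
})
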
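#' Configuration for robust ensemble ICA
#'
#' Parameters of the robust decomposition: an ensemble of randomly
#' initialized FastICA runs is clustered with a density-based algorithm on
#' the correlation distance `1 - |r|`, cluster centroids become candidate
#' components, and the whole ensemble-plus-clustering procedure is repeated
#' with fresh seeds; only components reproduced in every repeat are kept.
#'
#' @param n_runs FastICA runs per ensemble (default 100).
#' @param tol FastICA convergence tolerance (default 1e-6).
#' @param variance_fraction Fraction of variance the PCA dimension must
#'   explain (default 0.99).
#' @param cluster_distance Neighborhood radius on the `1 - |r|` distance
#'   (default 0.1).
#' @param min_frac Minimum cluster size as a fraction of `n_runs`
#'   (default 0.5).
#' @param n_repeats Number of independent ensemble repeats for the
#'   consistency filter (default 100).
#' @param base_seed Seed from which all run seeds are derived.
#' @param max_iter FastICA iteration cap per run (default 200). A run that
#'   has not met `tol` by then is retried once from a fresh seed; if the
#'   retry does not strictly converge either, its final iterate is used and
#'   the run is counted as unconverged. In high-dimensional regimes most
#'   whitened directions are near-Gaussian and the symmetric fixed point
#'   oscillates below the tolerance scale indefinitely; the clustering and
#'   repeat-consistency stages are the mechanism that filters any unstable
#'   components such runs contribute.
#' @param fast_test If `TRUE`, use a reduced `n_runs = n_repeats = 10`
#'   setting for quick exploratory runs and tests.
#' @return An object of class `ica_config`.
#' @export
ica_config <- function(n_runs = 100, tol = 1e-6, variance_fraction = 0.99,
                       cluster_distance = 0.1, min_frac = 0.5,
                       n_repeats = 100, base_seed = 42L, max_iter = 200,
                       fast_test = FALSE) {
  if (fast_test) { n_runs <- 10; n_repeats <- 10 }
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  if (cluster_distance <= 0 || cluster_distance >= 2)
    stop("cluster_distance must be in (0, 2)")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  structure(list(n_runs = as.integer(n_runs), tol = tol,
                 variance_fraction = variance_fraction,
                 cluster_distance = cluster_distance, min_frac = min_frac,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 max_iter = as.integer(max_iter)),
            class = "ica_config")
}

#' Select the decomposition dimension by explained variance
#'
#' Returns the smallest number of principal components of the
#' column-centered matrix whose cumulative explained variance reaches
#' `variance_fraction`.
#'
#' @param X Numeric matrix (promoters x conditions), finite entries.
#' @param variance_fraction Target cumulative variance fraction.
#' @return Integer dimension `k`, `1 <= k <= min(dim(X))`.
#' @export
select_dimension <- function(X, variance_fraction = 0.99) {
  if (nrow(X) < 2 || ncol(X) < 2) stop("X must have at least 2 rows and columns")
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d2 <- svd(Xc, nu = 0, nv = 0)$d^2
  total <- sum(d2)
  if (total <= 0) stop("X has zero variance")
  as.integer(which(cumsum(d2) / total >= variance_fraction - 1e-12)[1])
}

# Normalize and orient one (m, a) component pair in place: unit-L2 gene
# vector with its largest-magnitude entry positive; the activity vector is
# rescaled so m %*% a is unchanged.
normalize_component <- function(m, a) {
  nm <- sqrt(sum(m^2))
  if (nm == 0) return(list(m = m, a = a))
  s <- orient_sign(m / nm)
  list(m = s * m / nm, a = s * nm * a)
}

# Whiten the column-centered matrix once per ensemble: with thin SVD
# Xc = U D V', the whitened data are Z = sqrt(n) * t(U_k) (k x n, identity
# covariance across the n gene samples).
whiten_matrix <- function(Xc, k) {
  sv <- svd(Xc, nu = k, nv = 0)
  if (sv$d[k] <= sqrt(.Machine$double.eps) * sv$d[1])
    stop("matrix is numerically rank-deficient at the selected dimension")
  sqrt(nrow(Xc)) * t(sv$u)
}

#' Run an ensemble of randomly initialized FastICA decompositions
#'
#' Each run decomposes the column-centered matrix into `k` gene-space
#' sources (symmetric/parallel FastICA, log-cosh contrast) from a random
#' orthogonal initialization; sources are unit-L2-normalized and
#' sign-oriented so the largest-magnitude promoter weight is positive. The
#' data are whitened once per ensemble; the fixed-point iteration runs in
#' compiled code. A run that fails to converge within the iteration cap is
#' retried once with a derived seed and then skipped with a message.
#'
#' @param X Fold-change matrix (promoters x conditions).
#' @param k Number of components, from [select_dimension()].
#' @param config An [ica_config()].
#' @param base_seed Seed for this ensemble (defaults to the config's).
#' @return List of class `ica_ensemble`; each element has `M`
#'   (promoters x k, unit columns) and `A` (k x conditions).
#' @export
run_ica_ensemble <- function(X, k, config = ica_config(),
                             base_seed = config$base_seed) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  Z <- whiten_matrix(Xc, k)
  runs <- vector("list", config$n_runs)
  n_unconverged <- 0L
  for (r in seq_len(config$n_runs)) {
    fit <- NULL
    for (attempt in 0:1) {
      set.seed(derive_seed(base_seed, 101 * r + attempt))
      W0 <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
      cand <- .fastica_sym(Z, W0, config$tol, config$max_iter, 1.0)
      if (isTRUE(cand$converged)) { fit <- cand; break }
    }
    if (is.null(fit)) {
      # use the retry's final iterate: the downstream clustering and
      # repeat-consistency filter discard anything unstable it contributes
      if (!all(is.finite(cand$W))) {
        message(sprintf("ICA run %d produced non-finite values; skipped", r))
        next
      }
      n_unconverged <- n_unconverged + 1L
      fit <- cand
    }
    S <- fit$W %*% Z                 # k x n gene-space sources
    Amix <- S %*% Xc / n             # k x p activities (least squares)
    M <- matrix(0, n, k, dimnames = list(rownames(X), NULL))
    A <- matrix(0, k, ncol(X), dimnames = list(NULL, colnames(X)))
    for (j in seq_len(k)) {
      comp <- normalize_component(S[j, ], Amix[j, ])
      M[, j] <- comp$m
      A[j, ] <- comp$a
    }
    runs[[r]] <- list(M = M, A = A)
  }
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0L) stop("no usable ICA run")
  if (n_unconverged > 0)
    message(sprintf("%d of %d ICA runs did not reach tol=%g within %d iterations; final iterates used",
                    n_unconverged, config$n_runs, config$tol, config$max_iter))
  structure(runs, class = "ica_ensemble", k = k,
            n_runs_requested = config$n_runs, n_unconverged = n_unconverged)
}

# Density-based clustering (DBSCAN semantics) on a precomputed distance
# matrix: a point is core if at least min_pts points (itself included) lie
# within eps; clusters grow from core points; border points join the first
# cluster that reaches them; everything else is noise.
dbscan_distance <- function(D, eps, min_pts) {
  n <- nrow(D)
  neighbor <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbor, length, integer(1)) >= min_pts
  labels <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in neighbor[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Cluster the pooled components of an ICA ensemble
#'
#' Pools the gene-space components of every run and clusters them with
#' DBSCAN on the distance `d(u, v) = 1 - |cor(u, v)|`, so a component and
#' its negation coincide. The minimum cluster size is
#' `ceiling(min_frac * n_runs)` — at least half the runs under the default,
#' i.e. one member per run for a reproducible component. Noise points are
#' discarded.
#'
#' @param ensemble An `ica_ensemble`.
#' @param cluster_distance Neighborhood radius on `1 - |r|`.
#' @param min_frac Minimum cluster size as a fraction of the requested
#'   number of runs.
#' @return List of clusters; each has `idx` (pooled column indices), `run`
#'   (run of origin) and `comp` (component index within the run).
#' @export
cluster_components <- function(ensemble, cluster_distance = 0.1,
                               min_frac = 0.5) {
  stopifnot(length(ensemble) > 0)
  n_runs <- attr(ensemble, "n_runs_requested") %||% length(ensemble)
  P <- do.call(cbind, lapply(ensemble, function(r) r$M))
  run_of <- rep(seq_along(ensemble),
                vapply(ensemble, function(r) ncol(r$M), integer(1)))
  comp_of <- unlist(lapply(ensemble, function(r) seq_len(ncol(r$M))))
  D <- 1 - abs(stats::cor(P))
  min_pts <- as.integer(ceiling(min_frac * n_runs))
  labels <- dbscan_distance(D, cluster_distance, min_pts)
  lapply(setdiff(sort(unique(labels)), 0L), function(cl) {
    idx <- which(labels == cl)
    list(idx = idx, run = run_of[idx], comp = comp_of[idx])
  })
}

# Sign-aligned centroid of one cluster: members are aligned to the first
# member by the sign of their correlation, averaged, re-normalized to unit
# L2; activity vectors get the matching alignment and the inverse scaling so
# the centroid reconstruction equals the mean member reconstruction.
cluster_centroid <- function(ensemble, cluster) {
  ref <- ensemble[[cluster$run[1]]]$M[, cluster$comp[1]]
  Ms <- mapply(function(r, j) {
    m <- ensemble[[r]]$M[, j]
    s <- sign(sum(m * ref)); if (s == 0) s <- 1
    s * m
  }, cluster$run, cluster$comp)
  As <- mapply(function(r, j) {
    m <- ensemble[[r]]$M[, j]
    s <- sign(sum(m * ref)); if (s == 0) s <- 1
    s * ensemble[[r]]$A[j, ]
  }, cluster$run, cluster$comp)
  m <- rowMeans(Ms)
  a <- rowMeans(As)
  normalize_component(m, a)
}

# One ensemble + clustering pass: returns centroid M (genes x k_c) and A
# (k_c x conditions), plus cluster sizes and the fraction of runs
# represented in each cluster.
robust_pass <- function(X, k, config, base_seed) {
  ensemble <- run_ica_ensemble(X, k, config, base_seed)
  clusters <- cluster_components(ensemble, config$cluster_distance,
                                 config$min_frac)
  if (length(clusters) == 0L)
    return(list(M = matrix(numeric(0), nrow(X), 0), A = matrix(numeric(0), 0, ncol(X)),
                size = integer(0), run_freq = numeric(0)))
  cents <- lapply(clusters, cluster_centroid, ensemble = ensemble)
  list(
    M = do.call(cbind, lapply(cents, `[[`, "m")),
    A = do.call(rbind, lapply(cents, `[[`, "a")),
    size = vapply(clusters, function(cl) length(cl$idx), integer(1)),
    run_freq = vapply(clusters, function(cl)
      length(unique(cl$run)) / length(ensemble), numeric(1))
  )
}

#' Robust independent components of a fold-change matrix
#'
#' The full robust decomposition: the PCA dimension `k` is chosen to
#' explain `variance_fraction` of the variance; `n_runs` randomly seeded
#' FastICA runs are clustered into reproducible components; and the whole
#' procedure is repeated `n_repeats` times with fresh seeds. A component
#' from the first repeat is retained only if every other repeat produced a
#' cluster centroid correlated with it at `|r| > 1 - cluster_distance`
#' (greedy one-to-one matching by descending `|r|`). Retained components
#' form the promoter-weight matrix `M` (unit-L2, sign-oriented columns,
#' ids `im_0, im_1, ...`) and activity matrix `A`, with
#' `X ~ M %*% A + column means`.
#'
#' @param X Fold-change matrix (promoters x conditions).
#' @param config An [ica_config()].
#' @return Object of class `ica_decomposition`: list with `M`, `A`,
#'   `col_means`, `component_ids`, `cluster_size`, `run_freq`, `k_pca`,
#'   `n_robust`, `config`.
#' @export
robust_ica <- function(X, config = ica_config()) {
  k <- select_dimension(X, config$variance_fraction)
  passes <- lapply(seq_len(config$n_repeats), function(rep)
    robust_pass(X, k, config, derive_seed(config$base_seed, 7000 + rep)))
  first <- passes[[1]]
  keep <- seq_len(ncol(first$M))
  if (length(keep) && config$n_repeats > 1) {
    for (p in passes[-1]) {
      if (ncol(p$M) == 0L) { keep <- integer(0); break }
      R <- abs(stats::cor(first$M[, keep, drop = FALSE], p$M))
      matched <- rep(FALSE, length(keep))
      used <- rep(FALSE, ncol(p$M))
      repeat {
        best <- which(R == max(R), arr.ind = TRUE)[1, ]
        if (R[best[1], best[2]] <= 1 - config$cluster_distance) break
        matched[best[1]] <- TRUE
        used[best[2]] <- TRUE
        R[best[1], ] <- -Inf
        R[, best[2]] <- -Inf
        if (all(matched) || all(used)) break
      }
      keep <- keep[matched]
      if (length(keep) == 0L) break
    }
  }

  M <- first$M[, keep, drop = FALSE]
  A <- first$A[keep, , drop = FALSE]
  ids <- if (length(keep)) sprintf("im_%d", seq_along(keep) - 1) else character(0)
  colnames(M) <- ids
  rownames(M) <- rownames(X)
  rownames(A) <- ids
  colnames(A) <- colnames(X)
  structure(
    list(M = M, A = A, col_means = colMeans(X),
         component_ids = ids, cluster_size = first$size[keep],
         run_freq = first$run_freq[keep], k_pca = k,
         n_robust = length(keep), config = config),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("Robust ICA decomposition: %d promoters x %d conditions\n",
              nrow(x$M), ncol(x$A)))
  cat(sprintf("  PCA dimension k = %d; robust components retained = %d\n",
              x$k_pca, x$n_robust))
  if (x$n_robust == 0) cat("  (no robust components)\n")
  invisible(x)
}

#' Reconstruct the data matrix from a decomposition
#' @param decomp An `ica_decomposition`.
#' @return Numeric matrix `M %*% A` plus the stored column means.
#' @export
reconstruct <- function(decomp) {
  sweep(decomp$M %*% decomp$A, 2, decomp$col_means, `+`)
}

#' Write / read decomposition matrices as delimited text
#'
#' `M` is written promoters x components (first column `promoter_id`), `A`
#' components x conditions (first column `component_id`); component ids are
#' `im_0 ... im_{k-1}`.
#'
#' @param decomp An `ica_decomposition`.
#' @param m_path,a_path File paths.
#' @param header_lines Optional `#` comment lines to prepend.
#' @export
write_decomposition <- function(decomp, m_path, a_path, header_lines = NULL) {
  mdt <- data.table::data.table(promoter_id = rownames(decomp$M))
  mdt <- cbind(mdt, data.table::as.data.table(decomp$M))
  adt <- data.table::data.table(component_id = rownames(decomp$A))
  adt <- cbind(adt, data.table::as.data.table(decomp$A))
  for (spec in list(list(mdt, m_path), list(adt, a_path))) {
    if (length(header_lines)) writeLines(paste0("# ", header_lines), spec[[2]])
    data.table::fwrite(spec[[1]], spec[[2]], sep = "\t",
                       append = length(header_lines) > 0, col.names = TRUE)
  }
  invisible(c(m_path, a_path))
}
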
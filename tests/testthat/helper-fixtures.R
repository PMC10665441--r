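# Shared fixtures and independent oracles for the test suite.

six_metals <- c("zinc", "copper", "lead", "iron", "cadmium", "chromium")

# The five-component planted layout used for recovery experiments:
# fast + intermediate (zinc), steady (copper, iron), late (cadmium).
recovery_shapes <- data.frame(
  metal = c("zinc", "zinc", "copper", "iron", "cadmium"),
  shape = c("fast", "intermediate", "steady", "steady", "late")
)

recovery_config <- function(seed, noise_sd = 0.2, spike_prob = 0,
                            n_promoters = 300) {
  synthetic_config(
    n_promoters = n_promoters, metals = six_metals,
    shape_assignment = recovery_shapes, weight_sparsity = 0.05,
    weight_scale = 1, noise_sd = noise_sd, spike_prob = spike_prob,
    seed = seed
  )
}

# A small two-metal config with monotone activation shapes (the median
# filter preserves locally monotone signal exactly, so these support exact
# round-trip checks when noise, spikes and drift are off).
monotone_config <- function(seed = 7, noise_sd = 0, spike_prob = 0,
                            control_drift_per_min = 0, n_promoters = 40) {
  metals <- c("zinc", "copper")
  synthetic_config(
    n_promoters = n_promoters, metals = metals,
    shape_assignment = data.frame(metal = metals,
                                  shape = c("steady", "late")),
    weight_sparsity = 0.1, weight_scale = 1, noise_sd = noise_sd,
    spike_prob = spike_prob,
    control_drift_per_min = control_drift_per_min, seed = seed
  )
}

# Greedy one-to-one matching of estimated components (columns of M_est) to
# planted columns by descending |Pearson r|; returns the vector of matched
# correlations (NA for unmatched planted columns).
match_planted <- function(M_est, M_true) {
  if (is.null(dim(M_est)) || ncol(M_est) == 0)
    return(rep(NA_real_, ncol(M_true)))
  R <- abs(stats::cor(M_est, M_true))
  out <- rep(NA_real_, ncol(M_true))
  for (i in seq_len(min(ncol(M_est), ncol(M_true)))) {
    b <- which(R == max(R), arr.ind = TRUE)[1, ]
    out[b[2]] <- R[b[1], b[2]]
    R[b[1], ] <- -1
    R[, b[2]] <- -1
  }
  out
}

# Independent oracle for the K-squared membership threshold: evaluate every
# prefix of the |weight|-sorted column and take the shortest prefix whose
# remainder tests below the cutoff.
prefix_scan_members <- function(weights, cutoff = 800, positive_only = TRUE) {
  ord <- order(abs(weights), decreasing = TRUE)
  w <- weights[ord]
  n <- length(w)
  for (i in 0:(n - 20)) {
    if (dagostino_k2(w[(i + 1):n]) < cutoff) {
      removed <- names(w)[seq_len(i)]
      if (positive_only) removed <- removed[w[seq_len(i)] > 0]
      return(removed)
    }
  }
  stop("prefix scan exhausted")
}

# Direct running-median oracle with zero padding.
running_median_oracle <- function(x, k) {
  h <- (k - 1) %/% 2
  xp <- c(numeric(h), x, numeric(h))
  sapply(seq_along(x), function(i) median(xp[i:(i + k - 1)]))
}
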
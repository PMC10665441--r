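#' Configuration for the synthetic Dynomics-like data generator
#'
#' Defines planted iModulon structure and acquisition parameters for
#' synthetic promoter-reporter data. Defaults emulate the study conditions
#' of a six-metal induction experiment on a ~1800-promoter library: ten
#' biological modules (four zinc-associated with fast, intermediate, steady
#' and partial-steady activation; steady and late copper modules; one steady
#' module each for lead, iron, cadmium and chromium), sparse heavy-tailed
#' promoter weights, and 4-h induction windows sampled every 10 min.
#'
#' @param n_promoters Number of promoters in the library.
#' @param metals Condition labels, in induction order.
#' @param shape_assignment `data.frame` with columns `metal` and `shape`
#'   (one row per planted component); `shape` must be one of the labels
#'   accepted by [make_shape_template()].
#' @param weight_sparsity Fraction of promoters with a planted (member)
#'   weight per component, in (0, 1].
#' @param weight_scale Magnitude of planted member weights.
#' @param background_level Camera/chip background fluorescence (a.u.).
#' @param baseline_level Basal reporter fluorescence of the promoterless
#'   control above background (a.u.).
#' @param noise_sd Additive Gaussian noise on log2 activity, per raw sample.
#' @param spike_prob Per-sample probability of an impulse artifact in the
#'   raw fluorescence (exercises the median filter).
#' @param control_drift_per_min Slope of the slow linear culture trend
#'   shared by all strains (fractional change per minute).
#' @param seed RNG seed; all generator outputs are reproducible from it.
#' @param design An [experiment_design()]; defaults to one window per metal.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_promoters = 1805,
                             metals = c("zinc", "copper", "lead", "iron",
                                        "cadmium", "chromium"),
                             shape_assignment = default_shape_assignment(metals),
                             weight_sparsity = 0.01,
                             weight_scale = 1,
                             background_level = 100,
                             baseline_level = 200,
                             noise_sd = 0.1,
                             spike_prob = 0.001,
                             control_drift_per_min = 2e-5,
                             seed = 1L,
                             design = experiment_design(metals)) {
  shape_assignment <- as.data.frame(shape_assignment)
  k <- nrow(shape_assignment)
  if (k > n_promoters) stop("more planted components than promoters")
  if (!all(c("metal", "shape") %in% names(shape_assignment)))
    stop("shape_assignment needs columns 'metal' and 'shape'")
  if (!all(shape_assignment$metal %in% metals))
    stop("shape_assignment refers to a metal not in 'metals'")
  bad <- setdiff(shape_assignment$shape, SHAPE_LABELS)
  if (length(bad)) stop("unknown shape label: '", bad[1], "'")
  if (weight_sparsity <= 0 || weight_sparsity > 1)
    stop("weight_sparsity must be in (0, 1]")
  if (weight_scale <= 0 || background_level <= 0 || baseline_level <= 0)
    stop("all scales must be positive")
  if (noise_sd < 0 || spike_prob < 0 || spike_prob > 1)
    stop("invalid noise_sd or spike_prob")
  if (!identical(design$metals, as.character(metals)))
    stop("design metals must match 'metals'")

  structure(
    list(n_promoters = as.integer(n_promoters), metals = as.character(metals),
         shape_assignment = shape_assignment, k_true = k,
         weight_sparsity = weight_sparsity, weight_scale = weight_scale,
         background_level = background_level, baseline_level = baseline_level,
         noise_sd = noise_sd, spike_prob = spike_prob,
         control_drift_per_min = control_drift_per_min,
         seed = as.integer(seed), design = design),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_shape_assignment <- function(metals) {
  base <- data.frame(metal = metals, shape = "steady")
  extra <- data.frame(
    metal = c(metals[1], metals[1], metals[1], metals[2]),
    shape = c("fast", "intermediate", "partial_steady", "late")
  )
  rbind(base, extra[extra$metal %in% metals, , drop = FALSE])
}

#' Generate planted iModulon structure
#'
#' Draws the planted promoter-weight matrix `M_true` and activity matrix
#' `A_true` for a synthetic experiment. Each component receives a
#' non-overlapping binomial support of member promoters with weights
#' `weight_scale * (1 + N(0, 0.05^2))`; non-members get small Gaussian
#' weights `N(0, (weight_scale/20)^2)` so the weight distribution has a
#' realistic near-normal bulk for the K-squared thresholding to work
#' against. `A_true` rows carry the component's shape template inside its
#' assigned metal window and are zero elsewhere.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_truth`: list with `M_true`
#'   (promoters x k), `A_true` (k x conditions), `member_sets`,
#'   `shape_labels`, `metals` (assigned metal per component), `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_promoters
  k <- config$k_true
  design <- config$design
  promoters <- sprintf("P%04d", seq_len(n))
  labels <- condition_labels(design, "induction")

  set.seed(derive_seed(config$seed, 1))
  M <- matrix(stats::rnorm(n * k, 0, config$weight_scale / 20), n, k,
              dimnames = list(promoters,
                              if (k) sprintf("im_%d", seq_len(k) - 1)))
  A <- matrix(0, k, length(labels),
              dimnames = list(if (k) sprintf("im_%d", seq_len(k) - 1), labels))
  member_sets <- vector("list", k)
  available <- seq_len(n)
  for (j in seq_len(k)) {
    picked <- available[stats::runif(length(available)) < config$weight_sparsity]
    if (length(picked) == 0L) picked <- sample(available, 1L)
    available <- setdiff(available, picked)
    M[picked, j] <- config$weight_scale *
      (1 + stats::rnorm(length(picked), 0, 0.05))
    member_sets[[j]] <- promoters[picked]
    tpl <- make_shape_template(config$shape_assignment$shape[j],
                               design$n_induction_points)
    cols <- metal_window_columns(design, config$shape_assignment$metal[j],
                                 "induction")
    A[j, cols] <- tpl
  }

  structure(
    list(M_true = M, A_true = A, member_sets = member_sets,
         shape_labels = config$shape_assignment$shape,
         metals = config$shape_assignment$metal, config = config),
    class = "synthetic_truth"
  )
}

#' Realize a fold-change matrix from planted structure
#'
#' Computes `X = M_true %*% A_true + E` with i.i.d. Gaussian noise
#' `E ~ N(0, noise_sd^2)`. Row names are promoter ids, column names
#' `metal:j` condition labels.
#'
#' @param truth A `synthetic_truth`.
#' @param noise_sd Noise standard deviation on the fold-change scale.
#' @param seed RNG seed for the noise draw.
#' @return Numeric matrix (promoters x conditions) with attribute
#'   `phase = "induction"`.
#' @export
generate_fold_change <- function(truth, noise_sd = truth$config$noise_sd,
                                 seed = truth$config$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  X <- truth$M_true %*% truth$A_true
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 2))
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  }
  attr(X, "phase") <- "induction"
  X
}

# Piecewise-linear planted log2 activity of one component on the raw grid.
# Inside the window the template is interpolated from an anchor of 0 at the
# window start; the final value is held for a 60-min plateau after the
# window (stable GFP does not vanish instantly), then decays exponentially
# (half-life ~80 min) and is truncated to exactly zero after 480 min so the
# next window starts from a clean baseline.
component_activity_on_grid <- function(truth, j, grid) {
  config <- truth$config
  design <- config$design
  metal <- truth$metals[j]
  tpl <- make_shape_template(truth$shape_labels[j], design$n_induction_points)
  t0 <- design$induction_start_min[[metal]]
  tend <- design$induction_end_min[[metal]]
  samp <- induction_times(design, metal)
  plateau <- 60
  decay_len <- 480
  tau <- 80 / log(2)

  a <- numeric(length(grid))
  inside <- grid >= t0 & grid <= samp[length(samp)]
  a[inside] <- stats::approx(c(t0, samp), c(0, tpl), xout = grid[inside])$y
  hold <- grid > samp[length(samp)] & grid <= tend + plateau
  a[hold] <- tpl[length(tpl)]
  dec <- grid > tend + plateau & grid <= tend + plateau + decay_len
  a[dec] <- tpl[length(tpl)] * exp(-(grid[dec] - tend - plateau) / tau)
  a
}

#' Generate raw fluorescence time series
#'
#' Simulates the acquisition chain of a microfluidic reporter experiment.
#' For promoter i with planted log2 activity `la_i(t)` (weights times the
#' component activity profiles, plus per-sample Gaussian noise), the raw
#' signal is
#' `raw_i(t) = background + baseline * c(t) * (1 + 2^la_i(t)) [+ spikes]`,
#' where `c(t)` is a slowly drifting common culture trend shared by all
#' strains and the promoterless control reads
#' `background + baseline * c(t)`. Running the preprocessing chain
#' (background correction, median filter, control normalization, log2 fold
#' change) on this output recovers `la_i` exactly at the sampled points
#' when noise and spikes are off and the planted activity is locally
#' monotone, and within ~3 x `noise_sd` otherwise.
#'
#' @param truth A `synthetic_truth`.
#' @param design An [experiment_design()]; defaults to the config's.
#' @param config A [synthetic_config()]; defaults to the truth's.
#' @return List with `series` and `control`, both long-format
#'   `data.table`s with columns `promoter_id`, `time_min`, `fluorescence`,
#'   `background` (the control has `promoter_id = "promoterless"`), plus
#'   the `design`.
#' @export
generate_raw_fluorescence <- function(truth, design = truth$config$design,
                                      config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  grid <- design_grid(design)
  needed <- unlist(lapply(design$metals, function(m)
    c(reference_time(design, m, "induction"), induction_times(design, m),
      recovery_times(design, m))))
  if (!all(needed %in% grid))
    stop("design sampling grid does not cover all induction/recovery windows")

  n <- config$n_promoters
  k <- truth$config$k_true
  promoters <- rownames(truth$M_true)
  drift <- 1 + config$control_drift_per_min * grid

  act <- matrix(0, k, length(grid))
  for (j in seq_len(k)) act[j, ] <- component_activity_on_grid(truth, j, grid)
  la <- if (k) truth$M_true %*% act else matrix(0, n, length(grid))

  set.seed(derive_seed(config$seed, 3))
  if (config$noise_sd > 0)
    la <- la + matrix(stats::rnorm(length(la), 0, config$noise_sd),
                      nrow(la), ncol(la))

  base <- rep(config$baseline_level * drift, each = n)
  raw <- config$background_level + base * (1 + 2^as.vector(la))
  if (config$spike_prob > 0) {
    hit <- stats::runif(length(raw)) < config$spike_prob
    raw[hit] <- raw[hit] + 20 * config$baseline_level
  }

  series <- data.table::data.table(
    promoter_id = rep(promoters, times = length(grid)),
    time_min = rep(grid, each = n),
    fluorescence = raw,
    background = config$background_level
  )
  data.table::setorder(series, promoter_id, time_min)
  control <- data.table::data.table(
    promoter_id = "promoterless",
    time_min = grid,
    fluorescence = config$background_level + config$baseline_level * drift,
    background = config$background_level
  )
  list(series = series[], control = control[], design = design)
}

#' Write / read a long-format fluorescence series
#'
#' Delimited text with columns `promoter_id`, `time_min`, `fluorescence`,
#' `background`.
#'
#' @param series A long-format `data.table`.
#' @param path File path.
#' @return `read_series()` returns a `data.table`.
#' @export
write_series <- function(series, path) {
  data.table::fwrite(series, path, sep = "\t")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  need <- c("promoter_id", "time_min", "fluorescence", "background")
  dt <- data.table::fread(path, sep = "\t")
  if (!all(need %in% names(dt)))
    stop("series file must have columns: ", paste(need, collapse = ", "))
  dt[, need, with = FALSE]
}
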
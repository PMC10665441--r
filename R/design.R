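#' Experiment design for a multi-metal induction time course
#'
#' Describes the timing layout of a heavy-metal induction experiment on a
#' microfluidic reporter platform: for each metal an induction window
#' (default 4 h), a raw imaging grid (default every 10 min), and the sampled
#' fold-change time points (default every 40 min; 6 during induction, 20
#' during recovery). Induction fold changes are referenced to the window
#' start, recovery fold changes to the window end.
#'
#' @param metals Character vector of condition labels, in induction order.
#' @param induction_start_min Numeric vector of window start times (minutes),
#'   one per metal. Default spaces windows 1200 min apart starting at 60 min,
#'   which leaves room for the 20-point recovery tail of each window.
#' @param induction_length_min Length of each induction window in minutes.
#' @param raw_spacing_min Spacing of the raw imaging grid in minutes.
#' @param sample_spacing_min Spacing of the sampled fold-change points.
#' @param n_induction_points Sampled points per induction window.
#' @param n_recovery_points Sampled points per recovery period.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design(c("zinc", "copper"))
#' induction_times(d, "zinc")
#' @export
experiment_design <- function(metals,
                              induction_start_min = 60 + 1200 * (seq_along(metals) - 1),
                              induction_length_min = 240,
                              raw_spacing_min = 10,
                              sample_spacing_min = 40,
                              n_induction_points = 6,
                              n_recovery_points = 20) {
  metals <- as.character(metals)
  if (length(metals) == 0L || anyDuplicated(metals) > 0L)
    stop("'metals' must be a non-empty vector of unique labels")
  if (length(induction_start_min) != length(metals))
    stop("one induction start per metal is required")
  if (induction_length_min <= 0 || raw_spacing_min <= 0 || sample_spacing_min <= 0)
    stop("all durations must be positive")
  if (n_induction_points * sample_spacing_min > induction_length_min)
    stop("sampled induction points do not fit in the induction window")
  if (sample_spacing_min %% raw_spacing_min != 0)
    stop("sample spacing must be a multiple of the raw grid spacing")
  ord <- order(induction_start_min)
  if (!identical(ord, seq_along(metals)))
    stop("induction windows must be given in chronological order")
  end <- induction_start_min + induction_length_min
  if (any(induction_start_min[-1] < end[-length(end)]))
    stop("induction windows overlap")

  structure(
    list(
      metals = metals,
      induction_start_min = stats::setNames(as.numeric(induction_start_min), metals),
      induction_end_min = stats::setNames(as.numeric(end), metals),
      induction_length_min = induction_length_min,
      raw_spacing_min = raw_spacing_min,
      sample_spacing_min = sample_spacing_min,
      n_induction_points = as.integer(n_induction_points),
      n_recovery_points = as.integer(n_recovery_points)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", length(x$metals), "induction windows\n")
  cat("  metals:", paste(x$metals, collapse = ", "), "\n")
  cat(sprintf("  window length %d min, raw grid %d min, samples every %d min\n",
              x$induction_length_min, x$raw_spacing_min, x$sample_spacing_min))
  cat(sprintf("  %d induction + %d recovery points per window\n",
              x$n_induction_points, x$n_recovery_points))
  invisible(x)
}

#' Sampled time points of a design
#'
#' `induction_times()` returns the sampled induction time points for one
#' metal (window start + j * spacing, j = 1..n; the reference point at the
#' window start is not itself a sample). `recovery_times()` returns the
#' post-induction points (window end + j * spacing). `design_grid()` returns
#' the full raw imaging grid, extended past the last sampled point so that
#' median filtering has data on both sides of every sample.
#'
#' @param design An `experiment_design`.
#' @param metal One of `design$metals`.
#' @return Numeric vector of times in minutes.
#' @export
induction_times <- function(design, metal) {
  stopifnot(inherits(design, "experiment_design"))
  design$induction_start_min[[metal]] +
    design$sample_spacing_min * seq_len(design$n_induction_points)
}

#' @rdname induction_times
#' @export
recovery_times <- function(design, metal) {
  stopifnot(inherits(design, "experiment_design"))
  design$induction_end_min[[metal]] +
    design$sample_spacing_min * seq_len(design$n_recovery_points)
}

#' @rdname induction_times
#' @param margin_min Extra grid time beyond the last sampled point.
#' @export
design_grid <- function(design, margin_min = 60) {
  stopifnot(inherits(design, "experiment_design"))
  last <- max(vapply(design$metals, function(m) max(recovery_times(design, m)),
                     numeric(1)))
  seq(0, last + margin_min, by = design$raw_spacing_min)
}

#' Reference time point for a phase
#'
#' Induction fold changes are referenced to the start of the metal's
#' induction window; recovery fold changes to its end.
#'
#' @inheritParams induction_times
#' @param phase `"induction"` or `"recovery"`.
#' @return Time in minutes.
#' @export
reference_time <- function(design, metal, phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  if (phase == "induction") design$induction_start_min[[metal]]
  else design$induction_end_min[[metal]]
}

#' @rdname reference_time
#' @export
sampled_times <- function(design, metal, phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  if (phase == "induction") induction_times(design, metal)
  else recovery_times(design, metal)
}

#' Condition labels of a fold-change matrix
#'
#' Columns are ordered metal-major, then time point: `"zinc:1" ... "zinc:6",
#' "copper:1", ...`.
#'
#' @inheritParams reference_time
#' @return Character vector of `metal:j` labels.
#' @export
condition_labels <- function(design, phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  n <- if (phase == "induction") design$n_induction_points else design$n_recovery_points
  as.vector(t(outer(design$metals, seq_len(n), paste, sep = ":")))
}

#' Column indices of one metal's window in a fold-change matrix
#' @inheritParams reference_time
#' @return Integer vector of column positions.
#' @keywords internal
metal_window_columns <- function(design, metal, phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  n <- if (phase == "induction") design$n_induction_points else design$n_recovery_points
  i <- match(metal, design$metals)
  if (is.na(i)) stop("unknown metal: ", metal)
  (i - 1L) * n + seq_len(n)
}
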
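#' Background-correct a fluorescence series
#'
#' Converts raw fluorescence into signal amplification over the local
#' background: `value = (raw - background) / background`. This removes
#' camera/chip signal unrelated to the cells.
#'
#' @param series Long-format `data.table` with columns `promoter_id`,
#'   `time_min`, `fluorescence`, `background`.
#' @return `data.table` with columns `promoter_id`, `time_min`, `value`.
#' @export
background_correct <- function(series) {
  dt <- data.table::as.data.table(series)
  bad <- which(dt$background <= 0)
  if (length(bad))
    stop(sprintf("non-positive background for promoter %s at t=%g min",
                 dt$promoter_id[bad[1]], dt$time_min[bad[1]]))
  out <- dt[, list(promoter_id, time_min,
                   value = (fluorescence - background) / background)]
  data.table::setorder(out, promoter_id, time_min)
  out[]
}

#' Running median filter with zero-padded edges
#'
#' Applies a running median of odd width `kernel_size` to a numeric vector,
#' padding both ends with zeros (the convention of the common
#' signal-processing implementation of 1-d median filtering). Removes
#' isolated impulse artifacts while preserving locally monotone signal
#' exactly.
#'
#' @param x Numeric vector.
#' @param kernel_size Odd integer window width (default 11, i.e. +/-50 min
#'   on a 10-min grid).
#' @return Filtered vector, same length as `x`.
#' @examples
#' median_filter(c(0, 0, 5, 0, 0), 3)  # impulse removed
#' @export
median_filter <- function(x, kernel_size = 11) {
  k <- as.integer(kernel_size)
  if (k < 1 || k %% 2L == 0L) stop("kernel_size must be odd and >= 1")
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  if (length(x) < 1L) return(x)
  xp <- c(numeric(h), x, numeric(h))
  stats::runmed(xp, k, endrule = "keep")[(h + 1L):(h + length(x))]
}

#' @rdname median_filter
#' @param series Long-format `data.table` with a `value` column; the filter
#'   is applied per promoter along the time axis.
#' @export
median_filter_series <- function(series, kernel_size = 11) {
  dt <- data.table::as.data.table(series)
  data.table::setorder(dt, promoter_id, time_min)
  dt[, value := median_filter(value, kernel_size), by = promoter_id]
  dt[]
}

#' Normalize by the promoterless control
#'
#' Subtracts and divides the processed control signal:
#' `value = (s(t) - c(t)) / c(t)` on the intersection of the two time
#' grids. The control series is the mean processed signal of promoterless
#' strains, shared across all promoters.
#'
#' @param series Processed long-format `data.table` (`promoter_id`,
#'   `time_min`, `value`).
#' @param control_series Processed control as a `data.table` with
#'   `time_min`, `value`.
#' @return Normalized `data.table`, restricted to the shared grid.
#' @export
control_normalize <- function(series, control_series) {
  dt <- data.table::as.data.table(series)
  ctrl <- data.table::as.data.table(control_series)[, list(time_min, cvalue = value)]
  shared <- intersect(unique(dt$time_min), ctrl$time_min)
  if (length(shared) == 0L) stop("series and control share no time points")
  bad <- ctrl[time_min %in% shared & cvalue <= 0]
  if (nrow(bad))
    stop(sprintf("control signal non-positive at t=%g min", bad$time_min[1]))
  out <- merge(dt, ctrl, by = "time_min")
  out[, value := (value - cvalue) / cvalue]
  out[, cvalue := NULL]
  data.table::setorder(out, promoter_id, time_min)
  out[]
}

#' Full preprocessing chain for promoter and control series
#'
#' Fixed order: background correction, median filter (kernel 11 by
#' default), then normalization by the identically processed promoterless
#' control.
#'
#' @param series,control Raw long-format `data.table`s
#'   (`promoter_id`, `time_min`, `fluorescence`, `background`).
#' @param kernel_size Median filter width.
#' @return Normalized long-format `data.table`.
#' @export
preprocess_series <- function(series, control, kernel_size = 11) {
  s <- median_filter_series(background_correct(series), kernel_size)
  c_proc <- median_filter_series(background_correct(control), kernel_size)
  cmean <- c_proc[, list(value = mean(value)), by = time_min]
  control_normalize(s, cmean)
}

#' Build a windowed log2 fold-change matrix
#'
#' For each metal window the normalized signal is read at the phase's
#' sampled points and referenced to the window anchor (induction: window
#' start; recovery: window end); entries are
#' `log2(value(t_j) / value(t_ref))`. Columns are ordered metal-major then
#' time point (`metal:j`), giving `n_metals * n_points` columns.
#'
#' Rows whose normalized signal is non-positive at any used point are
#' offset-stabilized: a small positive constant
#' `eps = 1e-3 * median(positive normalized values)` is added to both
#' numerator and denominator of every ratio in that row; rows that remain
#' non-positive (or produce non-finite entries) are dropped with a warning.
#' Strictly positive rows are left untouched, so well-expressed promoters
#' are computed exactly.
#'
#' @param normalized Long-format normalized `data.table` from
#'   [preprocess_series()].
#' @param design An [experiment_design()].
#' @param phase `"induction"` (6 points, referenced to window start) or
#'   `"recovery"` (20 points, referenced to window end).
#' @return Numeric matrix (promoters x conditions) with `metal:j` column
#'   names and attribute `phase`.
#' @export
build_fold_change_matrix <- function(normalized, design,
                                     phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  dt <- data.table::as.data.table(normalized)
  labels <- condition_labels(design, phase)
  promoters <- unique(dt$promoter_id)

  # used time points: reference + sampled, per metal
  refs <- vapply(design$metals, function(m) reference_time(design, m, phase),
                 numeric(1))
  samp <- lapply(design$metals, function(m) sampled_times(design, m, phase))
  names(samp) <- design$metals
  grid <- unique(dt$time_min)
  for (m in design$metals) {
    miss <- which(!(samp[[m]] %in% grid))
    if (!(refs[[m]] %in% grid))
      stop(sprintf("reference time %g min (metal %s) not on the series grid",
                   refs[[m]], m))
    if (length(miss))
      stop(sprintf("missing time point for metal %s, j=%d", m, miss[1]))
  }

  used <- sort(unique(c(refs, unlist(samp))))
  wide <- data.table::dcast(dt[time_min %in% used], promoter_id ~ time_min,
                            value.var = "value")
  V <- as.matrix(wide[, -1])
  rownames(V) <- wide$promoter_id
  tcols <- as.numeric(colnames(V))
  if (anyNA(V)) {
    has_na <- rownames(V)[apply(V, 1, anyNA)]
    stop(sprintf("missing time point for promoter %s", has_na[1]))
  }

  eps <- 1e-3 * stats::median(V[V > 0])
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  needs_offset <- apply(V, 1, function(v) any(v <= 0))
  off <- ifelse(needs_offset, eps, 0)
  still_nonpos <- apply(V + off, 1, function(v) any(v <= 0))

  X <- matrix(NA_real_, nrow(V), length(labels),
              dimnames = list(rownames(V), labels))
  for (i in seq_along(design$metals)) {
    m <- design$metals[i]
    ref <- V[, match(refs[[m]], tcols)] + off
    sel <- V[, match(samp[[m]], tcols), drop = FALSE] + off
    X[, metal_window_columns(design, m, phase)] <- log2(sel / ref)
  }

  keep <- !still_nonpos & apply(X, 1, function(r) all(is.finite(r)))
  if (any(!keep))
    warning(sprintf("dropped %d promoter row(s) with non-finite fold changes: %s",
                    sum(!keep),
                    paste(utils::head(rownames(X)[!keep], 5), collapse = ", ")))
  X <- X[keep, , drop = FALSE]
  attr(X, "phase") <- phase
  X
}

#' Write / read a fold-change matrix as delimited text
#'
#' Tab-separated, promoter ids in the first column (`promoter_id`), one
#' `metal:j` column per condition. Comment lines starting with `#` (such as
#' provenance headers written by [run_pipeline()]) are ignored on read.
#'
#' @param X Fold-change matrix.
#' @param path File path.
#' @param header_lines Optional character vector of `#` comment lines to
#'   prepend.
#' @return `read_fold_change_matrix()` returns a numeric matrix.
#' @export
write_fold_change_matrix <- function(X, path, header_lines = NULL) {
  dt <- data.table::data.table(promoter_id = rownames(X))
  dt <- cbind(dt, data.table::as.data.table(X))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), path)
  data.table::fwrite(dt, path, sep = "\t", append = length(header_lines) > 0,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_fold_change_matrix
#' @export
read_fold_change_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = lines, sep = "\t")
  X <- as.matrix(dt[, -1])
  rownames(X) <- dt[[1]]
  X
}
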
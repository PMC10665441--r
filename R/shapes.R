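#' Temporal activation shape templates
#'
#' Canonical within-window activity profiles used by the synthetic-data
#' generator. Each template is a nonnegative vector over the sampled time
#' points of one induction window, max-normalized to 1; amplitude is carried
#' by the promoter weights, mirroring the scale indeterminacy of ICA.
#'
#' Shapes:
#' * `steady`: linear ramp from 1/n to 1 — activity builds over the whole
#'   window.
#' * `fast`: peak at the first sampled point with geometric decay
#'   (ratio 0.5) — an immediate response that fades.
#' * `intermediate`: unimodal peak at position `ceiling(n/2) + 1` with
#'   linear flanks — activity concentrated mid-window.
#' * `partial_steady`: linear ramp that collapses to 0.1 at the final
#'   point — steady build-up cut off by late repression.
#' * `late`: zero for the first half of the window, then a linear ramp —
#'   activation starting roughly halfway through the window.
#'
#' @param shape_label One of `"fast"`, `"intermediate"`, `"steady"`,
#'   `"partial_steady"`, `"late"`.
#' @param n_timepoints Number of sampled points in the window (>= 3).
#' @return Numeric vector of length `n_timepoints`, in `[0, 1]`, max 1.
#' @examples
#' make_shape_template("steady", 6)
#' make_shape_template("fast", 6)
#' @export
make_shape_template <- function(shape_label, n_timepoints) {
  if (n_timepoints < 3) stop("n_timepoints must be >= 3")
  n <- as.integer(n_timepoints)
  v <- switch(shape_label,
    steady = seq_len(n) / n,
    fast = 0.5^(seq_len(n) - 1),
    intermediate = {
      p <- ceiling(n / 2) + 1L
      up <- seq_len(p) / p
      down <- 1 - (seq_len(n - p)) / (n - p + 1L)
      c(up, down)
    },
    partial_steady = {
      ramp <- seq_len(n - 1L) / (n - 1L)
      c(ramp, 0.1)
    },
    late = {
      h <- floor(n / 2)
      c(rep(0, h), seq_len(n - h) / (n - h))
    },
    stop("unknown shape label: '", shape_label, "'")
  )
  v / max(v)
}

SHAPE_LABELS <- c("fast", "intermediate", "steady", "partial_steady", "late")
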
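#' D'Agostino K-squared omnibus normality statistic
#'
#' `K^2 = Z_skew^2 + Z_kurt^2`, combining D'Agostino's transformed sample
#' skewness statistic with the Anscombe-Glynn transformed kurtosis
#' statistic. Large values indicate a heavy-tailed or outlier-bearing
#' distribution; for a promoter-weight column this flags the presence of
#' genuinely regulated promoters above the near-normal bulk.
#'
#' @param values Numeric vector, at least 20 finite values (the
#'   small-sample normal approximations are unstable below that).
#' @return Nonnegative scalar statistic.
#' @export
dagostino_k2 <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 20) stop("dagostino_k2 requires at least 20 finite values")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("dagostino_k2 is undefined for a constant sample")
  m3 <- mean(xc^3); m4 <- mean(xc^4)

  # transformed skewness (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # transformed kurtosis (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  Ak <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xk * sqrt(2 / (Ak - 4))
  term2 <- sign(denom) * ((1 - 2 / Ak) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * Ak)) - term2) / sqrt(2 / (9 * Ak))

  z_skew^2 + z_kurt^2
}

#' Membership threshold configuration
#' @param k2_cutoff K-squared cutoff below which the remaining weight
#'   distribution is considered normal (default 800).
#' @param positive_only Keep only positively weighted promoters as members
#'   (default `TRUE`).
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(k2_cutoff = 800, positive_only = TRUE) {
  if (k2_cutoff <= 0) stop("k2_cutoff must be positive")
  structure(list(k2_cutoff = k2_cutoff, positive_only = positive_only),
            class = "threshold_config")
}

#' Iterative K-squared membership threshold for one weight column
#'
#' Promoters are removed one at a time in order of decreasing `|weight|`,
#' recomputing the K-squared statistic of the remaining distribution after
#' each removal, until it falls below the cutoff. The membership boundary
#' is the `|weight|` of the last promoter removed (`+Inf`, with an empty
#' member set, if the column is near-normal from the start). Members are
#' the removed promoters with positive weight when `positive_only` is set.
#'
#' @param weights Named numeric vector (one column of `M`; names are
#'   promoter ids).
#' @param cfg A [threshold_config()].
#' @return List with `threshold`, `members` (character), `removed` (all
#'   removed ids regardless of sign), `k2_final`.
#' @export
compute_threshold <- function(weights, cfg = threshold_config()) {
  if (is.null(names(weights))) stop("weights must be named by promoter id")
  ord <- order(abs(weights), decreasing = TRUE)
  w <- weights[ord]
  n <- length(w)
  n_removed <- 0L
  repeat {
    remaining <- w[(n_removed + 1L):n]
    if (length(remaining) < 20)
      stop("degenerate component: fewer than 20 promoters remain above cutoff")
    k2 <- dagostino_k2(remaining)
    if (k2 < cfg$k2_cutoff) break
    n_removed <- n_removed + 1L
  }
  removed <- names(w)[seq_len(n_removed)]
  members <- if (cfg$positive_only) removed[w[seq_len(n_removed)] > 0] else removed
  list(threshold = if (n_removed) abs(w[[n_removed]]) else Inf,
       members = members, removed = removed, k2_final = k2)
}

#' Flag components dominated by a single promoter
#'
#' A component is discarded as uninformative when its membership is a
#' single promoter, or when one promoter's squared weight exceeds `share`
#' of the column's total squared weight — both signatures of a noisy
#' promoter rather than a co-regulated set.
#'
#' @param weights Numeric weight column.
#' @param members Character vector of member ids.
#' @param share Dominance threshold on the squared-weight share
#'   (default 0.7).
#' @return Logical.
#' @export
flag_single_promoter <- function(weights, members, share = 0.7) {
  length(members) == 1L || max(weights^2) / sum(weights^2) > share
}

#' Assign the primary inducing metal of a component
#'
#' Each metal's aggregate activity is the sum of the component's activity
#' row over that metal's window columns; the metal with the largest
#' aggregate wins, ties going to the earlier metal in the design order.
#'
#' @param a_row Activity row (length `n_metals * n_points`).
#' @param design An [experiment_design()].
#' @param phase `"induction"` or `"recovery"`.
#' @return A metal label.
#' @export
assign_primary_metal <- function(a_row, design,
                                 phase = c("induction", "recovery")) {
  phase <- match.arg(phase)
  agg <- vapply(design$metals, function(m)
    sum(a_row[metal_window_columns(design, m, phase)]), numeric(1))
  design$metals[which.max(agg)]
}

#' Classify the temporal activation shape of an induction window
#'
#' Computes the center of mass (CM) of the nonnegative part of the
#' activity profile, `CM = sum(i * max(a_i, 0)) / sum(max(a_i, 0))` over
#' 1-based positions, and the highest peak (HP), the 1-based position of
#' the maximum activity (earliest on ties). The label is decided by
#' precedence from most to least specific region:
#' Fast (`CM <= 4` and `HP <= 3`), Intermediate (`CM <= 4` and `HP <= 4`),
#' Steady (`CM <= 5` and `HP >= 4`), otherwise Other. Negative activities
#' are clipped (not absolute-valued) in the CM so that repression cannot
#' shift the activation mass. Profiles with no positive activity get
#' `cm = NA` and label Other.
#'
#' @param a_window Activity values over one 6-point induction window.
#' @return List with `cm`, `hp`, `label`.
#' @examples
#' classify_shape(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))  # Steady
#' classify_shape(c(1, 0.5, 0.2, 0.1, 0, 0))        # Fast
#' @export
classify_shape <- function(a_window) {
  n <- length(a_window)
  if (n != 6) stop("shape classification is defined for 6-point windows")
  if (!all(is.finite(a_window))) stop("activity window must be finite")
  w <- pmax(a_window, 0)
  hp <- which.max(a_window)
  if (sum(w) == 0)
    return(list(cm = NA_real_, hp = hp, label = "Other"))
  cm <- sum(seq_len(n) * w) / sum(w)
  label <-
    if (cm <= 4 && hp <= 3) "Fast"
    else if (cm <= 4 && hp <= 4) "Intermediate"
    else if (cm <= 5 && hp >= 4) "Steady"
    else "Other"
  list(cm = cm, hp = hp, label = label)
}

#' Characterize the components of a decomposition as iModulons
#'
#' Applies the K-squared membership threshold, the single-promoter discard
#' flag, primary-metal assignment, and (for 6-point induction windows)
#' temporal shape classification to every robust component. Recovery-phase
#' components receive CM/HP within their primary metal's window but label
#' `"Other"`: the printed shape rules are specific to the 6-point induction
#' window.
#'
#' @param decomp An `ica_decomposition`.
#' @param design An [experiment_design()].
#' @param phase `"induction"` or `"recovery"`.
#' @param cfg A [threshold_config()].
#' @param share Dominance threshold for [flag_single_promoter()].
#' @return Object of class `imodulon_set`: list with `summary` (one row
#'   per component: id, n_members, threshold, discarded, reason,
#'   primary_metal, cm, hp, shape), `membership` (long table:
#'   imodulon_id, promoter_id, weight), `members` (named list), `decomp`.
#' @export
characterize_imodulons <- function(decomp, design,
                                   phase = c("induction", "recovery"),
                                   cfg = threshold_config(), share = 0.7) {
  phase <- match.arg(phase)
  n_pts <- if (phase == "induction") design$n_induction_points
           else design$n_recovery_points
  if (ncol(decomp$A) != length(design$metals) * n_pts)
    stop("activity matrix width does not match the design/phase")

  rows <- list(); memb <- list(); member_sets <- list()
  for (i in seq_len(decomp$n_robust)) {
    id <- decomp$component_ids[i]
    w <- decomp$M[, i]
    thr <- compute_threshold(w, cfg)
    discarded <- flag_single_promoter(w, thr$members, share)
    metal <- assign_primary_metal(decomp$A[i, ], design, phase)
    win <- decomp$A[i, metal_window_columns(design, metal, phase)]
    if (phase == "induction" && n_pts == 6) {
      shp <- classify_shape(win)
    } else {
      wpos <- pmax(win, 0)
      shp <- list(cm = if (sum(wpos) > 0)
                        sum(seq_along(win) * wpos) / sum(wpos) else NA_real_,
                  hp = which.max(win), label = "Other")
    }
    rows[[i]] <- data.table::data.table(
      imodulon_id = id, n_members = length(thr$members),
      threshold = thr$threshold, discarded = discarded,
      reason = if (discarded) "single high-coefficient promoter" else "",
      primary_metal = metal, cm = shp$cm, hp = shp$hp, shape = shp$label
    )
    if (length(thr$members))
      memb[[i]] <- data.table::data.table(
        imodulon_id = id, promoter_id = thr$members,
        weight = w[thr$members])
    member_sets[[id]] <- thr$members
  }
  structure(
    list(summary = if (length(rows)) data.table::rbindlist(rows)
                   else data.table::data.table(),
         membership = if (length(memb)) data.table::rbindlist(memb)
                      else data.table::data.table(imodulon_id = character(),
                                                  promoter_id = character(),
                                                  weight = numeric()),
         members = member_sets, phase = phase, decomp = decomp),
    class = "imodulon_set"
  )
}

#' @export
print.imodulon_set <- function(x, ...) {
  cat(sprintf("iModulon set (%s phase): %d components, %d discarded\n",
              x$phase, nrow(x$summary),
              if (nrow(x$summary)) sum(x$summary$discarded) else 0L))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Functional category shift between induction and recovery
#'
#' Counts unique member promoters per functional category in each phase,
#' given a user-supplied annotation table (such tables come from manual
#' literature curation and are consumed, not created, here). Members
#' without an annotation count as `"other"`.
#'
#' @param induction_members Character vector of member promoter ids during
#'   induction (union over non-discarded iModulons).
#' @param recovery_members Same for the recovery phase.
#' @param annotation `data.frame` with columns `promoter_id` and
#'   `category`; categories are typically `"stress/damage"`,
#'   `"transcription/translation/synthesis"` and `"other"`.
#' @return `data.table` with columns `phase`, `category`, `n`, `fraction`
#'   (fraction of that phase's unique members; `NA` if the phase has no
#'   members).
#' @export
summarize_category_shift <- function(induction_members, recovery_members,
                                     annotation) {
  annotation <- data.table::as.data.table(annotation)
  if (!all(c("promoter_id", "category") %in% names(annotation)))
    stop("annotation needs columns 'promoter_id' and 'category'")
  cats <- unique(c(annotation$category, "other"))
  one_phase <- function(members, phase) {
    members <- unique(members)
    cat_of <- annotation$category[match(members, annotation$promoter_id)]
    cat_of[is.na(cat_of)] <- "other"
    n <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
    data.table::data.table(
      phase = phase, category = cats, n = n,
      fraction = if (length(members)) n / length(members) else NA_real_)
  }
  rbind(one_phase(induction_members, "induction"),
        one_phase(recovery_members, "recovery"))
}
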
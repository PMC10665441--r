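#' Validate raw input series
#'
#' Diagnostic checks on long-format fluorescence data before analysis:
#' duplicate (promoter, time) records, non-finite values, irregular time
#' grids, and promoter time points missing from the control grid. Inputs
#' are never modified.
#'
#' @param series Long-format `data.table` (`promoter_id`, `time_min`,
#'   `fluorescence`, `background`).
#' @param control Control series of the same shape (optional).
#' @return `data.table` of diagnostics with columns `check`, `promoter_id`,
#'   `time_min`, `detail`; zero rows when the inputs are clean.
#' @export
validate_inputs <- function(series, control = NULL) {
  dt <- data.table::as.data.table(series)
  out <- list()
  dup <- dt[duplicated(dt[, list(promoter_id, time_min)])]
  if (nrow(dup))
    out[[length(out) + 1L]] <- data.table::data.table(
      check = "duplicate_record", promoter_id = dup$promoter_id,
      time_min = dup$time_min, detail = "duplicated (promoter, time) pair")
  for (col in c("fluorescence", "background")) {
    bad <- dt[!is.finite(dt[[col]])]
    if (nrow(bad))
      out[[length(out) + 1L]] <- data.table::data.table(
        check = "non_finite", promoter_id = bad$promoter_id,
        time_min = bad$time_min, detail = paste("non-finite", col))
  }
  spacing <- dt[order(time_min),
                list(irregular = length(unique(diff(unique(time_min)))) > 1L),
                by = promoter_id]
  irr <- spacing[irregular == TRUE]
  if (nrow(irr))
    out[[length(out) + 1L]] <- data.table::data.table(
      check = "irregular_grid", promoter_id = irr$promoter_id,
      time_min = NA_real_, detail = "uneven time spacing")
  if (!is.null(control)) {
    ctrl_t <- unique(data.table::as.data.table(control)$time_min)
    miss <- dt[!(time_min %in% ctrl_t)]
    if (nrow(miss))
      out[[length(out) + 1L]] <- data.table::data.table(
        check = "missing_control_time", promoter_id = miss$promoter_id,
        time_min = miss$time_min, detail = "time point absent from control")
  }
  if (length(out)) data.table::rbindlist(out)
  else data.table::data.table(check = character(), promoter_id = character(),
                              time_min = numeric(), detail = character())
}

#' Configuration for an end-to-end pipeline run
#'
#' Inputs are either a `synthetic_config` (data are generated), file paths
#' to raw series/control text files plus a design, or a prebuilt
#' fold-change matrix.
#'
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param series_path,control_path Paths to long-format raw series files.
#' @param matrix_path Path to a prebuilt fold-change matrix.
#' @param design An [experiment_design()]; required with file inputs.
#' @param phases Phases to analyze: subset of
#'   `c("induction", "recovery")`.
#' @param ica An [ica_config()].
#' @param threshold A [threshold_config()].
#' @param share Single-promoter dominance threshold.
#' @param kernel_size Median filter width.
#' @param annotation Optional promoter annotation table for the category
#'   shift summary.
#' @param out_dir Output directory for intermediate and final artifacts.
#' @param seed Global seed; also recorded in every output header.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, series_path = NULL,
                            control_path = NULL, matrix_path = NULL,
                            design = if (!is.null(synthetic)) synthetic$design,
                            phases = "induction",
                            ica = ica_config(), threshold = threshold_config(),
                            share = 0.7, kernel_size = 11, annotation = NULL,
                            out_dir = tempfile("dynomodulon_run_"),
                            seed = 1L) {
  n_inputs <- sum(!is.null(synthetic), !is.null(series_path),
                  !is.null(matrix_path))
  if (n_inputs != 1L)
    stop("exactly one of 'synthetic', 'series_path' or 'matrix_path' is required")
  for (p in c(series_path, control_path, matrix_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if (!is.null(series_path) && is.null(control_path))
    stop("'control_path' is required with 'series_path'")
  if (is.null(design) && is.null(matrix_path))
    stop("an experiment design is required")
  phases <- match.arg(phases, c("induction", "recovery"), several.ok = TRUE)
  structure(list(synthetic = synthetic, series_path = series_path,
                 control_path = control_path, matrix_path = matrix_path,
                 design = design, phases = phases, ica = ica,
                 threshold = threshold, share = share,
                 kernel_size = kernel_size, annotation = annotation,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

output_header <- function(config, inputs = character()) {
  digest <- if (length(inputs))
    paste(substr(unname(tools::md5sum(inputs)), 1, 12), collapse = ",")
  else "none"
  c(sprintf("dynomodulon %s",
            as.character(utils::packageVersion("dynomodulon"))),
    sprintf("seed=%d input_digest=%s", config$seed, digest))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in order — synthesize or ingest raw data,
#' preprocess into windowed log2 fold-change matrices, robust ensemble
#' ICA, iModulon characterization, and (with annotations) the category
#' shift summary — writing every intermediate artifact to
#' `config$out_dir`. Re-running with the same config and seed reproduces
#' the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: per phase the matrix shape,
#'   selected `k`, number of robust components, the iModulon summary, and
#'   discard count; plus the config echo and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(config$series_path, config$control_path, config$matrix_path)
  hdr <- output_header(config, inputs)
  design <- config$design

  matrices <- list()
  if (!is.null(config$matrix_path)) {
    X <- read_fold_change_matrix(config$matrix_path)
    matrices[[config$phases[1]]] <- X
  } else {
    if (!is.null(config$synthetic)) {
      truth <- generate_truth(config$synthetic)
      raw <- generate_raw_fluorescence(truth)
      write_series(raw$series, file.path(config$out_dir, "raw_series.tsv"))
      write_series(raw$control, file.path(config$out_dir, "raw_control.tsv"))
      series <- raw$series; control <- raw$control
    } else {
      series <- read_series(config$series_path)
      control <- read_series(config$control_path)
    }
    diag <- validate_inputs(series, control)
    if (nrow(diag))
      message(sprintf("input validation: %d issue(s); see validation.tsv",
                      nrow(diag)))
    data.table::fwrite(diag, file.path(config$out_dir, "validation.tsv"),
                       sep = "\t")
    normalized <- preprocess_series(series, control, config$kernel_size)
    data.table::fwrite(normalized,
                       file.path(config$out_dir, "normalized_series.tsv"),
                       sep = "\t")
    for (ph in config$phases)
      matrices[[ph]] <- build_fold_change_matrix(normalized, design, ph)
  }

  phase_results <- list()
  for (ph in names(matrices)) {
    X <- matrices[[ph]]
    write_fold_change_matrix(
      X, file.path(config$out_dir, sprintf("X_%s.tsv", ph)), hdr)
    decomp <- tryCatch(
      robust_ica(X, config$ica),
      error = function(e) stop("stage robust_ica (", ph, " phase): ",
                               conditionMessage(e), call. = FALSE))
    write_decomposition(decomp,
                        file.path(config$out_dir, sprintf("M_%s.tsv", ph)),
                        file.path(config$out_dir, sprintf("A_%s.tsv", ph)),
                        hdr)
    imods <- if (!is.null(design) && decomp$n_robust > 0)
      characterize_imodulons(decomp, design, ph, config$threshold,
                             config$share)
    else NULL
    if (!is.null(imods)) {
      data.table::fwrite(imods$summary,
                         file.path(config$out_dir,
                                   sprintf("imodulon_summary_%s.tsv", ph)),
                         sep = "\t")
      data.table::fwrite(imods$membership,
                         file.path(config$out_dir,
                                   sprintf("membership_%s.tsv", ph)),
                         sep = "\t")
    }
    phase_results[[ph]] <- list(
      matrix_shape = dim(X), k_pca = decomp$k_pca,
      n_robust = decomp$n_robust, decomp = decomp, imodulons = imods,
      n_discarded = if (!is.null(imods) && nrow(imods$summary))
        sum(imods$summary$discarded) else 0L)
  }

  shift <- NULL
  if (!is.null(config$annotation) &&
      all(c("induction", "recovery") %in% names(phase_results))) {
    mem <- lapply(c("induction", "recovery"), function(ph) {
      im <- phase_results[[ph]]$imodulons
      if (is.null(im) || nrow(im$summary) == 0) character(0)
      else unique(im$membership[
        im$membership$imodulon_id %in%
          im$summary$imodulon_id[!im$summary$discarded]]$promoter_id)
    })
    shift <- summarize_category_shift(mem[[1]], mem[[2]], config$annotation)
    data.table::fwrite(shift, file.path(config$out_dir, "category_shift.tsv"),
                       sep = "\t")
  }

  structure(list(phases = phase_results, category_shift = shift,
                 config = config, out_dir = config$out_dir, header = hdr),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("dynomodulon pipeline run ->", x$out_dir, "\n")
  for (ph in names(x$phases)) {
    r <- x$phases[[ph]]
    cat(sprintf("  %s: X is %d x %d; k = %d; robust components = %d (%d discarded)\n",
                ph, r$matrix_shape[1], r$matrix_shape[2], r$k_pca,
                r$n_robust, r$n_discarded))
  }
  if (!is.null(x$category_shift)) {
    cat("  category shift:\n")
    print(x$category_shift)
  }
  invisible(x)
}
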
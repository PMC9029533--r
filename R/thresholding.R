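#' Threshold specification
#'
#' A global expression cutoff, given either as an exact value in expression
#' units or as a percentile in \[0, 100\] of the pooled expression values of
#' all loaded samples.
#'
#' @param value numeric: the exact cutoff, or the percentile.
#' @param mode `"exact"` (default) or `"percentile"`.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(value, mode = c("exact", "percentile")) {
  mode <- match.arg(mode)
  if (mode == "percentile" && (value < 0 || value > 100)) {
    stop("percentile must lie in [0, 100]")
  }
  structure(list(mode = mode, value = value), class = "threshold_spec")
}

#' Thresholding configuration
#'
#' Three approaches classify genes as expressed or suppressed:
#' * `GT1` — one global threshold; expressed iff value > threshold.
#' * `LT1` — one global threshold plus per-gene local thresholds; genes at or
#'   below the global are suppressed, genes above it are judged against
#'   their local threshold (no local: the global decision stands).
#' * `LT2` — lower and upper global thresholds; above upper = expressed,
#'   below lower = suppressed, the middle zone is decided by the local
#'   threshold (no local: suppressed, conservatively).
#'
#' @param approach `"GT1"`, `"LT1"` or `"LT2"`.
#' @param lower [threshold_spec()] for the (lower) global threshold.
#' @param upper [threshold_spec()] for the upper global threshold (LT2 only).
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(approach = c("GT1", "LT1", "LT2"),
                             lower, upper = NULL) {
  approach <- match.arg(approach)
  if (!inherits(lower, "threshold_spec")) stop("lower must be a threshold_spec")
  if (approach == "LT2") {
    if (is.null(upper)) stop("LT2 requires both lower and upper global thresholds")
    if (!inherits(upper, "threshold_spec")) stop("upper must be a threshold_spec")
  } else if (!is.null(upper)) {
    stop(approach, " uses a single global threshold; upper must be NULL")
  }
  structure(list(approach = approach, lower = lower, upper = upper),
            class = "threshold_config")
}

#' Resolve a threshold specification to a numeric cutoff
#'
#' Exact mode returns the value unchanged. Percentile mode interpolates
#' linearly between closest ranks, inclusive of the extremes
#' ([stats::quantile()] type 7), over the pooled expression values.
#'
#' @param spec a [threshold_spec()].
#' @param values pooled expression values of all samples in the run.
#' @return Numeric cutoff in expression units.
#' @export
resolve_threshold <- function(spec, values = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$mode == "exact") return(spec$value)
  if (is.null(values) || !length(values)) {
    stop("percentile threshold needs a non-empty pool of expression values")
  }
  unname(stats::quantile(values, probs = spec$value / 100, type = 7, names = FALSE))
}

#' Per-gene local thresholds
#'
#' The local threshold of a gene is the arithmetic mean of its expression
#' across the replicate samples of one phenotype in which it was measured.
#' At least two samples are required — with a single sample there is no
#' between-sample signal and the global-only GT1 approach applies.
#'
#' @param samples list of `transcriptome_dataset`, all of one phenotype.
#' @return Named numeric vector, gene id -> local threshold.
#' @export
compute_local_thresholds <- function(samples) {
  if (length(samples) < 2) {
    stop("local thresholds require at least two samples of the same ",
         "condition; with a single sample use the GT1 approach")
  }
  phen <- unique(vapply(samples, function(d) d$phenotype, character(1)))
  if (length(phen) != 1) {
    stop("samples span multiple phenotypes: ", paste(phen, collapse = ", "))
  }
  genes <- unique(unlist(lapply(samples, function(d) names(d$expression))))
  vapply(stats::setNames(genes, genes), function(g) {
    vals <- vapply(samples, function(d) unname(d$expression[g])[1], numeric(1))
    mean(vals[!is.na(vals)])  # mean over the samples where g was measured
  }, numeric(1))
}

#' Classify genes as expressed or suppressed
#'
#' Applies the configured thresholding approach to one sample. Comparisons
#' are strict: a value exactly equal to a threshold is *not* above it, so it
#' is suppressed under GT1/LT1 global and local rules, and falls into the
#' middle zone at the LT2 boundaries.
#'
#' @param dataset a `transcriptome_dataset`.
#' @param config a [threshold_config()].
#' @param locals named numeric vector of per-gene local thresholds
#'   (required for LT1/LT2; see [compute_local_thresholds()]).
#' @param pool pooled expression values used to resolve percentile
#'   thresholds; defaults to this dataset's values.
#' @return A `gene_classification`: list with `phenotype`, `sample`,
#'   `status` (named character, `"expressed"`/`"suppressed"`), `applied`
#'   (named numeric, the threshold that decided each gene) and
#'   `resolved_globals`.
#' @export
classify <- function(dataset, config, locals = NULL, pool = NULL) {
  stopifnot(inherits(dataset, "transcriptome_dataset"),
            inherits(config, "threshold_config"))
  if (is.null(pool)) pool <- dataset$expression
  lower <- resolve_threshold(config$lower, pool)
  upper <- if (config$approach == "LT2") resolve_threshold(config$upper, pool) else NULL
  if (!is.null(upper) && lower > upper) {
    stop("resolved lower global threshold (", lower,
         ") exceeds upper global threshold (", upper, ")")
  }
  if (config$approach %in% c("LT1", "LT2") && is.null(locals)) {
    stop(config$approach, " requires local thresholds ",
         "(compute_local_thresholds over >=2 same-condition samples)")
  }

  vals <- dataset$expression
  genes <- names(vals)
  status <- character(length(vals))
  applied <- numeric(length(vals))

  for (i in seq_along(vals)) {
    v <- vals[[i]]
    g <- genes[i]
    loc <- if (!is.null(locals) && g %in% names(locals)) locals[[g]] else NA_real_
    if (config$approach == "GT1") {
      status[i] <- if (v > lower) "expressed" else "suppressed"
      applied[i] <- lower
    } else if (config$approach == "LT1") {
      if (v <= lower) {
        status[i] <- "suppressed"; applied[i] <- lower
      } else if (is.na(loc)) {
        status[i] <- "expressed"; applied[i] <- lower   # global fallback
      } else {
        status[i] <- if (v > loc) "expressed" else "suppressed"
        applied[i] <- loc
      }
    } else { # LT2
      if (v > upper) {
        status[i] <- "expressed"; applied[i] <- upper
      } else if (v < lower) {
        status[i] <- "suppressed"; applied[i] <- lower
      } else if (is.na(loc)) {
        status[i] <- "suppressed"; applied[i] <- upper  # no local: conservative
      } else {
        status[i] <- if (v > loc) "expressed" else "suppressed"
        applied[i] <- loc
      }
    }
  }

  structure(
    list(phenotype = dataset$phenotype, sample = dataset$sample,
         values = vals,
         status = stats::setNames(status, genes),
         applied = stats::setNames(applied, genes),
         resolved_globals = c(lower = lower,
                              upper = if (is.null(upper)) NA_real_ else upper),
         approach = config$approach),
    class = "gene_classification"
  )
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("gene_classification", paste0(x$phenotype, "_", x$sample),
      "|", x$approach, "|",
      sum(x$status == "expressed"), "expressed /",
      sum(x$status == "suppressed"), "suppressed\n")
  invisible(x)
}
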
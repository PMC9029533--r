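FLUX_TOL <- 1e-6

#' Split genes into high- and low-expression lists
#'
#' @param classification a [classify()] result.
#' @return list of two data.frames `high` and `low`, each with columns
#'   `gene`, `value`, `deciding_threshold`; disjoint and jointly exhaustive
#'   over the sample's genes.
#' @export
filter_high_low <- function(classification) {
  stopifnot(inherits(classification, "gene_classification"))
  genes <- names(classification$status)
  df <- data.frame(gene = genes,
                   value = unname(classification$values[genes]),
                   deciding_threshold = unname(classification$applied[genes]),
                   stringsAsFactors = FALSE)
  list(high = df[classification$status == "expressed", , drop = FALSE],
       low = df[classification$status == "suppressed", , drop = FALSE])
}

#' Low-expression genes only
#'
#' @param classification a [classify()] result.
#' @return data.frame `gene`, `value`, `deciding_threshold` for suppressed
#'   genes.
#' @export
filter_low <- function(classification) {
  filter_high_low(classification)$low
}

#' Compare gene expression between phenotypes
#'
#' Pairwise comparison of the first dataset against each of the others over
#' a shared gene universe. Ratios are `value_A / value_B`; when either side
#' is 0 a pseudo-count is added to both so the ratio stays finite. A gene is
#' `up` if ratio > `min_fold`, `down` if ratio < 1/`min_fold`, else
#' `unchanged`.
#'
#' @param datasets list of >= 2 `transcriptome_dataset`.
#' @param min_fold fold-change threshold (>= 1); 1 means any difference
#'   counts.
#' @param pseudo pseudo-count added to both sides when either is 0.
#' @return data.frame with columns `comparison`, `gene`, `value_A`,
#'   `value_B`, `ratio`, `direction`.
#' @export
compare_expression <- function(datasets, min_fold = 1.0, pseudo = 1.0) {
  stopifnot(length(datasets) >= 2, min_fold >= 1)
  universe <- names(datasets[[1]]$expression)
  for (d in datasets[-1]) {
    a_only <- setdiff(universe, names(d$expression))
    b_only <- setdiff(names(d$expression), universe)
    if (length(a_only) || length(b_only)) {
      stop("gene sets differ between datasets; only in first: ",
           paste(a_only, collapse = ", "), "; only in ",
           d$phenotype, "_", d$sample, ": ", paste(b_only, collapse = ", "))
    }
  }
  ref <- datasets[[1]]
  out <- lapply(datasets[-1], function(d) {
    a <- unname(ref$expression[universe])
    b <- unname(d$expression[universe])
    add <- ifelse(a == 0 | b == 0, pseudo, 0)
    ratio <- (a + add) / (b + add)
    direction <- ifelse(ratio > min_fold, "up",
                        ifelse(ratio < 1 / min_fold, "down", "unchanged"))
    data.frame(comparison = paste0(ref$phenotype, "_", ref$sample, "_vs_",
                                   d$phenotype, "_", d$sample),
               gene = universe, value_A = a, value_B = b,
               ratio = ratio, direction = direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# audit causes that mark a reaction as constrained by expression evidence
expression_causes <- c("expression_bound", "gene_deletion")

#' Reactions silenced by low expression
#'
#' Reactions that carry no flux anywhere in their FVA range *and* whose
#' shutdown is expression-derived (an `expression_bound` or `gene_deletion`
#' audit entry). Structurally blocked reactions of the source model are not
#' reported.
#'
#' @param context a [build_context_model()] result.
#' @param fva_result [fva()] computed on `context`.
#' @return data.frame `reaction`, `min`, `max`, `cause`.
#' @export
non_flux_reactions <- function(context, fva_result) {
  stopifnot(inherits(context, "context_model"))
  aud <- context$audit[context$audit$cause %in% expression_causes, , drop = FALSE]
  zero <- fva_result$reaction[pmax(abs(fva_result$min), abs(fva_result$max)) <= FLUX_TOL]
  keep <- fva_result$reaction %in% intersect(zero, aud$reaction)
  res <- fva_result[keep, c("reaction", "min", "max"), drop = FALSE]
  res$cause <- aud$cause[match(res$reaction, aud$reaction)]
  rownames(res) <- NULL
  as.data.frame(res)
}

#' Rate-limiting reactions
#'
#' Reactions whose expression-derived bound is exactly what the network
#' achieves: the FVA maximum equals the applied upper bound (or, for
#' backward-irreversible reactions, the FVA minimum equals the applied
#' lower bound) within tolerance. These are the reactions where the
#' transcriptome cap binds the flux.
#'
#' @param context a [build_context_model()] result.
#' @param fva_result [fva()] computed on `context`.
#' @param tol numeric tolerance on the equality.
#' @return data.frame `reaction`, `bound`, `fva_extreme`, `side`.
#' @export
rate_limiting_reactions <- function(context, fva_result, tol = FLUX_TOL) {
  stopifnot(inherits(context, "context_model"))
  aud <- context$audit[context$audit$cause == "expression_bound", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(aud))) {
    id <- aud$reaction[k]
    i <- match(id, fva_result$reaction)
    if (is.na(i)) next
    new_ub <- aud$new_ub[k]
    new_lb <- aud$new_lb[k]
    capped_ub <- new_ub < aud$old_ub[k]
    capped_lb <- new_lb > aud$old_lb[k]
    if (capped_ub && abs(fva_result$max[i] - new_ub) <= tol) {
      out[[length(out) + 1L]] <- data.frame(reaction = id, bound = new_ub,
                                            fva_extreme = fva_result$max[i],
                                            side = "upper",
                                            stringsAsFactors = FALSE)
    } else if (capped_lb && abs(fva_result$min[i] - new_lb) <= tol) {
      out[[length(out) + 1L]] <- data.frame(reaction = id, bound = new_lb,
                                            fva_extreme = fva_result$min[i],
                                            side = "lower",
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(reaction = character(), bound = numeric(),
                      fva_extreme = numeric(), side = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Flux shifts between phenotypes
#'
#' Compares two FVA results reaction by reaction. Both the ratio of FVA
#' minima and of FVA maxima (A/B) are reported; the direction comes from
#' the ratio of flux-range magnitudes (`max(|min|, |max|)` per side), so
#' swapping A and B inverts every ratio and flips up/down. A reaction whose
#' range magnitude falls below the flux tolerance on one side only is
#' `new` (flux in A only) or `lost` (flux in B only), with `NA` sentinel
#' ratios.
#'
#' @param fva_A,fva_B [fva()] results over the same reaction universe.
#' @return data.frame `reaction`, `min_A`, `max_A`, `min_B`, `max_B`,
#'   `ratio_min`, `ratio_max`, `direction`.
#' @export
flux_shifts <- function(fva_A, fva_B) {
  if (!setequal(fva_A$reaction, fva_B$reaction)) {
    stop("reaction sets differ: only in A: ",
         paste(setdiff(fva_A$reaction, fva_B$reaction), collapse = ", "),
         "; only in B: ",
         paste(setdiff(fva_B$reaction, fva_A$reaction), collapse = ", "))
  }
  ord <- match(fva_A$reaction, fva_B$reaction)
  minA <- fva_A$min; maxA <- fva_A$max
  minB <- fva_B$min[ord]; maxB <- fva_B$max[ord]
  magA <- pmax(abs(minA), abs(maxA))
  magB <- pmax(abs(minB), abs(maxB))

  ratio_of <- function(a, b) ifelse(abs(b) <= FLUX_TOL, NA_real_, a / b)
  ratio_min <- ratio_of(minA, minB)
  ratio_max <- ratio_of(maxA, maxB)
  mag_ratio <- ratio_of(magA, magB)

  direction <- character(length(magA))
  for (i in seq_along(magA)) {
    if (magA[i] <= FLUX_TOL && magB[i] <= FLUX_TOL) {
      direction[i] <- "unchanged"
    } else if (magB[i] <= FLUX_TOL) {
      direction[i] <- "new"
    } else if (magA[i] <= FLUX_TOL) {
      direction[i] <- "lost"
    } else if (mag_ratio[i] > 1 + FLUX_TOL) {
      direction[i] <- "up"
    } else if (mag_ratio[i] < 1 - FLUX_TOL) {
      direction[i] <- "down"
    } else {
      direction[i] <- "unchanged"
    }
  }
  data.frame(reaction = fva_A$reaction,
             min_A = minA, max_A = maxA, min_B = minB, max_B = maxB,
             ratio_min = ratio_min, ratio_max = ratio_max,
             direction = direction, stringsAsFactors = FALSE)
}
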
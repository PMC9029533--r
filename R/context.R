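new_context_model <- function(model, audit = NULL, deleted_genes = character(0)) {
  if (is.null(audit)) {
    audit <- data.frame(reaction = character(), old_lb = numeric(),
                        old_ub = numeric(), new_lb = numeric(),
                        new_ub = numeric(), cause = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(model = model, audit = audit, deleted_genes = deleted_genes),
            class = "context_model")
}

audit_row <- function(id, old_lb, old_ub, new_lb, new_ub, cause) {
  data.frame(reaction = id, old_lb = old_lb, old_ub = old_ub,
             new_lb = new_lb, new_ub = new_ub, cause = cause,
             stringsAsFactors = FALSE)
}

set_bounds <- function(ctx, id, lb, ub, cause) {
  k <- match(id, ctx$model$reactions$id)
  old_lb <- ctx$model$reactions$lower_bound[k]
  old_ub <- ctx$model$reactions$upper_bound[k]
  if (old_lb == lb && old_ub == ub) return(ctx)
  ctx$model$reactions$lower_bound[k] <- lb
  ctx$model$reactions$upper_bound[k] <- ub
  ctx$audit <- rbind(ctx$audit, audit_row(id, old_lb, old_ub, lb, ub, cause))
  ctx
}

#' @export
print.context_model <- function(x, ...) {
  cat("context_model:", nrow(x$audit), "bound changes,",
      length(x$deleted_genes), "gene deletions\n")
  invisible(x)
}

#' Apply medium-composition bounds
#'
#' Sets the bounds of every reaction listed in the medium file. With
#' `close_unlisted`, every *other* exchange reaction loses its uptake
#' capacity (negative lower bound raised to 0), so the model can consume
#' only what the medium provides.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_composition()].
#' @param close_unlisted logical; close uptake of unlisted exchanges.
#' @return A `context_model` with an audit trail of every change
#'   (cause `"medium"`).
#' @export
apply_medium <- function(model, medium, close_unlisted = FALSE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(medium, "medium_composition"))
  unknown <- setdiff(medium$bounds$reaction, model$reactions$id)
  if (length(unknown)) {
    stop("medium lists reaction(s) absent from the model: ",
         paste(unknown, collapse = ", "))
  }
  ctx <- new_context_model(model)
  for (k in seq_len(nrow(medium$bounds))) {
    ctx <- set_bounds(ctx, medium$bounds$reaction[k],
                      medium$bounds$lower_bound[k],
                      medium$bounds$upper_bound[k], "medium")
  }
  if (close_unlisted) {
    for (id in setdiff(exchange_reactions(model), medium$bounds$reaction)) {
      k <- match(id, ctx$model$reactions$id)
      if (ctx$model$reactions$lower_bound[k] < 0) {
        ctx <- set_bounds(ctx, id, 0, ctx$model$reactions$upper_bound[k], "medium")
      }
    }
  }
  ctx
}

#' Map expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR against one sample's expression values
#' under the chosen operator scheme. Reactions without a GPR are undefined
#' (`NA`): expression never constrains them.
#'
#' @param model a `metabolic_model`.
#' @param dataset a `transcriptome_dataset`.
#' @param scheme a [mapping_scheme()].
#' @param missing_policy passed to [evaluate_gpr()].
#' @return Named numeric vector, reaction id -> mapped value (NA when
#'   undefined).
#' @export
map_reaction_expression <- function(model, dataset, scheme = mapping_scheme(),
                                    missing_policy = "skip") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(dataset, "transcriptome_dataset"))
  out <- rep(NA_real_, nrow(model$reactions))
  names(out) <- model$reactions$id
  for (k in seq_len(nrow(model$reactions))) {
    gpr <- model$reactions$gpr[k]
    if (!nzchar(gpr)) next
    expr <- tryCatch(parse_gpr(gpr), error = function(e) {
      stop("reaction ", model$reactions$id[k], ": ", conditionMessage(e))
    })
    out[k] <- evaluate_gpr(expr, dataset$expression, scheme, missing_policy)
  }
  out
}

# Cap one reaction's bounds at magnitude v according to its direction.
# Expression caps only ever tighten: min against ub, max against lb.
cap_reaction <- function(ctx, id, v, direction, option) {
  k <- match(id, ctx$model$reactions$id)
  lb <- ctx$model$reactions$lower_bound[k]
  ub <- ctx$model$reactions$upper_bound[k]
  if (direction == "irreversible") {
    ctx <- set_bounds(ctx, id, lb, min(ub, v), "expression_bound")
  } else if (direction == "backward_irreversible") {
    ctx <- set_bounds(ctx, id, max(lb, -v), ub, "expression_bound")
  } else if (option != "IRREVERSIBLE_ONLY") {
    ctx <- set_bounds(ctx, id, max(lb, -v), min(ub, v), "expression_bound")
  }
  ctx
}

#' Build a context-specific model
#'
#' Applies medium bounds, then integrates one sample's expression into the
#' model under one of four constraining options. Mapped GPR values act as
#' magnitude caps on flux (they only tighten bounds, never widen them):
#'
#' * `IRREVERSIBLE_ONLY` — caps irreversible reactions (upper bound) and
#'   backward-irreversible ones (lower bound); reversible reactions are
#'   left untouched.
#' * `ALL_REACTIONS` — as above, and reversible reactions are capped in
#'   both directions.
#' * `NONESSENTIAL_DELETION` — each suppressed gene is knocked out only if
#'   its single-gene-deletion growth ratio equals 1 (deletion does not
#'   affect growth); essential suppressed genes are skipped and audited.
#'   Expression caps are then applied as in `ALL_REACTIONS` to the
#'   reactions that remain open.
#' * `MEET_MIN_GROWTH` — an auxiliary model carrying only the medium and
#'   the non-essential gene deletions fixes the growth optimum; a cap is
#'   applied only where the mapped value is at least the reaction's minimum
#'   flux requirement at that growth, otherwise the cap is skipped and
#'   audited (`"skipped_min_growth"`), so integration cannot starve growth.
#'
#' @param model a `metabolic_model`.
#' @param dataset a `transcriptome_dataset`.
#' @param classification [classify()] result for `dataset` (needed by the
#'   deletion-based options; may be `NULL` for the first two).
#' @param scheme a [mapping_scheme()].
#' @param option constraining option (see above).
#' @param medium optional [medium_composition()].
#' @param close_unlisted passed to [apply_medium()].
#' @param scale linear factor applied to mapped values before use as bounds
#'   (expression units are used verbatim by default; see the vignette for
#'   the caveat).
#' @param missing_policy passed to [evaluate_gpr()].
#' @param grratio_tol tolerance on `grRatio == 1` for non-essential calls.
#' @return A `context_model`: mutated model copy, audit trail
#'   (causes `medium`, `expression_bound`, `gene_deletion`,
#'   `skipped_min_growth`, `skipped_essential`) and `deleted_genes`.
#' @export
build_context_model <- function(model, dataset, classification = NULL,
                                scheme = mapping_scheme(),
                                option = c("IRREVERSIBLE_ONLY", "ALL_REACTIONS",
                                           "NONESSENTIAL_DELETION", "MEET_MIN_GROWTH"),
                                medium = NULL, close_unlisted = FALSE,
                                scale = 1.0, missing_policy = "skip",
                                grratio_tol = 1e-6) {
  option <- match.arg(option)
  stopifnot(inherits(model, "metabolic_model"))
  ctx <- if (!is.null(medium)) {
    apply_medium(model, medium, close_unlisted)
  } else {
    new_context_model(model)
  }

  if (option %in% c("NONESSENTIAL_DELETION", "MEET_MIN_GROWTH")) {
    if (is.null(classification)) {
      stop(option, " requires a gene classification of the dataset")
    }
    suppressed <- names(classification$status)[classification$status == "suppressed"]
    suppressed <- intersect(suppressed, ctx$model$genes)
    wt <- fba(ctx$model)
    if (wt$status != "optimal") stop("model infeasible before gene deletion")
    if (wt$objective_value <= 0) stop("wild-type growth is zero; grRatio undefined")
    for (g in suppressed) {
      # grRatio of g on top of the deletions accepted so far, so a pair of
      # suppressed isozymes cannot both slip through one at a time
      trial <- delete_genes(ctx$model, c(ctx$deleted_genes, g))$model
      ko <- fba(trial)
      gr <- if (ko$status == "optimal") ko$objective_value / wt$objective_value else 0
      if (abs(gr - 1) <= grratio_tol) {
        blocked <- delete_genes(ctx$model, c(ctx$deleted_genes, g))$blocked
        ctx$deleted_genes <- c(ctx$deleted_genes, g)
        for (id in blocked) {
          k <- match(id, ctx$model$reactions$id)
          if (ctx$model$reactions$lower_bound[k] != 0 ||
              ctx$model$reactions$upper_bound[k] != 0) {
            ctx <- set_bounds(ctx, id, 0, 0, "gene_deletion")
          }
        }
      } else {
        ctx$audit <- rbind(ctx$audit,
                           audit_row(paste0("gene:", g), NA, NA, NA, NA,
                                     "skipped_essential"))
      }
    }
  }

  mapped <- map_reaction_expression(ctx$model, dataset, scheme, missing_policy)
  mapped <- mapped * scale

  requirement <- NULL
  if (option == "MEET_MIN_GROWTH") {
    aux_check <- fba(ctx$model)
    if (aux_check$status != "optimal") {
      active <- ctx$audit[ctx$audit$cause %in% c("medium", "gene_deletion"), ]
      stop("auxiliary model (medium + deletions only) is ", aux_check$status,
           "; active constraints:\n",
           paste(utils::capture.output(print(active)), collapse = "\n"))
    }
    requirement <- min_growth_requirements(ctx)
  }

  dirs <- reaction_directions(ctx$model)
  for (id in ctx$model$reactions$id) {
    v <- mapped[[id]]
    if (is.na(v)) next
    k <- match(id, ctx$model$reactions$id)
    if (ctx$model$reactions$lower_bound[k] == 0 &&
        ctx$model$reactions$upper_bound[k] == 0) next  # already blocked
    if (option == "MEET_MIN_GROWTH" && v < requirement[[id]]) {
      ctx$audit <- rbind(ctx$audit,
                         audit_row(id, NA, NA, NA, NA, "skipped_min_growth"))
      next
    }
    opt_for_cap <- if (option == "IRREVERSIBLE_ONLY") option else "ALL_REACTIONS"
    ctx <- cap_reaction(ctx, id, v, dirs[[id]], opt_for_cap)
  }
  ctx
}
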
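#' Flux balance analysis
#'
#' Solves the canonical FBA linear program: optimise the flux of the
#' objective (biomass) reaction subject to steady state `S v = 0` and the
#' reaction bounds.
#'
#' @param model a `metabolic_model` (or the `$model` of a
#'   [build_context_model()] result).
#' @param sense `"maximize"` (default) or `"minimize"`.
#' @return A `flux_solution`: list with `objective_value`, `fluxes` (named
#'   vector) and `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#'   Only `objective_value` is unique at degenerate optima; the flux vector
#'   is one optimal vertex.
#' @export
#' @examples
#' m <- generate_toy_model(n_linear = 3)
#' fba(m)$objective_value
fba <- function(model, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  model <- as_metabolic_model(model)
  S <- stoichiometric_matrix(model)
  rx <- model$reactions
  obj <- as.numeric(rx$id == model$objective_reaction)
  sol <- solve_lp(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                  rx$lower_bound, rx$upper_bound,
                  maximize = (sense == "maximize"))
  if (sol$status != "optimal") {
    return(structure(list(objective_value = NA_real_, fluxes = NULL,
                          status = sol$status), class = "flux_solution"))
  }
  structure(list(objective_value = sol$objective,
                 fluxes = stats::setNames(sol$x, rx$id),
                 status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, "| objective =", x$objective_value, "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, the minimal and maximal feasible flux while the
#' objective flux is held at at least `fraction_of_optimum` times its FBA
#' optimum.
#'
#' @param model a `metabolic_model` or context model.
#' @param fraction_of_optimum fraction in \[0, 1\] of the FBA optimum that
#'   must be maintained; 1.0 (default) fixes the optimum.
#' @param reactions optional subset of reaction ids.
#' @return An `fva_result`: data.frame with columns `reaction`, `min`, `max`
#'   plus attribute `fraction_of_optimum`.
#' @export
fva <- function(model, fraction_of_optimum = 1.0, reactions = NULL) {
  model <- as_metabolic_model(model)
  base <- fba(model)
  if (base$status != "optimal") {
    stop("FVA requires an optimal FBA solution; status: ", base$status)
  }
  S <- stoichiometric_matrix(model)
  rx <- model$reactions
  if (is.null(reactions)) reactions <- rx$id
  unknown <- setdiff(reactions, rx$id)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))

  objrow <- as.numeric(rx$id == model$objective_reaction)
  mat <- rbind(S, objrow)
  dir <- c(rep("=", nrow(S)), ">=")
  rhs <- c(rep(0, nrow(S)), fraction_of_optimum * base$objective_value)

  res <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    e <- as.numeric(rx$id == reactions[k])
    lo <- solve_lp(e, mat, dir, rhs, rx$lower_bound, rx$upper_bound, maximize = FALSE)
    hi <- solve_lp(e, mat, dir, rhs, rx$lower_bound, rx$upper_bound, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible at fraction ", fraction_of_optimum,
           " for reaction ", reactions[k])
    }
    res$min[k] <- lo$objective
    res$max[k] <- hi$objective
  }
  structure(res, fraction_of_optimum = fraction_of_optimum,
            class = c("fva_result", "data.frame"))
}

#' Single-gene deletion growth ratio
#'
#' Knocks out one gene (Boolean GPR evaluation: reactions whose rule becomes
#' unsatisfiable get bounds (0, 0)) and reports
#' `grRatio = deletion-strain FBA optimum / wild-type FBA optimum`.
#'
#' @param model a `metabolic_model` or context model.
#' @param gene gene id to delete.
#' @return Numeric grRatio in \[0, 1\] up to solver tolerance.
#' @export
single_gene_deletion <- function(model, gene) {
  model <- as_metabolic_model(model)
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type FBA not optimal: ", wt$status)
  if (wt$objective_value <= 0) {
    stop("wild-type growth is zero; grRatio undefined")
  }
  ko <- delete_genes(model, gene)
  mut <- fba(ko$model)
  if (mut$status != "optimal") return(0)
  mut$objective_value / wt$objective_value
}

# Apply Boolean knockouts: block every reaction whose GPR is unsatisfiable
# without the deleted genes. Returns the modified model plus the blocked ids.
delete_genes <- function(model, genes) {
  blocked <- character(0)
  for (k in seq_len(nrow(model$reactions))) {
    gpr <- model$reactions$gpr[k]
    if (!nzchar(gpr)) next
    expr <- parse_gpr(gpr)
    if (!evaluate_gpr_boolean(expr, genes)) {
      model$reactions$lower_bound[k] <- 0
      model$reactions$upper_bound[k] <- 0
      blocked <- c(blocked, model$reactions$id[k])
    }
  }
  list(model = model, blocked = blocked)
}

#' Per-reaction minimum flux requirements at optimal growth
#'
#' Given an auxiliary context model (medium plus gene deletions only), fixes
#' growth at that model's FBA optimum and reports, per reaction, the minimum
#' flux magnitude any optimal steady state must carry: from the FVA range
#' \[a, b\] at fixed growth, 0 if the range straddles 0, else min(|a|, |b|).
#'
#' @param aux_model a `metabolic_model` or context model.
#' @return Named numeric vector, reaction id -> required flux magnitude.
#' @export
min_growth_requirements <- function(aux_model) {
  model <- as_metabolic_model(aux_model)
  ranges <- fva(model, fraction_of_optimum = 1.0)
  req <- ifelse(ranges$min > 0, ranges$min,
                ifelse(ranges$max < 0, -ranges$max, 0))
  stats::setNames(pmax(req, 0), ranges$reaction)
}

# Accept either a bare metabolic_model or a context_model wrapper.
as_metabolic_model <- function(x) {
  if (inherits(x, "context_model")) return(x$model)
  if (inherits(x, "metabolic_model")) return(x)
  stop("expected a metabolic_model or context_model")
}
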
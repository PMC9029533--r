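#' Construct a metabolic model
#'
#' A `metabolic_model` is the in-memory representation of a constraint-based
#' (stoichiometric) model: metabolite and gene inventories, a reaction table
#' with flux bounds and GPR (gene-protein-reaction) rules, a sparse
#' stoichiometry triplet table and the id of the biomass (objective) reaction.
#'
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`
#'   (flux, mmol g-1 h-1), `gpr` (Boolean rule text, possibly empty).
#' @param stoichiometry data.frame with columns `metabolite`, `reaction`,
#'   `coefficient` (one row per nonzero entry).
#' @param metabolites character vector of metabolite ids; defaults to those
#'   referenced by `stoichiometry`.
#' @param genes character vector of gene ids; defaults to the genes referenced
#'   by the GPR rules.
#' @param objective_reaction id of the reaction whose flux is optimised.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, stoichiometry,
                            metabolites = NULL, genes = NULL,
                            objective_reaction) {
  stopifnot(is.data.frame(reactions), is.data.frame(stoichiometry))
  required <- c("id", "lower_bound", "upper_bound", "gpr")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols)) {
    stop("reactions table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  reactions$id <- as.character(reactions$id)
  reactions$gpr <- ifelse(is.na(reactions$gpr), "", as.character(reactions$gpr))
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  bad <- reactions$id[reactions$lower_bound > reactions$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound for reaction(s): ",
                        paste(bad, collapse = ", "))

  if (is.null(metabolites)) metabolites <- unique(as.character(stoichiometry$metabolite))
  gpr_genes <- unique(unlist(lapply(reactions$gpr, gpr_genes)))
  if (is.null(genes)) {
    genes <- gpr_genes
  } else {
    undeclared <- setdiff(gpr_genes, genes)
    if (length(undeclared)) {
      stop("GPR rules reference undeclared gene(s): ",
           paste(undeclared, collapse = ", "))
    }
  }

  stoichiometry$metabolite <- as.character(stoichiometry$metabolite)
  stoichiometry$reaction <- as.character(stoichiometry$reaction)
  if (!all(stoichiometry$metabolite %in% metabolites)) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(setdiff(stoichiometry$metabolite, metabolites), collapse = ", "))
  }
  if (!all(stoichiometry$reaction %in% reactions$id)) {
    stop("stoichiometry references undeclared reaction(s): ",
         paste(setdiff(stoichiometry$reaction, reactions$id), collapse = ", "))
  }
  if (!objective_reaction %in% reactions$id) {
    stop("objective reaction '", objective_reaction, "' is not a declared reaction")
  }

  structure(
    list(
      metabolites = metabolites,
      genes = genes,
      reactions = reactions[, required],
      stoichiometry = stoichiometry[, c("metabolite", "reaction", "coefficient")],
      objective_reaction = objective_reaction
    ),
    class = "metabolic_model"
  )
}

#' Reaction directionality
#'
#' Classifies each reaction from its bounds: `irreversible` (lb >= 0),
#' `backward_irreversible` (ub <= 0), otherwise `reversible`.
#'
#' @param model a `metabolic_model`.
#' @return Named character vector over reaction ids.
#' @export
reaction_directions <- function(model) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  dir <- ifelse(lb >= 0, "irreversible",
                ifelse(ub <= 0, "backward_irreversible", "reversible"))
  stats::setNames(dir, model$reactions$id)
}

#' Dense stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return metabolite x reaction numeric matrix S such that steady state is
#'   `S v = 0`.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, length(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, model$metabolites),
          match(st$reaction, model$reactions$id))] <- st$coefficient
  S
}

#' Exchange reactions of a model
#'
#' An exchange (boundary) reaction touches exactly one metabolite; its
#' negative lower bound encodes the maximal uptake rate.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  counts <- table(model$stoichiometry$reaction)
  names(counts)[counts == 1]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  cat("objective:", x$objective_reaction, "\n")
  invisible(x)
}

#' Construct a transcriptome dataset
#'
#' One sample of one phenotype: a map from gene id to a non-negative
#' expression measurement (sequencing reads or normalised counts).
#'
#' @param phenotype phenotype (condition) label.
#' @param sample sample label within the phenotype.
#' @param expression named numeric vector, gene id -> value (>= 0).
#' @return An object of class `transcriptome_dataset`.
#' @export
transcriptome_dataset <- function(phenotype, sample, expression) {
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    stop("expression must be a named vector of gene values")
  }
  if (anyDuplicated(names(expression))) {
    stop("duplicate gene id(s) in sample '", sample, "': ",
         paste(unique(names(expression)[duplicated(names(expression))]), collapse = ", "))
  }
  if (any(!is.finite(expression)) || any(expression < 0)) {
    stop("expression values must be finite and non-negative")
  }
  structure(list(phenotype = phenotype, sample = sample,
                 expression = expression),
            class = "transcriptome_dataset")
}

#' @export
print.transcriptome_dataset <- function(x, ...) {
  cat("transcriptome_dataset", paste0(x$phenotype, "_", x$sample), ":",
      length(x$expression), "genes\n")
  invisible(x)
}

#' Construct a medium composition
#'
#' Exchange-reaction bounds describing the growth medium, plus an optional
#' specific growth rate.
#'
#' @param bounds data.frame with columns `reaction`, `lower_bound`,
#'   `upper_bound` (mmol g-1 h-1).
#' @param growth_rate optional specific growth rate (h-1).
#' @return An object of class `medium_composition`.
#' @export
medium_composition <- function(bounds, growth_rate = NULL) {
  stopifnot(is.data.frame(bounds))
  needed <- c("reaction", "lower_bound", "upper_bound")
  if (!all(needed %in% names(bounds))) {
    stop("medium bounds need columns: ", paste(needed, collapse = ", "))
  }
  bad <- bounds$reaction[bounds$lower_bound > bounds$upper_bound]
  if (length(bad)) stop("medium lower_bound > upper_bound for: ",
                        paste(bad, collapse = ", "))
  structure(list(bounds = bounds[, needed], growth_rate = growth_rate),
            class = "medium_composition")
}
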
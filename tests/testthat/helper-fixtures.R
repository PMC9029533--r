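# Shared fixtures: the seven-gene worked example, random GPR trees and an
# evaluator independent of parse_gpr()/evaluate_gpr().

table1_values <- c(YDL227C = 871, YDL226C = 126, YDL225W = 319,
                   YDL224C = 56, YDL223C = 13, YDL222C = 3, YDL221W = 135)

table1_dataset <- function() transcriptome_dataset("WT", "S1", table1_values)

# random GPR tree built as a plain nested list, NOT a gpr_node
rand_gpr_tree <- function(genes, depth) {
  if (depth <= 0 || stats::runif(1) < 0.35) {
    return(list(type = "leaf", gene = sample(genes, 1)))
  }
  n_children <- sample(2:3, 1)
  list(type = sample(c("AND", "OR"), 1),
       kids = lapply(seq_len(n_children), function(i)
         rand_gpr_tree(genes, depth - 1)))
}

render_gpr_tree <- function(tree) {
  if (tree$type == "leaf") return(tree$gene)
  op <- if (tree$type == "AND") " and " else " or "
  paste0("(", paste(vapply(tree$kids, render_gpr_tree, character(1)),
                    collapse = op), ")")
}

# brute-force evaluation of the test's own tree; geometric mean via the
# product formula so the arithmetic route differs from the implementation
oracle_eval_tree <- function(tree, values, and_op, or_op) {
  if (tree$type == "leaf") return(values[[tree$gene]])
  xs <- vapply(tree$kids, oracle_eval_tree, numeric(1),
               values = values, and_op = and_op, or_op = or_op)
  if (tree$type == "AND") {
    if (and_op == "MIN") min(xs) else prod(xs)^(1 / length(xs))
  } else {
    if (or_op == "MAX") max(xs) else sum(xs)
  }
}

all_schemes <- list(
  mapping_scheme("MIN", "MAX"),
  mapping_scheme("MIN", "SUM"),
  mapping_scheme("GEOMETRIC_MEAN", "MAX"),
  mapping_scheme("GEOMETRIC_MEAN", "SUM")
)

expect_status <- function(classification, expressed, suppressed) {
  for (g in expressed) {
    expect_identical(unname(classification$status[g]), "expressed",
                     label = paste0("status of ", g))
  }
  for (g in suppressed) {
    expect_identical(unname(classification$status[g]), "suppressed",
                     label = paste0("status of ", g))
  }
}

max_mass_imbalance <- function(model, fluxes) {
  S <- stoichiometric_matrix(model)
  max(abs(S %*% fluxes[colnames(S)]))
}
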
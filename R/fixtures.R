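#' Generate a toy metabolic model
#'
#' A deterministic linear pathway `EX_S -> chain -> BIOMASS` with optional
#' redundant parallel branches, an isozyme-gated reaction (GPR
#' `"gA or gB"`) and an enzyme-complex reaction (GPR `"gC and gD"`). The
#' substrate exchange has uptake bound `uptake_lb` (default -10), so the
#' FBA optimum of the default chain is 10. Every chain reaction `Ri`
#' carries a dedicated gene `gRi`.
#'
#' @param n_linear number of chain reactions between uptake and biomass
#'   (>= 2).
#' @param n_parallel number of extra branches running from the substrate
#'   straight to the last chain metabolite (redundant routes).
#' @param with_isozymes gate the first chain reaction with `"gA or gB"`.
#' @param with_complex gate the second chain reaction with `"gC and gD"`.
#' @param uptake_lb lower (uptake) bound of the substrate exchange.
#' @param default_bound magnitude used for unconstrained bounds.
#' @param seed unused (the construction is deterministic); kept so toy
#'   specs are self-describing.
#' @return A [metabolic_model()].
#' @export
#' @examples
#' m <- generate_toy_model(n_linear = 3)
#' fba(m)$objective_value  # 10
generate_toy_model <- function(n_linear = 3, n_parallel = 0,
                               with_isozymes = FALSE, with_complex = FALSE,
                               uptake_lb = -10, default_bound = 1000,
                               seed = 1L) {
  stopifnot(n_linear >= 2)
  mets <- paste0("M", seq_len(n_linear))   # M1 ... Mn; EX feeds M1
  rx <- list()
  st <- list()
  add_rx <- function(id, lb, ub, gpr, stoich) {
    rx[[length(rx) + 1L]] <<- data.frame(id = id, lower_bound = lb,
                                         upper_bound = ub, gpr = gpr,
                                         stringsAsFactors = FALSE)
    st[[length(st) + 1L]] <<- data.frame(metabolite = names(stoich),
                                         reaction = id,
                                         coefficient = unname(stoich),
                                         stringsAsFactors = FALSE)
  }
  add_rx("EX_S", uptake_lb, 0, "", c(M1 = -1))
  for (i in seq_len(n_linear - 1)) {
    gpr <- paste0("gR", i)
    if (i == 1 && with_isozymes) gpr <- "gA or gB"
    if (i == 2 && with_complex) gpr <- "gC and gD"
    add_rx(paste0("R", i), 0, default_bound, gpr,
           stats::setNames(c(-1, 1), mets[c(i, i + 1)]))
  }
  for (p in seq_len(n_parallel)) {
    add_rx(paste0("P", p), 0, default_bound, paste0("gP", p),
           stats::setNames(c(-1, 1), mets[c(1, n_linear)]))
  }
  add_rx("BIOMASS", 0, default_bound, "",
         stats::setNames(-1, mets[n_linear]))
  metabolic_model(do.call(rbind, rx), do.call(rbind, st),
                  objective_reaction = "BIOMASS")
}

#' Generate synthetic transcriptome samples
#'
#' Draws per-gene expression from one of two log-normal components
#' ("low" and "high" expression modes, the standard shape for read
#' counts), according to planted labels, independently per sample.
#' Defaults place the modes at meanlog 3 and 7 (medians ~20 and ~1100
#' reads), well separated. Reproducible under `seed`; the planted labels
#' travel with the result for recovery tests.
#'
#' @param genes character vector of gene ids.
#' @param n_samples number of replicate samples to draw.
#' @param planted_labels named character vector over `genes` with values
#'   `"high"`/`"low"`; defaults to alternating labels.
#' @param meanlog,sdlog length-2 numeric: log-scale location and spread of
#'   the (low, high) components.
#' @param phenotype phenotype label stamped on every sample.
#' @param seed integer seed.
#' @return list with `datasets` (list of [transcriptome_dataset()], samples
#'   `S1..Sn`) and `labels` (the planted labels).
#' @export
generate_transcriptome <- function(genes, n_samples = 3,
                                   planted_labels = NULL,
                                   meanlog = c(3, 7), sdlog = c(0.5, 0.5),
                                   phenotype = "SYN", seed = 1L) {
  stopifnot(length(genes) >= 1, n_samples >= 1)
  if (is.null(planted_labels)) {
    planted_labels <- stats::setNames(
      rep(c("low", "high"), length.out = length(genes)), genes)
  }
  stopifnot(all(genes %in% names(planted_labels)),
            all(planted_labels %in% c("low", "high")))
  comp <- ifelse(planted_labels[genes] == "high", 2L, 1L)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  datasets <- lapply(seq_len(n_samples), function(s) {
    vals <- stats::rlnorm(length(genes), meanlog = meanlog[comp],
                          sdlog = sdlog[comp])
    transcriptome_dataset(phenotype, paste0("S", s),
                          stats::setNames(vals, genes))
  })
  list(datasets = datasets, labels = planted_labels[genes])
}

#' Write transcriptome datasets as CSV sheets
#'
#' Emits one `<phenotype>_<sample>.csv` per dataset (columns `GeneId`,
#' `Data`), the same layout [read_transcriptome()] accepts.
#'
#' @param datasets list of [transcriptome_dataset()].
#' @param path output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_transcriptome <- function(datasets, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(datasets, function(d) {
    f <- file.path(path, paste0(d$phenotype, "_", d$sample, ".csv"))
    utils::write.csv(data.frame(GeneId = names(d$expression),
                                Data = unname(d$expression)),
                     f, row.names = FALSE)
    f
  }, character(1))
  invisible(files)
}
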
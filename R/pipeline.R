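NON_OPT_TASKS <- c("filter-high-low", "filter-low", "compare-expression")
POST_OPT_TASKS <- c("non-flux", "rate-limiting", "flux-shifts")

#' Assemble a run configuration
#'
#' Validates the combination of inputs and selected tasks before any
#' computation: post-optimization tasks need a metabolic model, the local
#' thresholding approaches need replicate samples, and threshold strings
#' may be exact values or percentiles in the form `"p75"`.
#'
#' @param transcriptome path(s) accepted by [read_transcriptome()].
#' @param model optional model path for [read_model()].
#' @param medium optional medium path for [read_medium()].
#' @param out output directory for reports.
#' @param tasks character vector from `filter-high-low`, `filter-low`,
#'   `compare-expression`, `non-flux`, `rate-limiting`, `flux-shifts`.
#' @param approach `"GT1"`, `"LT1"` or `"LT2"`.
#' @param lower,upper threshold strings: a number, or `"pN"` for the Nth
#'   percentile of the pooled expression values.
#' @param and_op,or_op GPR operators: `"min"`/`"gm"` and `"max"`/`"sum"`.
#' @param constrain constraining option: `"irrev"`, `"all"`,
#'   `"nonessential"` or `"mingrow"`.
#' @param fraction FVA fraction of optimum.
#' @param close_uptakes close uptake of exchanges the medium does not list.
#' @param bounds optional manual bounds, either a data.frame
#'   (`reaction`, `lower_bound`, `upper_bound`) or strings `"R:LB:UB"`;
#'   they override medium-file values for the same reaction.
#' @param min_fold fold threshold for `compare-expression`.
#' @param seed integer seed recorded in the config echo.
#' @return A `run_config` list.
#' @export
run_config <- function(transcriptome, model = NULL, medium = NULL,
                       out = "gemtx_reports",
                       tasks = "filter-high-low",
                       approach = "GT1", lower = "p50", upper = NULL,
                       and_op = "min", or_op = "max",
                       constrain = "all", fraction = 1.0,
                       close_uptakes = FALSE, bounds = NULL,
                       min_fold = 1.0, seed = 1L) {
  tasks <- match.arg(tasks, c(NON_OPT_TASKS, POST_OPT_TASKS), several.ok = TRUE)
  approach <- match.arg(approach, c("GT1", "LT1", "LT2"))
  if (any(tasks %in% POST_OPT_TASKS) && is.null(model)) {
    stop("post-optimization task(s) ",
         paste(intersect(tasks, POST_OPT_TASKS), collapse = ", "),
         " require a metabolic model; only a transcriptome was provided")
  }
  parse_thr <- function(s) {
    if (is.null(s)) return(NULL)
    if (inherits(s, "threshold_spec")) return(s)
    s <- as.character(s)
    if (grepl("^[pP]", s)) threshold_spec(as.numeric(sub("^[pP]", "", s)),
                                          "percentile")
    else threshold_spec(as.numeric(s), "exact")
  }
  if (is.character(bounds)) {
    parts <- strsplit(bounds, ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 3
    if (any(bad)) stop("manual bounds must be 'REACTION:LB:UB'")
    bounds <- data.frame(reaction = vapply(parts, `[`, "", 1),
                         lower_bound = as.numeric(vapply(parts, `[`, "", 2)),
                         upper_bound = as.numeric(vapply(parts, `[`, "", 3)),
                         stringsAsFactors = FALSE)
  }
  structure(list(
    transcriptome = transcriptome, model = model, medium = medium, out = out,
    tasks = tasks, approach = approach,
    lower = parse_thr(lower), upper = parse_thr(upper),
    scheme = mapping_scheme(
      and_operator = switch(match.arg(and_op, c("min", "gm")),
                            min = "MIN", gm = "GEOMETRIC_MEAN"),
      or_operator = switch(match.arg(or_op, c("max", "sum")),
                           max = "MAX", sum = "SUM")),
    constrain = switch(match.arg(constrain,
                                 c("irrev", "all", "nonessential", "mingrow")),
                       irrev = "IRREVERSIBLE_ONLY", all = "ALL_REACTIONS",
                       nonessential = "NONESSENTIAL_DELETION",
                       mingrow = "MEET_MIN_GROWTH"),
    fraction = fraction, close_uptakes = close_uptakes,
    bounds = bounds, min_fold = min_fold, seed = as.integer(seed)
  ), class = "run_config")
}

key_of <- function(d) paste0(d$phenotype, "_", d$sample)

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading, threshold resolution and gene
#' classification, then (only when a model is supplied and a
#' post-optimization task is selected) context-model construction and
#' FVA, then the selected tasks, and finally one report sheet per task and
#' sample via [write_report()]. Runs without any LP solve when only
#' non-optimization tasks are selected. Progress and every resolved
#' decision (thresholds, skipped genes, audit sizes) are logged to stderr.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the classifications, context models, FVA
#'   and task results; reports are written under `config$out`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  datasets <- read_transcriptome(config$transcriptome)
  say("loaded ", length(datasets), " transcriptome sample(s)")
  pool <- unlist(lapply(datasets, function(d) d$expression))

  by_phen <- group_by_phenotype(datasets)
  locals <- NULL
  if (config$approach %in% c("LT1", "LT2")) {
    thin <- names(by_phen)[vapply(by_phen, length, integer(1)) < 2]
    if (length(thin)) {
      stop(config$approach, " requires at least two samples per condition; ",
           "phenotype(s) with a single sample: ",
           paste(thin, collapse = ", "), ". Use GT1 instead.")
    }
    locals <- lapply(by_phen, compute_local_thresholds)
  }

  cfg <- threshold_config(config$approach, lower = config$lower,
                          upper = config$upper)
  classifications <- lapply(datasets, function(d) {
    cl <- classify(d, cfg, locals = locals[[d$phenotype]], pool = pool)
    say(key_of(d), ": ", sum(cl$status == "expressed"), " expressed / ",
        sum(cl$status == "suppressed"), " suppressed (globals: ",
        paste(round(cl$resolved_globals[!is.na(cl$resolved_globals)], 4),
              collapse = ", "), ")")
    cl
  })
  names(classifications) <- vapply(datasets, key_of, character(1))

  reports <- list()
  results <- list(classifications = classifications)

  resolved <- classifications[[1]]$resolved_globals
  reports[["run_config"]] <- data.frame(
    key = c("approach", "lower_global", "upper_global", "and_op", "or_op",
            "constrain", "fraction", "tasks", "seed"),
    value = c(config$approach, resolved[["lower"]], resolved[["upper"]],
              config$scheme$and_operator, config$scheme$or_operator,
              config$constrain, config$fraction,
              paste(config$tasks, collapse = ";"), config$seed),
    stringsAsFactors = FALSE)

  for (i in seq_along(datasets)) {
    k <- key_of(datasets[[i]])
    if ("filter-high-low" %in% config$tasks) {
      hl <- filter_high_low(classifications[[i]])
      reports[[paste0("high_", k)]] <- hl$high
      reports[[paste0("low_", k)]] <- hl$low
    }
    if ("filter-low" %in% config$tasks) {
      reports[[paste0("filterlow_", k)]] <- filter_low(classifications[[i]])
    }
  }
  if ("compare-expression" %in% config$tasks) {
    if (length(datasets) < 2) stop("compare-expression needs >= 2 datasets")
    cmp <- compare_expression(datasets, min_fold = config$min_fold)
    results$compare_expression <- cmp
    for (cid in unique(cmp$comparison)) {
      reports[[paste0("compare_", cid)]] <-
        cmp[cmp$comparison == cid, setdiff(names(cmp), "comparison")]
    }
  }

  if (any(config$tasks %in% POST_OPT_TASKS)) {
    model <- read_model(config$model)
    say("model: ", length(model$metabolites), " metabolites, ",
        nrow(model$reactions), " reactions")
    medium <- if (!is.null(config$medium)) read_medium(config$medium) else NULL
    if (!is.null(config$bounds)) {
      mb <- config$bounds
      if (is.null(medium)) {
        medium <- medium_composition(mb)
      } else {
        kept <- medium$bounds[!medium$bounds$reaction %in% mb$reaction, ,
                              drop = FALSE]
        medium <- medium_composition(rbind(kept, mb), medium$growth_rate)
      }
    }

    contexts <- list()
    fvas <- list()
    for (i in seq_along(datasets)) {
      k <- key_of(datasets[[i]])
      ctx <- build_context_model(model, datasets[[i]], classifications[[i]],
                                 scheme = config$scheme,
                                 option = config$constrain, medium = medium,
                                 close_unlisted = config$close_uptakes)
      say(k, ": ", nrow(ctx$audit), " audit entries, ",
          length(ctx$deleted_genes), " gene deletions")
      contexts[[k]] <- ctx
      fvas[[k]] <- fva(ctx, fraction_of_optimum = config$fraction)
      reports[[paste0("constraints_", k)]] <- ctx$audit
    }
    results$contexts <- contexts
    results$fva <- fvas

    for (k in names(contexts)) {
      if ("non-flux" %in% config$tasks) {
        reports[[paste0("nonflux_", k)]] <-
          non_flux_reactions(contexts[[k]], fvas[[k]])
      }
      if ("rate-limiting" %in% config$tasks) {
        reports[[paste0("ratelimiting_", k)]] <-
          rate_limiting_reactions(contexts[[k]], fvas[[k]])
      }
    }
    if ("flux-shifts" %in% config$tasks) {
      if (length(contexts) < 2) stop("flux-shifts needs >= 2 datasets")
      ref <- names(contexts)[1]
      for (k in names(contexts)[-1]) {
        reports[[paste0("fluxshifts_", ref, "_vs_", k)]] <-
          flux_shifts(fvas[[ref]], fvas[[k]])
      }
    }
  }

  files <- write_report(reports, config$out)
  say("wrote ", length(files), " report sheet(s) to ", config$out)
  results$reports <- reports
  invisible(results)
}
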
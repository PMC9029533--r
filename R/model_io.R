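#' Read a metabolic model
#'
#' Supported formats:
#' * `sbml` — SBML Level 3 with the FBC package (flux bounds as parameters,
#'   gene associations as `geneProductAssociation`, objective from the
#'   active `fbc:objective`).
#' * `json` — the COBRA community JSON schema (`metabolites`, `reactions`
#'   with `lower_bound`/`upper_bound`/`gene_reaction_rule`/
#'   `objective_coefficient`, `genes`).
#' * `tabular` — a directory holding `reactions.csv`
#'   (`id, lower_bound, upper_bound, gpr, objective`) and `stoich.csv`
#'   (`metabolite, reaction, coefficient`).
#'
#' GPR strings are preserved verbatim; every gene they reference must be
#' declared in the model's gene inventory.
#'
#' @param path file path (directory for `tabular`).
#' @param format `"sbml"`, `"json"` or `"tabular"`; guessed from the path
#'   when omitted.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "tabular"
              else switch(tolower(tools::file_ext(path)),
                          xml = , sbml = "sbml", json = "json",
                          stop("cannot guess model format from '", path, "'"))
  }
  format <- match.arg(format, c("sbml", "json", "tabular"))
  if (!file.exists(path)) stop("model path does not exist: ", path)
  switch(format,
         sbml = read_model_sbml(path),
         json = read_model_json(path),
         tabular = read_model_tabular(path))
}

read_model_tabular <- function(path) {
  rx_file <- file.path(path, "reactions.csv")
  st_file <- file.path(path, "stoich.csv")
  for (f in c(rx_file, st_file)) if (!file.exists(f)) stop("missing file: ", f)
  rx <- utils::read.csv(rx_file, stringsAsFactors = FALSE,
                        colClasses = c(gpr = "character"))
  st <- utils::read.csv(st_file, stringsAsFactors = FALSE)
  obj <- rx$id[as.logical(rx$objective)]
  if (length(obj) != 1) stop("exactly one reaction must carry the objective flag")
  rx$lower_bound <- as.numeric(rx$lower_bound)
  rx$upper_bound <- as.numeric(rx$upper_bound)
  metabolic_model(rx, st, objective_reaction = obj)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) stop("JSON model lacks '", field, "'")
  }
  rxs <- doc$reactions
  rx <- data.frame(
    id = vapply(rxs, function(r) r$id, character(1)),
    lower_bound = vapply(rxs, function(r) as.numeric(r$lower_bound), numeric(1)),
    upper_bound = vapply(rxs, function(r) as.numeric(r$upper_bound), numeric(1)),
    gpr = vapply(rxs, function(r) {
      g <- r$gene_reaction_rule
      if (is.null(g)) "" else as.character(g)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  st <- do.call(rbind, lapply(rxs, function(r) {
    mets <- r$metabolites
    if (!length(mets)) return(NULL)
    data.frame(metabolite = names(mets), reaction = r$id,
               coefficient = as.numeric(unlist(mets)),
               stringsAsFactors = FALSE)
  }))
  obj_coef <- vapply(rxs, function(r) {
    if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient)
  }, numeric(1))
  obj <- rx$id[obj_coef != 0]
  if (length(obj) != 1) stop("expected exactly one reaction with nonzero ",
                             "objective_coefficient, found ", length(obj))
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  genes <- if (is.null(doc$genes)) NULL
           else vapply(doc$genes, function(g) g$id, character(1))
  metabolic_model(rx, st, metabolites = mets, genes = genes,
                  objective_reaction = obj)
}

# SBML ids must be SIds; gene/species ids round-trip through a label
sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("unparseable SBML: ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (inherits(model_node, "xml_missing")) stop("SBML file has no <model> element")

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- xml2::xml_attr(sp, "id")[!boundary]

  # fbc-namespaced elements keep their namespace even after ns stripping,
  # so they are matched by local name
  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_ids <- xml2::xml_attr(gp, "id")
  gp_labels <- xml2::xml_attr(gp, "label")
  gp_labels[is.na(gp_labels)] <- gp_ids[is.na(gp_labels)]
  gene_of <- stats::setNames(gp_labels, gp_ids)

  assoc_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      g <- gene_of[[ref]]
      return(if (is.null(g)) ref else g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_text, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("SBML model declares no reactions")
  n <- length(rx_nodes)
  rx <- data.frame(id = character(n), lower_bound = numeric(n),
                   upper_bound = numeric(n), gpr = character(n),
                   stringsAsFactors = FALSE)
  st <- list()
  for (k in seq_len(n)) {
    node <- rx_nodes[[k]]
    id <- xml2::xml_attr(node, "id")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref) ||
        is.na(pvals[lb_ref]) || is.na(pvals[ub_ref])) {
      stop("reaction '", id, "': missing or unresolved FBC flux bound")
    }
    rx$id[k] <- id
    rx$lower_bound[k] <- pvals[[lb_ref]]
    rx$upper_bound[k] <- pvals[[ub_ref]]
    ga <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    rx$gpr[k] <- if (inherits(ga, "xml_missing")) "" else {
      txt <- assoc_text(xml2::xml_child(ga))
      sub("^\\((.*)\\)$", "\\1", txt)
    }
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./", side, "/speciesReference"))
      for (r in refs) {
        species <- xml2::xml_attr(r, "species")
        if (!species %in% mets) next  # boundary species: not balanced
        coef <- xml2::xml_attr(r, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        st[[length(st) + 1L]] <- data.frame(metabolite = species, reaction = id,
                                            coefficient = sign * coef,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  st <- if (length(st)) do.call(rbind, st) else
    data.frame(metabolite = character(), reaction = character(),
               coefficient = numeric())

  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing")) stop("SBML model declares no FBC objective")
  obj_id <- xml2::xml_attr(fo, "reaction")

  genes <- unname(gene_of)
  metabolic_model(rx, st, metabolites = mets,
                  genes = if (length(genes)) genes else NULL,
                  objective_reaction = obj_id)
}

#' Write a metabolic model
#'
#' Writes the tabular dialect (a directory with `reactions.csv` and
#' `stoich.csv`) or SBML Level 3 + FBC. Both round-trip through
#' [read_model()] with identical bounds, GPR rules and stoichiometry.
#'
#' @param model a [metabolic_model()].
#' @param path output directory (`tabular`) or file path (`sbml`).
#' @param format `"tabular"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "metabolic_model"))
  if (format == "tabular") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    rx <- model$reactions
    rx$objective <- as.integer(rx$id == model$objective_reaction)
    utils::write.csv(rx, file.path(path, "reactions.csv"), row.names = FALSE)
    utils::write.csv(model$stoichiometry, file.path(path, "stoich.csv"),
                     row.names = FALSE)
  } else {
    write_model_sbml(model, path)
  }
  invisible(path)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  rx <- model$reactions
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>'
  )
  lines <- c(lines, '    <listOfSpecies>',
             sprintf(paste0('      <species id="%s" compartment="c" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"/>'),
                     esc(model$metabolites)),
             '    </listOfSpecies>')
  bounds <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  pid <- stats::setNames(paste0("par_", seq_along(bounds)), num(bounds))
  lines <- c(lines, '    <listOfParameters>',
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     pid, names(pid)),
             '    </listOfParameters>')
  if (length(model$genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf(paste0('      <fbc:geneProduct fbc:id="G_%s" ',
                              'fbc:label="%s"/>'),
                       sbml_sid(model$genes), esc(model$genes)),
               '    </fbc:listOfGeneProducts>')
  }
  assoc_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$kind == "gene") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, sbml_sid(node$gene)))
    }
    tag <- if (node$kind == "and") "fbc:and" else "fbc:or"
    c(sprintf('%s<%s>', pad, tag),
      unlist(lapply(node$children, assoc_xml, indent = indent + 2)),
      sprintf('%s</%s>', pad, tag))
  }
  lines <- c(lines, '    <listOfReactions>')
  for (k in seq_len(nrow(rx))) {
    id <- rx$id[k]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(id), tolower(rx$lower_bound[k] < 0),
      pid[[num(rx$lower_bound[k])]], pid[[num(rx$upper_bound[k])]]))
    st <- model$stoichiometry[model$stoichiometry$reaction == id, , drop = FALSE]
    for (side in c("listOfReactants", "listOfProducts")) {
      rows <- if (side == "listOfReactants") st[st$coefficient < 0, , drop = FALSE]
              else st[st$coefficient > 0, , drop = FALSE]
      if (!nrow(rows)) next
      lines <- c(lines, sprintf('        <%s>', side),
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(rows$metabolite), num(abs(rows$coefficient))),
                 sprintf('        </%s>', side))
    }
    if (nzchar(rx$gpr[k])) {
      expr <- parse_gpr(rx$gpr[k])
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 assoc_xml(expr, 10),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                            'fbc:coefficient="1"/>'),
                     esc(model$objective_reaction)),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>',
             '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

# phenotype_sample from a sheet or file name: split on the LAST underscore;
# no underscore means a phenotype with a single anonymous sample "1".
parse_sheet_name <- function(name) {
  if (!grepl("_", name)) return(c(phenotype = name, sample = "1"))
  c(phenotype = sub("_[^_]*$", "", name),
    sample = sub("^.*_", "", name))
}

transcriptome_from_table <- function(tab, sheet) {
  if (!all(c("GeneId", "Data") %in% names(tab))) {
    stop("sheet '", sheet, "': expected columns GeneId and Data, found: ",
         paste(names(tab), collapse = ", "))
  }
  if (!nrow(tab)) stop("sheet '", sheet, "' is empty")
  vals <- suppressWarnings(as.numeric(tab$Data))
  bad <- which(is.na(vals) | vals < 0)
  if (length(bad)) {
    stop("sheet '", sheet, "': non-numeric or negative Data at row(s) ",
         paste(bad, collapse = ", "))
  }
  ps <- parse_sheet_name(sheet)
  transcriptome_dataset(ps[["phenotype"]], ps[["sample"]],
                        stats::setNames(vals, as.character(tab$GeneId)))
}

#' Read transcriptome datasets
#'
#' Accepts an xlsx workbook (one sheet per sample; needs the readxl
#' package) or one or more CSV files (one file per sample; the file name
#' sans extension plays the sheet-name role). Every sheet must have the
#' columns `GeneId` and `Data`. The sheet name encodes
#' `<phenotype>_<sample>`, split on the last underscore; a name without an
#' underscore is a phenotype with a single anonymous sample.
#'
#' @param path path to an xlsx file, a vector of CSV paths, or a directory
#'   of CSV files.
#' @return List of [transcriptome_dataset()], one per sheet/file.
#' @export
read_transcriptome <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(path)) stop("no CSV files found in directory")
  }
  out <- list()
  for (p in path) {
    if (!file.exists(p)) stop("file does not exist: ", p)
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("xlsx", "xls")) {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package; CSV input needs none")
      }
      for (sheet in readxl::excel_sheets(p)) {
        tab <- as.data.frame(readxl::read_excel(p, sheet = sheet))
        out[[length(out) + 1L]] <- transcriptome_from_table(tab, sheet)
      }
    } else {
      tab <- utils::read.csv(p, stringsAsFactors = FALSE)
      sheet <- tools::file_path_sans_ext(basename(p))
      out[[length(out) + 1L]] <- transcriptome_from_table(tab, sheet)
    }
  }
  keys <- vapply(out, function(d) paste0(d$phenotype, "_", d$sample), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate phenotype/sample pair(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  out
}

#' Group transcriptome datasets by phenotype
#'
#' @param datasets list of [transcriptome_dataset()].
#' @return Named list of lists, one entry per phenotype.
#' @export
group_by_phenotype <- function(datasets) {
  phens <- vapply(datasets, function(d) d$phenotype, character(1))
  lapply(split(seq_along(datasets), phens), function(i) datasets[i])
}

#' Read a medium-composition table
#'
#' CSV or xlsx with columns `reaction`, `lower_bound`, `upper_bound`
#' (mmol g-1 h-1). A row whose reaction id is `growth_rate`
#' (case-insensitive) supplies the optional specific growth rate (h-1)
#' through its `lower_bound` field.
#'
#' @param path file path.
#' @return A [medium_composition()].
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package; CSV input needs none")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  names(tab) <- tolower(names(tab))
  alias <- function(cands) {
    hit <- intersect(cands, names(tab))
    if (!length(hit)) stop("medium file lacks a column among: ",
                           paste(cands, collapse = ", "))
    tab[[hit[1]]]
  }
  df <- data.frame(reaction = as.character(alias(c("reaction", "reaction_id", "id"))),
                   lower_bound = as.numeric(alias(c("lower_bound", "lb", "lower"))),
                   upper_bound = as.numeric(alias(c("upper_bound", "ub", "upper"))),
                   stringsAsFactors = FALSE)
  gr_row <- tolower(df$reaction) %in% c("growth_rate", "growth rate")
  growth_rate <- if (any(gr_row)) df$lower_bound[gr_row][1] else NULL
  medium_composition(df[!gr_row, , drop = FALSE], growth_rate = growth_rate)
}

#' Write task results as report tables
#'
#' Writes one CSV file per result sheet into a directory, preserving each
#' table's column order. Sheets are named after their source
#' phenotype/sample (and task), matching the input sheet-naming convention.
#'
#' @param results a named list of data.frames (sheet name -> table), or a
#'   single data.frame (written as sheet `"results"`).
#' @param path output directory; created if needed.
#' @param format only `"csv"` is supported for output; requesting `"xlsx"`
#'   raises an informative error.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("no spreadsheet writer is available; use format = 'csv' ",
         "(one file per sheet)")
  }
  if (is.data.frame(results)) results <- list(results = results)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("results must be a named list: sheet name -> data.frame")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sheet in names(results)) {
    f <- file.path(path, paste0(sheet, ".csv"))
    utils::write.csv(as.data.frame(results[[sheet]]), f, row.names = FALSE,
                     na = "")
    files <- c(files, f)
  }
  invisible(files)
}
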
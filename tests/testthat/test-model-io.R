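test_that("direction classification follows the bounds", {
  m <- generate_toy_model()
  m$reactions$lower_bound[2] <- 0;     m$reactions$upper_bound[2] <- 1000
  m$reactions$lower_bound[3] <- -1000; m$reactions$upper_bound[3] <- 0
  dirs <- reaction_directions(m)
  expect_equal(unname(dirs[m$reactions$id[2]]), "irreversible")
  expect_equal(unname(dirs[m$reactions$id[3]]), "backward_irreversible")
  expect_equal(unname(dirs[["EX_S"]]), "backward_irreversible")  # lb -10, ub 0
})

test_that("model invariants are enforced at construction", {
  rx <- data.frame(id = c("R1", "B"), lower_bound = 0, upper_bound = 10,
                   gpr = c("gX and gY", ""))
  st <- data.frame(metabolite = c("A", "A"), reaction = c("R1", "B"),
                   coefficient = c(1, -1))
  expect_error(metabolic_model(rx, st, genes = "gX", objective_reaction = "B"),
               "undeclared gene.*gY")
  expect_error(metabolic_model(rx, st, objective_reaction = "nope"),
               "not a declared reaction")
  rx_bad <- rx; rx_bad$lower_bound[1] <- 20
  expect_error(metabolic_model(rx_bad, st, objective_reaction = "B"),
               "lower_bound > upper_bound")
})

test_that("tabular round-trip preserves bounds, GPRs and stoichiometry", {
  m <- generate_toy_model(n_linear = 4, n_parallel = 1,
                          with_isozymes = TRUE, with_complex = TRUE)
  dir <- withr::local_tempdir()
  write_model(m, dir, "tabular")
  m2 <- read_model(dir, "tabular")
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$objective_reaction, m$objective_reaction)
  st_a <- m$stoichiometry[order(m$stoichiometry$reaction,
                                m$stoichiometry$metabolite), ]
  st_b <- m2$stoichiometry[order(m2$stoichiometry$reaction,
                                 m2$stoichiometry$metabolite), ]
  expect_equal(unname(as.matrix(st_b)), unname(as.matrix(st_a)))
})

test_that("SBML round-trip preserves the model and its optima", {
  m <- generate_toy_model(n_linear = 4, n_parallel = 1,
                          with_isozymes = TRUE, with_complex = TRUE)
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  m2 <- read_model(f, "sbml")
  expect_setequal(m2$metabolites, m$metabolites)
  expect_setequal(m2$genes, m$genes)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$objective_reaction, m$objective_reaction)
  expect_equal(stoichiometric_matrix(m2)[m$metabolites, m$reactions$id],
               stoichiometric_matrix(m))
  # GPR text may gain explicit parentheses; semantics must be identical
  vals <- stats::setNames(seq(10, 10 * length(m$genes), by = 10), m$genes)
  for (k in seq_len(nrow(m$reactions))) {
    for (scheme in all_schemes) {
      expect_equal(
        evaluate_gpr(parse_gpr(m2$reactions$gpr[k]), vals, scheme),
        evaluate_gpr(parse_gpr(m$reactions$gpr[k]), vals, scheme))
    }
  }
  expect_equal(fba(m2)$objective_value, fba(m)$objective_value)
})

test_that("JSON models in the COBRA community schema are read", {
  f <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    metabolites = list(list(id = "A"), list(id = "B")),
    genes = list(list(id = "g1"), list(id = "g2")),
    reactions = list(
      list(id = "EX_A", lower_bound = -10, upper_bound = 0,
           metabolites = list(A = -1)),
      list(id = "R1", lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "g1 or g2",
           metabolites = list(A = -1, B = 1)),
      list(id = "BIO", lower_bound = 0, upper_bound = 1000,
           objective_coefficient = 1, metabolites = list(B = -1))
    ))
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  m <- read_model(f, "json")
  expect_equal(m$objective_reaction, "BIO")
  expect_equal(m$reactions$gpr[m$reactions$id == "R1"], "g1 or g2")
  expect_equal(fba(m)$objective_value, 10)
})

test_that("unparseable model files fail with a format error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", f)   # mismatched tags
  expect_error(read_model(f, "sbml"), "SBML")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model/></sbml>", f2) # no reactions
  expect_error(read_model(f2, "sbml"), "no reactions|reaction")
})

test_that("transcriptome sheets parse names and validate their tables", {
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(GeneId = names(table1_values),
                              Data = unname(table1_values)),
                   file.path(dir, "WT_S1.csv"), row.names = FALSE)
  utils::write.csv(data.frame(GeneId = c("g1", "g2"), Data = c(1, 2)),
                   file.path(dir, "WT_S2.csv"), row.names = FALSE)
  ds <- read_transcriptome(dir)
  expect_length(ds, 2)
  expect_equal(ds[[1]]$phenotype, "WT")
  expect_equal(ds[[1]]$sample, "S1")
  expect_length(ds[[1]]$expression, 7)
  expect_equal(unname(ds[[1]]$expression["YDL227C"]), 871)
  # both sheets share the phenotype
  grp <- group_by_phenotype(ds)
  expect_named(grp, "WT")
  expect_length(grp$WT, 2)

  # last-underscore split; no underscore = anonymous sample
  expect_equal(parse_sheet_name("cond_A_S1"),
               c(phenotype = "cond_A", sample = "S1"))
  expect_equal(unname(parse_sheet_name("WT")[["sample"]]), "1")
})

test_that("regrouping by phenotype partitions the samples", {
  dir <- withr::local_tempdir()
  for (nm in c("WT_S1", "WT_S2", "MUT_S1")) {
    utils::write.csv(data.frame(GeneId = "g1", Data = 1),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  ds <- read_transcriptome(dir)
  grp <- group_by_phenotype(ds)
  keys_in <- sort(vapply(ds, function(d) paste0(d$phenotype, "_", d$sample),
                         character(1)))
  keys_out <- sort(unname(unlist(lapply(grp, function(g)
    vapply(g, function(d) paste0(d$phenotype, "_", d$sample), character(1))))))
  expect_identical(keys_out, keys_in)
})

test_that("transcriptome schema violations are precise errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Gene = "g1", Value = 1), f, row.names = FALSE)
  expect_error(read_transcriptome(f), "GeneId")

  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(GeneId = c("g1", "g2"), Data = c(5, -1)),
                   f2, row.names = FALSE)
  expect_error(read_transcriptome(f2), "row\\(s\\) 2")

  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(GeneId = character(), Data = numeric()),
                   f3, row.names = FALSE)
  expect_error(read_transcriptome(f3), "empty")

  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(GeneId = c("g1", "g1"), Data = c(1, 2)),
                   f4, row.names = FALSE)
  expect_error(read_transcriptome(f4), "duplicate gene")
})

test_that("medium files read bounds and the optional growth rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(reaction = c("EX_glc", "growth_rate"),
                              lower_bound = c(-10, 0.3),
                              upper_bound = c(0, 0.3)),
                   f, row.names = FALSE)
  med <- read_medium(f)
  expect_equal(med$bounds$reaction, "EX_glc")
  expect_equal(med$bounds$lower_bound, -10)
  expect_equal(med$growth_rate, 0.3)

  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(reaction = "R1", lower_bound = 5,
                              upper_bound = 2), f2, row.names = FALSE)
  expect_error(read_medium(f2), "lower_bound > upper_bound")
})

test_that("reports land as one deterministic CSV per sheet", {
  dir <- withr::local_tempdir()
  res <- list(
    high_WT_S1 = data.frame(gene = "g1", value = 10, deciding_threshold = 5),
    empty_sheet = data.frame(gene = character(), value = numeric())
  )
  files <- write_report(res, dir)
  expect_setequal(basename(files), c("high_WT_S1.csv", "empty_sheet.csv"))
  back <- utils::read.csv(file.path(dir, "high_WT_S1.csv"))
  expect_equal(names(back), c("gene", "value", "deciding_threshold"))
  # an empty result keeps its header row
  hdr <- readLines(file.path(dir, "empty_sheet.csv"))
  expect_match(hdr[1], "gene")
  expect_error(write_report(res, dir, format = "xlsx"), "csv")
})
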
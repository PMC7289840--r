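test_that("TSV and BIOM round trips preserve counts, ids and labels", {
  tb <- tinyTable()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOtuTable(tb, tsv, format = "tsv")
  back <- readOtuTable(tsv, format = "tsv", rank = "family")
  expect_identical(otuCounts(back)[taxonLabels(tb), sampleIds(tb)], otuCounts(tb))

  biom <- withr::local_tempfile(fileext = ".biom")
  writeOtuTable(tb, biom, format = "biom")
  back2 <- readOtuTable(biom, format = "biom", rank = "family")
  expect_equal(otuCounts(back2)[taxonLabels(tb), sampleIds(tb)], otuCounts(tb),
               ignore_attr = FALSE)

  # BIOM twin of the TSV file carries identical counts
  expect_equal(otuCounts(back2)[taxonLabels(back), sampleIds(back)],
               otuCounts(back))
})

test_that("ingest validation rejects malformed tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tF1\tF2", "S1\t3\t4", "S1\t1\t2"), f)
  expect_error(readOtuTable(f, "tsv", "family"), "duplicated")

  m <- tinyCounts()
  m[1, 1] <- -2
  expect_error(otuTable(m, rank = "family"), "nonnegative")
  m <- tinyCounts(); m[1, 1] <- 1.5
  expect_error(otuTable(m, rank = "family"), "integer")
  m <- tinyCounts(); m[, 2] <- 0
  expect_error(otuTable(m, rank = "family"), "zero-total")
  expect_error(otuTable(matrix(nrow = 0, ncol = 0), rank = "family"), "empty")
})

test_that("metadata join is strict and field-validated", {
  m <- tinyCounts()
  md <- data.frame(disease = c("AAV", "AAV", "sarcoidosis"),
                   sex = c("female", "male", "female"),
                   row.names = paste0("S", 1:3))
  tb <- otuTable(m, rank = "family", sampleData = md)
  expect_identical(as.character(sampleData(tb)$disease), md$disease)

  expect_error(otuTable(m, rank = "family", sampleData = md[1:2, , drop = FALSE]),
               "missing sample")
  bad <- md; bad$disease[1] <- "IPF"
  expect_error(otuTable(m, rank = "family", sampleData = bad), "invalid disease")
  odd <- md; odd$bvas <- c(12, 8, 5)  # BVAS on a sarcoidosis sample
  expect_warning(otuTable(m, rank = "family", sampleData = odd), "non-AAV")
})

test_that("rank aggregation sums counts and conserves per-sample totals", {
  set.seed(42)
  m <- matrix(rpois(10 * 4, 6), nrow = 10,
              dimnames = list(paste0("OTU", 1:10), paste0("S", 1:4)))
  m[1, ] <- m[1, ] + 1  # guard against zero-total samples
  tb <- otuTable(m, rank = "otu")
  fam <- c("Fa", "Fa", "Fb", "Fb", "Fb", "Fc", "Fc", "Fd", NA, "Fd")
  tax <- data.frame(otu = rownames(m), family = fam)

  agg <- aggregateToRank(tb, tax, rank = "family")
  # additivity against an independent group-by oracle
  grp <- ifelse(is.na(fam), "__unassigned__", fam)
  oracle <- t(sapply(sort(unique(grp)), function(g)
    colSums(m[grp == g, , drop = FALSE])))
  expect_equal(otuCounts(agg)[rownames(oracle), ], oracle)
  # conservation
  expect_equal(colSums(otuCounts(agg)), colSums(m))
  # 10 OTUs -> 4 families plus the unassigned pool
  expect_setequal(taxonLabels(agg), c("Fa", "Fb", "Fc", "Fd", "__unassigned__"))

  dropped <- aggregateToRank(tb, tax, rank = "family", dropUnassigned = TRUE)
  expect_false("__unassigned__" %in% taxonLabels(dropped))
  expect_error(aggregateToRank(tb, tax[, "otu", drop = FALSE], rank = "genus"),
               "no 'genus' column")
})

test_that("subsetTaxa follows set semantics and flags zero-total samples", {
  tb <- tinyTable()
  all4 <- taxaSet(paste0("F", 1:4), rank = "family")
  expect_identical(otuCounts(subsetTaxa(tb, all4, "restrict")), otuCounts(tb))
  expect_error(subsetTaxa(tb, all4, "exclude"), "0 taxa")

  # restrict(S) == exclude(complement(S))
  s <- taxaSet(c("F1", "F3"), rank = "family")
  comp <- taxaSet(c("F2", "F4"), rank = "family")
  expect_identical(otuCounts(subsetTaxa(tb, s, "restrict")),
                   otuCounts(subsetTaxa(tb, comp, "exclude")))

  # unmatched labels reported, not an error
  expect_message(subsetTaxa(tb, taxaSet(c("F1", "F9"), rank = "family"), "restrict"),
                 "1 taxa-set label")
  # rank mismatch is an error
  expect_error(subsetTaxa(tb, taxaSet("F1", rank = "genus"), "restrict"),
               "rank mismatch")

  # zero-total sample flagged, retained
  m <- tinyCounts()
  m["F1", ] <- c(10, 0, 0); m["F2", ] <- c(0, 5, 5)
  m["F3", ] <- c(0, 1, 2); m["F4", ] <- c(0, 3, 1)
  tb2 <- otuTable(m, rank = "family")
  sub <- suppressMessages(subsetTaxa(tb2, taxaSet("F1", rank = "family"), "restrict"))
  expect_identical(flaggedSamples(sub), c("S2", "S3"))
  expect_identical(ncol(sub), 3L)
})

test_that("excluding the 96 planted oral families from a 144-family cohort leaves 48", {
  co <- makeCohort(presetScenarios()$null, seed = 101)
  vag <- taxaSet(co$truth$oralTaxa, rank = "family", provenance = "vagrant@>0.05")
  expect_length(co$truth$oralTaxa, 96)
  left <- suppressMessages(subsetTaxa(co$table, vag, "exclude"))
  expect_identical(nrow(left), 48L)
})
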
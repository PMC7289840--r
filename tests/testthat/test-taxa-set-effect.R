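test_that("standardized U matches brute-force enumeration and hand values", {
  # values 1:4, groups A A B B: U(A) = 0, z = -2/sqrt(5/3)
  z <- standardizedU(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(z, -2 / sqrt(20 / 12), tolerance = 1e-12)
  expect_equal(z, -1.5492, tolerance = 1e-4)
  # brute force: permutation distribution of U has mean n1 n2 / 2
  or <- oracleMwuExact(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(or$u, 0)
  expect_equal(mean(or$dist), 2)
  # extreme separation: U = n1 n2 and z maximal over label assignments
  zs <- apply(utils::combn(6, 3), 2, function(ix) {
    g <- rep("B", 6); g[ix] <- "A"
    standardizedU(c(10, 20, 30, 1, 2, 3), g)
  })
  zTop <- standardizedU(c(10, 20, 30, 1, 2, 3), c("A", "A", "A", "B", "B", "B"))
  expect_equal(zTop, max(zs))
  # antisymmetry under label exchange
  set.seed(4)
  v <- rnorm(9); g <- sample(c("A", "B"), 9, TRUE, prob = c(0.5, 0.5))
  g[1:2] <- c("A", "B")
  expect_equal(standardizedU(v, factor(g, levels = c("B", "A"))),
               -standardizedU(v, factor(g, levels = c("A", "B"))))
  # monotone data effect: shifting one group up moves z up
  z0 <- standardizedU(v, g)
  v2 <- v + (g == "A") * 10
  expect_gt(standardizedU(v2, g), z0)
  expect_error(standardizedU(c(1, 1, 1, 1), c("A", "A", "B", "B")), "zero variance")
  expect_error(standardizedU(1:3, c("A", "A", "A")), "2 levels")
})

test_that("percentile rank follows the declared tie conventions", {
  expect_equal(percentileRank(0, 1:10), 0)
  expect_equal(percentileRank(50, 1:99), 100 * 50 / 99)
  expect_equal(percentileRank(5, 5), 100)          # default "<=" at a tie
  expect_equal(percentileRank(5, 5, ties = "lt"), 0)
  expect_equal(percentileRank(5, 5, ties = "mid"), 50)
  expect_equal(percentileRank(99.5, 1:99), 100)
  expect_error(percentileRank(1, numeric()), "empty")
})

test_that("null ECDF is reproducible, draws from the full detected list, and honors boundaries", {
  co <- makeCohort(cohortScenario(nAav = 6, nSarc = 6, seed = 5), seed = 5)
  det <- detectedTaxa(co$table)
  obs <- taxaSet(det[1:9], rank = "family")
  r1 <- nullEcdf(co$table, obs, "standardized_U", nDraws = 150, seed = 99)
  r2 <- nullEcdf(co$table, obs, "standardized_U", nDraws = 150, seed = 99)
  expect_identical(r1@nullDraws, r2@nullDraws)  # bit-for-bit
  expect_identical(r1@percentileRank, r2@percentileRank)
  expect_identical(r1@k, 9L)

  # observed set = all detected taxa: every draw is the same set, so all
  # null statistics equal the observed one -> rank 100 under "<="
  all_ <- taxaSet(det, rank = "family")
  rAll <- nullEcdf(co$table, all_, "standardized_U", nDraws = 30, seed = 1)
  expect_equal(stats::sd(rAll@nullDraws), 0)
  expect_equal(rAll@observed, rAll@nullDraws[1])
  expect_equal(rAll@percentileRank, 100)

  expect_error(nullEcdf(co$table, taxaSet("NotThere", rank = "family"),
                        "standardized_U", nDraws = 10, seed = 1),
               "no taxa")
})

test_that("slope statistic uses AAV samples only and needs BVAS", {
  co <- makeCohort(presetScenarios()$bvas_slope, seed = 21)
  det <- detectedTaxa(co$table)
  obs <- taxaSet(det, rank = "family")
  r <- nullEcdf(co$table, obs, "ols_slope", nDraws = 20, seed = 2)
  # observed equals the direct AAV-only regression of diversity on BVAS
  d <- sampleDiversity(co$table)
  aav <- co$metadata$disease == "AAV"
  beta <- stats::cov(co$metadata$bvas[aav], d[aav]) / stats::var(co$metadata$bvas[aav])
  expect_equal(r@observed, beta, tolerance = 1e-10)

  noBvas <- co$table
  SummarizedExperiment::colData(noBvas) <-
    SummarizedExperiment::colData(noBvas)[, c("disease", "sex")]
  expect_error(nullEcdf(noBvas, obs, "ols_slope", nDraws = 5, seed = 1), "bvas")
})

test_that("degenerate draws are discarded and a too-sparse table errors", {
  # A only in AAV, B only in sarcoidosis, C and D everywhere: any draw of
  # k = 2 that picks {A, B} gives every sample a single-taxon subcommunity
  # (diversity identically 1), a degenerate statistic -> 1/6 of draws
  # discarded, above the 10% cap
  m <- rbind(A = c(5, 7, 0, 0), B = c(0, 0, 6, 8),
             C = c(9, 2, 5, 1), D = c(1, 6, 2, 7))
  colnames(m) <- paste0("S", 1:4)
  md <- data.frame(disease = c("AAV", "AAV", "sarcoidosis", "sarcoidosis"),
                   row.names = colnames(m))
  tb <- otuTable(m, rank = "family", sampleData = md)
  expect_error(
    suppressMessages(nullEcdf(tb, taxaSet(c("C", "D"), rank = "family"),
                              "standardized_U", nDraws = 200, seed = 7)),
    "too sparse")
})

test_that("stratified analysis reduces to the filtered analysis per level", {
  co <- makeCohort(cohortScenario(nAav = 8, nSarc = 8, seed = 9), seed = 9)
  # force a single-level stratum
  md <- as.data.frame(SummarizedExperiment::colData(co$table))
  md$sex <- "female"
  tb <- otuTable(otuCounts(co$table), rank = "family", sampleData = md)
  obs <- taxaSet(detectedTaxa(tb)[1:7], rank = "family")
  st <- stratifiedNullEcdf(tb, obs, "standardized_U", stratum = "sex",
                           nDraws = 100, seed = 40)
  expect_length(st, 1)
  direct <- nullEcdf(tb, obs, "standardized_U", nDraws = 100, seed = 41,
                     stratumFilter = list(sex = "female"))
  expect_identical(st[["sex=female"]]@nullDraws, direct@nullDraws)
  expect_identical(st[["sex=female"]]@percentileRank, direct@percentileRank)
  # unusable level is skipped with a message, not an error
  md$sex <- c(rep("female", 14), "male", "male")
  tb2 <- otuTable(otuCounts(co$table), rank = "family", sampleData = md)
  expect_message(
    st2 <- stratifiedNullEcdf(tb2, obs, "standardized_U", stratum = "sex",
                              nDraws = 50, seed = 1),
    "skipping")
  expect_named(st2, "sex=female")
})

test_that("results export as JSON with an audit trail of draws", {
  co <- makeCohort(cohortScenario(nAav = 5, nSarc = 5, seed = 2), seed = 2)
  obs <- taxaSet(detectedTaxa(co$table)[1:5], rank = "family")
  r <- nullEcdf(co$table, obs, "standardized_U", nDraws = 40, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeNullEcdfResult(r, f)
  rec <- jsonlite::read_json(f)
  expect_equal(rec$percentile_rank, r@percentileRank)
  expect_equal(rec$k, 5)
  draws <- utils::read.delim(paste0(f, ".draws.tsv"))
  expect_equal(draws$null_draw, r@nullDraws, tolerance = 1e-12)
})
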
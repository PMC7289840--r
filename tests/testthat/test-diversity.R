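test_that("Simpson-family indices match closed forms and boundary cases", {
  expect_equal(inverseSimpson(c(10, 10, 10, 10)), 4)
  expect_equal(inverseSimpson(c(7, 0, 0)), 1)
  expect_equal(inverseSimpson(c(1, 2, 3)), 36 / 14)
  expect_equal(simpsonIndex(c(10, 10, 10, 10)), 0.25)
  expect_equal(simpsonIndex(c(1, 0)), 1)
  expect_equal(simpsonIndex(c(1, 2, 3)), 14 / 36)
  expect_equal(inverseSimpson(c(1, 2, 3), gini = TRUE), 1 / (1 - 14 / 36))
  expect_error(inverseSimpson(c(0, 0)), "all-zero")
  expect_error(inverseSimpson(c(5, 0), gini = TRUE), "undefined")
})

test_that("inverse Simpson is scale-invariant and bounded by taxon richness", {
  set.seed(11)
  for (i in 1:25) {
    v <- rpois(sample(3:30, 1), lambda = sample(1:20, 1))
    if (sum(v) == 0) v[1] <- 1
    d <- inverseSimpson(v)
    expect_equal(inverseSimpson(v * sample(c(2, 7, 1000), 1)), d,
                 tolerance = 1e-12)
    s <- sum(v > 0)
    expect_lte(d, s + 1e-12)
    expect_equal(d, oracleInvSimpson(v))
  }
  # equality iff uniform over positive taxa
  expect_equal(inverseSimpson(c(3, 3, 3, 0)), 3)
  expect_lt(inverseSimpson(c(3, 3, 2, 0)), 3)
})

test_that("Morisita-Horn matches hand calculations and its oracle", {
  expect_equal(morisitaHorn(c(1, 1), c(1, 0)), 1 / 3)
  expect_equal(morisitaHorn(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(morisitaHorn(c(3, 1, 4), c(6, 2, 8)), 0)  # identical composition
  expect_equal(morisitaHorn(c(1, 2, 0, 0), c(0, 0, 3, 4)), 1)
  expect_error(morisitaHorn(c(0, 0), c(1, 1)), "zero_total_sample")
  expect_error(morisitaHorn(c(1, 1), c(1, 1, 1)), "unequal length")
  set.seed(12)
  for (i in 1:20) {
    x <- rpois(8, 5) + c(1, rep(0, 7)); y <- rpois(8, 5) + c(1, rep(0, 7))
    d <- morisitaHorn(x, y)
    expect_equal(d, morisitaHorn(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, max(0, min(1, oracleMorisitaHorn(x, y))), tolerance = 1e-12)
  }
})

test_that("Morisita-Horn matrix equals the scalar operation pairwise", {
  co <- makeCohort(cohortScenario(nAav = 4, nSarc = 4, seed = 3), seed = 3)
  tb <- co$table
  D <- morisitaHornMatrix(tb)
  v <- dissValues(D)
  cts <- otuCounts(tb)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(v[i, j], morisitaHorn(cts[, i], cts[, j]), tolerance = 1e-10)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(0, 8))

  # permutation equivariance
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  tbPerm <- otuTable(cts[, perm], rank = "family")
  vPerm <- dissValues(morisitaHornMatrix(tbPerm))
  expect_equal(vPerm, v[perm, perm])

  # zero-total samples excluded with a message; < 2 usable is an error
  m <- tinyCounts()
  sub <- suppressMessages(subsetTaxa(otuTable(m, rank = "family"),
                                     taxaSet("F3", rank = "family"), "restrict"))
  expect_message(morisitaHornMatrix(sub), "excluding zero-total")
  one <- suppressMessages(subsetTaxa(
    otuTable(matrix(c(4, 0, 0, 3, 0, 2), 2,
                    dimnames = list(c("F1", "F2"), c("S1", "S2", "S3"))),
             rank = "family"),
    taxaSet("F1", rank = "family"), "restrict"))
  expect_error(suppressMessages(morisitaHornMatrix(one)), "fewer than 2")
})

test_that("between-taxa Jaccard handles hand cases and degenerate taxa", {
  m <- matrix(c(1, 1, 0,
                0, 1, 1,
                2, 3, 0,
                0, 0, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "Asame", "Empty"), paste0("S", 1:3)))
  m[1, 1] <- 1  # A present in S1,S2; B in S2,S3 -> Jaccard 2/3
  tb <- otuTable(rbind(m[1:3, ], Anchor = c(1, 1, 1)), rank = "family")
  D <- dissValues(jaccardBetweenTaxa(tb))
  expect_equal(D["A", "B"], 2 / 3)
  expect_equal(D["A", "Asame"], 0)   # identical presence patterns
  tb2 <- otuTable(rbind(m[1:2, ], Other = c(0, 0, 5)), rank = "family")
  expect_equal(dissValues(jaccardBetweenTaxa(tb2))["A", "Other"], 1)

  # two all-absent taxa sit at distance 0, flagged via message
  m3 <- rbind(A = c(1, 1, 0), Empty1 = c(0, 0, 0), Empty2 = c(0, 0, 0),
              Anchor = c(1, 1, 1))
  colnames(m3) <- paste0("S", 1:3)
  tb3 <- otuTable(m3, rank = "family")
  expect_message(D3 <- jaccardBetweenTaxa(tb3), "degenerate")
  expect_equal(dissValues(D3)["Empty1", "Empty2"], 0)
})

test_that("dissimilarity matrices survive a TSV round trip", {
  D <- randomDissimilarity(6, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDissimilarity(D, f)
  back <- readDissimilarity(f, metric = "morisita_horn")
  expect_equal(dissValues(back), dissValues(D), tolerance = 1e-9)
})

test_that("sampleDiversity returns NA for flagged zero-total samples", {
  m <- tinyCounts(); m["F1", ] <- c(10, 0, 0)
  m["F2", ] <- c(0, 5, 5); m["F3", ] <- c(0, 1, 2); m["F4", ] <- c(0, 3, 1)
  tb <- otuTable(m, rank = "family")
  sub <- suppressMessages(subsetTaxa(tb, taxaSet("F1", rank = "family"), "restrict"))
  d <- suppressMessages(sampleDiversity(sub))
  expect_equal(unname(d["S1"]), 1)
  expect_true(all(is.na(d[c("S2", "S3")])))
  full <- sampleDiversity(tb)
  expect_equal(unname(full["S1"]), oracleInvSimpson(m[, "S1"]))
})
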
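test_that("Wilson interval matches the closed form and an independent implementation", {
  # prop.test without continuity correction is the Wilson score interval
  for (kn in list(c(98, 100), c(45, 50), c(237, 242), c(10, 400), c(1, 3))) {
    wi <- wilsonInterval(kn[1], kn[2])
    ref <- suppressWarnings(
      stats::prop.test(kn[1], kn[2], correct = FALSE)$conf.int)
    expect_equal(wi@lower, ref[1], tolerance = 1e-9)
    expect_equal(wi@upper, ref[2], tolerance = 1e-9)
    expect_lte(wi@lower, kn[1] / kn[2])
    expect_gte(wi@upper, kn[1] / kn[2])
  }
  expect_equal(wilsonInterval(98, 100)@lower, 0.930, tolerance = 1e-3)
  expect_equal(wilsonInterval(0, 10)@lower, 0)
  expect_equal(wilsonInterval(10, 10)@upper, 1)
  # monotone in k; widens with conf
  lows <- vapply(0:20, function(k) wilsonInterval(k, 20)@lower, numeric(1))
  expect_true(all(diff(lows) > 0))
  w95 <- wilsonInterval(9, 12, 0.95); w99 <- wilsonInterval(9, 12, 0.99)
  expect_lt(w99@lower, w95@lower); expect_gt(w99@upper, w95@upper)
  expect_error(wilsonInterval(5, 4), "k <= n")
  expect_error(wilsonInterval(2, 10, conf = 1.2), "conf")
})

test_that("minimum prevalence for the Wilson lower bound behaves over n", {
  expect_false(minPrevalenceForLowerBound(1)$attainable)
  r250 <- minPrevalenceForLowerBound(250)
  expect_equal(r250$fraction, 0.98)
  expect_identical(r250$k, 245L)
  # the returned k is minimal: k clears the target, k - 1 does not
  for (n in c(150, 242, 400)) {
    r <- minPrevalenceForLowerBound(n)
    expect_gt(wilsonInterval(r$k, n)@lower, 0.95)
    expect_lte(wilsonInterval(r$k - 1, n)@lower, 0.95)
  }
  # decreasing trend in n (coarse-grained: lag 100 absorbs integer granularity)
  fr <- vapply(seq(100, 500, 50), function(n)
    minPrevalenceForLowerBound(n)$fraction, numeric(1))
  expect_true(all(fr[3:9] <= fr[1:7] + 1e-12))
})

test_that("inhabitant selection is strict at the threshold and consistent with the derived rule", {
  prev <- deterministicPrevalence(
    list(hard_palate = c(AllIn = 100, Border = 98, Out = 60)), total = 100)
  inh <- inhabitantTaxa(prev, "hard_palate", threshold = 0.98)
  expect_identical(setLabels(inh), "AllIn")   # 98/100 excluded: strictly over
  inh2 <- inhabitantTaxa(prev, "hard_palate", threshold = 0.98, strict = FALSE)
  expect_setequal(setLabels(inh2), c("AllIn", "Border"))
  expect_error(inhabitantTaxa(prev, "tongue_dorsum"), "unknown subsite")

  # planted recovery: 11 families at 99%, 30 at 60% -> exactly the 11
  cnt <- c(setNames(rep(99, 11), sprintf("In%02d", 1:11)),
           setNames(rep(60, 30), sprintf("Bg%02d", 1:30)))
  prev2 <- deterministicPrevalence(list(hard_palate = cnt), total = 100)
  expect_setequal(setLabels(inhabitantTaxa(prev2, "hard_palate")),
                  sprintf("In%02d", 1:11))

  # at n = 250 the derived minimal prevalence IS 0.98: selections agree
  r <- minPrevalenceForLowerBound(250)
  cnt3 <- setNames(c(250, 248, 246, 245, 244, 200), paste0("T", 1:6))
  prev3 <- deterministicPrevalence(list(hard_palate = cnt3), total = 250)
  expect_identical(
    setLabels(inhabitantTaxa(prev3, "hard_palate", threshold = 0.98)),
    setLabels(inhabitantTaxa(prev3, "hard_palate", threshold = r$fraction)))

  # nested thresholds
  for (t in c(0.6, 0.8, 0.95)) {
    lo <- setLabels(inhabitantTaxa(prev2, "hard_palate", threshold = t))
    hi <- setLabels(inhabitantTaxa(prev2, "hard_palate", threshold = t + 0.04))
    expect_true(all(hi %in% lo))
  }
})

test_that("vagrant selection uses strict union semantics across subsites", {
  prev <- deterministicPrevalence(
    list(saliva = c(A = 4, B = 6, C = 0, D = 5),
         throat = c(A = 4, B = 2, C = 80, D = 5)),
    total = 100)
  vg <- vagrantTaxa(prev, threshold = 0.05)
  expect_setequal(setLabels(vg), c("B", "C"))  # A at 4% everywhere; D at exactly 5%
  expect_true("D" %in% setLabels(vagrantTaxa(prev, threshold = 0.05, strict = FALSE)))
  # pooled alternative: B pools to 8/200 = 4% -> dropped
  expect_setequal(setLabels(vagrantTaxa(prev, threshold = 0.05, pooled = TRUE)), "C")
  # threshold 0 returns everything ever detected; threshold 1 nothing (strict)
  expect_setequal(setLabels(vagrantTaxa(prev, threshold = 0)), c("A", "B", "C", "D"))
  expect_length(vagrantTaxa(prev, threshold = 1), 0)
  expect_error(vagrantTaxa(prev, subsites = "gut"), "unknown subsite")
  expect_error(vagrantTaxa(prev, subsites = character()), "nonempty")
})

test_that("stability curve counts are monotone and flag the stable subsite", {
  cnt <- function(p11, pRest) c(setNames(rep(p11, 11), sprintf("In%02d", 1:11)),
                                setNames(rep(pRest, 20), sprintf("Bg%02d", 1:20)))
  prev <- deterministicPrevalence(
    list(hard_palate = cnt(199, 120),   # 11 taxa at 99.5%
         saliva = c(setNames(c(rep(199, 5), rep(197, 6)), sprintf("In%02d", 1:11)),
                    setNames(rep(120, 20), sprintf("Bg%02d", 1:20)))),
    total = 200)
  sc <- stabilityCurve(prev)
  # counts non-increasing in threshold per subsite
  for (s in c("hard_palate", "saliva")) {
    v <- sc@data$count[sc@data$subsite == s][order(
      sc@data$threshold[sc@data$subsite == s])]
    expect_true(all(diff(v) <= 0))
  }
  expect_identical(sc@stableSubsites, "hard_palate")
  # single-threshold call equals the inhabitant set size
  one <- stabilityCurve(prev, thresholds = c(0.98, 0.99))
  expect_equal(one@data$count[one@data$subsite == "hard_palate" &
                                one@data$threshold == 0.98],
               length(inhabitantTaxa(prev, "hard_palate", 0.98)))
  expect_error(stabilityCurve(prev, thresholds = c(0.99, 0.98)), "increasing")
})

test_that("prevalence tables validate and round-trip as TSV", {
  expect_error(prevalenceTable(data.frame(subsite = "a", taxon = "t",
                                          detected = 5, total = 4)),
               "detected")
  expect_error(prevalenceTable(data.frame(subsite = "a", taxon = "t",
                                          detected = 0, total = 0)),
               "total")
  prev <- deterministicPrevalence(list(saliva = c(A = 10, B = 2)), total = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePrevalenceTable(prev, f)
  back <- readPrevalenceTable(f, rank = "family")
  expect_equal(back@data, prev@data)
  expect_equal(prevalenceOf(back, "saliva"), c(A = 0.2, B = 0.04))
})

test_that("taxa sets round-trip with provenance", {
  ts <- taxaSet(c("Prevotellaceae", "Streptococcaceae"), rank = "family",
                provenance = "inhabitant:hard_palate@>0.98")
  f <- withr::local_tempfile(fileext = ".txt")
  writeTaxaSet(ts, f)
  back <- readTaxaSet(f)
  expect_identical(setLabels(back), setLabels(ts))
  expect_identical(provenance(back), provenance(ts))
  expect_identical(back@rank, "family")
})
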
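test_that("spearman equals brute-force average-rank correlation", {
  expect_equal(spearmanCor(1:5, 1:5), 1)
  expect_equal(spearmanCor(1:5, 5:1), -1)
  # with ties: rank-then-correlate oracle
  x <- c(3, 1, 4, 1, 5); y <- c(2, 7, 1, 8, 2)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  expect_equal(spearmanCor(x, y),
               sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))
  expect_error(spearmanCor(1:4, 1:5), "length")
})

test_that("REL classes use closed upper boundaries", {
  expect_equal(as.character(classifyRel(c(0.3, 0.31, 0.6, 0.61, 0))),
               c("REL<=0.3", "0.3<REL<=0.6", "0.3<REL<=0.6", "REL>0.6",
                 "REL<=0.3"))
  expect_error(classifyRel(1.2), "REL")
})

test_that("re-ranking categories follow the 0.990 / 0.980 cuts", {
  expect_equal(rerankCategory(c(0.990, 0.995, 0.985, 0.980, 0.9, 0.979)),
               c("none", "none", "small", "small", "large", "large"))
})

test_that("publishability and young-sire rules apply inclusive thresholds", {
  stats <- data.frame(
    sire = c("ok", "lowRel", "fewProg", "mat", "young"),
    code = 1:5,
    progenyRecorded = c(25L, 100L, 24L, 40L, 30L),
    daughtersWithRecordedProgeny = c(3L, 0L, 0L, 15L, 1L),
    recordedGrandProgeny = c(5L, 0L, 0L, 25L, 2L),
    maxRelDirect = c(0.5, 0.49, 0.9, 0.7, 0.6),
    maxRelMaternal = c(0.4, 0.1, 0.2, 0.3, 0.29))
  pub <- selectPublishable(stats)
  expect_setequal(pub$direct, c("ok", "mat", "young"))   # 0.5 & 25 inclusive
  expect_setequal(pub$maternal, "mat")                   # 0.3 / 15 / 25 inclusive
  young <- selectYoungSires(stats)
  expect_setequal(young, "young")                        # strict < 0.3
})

test_that("top-k overlap counts and rank shifts match hand enumeration", {
  a <- setNames(10:1, letters[1:10])
  expect_equal(topKOverlap(a, a, 3)$overlap, 3)
  expect_equal(topKOverlap(a, a, 3)$meanShift, 0)
  # adversarial: top-3 of b are the bottom-3 of a
  b <- setNames(1:10, letters[1:10])
  expect_equal(topKOverlap(a, b, 3)$overlap, 0)
  # hand-built 10-sire example: swap ranks 1 and 4, keep others
  b2 <- a; b2[c("a", "d")] <- b2[c("d", "a")]
  tk <- topKOverlap(a, b2, 3)
  expect_equal(tk$overlap, 2)                   # {a,b,c} vs {d,b,c}
  expect_equal(tk$meanShift, 1)                 # shifts 3,0,0
  tk2 <- topKOverlap(a, b2, 100)
  expect_true(tk2$truncated)
  expect_equal(tk2$kUsed, 10)
})

test_that("EBV standard deviations are sample SDs per country and effect", {
  dat <- tinyDataset(seed = 43, nPerGeneration = 30)
  res <- runScenario(dat$phen, dat$ped, dat$params, "REF")
  sds <- ebvSdByGroup(res, 1:5)
  expect_equal(dim(sds), c(2L, 2L))
  expect_equal(sds["C1", "direct"], sd(ebv(res, "direct", "C1")[1:5, 1]))
  # two values a, b -> |a-b|/sqrt(2)
  two <- ebvSdByGroup(res, 1:2)
  expect_equal(two["C1", "direct"],
               unname(abs(diff(ebv(res, "direct", "C1")[1:2, 1]))) / sqrt(2))
  expect_error(ebvSdByGroup(res, 1L), "2")
})

test_that("the comparison report is self-consistent", {
  dat <- tinyDataset(seed = 47, nc = 2, nPerGeneration = 60,
                     recordedGenerations = 3)
  ref <- runScenario(dat$phen, dat$ped, dat$params, "REF", computeRel = TRUE)
  non <- runScenario(dat$phen, dat$ped, dat$params, "NONE")

  # comparing a scenario with itself: rho 1 and category "none" everywhere
  selfRep <- buildComparisonReport(list(REF = ref, SELF = ref), dat$ped,
                                   dat$phen, pairs = list(c("REF", "SELF")),
                                   k = 10)
  expect_equal(selfRep@rankCorrelations$rho,
               rep(1, nrow(selfRep@rankCorrelations)))
  expect_true(all(selfRep@rankCorrelations$category == "none"))
  expect_true(all(selfRep@topk$overlap == selfRep@topk$k))
  expect_true(all(selfRep@topk$meanShift == 0))

  rep_ <- buildComparisonReport(list(REF = ref, NONE = non), dat$ped,
                                dat$phen, k = 10)
  rc <- rep_@rankCorrelations
  expect_true(all(rc$rho >= -1 & rc$rho <= 1))
  # cohort sizes agree with the selector outputs
  stats <- computeSireStats(dat$ped, dat$phen, ref)
  pub <- selectPublishable(stats)
  sz <- rep_@cohortSizes
  expect_equal(sz$n[sz$cohort == "publishable.direct"], length(pub$direct))
  expect_equal(sz$n[sz$cohort == "young"],
               length(selectYoungSires(stats)))
  conn <- findConnections(dat$ped, dat$phen)
  expect_equal(sz$n[sz$cohort == "cb"], length(conn$cb))
  # maternal-publishable sires are a subset of direct-publishable
  expect_true(all(pub$maternal %in% pub$direct))
  expect_true(all(selectYoungSires(stats) %in% pub$direct))
  # the three REL classes partition the animals on every scale
  for (cc in dat$params@countries) {
    cls <- classifyRel(reliability(ref, "maternal", cc)[, 1])
    expect_equal(sum(table(cls)), nAnimals(dat$ped))
  }
  # a missing REL scenario is an error
  expect_error(buildComparisonReport(list(REF = non, NONE = non),
                                     dat$ped, dat$phen), "reliabilities")
})

test_that("per-sire statistics count recorded progeny through the pedigree", {
  ids <- c("S", "D1", "D2", "G1", "G2", "G3", "B1")
  ped <- pedigree(ids,
                  sire = c(NA, "S", "S", "B1", "B1", "B1", NA),
                  dam = c(NA, NA, NA, "D1", "D1", "D2", NA),
                  sex = c("M", "F", "F", "M", "F", "M", "M"))
  rec <- match(c("D1", "G1", "G2", "G3"), ped@id)
  phen <- new("PhenotypeTable", animal = rec, dam = ped@dam[rec],
              country = rep("AA", 4), aww = rep(240, 4),
              factors = data.frame(cg = "x", sex = ped@sex[rec]))
  res <- new("EvaluationResult", scenario = "REF", countries = "AA",
             ebv = matrix(0, 7, 2, dimnames = list(ped@id, NULL)),
             rel = matrix(0.5, 7, 2, dimnames = list(ped@id, NULL)),
             solver = list(), domestic = list())
  stats <- computeSireStats(ped, phen, res)
  sS <- stats[stats$sire == "S", ]
  expect_equal(sS$progenyRecorded, 1L)                  # D1 recorded, D2 not
  expect_equal(sS$daughtersWithRecordedProgeny, 2L)     # D1 (G1,G2), D2 (G3)
  expect_equal(sS$recordedGrandProgeny, 3L)
  sB <- stats[stats$sire == "B1", ]
  expect_equal(sB$progenyRecorded, 3L)
  expect_equal(sB$daughtersWithRecordedProgeny, 0L)     # G2 has no progeny
})
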
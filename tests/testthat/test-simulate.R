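test_that("the generator is reproducible and respects its knobs", {
  cfg <- simConfig(seed = 5, params = tinyParams(2), countries = c("C1", "C2"),
                   proportions = c(.6, .4), nPerGeneration = 40,
                   herdsPerCountry = 2)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$ped@id, d2$ped@id)
  expect_identical(d1$ped@sire, d2$ped@sire)
  expect_identical(d1$phen@aww, d2$phen@aww)
  expect_identical(d1$tbv, d2$tbv)

  # founders-only pedigree: no inbreeding, no records requested
  cfg0 <- simConfig(seed = 5, params = tinyParams(2), countries = c("C1", "C2"),
                    proportions = c(.5, .5), nPerGeneration = 30,
                    generations = 0, recordedGenerations = 0)
  ped0 <- simulatePedigree(cfg0)
  expect_true(all(is.na(ped0@sire)))
  expect_equal(ped0@f, rep(0, nAnimals(ped0)))

  # invalid proportions are rejected
  expect_error(simConfig(proportions = c(.5, .6),
                         countries = c("A", "B"), params = tinyParams(2)),
               "sum to 1")
})

test_that("sire exchange drives common-bull connectedness", {
  base <- function(p, s) simConfig(seed = s, params = tinyParams(2),
                                   countries = c("C1", "C2"),
                                   proportions = c(.5, .5),
                                   nPerGeneration = 60, pAbroad = p,
                                   damsPerSire = 3, herdsPerCountry = 2)
  # no foreign matings: zero common bulls
  d0 <- simulateDataset(base(0, 1))
  expect_equal(length(findConnections(d0$ped, d0$phen)$cb), 0L)

  # foreign sire slots: CB count matches direct enumeration over the pedigree
  d2 <- simulateDataset(base(0.3, 2))
  conn <- findConnections(d2$ped, d2$phen)
  recC <- rep(NA_character_, nAnimals(d2$ped))
  recC[d2$phen@animal] <- d2$phen@country
  manual <- 0L
  for (ss in unique(d2$ped@sire[!is.na(d2$ped@sire)])) {
    kids <- which(!is.na(d2$ped@sire) & d2$ped@sire == ss)
    if (length(unique(na.omit(recC[kids]))) >= 2L) manual <- manual + 1L
  }
  expect_equal(length(conn$cb), manual)
  expect_gt(manual, 0L)

  # connectedness increases with the exchange rate (averaged over seeds)
  cb <- sapply(c(0, 0.25, 0.7), function(p)
    mean(sapply(1:6, function(s) {
      d <- simulateDataset(base(p, s))
      length(findConnections(d$ped, d$phen)$cb)
    })))
  expect_true(all(diff(cb) > 0))
})

test_that("founder breeding values follow N(0, G)", {
  p <- tinyParams(2)
  G <- genCov(p)
  n <- 20000
  ped <- suppressWarnings(pedigree(sprintf("F%05d", 1:n), rep(NA, n), rep(NA, n)))
  tbv <- simulateGeneticEffects(ped, G, seed = 99)
  emp <- cov(tbv)
  expect_lt(max(abs(diag(emp) / diag(G) - 1)), 0.05)
  expect_lt(max(abs(emp - G) / sqrt(diag(G) %o% diag(G))), 0.05)
  expect_error(simulateGeneticEffects(ped, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("offspring breeding values center on the parent average", {
  p <- tinyParams(1)
  G <- genCov(p)
  n <- 10000
  ids <- c("S", "D", sprintf("K%05d", 1:n))
  ped <- pedigree(ids, c(NA, NA, rep("S", n)), c(NA, NA, rep("D", n)),
                  sex = c("M", "F", rep("F", n)))
  tbv <- simulateGeneticEffects(ped, G, seed = 7)
  pa <- (tbv["S", ] + tbv["D", ]) / 2
  sibMean <- colMeans(tbv[-(1:2), ])
  expect_lt(max(abs(sibMean - pa)), 4 * sqrt(max(diag(G)) / 2 / n) * 3)
  # Mendelian sampling variance is half the genetic variance here
  expect_equal(unname(apply(tbv[-(1:2), ], 2, var)), unname(0.5 * diag(G)),
               tolerance = 0.1)

  # diagonal G gives uncorrelated traits
  Gd <- diag(diag(G))
  tbvD <- simulateGeneticEffects(ped, Gd, seed = 8)
  offD <- cor(tbvD[-(1:2), ])
  expect_lt(max(abs(offD[upper.tri(offD)])), 0.05)
})

test_that("phenotypes decompose as the generative model dictates", {
  # all variance into the residual: sample variance tracks sigma2_e
  p <- tinyParams(1)
  p@sd[] <- 1e-3; p@peVar[] <- 1e-6
  cfg <- simConfig(seed = 11, params = p, countries = "C1", proportions = 1,
                   nPerGeneration = 3000, generations = 1,
                   recordedGenerations = 1, herdsPerCountry = 1,
                   cgSd = 0, sexEffect = 0, progenyPerDam = 3)
  dat <- simulateDataset(cfg)
  expect_lt(abs(var(dat$phen@aww) - 600), 0.1 * 600)

  # full-sib phenotypic covariance ~ 0.5 sigma2_d with negligible
  # maternal and PE variance
  p2 <- tinyParams(1)
  p2@sd[2] <- 1e-3; p2@peVar[] <- 1e-6
  cfg2 <- simConfig(seed = 12, params = p2, countries = "C1", proportions = 1,
                    nPerGeneration = 6000, generations = 1,
                    recordedGenerations = 1, herdsPerCountry = 1,
                    cgSd = 0, sexEffect = 0, progenyPerDam = 2, damsPerSire = 1)
  dat2 <- simulateDataset(cfg2)
  fam <- split(seq_along(dat2$phen@animal), dat2$phen@dam)
  pairs <- do.call(rbind, lapply(fam[lengths(fam) == 2], function(i)
    dat2$phen@aww[i]))
  sigD <- unname(p2@sd[1]^2)
  expect_lt(abs(cov(pairs[, 1], pairs[, 2]) - 0.5 * sigD), 0.3 * sigD)

  # a country without maternal PE draws no PE effects
  p3 <- tinyParams(2); p3@peVar["C2"] <- 0
  cfg3 <- simConfig(seed = 13, params = p3, countries = c("C1", "C2"),
                    proportions = c(.5, .5), nPerGeneration = 40)
  expect_silent(simulateDataset(cfg3))
})

test_that("datasets round-trip through disk and are byte-stable", {
  dat <- tinyDataset(seed = 17, nPerGeneration = 30)
  d1 <- withr::local_tempdir()
  writeDataset(dat, d1)
  expect_setequal(list.files(d1), c("pedigree.tsv", "phenotypes.tsv",
                                    "params.yaml", "tbv.tsv"))
  back <- readDataset(d1)
  expect_identical(back$ped@id, dat$ped@id)
  expect_identical(back$ped@sire, dat$ped@sire)
  expect_equal(back$phen@aww, dat$phen@aww)
  expect_equal(back$phen@factors, dat$phen@factors, ignore_attr = TRUE)
  expect_equal(back$params@phi, dat$params@phi)
  expect_equal(unname(back$tbv), unname(dat$tbv))

  # identical seed: byte-identical files
  d2 <- withr::local_tempdir()
  writeDataset(simulateDataset(dat$cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # the evaluation inputs remain usable without the TBV file
  file.remove(file.path(d1, "tbv.tsv"))
  noTbv <- readDataset(d1)
  expect_null(noTbv$tbv)
  expect_s4_class(runScenario(noTbv$phen, noTbv$ped, noTbv$params, "REF"),
                  "EvaluationResult")
})

test_that("default conditions mirror the reference data skew", {
  cfg <- simConfig(seed = 1)
  expect_equal(cfg@countries[6], "FRA")
  expect_equal(cfg@proportions[6], 0.871, tolerance = 1e-6)
  expect_equal(sum(cfg@proportions), 1)
  expect_equal(cfg@nPerGeneration, 2500L)   # ~5,000 recorded by default
  expect_equal(cfg@recordedGenerations, 2L)
})
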
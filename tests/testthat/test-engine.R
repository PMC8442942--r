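test_that("a single mean-only record yields a well-posed degenerate system", {
  p <- tinyParams(1)
  ped <- pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
  phen <- new("PhenotypeTable", animal = 3L, dam = match("D", ped@id),
              country = "C1", aww = 260,
              factors = data.frame(mu = "1"))
  spec <- modelSpec("C1", fixed = "mu", fitPE = TRUE)
  mme <- assembleMME(phen, ped, p, spec)
  # 1 mean + 1 PE level + 2 traits x 3 animals
  expect_equal(length(mme@rhs), 1L + 1L + 2L * 3L)
  sol <- solvePCG(mme, tol = 1e-10)
  expect_equal(sol$solution[1], 260)             # mean absorbs the record
  expect_equal(max(abs(sol$solution[-1])), 0, tolerance = 1e-8)

  # right-hand side of zeros: zero solution without iterating
  mme@rhs[] <- 0
  z <- solvePCG(mme)
  expect_identical(z$solution, numeric(length(mme@rhs)))
  expect_identical(z$iterations, 0L)
})

test_that("sparse assembly matches a first-principles dense reconstruction", {
  dat <- tinyDataset(seed = 3, nPerGeneration = 10, generations = 2,
                     recordedGenerations = 2)
  expect_lte(nAnimals(dat$ped), 40)
  mme <- assembleMME(dat$phen, dat$ped, dat$params)
  oracle <- denseMMEOracle(dat$phen, dat$ped, dat$params)
  expect_equal(as.matrix(mmeMaterialize(mme)), oracle$C,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mme@rhs, oracle$rhs, tolerance = 1e-10)
  # operator form agrees with the materialized matrix
  set.seed(1)
  v <- rnorm(length(mme@rhs))
  expect_equal(mmeMatvec(mme, v), as.numeric(mmeMaterialize(mme) %*% v),
               tolerance = 1e-10)
})

test_that("PCG solutions match a dense solve and satisfy the normal equations", {
  dat <- tinyDataset(seed = 5, nPerGeneration = 60)
  mme <- assembleMME(dat$phen, dat$ped, dat$params)
  expect_lte(length(mme@rhs), 2000)
  xd <- solve(as.matrix(mmeMaterialize(mme)), mme@rhs)
  sol <- solvePCG(mme, tol = 1e-9)
  expect_lt(max(abs(sol$solution - xd)), 1e-6)
  expect_lt(sol$relResidual, 1e-6)
  expect_error(solvePCG(mme, tol = 1e-12, maxIter = 2L), "PCG")
})

test_that("adding a constant to one country's records shifts only its fixed effects", {
  dat <- tinyDataset(seed = 7, nPerGeneration = 40)
  r1 <- runScenario(dat$phen, dat$ped, dat$params, "REF", tol = 1e-9)
  shifted <- dat$phen
  shifted@aww <- shifted@aww + ifelse(shifted@country == "C1", 50, 0)
  r2 <- runScenario(shifted, dat$ped, dat$params, "REF", tol = 1e-9)
  expect_lt(max(abs(r1@ebv - r2@ebv)), 1e-6)
})

test_that("NAT decouples into independent single-country evaluations", {
  dat <- tinyDataset(seed = 11, nc = 3, nPerGeneration = 45)
  nat <- runScenario(dat$phen, dat$ped, dat$params, "NAT", tol = 1e-9)
  for (cc in dat$params@countries) {
    pc <- subsetCountries(dat$params, cc)
    ph <- phenSubset(dat$phen, dat$phen@country == cc)
    single <- runScenario(ph, dat$ped, pc, "REF", tol = 1e-9)
    expect_lt(max(abs(ebv(nat, "direct", cc) - ebv(single, "direct", cc))), 1e-3)
    expect_lt(max(abs(ebv(nat, "maternal", cc) - ebv(single, "maternal", cc))), 1e-3)
  }
  # NAT carries the domestic sets
  expect_named(nat@domestic, dat$params@countries)
})

test_that("NONE equals REF when the direct-maternal block is already zero", {
  p <- tinyParams(2, rdm = 0)
  p@phi[1:2, 3:4] <- 0; p@phi[3:4, 1:2] <- 0
  cfg <- simConfig(seed = 13, params = p, countries = p@countries,
                   proportions = c(.5, .5), nPerGeneration = 40,
                   herdsPerCountry = 2)
  dat <- simulateDataset(cfg)
  rRef <- runScenario(dat$phen, dat$ped, dat$params, "REF", tol = 1e-9)
  rNone <- runScenario(dat$phen, dat$ped, dat$params, "NONE", tol = 1e-9)
  expect_equal(rRef@ebv, rNone@ebv, tolerance = 1e-10)
})

test_that("records with unknown dams drop maternal and PE terms", {
  p <- tinyParams(1)
  ped <- pedigree(c("S", "D", "X", "Y"), c(NA, NA, "S", "S"),
                  c(NA, NA, "D", NA), sex = c("M", "F", "F", "F"))
  phen <- new("PhenotypeTable", animal = c(3L, 4L), dam = ped@dam[3:4],
              country = c("C1", "C1"), aww = c(250, 270),
              factors = data.frame(mu = c("1", "1")))
  spec <- modelSpec("C1", fixed = "mu", fitPE = TRUE)
  mme <- assembleMME(phen, ped, p, spec)
  expect_equal(sum(mme@eqInfo$type == "pe"), 1L)   # only the known dam
  sol <- solvePCG(mme, tol = 1e-9)
  expect_true(all(is.finite(sol$solution)))
})

test_that("countries without maternal PE are representable", {
  p <- tinyParams(2)
  p@peVar["C2"] <- 0                                # DEU-style country
  cfg <- simConfig(seed = 17, params = p, countries = p@countries,
                   proportions = c(.5, .5), nPerGeneration = 30,
                   herdsPerCountry = 2)
  dat <- simulateDataset(cfg)
  mme <- assembleMME(dat$phen, dat$ped, dat$params)
  expect_equal(unique(mme@eqInfo$country[mme@eqInfo$type == "pe"]), "C1")
})

test_that("random environmental effects enter as IID blocks", {
  p <- tinyParams(1)
  p@randomEnvVar[["C1"]] <- c(hy = 30)
  ped <- randPed(30, seed = 3, pUnknown = 0.2)
  rec <- which(!is.na(ped@dam))
  set.seed(1)
  phen <- new("PhenotypeTable", animal = rec, dam = ped@dam[rec],
              country = rep("C1", length(rec)),
              aww = rnorm(length(rec), 250, 20),
              factors = data.frame(mu = "1",
                                   hy = sample(c("h1", "h2", "h3"),
                                               length(rec), TRUE)))
  spec <- modelSpec("C1", fixed = "mu", randomEnv = list(C1 = "hy"),
                    fitPE = TRUE)
  mme <- assembleMME(phen, ped, p, spec)
  expect_equal(sum(mme@eqInfo$type == "env"), 3L)
  oracle <- denseMMEOracle(phen, ped, p, spec)
  expect_equal(as.matrix(mmeMaterialize(mme)), oracle$C, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exact reliabilities come from the inverse coefficient matrix", {
  dat <- tinyDataset(seed = 19, nPerGeneration = 40)
  mme <- assembleMME(dat$phen, dat$ped, dat$params)
  rel <- computeReliability(mme)
  expect_true(all(rel >= 0 & rel < 1))
  # oracle: plain dense inversion
  Ci <- solve(as.matrix(mmeMaterialize(mme)))
  pev <- diag(Ci)[(mme@nNonGen + 1):length(mme@rhs)]
  relOracle <- 1 - t(matrix(pev, nrow = mme@nTraits)) /
    rep(1, mme@nAnimals) %o% unname(mme@genVar)
  relOracle[relOracle < 0] <- 0
  expect_equal(unname(rel), unname(relOracle), tolerance = 1e-8)

  # an unconnected, unrecorded animal has REL 0
  ids <- c(animalIds(dat$ped), "LONER")
  ped2 <- pedigree(ids, c(ifelse(is.na(dat$ped@sire), NA,
                                 dat$ped@id[dat$ped@sire]), NA),
                   c(ifelse(is.na(dat$ped@dam), NA,
                            dat$ped@id[dat$ped@dam]), NA),
                   sex = c(dat$ped@sex, NA))
  phen2 <- new("PhenotypeTable",
               animal = match(dat$ped@id[dat$phen@animal], ped2@id),
               dam = match(dat$ped@id[dat$phen@dam], ped2@id),
               country = dat$phen@country, aww = dat$phen@aww,
               factors = dat$phen@factors)
  mme2 <- assembleMME(phen2, ped2, dat$params)
  rel2 <- computeReliability(mme2)
  expect_equal(unname(rel2["LONER", ]), rep(0, 4))

  expect_error(computeReliability(mme, maxUnknowns = 10L), "guard")
  expect_error(mmeMaterialize(mme, maxUnknowns = 10L), "guard")
})

test_that("reliabilities vanish as the residual variance explodes", {
  # reliabilities do not depend on the observations, so one dataset serves
  # all three residual-variance settings
  dat <- tinyDataset(seed = 23, nc = 1, nPerGeneration = 30)
  dom <- domesticSet(dat$ped, dat$phen, "C1")
  rels <- sapply(c(1, 10, 100), function(mult) {
    p <- dat$params
    p@residualVar[] <- p@residualVar * mult
    mean(computeReliability(assembleMME(dat$phen, dat$ped, p),
                            adjustInbreeding = TRUE)[dom, 1])
  })
  expect_true(all(diff(rels) < 0))
})

test_that("estimated and true breeding values calibrate at desk scale", {
  # regression of TBV on EBV near 1 and cor^2 near mean REL, averaged over
  # seeds (single desk-scale runs are noisy)
  slopes <- numeric(0); gaps <- numeric(0)
  for (s in 1:3) {
    dat <- tinyDataset(seed = 28 + s, nc = 2, nPerGeneration = 200,
                       recordedGenerations = 3)
    res <- runScenario(dat$phen, dat$ped, dat$params, "REF")
    relAdj <- computeReliability(assembleMME(dat$phen, dat$ped, dat$params),
                                 adjustInbreeding = TRUE)
    for (cc in dat$params@countries) {
      sel <- dat$phen@animal[dat$phen@country == cc]
      est <- ebv(res, "direct", cc)[sel, 1]
      tru <- dat$tbv[sel, paste0("direct.", cc)]
      slopes <- c(slopes,
                  sum((est - mean(est)) * (tru - mean(tru))) /
                    sum((est - mean(est))^2))
      gaps <- c(gaps,
                cor(est, tru)^2 - mean(relAdj[sel, paste0("direct.", cc)]))
    }
  }
  expect_gt(mean(slopes), 0.85); expect_lt(mean(slopes), 1.15)
  # cor^2 pools animals of unequal REL, so it sits slightly above the mean
  # REL at desk scale; a 0.1 band still catches wiring errors
  expect_lt(abs(mean(gaps)), 0.1)
})

test_that("a non-PD mask without bending is a clear error", {
  p <- defaultParams()
  dat <- tinyDataset(seed = 31, nPerGeneration = 20)
  expect_error(
    runScenario(dat$phen, dat$ped,
                geneticParameters(dat$params@countries, p@phi[c(1:2, 9:10), c(1:2, 9:10)],
                                  dat$params@sd, dat$params@residualVar,
                                  dat$params@peVar),
                "CUR", bend = FALSE),
    NA)  # a PD subset must not error even with bending disabled
  gSing <- tinyParams(2, rBetween = 1)                 # perfectly correlated
  expect_error(assembleMME(dat$phen, dat$ped, gSing), "bend")
})
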
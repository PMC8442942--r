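# shared fixtures, built in code

# random valid pedigree with consistent sexes; parents drawn from earlier animals
randPed <- function(n, seed = 1, pUnknown = 0.3) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("R%03d", seq_len(n))
  for (i in 3:n) {
    prevM <- which(sex[seq_len(i - 1)] == "M")
    prevF <- which(sex[seq_len(i - 1)] == "F")
    if (length(prevM) && stats::runif(1) > pUnknown)
      sire[i] <- ids[prevM[sample.int(length(prevM), 1)]]
    if (length(prevF) && stats::runif(1) > pUnknown)
      dam[i] <- ids[prevF[sample.int(length(prevF), 1)]]
  }
  pedigree(ids, sire, dam, sex = sex)
}

# small two/three-country parameter set with moderate correlations;
# positive definite for nc <= 3 at the defaults
tinyParams <- function(nc = 2, rdm = -0.25, rBetween = 0.6) {
  cn <- paste0("C", seq_len(nc))
  Tt <- 2 * nc
  phi <- diag(Tt)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i != j) {
      phi[i, j] <- rBetween                  # direct-direct
      phi[nc + i, nc + j] <- rBetween        # maternal-maternal
    }
    phi[i, nc + j] <- phi[nc + j, i] <- if (i == j) rdm else 0.05
  }
  phi <- (phi + t(phi)) / 2; diag(phi) <- 1
  geneticParameters(cn, phi, sd = rep(c(15, 8), each = nc),
                    residualVar = rep(600, nc), peVar = rep(40, nc))
}

# small simulated dataset (defaults: 2 countries, ~200 animals)
tinyDataset <- function(seed = 1, nc = 2, nPerGeneration = 80, ...) {
  p <- tinyParams(nc)
  cfg <- simConfig(seed = seed, params = p, countries = p@countries,
                   proportions = rep(1 / nc, nc),
                   nPerGeneration = nPerGeneration, herdsPerCountry = 2, ...)
  simulateDataset(cfg)
}

# subset a PhenotypeTable by a logical/integer record index
phenSubset <- function(phen, keep) {
  new("PhenotypeTable", animal = phen@animal[keep], dam = phen@dam[keep],
      country = phen@country[keep], aww = phen@aww[keep],
      factors = phen@factors[keep, , drop = FALSE])
}

# first-principles dense MME: same equation ordering as the assembly's
# eqInfo, but entries accumulated record by record with explicit loops and
# the genetic precision from dense inverses of tabular A and G
denseMMEOracle <- function(phen, ped, params, spec = defaultModelSpec(params)) {
  mme <- assembleMME(phen, ped, params, spec)   # ordering reference only
  cn <- params@countries
  nc <- length(cn)
  Tt <- 2 * nc
  N <- nAnimals(ped)
  nNG <- mme@nNonGen
  n <- nNG + N * Tt
  eq <- mme@eqInfo
  C <- matrix(0, n, n)
  rhs <- numeric(n)
  eqCol <- function(country, type, term, level) {
    hit <- which(eq$country == country & eq$type == type &
                 eq$term == term & eq$level == level)
    stopifnot(length(hit) <= 1)
    hit
  }
  for (r in seq_along(phen@animal)) {
    cc <- phen@country[r]
    ci <- match(cc, cn)
    cols <- integer(0)
    for (ff in spec@fixed[[cc]])
      cols <- c(cols, eqCol(cc, "fixed", ff, as.character(phen@factors[[ff]][r])))
    for (rf in spec@randomEnv[[cc]])
      cols <- c(cols, eqCol(cc, "env", rf, as.character(phen@factors[[rf]][r])))
    if (spec@fitPE[cc] && !is.na(phen@dam[r]))
      cols <- c(cols, eqCol(cc, "pe", "dam", ped@id[phen@dam[r]]))
    cols <- c(cols, nNG + (phen@animal[r] - 1) * Tt + ci)
    if (!is.na(phen@dam[r]))
      cols <- c(cols, nNG + (phen@dam[r] - 1) * Tt + nc + ci)
    wr <- 1 / params@residualVar[ci]
    for (a in cols) for (b in cols) C[a, b] <- C[a, b] + wr
    rhs[cols] <- rhs[cols] + wr * phen@aww[r]
  }
  for (k in seq_len(nNG))
    if (eq$type[k] == "env") C[k, k] <- C[k, k] +
      1 / params@randomEnvVar[[eq$country[k]]][eq$term[k]]
    else if (eq$type[k] == "pe") C[k, k] <- C[k, k] +
      1 / params@peVar[eq$country[k]]
  gi <- (nNG + 1):n
  C[gi, gi] <- C[gi, gi] +
    kronecker(solve(tabularA(ped)), solve(genCov(params)))
  list(C = C, rhs = rhs)
}
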
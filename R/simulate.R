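#' Construct a simulation configuration
#'
#' Defaults are the package's reference study conditions: eight country
#' populations in the proportions of the Limousin weaning-weight exchange
#' (one country holding 87\% of the data), the packaged genetic parameters,
#' three discrete offspring generations of 2,500 animals after a founder
#' generation, the last two generations recorded (about 5,000 records), 3
#' progeny per dam, 10 dams per sire and a 0.2 probability that a sire slot
#' is filled from abroad.
#'
#' @param seed integer RNG seed.
#' @param params a [GeneticParameters-class] (default [defaultParams()]).
#' @param countries,proportions country labels and relative population
#'   sizes (defaults from \code{params} and the reference data skew).
#' @param nPerGeneration offspring born per generation (default 2500).
#' @param generations offspring generations (default 3).
#' @param recordedGenerations how many last generations carry records
#'   (default 2).
#' @param herdsPerCountry herds per country (default 5).
#' @param progenyPerDam,damsPerSire family-size knobs (defaults 3, 10).
#' @param pAbroad probability a sire slot is foreign (default 0.2).
#' @param sexEffect fixed male effect (kg, default 15).
#' @param cgSd SD of contemporary-group effects (kg, default 10).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, params = defaultParams(),
                      countries = params@countries,
                      proportions = NULL,
                      nPerGeneration = 2500L, generations = 3L,
                      recordedGenerations = 2L, herdsPerCountry = 5L,
                      progenyPerDam = 3L, damsPerSire = 10L,
                      pAbroad = 0.2, sexEffect = 15, cgSd = 10) {
  if (is.null(proportions)) {
    ref <- c(CZE = 0.003, DFS = 0.029, ESP = 0.011, GBR = 0.041,
             IRL = 0.007, FRA = 0.871, DEU = 0.028, CHE = 0.010)
    proportions <- if (all(countries %in% names(ref))) unname(ref[countries])
      else rep(1 / length(countries), length(countries))
    proportions <- proportions / sum(proportions)
  }
  new("SimConfig", seed = as.integer(seed), countries = countries,
      proportions = proportions, nPerGeneration = as.integer(nPerGeneration),
      generations = as.integer(generations),
      recordedGenerations = as.integer(recordedGenerations),
      herdsPerCountry = as.integer(herdsPerCountry),
      progenyPerDam = as.integer(progenyPerDam),
      damsPerSire = as.integer(damsPerSire), pAbroad = pAbroad,
      sexEffect = sexEffect, cgSd = cgSd, params = params)
}

# sample that never deparses a length-1 vector into 1:x
.resample <- function(x, size, replace = FALSE)
  x[sample.int(length(x), size, replace = replace)]

# allocate nTotal animals over countries by proportion, each country >= minPer
.allocCountries <- function(nTotal, prop, minPer = 4L) {
  n <- pmax(minPer, round(nTotal * prop))
  # absorb the rounding surplus/deficit into the largest country
  big <- which.max(prop)
  n[big] <- n[big] + (nTotal - sum(n))
  if (n[big] < minPer) stop("population too small for the requested countries")
  n
}

#' Simulate a multi-country discrete-generation pedigree
#'
#' Founders are allocated to countries and herds; each later generation is
#' produced by mating within-country dams (progenyPerDam offspring each) to
#' active sires of the previous generation. Each mating uses, with
#' probability \code{pAbroad}, a foreign active sire instead of a domestic
#' one; exported bulls keep their domestic matings, which creates the
#' common-bull connectedness of international evaluations. Offspring
#' inherit their dam's country and herd.
#'
#' @param cfg a [SimConfig-class]. The RNG seed is taken from the config.
#' @return a [Pedigree-class] with countries, sexes, birth years (the
#'   generation number) and inbreeding filled in; herd assignments are
#'   attached as attribute \code{"herd"} and generation as \code{"gen"}.
#' @export
simulatePedigree <- function(cfg) {
  set.seed(cfg@seed)
  cn <- cfg@countries
  nFound <- .allocCountries(cfg@nPerGeneration, cfg@proportions)
  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); country <- character(0); herd <- integer(0)
  gen <- integer(0)
  cnt <- 0L
  newIds <- function(k) sprintf("A%06d", cnt + seq_len(k))
  for (ci in seq_along(cn)) {
    k <- nFound[ci]
    ids <- newIds(k); cnt <- cnt + k
    id <- c(id, ids); sire <- c(sire, rep(NA, k)); dam <- c(dam, rep(NA, k))
    sex <- c(sex, sample(c("M", "F"), k, replace = TRUE))
    country <- c(country, rep(cn[ci], k))
    herd <- c(herd, sample.int(cfg@herdsPerCountry, k, replace = TRUE))
    gen <- c(gen, rep(0L, k))
  }
  # ensure every country has at least one male and one female founder
  for (ci in seq_along(cn)) {
    idx <- which(country == cn[ci] & gen == 0L)
    if (all(sex[idx] == "M")) sex[idx[1]] <- "F"
    if (all(sex[idx] == "F")) sex[idx[1]] <- "M"
  }
  for (g in seq_len(cfg@generations)) {
    prev <- which(gen == g - 1L)
    nOff <- .allocCountries(cfg@nPerGeneration, cfg@proportions)
    # pass 1: domestic breeding sires per country (the "active" bulls)
    domPool <- vector("list", length(cn))
    damsC <- vector("list", length(cn))
    for (ci in seq_along(cn)) {
      females <- prev[sex[prev] == "F" & country[prev] == cn[ci]]
      males <- prev[sex[prev] == "M" & country[prev] == cn[ci]]
      if (!length(females)) stop("no dams available in ", cn[ci])
      if (!length(males)) stop("no sires available in ", cn[ci])
      nDams <- min(length(females), max(1L, ceiling(nOff[ci] / cfg@progenyPerDam)))
      damsC[[ci]] <- .resample(females, nDams)
      nSires <- max(1L, ceiling(nDams / cfg@damsPerSire))
      domPool[[ci]] <- .resample(males, min(nSires, length(males)),
                                 replace = nSires > length(males))
    }
    # pass 2: matings; each dam may be served by a foreign active sire,
    # drawn from the other countries' domestic assignments so that exported
    # bulls keep their home usage (the common-bull structure)
    for (ci in seq_along(cn)) {
      dams <- damsC[[ci]]
      nDams <- length(dams)
      pool <- domPool[[ci]]
      damSire <- pool[1L + (seq_len(nDams) - 1L) %% length(pool)]
      foreignSires <- unique(unlist(domPool[-ci]))
      abroad <- which(stats::runif(nDams) < cfg@pAbroad)
      if (length(abroad) && length(foreignSires))
        damSire[abroad] <- .resample(foreignSires, length(abroad),
                                     replace = TRUE)
      nk <- rep(cfg@progenyPerDam, nDams)
      surplus <- sum(nk) - nOff[ci]
      while (surplus > 0L) {      # trim litter sizes to the target count
        j <- which(nk > 1L)[1L]
        if (is.na(j)) break
        cut <- min(surplus, nk[j] - 1L)
        nk[j] <- nk[j] - cut; surplus <- surplus - cut
      }
      k <- sum(nk)
      ids <- newIds(k); cnt <- cnt + k
      id <- c(id, ids)
      sire <- c(sire, id[rep(damSire, nk)])
      dam <- c(dam, id[rep(dams, nk)])
      sx <- sample(c("M", "F"), k, replace = TRUE)
      if (k >= 2L) {              # keep both sexes present in every cohort
        if (all(sx == "M")) sx[1] <- "F"
        if (all(sx == "F")) sx[1] <- "M"
      }
      sex <- c(sex, sx)
      country <- c(country, rep(cn[ci], k))
      herd <- c(herd, rep(herd[dams], nk))
      gen <- c(gen, rep(g, k))
    }
  }
  ped <- pedigree(id, sire, dam, birthYear = gen, sex = sex, country = country)
  ord <- match(ped@id, id)
  attr(ped, "herd") <- herd[ord]
  attr(ped, "gen") <- gen[ord]
  ped
}

#' Simulate true breeding values under G x A
#'
#' Founders (and unknown-parent contributions) are drawn from N(0, G);
#' non-founders are the parent average plus a Mendelian-sampling deviation
#' with covariance \eqn{G \cdot (0.5 - 0.25 (F_s + F_d))}, an unknown
#' parent contributing like a founder.
#'
#' @param ped a [Pedigree-class] with inbreeding computed.
#' @param G positive-definite genetic covariance matrix (kg^2).
#' @param seed optional seed; when NULL the current RNG state is used.
#' @return matrix animals x traits of true breeding values (kg).
#' @export
simulateGeneticEffects <- function(ped, G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- tryCatch(chol(G), error = function(e)
    stop("G must be positive definite"))
  L <- t(ch)
  Tt <- nrow(G)
  n <- length(ped@id)
  Z <- L %*% matrix(stats::rnorm(Tt * n), Tt, n)
  tbv <- matrix(0, Tt, n)
  s <- ped@sire; d <- ped@dam
  F <- ped@f
  for (i in seq_len(n)) {
    fs <- if (is.na(s[i])) -1 else F[s[i]]
    fd <- if (is.na(d[i])) -1 else F[d[i]]
    ms <- 0.5 - 0.25 * (fs + fd)
    pa <- 0
    if (!is.na(s[i])) pa <- pa + 0.5 * tbv[, s[i]]
    if (!is.na(d[i])) pa <- pa + 0.5 * tbv[, d[i]]
    tbv[, i] <- pa + sqrt(ms) * Z[, i]
  }
  out <- t(tbv)
  dimnames(out) <- list(ped@id,
                        if (!is.null(dimnames(G)[[1]])) rownames(G) else NULL)
  out
}

#' Simulate weaning-weight phenotypes from the generative model
#'
#' For each recorded animal in country i:
#' AWW = contemporary-group effect + sex effect + optional random
#' environmental effects + own direct TBV on scale i + dam's maternal TBV
#' on scale i + dam's permanent-environment effect + residual. Only animals
#' of the last \code{recordedGenerations} generations are recorded; all of
#' them have known dams by construction.
#'
#' @param ped pedigree from [simulatePedigree()] (carries herd/gen
#'   attributes).
#' @param tbv matrix from [simulateGeneticEffects()].
#' @param cfg the [SimConfig-class] used to build the pedigree.
#' @return a [PhenotypeTable-class] with factor columns \code{cg} and
#'   \code{sex}.
#' @export
simulatePhenotypes <- function(ped, tbv, cfg) {
  cn <- cfg@countries
  nc <- length(cn)
  gen <- attr(ped, "gen"); herd <- attr(ped, "herd")
  if (is.null(gen) || is.null(herd))
    stop("pedigree must come from simulatePedigree()")
  recGen <- (cfg@generations - cfg@recordedGenerations + 1L):cfg@generations
  rec <- which(gen %in% recGen & !is.na(ped@dam))
  ci <- match(ped@country[rec], cn)
  cg <- paste(ped@country[rec], herd[rec], gen[rec], sep = "-")
  cgLev <- unique(cg)
  cgEff <- stats::setNames(stats::rnorm(length(cgLev), 0, cfg@cgSd), cgLev)
  params <- cfg@params
  dams <- ped@dam[rec]
  peKey <- paste(dams, ci, sep = "-")
  peLev <- unique(peKey)
  peVarRec <- params@peVar[ci]
  peEff <- stats::setNames(stats::rnorm(length(peLev)), peLev)
  peDraw <- peEff[peKey] * sqrt(peVarRec)        # per-country PE variance
  peDraw[peVarRec <= 0] <- 0
  aww <- 250 +                                    # base weight level (kg)
    cgEff[cg] +
    ifelse(ped@sex[rec] == "M", cfg@sexEffect, 0) +
    tbv[cbind(rec, ci)] +
    tbv[cbind(dams, nc + ci)] +
    peDraw +
    stats::rnorm(length(rec), 0, sqrt(params@residualVar[ci]))
  new("PhenotypeTable", animal = rec, dam = dams,
      country = ped@country[rec], aww = as.numeric(aww),
      factors = data.frame(cg = cg, sex = ped@sex[rec],
                           stringsAsFactors = FALSE))
}

#' Simulate a complete dataset
#'
#' Pedigree, true breeding values and phenotypes in one call, fully
#' reproducible from the config seed. When the configured correlation
#' matrix is not positive definite at the 1e-3 threshold (as happens with
#' correlation tables printed to 2 decimals), the generative covariance is
#' built from its bent version; the returned \code{params} keep the
#' original matrix, which the evaluation side masks and bends itself.
#'
#' @param cfg a [SimConfig-class].
#' @return list with \code{ped}, \code{tbv}, \code{phen}, \code{params},
#'   \code{cfg}.
#' @export
simulateDataset <- function(cfg) {
  ped <- simulatePedigree(cfg)          # seeds the RNG from cfg@seed
  phi <- cfg@params@phi
  if (!checkPSD(phi, 1e-3)$psd) phi <- bendUnweighted(phi, 1e-3)
  G <- buildG(cfg@params@sd, phi)
  tbv <- simulateGeneticEffects(ped, G)
  phen <- simulatePhenotypes(ped, tbv, cfg)
  list(ped = ped, tbv = tbv, phen = phen, params = cfg@params, cfg = cfg)
}
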
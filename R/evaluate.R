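#' Run one evaluation scenario
#'
#' Applies the scenario mask to the correlation matrix, bends it if it is
#' not positive definite at the bending threshold, builds \eqn{G = S\Phi S},
#' assembles the mixed-model equations and solves them by PCG. EBVs are
#' produced for every pedigree animal on every country scale for both the
#' direct and the maternal effect. For scenario NAT the per-country domestic
#' sets are attached to the result.
#'
#' @param phen a [PhenotypeTable-class].
#' @param ped a [Pedigree-class].
#' @param params a [GeneticParameters-class].
#' @param scenario one of REF, CUR, NONE, NAT.
#' @param spec a [ModelSpec-class]; default [defaultModelSpec()].
#' @param bend bend a non-positive-definite masked matrix (default TRUE);
#'   with \code{bend = FALSE} such a matrix is an error naming the minimum
#'   eigenvalue.
#' @param bendThreshold eigenvalue threshold for [bendUnweighted()]
#'   (default 1e-3).
#' @param tol,maxIter PCG settings (defaults 1e-7, 5000).
#' @param computeRel also compute exact reliabilities (desk scale only).
#' @param relGuard size guard forwarded to [computeReliability()].
#' @param useInbreeding account for inbreeding in the A-inverse.
#' @return an [EvaluationResult-class].
#' @export
runScenario <- function(phen, ped, params, scenario = "REF",
                        spec = defaultModelSpec(params),
                        bend = TRUE, bendThreshold = 1e-3,
                        tol = 1e-7, maxIter = 5000L,
                        computeRel = FALSE, relGuard = 20000L,
                        useInbreeding = TRUE) {
  scenario <- match.arg(scenario, c("REF", "CUR", "NONE", "NAT"))
  phi <- applyScenario(params@phi, scenario)
  chk <- checkPSD(phi, bendThreshold)
  bendIter <- 0L
  if (!chk$psd) {
    if (!bend)
      stop(sprintf("masked correlation matrix is not positive definite (min eigenvalue %.4g) and bending is disabled",
                   chk$minEigen))
    phi <- bendUnweighted(phi, threshold = bendThreshold)
    bendIter <- attr(phi, "iterations")
  }
  p2 <- geneticParameters(params@countries, phi, params@sd,
                          params@residualVar, params@peVar,
                          params@randomEnvVar)
  mme <- assembleMME(phen, ped, p2, spec, useInbreeding = useInbreeding)
  sol <- solvePCG(mme, tol = tol, maxIter = maxIter)
  gi <- (mme@nNonGen + 1L):length(mme@rhs)
  E <- matrix(sol$solution[gi], nrow = mme@nTraits)
  ebvM <- t(E)
  dimnames(ebvM) <- list(ped@id, mme@traitLabels)
  rel <- NULL
  if (computeRel) rel <- computeReliability(mme, maxUnknowns = relGuard)
  dom <- list()
  if (scenario == "NAT")
    dom <- stats::setNames(lapply(params@countries, function(cc)
      domesticSet(ped, phen, cc)), params@countries)
  new("EvaluationResult", scenario = scenario, countries = params@countries,
      ebv = ebvM, rel = rel,
      solver = list(iterations = sol$iterations,
                    convergence = sol$convergence,
                    relResidual = sol$relResidual,
                    bent = !chk$psd, bendIterations = bendIter,
                    minEigenBefore = chk$minEigen,
                    tol = tol, bendThreshold = bendThreshold),
      domestic = dom)
}

#' Exact reliabilities from the inverse coefficient matrix
#'
#' Reliability is \eqn{1 - PEV / \sigma^2_g} where the prediction error
#' variance is the diagonal of the inverse of the full coefficient matrix at
#' the corresponding genetic equation and \eqn{\sigma^2_g} is the national
#' genetic variance of the trait. By default the national variance is used
#' as-is; with \code{adjustInbreeding = TRUE} the denominator becomes
#' \eqn{(1 + F_i)\sigma^2_g}, the animal's own prior variance, which keeps
#' reliabilities of uninformed inbred animals at zero instead of clamping.
#' Exact inversion is only feasible at desk scale, hence the size guard.
#'
#' @param mme an [MME-class].
#' @param maxUnknowns refuse systems larger than this (default 20000).
#' @param adjustInbreeding divide by (1 + F) (default FALSE).
#' @return matrix animals x traits of reliabilities in [0, 1).
#' @export
computeReliability <- function(mme, maxUnknowns = 20000L,
                               adjustInbreeding = FALSE) {
  n <- length(mme@rhs)
  if (n > maxUnknowns)
    stop("system has ", n, " unknowns, above the reliability guard of ",
         maxUnknowns, "; evaluate a subset or raise the guard knowingly")
  C <- as.matrix(mmeMaterialize(mme, maxUnknowns = maxUnknowns))
  ch <- tryCatch(chol(C), error = function(e)
    stop("coefficient matrix is singular; check fixed-effect coding"))
  pev <- diag(chol2inv(ch))[(mme@nNonGen + 1L):n]
  P <- t(matrix(pev, nrow = mme@nTraits))
  denom <- rep(1, mme@nAnimals) %o% unname(mme@genVar)
  if (adjustInbreeding) denom <- (1 + mme@f) * denom
  rel <- 1 - P / denom
  rel[rel < 0] <- 0
  rel[rel >= 1] <- 1 - 1e-12
  dimnames(rel) <- list(mme@animalIds, mme@traitLabels)
  rel
}

#' Domestic animals of a country
#'
#' Animals with an own phenotype in the country, or any ancestor with a
#' phenotype there (descendants' records do not count).
#'
#' @param ped a [Pedigree-class].
#' @param phen a [PhenotypeTable-class].
#' @param country country label.
#' @return integer vector of internal codes, named by animal id.
#' @export
domesticSet <- function(ped, phen, country) {
  n <- length(ped@id)
  rec <- logical(n)
  rec[phen@animal[phen@country == country]] <- TRUE
  dom <- logical(n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    dom[i] <- rec[i] || (!is.na(s) && dom[s]) || (!is.na(d) && dom[d])
  }
  stats::setNames(which(dom), ped@id[dom])
}
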
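#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t diag
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Pedigree of animals with topological internal coding
#'
#' Animals carry 1-based internal codes assigned so that parents always
#' precede their offspring. Unknown parents are \code{NA}. The slot \code{f}
#' holds pedigree inbreeding coefficients (diag(A) - 1).
#'
#' @slot id external animal labels, one per animal, unique.
#' @slot sire,dam internal code of the sire/dam or \code{NA} when unknown.
#' @slot birthYear integer birth year (\code{NA} allowed).
#' @slot sex \code{"M"}, \code{"F"} or \code{NA}.
#' @slot country country label of registration (\code{NA} allowed).
#' @slot f inbreeding coefficient per animal, in [0, 1).
#'
#' @seealso [readPedigree()], [buildAInverse()], [tabularA()]
#' @export
setClass("Pedigree", representation(
  id = "character", sire = "integer", dam = "integer",
  birthYear = "integer", sex = "character", country = "character",
  f = "numeric"
))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  lens <- c(length(object@sire), length(object@dam), length(object@birthYear),
            length(object@sex), length(object@country), length(object@f))
  if (any(lens != n)) return("all slots must have one entry per animal")
  if (anyDuplicated(object@id)) return("duplicated animal ids")
  code <- seq_len(n)
  bad <- which(!is.na(object@sire) & object@sire >= code)
  if (length(bad)) return(sprintf("sire code not before animal %s", object@id[bad[1]]))
  bad <- which(!is.na(object@dam) & object@dam >= code)
  if (length(bad)) return(sprintf("dam code not before animal %s", object@id[bad[1]]))
  sx <- object@sex[stats::na.omit(unique(object@sire))]
  if (any(!is.na(sx) & sx != "M")) return("a sire is recorded as female")
  sx <- object@sex[stats::na.omit(unique(object@dam))]
  if (any(!is.na(sx) & sx != "F")) return("a dam is recorded as male")
  if (length(object@f) && (any(object@f < 0) || any(object@f >= 1)))
    return("inbreeding must lie in [0, 1)")
  TRUE
})

#' Across-country genetic parameters
#'
#' Holds the across-country genetic correlation matrix \eqn{\Phi} for direct
#' and maternal effects (order \code{2 * nCountries}, trait order
#' \code{[direct 1..n, maternal 1..n]}), national genetic standard deviations
#' (kg), and per-country environmental variances. The genetic covariance
#' matrix is derived as \eqn{G = S \Phi S} by [genCov()].
#'
#' @slot countries ordered country labels.
#' @slot phi correlation matrix, symmetric with unit diagonal.
#' @slot sd national genetic standard deviations (kg), one per trait.
#' @slot residualVar per-country residual variance (kg^2).
#' @slot peVar per-country maternal permanent-environment variance (kg^2);
#'   0 means the effect is not fitted (as for DEU).
#' @slot randomEnvVar named list per country of named numeric vectors giving
#'   variances of additional random environmental factors (may be empty).
#'
#' @seealso [buildG()], [applyScenario()], [bendUnweighted()], [readParams()]
#' @export
setClass("GeneticParameters", representation(
  countries = "character", phi = "matrix", sd = "numeric",
  residualVar = "numeric", peVar = "numeric", randomEnvVar = "list"
))

setValidity("GeneticParameters", function(object) {
  nc <- length(object@countries)
  nt <- 2L * nc
  if (!all(dim(object@phi) == nt)) return("phi must be 2*nCountries square")
  if (!isSymmetric(unname(object@phi), tol = 1e-10)) return("phi must be symmetric")
  if (max(abs(diag(object@phi) - 1)) > 1e-10) return("phi must have unit diagonal")
  if (any(abs(object@phi) > 1 + 1e-10)) return("phi entries must lie in [-1, 1]")
  if (length(object@sd) != nt || any(object@sd <= 0))
    return("sd must hold one positive value per trait")
  if (length(object@residualVar) != nc || any(object@residualVar <= 0))
    return("residualVar must hold one positive value per country")
  if (length(object@peVar) != nc || any(object@peVar < 0))
    return("peVar must hold one non-negative value per country")
  if (length(object@randomEnvVar) != nc)
    return("randomEnvVar must hold one (possibly empty) vector per country")
  TRUE
})

#' Phenotype records for age-adjusted weaning weight
#'
#' One record at most per animal; each record belongs to exactly one country.
#' Fixed/random environmental factor levels are carried in a data.frame
#' aligned with the records.
#'
#' @slot animal internal pedigree code of the recorded animal.
#' @slot dam internal code of the dam (\code{NA} when unknown).
#' @slot country country of recording.
#' @slot aww age-adjusted weaning weight (kg), finite and positive.
#' @slot factors data.frame of factor columns (e.g. \code{cg}, \code{sex}).
#' @export
setClass("PhenotypeTable", representation(
  animal = "integer", dam = "integer", country = "character",
  aww = "numeric", factors = "data.frame"
))

setValidity("PhenotypeTable", function(object) {
  n <- length(object@animal)
  if (length(object@dam) != n || length(object@country) != n ||
      length(object@aww) != n || nrow(object@factors) != n)
    return("all slots must have one entry per record")
  if (anyDuplicated(object@animal)) return("more than one record for an animal")
  if (any(!is.finite(object@aww)) || any(object@aww <= 0))
    return("AWW must be finite and positive")
  TRUE
})

#' National model structure per country
#'
#' Which fixed-effect factors, random environmental factors, and whether a
#' maternal permanent-environment effect are fitted in each country's
#' national model. Variances live in [GeneticParameters-class].
#'
#' @slot countries ordered country labels.
#' @slot fixed list per country of fixed-effect factor names.
#' @slot randomEnv list per country of random environmental factor names.
#' @slot fitPE logical per country; maternal PE fitted or not.
#' @export
setClass("ModelSpec", representation(
  countries = "character", fixed = "list", randomEnv = "list", fitPE = "logical"
))

setValidity("ModelSpec", function(object) {
  nc <- length(object@countries)
  if (length(object@fixed) != nc || length(object@randomEnv) != nc ||
      length(object@fitPE) != nc)
    return("fixed, randomEnv and fitPE need one entry per country")
  TRUE
})

#' Assembled mixed-model equations
#'
#' Henderson's MME for the multi-country maternal-effects animal model, kept
#' in operator form: \code{dataPart} holds every contribution except the
#' genetic precision, which is applied as \eqn{A^{-1} \otimes G^{-1}}
#' (animal-major layout) through the Kronecker identity. Use
#' [mmeMatvec()] for products, [mmeMaterialize()] for an explicit sparse
#' coefficient matrix at desk scale.
#'
#' @slot dataPart sparse matrix with record, random-environment and PE
#'   contributions over all equations.
#' @slot rhs right-hand side.
#' @slot AInv sparse inverse numerator relationship matrix.
#' @slot Ginv inverse genetic covariance matrix (2*nCountries square).
#' @slot nNonGen number of non-genetic equations (they come first).
#' @slot nAnimals,nTraits genetic block dimensions.
#' @slot eqInfo data.frame describing non-genetic equations
#'   (country, type, term, level).
#' @slot traitLabels labels of the genetic traits.
#' @slot animalIds external animal labels in pedigree order.
#' @slot genVar genetic variance per trait (kg^2), for reliabilities.
#' @slot f inbreeding coefficients, for the optional (1+F) reliability
#'   adjustment.
#' @export
setClass("MME", representation(
  dataPart = "Matrix", rhs = "numeric", AInv = "Matrix", Ginv = "matrix",
  nNonGen = "integer", nAnimals = "integer", nTraits = "integer",
  eqInfo = "data.frame", traitLabels = "character", animalIds = "character",
  genVar = "numeric", f = "numeric"
))

#' Result of one evaluation scenario
#'
#' EBVs (kg) and, when computed, reliabilities for every pedigree animal on
#' every country scale for both the direct and the maternal effect.
#' Columns are labelled \code{direct.XXX}, \code{maternal.XXX}.
#'
#' @slot scenario scenario name (REF, CUR, NONE, NAT or custom).
#' @slot countries country labels.
#' @slot ebv matrix animals x traits of EBVs (kg).
#' @slot rel matrix of reliabilities in [0, 1), or NULL when not computed.
#' @slot solver list of solver metadata (iterations, convergence, residual).
#' @slot domestic named list per country of domestic animal codes (filled
#'   for scenario NAT).
#' @export
setClass("EvaluationResult", representation(
  scenario = "character", countries = "character", ebv = "matrix",
  rel = "matrixOrNULL", solver = "list", domestic = "list"
))

setValidity("EvaluationResult", function(object) {
  nt <- 2L * length(object@countries)
  if (ncol(object@ebv) != nt) return("ebv needs 2 columns per country")
  if (!is.null(object@rel)) {
    if (!all(dim(object@rel) == dim(object@ebv))) return("rel dims must match ebv")
    r <- object@rel[!is.na(object@rel)]
    if (length(r) && (any(r < -1e-8) || any(r >= 1))) return("rel must lie in [0, 1)")
  }
  TRUE
})

#' Configuration of the synthetic multi-country data generator
#'
#' Defaults emulate the structure of the Limousin weaning-weight exchange:
#' eight country populations of very unequal size (one at 87%), herds nested
#' in countries, sires serving dams in several countries, discrete
#' generations with the last two recorded, and phenotypes generated from the
#' maternal-effects multi-trait model with the packaged genetic parameters.
#'
#' @slot seed integer RNG seed.
#' @slot countries country labels.
#' @slot proportions relative population sizes, summing to 1.
#' @slot nPerGeneration total offspring born per generation.
#' @slot generations number of offspring generations after the founders.
#' @slot recordedGenerations how many of the last generations are recorded.
#' @slot herdsPerCountry number of herds per country.
#' @slot progenyPerDam progeny per mated dam per generation.
#' @slot damsPerSire dams served per sire.
#' @slot pAbroad probability that a sire slot is filled by a foreign bull
#'   (drives common-bull connectedness).
#' @slot sexEffect additive fixed effect of male sex (kg).
#' @slot cgSd standard deviation of contemporary-group effects (kg).
#' @slot params [GeneticParameters-class] used for simulation.
#' @export
setClass("SimConfig", representation(
  seed = "integer", countries = "character", proportions = "numeric",
  nPerGeneration = "integer", generations = "integer",
  recordedGenerations = "integer", herdsPerCountry = "integer",
  progenyPerDam = "integer", damsPerSire = "integer", pAbroad = "numeric",
  sexEffect = "numeric", cgSd = "numeric", params = "GeneticParameters"
))

setValidity("SimConfig", function(object) {
  if (abs(sum(object@proportions) - 1) > 1e-8) return("proportions must sum to 1")
  if (length(object@proportions) != length(object@countries))
    return("one proportion per country")
  if (object@pAbroad < 0 || object@pAbroad > 1) return("pAbroad in [0, 1]")
  if (object@recordedGenerations > object@generations)
    return("cannot record more generations than simulated")
  if (object@generations < 0) return("generations must be >= 0")
  if (object@progenyPerDam < 1 || object@damsPerSire < 1)
    return("progenyPerDam and damsPerSire must be >= 1")
  TRUE
})

#' Re-ranking comparison report between scenarios
#'
#' @slot rankCorrelations data.frame: pair, country, effect, cohort, n,
#'   rho (Spearman), category (none/small/large).
#' @slot topk data.frame of top-k overlap counts and mean rank shifts.
#' @slot ebvSd data.frame of domestic EBV standard deviations (kg).
#' @slot cohortSizes data.frame of cohort membership counts.
#' @export
setClass("ComparisonReport", representation(
  rankCorrelations = "data.frame", topk = "data.frame",
  ebvSd = "data.frame", cohortSizes = "data.frame"
))
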
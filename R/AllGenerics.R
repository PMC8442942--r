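#' Number of animals in an object
#' @param x a [Pedigree-class] or [PhenotypeTable-class].
#' @return integer count.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' External animal labels
#' @param x a [Pedigree-class].
#' @return character vector in internal code order.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Inbreeding coefficients
#' @param x a [Pedigree-class].
#' @return numeric vector of F per animal.
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))

#' Country labels of an object
#' @param x an object carrying country information.
#' @return character vector.
#' @export
setGeneric("countries", function(x) standardGeneric("countries"))

#' Genetic covariance matrix G = S Phi S
#' @param x a [GeneticParameters-class].
#' @return covariance matrix (kg^2) with diagonal sd^2.
#' @export
setGeneric("genCov", function(x) standardGeneric("genCov"))

#' Trait labels (direct.XXX, maternal.XXX)
#' @param x an object with countries.
#' @return character vector of length 2 * nCountries.
#' @export
setGeneric("traitLabels", function(x) standardGeneric("traitLabels"))

#' Estimated breeding values
#' @param x an [EvaluationResult-class].
#' @param effect "direct", "maternal" or "both" (default).
#' @param country optional country label to restrict to one scale.
#' @return matrix of EBVs (kg), animals in rows.
#' @export
setGeneric("ebv", function(x, effect = "both", country = NULL) standardGeneric("ebv"))

#' Reliabilities of estimated breeding values
#' @inheritParams ebv
#' @return matrix of reliabilities in [0, 1), or NULL if not computed.
#' @export
setGeneric("reliability", function(x, effect = "both", country = NULL)
  standardGeneric("reliability"))

#' @describeIn nAnimals number of animals in a pedigree
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' @describeIn nAnimals number of records in a phenotype table
setMethod("nAnimals", "PhenotypeTable", function(x) length(x@animal))

#' @describeIn animalIds labels in pedigree order
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @describeIn inbreeding coefficients in pedigree order
setMethod("inbreeding", "Pedigree", function(x) stats::setNames(x@f, x@id))

#' @describeIn countries of a parameter set
setMethod("countries", "GeneticParameters", function(x) x@countries)

#' @describeIn countries of an evaluation result
setMethod("countries", "EvaluationResult", function(x) x@countries)

#' @describeIn countries of a model specification
setMethod("countries", "ModelSpec", function(x) x@countries)

.traitLabels <- function(cn) c(paste0("direct.", cn), paste0("maternal.", cn))

#' @describeIn traitLabels for a parameter set
setMethod("traitLabels", "GeneticParameters", function(x) .traitLabels(x@countries))

#' @describeIn traitLabels for an evaluation result
setMethod("traitLabels", "EvaluationResult", function(x) .traitLabels(x@countries))

#' @describeIn genCov build G from sd and phi
setMethod("genCov", "GeneticParameters", function(x) buildG(x@sd, x@phi))

.pickTraits <- function(x, m, effect, country) {
  lab <- .traitLabels(x@countries)
  colnames(m) <- lab
  keep <- rep(TRUE, length(lab))
  if (effect != "both")
    keep <- keep & startsWith(lab, match.arg(effect, c("direct", "maternal")))
  if (!is.null(country))
    keep <- keep & endsWith(lab, paste0(".", country))
  m[, keep, drop = FALSE]
}

#' @describeIn ebv extract EBVs from a result
setMethod("ebv", "EvaluationResult", function(x, effect = "both", country = NULL)
  .pickTraits(x, x@ebv, effect, country))

#' @describeIn reliability extract reliabilities from a result
setMethod("reliability", "EvaluationResult", function(x, effect = "both", country = NULL) {
  if (is.null(x@rel)) return(NULL)
  .pickTraits(x, x@rel, effect, country)
})

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat(sprintf("Pedigree with %d animals (%d founders), %d countries\n",
              n, sum(is.na(object@sire) & is.na(object@dam)),
              length(unique(stats::na.omit(object@country)))))
  cat(sprintf("  mean inbreeding F = %.4f, max F = %.4f\n",
              mean(object@f), if (n) max(object@f) else 0))
})

setMethod("show", "GeneticParameters", function(object) {
  cat(sprintf("GeneticParameters for %d countries: %s\n",
              length(object@countries), paste(object@countries, collapse = ", ")))
  ev <- eigen(object@phi, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  phi %dx%d, min eigenvalue %.4g\n", nrow(object@phi),
              ncol(object@phi), min(ev)))
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable with %d records in %d countries\n",
              length(object@animal), length(unique(object@country))))
  cat(sprintf("  AWW mean %.1f kg, factors: %s\n", mean(object@aww),
              paste(names(object@factors), collapse = ", ")))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s]: %d animals x %d traits\n",
              object@scenario, nrow(object@ebv), ncol(object@ebv)))
  if (!is.null(object@solver$iterations))
    cat(sprintf("  solver: %d PCG iterations, convergence %.3g\n",
                object@solver$iterations, object@solver$convergence))
  if (!is.null(object@rel)) cat("  reliabilities: computed\n")
})

setMethod("show", "MME", function(object) {
  cat(sprintf("MME: %d equations (%d non-genetic + %d animals x %d traits)\n",
              length(object@rhs), object@nNonGen, object@nAnimals, object@nTraits))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %d countries, %d+%d generations, ~%d offspring/gen\n",
              object@seed, length(object@countries), 1L, object@generations,
              object@nPerGeneration))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: %d rank-correlation cells, %d top-k rows, %d SD rows\n",
              nrow(object@rankCorrelations), nrow(object@topk), nrow(object@ebvSd)))
})
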
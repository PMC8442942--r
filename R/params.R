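#' Construct a GeneticParameters object
#'
#' @param countries ordered country labels.
#' @param phi correlation matrix of order \code{2 * length(countries)},
#'   trait order [direct 1..n, maternal 1..n].
#' @param sd national genetic standard deviations (kg) per trait, same order.
#' @param residualVar,peVar per-country residual and maternal
#'   permanent-environment variances (kg^2); \code{peVar = 0} means PE is
#'   not fitted for that country.
#' @param randomEnvVar optional named list per country of named variances of
#'   additional random environmental factors.
#' @return a [GeneticParameters-class].
#' @export
geneticParameters <- function(countries, phi, sd, residualVar, peVar,
                              randomEnvVar = NULL) {
  nc <- length(countries)
  if (is.null(randomEnvVar)) randomEnvVar <- rep(list(numeric(0)), nc)
  names(randomEnvVar) <- countries
  phi <- unname(as.matrix(phi))
  lab <- .traitLabels(countries)
  dimnames(phi) <- list(lab, lab)
  new("GeneticParameters", countries = countries, phi = phi,
      sd = stats::setNames(as.numeric(sd), lab),
      residualVar = stats::setNames(as.numeric(residualVar), countries),
      peVar = stats::setNames(as.numeric(peVar), countries),
      randomEnvVar = randomEnvVar)
}

#' Genetic covariance matrix G = S Phi S
#'
#' @param sd vector of genetic standard deviations (kg).
#' @param phi symmetric correlation matrix with unit diagonal.
#' @return covariance matrix (kg^2), diagonal sd^2.
#' @examples
#' buildG(c(2, 3), diag(2))
#' @export
buildG <- function(sd, phi) {
  phi <- as.matrix(phi)
  if (!isSymmetric(unname(phi), tol = 1e-10)) stop("phi must be symmetric")
  if (any(sd <= 0)) stop("sd must be strictly positive")
  G <- sd * phi * rep(sd, each = length(sd))
  (G + t(G)) / 2
}

.dmBlockMask <- function(nc, offDiagOnly) {
  m <- matrix(FALSE, 2 * nc, 2 * nc)
  blk <- matrix(TRUE, nc, nc)
  if (offDiagOnly) diag(blk) <- FALSE
  m[seq_len(nc), nc + seq_len(nc)] <- blk
  m[nc + seq_len(nc), seq_len(nc)] <- t(blk)
  m
}

#' Apply a scenario mask to a correlation matrix
#'
#' Scenarios zero correlation blocks of the [direct, maternal] x country
#' correlation matrix: \code{REF} keeps everything; \code{CUR} zeroes only
#' the between-country direct-maternal correlations (off-diagonal of the
#' direct-maternal block); \code{NONE} zeroes the whole direct-maternal
#' block; \code{NAT} zeroes every between-country correlation (direct,
#' maternal and direct-maternal) and keeps the within-country
#' direct-maternal correlations, which makes the model equivalent to
#' independent single-country evaluations.
#'
#' @param phi correlation matrix of order 2 * nCountries.
#' @param scenario one of \code{"REF"}, \code{"CUR"}, \code{"NONE"},
#'   \code{"NAT"}.
#' @return masked copy of \code{phi}.
#' @export
applyScenario <- function(phi, scenario) {
  scenario <- match.arg(scenario, c("REF", "CUR", "NONE", "NAT"))
  nc <- nrow(phi) / 2
  if (nc != round(nc)) stop("phi must have even order")
  out <- phi
  if (scenario == "CUR") out[.dmBlockMask(nc, offDiagOnly = TRUE)] <- 0
  if (scenario == "NONE") out[.dmBlockMask(nc, offDiagOnly = FALSE)] <- 0
  if (scenario == "NAT") {
    keep <- diag(TRUE, 2 * nc)
    keep[.dmBlockMask(nc, offDiagOnly = FALSE) & !.dmBlockMask(nc, TRUE)] <- TRUE
    out[!keep] <- 0
  }
  out
}

#' Positive-definiteness check against a threshold
#'
#' @param m symmetric matrix.
#' @param threshold minimum acceptable eigenvalue (default 1e-3).
#' @return list with \code{psd} (logical) and \code{minEigen}.
#' @export
checkPSD <- function(m, threshold = 1e-3) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= threshold, minEigen = min(ev))
}

#' Unweighted bending of a correlation matrix
#'
#' Iteratively eigendecomposes the matrix, replaces eigenvalues below the
#' threshold with the threshold, reconstructs, and rescales to unit
#' diagonal, until the minimum eigenvalue reaches the threshold (up to a
#' relative tolerance of 1e-6). A matrix that already complies is returned
#' unchanged. All national variances are preserved because the correlation
#' scale is restored every iteration.
#'
#' @param phi symmetric matrix with unit diagonal.
#' @param threshold minimum eigenvalue to enforce (default 1e-3).
#' @param maxIter iteration cap (default 10000).
#' @return bent correlation matrix with attributes \code{iterations} and
#'   \code{minEigen}.
#' @export
bendUnweighted <- function(phi, threshold = 1e-3, maxIter = 10000L) {
  m <- as.matrix(phi)
  if (!isSymmetric(unname(m), tol = 1e-10)) stop("phi must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) stop("phi must have unit diagonal")
  it <- 0L
  repeat {
    e <- eigen(m, symmetric = TRUE)
    minE <- min(e$values)
    if (minE >= threshold * (1 - 1e-6)) break
    if (it >= maxIter)
      stop(sprintf("bending did not converge in %d iterations (min eigenvalue %.3g)",
                   maxIter, minE))
    v <- pmax(e$values, threshold)
    m <- e$vectors %*% (v * t(e$vectors))
    dd <- sqrt(diag(m))
    m <- m / outer(dd, dd)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    it <- it + 1L
  }
  dimnames(m) <- dimnames(phi)
  attr(m, "iterations") <- it
  attr(m, "minEigen") <- minE
  m
}

#' Genetic parameters for a subset of countries
#'
#' @param params a [GeneticParameters-class].
#' @param keep countries to retain, in the parent object's order.
#' @return a [GeneticParameters-class] restricted to \code{keep}.
#' @export
subsetCountries <- function(params, keep) {
  idx <- match(keep, params@countries)
  if (anyNA(idx)) stop("unknown country: ", keep[is.na(idx)][1])
  nc <- length(params@countries)
  tidx <- c(idx, nc + idx)
  geneticParameters(params@countries[idx],
                    params@phi[tidx, tidx, drop = FALSE],
                    params@sd[tidx],
                    params@residualVar[idx], params@peVar[idx],
                    params@randomEnvVar[idx])
}

#' Read genetic parameters from a YAML file
#'
#' The file carries the country list, the full correlation matrix as rows,
#' genetic variances per trait, and per-country residual / maternal-PE /
#' random-environment variances (see the packaged
#' \code{limousin_ww_params.yaml} for the layout).
#'
#' @param path file path.
#' @return a [GeneticParameters-class].
#' @export
readParams <- function(path) {
  y <- yaml::read_yaml(path)
  cn <- as.character(y$countries)
  phi <- do.call(rbind, lapply(y$correlations, as.numeric))
  gv <- c(as.numeric(y$genetic_variances$direct[cn]),
          as.numeric(y$genetic_variances$maternal[cn]))
  rev_ <- lapply(cn, function(cc) {
    v <- y$random_env_variances[[cc]]
    if (is.null(v)) numeric(0) else unlist(v)
  })
  geneticParameters(cn, phi, sqrt(gv),
                    residualVar = as.numeric(y$residual_variances[cn]),
                    peVar = as.numeric(y$pe_variances[cn]),
                    randomEnvVar = rev_)
}

#' Write genetic parameters to a YAML file
#'
#' @param params a [GeneticParameters-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeParams <- function(params, path) {
  cn <- params@countries
  nc <- length(cn)
  gv <- params@sd^2
  y <- list(
    countries = as.list(cn),
    genetic_variances = list(
      direct = as.list(stats::setNames(unname(gv[seq_len(nc)]), cn)),
      maternal = as.list(stats::setNames(unname(gv[nc + seq_len(nc)]), cn))),
    correlations = lapply(seq_len(2 * nc), function(i) as.numeric(params@phi[i, ])),
    residual_variances = as.list(stats::setNames(unname(params@residualVar), cn)),
    pe_variances = as.list(stats::setNames(unname(params@peVar), cn)),
    random_env_variances = lapply(params@randomEnvVar, function(v)
      if (length(v)) as.list(v) else NULL)
  )
  yaml::write_yaml(y, path, precision = 12L)
  invisible(path)
}

#' Packaged Limousin weaning-weight genetic parameters
#'
#' The across-country direct/maternal genetic correlation matrix and
#' national genetic variances estimated for Limousin age-adjusted weaning
#' weight across eight European populations, plus package-convention
#' environmental variances (residual variances chosen so that the direct
#' heritability is 0.25 per country; maternal PE variance 5% of phenotypic
#' variance, not fitted for DEU).
#'
#' @return a [GeneticParameters-class] for countries CZE, DFS, ESP, GBR,
#'   IRL, FRA, DEU, CHE.
#' @export
defaultParams <- function() {
  readParams(system.file("extdata", "limousin_ww_params.yaml",
                         package = "amaci", mustWork = TRUE))
}
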
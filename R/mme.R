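#' Construct a ModelSpec
#'
#' @param countries ordered country labels.
#' @param fixed character vector of fixed-effect factor names applied to all
#'   countries, or a list per country.
#' @param randomEnv list per country of random environmental factor names
#'   (default: none).
#' @param fitPE logical per country (recycled); whether maternal permanent
#'   environment is fitted.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(countries, fixed = c("cg", "sex"), randomEnv = NULL,
                      fitPE = TRUE) {
  nc <- length(countries)
  if (!is.list(fixed)) fixed <- rep(list(fixed), nc)
  if (is.null(randomEnv)) randomEnv <- rep(list(character(0)), nc)
  names(fixed) <- names(randomEnv) <- countries
  new("ModelSpec", countries = countries, fixed = fixed,
      randomEnv = randomEnv, fitPE = stats::setNames(rep(fitPE, length.out = nc), countries))
}

#' Default national model structure implied by a parameter set
#'
#' Contemporary group and sex as fixed effects everywhere; random
#' environmental factors and the maternal-PE flag taken from the variances
#' present in \code{params} (PE is fitted where its variance is positive).
#'
#' @param params a [GeneticParameters-class].
#' @return a [ModelSpec-class].
#' @export
defaultModelSpec <- function(params) {
  modelSpec(params@countries,
            fixed = c("cg", "sex"),
            randomEnv = lapply(params@randomEnvVar, names),
            fitPE = params@peVar > 0)
}

#' Assemble the mixed-model equations
#'
#' Builds Henderson's MME for the multi-country maternal-effects animal
#' model: per-country fixed-effect blocks (first factor full, subsequent
#' factors treatment-coded to keep the system full-rank), per-country IID
#' random environmental blocks, maternal permanent-environment blocks over
#' the dams recorded in each country, and a genetic block of
#' \code{2 * nCountries} equations per animal with precision
#' \eqn{A^{-1} \otimes G^{-1}} (animal-major ordering). Residuals are
#' block-diagonal by country. Records with an unknown dam drop their
#' maternal-genetic and PE terms.
#'
#' @param phen a [PhenotypeTable-class].
#' @param ped a [Pedigree-class].
#' @param params a [GeneticParameters-class] whose correlation matrix must
#'   be positive definite (bend first if needed).
#' @param spec a [ModelSpec-class]; default [defaultModelSpec()].
#' @param useInbreeding passed to [buildAInverse()].
#' @return an [MME-class].
#' @export
assembleMME <- function(phen, ped, params, spec = defaultModelSpec(params),
                        useInbreeding = TRUE) {
  cn <- params@countries
  nc <- length(cn)
  Tt <- 2L * nc
  N <- length(ped@id)
  if (any(!phen@country %in% cn))
    stop("record country not in parameter set: ",
         setdiff(phen@country, cn)[1])
  if (any(phen@animal < 1L | phen@animal > N))
    stop("record references an animal outside the pedigree")
  G <- genCov(params)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch))
    stop("G is singular or not positive definite; bend the correlation matrix first")
  Ginv <- chol2inv(ch)

  nrec <- length(phen@animal)
  recCountry <- match(phen@country, cn)
  w <- 1 / params@residualVar[recCountry]

  # --- non-genetic equations ---------------------------------------------
  eqCountry <- character(0); eqType <- character(0)
  eqTerm <- character(0); eqLevel <- character(0); eqPrec <- numeric(0)
  ti <- integer(0); tj <- integer(0)      # triplets of the record design W
  addCols <- function(recIdx, keys) {
    # map records to equation columns by level key; returns col ids (local)
    lev <- unique(keys)
    list(lev = lev, col = match(keys, lev))
  }
  nEq <- 0L
  for (ci in seq_len(nc)) {
    rec <- which(recCountry == ci)
    if (!length(rec)) next
    ff <- spec@fixed[[cn[ci]]]
    missing <- setdiff(c(ff, spec@randomEnv[[cn[ci]]]), names(phen@factors))
    if (length(missing))
      stop("factor '", missing[1], "' named in the model is not a phenotype column")
    for (k in seq_along(ff)) {
      keys <- as.character(phen@factors[[ff[k]]][rec])
      m <- addCols(rec, keys)
      drop <- if (k > 1L) 1L else 0L      # treatment coding after first factor
      keep <- m$col > drop
      colId <- m$col - drop
      nlev <- length(m$lev) - drop
      if (nlev > 0L) {
        ti <- c(ti, rec[keep]); tj <- c(tj, nEq + colId[keep])
        eqCountry <- c(eqCountry, rep(cn[ci], nlev))
        eqType <- c(eqType, rep("fixed", nlev))
        eqTerm <- c(eqTerm, rep(ff[k], nlev))
        eqLevel <- c(eqLevel, m$lev[(drop + 1L):length(m$lev)])
        eqPrec <- c(eqPrec, rep(0, nlev))
        nEq <- nEq + nlev
      }
    }
    for (rf in spec@randomEnv[[cn[ci]]]) {
      vr <- params@randomEnvVar[[cn[ci]]][rf]
      if (is.na(vr) || vr <= 0)
        stop("no positive variance for random factor '", rf, "' in ", cn[ci])
      keys <- as.character(phen@factors[[rf]][rec])
      m <- addCols(rec, keys)
      nlev <- length(m$lev)
      ti <- c(ti, rec); tj <- c(tj, nEq + m$col)
      eqCountry <- c(eqCountry, rep(cn[ci], nlev))
      eqType <- c(eqType, rep("env", nlev))
      eqTerm <- c(eqTerm, rep(rf, nlev))
      eqLevel <- c(eqLevel, m$lev)
      eqPrec <- c(eqPrec, rep(1 / vr, nlev))
      nEq <- nEq + nlev
    }
    if (spec@fitPE[cn[ci]]) {
      if (params@peVar[ci] <= 0)
        stop("PE fitted for ", cn[ci], " but its PE variance is not positive")
      known <- rec[!is.na(phen@dam[rec])]
      if (length(known)) {
        keys <- as.character(phen@dam[known])
        m <- addCols(known, keys)
        nlev <- length(m$lev)
        ti <- c(ti, known); tj <- c(tj, nEq + m$col)
        eqCountry <- c(eqCountry, rep(cn[ci], nlev))
        eqType <- c(eqType, rep("pe", nlev))
        eqTerm <- c(eqTerm, rep("dam", nlev))
        eqLevel <- c(eqLevel, ped@id[as.integer(m$lev)])
        eqPrec <- c(eqPrec, rep(1 / params@peVar[ci], nlev))
        nEq <- nEq + nlev
      }
    }
  }
  nNonGen <- nEq

  # --- genetic columns (animal-major: (a-1)*T + t) -----------------------
  genCol <- function(a, t) nNonGen + (a - 1L) * Tt + t
  ti <- c(ti, seq_len(nrec))
  tj <- c(tj, genCol(phen@animal, recCountry))
  known <- which(!is.na(phen@dam))
  ti <- c(ti, known)
  tj <- c(tj, genCol(phen@dam[known], nc + recCountry[known]))

  nTot <- nNonGen + N * Tt
  W <- Matrix::sparseMatrix(i = ti, j = tj, x = 1, dims = c(nrec, nTot))
  Wh <- sqrt(w) * W
  dataPart <- Matrix::crossprod(Wh)
  if (nNonGen > 0L)
    dataPart <- dataPart + Matrix::Diagonal(nTot, c(eqPrec, numeric(N * Tt)))
  rhs <- as.numeric(Matrix::crossprod(W, w * phen@aww))

  new("MME",
      dataPart = methods::as(dataPart, "generalMatrix"),
      rhs = rhs,
      AInv = buildAInverse(ped, useInbreeding = useInbreeding),
      Ginv = Ginv, nNonGen = nNonGen, nAnimals = N, nTraits = Tt,
      eqInfo = data.frame(country = eqCountry, type = eqType,
                          term = eqTerm, level = eqLevel,
                          stringsAsFactors = FALSE),
      traitLabels = .traitLabels(cn), animalIds = ped@id,
      genVar = stats::setNames(diag(G), .traitLabels(cn)), f = ped@f)
}

#' Coefficient-matrix product without materializing the genetic Kronecker
#'
#' Computes \code{C \%*\% v} where the genetic precision
#' \eqn{A^{-1} \otimes G^{-1}} is applied through the identity
#' \eqn{(A^{-1} \otimes G^{-1}) vec(V) = vec(G^{-1} V A^{-1})}.
#'
#' @param mme an [MME-class].
#' @param v numeric vector of length \code{length(mme@rhs)}.
#' @return numeric vector.
#' @export
mmeMatvec <- function(mme, v) {
  r <- as.numeric(mme@dataPart %*% v)
  gi <- (mme@nNonGen + 1L):length(v)
  V <- matrix(v[gi], nrow = mme@nTraits)
  r[gi] <- r[gi] + as.numeric(mme@Ginv %*% as.matrix(V %*% mme@AInv))
  r
}

#' Materialize the full sparse coefficient matrix
#'
#' Intended for desk-scale oracles and exact reliabilities; refuses systems
#' above \code{maxUnknowns}.
#'
#' @param mme an [MME-class].
#' @param maxUnknowns size guard (default 20000).
#' @return sparse symmetric coefficient matrix.
#' @export
mmeMaterialize <- function(mme, maxUnknowns = 20000L) {
  n <- length(mme@rhs)
  if (n > maxUnknowns)
    stop("system has ", n, " unknowns, above the materialization guard of ",
         maxUnknowns, "; use the operator form")
  K <- Matrix::kronecker(mme@AInv, methods::as(mme@Ginv, "generalMatrix"))
  ng <- mme@nNonGen
  C <- mme@dataPart
  gi <- (ng + 1L):n
  C[gi, gi] <- C[gi, gi] + K
  methods::as(C, "generalMatrix")
}

# block-Jacobi preconditioner: per-animal TxT genetic blocks, scalars elsewhere
.blockJacobi <- function(mme) {
  n <- length(mme@rhs)
  Tt <- mme@nTraits
  N <- mme@nAnimals
  ng <- mme@nNonGen
  dp <- Matrix::diag(mme@dataPart)
  ad <- Matrix::diag(mme@AInv)
  x <- numeric(ng + N * Tt * Tt)
  irow <- integer(length(x)); jcol <- integer(length(x))
  if (ng > 0L) {
    irow[seq_len(ng)] <- jcol[seq_len(ng)] <- seq_len(ng)
    x[seq_len(ng)] <- 1 / dp[seq_len(ng)]
  }
  idx <- as.matrix(expand.grid(seq_len(Tt), seq_len(Tt)))
  off <- ng
  pos <- ng
  for (a in seq_len(N)) {
    B <- mme@Ginv * ad[a]
    dseq <- dp[off + seq_len(Tt)]
    diag(B) <- diag(B) + dseq
    Bi <- chol2inv(chol(B))
    sel <- pos + seq_len(Tt * Tt)
    irow[sel] <- off + idx[, 1L]
    jcol[sel] <- off + idx[, 2L]
    x[sel] <- as.numeric(Bi)
    off <- off + Tt
    pos <- pos + Tt * Tt
  }
  Matrix::sparseMatrix(i = irow, j = jcol, x = x, dims = c(n, n))
}

#' Solve the mixed-model equations by preconditioned conjugate gradients
#'
#' Block-Jacobi preconditioning (one inverse 2*nCountries block per animal,
#' scalar inverses elsewhere). The stopping rule is the square root of the
#' relative difference between solutions of two consecutive iterations,
#' \eqn{\sqrt{\|x_k - x_{k-1}\|^2 / \|x_k\|^2} \le tol}; the relative
#' residual of the normal equations is reported alongside.
#'
#' @param mme an [MME-class].
#' @param tol convergence criterion (default 1e-7).
#' @param maxIter iteration cap (default 5000); exceeding it is an error
#'   carrying the convergence trace.
#' @return list with \code{solution}, \code{iterations}, \code{convergence}
#'   (final criterion value), \code{relResidual} and \code{trace}.
#' @export
solvePCG <- function(mme, tol = 1e-7, maxIter = 5000L) {
  b <- mme@rhs
  n <- length(b)
  if (all(b == 0))
    return(list(solution = numeric(n), iterations = 0L, convergence = 0,
                relResidual = 0, trace = numeric(0)))
  Minv <- .blockJacobi(mme)
  x <- numeric(n)
  r <- b
  z <- as.numeric(Minv %*% r)
  p <- z
  rz <- sum(r * z)
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    q <- mmeMatvec(mme, p)
    alpha <- rz / sum(p * q)
    dx <- alpha * p
    x <- x + dx
    r <- r - alpha * q
    cd <- sqrt(sum(dx * dx) / sum(x * x))
    trace <- c(trace, cd)
    if (cd <= tol) break
    if (it >= maxIter) {
      err <- simpleError(sprintf(
        "PCG did not reach %.1g in %d iterations (last criterion %.3g)",
        tol, maxIter, cd))
      err$trace <- trace
      stop(err)
    }
    z <- as.numeric(Minv %*% r)
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  relres <- sqrt(sum((b - mmeMatvec(mme, x))^2) / sum(b * b))
  list(solution = x, iterations = it, convergence = trace[length(trace)],
       relResidual = relres, trace = trace)
}
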
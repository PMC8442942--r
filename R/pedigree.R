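#' Build a validated, topologically recoded pedigree
#'
#' Animals are assigned 1-based internal codes so that parents always precede
#' their offspring. Labels appearing only as parents are added as founders
#' with unknown parents (the common pedigree-file dialect). A cycle in the
#' parent graph is a hard error naming one animal on the cycle. Sexes of
#' sires/dams are filled in as male/female where missing.
#'
#' @param id external animal labels.
#' @param sire,dam external labels of parents; \code{NA}, \code{""} or
#'   \code{"0"} mean unknown.
#' @param birthYear,sex,country optional per-animal columns. Sex accepts
#'   M/F, male/female or 1/2.
#' @param computeF compute inbreeding coefficients (default TRUE).
#' @return a [Pedigree-class].
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
#' nAnimals(ped)
#' @export
pedigree <- function(id, sire, dam, birthYear = NULL, sex = NULL,
                     country = NULL, computeF = TRUE) {
  id <- as.character(id)
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  sire <- norm(sire); dam <- norm(dam)
  if (anyDuplicated(id)) stop("duplicated animal ids: ", id[duplicated(id)][1])

  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {  # implicit founders
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    pad <- function(x, fill) if (is.null(x)) NULL else c(x, rep(fill, length(extra)))
    birthYear <- pad(birthYear, NA_integer_)
    sex <- pad(sex, NA_character_)
    country <- pad(country, NA_character_)
  }
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)

  # iterative depth computation with cycle detection
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 = new, 1 = on stack, 2 = done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 2L) { stack <- stack[-length(stack)]; next }
      state[v] <- 1L
      par <- c(si[v], di[v]); par <- par[!is.na(par)]
      pend <- par[state[par] != 2L]
      if (length(pend)) {
        if (any(state[pend] == 1L))
          stop("pedigree cycle detected involving animal ", id[pend[state[pend] == 1L][1]])
        stack <- c(stack, pend)
      } else {
        depth[v] <- if (length(par)) max(depth[par]) + 1L else 0L
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  ord <- order(depth, seq_len(n))
  rank <- integer(n); rank[ord] <- seq_len(n)

  sex2 <- if (is.null(sex)) rep(NA_character_, n) else {
    s <- toupper(substr(as.character(sex), 1, 1))
    ifelse(s %in% c("M", "1"), "M", ifelse(s %in% c("F", "2"), "F", NA_character_))
  }
  sireIdx <- stats::na.omit(unique(si)); damIdx <- stats::na.omit(unique(di))
  if (any(sex2[sireIdx] == "F", na.rm = TRUE))
    stop("animal recorded as female appears as a sire: ",
         id[sireIdx[which(sex2[sireIdx] == "F")[1]]])
  if (any(sex2[damIdx] == "M", na.rm = TRUE))
    stop("animal recorded as male appears as a dam: ",
         id[damIdx[which(sex2[damIdx] == "M")[1]]])
  sex2[sireIdx] <- "M"
  sex2[damIdx] <- "F"

  ped <- new("Pedigree",
    id = id[ord],
    sire = rank[si][ord],
    dam = rank[di][ord],
    birthYear = if (is.null(birthYear)) rep(NA_integer_, n) else as.integer(birthYear)[ord],
    sex = sex2[ord],
    country = if (is.null(country)) rep(NA_character_, n) else as.character(country)[ord],
    f = numeric(n))
  if (computeF) ped@f <- computeInbreeding(ped)
  validObject(ped)
  ped
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes F = diag(A) - 1 without forming A, by accumulating the
#' within-family (Mendelian-sampling) variances of each animal's ancestors.
#' Founders and animals with an unknown parent that is unrelated to the
#' other parent get F consistent with unknown parents being unrelated
#' base-population animals.
#'
#' @param ped a [Pedigree-class].
#' @return numeric vector of F in [0, 1), founders 0.
#' @export
computeInbreeding <- function(ped) {
  n <- length(ped@id)
  s <- ped@sire; d <- ped@dam
  F <- numeric(n)
  D <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (is.na(s[i])) -1 else F[s[i]]
    fd <- if (is.na(d[i])) -1 else F[d[i]]
    D[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s[i]) || is.na(d[i])) { F[i] <- 0; next }
    # ancestors of i (including i), processed in decreasing code order
    anc <- i
    frontier <- i
    while (length(frontier)) {
      pf <- c(s[frontier], d[frontier])
      pf <- unique(pf[!is.na(pf)])
      pf <- pf[!(pf %in% anc)]
      anc <- c(anc, pf)
      frontier <- pf
    }
    anc <- sort(anc, decreasing = TRUE)
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      if (!is.na(s[j])) L[s[j]] <- L[s[j]] + lj / 2
      if (!is.na(d[j])) L[d[j]] <- L[d[j]] + lj / 2
      aii <- aii + lj * lj * D[j]
    }
    L[anc] <- 0
    F[i] <- aii - 1
  }
  F
}

#' Numerator relationship matrix by the recursive tabular method
#'
#' Dense construction, intended as an oracle and for desk-scale pedigrees;
#' refuses pedigrees above \code{maxAnimals}.
#'
#' @param ped a [Pedigree-class].
#' @param maxAnimals size guard (default 3000).
#' @return dense symmetric matrix with diag = 1 + F.
#' @export
tabularA <- function(ped, maxAnimals = 3000L) {
  n <- length(ped@id)
  if (n > maxAnimals)
    stop("pedigree has ", n, " animals, above the dense-A guard of ", maxAnimals)
  s <- ped@sire; d <- ped@dam
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    as_ <- if (is.na(s[i])) numeric(i - 1L) else A[prev, s[i]]
    ad_ <- if (is.na(d[i])) numeric(i - 1L) else A[prev, d[i]]
    if (i > 1L) {
      A[prev, i] <- 0.5 * (as_ + ad_)
      A[i, prev] <- A[prev, i]
    }
    asd <- if (is.na(s[i]) || is.na(d[i])) 0 else A[s[i], d[i]]
    A[i, i] <- 1 + 0.5 * asd
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Mendelian-sampling variances adjusted for parental
#' inbreeding (Meuwissen-Luo style); at most 9 nonzero contributions per
#' animal. Set \code{useInbreeding = FALSE} to ignore inbreeding in the
#' Mendelian-sampling variances.
#'
#' @param ped a [Pedigree-class] with F computed.
#' @param useInbreeding account for parental inbreeding (default TRUE).
#' @return sparse symmetric \code{dsCMatrix}.
#' @export
buildAInverse <- function(ped, useInbreeding = TRUE) {
  n <- length(ped@id)
  s <- ped@sire; d <- ped@dam
  F <- if (useInbreeding) ped@f else numeric(n)
  fs <- ifelse(is.na(s), -1, F[ifelse(is.na(s), 1L, s)])
  fd <- ifelse(is.na(d), -1, F[ifelse(is.na(d), 1L, d)])
  alpha <- 1 / (0.5 - 0.25 * (fs + fd))
  ii <- seq_len(n)
  ti <- ii; tj <- ii; tx <- alpha                    # (i,i) += alpha
  ks <- which(!is.na(s)); kd <- which(!is.na(d)); kb <- which(!is.na(s) & !is.na(d))
  ti <- c(ti, ks, kd, s[ks], d[kd], s[kb])
  tj <- c(tj, s[ks], d[kd], s[ks], d[kd], d[kb])
  tx <- c(tx, -alpha[ks] / 2, -alpha[kd] / 2,
          alpha[ks] / 4, alpha[kd] / 4, alpha[kb] / 4)
  lo <- pmin(ti, tj); hi <- pmax(ti, tj)
  Matrix::sparseMatrix(i = hi, j = lo, x = tx, dims = c(n, n), symmetric = TRUE,
                       dimnames = list(ped@id, ped@id))
}

#' Cross-country genetic connections: common bulls and common MGS
#'
#' A common bull (CB) is a sire with recorded offspring in two or more
#' countries; a common maternal grand-sire (CMGS) is a sire whose daughters
#' have recorded progeny in two or more countries.
#'
#' @param ped a [Pedigree-class].
#' @param phen a [PhenotypeTable-class] linked to \code{ped}.
#' @return list with \code{sireCountries} (list per sire of countries with
#'   recorded offspring), \code{mgsCountries} (per MGS, countries with
#'   recorded daughters' offspring), \code{cb}, \code{cmgs} (labels with
#'   >= 2 countries), and \code{overlap}.
#' @export
findConnections <- function(ped, phen) {
  n <- length(ped@id)
  recCountry <- rep(NA_character_, n)
  recCountry[phen@animal] <- phen@country

  sires <- sort(unique(ped@sire[!is.na(ped@sire)]))
  hasRec <- !is.na(recCountry)
  sireCountries <- lapply(sires, function(ss) {
    off <- which(!is.na(ped@sire) & ped@sire == ss & hasRec)
    sort(unique(recCountry[off]))
  })
  names(sireCountries) <- ped@id[sires]

  mgsCountries <- lapply(sires, function(ss) {
    daughters <- which(!is.na(ped@sire) & ped@sire == ss & ped@sex == "F")
    goff <- which(!is.na(ped@dam) & ped@dam %in% daughters & hasRec)
    sort(unique(recCountry[goff]))
  })
  names(mgsCountries) <- ped@id[sires]

  cb <- names(sireCountries)[vapply(sireCountries, length, 1L) >= 2L]
  cmgs <- names(mgsCountries)[vapply(mgsCountries, length, 1L) >= 2L]
  list(sireCountries = sireCountries, mgsCountries = mgsCountries,
       cb = cb, cmgs = cmgs, overlap = intersect(cb, cmgs))
}
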
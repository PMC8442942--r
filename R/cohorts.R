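#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks, via
#' \code{stats::cor(method = "spearman")}.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar in [-1, 1].
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 values")
  stats::cor(x, y, method = "spearman")
}

#' Reliability class of an EBV
#'
#' Three classes with closed upper bounds: \code{REL <= 0.3},
#' \code{0.3 < REL <= 0.6} and \code{REL > 0.6}.
#'
#' @param rel reliability values in [0, 1).
#' @return factor with the three class labels.
#' @export
classifyRel <- function(rel) {
  if (any(rel < 0 | rel >= 1, na.rm = TRUE)) stop("REL must lie in [0, 1)")
  cut(rel, breaks = c(-Inf, 0.3, 0.6, Inf),
      labels = c("REL<=0.3", "0.3<REL<=0.6", "REL>0.6"), right = TRUE)
}

#' Re-ranking category from a rank correlation
#'
#' \code{none} when >= 0.990, \code{small} when in [0.980, 0.990),
#' \code{large} otherwise.
#'
#' @param rankCorr rank correlations in [-1, 1].
#' @return character vector of categories.
#' @export
rerankCategory <- function(rankCorr) {
  ifelse(rankCorr >= 0.990, "none",
         ifelse(rankCorr >= 0.980, "small", "large"))
}

#' Per-sire progeny and reliability statistics
#'
#' For every animal appearing as a sire: recorded progeny across all
#' countries, daughters with recorded progeny, recorded grand-progeny
#' through daughters, and the maximum direct/maternal reliability over
#' country scales (NA when the result carries no reliabilities).
#'
#' @param ped a [Pedigree-class].
#' @param phen a [PhenotypeTable-class].
#' @param result an [EvaluationResult-class], ideally with reliabilities.
#' @return data.frame with one row per sire.
#' @export
computeSireStats <- function(ped, phen, result) {
  n <- length(ped@id)
  hasRec <- logical(n)
  hasRec[phen@animal] <- TRUE
  sires <- sort(unique(ped@sire[!is.na(ped@sire)]))
  progRec <- daughtersRec <- grandRec <- integer(length(sires))
  for (k in seq_along(sires)) {
    ss <- sires[k]
    off <- which(!is.na(ped@sire) & ped@sire == ss)
    progRec[k] <- sum(hasRec[off])
    daughters <- off[ped@sex[off] == "F"]
    if (length(daughters)) {
      nGrand <- vapply(daughters, function(dd)
        sum(hasRec[which(!is.na(ped@dam) & ped@dam == dd)]), 1L)
      daughtersRec[k] <- sum(nGrand > 0L)
      grandRec[k] <- sum(nGrand)
    }
  }
  relD <- relM <- rep(NA_real_, length(sires))
  if (!is.null(result@rel)) {
    relD <- apply(reliability(result, "direct")[sires, , drop = FALSE], 1, max)
    relM <- apply(reliability(result, "maternal")[sires, , drop = FALSE], 1, max)
  }
  data.frame(sire = ped@id[sires], code = sires,
             progenyRecorded = progRec,
             daughtersWithRecordedProgeny = daughtersRec,
             recordedGrandProgeny = grandRec,
             maxRelDirect = relD, maxRelMaternal = relM,
             stringsAsFactors = FALSE)
}

#' Publishable sires for direct and maternal international EBVs
#'
#' Direct: maximum direct REL >= 0.5 on at least one country scale and
#' >= 25 recorded progeny across countries. Maternal: a publishable direct
#' EBV, maximum maternal REL >= 0.3, >= 15 daughters with recorded progeny
#' and >= 25 recorded grand-progeny from daughters.
#'
#' @param stats output of [computeSireStats()].
#' @param relDirect,relMaternal REL thresholds (defaults 0.5, 0.3).
#' @param minProgeny,minDaughters,minGrandProgeny count thresholds
#'   (defaults 25, 15, 25).
#' @return list with character vectors \code{direct} and \code{maternal}.
#' @export
selectPublishable <- function(stats, relDirect = 0.5, relMaternal = 0.3,
                              minProgeny = 25L, minDaughters = 15L,
                              minGrandProgeny = 25L) {
  dirOk <- !is.na(stats$maxRelDirect) & stats$maxRelDirect >= relDirect &
    stats$progenyRecorded >= minProgeny
  matOk <- dirOk & !is.na(stats$maxRelMaternal) &
    stats$maxRelMaternal >= relMaternal &
    stats$daughtersWithRecordedProgeny >= minDaughters &
    stats$recordedGrandProgeny >= minGrandProgeny
  list(direct = stats$sire[dirOk], maternal = stats$sire[matOk])
}

#' Young sires: publishable direct EBV but uninformative maternal EBV
#'
#' Direct-publishable sires whose maternal REL is strictly below the
#' threshold on every country scale.
#'
#' @inheritParams selectPublishable
#' @param relBelow strict maternal REL upper bound (default 0.3).
#' @return character vector of sire labels.
#' @export
selectYoungSires <- function(stats, relBelow = 0.3, relDirect = 0.5,
                             minProgeny = 25L) {
  pub <- selectPublishable(stats, relDirect = relDirect, minProgeny = minProgeny)
  young <- stats$sire %in% pub$direct & !is.na(stats$maxRelMaternal) &
    stats$maxRelMaternal < relBelow
  stats$sire[young]
}

#' Top-k overlap and mean rank shift between two rankings
#'
#' Counts how many of the top \code{k} candidates by \code{ebvA} are also in
#' the top \code{k} by \code{ebvB}, and the mean absolute change in rank of
#' A's top-k when re-ranked under B. Ranks are computed within the common
#' candidate set; with fewer than \code{k} candidates all are used and the
#' result is flagged.
#'
#' @param ebvA,ebvB named numeric vectors (names identify animals) over the
#'   candidate sets of the two scenarios.
#' @param k list size (default 100).
#' @return list with \code{overlap}, \code{meanShift}, \code{kUsed},
#'   \code{truncated}.
#' @export
topKOverlap <- function(ebvA, ebvB, k = 100L) {
  common <- intersect(names(ebvA), names(ebvB))
  if (!length(common)) stop("no common candidates")
  a <- ebvA[common]; b <- ebvB[common]
  kUsed <- min(k, length(common))
  rkA <- rank(-a, ties.method = "first")
  rkB <- rank(-b, ties.method = "first")
  topA <- common[rkA <= kUsed]
  topB <- common[rkB <= kUsed]
  list(overlap = length(intersect(topA, topB)),
       meanShift = mean(abs(rkA[topA] - rkB[topA])),
       kUsed = kUsed, truncated = kUsed < k)
}

#' EBV standard deviation within an animal group
#'
#' Sample standard deviation (n - 1) of EBVs per country scale and effect.
#'
#' @param result an [EvaluationResult-class].
#' @param group integer internal codes or character animal labels.
#' @return matrix countries x effects of SDs (kg).
#' @export
ebvSdByGroup <- function(result, group) {
  if (length(group) < 2L) stop("group must have at least 2 animals")
  m <- result@ebv[group, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  nc <- length(result@countries)
  out <- cbind(direct = sds[seq_len(nc)], maternal = sds[nc + seq_len(nc)])
  rownames(out) <- result@countries
  out
}

#' Cohort-wise re-ranking report between scenarios
#'
#' Mirrors the structure of published between-scenario comparisons:
#' Spearman rank correlations of direct and maternal EBVs per scenario
#' pair, country scale and cohort (all animals, common bulls, publishable
#' sires, young sires, and the three REL classes), top-k overlap among
#' publishable sires, and domestic EBV standard deviations per scenario.
#' Cohorts and REL classes are defined under \code{relScenario}
#' (REF in the published design).
#'
#' @param results named list of [EvaluationResult-class] objects.
#' @param ped a [Pedigree-class].
#' @param phen a [PhenotypeTable-class].
#' @param pairs list of character 2-vectors of scenario names; default all
#'   pairs of REF against CUR and NONE that are present.
#' @param relScenario scenario whose reliabilities define cohorts
#'   (default "REF"); that result must carry reliabilities.
#' @param k top-list size (default 100).
#' @return a [ComparisonReport-class].
#' @export
buildComparisonReport <- function(results, ped, phen, pairs = NULL,
                                  relScenario = "REF", k = 100L) {
  if (is.null(pairs)) {
    pairs <- list()
    for (s2 in c("CUR", "NONE"))
      if (all(c("REF", s2) %in% names(results)))
        pairs <- c(pairs, list(c("REF", s2)))
  }
  if (length(results) < 2L || !length(pairs))
    stop("need at least two evaluated scenarios and one pair")
  relRes <- results[[relScenario]]
  if (is.null(relRes) || is.null(relRes@rel))
    stop("scenario '", relScenario, "' with reliabilities is required for cohorts")
  stats <- computeSireStats(ped, phen, relRes)
  pub <- selectPublishable(stats)
  young <- selectYoungSires(stats)
  conn <- findConnections(ped, phen)
  cn <- relRes@countries
  N <- nrow(relRes@ebv)
  ids <- rownames(relRes@ebv)

  cohortIdx <- function(cohort, eff, cc) {
    switch(cohort,
      all = seq_len(N),
      cb = match(conn$cb, ids),
      publishable = match(if (eff == "direct") pub$direct else pub$maternal, ids),
      young = match(young, ids),
      stop("unknown cohort"))
  }
  relClasses <- function(eff, cc)
    classifyRel(reliability(relRes, eff, cc)[, 1])

  rcRows <- list(); szRows <- list(); tkRows <- list()
  for (pr in pairs) {
    rA <- results[[pr[1]]]; rB <- results[[pr[2]]]
    if (!identical(rownames(rA@ebv), rownames(rB@ebv)))
      stop("scenario results cover different animals")
    prLab <- paste(pr, collapse = "-")
    for (cc in cn) for (eff in c("direct", "maternal")) {
      lab <- paste0(eff, ".", cc)
      addRow <- function(cohort, idx) {
        idx <- idx[!is.na(idx)]
        if (length(idx) < 3L) return()
        rho <- spearmanCor(rA@ebv[idx, lab], rB@ebv[idx, lab])
        rcRows[[length(rcRows) + 1L]] <<- data.frame(
          pair = prLab, country = cc, effect = eff, cohort = cohort,
          n = length(idx), rho = rho, category = rerankCategory(rho),
          stringsAsFactors = FALSE)
      }
      addRow("all", cohortIdx("all", eff, cc))
      addRow("cb", cohortIdx("cb", eff, cc))
      addRow("publishable", cohortIdx("publishable", eff, cc))
      addRow("young", cohortIdx("young", eff, cc))
      cls <- relClasses(eff, cc)
      for (lv in levels(cls))
        addRow(lv, which(cls == lv))
      # top-k among publishable sires (REL-scenario publishable set)
      cand <- match(if (eff == "direct") pub$direct else pub$maternal, ids)
      cand <- cand[!is.na(cand)]
      if (length(cand) >= 3L) {
        tk <- topKOverlap(stats::setNames(rA@ebv[cand, lab], ids[cand]),
                          stats::setNames(rB@ebv[cand, lab], ids[cand]), k = k)
        tkRows[[length(tkRows) + 1L]] <- data.frame(
          pair = prLab, country = cc, effect = eff, k = tk$kUsed,
          overlap = tk$overlap, meanShift = tk$meanShift,
          truncated = tk$truncated, stringsAsFactors = FALSE)
      }
    }
  }
  szRows <- data.frame(
    cohort = c("cb", "publishable.direct", "publishable.maternal", "young"),
    n = c(length(conn$cb), length(pub$direct), length(pub$maternal),
          length(young)), stringsAsFactors = FALSE)

  sdRows <- list()
  for (sc in names(results)) for (cc in cn) {
    dom <- domesticSet(ped, phen, cc)
    if (length(dom) < 2L) next
    sds <- ebvSdByGroup(results[[sc]], dom)
    sdRows[[length(sdRows) + 1L]] <- data.frame(
      scenario = sc, country = cc,
      direct = sds[cc, "direct"], maternal = sds[cc, "maternal"],
      n = length(dom), stringsAsFactors = FALSE)
  }
  new("ComparisonReport",
      rankCorrelations = do.call(rbind, rcRows),
      topk = if (length(tkRows)) do.call(rbind, tkRows) else data.frame(),
      ebvSd = do.call(rbind, sdRows),
      cohortSizes = szRows)
}
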
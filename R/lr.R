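#' LR-method ratio of population accuracies
#'
#' Pearson correlation between EBVs of a partial and a whole evaluation,
#' computed from the centered cross-products. Under the LR method this
#' estimates the ratio acc_p / acc_w of population accuracies.
#'
#' @param uP,uW aligned EBV vectors (kg) of the partial and whole
#'   evaluation over a common animal set (length >= 3, no missing values).
#' @return scalar in [-1, 1].
#' @export
rhoPW <- function(uP, uW) {
  if (length(uP) != length(uW)) stop("EBV vectors must be aligned")
  if (length(uP) < 3L) stop("need at least 3 animals")
  if (anyNA(uP) || anyNA(uW)) stop("missing EBVs are not allowed")
  p <- uP - mean(uP)
  w <- uW - mean(uW)
  den <- sqrt(sum(w * w) * sum(p * p))
  if (den == 0) stop("zero variance in EBVs")
  sum(p * w) / den
}

#' Relative increase in population accuracy
#'
#' The percent gain \eqn{(1/\rho - 1) \cdot 100} implied by an accuracy
#' ratio \eqn{\rho = acc_p / acc_w}; e.g. \eqn{\rho = 0.8} means the whole
#' evaluation increased accuracy by 25\%.
#'
#' @param rho accuracy ratio in (0, 1].
#' @return percent increase.
#' @examples
#' accuracyIncrease(0.8)  # 25
#' @export
accuracyIncrease <- function(rho) {
  if (any(rho <= 0) || any(rho > 1 + 1e-12))
    stop("rho must lie in (0, 1] for the ratio interpretation")
  (1 / rho - 1) * 100
}

#' LR-method dispersion estimator
#'
#' Slope of the regression of whole-evaluation EBVs on partial-evaluation
#' EBVs, \eqn{cov(\hat u_w, \hat u_p) / var(\hat u_p)}; expectation 1 when
#' both evaluations are equally dispersed.
#'
#' @inheritParams rhoPW
#' @return scalar slope.
#' @export
dispersionB <- function(uP, uW) {
  if (length(uP) != length(uW)) stop("EBV vectors must be aligned")
  if (length(uP) < 3L) stop("need at least 3 animals")
  p <- uP - mean(uP)
  vp <- sum(p * p)
  if (vp == 0) stop("zero variance in partial EBVs")
  sum(p * (uW - mean(uW))) / vp
}

#' LR validation report over scenario pairs
#'
#' For each ordered (partial, whole) scenario pair, country scale and
#' effect, computes the accuracy ratio rho, the percent accuracy increase
#' and the dispersion slope. Pairs involving NAT are evaluated on each
#' country's domestic set (taken from the NAT result); other pairs on all
#' animals.
#'
#' @param results named list of [EvaluationResult-class] objects, names
#'   being scenario names.
#' @param pairs list of character 2-vectors \code{c(partial, whole)};
#'   default compares NONE against CUR and REF, and NAT against CUR and REF
#'   when present.
#' @return data.frame with columns pair, country, effect, group, n, rho,
#'   increase_pct, b_slope.
#' @export
lrReport <- function(results, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- list()
    for (w in c("CUR", "REF")) {
      if ("NONE" %in% names(results) && w %in% names(results))
        pairs <- c(pairs, list(c("NONE", w)))
      if ("NAT" %in% names(results) && w %in% names(results))
        pairs <- c(pairs, list(c("NAT", w)))
    }
  }
  rows <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(results)))
      stop("missing scenario results for pair ", paste(pr, collapse = "-"))
    rp <- results[[pr[1]]]; rw <- results[[pr[2]]]
    if (!identical(rownames(rp@ebv), rownames(rw@ebv)))
      stop("scenario results cover different animal sets")
    cn <- rp@countries
    domestic <- "NAT" %in% pr
    domres <- if (domestic) results[["NAT"]] else NULL
    for (cc in cn) for (eff in c("direct", "maternal")) {
      lab <- paste0(eff, ".", cc)
      sel <- if (domestic) domres@domestic[[cc]] else seq_len(nrow(rp@ebv))
      if (length(sel) < 3L) next
      p <- rp@ebv[sel, lab]; w <- rw@ebv[sel, lab]
      rho <- rhoPW(p, w)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(pr, collapse = "-"), country = cc, effect = eff,
        group = if (domestic) "domestic" else "all",
        n = length(sel), rho = rho,
        increase_pct = if (rho > 0) accuracyIncrease(min(rho, 1)) else NA_real_,
        b_slope = dispersionB(p, w), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
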
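.writeHeader <- function(con, meta) {
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
}

.readTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a pedigree file
#'
#' Delimited text (tab, comma or whitespace), one row per animal, unknown
#' parents coded "0" or empty. Columns are located through \code{dialect},
#' a named map from the roles \code{animal}, \code{sire}, \code{dam} and
#' optionally \code{birth_year}, \code{sex}, \code{country} to column names
#' or positions. With a header row matching the default names no dialect is
#' needed.
#'
#' @param path file path.
#' @param dialect named list or character vector mapping roles to columns.
#' @param ... passed to [pedigree()] (e.g. \code{computeF}).
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, dialect = NULL, ...) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  hasHeader <- grepl("animal", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (is.null(dialect)) {
    dialect <- list(animal = 1, sire = 2, dam = 3)
    if (hasHeader) {
      nm <- tolower(names(df))
      dialect <- as.list(stats::setNames(
        match(c("animal", "sire", "dam", "birth_year", "sex", "country"), nm),
        c("animal", "sire", "dam", "birth_year", "sex", "country")))
      dialect <- dialect[!is.na(unlist(dialect))]
    }
  }
  col <- function(role) if (is.null(dialect[[role]])) NULL else df[[dialect[[role]]]]
  pedigree(col("animal"), col("sire"), col("dam"),
           birthYear = if (!is.null(col("birth_year")))
             suppressWarnings(as.integer(col("birth_year"))),
           sex = col("sex"), country = col("country"), ...)
}

#' Write a pedigree file
#'
#' Tab-delimited with header \code{animal sire dam birth_year sex country};
#' unknown entries written as "0". Re-reading reproduces the identical
#' internal structure.
#'
#' @param ped a [Pedigree-class].
#' @param path output path.
#' @param meta optional named list written as \code{# key: value} comments.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path, meta = NULL) {
  z <- function(x) ifelse(is.na(x), "0", x)
  df <- data.frame(animal = ped@id,
                   sire = z(ped@id[ped@sire]),
                   dam = z(ped@id[ped@dam]),
                   birth_year = z(as.character(ped@birthYear)),
                   sex = z(ped@sex), country = z(ped@country))
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, meta)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype file
#'
#' Tab-delimited with columns \code{animal}, \code{dam}, \code{country},
#' \code{aww_kg} and any factor columns; animal/dam are external labels
#' resolved against the pedigree.
#'
#' @param path file path.
#' @param ped the [Pedigree-class] the records refer to.
#' @return a [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path, ped) {
  df <- .readTable(path)
  need <- c("animal", "dam", "country", "aww_kg")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  an <- match(as.character(df$animal), ped@id)
  if (anyNA(an)) stop("phenotype animal not in pedigree: ",
                      df$animal[is.na(an)][1])
  dm <- match(as.character(df$dam), ped@id)
  fac <- df[, setdiff(names(df), need), drop = FALSE]
  fac[] <- lapply(fac, as.character)
  new("PhenotypeTable", animal = an, dam = dm,
      country = as.character(df$country), aww = as.numeric(df$aww_kg),
      factors = fac)
}

#' Write a phenotype file
#'
#' @param phen a [PhenotypeTable-class].
#' @param ped the matching [Pedigree-class].
#' @param path output path.
#' @param meta optional header comments.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(phen, ped, path, meta = NULL) {
  df <- cbind(data.frame(animal = ped@id[phen@animal],
                         dam = ifelse(is.na(phen@dam), "0", ped@id[phen@dam]),
                         country = phen@country,
                         aww_kg = phen@aww),
              phen@factors)
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, meta)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation result
#'
#' One row per animal with EBV (and REL when present) per country scale and
#' effect; scenario and solver metadata as header comments.
#'
#' @param result an [EvaluationResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationResult <- function(result, path) {
  df <- data.frame(animal = rownames(result@ebv), result@ebv,
                   check.names = FALSE)
  if (!is.null(result@rel)) {
    rel <- result@rel
    colnames(rel) <- paste0("rel.", colnames(result@ebv))
    df <- cbind(df, rel)
  }
  meta <- c(list(scenario = result@scenario),
            result@solver[c("iterations", "convergence", "relResidual",
                            "bent", "bendIterations")])
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, meta)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an evaluation result written by [writeEvaluationResult()]
#'
#' @param path file path.
#' @param countries country labels of the evaluation.
#' @return an [EvaluationResult-class] (solver metadata reduced to what the
#'   header carries).
#' @export
readEvaluationResult <- function(path, countries) {
  hdr <- grep("^# ", readLines(path, n = 20L), value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*", "", kv); v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- v
  }
  df <- .readTable(path)
  lab <- .traitLabels(countries)
  ebvM <- as.matrix(df[, lab])
  rownames(ebvM) <- df$animal
  relCols <- paste0("rel.", lab)
  rel <- NULL
  if (all(relCols %in% names(df))) {
    rel <- as.matrix(df[, relCols])
    dimnames(rel) <- list(df$animal, lab)
  }
  new("EvaluationResult", scenario = meta$scenario %||% "unknown",
      countries = countries, ebv = ebvM, rel = rel,
      solver = meta, domestic = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to a directory
#'
#' Produces \code{pedigree.tsv}, \code{phenotypes.tsv}, \code{params.yaml}
#' and \code{tbv.tsv} (true breeding values, for validation only). Every
#' file header records the seed; identical configs give byte-identical
#' files. The evaluation inputs are complete without \code{tbv.tsv}.
#'
#' @param dat list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = dat$cfg@seed, generator = "amaci")
  writePedigree(dat$ped, file.path(dir, "pedigree.tsv"), meta = meta)
  writePhenotypes(dat$phen, dat$ped, file.path(dir, "phenotypes.tsv"), meta = meta)
  writeParams(dat$params, file.path(dir, "params.yaml"))
  con <- file(file.path(dir, "tbv.tsv"), "w")
  .writeHeader(con, meta)
  utils::write.table(data.frame(animal = rownames(dat$tbv), dat$tbv,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir directory containing \code{pedigree.tsv},
#'   \code{phenotypes.tsv} and \code{params.yaml} (and optionally
#'   \code{tbv.tsv}).
#' @return list with \code{ped}, \code{phen}, \code{params} and \code{tbv}
#'   (NULL when absent).
#' @export
readDataset <- function(dir) {
  ped <- readPedigree(file.path(dir, "pedigree.tsv"))
  phen <- readPhenotypes(file.path(dir, "phenotypes.tsv"), ped)
  params <- readParams(file.path(dir, "params.yaml"))
  tbvPath <- file.path(dir, "tbv.tsv")
  tbv <- NULL
  if (file.exists(tbvPath)) {
    df <- .readTable(tbvPath)
    tbv <- as.matrix(df[, -1, drop = FALSE])
    rownames(tbv) <- df$animal
    tbv <- tbv[ped@id, , drop = FALSE]
  }
  list(ped = ped, phen = phen, params = params, tbv = tbv)
}

#' Write a comparison report as delimited tables
#'
#' Produces \code{rank_correlations.tsv}, \code{topk_overlap.tsv},
#' \code{ebv_sd.tsv} and \code{cohort_membership.tsv}.
#'
#' @param report a [ComparisonReport-class].
#' @param dir output directory.
#' @param meta optional header comments.
#' @return \code{dir}, invisibly.
#' @export
writeComparisonReport <- function(report, dir, meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    con <- file(file.path(dir, name), "w"); on.exit(close(con))
    .writeHeader(con, meta)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report@rankCorrelations, "rank_correlations.tsv")
  wt(report@topk, "topk_overlap.tsv")
  wt(report@ebvSd, "ebv_sd.tsv")
  wt(report@cohortSizes, "cohort_membership.tsv")
  invisible(dir)
}
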
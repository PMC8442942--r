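#' Simulate a dataset and write it to disk
#'
#' @param cfg a [SimConfig-class] (or a YAML config path readable by
#'   [readRunConfig()]).
#' @param outDir output directory.
#' @return the dataset directory, invisibly.
#' @export
cmdSimulate <- function(cfg, outDir) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)$sim
  dat <- simulateDataset(cfg)
  writeDataset(dat, outDir)
}

#' Evaluate scenarios on a dataset directory
#'
#' Runs [runScenario()] for each requested scenario and writes one EBV/REL
#' table per scenario plus a small log recording PSD status, bending and
#' PCG iterations.
#'
#' @param dataDir directory from [cmdSimulate()] / [writeDataset()].
#' @param outDir output directory.
#' @param scenarios character vector among REF, CUR, NONE, NAT.
#' @param pcgTol PCG convergence criterion (default 1e-7).
#' @param bendThreshold bending threshold (default 1e-3).
#' @param computeRel compute exact reliabilities (desk scale, default
#'   FALSE).
#' @param relGuard,maxIter guards for reliabilities and PCG.
#' @return named list of [EvaluationResult-class], invisibly.
#' @export
cmdEvaluate <- function(dataDir, outDir, scenarios = c("REF", "CUR", "NONE", "NAT"),
                        pcgTol = 1e-7, bendThreshold = 1e-3,
                        computeRel = FALSE, relGuard = 20000L,
                        maxIter = 5000L) {
  dat <- readDataset(dataDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  logLines <- character(0)
  for (sc in scenarios) {
    res <- runScenario(dat$phen, dat$ped, dat$params, scenario = sc,
                       tol = pcgTol, bendThreshold = bendThreshold,
                       computeRel = computeRel, relGuard = relGuard,
                       maxIter = maxIter)
    results[[sc]] <- res
    writeEvaluationResult(res, file.path(outDir, sprintf("ebv_%s.tsv", sc)))
    logLines <- c(logLines, sprintf(
      "%s: minEigen=%.4g bent=%s bendIter=%d pcgIter=%d conv=%.3g relres=%.3g",
      sc, res@solver$minEigenBefore, res@solver$bent,
      res@solver$bendIterations, res@solver$iterations,
      res@solver$convergence, res@solver$relResidual))
  }
  writeLines(logLines, file.path(outDir, "evaluation.log"))
  invisible(results)
}

#' Compare evaluated scenarios: re-ranking and LR reports
#'
#' @param dataDir dataset directory.
#' @param evalDir directory with \code{ebv_<scenario>.tsv} files.
#' @param outDir report output directory.
#' @param scenarios scenarios to load (default: all files found).
#' @param k top-list size (default 100).
#' @return list with the [ComparisonReport-class] and the LR data.frame,
#'   invisibly.
#' @export
cmdCompare <- function(dataDir, evalDir, outDir, scenarios = NULL, k = 100L) {
  dat <- readDataset(dataDir)
  if (is.null(scenarios)) {
    files <- list.files(evalDir, pattern = "^ebv_.*\\.tsv$")
    scenarios <- sub("^ebv_(.*)\\.tsv$", "\\1", files)
  }
  if (length(scenarios) < 2L) stop("need at least two evaluated scenarios")
  results <- stats::setNames(lapply(scenarios, function(sc)
    readEvaluationResult(file.path(evalDir, sprintf("ebv_%s.tsv", sc)),
                         dat$params@countries)), scenarios)
  if ("NAT" %in% scenarios)   # domestic sets are recomputed from the data
    results$NAT@domestic <- stats::setNames(
      lapply(dat$params@countries, function(cc)
        domesticSet(dat$ped, dat$phen, cc)), dat$params@countries)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rep_ <- NULL
  if (!is.null(results$REF) && !is.null(results$REF@rel)) {
    rep_ <- buildComparisonReport(results, dat$ped, dat$phen, k = k)
    writeComparisonReport(rep_, outDir,
                          meta = list(scenarios = paste(scenarios, collapse = ",")))
  }
  lr <- lrReport(results)
  if (!is.null(lr)) {
    con <- file(file.path(outDir, "lr_report.tsv"), "w")
    .writeHeader(con, list(scenarios = paste(scenarios, collapse = ",")))
    utils::write.table(lr, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(list(comparison = rep_, lr = lr))
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys: \code{seed}, \code{scenarios}, \code{pcg_tol},
#' \code{bend_threshold}, \code{top_k}, \code{compute_rel}, \code{out_dir}
#' and a \code{sim:} block with [simConfig()] arguments
#' (\code{n_per_generation}, \code{generations},
#' \code{recorded_generations}, \code{herds_per_country},
#' \code{progeny_per_dam}, \code{dams_per_sire}, \code{p_abroad},
#' \code{params_file}).
#'
#' @param path YAML file.
#' @return list with \code{sim} (a [SimConfig-class]) and the remaining
#'   settings.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$sim %||% list()
  params <- if (!is.null(sim$params_file)) readParams(sim$params_file)
            else defaultParams()
  cfg <- simConfig(
    seed = y$seed %||% 1L, params = params,
    nPerGeneration = sim$n_per_generation %||% 2500L,
    generations = sim$generations %||% 3L,
    recordedGenerations = sim$recorded_generations %||% 2L,
    herdsPerCountry = sim$herds_per_country %||% 5L,
    progenyPerDam = sim$progeny_per_dam %||% 3L,
    damsPerSire = sim$dams_per_sire %||% 10L,
    pAbroad = sim$p_abroad %||% 0.2)
  list(sim = cfg,
       scenarios = y$scenarios %||% c("REF", "CUR", "NONE", "NAT"),
       pcgTol = y$pcg_tol %||% 1e-7,
       bendThreshold = y$bend_threshold %||% 1e-3,
       topK = y$top_k %||% 100L,
       computeRel = isTRUE(y$compute_rel),
       outDir = y$out_dir %||% "amaci_run")
}

#' Run the full pipeline: simulate, evaluate, compare
#'
#' Deterministic for a given config: identical config and seed give
#' byte-identical outputs.
#'
#' @param cfg a [SimConfig-class] or YAML config path.
#' @param outDir output root (subdirectories \code{data}, \code{eval},
#'   \code{reports}); defaults to the config's \code{out_dir} when a YAML
#'   path is given.
#' @param scenarios,pcgTol,bendThreshold,computeRel,k forwarded to the
#'   stages (YAML settings win when \code{cfg} is a path).
#' @return list of stage outputs, invisibly.
#' @export
runPipeline <- function(cfg, outDir = NULL,
                        scenarios = c("REF", "CUR", "NONE", "NAT"),
                        pcgTol = 1e-7, bendThreshold = 1e-3,
                        computeRel = FALSE, k = 100L) {
  if (is.character(cfg)) {
    rc <- readRunConfig(cfg)
    cfg <- rc$sim
    scenarios <- rc$scenarios; pcgTol <- rc$pcgTol
    bendThreshold <- rc$bendThreshold; computeRel <- rc$computeRel
    k <- rc$topK
    if (is.null(outDir)) outDir <- rc$outDir
  }
  if (is.null(outDir)) stop("outDir is required")
  dataDir <- file.path(outDir, "data")
  evalDir <- file.path(outDir, "eval")
  repDir <- file.path(outDir, "reports")
  cmdSimulate(cfg, dataDir)
  results <- cmdEvaluate(dataDir, evalDir, scenarios = scenarios,
                         pcgTol = pcgTol, bendThreshold = bendThreshold,
                         computeRel = computeRel)
  reports <- cmdCompare(dataDir, evalDir, repDir, scenarios = scenarios, k = k)
  invisible(list(results = results, reports = reports, outDir = outDir))
}
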
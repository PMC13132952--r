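## Configuration-driven orchestration of the analysis stages, with
## versioned artifacts (tables as CSV, fits as JSON, a plain-text log
## embedding package version, seed and config hash).

pipelineLog <- function(outDir, config, lines = character()) {
  log <- file.path(outDir, "run.log")
  hdr <- c(sprintf("twinpanel %s", as.character(packageVersion("twinpanel"))),
           sprintf("analysis: %s", config$analysis),
           sprintf("seed: %s", config$seed %||% "none"),
           sprintf("config_hash: %s", configHash(config)),
           lines)
  writeLines(hdr, log)
  log
}

writeFitJSON <- function(fit, path, extra = list()) {
  out <- c(list(model = fit@model@name,
                minus2LL = fit@minus2LL,
                converged = fit@converged,
                nPairs = as.list(fit@nPairs),
                estimates = as.list(fit@theta)),
           if (length(fit@se)) list(se = as.list(fit@se)),
           extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

loadPipelineData <- function(config) {
  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("input file not found: ", config$input)
    readTwinTable(config$input, schema = config$schema,
                  checkRanges = isTRUE(config$checkRanges))
  } else if (!is.null(config$scenario)) {
    sc <- do.call(simulationScenario, config$scenario)
    simulateScenario(sc, seed = config$seed)
  } else stop("config must provide 'input' or 'scenario'")
}

#' Run an analysis pipeline from a configuration
#'
#' Executes exactly one analysis stage per invocation and writes its
#' artifacts (CSV tables, JSON fits, a log with the package version, the
#' master seed and the config hash) to \code{outDir}. Stages:
#' \code{correlations}, \code{screen}, \code{fit-cholesky},
#' \code{fit-riclpm}, \code{simulate}, \code{recover}, and
#' \code{paper-pipeline}, which chains correlations, event screening, the
#' Cholesky AE/ACE comparison, RI-CLPMs for both negative event clusters,
#' and cross-lag likelihood-ratio tests.
#'
#' Report tables round shares to whole percents and estimates to two
#' decimals in their display columns; full-precision JSON is always
#' written alongside.
#'
#' @param config a named list or path to a YAML/JSON config file. Common
#'   fields: \code{analysis}, \code{seed} (mandatory for stochastic
#'   stages), \code{outDir}, and either \code{input} (+ optional
#'   \code{schema}, \code{checkRanges}) or \code{scenario} (arguments to
#'   \code{\link{simulationScenario}}).
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  analyses <- c("correlations", "screen", "fit-cholesky", "fit-riclpm",
                "simulate", "recover", "paper-pipeline")
  if (is.null(config$analysis) || !config$analysis %in% analyses)
    stop("config$analysis must be one of: ",
         paste(analyses, collapse = ", "))
  stochastic <- config$analysis %in%
    c("simulate", "recover", "paper-pipeline", "fit-cholesky", "fit-riclpm")
  if (stochastic && is.null(config$seed))
    stop("config$seed is mandatory for stochastic analyses")
  outDir <- config$outDir %||% stop("config$outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  arts <- switch(config$analysis,
    "correlations" = stageCorrelations(config, outDir),
    "screen" = stageScreen(config, outDir),
    "fit-cholesky" = stageCholesky(config, outDir),
    "fit-riclpm" = stageRiclpm(config, outDir),
    "simulate" = stageSimulate(config, outDir),
    "recover" = stageRecover(config, outDir),
    "paper-pipeline" = stagePaper(config, outDir))
  arts$log <- pipelineLog(outDir, config,
                          sprintf("artifact: %s", unlist(arts)))
  invisible(arts)
}

stageCorrelations <- function(config, outDir, ds = NULL) {
  ds <- ds %||% loadPipelineData(config)
  rep <- phenotypicCorrelations(ds, variables = config$variables,
                                alpha = config$alpha %||% 0.05)
  csv <- file.path(outDir, "correlations.csv")
  write.csv(rep, csv, row.names = FALSE)
  js <- file.path(outDir, "correlations.json")
  jsonlite::write_json(rep, js, digits = NA, na = "null")
  list(correlations_csv = csv, correlations_json = js)
}

stageScreen <- function(config, outDir, ds = NULL) {
  ds <- ds %||% loadPipelineData(config)
  rep <- phenotypicCorrelations(ds)
  dec <- screenEventCategory(rep, config$category %||% "posdep",
                             threshold = config$threshold %||% 0.10,
                             alpha = config$alpha %||% 0.05)
  js <- file.path(outDir, paste0("screen_", dec$category, ".json"))
  jsonlite::write_json(dec, js, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  list(screen_json = js)
}

## Table-1-style report: twin correlations plus standardized components
choleskyReport <- function(ds, fit, variables, outDir, tag = "") {
  fitSE <- standardErrors(fit, ds)
  sc <- standardizedComponents(fitSE)
  tw <- do.call(rbind, lapply(seq_along(variables), function(w) {
    tc <- twinCorrelations(ds, variables[w])
    data.frame(wave = w,
               rMZ = sprintf("%.2f [%.2f, %.2f]", tc$r[1], tc$lower[1],
                             tc$upper[1]),
               rDZ = sprintf("%.2f [%.2f, %.2f]", tc$r[2], tc$lower[2],
                             tc$upper[2]))
  }))
  fmt <- function(v, lo, hi) sprintf("%.2f [%.2f, %.2f]", v, lo, hi)
  tab <- data.frame(variable = variables, tw[, c("rMZ", "rDZ")],
                    a2 = fmt(sc$a2, sc$a2_lower, sc$a2_upper),
                    e2 = fmt(sc$e2, sc$e2_lower, sc$e2_upper))
  csv <- file.path(outDir, paste0("table1_components", tag, ".csv"))
  write.csv(tab, csv, row.names = FALSE)
  js <- file.path(outDir, paste0("cholesky_fit", tag, ".json"))
  writeFitJSON(fitSE, js, extra = list(standardized = sc))
  list(table1_csv = csv, cholesky_json = js)
}

stageCholesky <- function(config, outDir, ds = NULL) {
  ds <- ds %||% loadPipelineData(config)
  variables <- config$variables %||% c("wb1", "wb2", "wb3")
  opts <- config$optimizer %||% list()
  opts$seed <- opts$seed %||% config$seed
  cmp <- compareAceAe(ds, variables, opts)
  fit <- cmp$fits[[cmp$selected]]
  arts <- choleskyReport(ds, fit, variables, outDir)
  arts$selection <- file.path(outDir, "cholesky_selection.json")
  jsonlite::write_json(list(selected = cmp$selected,
                            aic = as.list(cmp$aic), dAIC = cmp$dAIC),
                       arts$selection, auto_unbox = TRUE, digits = NA)
  arts
}

## Table-2/3-style reports for one RI-CLPM fit
riclpmReport <- function(ds, fit, outDir, tag) {
  fitSE <- standardErrors(fit, ds)
  rv <- riVarianceShares(fitSE)
  sp <- standardizePaths(fitSE)
  shX <- rv$shares[rv$shares$trait == "x", ]
  spl <- rv$riSplit[rv$riSplit$trait == "x", ]
  t2 <- data.frame(measure = "wellbeing",
                   wave1 = sprintf("%.0f%%", 100 * shX$riShare[1]),
                   wave2 = sprintf("%.0f%%", 100 * shX$riShare[2]),
                   wave3 = sprintf("%.0f%%", 100 * shX$riShare[3]))
  for (k in spl$component)
    t2[[k]] <- sprintf("%.0f%%", 100 * spl$share[spl$component == k])
  t2csv <- file.path(outDir, paste0("table2_ri_shares_", tag, ".csv"))
  write.csv(t2, t2csv, row.names = FALSE)
  cl <- sp[sp$from != sp$to, ]
  t3 <- data.frame(path = cl$label,
                   estimate = sprintf("%.2f (%.3f)", cl$std,
                                      cl$stdSE %||% NA))
  t3csv <- file.path(outDir, paste0("table3_crosslags_", tag, ".csv"))
  write.csv(t3, t3csv, row.names = FALSE)
  sat <- fitSaturated(ds, fit@model@variables)
  ind <- fitIndependence(ds, fit@model@variables)
  fi <- fitIndices(fit, sat, ind)
  js <- file.path(outDir, paste0("riclpm_fit_", tag, ".json"))
  writeFitJSON(fitSE, js,
               extra = list(riShares = rv$shares, riSplit = rv$riSplit,
                            paths = sp,
                            fitIndices = list(chisq = fi@chisq, df = fi@df,
                                              p = fi@p, cfi = fi@cfi,
                                              tli = fi@tli,
                                              rmsea = fi@rmsea,
                                              aic = fi@aic)))
  list(table2_csv = t2csv, table3_csv = t3csv, riclpm_json = js)
}

stageRiclpm <- function(config, outDir, ds = NULL) {
  ds <- ds %||% loadPipelineData(config)
  trait <- config$trait %||% "negdep"
  cfgY <- if (trait == "negind") c("A", "C", "E") else c("A", "E")
  model <- buildRiclpmModel(list(x = c("A", "E"), y = cfgY),
                            traits = c(x = "wb", y = trait),
                            constraints = config$constraints %||% character())
  opts <- config$optimizer %||% list()
  opts$seed <- opts$seed %||% config$seed
  fit <- fitModel(model, ds, opts)
  arts <- riclpmReport(ds, fit, outDir, trait)
  if (!is.null(config$lrt)) {
    lrt <- testLaggedPaths(ds, fit, config$lrt, opts)
    arts$lrt <- file.path(outDir, paste0("lrt_", trait, ".json"))
    jsonlite::write_json(list(constrained = lrt$constrained,
                              chisq = lrt$lrt$chisq, df = lrt$lrt$df,
                              p = lrt$lrt$p),
                         arts$lrt, auto_unbox = TRUE, digits = NA)
  }
  arts
}

stageSimulate <- function(config, outDir) {
  sc <- do.call(simulationScenario, config$scenario %||% list())
  ds <- simulateScenario(sc, seed = config$seed)
  csv <- file.path(outDir, "simulated_twins.csv")
  writeTwinTable(ds, csv)
  list(dataset_csv = csv)
}

stageRecover <- function(config, outDir) {
  sc <- do.call(simulationScenario,
                modifyList(config$scenario %||% list(),
                           list(seed = config$seed)))
  rep <- recoveryStudy(sc, nReplicates = config$nReplicates %||% 50,
                       fitOptions = config$optimizer %||% list(),
                       computeSE = isTRUE(config$computeSE))
  csv <- file.path(outDir, "recovery_summary.csv")
  write.csv(rep$summary, csv, row.names = FALSE)
  js <- file.path(outDir, "recovery.json")
  jsonlite::write_json(list(summary = rep$summary,
                            nonconverged = rep$nonconverged,
                            valid = rep$valid, seed = rep$seed),
                       js, auto_unbox = TRUE, digits = NA)
  list(recovery_csv = csv, recovery_json = js)
}

## demo dataset for the full-paper preset: wellbeing + negative dependent
## events from their joint generating model, negative independent events
## from theirs, and positive dependent events as pure noise (independent
## of wellbeing, so the screening step excludes them). The three parts
## are drawn independently; the demo exercises the pipeline, it does not
## claim a joint generating structure across clusters.
paperDemoData <- function(seed, nMZ = 550, nDZ = 890) {
  d1 <- simulatePairs(riclpmTruth("negdep")$model,
                      riclpmTruth("negdep")$theta, nMZ, nDZ, seed)
  d2 <- simulatePairs(riclpmTruth("negind")$model,
                      riclpmTruth("negind")$theta, nMZ, nDZ,
                      deriveSeed(seed, 101))
  restore <- withr_seed(deriveSeed(seed, 202))
  on.exit(restore())
  p <- d1@pairs
  for (v in grep("^negind", names(d2@pairs), value = TRUE))
    p[[v]] <- d2@pairs[[v]]
  for (w in TWIN_WAVES) for (t in 1:2)
    p[[twinCol(paste0("posdep", w), t)]] <- rnorm(nrow(p))
  TwinDataset(p)
}

stagePaper <- function(config, outDir) {
  ds <- if (!is.null(config$input) || !is.null(config$scenario))
    loadPipelineData(config)
  else paperDemoData(config$seed, config$nMZ %||% 550,
                     config$nDZ %||% 890)
  arts <- stageCorrelations(config, outDir, ds = ds)
  arts <- c(arts, stageScreen(config, outDir, ds = ds))
  arts <- c(arts, stageCholesky(config, outDir, ds = ds))
  for (trait in c("negdep", "negind")) {
    cfg <- modifyList(config, list(trait = trait, lrt = "no_crosslags"))
    arts <- c(arts, stageRiclpm(cfg, outDir, ds = ds))
  }
  arts
}
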
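#' @include inference.R simulate.R io.R
NULL

.logStage <- function(logPath, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = logPath, append = TRUE)
  message(line)
}

.validateRunConfig <- function(config) {
  if (is.null(config$seed)) stop("config: seed is required")
  if (is.null(config$simulate)) {
    if (is.null(config$paths))
      stop("config: either a 'simulate' block or input 'paths' are required")
    need <- c("regional", "occurrences", "traits", "community", "colonists")
    miss <- setdiff(need, names(config$paths))
    if (length(miss))
      stop("config: missing input path(s): ", paste(miss, collapse = ", "))
    if (is.null(config$traits) || !length(config$traits))
      stop("config: trait list is required for file input")
    if (is.null(config$focalSite))
      stop("config: focalSite is required for file input")
  }
  invisible(config)
}

#' Run the full establishment-prediction pipeline
#'
#' Executes (optionally) simulate, then preprocess, pool construction,
#' environmental and biotic neighborhood scans, colonist predictions at the
#' selected models, the full neighborhood-size validation grid, and the
#' establishment validation; writes scan.csv, predictions.csv, grid.csv,
#' validation.txt, report.txt, a stage log, and the configuration (verbatim,
#' as YAML) into the output directory. All stochastic stages derive their
#' seeds deterministically from `config$seed`, so re-running with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config a named list or path to a YAML file. Fields: `seed`
#'   (required); either `simulate` (a list of [simulationConfig()] arguments)
#'   or `paths` (named regional/occurrences/traits/community/colonists) plus
#'   `traits` (modelled trait names), `logTraits`, `traitKind`, `focalSite`
#'   and optional `minSites`; optional `sizes`, `schemes` (default
#'   none/all_pairwise/parsimonious), `gridScheme`, `subset` ("all" or
#'   "native_only"), `basis`, `rePrediction`.
#' @param outdir output directory (default `config$outdir`).
#' @return the output directory, invisibly; stage results are returned as the
#'   attribute "results".
#' @export
runAnalysis <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateRunConfig(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("config: output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "log.txt")
  cat("", file = logPath)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  sizes <- if (!is.null(config$sizes)) as.list(config$sizes) else
    c(list("NN"), as.list(seq(0.1, 1, by = 0.1)))
  sizes <- lapply(sizes, function(s)
    if (identical(s, "NN") || identical(toupper(as.character(s)), "NN")) "NN"
    else as.numeric(s))
  schemes <- if (!is.null(config$schemes)) config$schemes else
    c("none", "all_pairwise", "parsimonious")
  basis <- if (!is.null(config$basis)) config$basis else "per-trait"
  rePred <- if (!is.null(config$rePrediction)) config$rePrediction else "plot"
  subset <- if (!is.null(config$subset)) config$subset else "all"
  gridScheme <- if (!is.null(config$gridScheme)) config$gridScheme else
    schemes[length(schemes)]

  if (!is.null(config$simulate)) {
    .logStage(logPath, "simulate", "generating synthetic assembly")
    simCfg <- do.call(simulationConfig,
                      c(list(seed = config$seed), config$simulate))
    assembly <- simulateAssembly(simCfg)
    traits <- assembly$traits
    pool <- assembly$pool
    community <- assembly$community
    colonists <- assembly$colonists
  } else {
    .logStage(logPath, "read", "reading input tables")
    tabs <- readAssemblyTables(config$paths,
                               traitKind = unlist(config$traitKind),
                               transformLog = config$logTraits)
    .logStage(logPath, "preprocess", "standardizing traits")
    modelled <- config$traits
    tm <- traitMatrix(tabs$traits)[, modelled, drop = FALSE]
    tt <- new("TraitTable", traits = tm,
              traitKind = traitKind(tabs$traits)[modelled],
              transformLog = tabs$traits@transformLog[modelled])
    ref <- intersect(tabs$regional, speciesIds(tt))
    traits <- preprocessTraits(tt, referenceSpecies = ref)
    .logStage(logPath, "pools", "building the habitat-specific pool")
    pool <- buildHabitatPool(tabs$occurrences, tabs$regional,
                             focalSite = config$focalSite,
                             minSites = if (is.null(config$minSites)) 2L
                                        else config$minSites)
    community <- tabs$community[tabs$community$site_id == config$focalSite, ,
                                drop = FALSE]
    checkCommunity(community, pool)
    colonists <- tabs$colonists
  }

  .logStage(logPath, "scan", "environmental neighborhood scan")
  envScan <- scanNeighborhoods(pool, traits, "environmental",
                               sizes = sizes, schemes = schemes,
                               basis = basis)
  .logStage(logPath, "scan", "biotic neighborhood scan")
  bioScan <- scanNeighborhoods(pool, traits, "biotic",
                               community = community,
                               sizes = sizes, schemes = schemes,
                               basis = basis)
  scanTab <- rbind(cbind(filter = "environmental", scanTable(envScan)),
                   cbind(filter = "biotic", scanTable(bioScan)))
  utils::write.csv(scanTab, file.path(outdir, "scan.csv"),
                   row.names = FALSE)

  .logStage(logPath, "predict", "colonist establishment predictions")
  species <- unique(as.character(colonists$species_id))
  center <- computeCenter(pool, traits, community, basis = basis)
  pred <- predictEstablishment(selectedModel(envScan),
                               selectedModel(bioScan),
                               pool, traits, community, species,
                               center = center, basis = basis,
                               rePrediction = rePred)
  writePredictionsCsv(pred, file.path(outdir, "predictions.csv"),
                      site = as.character(colonists$site_id[1]))

  .logStage(logPath, "validate", "establishment validation")
  actual <- actualEstablishment(colonists)
  sites <- tapply(as.character(colonists$site_id),
                  as.character(colonists$species_id), function(s) s[1])
  keep <- pred$species
  if (identical(subset, "native_only") && "is_native" %in% names(colonists)) {
    native <- unique(colonists$species_id[as.logical(colonists$is_native)])
    keep <- intersect(keep, native)
  }
  validation <- validateEstablishment(
    stats::setNames(pred$p_overall, pred$species)[keep], actual,
    sites = stats::setNames(as.character(sites), names(sites)))
  utils::capture.output(print(validation),
                        file = file.path(outdir, "validation.txt"))

  .logStage(logPath, "grid", "neighborhood-size validation grid")
  grid <- predictionGrid(envScan, bioScan, pool, traits, community,
                         colonists, scheme = gridScheme, subset = subset,
                         center = center, basis = basis,
                         rePrediction = rePred)
  writeGridCsv(grid, file.path(outdir, "grid.csv"))

  results <- list(envScan = envScan, bioticScan = bioScan,
                  predictions = pred, validation = validation, grid = grid,
                  pool = pool)
  .logStage(logPath, "report", "writing report")
  makeReport(outdir, results = results)
  .logStage(logPath, "done", "run complete")
  out <- outdir
  attr(out, "results") <- results
  invisible(out)
}

#' Write a human-readable run report
#'
#' Summarizes a completed run: the selected neighborhood size and interaction
#' scheme per filter with the AICc ranking, the coefficient table of each
#' selected model, degeneracy flags, the establishment validation statistics,
#' and the adjusted R-squared grid over neighborhood-size combinations.
#'
#' @param dir a run directory produced by [runAnalysis()].
#' @param results optional in-memory results (used internally); when NULL the
#'   CSV outputs in `dir` are summarized instead.
#' @return path to report.txt, invisibly.
#' @export
makeReport <- function(dir, results = NULL) {
  if (!dir.exists(dir)) stop("run directory not found: ", dir)
  path <- file.path(dir, "report.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("Establishment-prediction run report")
  w("===================================")
  if (is.null(results)) {
    scanPath <- file.path(dir, "scan.csv")
    if (!file.exists(scanPath)) {
      w("INCOMPLETE RUN: scan.csv missing")
      warning("incomplete run; partial report written")
      return(invisible(path))
    }
    tab <- utils::read.csv(scanPath)
    for (f in unique(tab$filter)) {
      sub <- tab[tab$filter == f, ]
      best <- sub[which.min(ifelse(sub$degenerate, Inf, sub$aicc)), ]
      w(sprintf("%s filter: selected %s / %s (AICc %.2f)",
                f, best$size, best$scheme, best$aicc))
    }
    return(invisible(path))
  }
  for (nm in c("envScan", "bioticScan")) {
    scan <- results[[nm]]
    sel <- selectedModel(scan)
    w("")
    w(sprintf("%s filter", toupper(scan@filter)))
    w(sprintf("  selected model: %s neighborhood, %s scheme, AICc %.2f",
              sel@neighborhood@label, sel@scheme, aicc(sel)))
    if (sel@degenerate)
      w("  flags: ", paste(sel@degeneracyReasons, collapse = ", "))
    w("  AICc ranking (delta from best):")
    tab <- scanTable(scan)
    tab <- tab[order(tab$aicc), ]
    for (i in seq_len(min(8, nrow(tab))))
      w(sprintf("    %-4s %-13s %10.2f %8.2f %s", tab$size[i],
                tab$scheme[i], tab$aicc[i], tab$delta_aicc[i],
                ifelse(tab$degenerate[i],
                       paste0("[", tab$reasons[i], "]"), "")))
    deg <- scanTable(scan)
    deg <- deg[deg$degenerate, ]
    if (nrow(deg)) {
      w("  degenerate fits:")
      for (i in seq_len(nrow(deg)))
        w(sprintf("    %-4s %-13s %s", deg$size[i], deg$scheme[i],
                  deg$reasons[i]))
    }
    w("  coefficients (standardized):")
    ct <- coefTable(sel)
    for (i in seq_len(nrow(ct)))
      w(sprintf("    %-22s %8.3f  (p = %s)", rownames(ct)[i],
                ct[i, "estimate"],
                ifelse(is.na(ct[i, "p"]), "NA",
                       sprintf("%.3g", ct[i, "p"]))))
  }
  w("")
  w("VALIDATION")
  v <- results$validation
  w(sprintf("  predicted establishment: slope %.3f, t = %.2f, p = %.3g",
            v$slope, v$t, v$p))
  w(sprintf("  adjusted R^2 = %.3f (n = %d species)", v$adjR2, v$n))
  if (length(v$note)) w("  note: ", v$note)
  w("")
  w("ADJUSTED R^2 GRID (rows: environmental size, cols: biotic size)")
  g <- results$grid
  w("       ", paste(sprintf("%6s", colnames(g)), collapse = " "))
  for (i in seq_len(nrow(g)))
    w(sprintf("  %-5s", rownames(g)[i]),
      paste(sprintf("%6s", ifelse(is.na(g[i, ]), "    NA",
                                  sprintf("%6.3f", g[i, ]))), collapse = " "))
  invisible(path)
}
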
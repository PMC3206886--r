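# End-to-end orchestration: simulate (optional) -> motion QC -> temporal
# preprocessing -> connectivity -> thresholded metrics -> targeted attack
# -> group statistics, with every stage written to disk and all
# randomness flowing from named seeds.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Numeric defaults follow
#' the emulated study where it states them: band 0.01-0.08 Hz, motion
#' limits 1.5 mm / 1.5 degrees, sparsity sweep 0.15-0.25 in 0.01 steps,
#' analysis sparsity 0.15, FDR level 0.05. Unknown arguments are rejected
#' (the constructor has no dots).
#'
#' @param inputDir directory holding \code{subjects.csv},
#'   \code{timeseries/}, \code{nuisance/}; \code{NULL} (default) simulates
#'   a cohort from \code{cohort} instead.
#' @param outputDir where stage outputs are written.
#' @param cohort a \linkS4class{CohortConfig} used when simulating.
#' @param sparsityLow,sparsityHigh,sparsityStep the threshold sweep.
#' @param analysisSparsity wiring cost for betweenness / attack / stats.
#' @param nRandom null-ensemble size for small-world ratios.
#' @param lowHz,highHz band-pass edges.
#' @param displacementLimitMm,rotationLimitDeg motion screening limits.
#' @param thresholdMode \code{"signed"} or \code{"absolute"} ranking.
#' @param ssType ANOVA sums-of-squares type, \code{"II"} or \code{"III"}.
#' @param fdrMethod \code{"BH"} or \code{"BY"}.
#' @param fdrQ FDR level.
#' @param seed master seed for the analysis stages.
#' @return List of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(inputDir = NULL, outputDir = tempfile("restnet"),
                           cohort = cohortConfig(),
                           sparsityLow = 0.15, sparsityHigh = 0.25,
                           sparsityStep = 0.01, analysisSparsity = 0.15,
                           nRandom = 100, lowHz = 0.01, highHz = 0.08,
                           displacementLimitMm = 1.5, rotationLimitDeg = 1.5,
                           thresholdMode = c("signed", "absolute"),
                           ssType = c("II", "III"),
                           fdrMethod = c("BH", "BY"), fdrQ = 0.05,
                           seed = 1) {
  thresholdMode <- match.arg(thresholdMode)
  ssType <- match.arg(ssType)
  fdrMethod <- match.arg(fdrMethod)
  if (sparsityLow > sparsityHigh)
    stop("malformed sparsity sweep: low exceeds high")
  if (sparsityStep <= 0) stop("sparsity step must be positive")
  if (analysisSparsity <= 0 || analysisSparsity > 1)
    stop("analysis sparsity must lie in (0, 1]")
  if (!is.null(inputDir) && !dir.exists(inputDir))
    stop("inputDir does not exist: ", inputDir)
  structure(list(inputDir = inputDir, outputDir = outputDir,
                 cohort = cohort, sparsityLow = sparsityLow,
                 sparsityHigh = sparsityHigh, sparsityStep = sparsityStep,
                 analysisSparsity = analysisSparsity, nRandom = nRandom,
                 lowHz = lowHz, highHz = highHz,
                 displacementLimitMm = displacementLimitMm,
                 rotationLimitDeg = rotationLimitDeg,
                 thresholdMode = thresholdMode, ssType = ssType,
                 fdrMethod = fdrMethod, fdrQ = fdrQ, seed = seed),
            class = "pipelineConfig")
}

.loadInputs <- function(config) {
  if (is.null(config$inputDir)) {
    cohort <- generateCohort(config$cohort)
    list(subjects = cohort@subjects, series = cohort@series,
         nuisance = cohort@nuisance)
  } else {
    subjects <- readSubjectTable(file.path(config$inputDir, "subjects.csv"))
    tr <- config$cohort@trSeconds
    series <- lapply(subjects$subject_id, function(id)
      readRoiTimeSeries(file.path(config$inputDir, "timeseries",
                                  paste0(id, ".tsv")), tr))
    names(series) <- subjects$subject_id
    nuisance <- lapply(subjects$subject_id, function(id) {
      nm <- readRoiTimeSeries(file.path(config$inputDir, "nuisance",
                                        paste0(id, ".tsv")), tr)@data
      NuisanceSet(nm[1:6, , drop = FALSE], nm[7, ], nm[8, ])
    })
    names(nuisance) <- subjects$subject_id
    list(subjects = subjects, series = series, nuisance = nuisance)
  }
}

#' Run the whole analysis pipeline
#'
#' Executes, in order: cohort simulation (or input loading), motion QC and
#' exclusion, band-pass filtering plus nuisance regression, per-subject
#' correlation matrices, the sparsity sweep with small-world metrics,
#' betweenness at the analysis sparsity, per-sex targeted-attack curves,
#' and the 2x2 group statistics (metric ANOVAs, duration partial
#' correlation controlling age, edge-level Fisher-z ANOVA). Every stage
#' writes its outputs under \code{config$outputDir}; re-running the same
#' configuration reproduces them bit-identically.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print stage progress (default FALSE).
#' @return Invisible list with the per-stage in-memory results:
#'   \code{subjects}, \code{qc}, \code{metrics} (per subject x sparsity),
#'   \code{betweenness}, \code{attack}, \code{stats}, \code{edges},
#'   \code{outputDir}.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(...)
  hash <- .configHash(c(config[setdiff(names(config),
                                       c("cohort", "inputDir", "outputDir"))],
                        .configAsList(config$cohort)))
  out <- config$outputDir
  for (d in c("", "qc", "matrices", "metrics", "robustness", "stats"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  say("stage: inputs")
  inputs <- tryCatch(.loadInputs(config),
                     error = function(e) stop("stage inputs: ",
                                              conditionMessage(e)))
  subjects <- inputs$subjects
  writeSubjectTable(subjects, file.path(out, "subjects.csv"), "inputs", hash)

  say("stage: qc")
  qc <- do.call(rbind, lapply(subjects$subject_id, function(id) {
    sm <- screenMotion(inputs$nuisance[[id]], config$displacementLimitMm,
                       config$rotationLimitDeg)
    data.frame(subject_id = id,
               max_displacement_mm = max(sm$summary$max_displacement_mm),
               max_rotation_deg = max(sm$summary$max_rotation_deg),
               pass = sm$pass)
  }))
  .writeTableWithHeader(qc, file.path(out, "qc", "qc.csv"), "qc", hash,
                        sep = ",")
  keep <- qc$subject_id[qc$pass]
  if (length(keep) < 4) stop("stage qc: fewer than 4 subjects survive QC")
  subjects <- subjects[subjects$subject_id %in% keep, , drop = FALSE]

  say("stage: preprocess + connectivity")
  svals <- round(seq(config$sparsityLow,
                     config$sparsityHigh + config$sparsityStep * 1e-8,
                     by = config$sparsityStep), 10)
  svals <- svals[svals <= config$sparsityHigh + 1e-12]
  sAnalysis <- config$analysisSparsity
  metricRows <- list()
  betwRows <- list()
  zRows <- list()
  graphsAnalysis <- list()
  pairNames <- NULL
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    pp <- tryCatch(
      preprocessSubject(inputs$series[[id]], inputs$nuisance[[id]],
                        config$lowHz, config$highHz),
      error = function(e) stop("stage preprocess (", id, "): ",
                               conditionMessage(e)))
    cm <- correlationMatrix(pp)
    writeMatrixTsv(cm@r, file.path(out, "matrices", paste0(id, "_r.tsv")),
                   "connectivity", hash)
    rUp <- cm@r[upper.tri(cm@r)]
    if (is.null(pairNames)) {
      idx <- which(upper.tri(cm@r), arr.ind = TRUE)
      pairNames <- paste(cm@regionLabels[idx[, 1]],
                         cm@regionLabels[idx[, 2]], sep = "--")
    }
    zRows[[id]] <- fisherZ(pmin(pmax(rUp, -0.999999), 0.999999))
    for (s in svals) {
      g <- thresholdBySparsity(cm, s, config$thresholdMode)
      if (!.isConnected(g@adjacency)) {
        metricRows[[paste(id, s)]] <-
          data.frame(subject_id = id, sparsity = s,
                     C = networkClustering(g), L = NA_real_,
                     Crand = NA_real_, Lrand = NA_real_, gamma = NA_real_,
                     lambda = NA_real_, sigma = NA_real_)
        next
      }
      sw <- smallWorldMetrics(g, nRandom = config$nRandom,
                              seed = config$seed + 7919 * i +
                                round(10000 * s))
      metricRows[[paste(id, s)]] <-
        data.frame(subject_id = id, sparsity = s, C = sw$C, L = sw$L,
                   Crand = sw$Crand, Lrand = sw$Lrand, gamma = sw$gamma,
                   lambda = sw$lambda, sigma = sw$sigma)
      if (isTRUE(all.equal(s, sAnalysis))) graphsAnalysis[[id]] <- g
    }
    gA <- thresholdBySparsity(cm, sAnalysis, config$thresholdMode)
    if (.isConnected(gA@adjacency)) {
      graphsAnalysis[[id]] <- gA
      betwRows[[id]] <- betweennessCentrality(gA)
    }
  }
  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL
  .writeTableWithHeader(metrics, file.path(out, "metrics", "metrics.csv"),
                        "metrics", hash, sep = ",")
  betw <- do.call(rbind, betwRows)
  .writeTableWithHeader(
    data.frame(subject_id = rownames(betw), betw, check.names = FALSE),
    file.path(out, "metrics", "betweenness.csv"), "metrics", hash, sep = ",")

  say("stage: robustness")
  attack <- list()
  for (sx in unique(subjects$sex)) {
    ids <- subjects$subject_id[subjects$sex == sx]
    ids <- intersect(ids, rownames(betw))
    ord <- attackOrder(betw[ids, , drop = FALSE])
    groups <- split(ids, subjects$group[match(ids, subjects$subject_id)])
    curves <- lapply(groups, function(gids)
      lapply(gids, function(id)
        targetedAttack(graphsAnalysis[[id]], ord, stopAtSingleton = FALSE)))
    cmp <- if (all(lengths(curves) >= 2) && length(curves) == 2)
      compareCurves(curves[[1]], curves[[2]], alpha = 0.05) else NULL
    attack[[sx]] <- list(order = ord, curves = curves, comparison = cmp)
    if (!is.null(cmp))
      .writeTableWithHeader(cmp,
        file.path(out, "robustness", paste0("attack_", sx, ".tsv")),
        "robustness", hash)
  }

  say("stage: stats")
  atS <- metrics[abs(metrics$sparsity - sAnalysis) < 1e-9 &
                   !is.na(metrics$sigma), ]
  sdat <- merge(atS, subjects, by = "subject_id")
  statsOut <- list()
  for (metric in c("C", "L", "gamma", "lambda", "sigma")) {
    an <- twoWayAnova(sdat[[metric]], sdat$sex, sdat$group, config$ssType)
    statsOut[[metric]] <- an
  }
  pInts <- vapply(statsOut, function(a)
    a$table$p[a$table$term == "sex:disease"], numeric(1))
  fdrInt <- fdrAdjust(pInts, config$fdrQ, config$fdrMethod)
  anovaTab <- do.call(rbind, lapply(names(statsOut), function(mn) {
    tb <- statsOut[[mn]]$table
    tb$metric <- mn
    tb
  }))
  .writeTableWithHeader(anovaTab, file.path(out, "stats", "anova.csv"),
                        "stats", hash, sep = ",")

  pat <- sdat[sdat$group == "patient" & !is.na(sdat$disease_duration), ]
  durCor <- if (nrow(pat) >= 5)
    partialCorrelation(pat$disease_duration, pat$sigma,
                       covariates = pat$age) else NULL

  zmat <- do.call(rbind, zRows)
  colnames(zmat) <- pairNames
  zmat <- zmat[subjects$subject_id, , drop = FALSE]
  edges <- edgeStats(zmat, subjects$sex, subjects$group, config$fdrQ,
                     config$fdrMethod)
  .writeTableWithHeader(edges[edges$increased, , drop = FALSE],
                        file.path(out, "stats", "edges_increased.csv"),
                        "stats", hash, sep = ",")

  manifest <- list(package = .pkgVersion(), config_hash = hash,
                   seed = config$seed, n_subjects = nrow(subjects),
                   sparsities = svals,
                   stages = c("inputs", "qc", "preprocess", "connectivity",
                              "metrics", "robustness", "stats"),
                   interaction_fdr = as.list(stats::setNames(
                     fdrInt$adjusted, names(statsOut))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 12)

  invisible(list(subjects = subjects, qc = qc, metrics = metrics,
                 betweenness = betw, attack = attack, stats = statsOut,
                 interactionFdr = fdrInt, durationPartial = durCor,
                 edges = edges, outputDir = out))
}
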
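#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Region-by-time BOLD signal matrix for one subject
#'
#' Container for one subject's regional time series: a regions x timepoints
#' real matrix, the ordered region labels, and the sampling interval (TR).
#'
#' @slot data numeric matrix, regions in rows, timepoints in columns.
#' @slot regionLabels character vector, one label per row of \code{data}.
#' @slot trSeconds sampling interval in seconds.
#' @export
setClass("RoiTimeSeries",
  slots = c(data = "matrix", regionLabels = "character", trSeconds = "numeric"))

setValidity("RoiTimeSeries", function(object) {
  if (!is.numeric(object@data)) return("data must be a numeric matrix")
  if (anyNA(object@data)) return("data contains missing values")
  if (nrow(object@data) != length(object@regionLabels))
    return("row count must equal the number of region labels")
  if (anyDuplicated(object@regionLabels))
    return("region labels must be unique")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    return("trSeconds must be a single positive number")
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data regions x timepoints numeric matrix.
#' @param regionLabels character vector of region labels; defaults to the
#'   row names of \code{data}.
#' @param trSeconds sampling interval in seconds (default 2).
#' @return A \linkS4class{RoiTimeSeries} object.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(40), 4, 10),
#'                     regionLabels = c("A", "B", "C", "D"))
#' @export
RoiTimeSeries <- function(data, regionLabels = rownames(data), trSeconds = 2) {
  if (is.null(regionLabels))
    regionLabels <- sprintf("R%03d", seq_len(nrow(data)))
  rownames(data) <- regionLabels
  new("RoiTimeSeries", data = data, regionLabels = as.character(regionLabels),
      trSeconds = as.numeric(trSeconds))
}

#' Nuisance signals accompanying one subject's scan
#'
#' Six rigid-body motion traces (three translations in mm, three rotations
#' in degrees) plus mean white-matter and ventricle (CSF) signals, all on
#' the subject's sampling grid.
#'
#' @slot motion 6 x timepoints numeric matrix (tx, ty, tz, rx, ry, rz).
#' @slot wmSignal numeric vector, white-matter mean signal.
#' @slot csfSignal numeric vector, ventricle mean signal.
#' @export
setClass("NuisanceSet",
  slots = c(motion = "matrix", wmSignal = "numeric", csfSignal = "numeric"))

setValidity("NuisanceSet", function(object) {
  if (nrow(object@motion) != 6L)
    return("motion matrix must have exactly 6 rows (3 translations, 3 rotations)")
  nt <- ncol(object@motion)
  if (length(object@wmSignal) != nt || length(object@csfSignal) != nt)
    return("wm/csf signals must match the motion time length")
  if (anyNA(object@motion) || anyNA(object@wmSignal) || anyNA(object@csfSignal))
    return("nuisance signals contain missing values")
  TRUE
})

#' Construct a NuisanceSet
#' @param motion 6 x timepoints matrix.
#' @param wmSignal,csfSignal numeric vectors of the same time length.
#' @return A \linkS4class{NuisanceSet} object.
#' @export
NuisanceSet <- function(motion, wmSignal, csfSignal) {
  rownames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  new("NuisanceSet", motion = motion, wmSignal = as.numeric(wmSignal),
      csfSignal = as.numeric(csfSignal))
}

#' Interregional Pearson correlation matrix
#'
#' Symmetric region x region matrix of Pearson correlation coefficients
#' with unit diagonal (set, not estimated).
#'
#' @slot r symmetric numeric matrix with diagonal exactly 1.
#' @slot regionLabels ordered region labels.
#' @export
setClass("ConnectivityMatrix",
  slots = c(r = "matrix", regionLabels = "character"))

setValidity("ConnectivityMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (nrow(r) != length(object@regionLabels))
    return("dimension must equal the number of region labels")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-10)))
    return("correlation matrix must be symmetric")
  if (any(diag(r) != 1)) return("diagonal must be exactly 1")
  off <- r[upper.tri(r)]
  if (any(off < -1 | off > 1)) return("off-diagonal entries must lie in [-1, 1]")
  TRUE
})

#' Construct a ConnectivityMatrix
#' @param r square symmetric numeric matrix; its diagonal is overwritten
#'   with exact 1s.
#' @param regionLabels region labels; defaults to the row names of \code{r}.
#' @return A \linkS4class{ConnectivityMatrix} object.
#' @export
ConnectivityMatrix <- function(r, regionLabels = rownames(r)) {
  if (is.null(regionLabels))
    regionLabels <- sprintf("R%03d", seq_len(nrow(r)))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(regionLabels, regionLabels)
  new("ConnectivityMatrix", r = r, regionLabels = as.character(regionLabels))
}

#' Binary undirected graph at a fixed wiring cost
#'
#' Unweighted adjacency matrix obtained by thresholding a connectivity
#' matrix at a given sparsity (edges present / edges possible), or built
#' directly as a test fixture.
#'
#' @slot adjacency 0/1 symmetric numeric matrix with zero diagonal.
#' @slot sparsity realized wiring cost, \eqn{2E / (N(N-1))}.
#' @slot regionLabels node labels.
#' @export
setClass("BinaryGraph",
  slots = c(adjacency = "matrix", sparsity = "numeric",
            regionLabels = "character"))

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (nrow(a) != length(object@regionLabels))
    return("dimension must equal the number of node labels")
  if (!all(a %in% c(0, 1))) return("adjacency entries must be 0 or 1")
  if (any(diag(a) != 0)) return("diagonal must be zero (no self-loops)")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  TRUE
})

#' Construct a BinaryGraph
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param regionLabels node labels; defaults to row names.
#' @return A \linkS4class{BinaryGraph}; the realized sparsity is computed
#'   from the edge count.
#' @export
BinaryGraph <- function(adjacency, regionLabels = rownames(adjacency)) {
  n <- nrow(adjacency)
  if (is.null(regionLabels)) regionLabels <- sprintf("R%03d", seq_len(n))
  adjacency <- matrix(as.numeric(adjacency), n, n)
  dimnames(adjacency) <- list(regionLabels, regionLabels)
  spars <- if (n > 1) sum(adjacency) / (n * (n - 1)) else 0
  new("BinaryGraph", adjacency = adjacency, sparsity = spars,
      regionLabels = as.character(regionLabels))
}

#' Synthetic cohort design parameters
#'
#' All knobs of the synthetic resting-state cohort: cell sizes of the 2x2
#' sex-by-disease design, signal dimensions, the modular (block) correlation
#' targets, the disease / sex-by-disease coupling perturbations, the
#' duration-coupling slope, temporal autocorrelation, nuisance mixing
#' strength and the master seed.
#'
#' @slot nFemalePerGroup,nMalePerGroup subjects per sex within each group.
#' @slot nRegions,nTimepoints signal dimensions.
#' @slot trSeconds sampling interval (s).
#' @slot nModules number of correlation blocks (communities).
#' @slot withinModuleR,betweenModuleR target Pearson correlations within and
#'   between blocks; must satisfy \code{withinModuleR > betweenModuleR} and
#'   both in (-1, 1).
#' @slot diseaseEffect additive reduction of within-module coupling on
#'   affected regions for patients.
#' @slot sexDiseaseInteraction extra reduction applied only to female
#'   patients on affected regions.
#' @slot durationSlope change of affected within-module coupling per year of
#'   migraine duration (centered at the cohort mean duration).
#' @slot noiseAr1 AR(1) coefficient of the regional signals.
#' @slot nuisanceWeight scale of the recorded nuisance-to-region mixing
#'   weights (0 disables nuisance contamination).
#' @slot affectedRegions integer indices of the perturbed regions; default
#'   (empty) means the whole first module.
#' @slot seed master seed; identical config + seed gives a bit-identical
#'   cohort.
#' @export
setClass("CohortConfig",
  slots = c(nFemalePerGroup = "numeric", nMalePerGroup = "numeric",
            nRegions = "numeric", nTimepoints = "numeric",
            trSeconds = "numeric", nModules = "numeric",
            withinModuleR = "numeric", betweenModuleR = "numeric",
            diseaseEffect = "numeric", sexDiseaseInteraction = "numeric",
            durationSlope = "numeric", noiseAr1 = "numeric",
            nuisanceWeight = "numeric", affectedRegions = "numeric",
            seed = "numeric"))

setValidity("CohortConfig", function(object) {
  if (object@nFemalePerGroup < 1 || object@nMalePerGroup < 1)
    return("each sex-by-group cell needs at least one subject")
  if (object@nRegions < 2) return("need at least 2 regions")
  if (object@nTimepoints < 30)
    return("n_timepoints must be at least 30 for correlation estimability")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (object@nModules < 1 || object@nModules > object@nRegions)
    return("nModules must lie in [1, nRegions]")
  w <- object@withinModuleR; b <- object@betweenModuleR
  if (w <= -1 || w >= 1 || b <= -1 || b >= 1)
    return("correlation targets must lie in (-1, 1)")
  if (w <= b)
    return("withinModuleR must exceed betweenModuleR")
  if (abs(object@noiseAr1) >= 1) return("noiseAr1 must lie in (-1, 1)")
  if (length(object@affectedRegions) &&
      (any(object@affectedRegions < 1) ||
       any(object@affectedRegions > object@nRegions)))
    return("affectedRegions out of range")
  TRUE
})

#' Construct a CohortConfig
#'
#' Defaults reproduce the emulated study design: a 2x2 sex-by-disease
#' cohort with 20 females and 18 males per group (76 subjects), 90 regions,
#' 205 volumes at TR = 2 s, six correlation modules, and coupling
#' perturbations sized so that the female-patient deficit and the
#' duration association are recoverable by the downstream statistics.
#'
#' @param nFemalePerGroup,nMalePerGroup cell sizes (defaults 20 and 18).
#' @param nRegions,nTimepoints,trSeconds signal dimensions (90, 205, 2).
#' @param nModules,withinModuleR,betweenModuleR block-correlation structure.
#' @param diseaseEffect,sexDiseaseInteraction,durationSlope coupling
#'   perturbations (see class documentation).
#' @param noiseAr1 temporal AR(1) coefficient.
#' @param nuisanceWeight nuisance mixing scale.
#' @param affectedRegions indices of perturbed regions; \code{NULL}
#'   (default) applies the coupling perturbations brain-wide, matching a
#'   globally altered small-world organization. Pass a subset to localize
#'   the deficit.
#' @param seed master seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' @export
cohortConfig <- function(nFemalePerGroup = 20, nMalePerGroup = 18,
                         nRegions = 90, nTimepoints = 205, trSeconds = 2,
                         nModules = 9, withinModuleR = 0.35,
                         betweenModuleR = 0.08, diseaseEffect = 0.03,
                         sexDiseaseInteraction = 0.06, durationSlope = 0.0075,
                         noiseAr1 = 0.3, nuisanceWeight = 0.1,
                         affectedRegions = NULL, seed = 1) {
  if (is.null(affectedRegions)) affectedRegions <- numeric(0)
  new("CohortConfig", nFemalePerGroup = nFemalePerGroup,
      nMalePerGroup = nMalePerGroup, nRegions = nRegions,
      nTimepoints = nTimepoints, trSeconds = trSeconds, nModules = nModules,
      withinModuleR = withinModuleR, betweenModuleR = betweenModuleR,
      diseaseEffect = diseaseEffect,
      sexDiseaseInteraction = sexDiseaseInteraction,
      durationSlope = durationSlope, noiseAr1 = noiseAr1,
      nuisanceWeight = nuisanceWeight, affectedRegions = affectedRegions,
      seed = seed)
}

#' A fully realized synthetic cohort
#'
#' @slot subjects data.frame of demographics and clinical covariates
#'   (controls carry NA clinical fields).
#' @slot series named list of \linkS4class{RoiTimeSeries}, one per subject.
#' @slot nuisance named list of \linkS4class{NuisanceSet}.
#' @slot mixing named list of the ground-truth nuisance mixing weight
#'   matrices (regions x 8), recorded so preprocessing can be audited.
#' @slot config the generating \linkS4class{CohortConfig}.
#' @export
setClass("SyntheticCohort",
  slots = c(subjects = "data.frame", series = "list", nuisance = "list",
            mixing = "list", config = "CohortConfig"))

setValidity("SyntheticCohort", function(object) {
  ids <- object@subjects$subject_id
  if (!identical(names(object@series), ids) ||
      !identical(names(object@nuisance), ids))
    return("series/nuisance lists must be keyed by subject_id in table order")
  TRUE
})
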
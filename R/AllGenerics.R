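#' Region labels of an object
#' @param x an object carrying region labels.
#' @return Character vector of labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "RoiTimeSeries", function(x) x@regionLabels)
#' @rdname regionLabels
#' @export
setMethod("regionLabels", "ConnectivityMatrix", function(x) x@regionLabels)
#' @rdname regionLabels
#' @export
setMethod("regionLabels", "BinaryGraph", function(x) x@regionLabels)

#' Signal matrix of a RoiTimeSeries
#' @param x a \linkS4class{RoiTimeSeries}.
#' @return The regions x timepoints matrix.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))
#' @rdname seriesMatrix
#' @export
setMethod("seriesMatrix", "RoiTimeSeries", function(x) x@data)

#' Sampling interval (TR) in seconds
#' @param x a \linkS4class{RoiTimeSeries}.
#' @return TR in seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname repetitionTime
#' @export
setMethod("repetitionTime", "RoiTimeSeries", function(x) x@trSeconds)

#' Correlation values of a ConnectivityMatrix
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return The region x region correlation matrix.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname corValues
#' @export
setMethod("corValues", "ConnectivityMatrix", function(x) x@r)

#' Adjacency matrix of a BinaryGraph
#' @param x a \linkS4class{BinaryGraph}.
#' @return 0/1 adjacency matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname adjacency
#' @export
setMethod("adjacency", "BinaryGraph", function(x) x@adjacency)

#' Realized sparsity (wiring cost) of a BinaryGraph
#' @param x a \linkS4class{BinaryGraph}.
#' @return Fraction of realized edges over possible node pairs.
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))
#' @rdname sparsity
#' @export
setMethod("sparsity", "BinaryGraph", function(x) x@sparsity)

#' Number of edges of a BinaryGraph
#' @param x a \linkS4class{BinaryGraph}.
#' @return Integer edge count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname edgeCount
#' @export
setMethod("edgeCount", "BinaryGraph", function(x) as.integer(sum(x@adjacency) / 2))

#' Degree sequence of a BinaryGraph
#' @param x a \linkS4class{BinaryGraph}.
#' @return Named integer vector of node degrees.
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))
#' @rdname degrees
#' @export
setMethod("degrees", "BinaryGraph", function(x) {
  d <- as.integer(rowSums(x@adjacency))
  names(d) <- x@regionLabels
  d
})

#' Subject table of a SyntheticCohort
#' @param x a \linkS4class{SyntheticCohort}.
#' @return data.frame of demographics and clinical covariates.
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))
#' @rdname subjectTable
#' @export
setMethod("subjectTable", "SyntheticCohort", function(x) x@subjects)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d regions x %d timepoints, TR = %gs\n",
              nrow(object@data), ncol(object@data), object@trSeconds))
})

setMethod("show", "NuisanceSet", function(object) {
  cat(sprintf("NuisanceSet: 6 motion + wm + csf traces, %d timepoints\n",
              ncol(object@motion)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@r)
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("ConnectivityMatrix: %d x %d, off-diagonal r in [%.3f, %.3f]\n",
              n, n, min(off), max(off)))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (sparsity %.4f)\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              object@sparsity))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0(
    "CohortConfig: 2x2 cohort, %dF + %dM per group; %d regions x %d ",
    "timepoints (TR %gs)\n  modules: %d, r_within = %.2f, r_between = %.2f\n",
    "  effects: disease %.3f, sex x disease %.3f, duration slope %.4f/yr\n"),
    object@nFemalePerGroup, object@nMalePerGroup, object@nRegions,
    object@nTimepoints, object@trSeconds, object@nModules,
    object@withinModuleR, object@betweenModuleR, object@diseaseEffect,
    object@sexDiseaseInteraction, object@durationSlope))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@subjects$group, object@subjects$sex)
  cat(sprintf("SyntheticCohort: %d subjects\n", nrow(object@subjects)))
  print(tab)
})
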
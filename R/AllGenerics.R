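#' Accessors for mihcTME classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{markerNames}/\code{markerThresholds}/\code{gatingTree} for
#' \code{\link{MarkerPanel}}; \code{nCells}/\code{cellIds}/\code{cellCoords}/
#' \code{cellIntensities} for \code{\link{CellTable}};
#' \code{compartmentAreas}/\code{gridLabels} for
#' \code{\link{SegmentationGrid}}; \code{featureValues} for
#' \code{\link{TMEFeatures}}; \code{clusterAssignments}/\code{clusterCentroids}/
#' \code{favorableClusters} for \code{\link{ClusterResult}};
#' \code{clinicalTable}/\code{truthTable}/\code{cohortTissues} for
#' \code{\link{SyntheticCohort}}.
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("markerThresholds", function(x) standardGeneric("markerThresholds"))
#' @rdname accessors
#' @export
setGeneric("gatingTree", function(x) standardGeneric("gatingTree"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))
#' @rdname accessors
#' @export
setGeneric("cellIntensities", function(x) standardGeneric("cellIntensities"))
#' @rdname accessors
#' @export
setGeneric("compartmentAreas", function(x) standardGeneric("compartmentAreas"))
#' @rdname accessors
#' @export
setGeneric("gridLabels", function(x) standardGeneric("gridLabels"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @rdname accessors
#' @export
setGeneric("favorableClusters", function(x) standardGeneric("favorableClusters"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("cohortTissues", function(x) standardGeneric("cohortTissues"))

#' @rdname accessors
setMethod("markerNames", "MarkerPanel", function(x) x@markers$name)
#' @rdname accessors
setMethod("markerThresholds", "MarkerPanel",
  function(x) setNames(x@markers$threshold, x@markers$name))
#' @rdname accessors
setMethod("gatingTree", "MarkerPanel", function(x) x@gating)
#' @rdname accessors
setMethod("nCells", "CellTable", function(x) length(x@cellIds))
#' @rdname accessors
setMethod("cellIds", "CellTable", function(x) x@cellIds)
#' @rdname accessors
setMethod("cellCoords", "CellTable", function(x) x@coords)
#' @rdname accessors
setMethod("cellIntensities", "CellTable", function(x) x@intensities)
#' @rdname accessors
setMethod("compartmentAreas", "SegmentationGrid", function(x) x@areas)
#' @rdname accessors
setMethod("gridLabels", "SegmentationGrid", function(x) x@labels)
#' @rdname accessors
setMethod("featureValues", "TMEFeatures", function(x) x@values)
#' @rdname accessors
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)
#' @rdname accessors
setMethod("clusterCentroids", "ClusterResult", function(x) x@centroids)
#' @rdname accessors
setMethod("favorableClusters", "ClusterResult", function(x) x@favorable)
#' @rdname accessors
setMethod("clinicalTable", "SyntheticCohort", function(x) x@clinical)
#' @rdname accessors
setMethod("truthTable", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("cohortTissues", "SyntheticCohort", function(x) x@tissues)

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d markers, %d terminal gate labels\n",
              nrow(object@markers), length(.collectGateLabels(object@gating)) + 1L))
  cat("  markers:", paste(head(object@markers$name, 8), collapse = ", "),
      if (nrow(object@markers) > 8) "...", "\n")
})

setMethod("show", "CellTable", function(object) {
  cat(sprintf("CellTable: %d cells x %d markers\n",
              nCells(object), ncol(object@intensities)))
})

setMethod("show", "SegmentationGrid", function(object) {
  a <- object@areas
  cat(sprintf("SegmentationGrid: %dx%d cells @ %g um | TN %.3f mm^2, ISA %.3f mm^2, background %.3f mm^2\n",
              nrow(object@labels), ncol(object@labels), object@pitch,
              a[["TN"]], a[["ISA"]], a[["background"]]))
})

setMethod("show", "TMEFeatures", function(object) {
  v <- object@values
  cat(sprintf("TMEFeatures: %d patients x %d features (%d missing entries)\n",
              nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "ClusterResult", function(object) {
  k <- length(object@favorable)
  cat(sprintf("ClusterResult: %d patients in %d clusters (%d favorable: %s)\n",
              length(object@assignments), k, sum(object@favorable),
              paste(which(object@favorable), collapse = ", ")))
})

setMethod("show", "CohortConfig", function(object) {
  ct <- object@counts
  cat(sprintf("CohortConfig: %d patients (%d ICI: %d DCB / %d non-DCB / %d early-censored), seed %d\n",
              ct[["n_total"]], ct[["n_ici"]], ct[["n_dcb"]], ct[["n_nondcb"]],
              ct[["n_earlycensor"]], object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d tissues, expression: %s\n",
              nrow(object@clinical), length(object@tissues),
              if (is.null(object@expression)) "none"
              else paste(dim(object@expression), collapse = " x ")))
})
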
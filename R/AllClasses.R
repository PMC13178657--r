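#' @import methods
#' @importFrom stats dnorm median quantile rbinom rexp rlnorm rnorm rpois runif plogis qlogis
#'   rbeta sd setNames var complete.cases pchisq pnorm pt p.adjust cor fisher.test
#'   wilcox.test cor.test qnorm
#' @importFrom utils read.csv write.csv head
NULL

#' MarkerPanel: an mIHC marker panel with per-marker thresholds and a gating tree
#'
#' A panel describes the antibody markers measured per cell (name, binarisation
#' threshold in the platform's intensity units, free-text role annotation) and
#' the hierarchical gating tree that maps binary marker calls onto mutually
#' exclusive cell-subset labels.
#'
#' @slot markers a \code{data.frame} with columns \code{name}, \code{threshold},
#'   \code{role}; one row per marker, names unique, thresholds strictly positive.
#' @slot gating a list of gate nodes. Each node is a list with elements
#'   \code{label} (character), \code{require} (named character vector of
#'   \code{"+"}/\code{"-"} marker requirements) and optionally \code{children}
#'   (a list of nodes). See \code{\link{assignSubsets}} for evaluation
#'   semantics.
#'
#' @seealso \code{\link{defaultPanel}}, \code{\link{readPanel}}
#' @export
setClass("MarkerPanel",
  representation(markers = "data.frame", gating = "list"))

.collectGateLabels <- function(nodes) {
  unlist(lapply(nodes, function(nd) {
    c(nd$label, if (!is.null(nd$children)) .collectGateLabels(nd$children))
  }), use.names = FALSE)
}

.collectGateMarkers <- function(nodes) {
  unlist(lapply(nodes, function(nd) {
    c(names(nd$require), if (!is.null(nd$children)) .collectGateMarkers(nd$children))
  }), use.names = FALSE)
}

setValidity("MarkerPanel", function(object) {
  m <- object@markers
  msgs <- character()
  if (!all(c("name", "threshold", "role") %in% names(m)))
    return("markers must have columns name, threshold, role")
  if (anyDuplicated(m$name))
    msgs <- c(msgs, sprintf("duplicated marker name(s): %s",
      paste(unique(m$name[duplicated(m$name)]), collapse = ", ")))
  if (!is.numeric(m$threshold) || any(!is.finite(m$threshold)) || any(m$threshold <= 0))
    msgs <- c(msgs, "all thresholds must be finite and > 0")
  if (length(object@gating)) {
    labs <- .collectGateLabels(object@gating)
    if (anyDuplicated(labs))
      msgs <- c(msgs, "gating labels must be unique within the tree")
    unknown <- setdiff(unique(.collectGateMarkers(object@gating)), m$name)
    if (length(unknown))
      msgs <- c(msgs, sprintf("gating predicates reference unknown marker(s): %s",
        paste(unknown, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' CellTable: one patient's single-cell proteotype table
#'
#' The pipeline's atomic input: one row per segmented cell, carrying its
#' position in micrometres (origin at the field's top-left corner, y increasing
#' downward) and one staining intensity per panel marker (arbitrary units,
#' non-negative).
#'
#' @slot cellIds character vector of per-patient-unique cell identifiers.
#' @slot coords numeric matrix with columns \code{x}, \code{y} (micrometres).
#' @slot intensities numeric matrix, cells x markers, column names are marker
#'   names.
#'
#' @seealso \code{\link{readCellTable}}, \code{\link{generatePatientTissue}}
#' @export
setClass("CellTable",
  representation(cellIds = "character", coords = "matrix", intensities = "matrix"))

setValidity("CellTable", function(object) {
  n <- length(object@cellIds)
  msgs <- character()
  if (nrow(object@coords) != n || nrow(object@intensities) != n)
    return("cellIds, coords and intensities must agree in length")
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@cellIds))
    msgs <- c(msgs, "cell ids must be unique")
  if (!identical(colnames(object@coords), c("x", "y")))
    msgs <- c(msgs, "coords must have columns x, y")
  else if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (is.null(colnames(object@intensities)))
    msgs <- c(msgs, "intensity columns must be named by marker")
  if (anyNA(object@intensities) || any(object@intensities < 0))
    msgs <- c(msgs, "intensities must be non-negative and non-missing")
  if (length(msgs)) msgs else TRUE
})

#' SegmentationGrid: raster tissue segmentation into TN / ISA / background
#'
#' A square raster of pitch \code{g} micrometres covering a patient's imaging
#' field. Each grid cell is labelled tumor-cell-nest (TN), intratumoral stroma
#' (ISA) or background (cell-free); physical areas per label are carried in
#' mm^2. Coordinates map to grid cells by half-open intervals
#' \code{[i*g, (i+1)*g)}.
#'
#' @slot labels integer matrix (rows = x bins, cols = y bins) with values
#'   1 = TN, 2 = ISA, 3 = background.
#' @slot pitch grid pitch in micrometres.
#' @slot areas named numeric, mm^2 for \code{TN}, \code{ISA}, \code{background}.
#'
#' @seealso \code{\link{segmentTissue}}, \code{\link{assignCompartment}}
#' @export
setClass("SegmentationGrid",
  representation(labels = "matrix", pitch = "numeric", areas = "numeric"))

setValidity("SegmentationGrid", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@areas)), sort(c("TN", "ISA", "background"))))
    msgs <- c(msgs, "areas must be named TN, ISA, background")
  else if (any(object@areas < 0))
    msgs <- c(msgs, "areas must be non-negative")
  tot <- prod(dim(object@labels)) * object@pitch^2 / 1e6
  if (length(object@areas) == 3L &&
      abs(sum(object@areas) - tot) > 1e-8 * max(tot, 1))
    msgs <- c(msgs, "label areas must sum to the grid area")
  if (length(msgs)) msgs else TRUE
})

#' TMEFeatures: the patients x TME-feature matrix
#'
#' Per-patient tumor-microenvironment features (compartment densities in
#' cells/mm^2, phenotype positivity fractions, effector-to-target ratios).
#' Undefined entries (zero denominators: absent parent population or zero
#' compartment area) are \code{NA} and are never imputed.
#'
#' @slot values numeric matrix, patients (rows, named) x features (columns).
#'
#' @seealso \code{\link{buildFeatureMatrix}}, \code{\link{clusterCohort}}
#' @export
setClass("TMEFeatures", representation(values = "matrix"))

setValidity("TMEFeatures", function(object) {
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    "feature matrix must have patient row names and feature column names"
  else TRUE
})

#' ClusterResult: hierarchical clustering of a patient cohort
#'
#' Result of average-linkage agglomerative clustering under the
#' uncentered-correlation distance, cut to \code{k} clusters, with per-cluster
#' centroid z-scores and the favorable-TME (fTME) flag from the centroid-sign
#' rule.
#'
#' @slot assignments named integer vector, cluster id (1..k) per patient.
#' @slot merge,height agglomeration record in \code{\link[stats]{hclust}}
#'   conventions (negative entries index original observations).
#' @slot centroids numeric matrix, clusters x clustering keys, mean z-scores.
#' @slot favorable logical per cluster: does the centroid satisfy the fTME rule.
#' @slot keys character, the feature names clustered on.
#'
#' @seealso \code{\link{averageLinkageCluster}}, \code{\link{selectFavorableClusters}}
#' @export
setClass("ClusterResult",
  representation(assignments = "integer", merge = "matrix", height = "numeric",
                 centroids = "matrix", favorable = "logical", keys = "character"))

#' CohortConfig: calibration of the synthetic mNSCLC cohort generator
#'
#' Bundles the stratum counts, the proportional-hazards outcome calibration,
#' tissue geometry, per-subset density targets, phenotype positivity targets and
#' the intensity model of the synthetic-cohort generator. The packaged default
#' (\code{\link{defaultCohortConfig}}) mirrors the study conditions of the
#' motivating cohort: 103 patients, 81 ICI-treated (30 durable-clinical-benefit,
#' 49 non-DCB, 2 early-censored), 19 EGFR-mutant / 13 ALK-fusion / 71 wild-type,
#' PFS hazard ratio 0.15 and OS hazard ratio 0.11 for DCB vs non-DCB, and a
#' multivariable hazard ratio of 1.79 for low vs high tumor-nest CD8 density.
#'
#' @slot counts named integer stratum sizes.
#' @slot survival named numeric outcome-model calibration (hazard ratios,
#'   baseline rates in 1/day, censoring horizon and DCB boundary in days).
#' @slot geometry list: field size (um), nest count/radius model.
#' @slot cells list: per-subset density targets (cells/mm^2, log-normal medians
#'   and log-SDs) per compartment, and stromal composition.
#' @slot markers list: phenotype positivity targets (beta means/concentrations).
#' @slot intensity named numeric: log-normal intensity model (\code{sigma},
#'   \code{offset} in units of sigma).
#' @slot expression list: gene panel size and planted log2 effects.
#' @slot seed integer default RNG seed.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{readCohortConfig}}
#' @export
setClass("CohortConfig",
  representation(counts = "integer", survival = "numeric", geometry = "list",
                 cells = "list", markers = "list", intensity = "numeric",
                 expression = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
  ct <- object@counts
  sv <- object@survival
  msgs <- character()
  need <- c("n_total", "n_ici", "n_egfr", "n_alk", "n_wt",
            "n_dcb", "n_nondcb", "n_earlycensor")
  if (!all(need %in% names(ct)))
    return(sprintf("counts must include %s", paste(need, collapse = ", ")))
  if (any(ct < 0)) msgs <- c(msgs, "all counts must be >= 0")
  if (ct[["n_dcb"]] + ct[["n_nondcb"]] + ct[["n_earlycensor"]] != ct[["n_ici"]])
    msgs <- c(msgs, "n_dcb + n_nondcb + n_earlycensor must equal n_ici")
  if (ct[["n_ici"]] > ct[["n_total"]])
    msgs <- c(msgs, "n_ici must not exceed n_total")
  if (ct[["n_egfr"]] + ct[["n_alk"]] + ct[["n_wt"]] != ct[["n_total"]])
    msgs <- c(msgs, "n_egfr + n_alk + n_wt must equal n_total")
  hr <- sv[c("hr_pfs_dcb", "hr_os_dcb", "hr_tncd8")]
  if (anyNA(hr) || any(hr <= 0))
    msgs <- c(msgs, "hazard ratios must be present and > 0")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: a generated cohort with clinical data, tissues and truths
#'
#' Everything \code{\link{generateCohort}} produces for one cohort: the clinical
#' metadata table, per-patient single-cell tables, the bulk expression matrix
#' for the transcriptome subset, and the generator's latent truth table
#' (planted outcome class, planted favorable-TME flag, latent densities) used
#' for parameter-recovery checks.
#'
#' @slot clinical data.frame, one row per patient (see
#'   \code{\link{readClinicalTable}} for the column contract).
#' @slot truth data.frame of generator truths keyed by \code{patient_id}.
#' @slot tissues named list of \code{\link{CellTable}} objects (may be empty
#'   when tissues were not requested).
#' @slot geometry named list of per-patient nest geometries.
#' @slot expression numeric samples x genes matrix or NULL.
#' @slot expressionGroup factor of expression group labels (EGFR status).
#' @slot panel the \code{\link{MarkerPanel}} used.
#' @slot config the \code{\link{CohortConfig}} used.
#' @export
setClass("SyntheticCohort",
  representation(clinical = "data.frame", truth = "data.frame",
                 tissues = "list", geometry = "list",
                 expression = "ANY", expressionGroup = "factor",
                 panel = "MarkerPanel", config = "CohortConfig"))
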
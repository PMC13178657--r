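#' Run the full TME-profiling pipeline on a cohort
#'
#' Convenience wrapper chaining the per-patient stages (gating, tissue
#' segmentation, compartmentalised quantification) with the cohort stages
#' (feature matrix, uncentered-correlation average-linkage clustering with
#' favorable-cluster selection, and the PFS hazard-ratio profile sweep over
#' the ICI arm).
#'
#' @param cohort a \code{\link{SyntheticCohort}} with tissues, or a named list
#'   of \code{\link{CellTable}}s plus a clinical table via \code{clinical}.
#' @param clinical clinical data.frame (taken from the cohort when omitted).
#' @param panel a \code{\link{MarkerPanel}} (taken from the cohort when
#'   omitted).
#' @param k number of clusters for the fTME stage.
#' @param params segmentation parameters.
#' @return list: \code{features} (\code{\link{TMEFeatures}}),
#'   \code{clustering} (see \code{\link{clusterCohort}}), \code{sweep}
#'   (profile table from \code{\link{profileSweep}} over ICI patients).
#' @export
runPipeline <- function(cohort, clinical = NULL, panel = NULL, k = 10,
                        params = segmentationParams()) {
  if (is(cohort, "SyntheticCohort")) {
    if (is.null(clinical)) clinical <- clinicalTable(cohort)
    if (is.null(panel)) panel <- cohort@panel
    tissues <- cohortTissues(cohort)
  } else tissues <- cohort
  if (!length(tissues)) stop("no tissues to profile")
  features <- buildFeatureMatrix(tissues, panel, params)

  m <- featureValues(features)
  ici <- clinical$patient_id[clinical$ici_treated == 1]
  ici <- intersect(rownames(m), ici)
  clustering <- clusterCohort(m[ici, , drop = FALSE], k = min(k, length(ici)))

  ciIci <- clinical[match(ici, clinical$patient_id), ]
  sweep <- suppressWarnings(
    profileSweep(m[ici, , drop = FALSE], ciIci$pfs_days, ciIci$pfs_event,
                 ftme = clustering$ftme[ici]))
  list(features = features, clustering = clustering, sweep = sweep)
}
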
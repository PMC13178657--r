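## label groups used by the feature builder
.subsetGroups <- list(
  cd8    = c("cd8_trm", "cd8_t"),
  trm    = "cd8_trm",
  cd4    = c("cd4_t", "treg", "th1"),
  t_all  = c("cd8_trm", "cd8_t", "cd4_t", "treg", "th1", "nkt", "t_other"),
  treg   = "treg",
  th1    = "th1",
  nk     = "nk",
  nkt    = "nkt",
  b      = "b_cell",
  tam    = c("tam_m2_cd206", "tam_m2_cd163", "tam_m1", "tam_other"),
  dc     = "dc",
  mdsc   = "mdsc",
  stromal = c("caf", "stromal_other"),
  cancer = "cancer")

#' Cell density in a compartment
#'
#' @param count non-negative cell count.
#' @param areaMM2 compartment area in mm^2.
#' @return cells/mm^2, or \code{NA_real_} when the area is zero (undefined, not
#'   an error).
#' @export
cellDensity <- function(count, areaMM2) {
  if (any(count < 0) || any(areaMM2 < 0))
    stop("counts and areas must be non-negative")
  ifelse(areaMM2 > 0, count / areaMM2, NA_real_)
}

#' Effector-to-target (E/T) cell-count ratio
#'
#' Number of effector-subset cells divided by the number of cancer cells in
#' the same compartment; undefined when no cancer cell is present.
#'
#' @param labels subset labels.
#' @param compartment compartment factor from \code{\link{assignCompartment}}.
#' @param numeratorSubset label(s) forming the numerator.
#' @param where compartment to evaluate in (default TN).
#' @param extra optional logical per-cell mask further restricting the
#'   numerator (e.g. a phenotype positivity requirement).
#' @return ratio, or \code{NA_real_} when the compartment has no cancer cells.
#' @export
etRatio <- function(labels, compartment, numeratorSubset, where = "TN",
                    extra = NULL) {
  inComp <- compartment == where
  nCancer <- sum(labels == "cancer" & inComp)
  if (nCancer == 0L) return(NA_real_)
  num <- labels %in% numeratorSubset & inComp
  if (!is.null(extra)) num <- num & extra
  sum(num) / nCancer
}

#' Dichotomize a feature across patients
#'
#' Median scheme: \code{high} strictly above the median, \code{low} at or
#' below it (ties go low). Quartile scheme: four groups \code{Q1..Q4} split at
#' the quartiles. Missing values stay unlabelled (\code{NA}).
#'
#' @param values numeric vector with optional \code{NA}s.
#' @param scheme \code{"median"} or \code{"quartile"}.
#' @return factor of group labels aligned with \code{values}.
#' @export
dichotomize <- function(values, scheme = c("median", "quartile")) {
  scheme <- match.arg(scheme)
  if (all(is.na(values))) stop("cannot dichotomize: all values are missing")
  if (scheme == "median") {
    med <- median(values, na.rm = TRUE)
    out <- ifelse(is.na(values), NA_character_,
                  ifelse(values > med, "high", "low"))
    factor(out, levels = c("low", "high"))
  } else {
    qs <- quantile(values, probs = c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    cut(values, breaks = c(-Inf, qs, Inf), labels = c("Q1", "Q2", "Q3", "Q4"),
        right = TRUE)
  }
}

#' Gate, segment and compartmentalise one patient's cell table
#'
#' Runs the per-patient stages in order: marker binarisation, hierarchical
#' subset assignment, TN/ISA tissue segmentation, and per-cell compartment
#' assignment.
#'
#' @param cells a \code{\link{CellTable}}.
#' @param panel a \code{\link{MarkerPanel}}.
#' @param params segmentation parameters (\code{\link{segmentationParams}}).
#' @return list with elements \code{calls}, \code{labels}, \code{grid},
#'   \code{compartment}.
#' @export
profilePatient <- function(cells, panel, params = segmentationParams()) {
  calls <- binarizeMarkers(cells, panel)
  labels <- assignSubsets(calls, panel)
  grid <- segmentTissue(cells, labels, params)
  comp <- assignCompartment(cells, grid)
  list(calls = calls, labels = labels, grid = grid, compartment = comp)
}

.countIn <- function(labels, comp, subset, where) {
  if (identical(where, "IT")) sum(labels %in% subset)
  else sum(labels %in% subset & comp == where)
}

#' TME features for one profiled patient
#'
#' Computes the per-patient feature vector: compartment-specific densities
#' (cells/mm^2; intratumoral \code{_it} features use the combined TN+ISA
#' area), phenotype positivity fractions (undefined when the parent population
#' is absent) and effector-to-target ratios against cancer cells in TN.
#'
#' @param profile output of \code{\link{profilePatient}}.
#' @return named numeric vector (NA encodes undefined entries).
#' @export
patientFeatures <- function(profile) {
  calls <- profile$calls
  labels <- profile$labels
  comp <- profile$compartment
  areas <- compartmentAreas(profile$grid)
  aTN <- areas[["TN"]]; aISA <- areas[["ISA"]]; aIT <- aTN + aISA
  g <- .subsetGroups

  inTN <- comp == "TN"
  masks <- lapply(g, function(s) labels %in% s)
  dens <- function(subset, where) {
    sel <- masks[[subset]]
    n <- switch(where, TN = sum(sel & inTN), ISA = sum(sel & !inTN), IT = sum(sel))
    a <- switch(where, TN = aTN, ISA = aISA, IT = aIT)
    cellDensity(n, a)
  }
  posFrac <- function(subset, marker, where = NULL) {
    sel <- masks[[subset]]
    if (identical(where, "TN")) sel <- sel & inTN
    else if (identical(where, "ISA")) sel <- sel & !inTN
    n <- sum(sel)
    if (n == 0L) return(NA_real_)
    sum(calls[sel, marker]) / n
  }
  ki67TrmTN <- sum(masks$trm & inTN & calls[, "Ki67"])

  c(t_density_it          = dens("t_all", "IT"),
    cd8_til_density_it    = dens("cd8", "IT"),
    non_cd8_t_density_it  = cellDensity(sum(masks$t_all & !masks$cd8), aIT),
    cd8_til_density_tn    = dens("cd8", "TN"),
    cd8_til_density_isa   = dens("cd8", "ISA"),
    trm_cd8_density_tn    = dens("trm", "TN"),
    trm_cd8_density_isa   = dens("trm", "ISA"),
    ki67_trm_cd8_density_tn = cellDensity(ki67TrmTN, aTN),
    treg_density_it       = dens("treg", "IT"),
    pd1_treg_density_it   = cellDensity(sum(masks$treg & calls[, "PD1"]), aIT),
    th1_density_it        = dens("th1", "IT"),
    nk_density_it         = dens("nk", "IT"),
    nkt_density_it        = dens("nkt", "IT"),
    b_density_it          = dens("b", "IT"),
    tam_density_it        = dens("tam", "IT"),
    cd206_tam_density_it  = cellDensity(sum(masks$tam & calls[, "CD206"]), aIT),
    mdsc_density_it       = dens("mdsc", "IT"),
    dc_density_it         = dens("dc", "IT"),
    cd206_pos_tam         = posFrac("tam", "CD206"),
    cd163_pos_tam         = posFrac("tam", "CD163"),
    fap_pos_stromal_isa   = posFrac("stromal", "FAP", "ISA"),
    cd73_pos_cancer       = posFrac("cancer", "CD73"),
    pd1_pos_cd8_tn        = posFrac("cd8", "PD1", "TN"),
    lag3_pos_cd8_tn       = posFrac("cd8", "LAG3", "TN"),
    tim3_pos_cd8_tn       = posFrac("cd8", "TIM3", "TN"),
    tigit_pos_cd8_tn      = posFrac("cd8", "TIGIT", "TN"),
    et_cd8_tn             = etRatio(labels, comp, g$cd8),
    et_trm_cd8_tn         = etRatio(labels, comp, g$trm),
    et_ki67_trm_cd8_tn    = etRatio(labels, comp, g$trm, extra = calls[, "Ki67"]))
}

#' Assemble the cohort feature matrix
#'
#' Runs \code{\link{profilePatient}} + \code{\link{patientFeatures}} over a
#' set of patients and stacks the results into the patients x features matrix
#' that feeds clustering and the survival profile sweep. Undefined entries are
#' \code{NA} and are never imputed.
#'
#' @param tissues named list of \code{\link{CellTable}} objects (names are
#'   patient ids), or a \code{\link{SyntheticCohort}}.
#' @param panel a \code{\link{MarkerPanel}} (taken from the cohort when a
#'   \code{SyntheticCohort} is given).
#' @param params segmentation parameters.
#' @return a \code{\link{TMEFeatures}}.
#' @export
buildFeatureMatrix <- function(tissues, panel = NULL,
                               params = segmentationParams()) {
  if (is(tissues, "SyntheticCohort")) {
    if (is.null(panel)) panel <- tissues@panel
    tissues <- cohortTissues(tissues)
  }
  if (is.null(panel)) stop("a MarkerPanel is required")
  rows <- lapply(tissues, function(ct) {
    patientFeatures(profilePatient(ct, panel, params))
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(tissues)
  new("TMEFeatures", values = values)
}
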
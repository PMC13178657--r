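#' Construct a MarkerPanel
#'
#' @param markers data.frame with columns \code{name}, \code{threshold},
#'   \code{role}.
#' @param gating gating tree (list of nodes); see \code{\link{assignSubsets}}.
#' @return a validated \code{\link{MarkerPanel}}.
#' @export
markerPanel <- function(markers, gating = list()) {
  markers$name <- as.character(markers$name)
  markers$threshold <- as.numeric(markers$threshold)
  markers$role <- as.character(markers$role)
  new("MarkerPanel", markers = markers, gating = gating)
}

#' The default 29-marker mIHC panel
#'
#' The packaged panel covers the lineage and phenotype markers of a 29-plex
#' tumor-microenvironment IHC platform: epithelial/tumor (panCK), pan-leukocyte
#' (CD45), T-cell lineage (CD3, CD4, CD8, FOXP3, T-bet), tissue-resident-memory
#' proxies (CD39, CD103), NK/B (CD56, CD20), myeloid (CD68, CD163, CD206,
#' CD11c, CD11b, CD33, HLA-DR), stromal (FAP, aSMA), vascular (CD31),
#' checkpoint/effector phenotype (PD-1, PD-L1, LAG-3, TIM-3, TIGIT, GZMB,
#' Ki-67) and the adenosine pathway ectonucleotidase CD73. Thresholds are in
#' the platform's normalised intensity units.
#'
#' @return a \code{\link{MarkerPanel}} with 29 markers and the default gating
#'   tree (\code{\link{defaultGatingTree}}).
#' @export
defaultPanel <- function() {
  markers <- data.frame(
    name = c("panCK", "CD45", "CD3", "CD4", "CD8", "FOXP3", "Tbet", "CD39",
             "CD103", "CD56", "CD20", "CD68", "CD163", "CD206", "CD11c",
             "CD11b", "CD33", "HLADR", "FAP", "aSMA", "CD31", "PD1", "PDL1",
             "LAG3", "TIM3", "TIGIT", "GZMB", "Ki67", "CD73"),
    threshold = c(1.2, 1.0, 1.0, 0.9, 1.0, 0.8, 0.8, 0.9,
                  0.9, 0.8, 1.0, 1.1, 0.9, 0.9, 0.9,
                  1.0, 0.8, 1.0, 1.0, 1.1, 0.9, 0.8, 0.8,
                  0.7, 0.7, 0.7, 0.8, 0.9, 0.9),
    role = c("epithelial/tumor lineage", "pan-leukocyte", "T cell", "helper T",
             "cytotoxic T", "Treg transcription factor", "Th1 transcription factor",
             "ectonucleotidase, Trm proxy", "integrin alphaE, Trm proxy",
             "NK lineage", "B lineage", "macrophage", "M2 macrophage",
             "mannose receptor, M2 macrophage", "dendritic cell",
             "myeloid integrin", "myeloid progenitor", "MHC class II",
             "fibroblast activation protein (CAF)", "smooth muscle actin",
             "endothelial", "checkpoint receptor", "checkpoint ligand",
             "checkpoint receptor", "checkpoint receptor", "checkpoint receptor",
             "effector granzyme", "proliferation", "ecto-5'-nucleotidase"),
    stringsAsFactors = FALSE)
  markerPanel(markers, defaultGatingTree())
}

.panelToList <- function(panel) {
  list(
    markers = lapply(seq_len(nrow(panel@markers)), function(i) {
      as.list(panel@markers[i, c("name", "threshold", "role")])
    }),
    gating = .gatingToList(panel@gating))
}

.gatingToList <- function(nodes) {
  lapply(nodes, function(nd) {
    out <- list(label = nd$label, require = as.list(nd$require))
    if (!is.null(nd$children)) out$children <- .gatingToList(nd$children)
    out
  })
}

.gatingFromList <- function(nodes) {
  lapply(nodes, function(nd) {
    out <- list(label = nd$label,
                require = vapply(nd$require, as.character, character(1)))
    if (!is.null(nd$children)) out$children <- .gatingFromList(nd$children)
    out
  })
}

#' Read / write a panel + gating configuration
#'
#' Panels are serialised as YAML with a \code{markers} sequence (name,
#' threshold, role; order preserved) and a nested \code{gating} tree.
#' \code{readPanel(writePanel(p))} is the identity.
#'
#' @param path file path.
#' @param panel a \code{\link{MarkerPanel}}.
#' @return \code{readPanel} returns a \code{\link{MarkerPanel}};
#'   \code{writePanel} returns \code{path} invisibly.
#' @export
readPanel <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$markers) || !length(doc$markers))
    stop("panel file has no markers")
  markers <- do.call(rbind, lapply(doc$markers, function(m) {
    data.frame(name = as.character(m$name),
               threshold = suppressWarnings(as.numeric(m$threshold)),
               role = if (is.null(m$role)) "" else as.character(m$role),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(markers$threshold) || any(markers$threshold <= 0))
    stop("panel format error: thresholds must be positive numbers")
  markerPanel(markers, .gatingFromList(doc$gating))
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "MarkerPanel"))
  yaml::write_yaml(.panelToList(panel), path)
  invisible(path)
}
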
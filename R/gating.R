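#' The default hierarchical gating taxonomy
#'
#' Encodes the mutually exclusive cell taxonomy used throughout the pipeline.
#' Cancer cells are panCK+CD45-; cancer-associated fibroblasts (CAFs) are
#' panCK-CD45-FAP+; remaining panCK-CD45- cells are other stromal cells. The
#' CD45+ leukocyte branch splits into T cells (CD3+; NKT if CD56+, CD8 T with a
#' tissue-resident-memory-like CD39+CD103+ leaf, CD4 T with Treg FOXP3+ and Th1
#' T-bet+FOXP3- leaves), NK (CD56+), B (CD20+), tumor-associated macrophages
#' (CD68+; M2 by CD206, M2 by CD163 without CD206, M1 HLA-DR+CD163-CD206-),
#' dendritic cells (CD68-CD11c+HLA-DR+) and MDSCs (CD11b+CD33+HLA-DR-). A
#' node's own label is the terminal for cells matching the node but none of its
#' children; cells matching no root node are labelled \code{other}.
#'
#' @return a gating tree (list of nodes) with 20 terminal labels.
#' @seealso \code{\link{assignSubsets}}, \code{\link{gatingLabels}}
#' @export
defaultGatingTree <- function() {
  list(
    list(label = "cancer", require = c(panCK = "+", CD45 = "-")),
    list(label = "leukocyte_other", require = c(CD45 = "+"), children = list(
      list(label = "t_other", require = c(CD3 = "+"), children = list(
        list(label = "nkt", require = c(CD56 = "+")),
        list(label = "cd8_t", require = c(CD8 = "+"), children = list(
          list(label = "cd8_trm", require = c(CD39 = "+", CD103 = "+")))),
        list(label = "cd4_t", require = c(CD4 = "+"), children = list(
          list(label = "treg", require = c(FOXP3 = "+")),
          list(label = "th1", require = c(Tbet = "+", FOXP3 = "-")))))),
      list(label = "nk", require = c(CD56 = "+")),
      list(label = "b_cell", require = c(CD20 = "+")),
      list(label = "tam_other", require = c(CD68 = "+"), children = list(
        list(label = "tam_m2_cd206", require = c(CD206 = "+")),
        list(label = "tam_m2_cd163", require = c(CD163 = "+", CD206 = "-")),
        list(label = "tam_m1",
             require = c(HLADR = "+", CD163 = "-", CD206 = "-")))),
      list(label = "dc", require = c(CD68 = "-", CD11c = "+", HLADR = "+")),
      list(label = "mdsc", require = c(CD11b = "+", CD33 = "+", HLADR = "-")))),
    list(label = "caf", require = c(panCK = "-", CD45 = "-", FAP = "+")),
    list(label = "stromal_other", require = c(panCK = "-", CD45 = "-")))
}

#' Terminal labels of a gating tree
#'
#' @param tree a gating tree (or a \code{\link{MarkerPanel}}).
#' @return character vector of all subset labels the tree can emit, including
#'   the fallback \code{"other"}.
#' @export
gatingLabels <- function(tree) {
  if (is(tree, "MarkerPanel")) tree <- gatingTree(tree)
  c(.collectGateLabels(tree), "other")
}

#' Binarise marker intensities against panel thresholds
#'
#' A cell is called positive for a marker when its intensity is greater than or
#' equal to the panel threshold (the boundary itself is positive).
#'
#' @param cells a \code{\link{CellTable}}.
#' @param panel a \code{\link{MarkerPanel}} whose markers all appear in the
#'   table.
#' @return logical matrix, cells x markers.
#' @export
binarizeMarkers <- function(cells, panel) {
  ints <- cellIntensities(cells)
  thr <- markerThresholds(panel)
  missing <- setdiff(names(thr), colnames(ints))
  if (length(missing))
    stop(sprintf("cell table lacks panel marker(s): %s",
                 paste(missing, collapse = ", ")))
  if (!identical(colnames(ints), names(thr)))
    ints <- ints[, names(thr), drop = FALSE]
  calls <- ints >= rep(thr, each = nrow(ints))
  rownames(calls) <- cellIds(cells)
  calls
}

.evalPredicate <- function(calls, idx, require) {
  unknown <- setdiff(names(require), colnames(calls))
  if (length(unknown))
    stop(sprintf("gating predicate references unknown marker(s): %s",
                 paste(unknown, collapse = ", ")))
  ok <- rep(TRUE, length(idx))
  for (m in names(require)) {
    v <- calls[idx, m]
    ok <- ok & if (require[[m]] == "+") v else !v
  }
  ok
}

## first-match-wins traversal over integer candidate indices
.assignRec <- function(calls, nodes, idx, labels) {
  for (nd in nodes) {
    if (!length(idx)) {
      .evalPredicate(calls, idx, nd$require)  # still validate the predicate
      if (!is.null(nd$children)) labels <- .assignRec(calls, nd$children, idx, labels)
      next
    }
    ok <- .evalPredicate(calls, idx, nd$require)
    hit <- idx[ok]
    if (length(hit)) {
      if (!is.null(nd$children)) {
        labels <- .assignRec(calls, nd$children, hit, labels)
        hit <- hit[is.na(labels[hit])]
      }
      labels[hit] <- nd$label
    }
    idx <- idx[!ok]
  }
  labels
}

#' Assign each cell a mutually exclusive subset label
#'
#' Traverses the gating tree in priority order with first-match-wins
#' semantics: a cell is routed to the first root node whose marker predicate it
#' satisfies, then recursively to the first matching child; if no child
#' matches, the node's own label is terminal. Cells matching no root node are
#' labelled \code{"other"}. The traversal is per-cell, so permuting the input
#' permutes the output identically.
#'
#' @param calls logical cells x markers matrix from
#'   \code{\link{binarizeMarkers}}.
#' @param tree a gating tree or a \code{\link{MarkerPanel}}.
#' @return character vector of subset labels, one per cell, named by cell id
#'   when \code{calls} has row names.
#' @export
assignSubsets <- function(calls, tree) {
  if (is(tree, "MarkerPanel")) tree <- gatingTree(tree)
  labels <- rep(NA_character_, nrow(calls))
  labels <- .assignRec(calls, tree, seq_len(nrow(calls)), labels)
  labels[is.na(labels)] <- "other"
  names(labels) <- rownames(calls)
  labels
}

#' Phenotype positivity fraction within a subset
#'
#' Fraction of cells of a given subset that are positive for a phenotype
#' marker. When the parent subset is absent the fraction is undefined and
#' \code{NA_real_} is returned — such patients are excluded from downstream
#' comparisons rather than imputed.
#'
#' @param calls logical cells x markers matrix.
#' @param labels subset labels from \code{\link{assignSubsets}}.
#' @param subset character vector of subset labels forming the denominator.
#' @param marker phenotype marker name.
#' @param keep optional logical mask restricting the cells considered (e.g. a
#'   compartment selection).
#' @return a fraction in [0, 1], or \code{NA_real_} when no subset cell exists.
#' @export
positivityFraction <- function(calls, labels, subset, marker, keep = NULL) {
  if (!marker %in% colnames(calls))
    stop(sprintf("unknown phenotype marker: %s", marker))
  sel <- labels %in% subset
  if (!is.null(keep)) sel <- sel & keep
  n <- sum(sel)
  if (n == 0L) return(NA_real_)
  sum(calls[sel, marker]) / n
}
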
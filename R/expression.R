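#' The default 726-gene expression panel
#'
#' Gene roster for the bulk-expression companion analyses: the immune/stromal
#' anchor genes used by the composite profile and differential analyses
#' (CD8A, CD8B, FOXP3, NT5E, MRC1, FAP, ...), the packaged signalling /
#' microenvironment signature genes, and synthetic filler symbols
#' (\code{IO360.Gxxx}) bringing the panel to its fixed size of 726 genes.
#'
#' @param size panel size (default 726).
#' @return character vector of unique gene symbols.
#' @export
defaultGenePanel <- function(size = 726) {
  core <- unique(c(
    "CD8A", "CD8B", "FOXP3", "NT5E", "MRC1", "FAP", "CD274", "PDCD1",
    "GZMB", "MKI67", "ENTPD1", "ITGAE", "CD68", "CD163", "MS4A1", "NCAM1",
    unlist(defaultGeneSets(), use.names = FALSE)))
  if (size < length(core)) stop("panel size smaller than the core gene list")
  c(core, sprintf("IO360.G%03d", seq_len(size - length(core))))
}

#' Packaged gene-set signatures
#'
#' Small literature-style gene sets for the signature scores used in the
#' expression companion: MAPK and NF-kB signalling (RTK downstream
#' activation), antigen presentation, angiogenesis, TGF-beta signalling and
#' autophagy.
#'
#' @return named list of character vectors.
#' @export
defaultGeneSets <- function() {
  list(
    mapk = c("MAPK1", "MAPK3", "MAP2K1", "MAP2K2", "BRAF", "RAF1", "EGFR",
             "KRAS", "DUSP4", "DUSP6"),
    nfkb = c("NFKB1", "NFKB2", "RELA", "RELB", "REL", "NFKBIA", "TNF", "IL1B"),
    antigen_presentation = c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2",
                             "TAPBP", "PSMB8", "PSMB9"),
    angiogenesis = c("VEGFA", "VEGFB", "VEGFC", "FLT1", "KDR", "PECAM1",
                     "ANGPT1", "ANGPT2", "TEK"),
    tgf_beta = c("TGFB1", "TGFB2", "TGFB3", "TGFBR1", "TGFBR2", "SMAD2",
                 "SMAD3", "SMAD4"),
    autophagy = c("ATG5", "ATG7", "ATG12", "BECN1", "MAP1LC3B", "SQSTM1",
                  "ULK1"))
}

#' Per-gene differential expression between two groups
#'
#' For every gene: log2 fold change as the difference of group means (the
#' matrix is log2-scale) and an unpaired two-tailed Welch t-test, with
#' Benjamini-Hochberg q-values over all genes. The fold change is
#' \code{mean(groupA) - mean(groupB)} where A is the first factor level.
#'
#' @param mat numeric samples x genes log2 expression matrix.
#' @param group factor of two levels aligned with rows of \code{mat}.
#' @return data.frame: \code{gene}, \code{log2fc}, \code{t}, \code{p}, \code{q}.
#' @export
differentialExpression <- function(mat, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  a <- group == levels(group)[1]
  b <- group == levels(group)[2]
  na <- sum(a); nb <- sum(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  ma <- colMeans(mat[a, , drop = FALSE])
  mb <- colMeans(mat[b, , drop = FALSE])
  va <- apply(mat[a, , drop = FALSE], 2L, var)
  vb <- apply(mat[b, , drop = FALSE], 2L, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  data.frame(gene = colnames(mat), log2fc = unname(ma - mb),
             t = unname(tstat), p = unname(p), q = bhAdjust(unname(p)),
             stringsAsFactors = FALSE)
}

#' Gene-set signature score per sample
#'
#' Mean of per-gene z-scores (standardised across samples) over the set
#' members present in the matrix — a transparent surrogate for proprietary
#' panel scoring algorithms. Absent members are reported via a warning; a set
#' with no member present is an error.
#'
#' @param mat numeric samples x genes log2 expression matrix.
#' @param geneSet character vector of gene symbols.
#' @return named numeric score per sample (cohort mean 0 by construction).
#' @export
signatureScore <- function(mat, geneSet) {
  if (!length(geneSet)) stop("empty gene set")
  present <- intersect(geneSet, colnames(mat))
  if (!length(present))
    stop("no gene-set member present in the expression matrix")
  absent <- setdiff(geneSet, present)
  if (length(absent))
    warning(sprintf("gene-set member(s) absent from matrix: %s",
                    paste(absent, collapse = ", ")))
  z <- scale(mat[, present, drop = FALSE])
  setNames(rowMeans(z), rownames(mat))
}

#' Composite fTME-mimicking transcriptional profile
#'
#' Labels a sample \code{fTME-like} when CD8B is above the cohort median while
#' MRC1 (CD206) and FAP are at or below their medians — the transcriptional
#' counterpart of the favorable-TME cluster (tumor-reactive CD8 without
#' M2-TAMs or CAFs). Median ties go low, so the CD8B "high" test is strict.
#'
#' @param mat numeric samples x genes log2 expression matrix.
#' @param genes the three profile genes, in the order (high, low, low).
#' @return factor per sample with levels \code{fTME-like}, \code{other}.
#' @export
compositeProfile <- function(mat, genes = c("CD8B", "MRC1", "FAP")) {
  missing <- setdiff(genes, colnames(mat))
  if (length(missing))
    stop(sprintf("expression matrix lacks gene(s): %s",
                 paste(missing, collapse = ", ")))
  hi <- mat[, genes[1]] > median(mat[, genes[1]])
  lo2 <- mat[, genes[2]] <= median(mat[, genes[2]])
  lo3 <- mat[, genes[3]] <= median(mat[, genes[3]])
  out <- ifelse(hi & lo2 & lo3, "fTME-like", "other")
  out <- factor(out, levels = c("fTME-like", "other"))
  names(out) <- rownames(mat)
  out
}
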
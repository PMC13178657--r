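#' Tissue segmentation parameters
#'
#' Defaults: 20 um grid pitch, 30 um Gaussian kernel bandwidth, a tumor-nest
#' density threshold of 2.5e-4 cells/um^2 (a single cancer cell cannot form a
#' nest, a cluster of five can), and a 100 um reach for calling stroma around
#' cells. Field extent may be given explicitly; otherwise it is inferred from
#' the cell coordinates.
#'
#' @param pitch grid pitch g, micrometres.
#' @param bandwidth Gaussian kernel SD, micrometres.
#' @param tau nest density threshold, cells/um^2.
#' @param dmax maximum distance from any cell for a grid cell to count as
#'   intratumoral stroma, micrometres.
#' @param fieldWidth,fieldHeight optional field extent, micrometres.
#' @return a parameter list for \code{\link{segmentTissue}}.
#' @export
segmentationParams <- function(pitch = 20, bandwidth = 30, tau = 2.5e-4,
                               dmax = 100, fieldWidth = NULL, fieldHeight = NULL) {
  list(pitch = pitch, bandwidth = bandwidth, tau = tau, dmax = dmax,
       fieldWidth = fieldWidth, fieldHeight = fieldHeight)
}

## cells binned on the half-open convention: coordinate x falls in bin
## floor(x/g)+1, i.e. the grid cell covering [i*g, (i+1)*g).
.binIndex <- function(coord, pitch, n) {
  pmin(pmax(floor(coord / pitch) + 1L, 1L), n)
}

.binCounts <- function(coords, pitch, nx, ny) {
  m <- matrix(0L, nx, ny)
  if (nrow(coords)) {
    ix <- .binIndex(coords[, 1], pitch, nx)
    iy <- .binIndex(coords[, 2], pitch, ny)
    m <- matrix(tabulate(ix + (iy - 1L) * nx, nbins = nx * ny), nx, ny)
  }
  m
}

## separable Gaussian kernel density on the grid, cells/um^2 at bin centres;
## the smoothing matrices depend only on (n, pitch, bandwidth) and are cached
.kdeCache <- new.env(parent = emptyenv())
.smoothMat <- function(n, pitch, bandwidth) {
  key <- paste(n, pitch, bandwidth, sep = "_")
  if (is.null(.kdeCache[[key]])) {
    idx <- seq_len(n)
    .kdeCache[[key]] <- outer(idx, idx,
                              function(i, j) dnorm((i - j) * pitch, sd = bandwidth))
  }
  .kdeCache[[key]]
}
.binnedKde <- function(counts, pitch, bandwidth) {
  Ax <- .smoothMat(nrow(counts), pitch, bandwidth)
  Ay <- .smoothMat(ncol(counts), pitch, bandwidth)
  Ax %*% counts %*% Ay
}

.brushCache <- new.env(parent = emptyenv())
.brush <- function(size, shape) {
  key <- paste0(shape, size)
  if (is.null(.brushCache[[key]]))
    .brushCache[[key]] <- EBImage::makeBrush(size, shape = shape)
  .brushCache[[key]]
}

.dilate <- function(mask, brush) {
  EBImage::dilate(mask * 1, brush) > 0
}

.erode <- function(mask, brush) {
  EBImage::erode(mask * 1, brush) > 0
}

#' Segment a field into tumor-nest (TN) and intratumoral-stroma (ISA) compartments
#'
#' A Gaussian kernel density of cancer-cell positions is evaluated on a square
#' grid; grid cells at or above the density threshold form the TN mask, which
#' is regularised by one pass of morphological closing (dilate then erode by
#' one grid cell). Non-TN grid cells within \code{dmax} of any cell are
#' intratumoral stroma; remaining grid cells are cell-free background, which is
#' excluded from both compartment areas.
#'
#' @param cells a \code{\link{CellTable}} (may be empty: the result is an
#'   all-background grid).
#' @param labels subset labels from \code{\link{assignSubsets}} identifying
#'   cancer cells.
#' @param params see \code{\link{segmentationParams}}.
#' @param cancerLabel subset label treated as cancer.
#' @return a \code{\link{SegmentationGrid}}.
#' @export
segmentTissue <- function(cells, labels, params = segmentationParams(),
                          cancerLabel = "cancer") {
  g <- params$pitch
  xy <- cellCoords(cells)
  w <- params$fieldWidth
  h <- params$fieldHeight
  if (is.null(w)) w <- if (nrow(xy)) max(xy[, "x"]) + g else g
  if (is.null(h)) h <- if (nrow(xy)) max(xy[, "y"]) + g else g
  nx <- max(1L, as.integer(ceiling(w / g)))
  ny <- max(1L, as.integer(ceiling(h / g)))

  lab <- matrix(3L, nx, ny)  # 1 TN, 2 ISA, 3 background
  if (nrow(xy)) {
    cancer <- .binCounts(xy[labels == cancerLabel, , drop = FALSE], g, nx, ny)
    tn <- matrix(FALSE, nx, ny)
    if (any(cancer > 0)) {
      dens <- .binnedKde(cancer, g, params$bandwidth)
      tn <- dens >= params$tau
      b3 <- .brush(3, "box")
      tn <- .erode(.dilate(tn, b3), b3)      # one closing pass
    }
    occupied <- .binCounts(xy, g, nx, ny) > 0
    reach <- 2L * as.integer(ceiling(params$dmax / g)) + 1L
    near <- .dilate(occupied, .brush(reach, "disc"))
    lab[near] <- 2L
    lab[tn] <- 1L
  }
  areas <- c(TN = sum(lab == 1L), ISA = sum(lab == 2L),
             background = sum(lab == 3L)) * g^2 / 1e6
  new("SegmentationGrid", labels = lab, pitch = g, areas = areas)
}

#' Assign each cell to a tissue compartment
#'
#' A cell takes the label of the grid cell containing its half-open interval
#' \code{[x, x+g)}; cells falling on background grid cells are assigned ISA
#' (they are, by definition, tissue).
#'
#' @param cells a \code{\link{CellTable}}.
#' @param grid a \code{\link{SegmentationGrid}} covering the cells.
#' @return factor of \code{"TN"}/\code{"ISA"} per cell.
#' @export
assignCompartment <- function(cells, grid) {
  xy <- cellCoords(cells)
  lab <- gridLabels(grid)
  ix <- .binIndex(xy[, "x"], grid@pitch, nrow(lab))
  iy <- .binIndex(xy[, "y"], grid@pitch, ncol(lab))
  v <- lab[cbind(ix, iy)]
  factor(ifelse(v == 1L, "TN", "ISA"), levels = c("TN", "ISA"))
}
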
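## shared fixtures: a tiny 4-marker panel with a 3-label tree, quick cell-table
## builders, and a scaled-down cohort configuration

tinyPanel <- function() {
  markers <- data.frame(
    name = c("A", "B", "C", "F"),
    threshold = c(1, 1, 1, 2),
    role = "test", stringsAsFactors = FALSE)
  tree <- list(
    list(label = "alpha", require = c(A = "+", B = "-")),
    list(label = "beta", require = c(B = "+"), children = list(
      list(label = "beta_c", require = c(C = "+")))))
  markerPanel(markers, tree)
}

## cells on a line with given marker intensities (one row per cell)
makeCells <- function(ints, x = NULL, y = NULL) {
  n <- nrow(ints)
  if (is.null(x)) x <- seq_len(n) * 10
  if (is.null(y)) y <- rep(5, n)
  cellTable(sprintf("c%03d", seq_len(n)), x, y, as.matrix(ints))
}

## a call matrix over the default 29-marker panel with the named markers on
callRow <- function(...) {
  pos <- c(...)
  m <- matrix(FALSE, 1, 29, dimnames = list(NULL, markerNames(defaultPanel())))
  m[, pos] <- TRUE
  m
}

## default calibration scaled down to a fast 14-patient cohort
miniConfig <- function(seed = 42) {
  cfg <- defaultCohortConfig()
  cfg@counts[c("n_total", "n_ici", "n_egfr", "n_alk", "n_wt", "n_dcb",
               "n_nondcb", "n_earlycensor", "n_ici_egfr", "n_ici_alk",
               "n_favorable", "n_favorable_dcb")] <-
    c(14L, 10L, 2L, 2L, 10L, 4L, 5L, 1L, 1L, 1L, 2L, 2L)
  cfg@geometry$field_width <- 1200
  cfg@geometry$field_height <- 1200
  cfg@geometry$nest_radius_median <- 300
  cfg@geometry$nest_radius_min <- 250
  cfg@geometry$nest_radius_max <- 330
  cfg@seed <- as.integer(seed)
  cfg
}

## one generated patient profile + geometry from the default calibration
sampleProfile <- function(seed = 5, overrides = list()) {
  cfg <- defaultCohortConfig()
  co <- generateCohort(cfg, tissues = FALSE, expression = FALSE, seed = seed)
  tr <- truthTable(co)
  prof <- c(as.list(tr[1, setdiff(names(tr), c("patient_id", "outcome_class",
                                               "favorable", "low_cd8_latent"))]),
            list(patient_id = "PTX", pdl1_tps = 40))
  prof[names(overrides)] <- overrides
  prof
}

zeroImmuneOverrides <- function() {
  subs <- c("cd8", "treg", "th1", "cd4", "nk", "nkt", "b", "tam", "dc",
            "mdsc", "leuk")
  out <- as.list(rep(0, 2 * length(subs)))
  names(out) <- c(paste0(subs, "_tn"), paste0(subs, "_isa"))
  out
}

## Rand index between two partitions
randIndex <- function(a, b) {
  n <- length(a)
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  agree <- sum(sa == sb) - n
  agree / (n * (n - 1))
}
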
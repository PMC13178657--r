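#' Construct a cohort-generator configuration
#'
#' See \code{\link{CohortConfig}} for slot semantics and
#' \code{\link{defaultCohortConfig}} for the packaged calibration.
#'
#' @param counts,survival,geometry,cells,markers,intensity,expression,seed
#'   components as documented in \code{\link{CohortConfig}}.
#' @return a validated \code{\link{CohortConfig}}.
#' @export
cohortConfig <- function(counts, survival, geometry, cells, markers,
                         intensity, expression, seed = 42L) {
  new("CohortConfig",
      counts = setNames(as.integer(counts), names(counts)),
      survival = survival, geometry = geometry, cells = cells,
      markers = markers, intensity = intensity, expression = expression,
      seed = as.integer(seed))
}

#' The packaged default cohort calibration
#'
#' Reads the default configuration shipped in \code{inst/extdata/}
#' (\code{default_cohort.yaml}): a 103-patient metastatic NSCLC cohort with 81
#' ICI-treated patients (30 durable-clinical-benefit, 49 non-DCB, 2
#' early-censored), 19 EGFR-mutant / 13 ALK-fusion / 71 wild-type tumors,
#' outcome calibration HR(PFS, DCB vs non-DCB) = 0.15, HR(OS) = 0.11,
#' multivariable HR(low vs high TN CD8 density) = 1.79, and an 11-patient
#' planted favorable-TME subset.
#'
#' @return a \code{\link{CohortConfig}}.
#' @export
defaultCohortConfig <- function() {
  readCohortConfig(system.file("extdata", "default_cohort.yaml",
                               package = "mihcTME", mustWork = TRUE))
}

.numVec <- function(x) setNames(vapply(x, as.numeric, numeric(1)), names(x))

#' Read / write a cohort configuration (YAML)
#'
#' @param path file path.
#' @param config a \code{\link{CohortConfig}}.
#' @return \code{readCohortConfig} returns a \code{\link{CohortConfig}};
#'   \code{writeCohortConfig} returns \code{path} invisibly.
#' @export
readCohortConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  asBeta <- function(x) {
    if (is.list(x) && !is.null(x$other))
      list(other = .numVec(x$other), favorable = .numVec(x$favorable))
    else .numVec(x)
  }
  cells <- doc$cells
  cells$densities <- lapply(cells$densities, .numVec)
  cells$trm_frac <- asBeta(cells$trm_frac)
  markers <- lapply(doc$markers, asBeta)
  expr <- doc$expression
  expr$effects <- .numVec(expr$effects)
  expr$set_effects <- .numVec(expr$set_effects)
  cohortConfig(counts = unlist(doc$counts), survival = .numVec(doc$survival),
               geometry = doc$geometry, cells = cells, markers = markers,
               intensity = .numVec(doc$intensity), expression = expr,
               seed = doc$seed)
}

#' @rdname readCohortConfig
#' @export
writeCohortConfig <- function(config, path) {
  doc <- list(counts = as.list(config@counts),
              survival = as.list(config@survival),
              geometry = config@geometry,
              cells = list(
                cancer_density = config@cells$cancer_density,
                stromal_density = config@cells$stromal_density,
                densities = lapply(config@cells$densities, as.list),
                trm_frac = lapply(config@cells$trm_frac, as.list)),
              markers = lapply(config@markers, function(x) {
                if (is.list(x)) lapply(x, as.list) else as.list(x)
              }),
              intensity = as.list(config@intensity),
              expression = list(
                n_genes = config@expression$n_genes,
                n_egfr = config@expression$n_egfr,
                n_wt = config@expression$n_wt,
                noise_sd = config@expression$noise_sd,
                effects = as.list(config@expression$effects),
                set_effects = as.list(config@expression$set_effects)),
              seed = config@seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

.childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 97 + as.numeric(index) * 7919) %% 2147483629 + 1)
}

## sample k elements from the vector x (never from 1:x)
.sampleFrom <- function(x, k) x[sample.int(length(x), min(k, length(x)))]

.cnt <- function(ct, name, default = 0L) {
  if (name %in% names(ct)) ct[[name]] else as.integer(default)
}

.rbeta1 <- function(n, ab) rbeta(n, ab[["a"]], ab[["b"]])

## per-patient latent TME parameters; favorable patients get the
## tumor-reactive-high / M2-low / CAF-low profile. A shared per-patient
## "inflammation" factor couples overall immune/stromal cellularity (CD8 and
## TAM densities, CAF fraction), as in real tumors where hot and desmoplastic
## phenotypes co-occur.
.drawLatents <- function(n, favorable, driver, cfg) {
  cl <- cfg@cells; mk <- cfg@markers
  dn <- cl$densities
  infl <- rnorm(n)
  lamb <- function(sub, comp, load = 0) {
    v <- dn[[sub]]
    z <- if (load > 0) load * infl + sqrt(1 - load^2) * rnorm(n) else rnorm(n)
    v[[comp]] * exp(v[["sdlog"]] * z)
  }
  pick <- function(spec) {
    out <- .rbeta1(n, spec$other)
    if (any(favorable)) out[favorable] <- .rbeta1(sum(favorable), spec$favorable)
    out
  }
  lat <- data.frame(
    cd8_tn = lamb("cd8", "tn", load = 0.75),
    cd8_isa = lamb("cd8", "isa", load = 0.5),
    treg_tn = lamb("treg", "tn"), treg_isa = lamb("treg", "isa"),
    th1_tn = lamb("th1", "tn"), th1_isa = lamb("th1", "isa"),
    cd4_tn = lamb("cd4", "tn"), cd4_isa = lamb("cd4", "isa"),
    nk_tn = lamb("nk", "tn"), nk_isa = lamb("nk", "isa"),
    nkt_tn = lamb("nkt", "tn"), nkt_isa = lamb("nkt", "isa"),
    b_tn = lamb("b", "tn"), b_isa = lamb("b", "isa"),
    tam_tn = lamb("tam", "tn", load = 0.85),
    tam_isa = lamb("tam", "isa", load = 0.85),
    dc_tn = lamb("dc", "tn"), dc_isa = lamb("dc", "isa"),
    mdsc_tn = lamb("mdsc", "tn"), mdsc_isa = lamb("mdsc", "isa"),
    leuk_tn = lamb("leukocyte_other", "tn"), leuk_isa = lamb("leukocyte_other", "isa"))
  lat$trm_frac <- pick(cl$trm_frac)
  lat$ki67_trm <- pick(mk$ki67_trm)
  lat$p206 <- pick(mk$cd206_tam)
  ## CAF fraction rides the inflammation factor in the background group
  caf <- plogis(qlogis(.rbeta1(n, mk$fap_stromal$other)) + 0.55 * infl)
  if (any(favorable))
    caf[favorable] <- .rbeta1(sum(favorable), mk$fap_stromal$favorable)
  lat$caf_frac <- caf
  lat$p163 <- .rbeta1(n, mk$cd163_tam)
  lat$ki67_cd8t <- .rbeta1(n, mk$ki67_cd8t)
  lat$ki67_cancer <- .rbeta1(n, mk$ki67_cancer)
  lat$pd1_trm <- .rbeta1(n, mk$pd1_trm)
  lat$pd1_cd8t <- .rbeta1(n, mk$pd1_cd8t)
  lat$pd1_treg <- .rbeta1(n, mk$pd1_treg)
  lat$pd1_cd4 <- .rbeta1(n, mk$pd1_cd4)
  lat$lag3_trm <- .rbeta1(n, mk$lag3_trm)
  lat$tim3_trm <- .rbeta1(n, mk$tim3_trm)
  lat$tigit_trm <- .rbeta1(n, mk$tigit_trm)
  lat$lag3_cd8t <- .rbeta1(n, mk$lag3_cd8t)
  lat$tim3_cd8t <- .rbeta1(n, mk$tim3_cd8t)
  lat$tigit_cd8t <- .rbeta1(n, mk$tigit_cd8t)
  lat$gzmb_cd8 <- .rbeta1(n, mk$gzmb_cd8)
  lat$tbet_nk <- .rbeta1(n, mk$tbet_nk)
  lat$pdl1_tam <- .rbeta1(n, mk$pdl1_tam)
  isDriver <- driver %in% c("EGFR", "ALK")
  lat$cd73_cancer <- .rbeta1(n, mk$cd73_cancer_wt)
  if (any(isDriver))
    lat$cd73_cancer[isDriver] <- .rbeta1(sum(isDriver), mk$cd73_cancer_driver)
  lat
}

#' Sample a patient's tissue geometry
#'
#' Nests are placed along the field diagonal with positional jitter;
#' radii are log-normal, clamped so every nest lies fully inside the field and
#' nests cannot overlap.
#'
#' @param geometry the \code{geometry} component of a
#'   \code{\link{CohortConfig}}.
#' @return list: \code{width}, \code{height} (um), \code{centers} (n x 2
#'   matrix), \code{radii} (um), \code{nestAreaMM2}, \code{stromaAreaMM2}.
#' @export
tissueGeometry <- function(geometry) {
  w <- geometry$field_width; h <- geometry$field_height
  k <- geometry$n_nests
  if (k == 0L) {
    return(list(width = w, height = h,
                centers = matrix(numeric(0), 0, 2), radii = numeric(0),
                nestAreaMM2 = 0, stromaAreaMM2 = w * h / 1e6))
  }
  r <- geometry$nest_radius_median * exp(rnorm(k, 0, geometry$nest_radius_sdlog))
  r <- pmin(pmax(r, geometry$nest_radius_min), geometry$nest_radius_max)
  frac <- (seq_len(k) - 0.5) / k
  jit <- geometry$nest_jitter
  cx <- frac * w + runif(k, -jit, jit)
  cy <- frac * h + runif(k, -jit, jit)
  cx <- pmin(pmax(cx, r), w - r)
  cy <- pmin(pmax(cy, r), h - r)
  list(width = w, height = h, centers = cbind(cx, cy), radii = r,
       nestAreaMM2 = sum(pi * r^2) / 1e6,
       stromaAreaMM2 = (w * h - sum(pi * r^2)) / 1e6)
}

.inNest <- function(x, y, geom) {
  inside <- rep(FALSE, length(x))
  if (!nrow(geom$centers)) return(inside)
  for (i in seq_along(geom$radii)) {
    inside <- inside |
      ((x - geom$centers[i, 1])^2 + (y - geom$centers[i, 2])^2 <= geom$radii[i]^2)
  }
  inside
}

.pointsInNests <- function(n, geom) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  areas <- geom$radii^2
  nest <- sample.int(length(geom$radii), n, replace = TRUE, prob = areas)
  rr <- geom$radii[nest] * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = geom$centers[nest, 1] + rr * cos(th),
        y = geom$centers[nest, 2] + rr * sin(th))
}

.pointsInStroma <- function(n, geom) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- runif(m, 0, geom$width); y <- runif(m, 0, geom$height)
    keep <- !.inNest(x, y, geom)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

## cell-level marker positivity probabilities per generated subset; built as a
## small subset x marker matrix and expanded by row indexing
.markerProbs <- function(labels, prof, panel) {
  mk <- markerNames(panel)
  subsets <- c("cancer", "caf", "stromal_other", "cd8_trm", "cd8_t", "treg",
               "th1", "cd4_t", "nkt", "t_other", "nk", "b_cell",
               "tam_m2_cd206", "tam_m2_cd163", "tam_m1", "tam_other", "dc",
               "mdsc", "leukocyte_other")
  P <- matrix(0, length(subsets), length(mk),
              dimnames = list(subsets, mk))
  set <- function(sub, marker, p) {
    P[sub, marker] <<- p
  }
  pdl1_cancer <- if (is.na(prof$pdl1_tps)) 0.3 else prof$pdl1_tps / 100
  set("cancer", "panCK", 1); set("cancer", "CD73", prof$cd73_cancer)
  set("cancer", "Ki67", prof$ki67_cancer); set("cancer", "PDL1", pdl1_cancer)
  set("caf", "FAP", 1); set("caf", "aSMA", 0.8)
  set("stromal_other", "aSMA", 0.3)
  for (sub in c("cd8_trm", "cd8_t", "treg", "th1", "cd4_t", "nkt", "t_other"))
    set(sub, "CD3", 1)
  for (sub in c("cd8_trm", "cd8_t", "treg", "th1", "cd4_t", "nkt", "t_other",
                "nk", "b_cell", "tam_m2_cd206", "tam_m2_cd163", "tam_m1",
                "tam_other", "dc", "mdsc", "leukocyte_other"))
    set(sub, "CD45", 1)
  set("cd8_trm", "CD8", 1); set("cd8_trm", "CD39", 1); set("cd8_trm", "CD103", 1)
  set("cd8_trm", "PD1", prof$pd1_trm); set("cd8_trm", "LAG3", prof$lag3_trm)
  set("cd8_trm", "TIM3", prof$tim3_trm); set("cd8_trm", "TIGIT", prof$tigit_trm)
  set("cd8_trm", "Ki67", prof$ki67_trm); set("cd8_trm", "GZMB", prof$gzmb_cd8)
  set("cd8_t", "CD8", 1); set("cd8_t", "CD39", 0.3)
  set("cd8_t", "PD1", prof$pd1_cd8t); set("cd8_t", "LAG3", prof$lag3_cd8t)
  set("cd8_t", "TIM3", prof$tim3_cd8t); set("cd8_t", "TIGIT", prof$tigit_cd8t)
  set("cd8_t", "Ki67", prof$ki67_cd8t); set("cd8_t", "GZMB", prof$gzmb_cd8)
  set("treg", "CD4", 1); set("treg", "FOXP3", 1)
  set("treg", "PD1", prof$pd1_treg); set("treg", "CD39", 0.4)
  set("treg", "Ki67", 0.1)
  set("th1", "CD4", 1); set("th1", "Tbet", 1)
  set("cd4_t", "CD4", 1); set("cd4_t", "PD1", prof$pd1_cd4)
  set("nkt", "CD56", 1); set("nkt", "CD8", 0.3)
  set("nk", "CD56", 1); set("nk", "GZMB", 0.6); set("nk", "Tbet", prof$tbet_nk)
  set("b_cell", "CD20", 1); set("b_cell", "HLADR", 0.8)
  for (sub in c("tam_m2_cd206", "tam_m2_cd163", "tam_m1", "tam_other")) {
    set(sub, "CD68", 1); set(sub, "CD11b", 1); set(sub, "PDL1", prof$pdl1_tam)
  }
  set("tam_m2_cd206", "CD206", 1); set("tam_m2_cd206", "CD163", 0.5)
  set("tam_m2_cd206", "HLADR", 0.5)
  set("tam_m2_cd163", "CD163", 1); set("tam_m2_cd163", "HLADR", 0.5)
  set("tam_m1", "HLADR", 1)
  set("dc", "CD11c", 1); set("dc", "HLADR", 1); set("dc", "CD11b", 0.5)
  set("mdsc", "CD11b", 1); set("mdsc", "CD33", 1)
  P[match(labels, subsets), , drop = FALSE]
}

#' Generate one patient's synthetic cell table
#'
#' Cancer cells are placed uniformly inside the nests only; CAFs and other
#' stromal cells only outside them; immune subsets follow homogeneous Poisson
#' processes with compartment-specific intensities from the patient profile.
#' Marker intensities are drawn from a two-component log-normal per marker
#' (positive component \code{threshold * exp(+offset*sigma)}, negative
#' \code{threshold * exp(-offset*sigma)}, both with log-SD \code{sigma}), so
#' thresholding at the panel threshold recovers the generating positivity
#' call with per-marker error \code{pnorm(-offset)}.
#'
#' @param prof patient profile: a list/one-row data.frame with the latent
#'   densities (cells/mm^2) and positivity probabilities drawn by
#'   \code{\link{generateCohort}}, plus \code{pdl1_tps} and
#'   \code{patient_id}.
#' @param geom a geometry from \code{\link{tissueGeometry}}.
#' @param panel a \code{\link{MarkerPanel}}.
#' @param cfg a \code{\link{CohortConfig}} (intensity model and structural
#'   densities).
#' @param seed optional integer seed for this patient's RNG stream.
#' @param withTruth return the generating subset labels alongside the table.
#' @return a \code{\link{CellTable}}, or (when \code{withTruth}) a list with
#'   \code{cells} and \code{labels}.
#' @export
generatePatientTissue <- function(prof, geom, panel, cfg, seed = NULL,
                                  withTruth = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  aTN <- geom$nestAreaMM2; aST <- geom$stromaAreaMM2
  tamSplit <- function(nTam) {
    if (nTam == 0L) return(character(0))
    u <- runif(nTam)
    p206 <- prof$p206; p163 <- (1 - p206) * prof$p163
    m1 <- (1 - p206 - p163) * cfg@markers$m1_frac
    ifelse(u < p206, "tam_m2_cd206",
           ifelse(u < p206 + p163, "tam_m2_cd163",
                  ifelse(u < p206 + p163 + m1, "tam_m1", "tam_other")))
  }
  immune <- c(cd8 = NA, treg = "treg", th1 = "th1", cd4 = "cd4_t", nk = "nk",
              nkt = "nkt", b = "b_cell", tam = NA, dc = "dc", mdsc = "mdsc",
              leuk = "leukocyte_other")

  labels <- character(0); xy <- matrix(numeric(0), 0, 2)
  addCells <- function(lab, pts) {
    labels <<- c(labels, lab)
    xy <<- rbind(xy, pts)
  }
  nCancer <- rpois(1, cfg@cells$cancer_density * aTN)
  addCells(rep("cancer", nCancer), .pointsInNests(nCancer, geom))
  nStroma <- rpois(1, cfg@cells$stromal_density * aST)
  nCaf <- rbinom(1, nStroma, prof$caf_frac)
  addCells(c(rep("caf", nCaf), rep("stromal_other", nStroma - nCaf)),
           .pointsInStroma(nStroma, geom))
  for (comp in c("tn", "isa")) {
    area <- if (comp == "tn") aTN else aST
    placer <- if (comp == "tn") .pointsInNests else .pointsInStroma
    for (sub in names(immune)) {
      lam <- prof[[paste0(sub, "_", comp)]]
      n <- rpois(1, lam * area)
      if (n == 0L) next
      lab <- if (sub == "cd8") {
        nTrm <- rbinom(1, n, prof$trm_frac)
        c(rep("cd8_trm", nTrm), rep("cd8_t", n - nTrm))
      } else if (sub == "tam") tamSplit(n) else rep(immune[[sub]], n)
      addCells(lab, placer(n, geom))
    }
  }
  n <- length(labels)
  ord <- sample.int(max(n, 1L))[seq_len(n)]
  labels <- labels[ord]; xy <- xy[ord, , drop = FALSE]

  P <- .markerProbs(labels, prof, panel)
  sg <- cfg@intensity[["sigma"]]; off <- cfg@intensity[["offset"]]
  thr <- markerThresholds(panel)
  npr <- length(P)
  B <- runif(npr) < P                      # positivity draws (matrix layout)
  ints <- exp(sg * (off * (2 * B - 1) + rnorm(npr)) +
              rep(log(thr), each = nrow(P)))
  dim(ints) <- dim(P)
  colnames(ints) <- names(thr)
  ids <- sprintf("%s_c%05d", prof$patient_id, seq_len(n))
  cells <- cellTable(ids, xy[, 1], xy[, 2], ints)
  if (withTruth) list(cells = cells, labels = setNames(labels, ids)) else cells
}

#' Generate a synthetic mNSCLC cohort
#'
#' Generates clinical metadata, per-patient spatial single-cell tables and a
#' bulk expression matrix with the statistical structure the downstream
#' analysis assumes:
#' \itemize{
#' \item stratum counts (total / ICI-treated / driver-oncogene status /
#'   outcome classes) match the configuration exactly;
#' \item the planted outcome class (durable clinical benefit, non-DCB,
#'   early-censored) carries the configured PFS and OS hazard ratios in an
#'   exponential proportional-hazards model whose log-hazard also includes the
#'   configured low-TN-CD8-density effect; responder status is sampled with
#'   odds tilted toward high-CD8 patients (the association the analysis
#'   targets);
#' \item observed PFS is a rank-preserving linear rescaling of the latent
#'   model times that places exactly \code{n_dcb} ICI patients at or beyond
#'   the one-year boundary, so the 1-year classifier reproduces the configured
#'   class counts exactly while Cox estimates (which depend only on ranks) are
#'   unaffected; administrative censoring at the configured horizon;
#' \item a planted favorable-TME subset (high functional tumor-reactive CD8,
#'   low M2-TAM, low CAF) of the configured size, enriched among responders.
#' }
#' Identical seeds give byte-identical cohorts; per-patient tissues use child
#' RNG streams keyed by patient index, so any patient's tissue can be
#' regenerated in isolation.
#'
#' @param config a \code{\link{CohortConfig}}.
#' @param tissues which per-patient cell tables to generate (the slowest
#'   part): \code{TRUE}/\code{"all"}, \code{"ici"} (ICI arm only; the spatial
#'   analyses are confined to that arm) or \code{FALSE}/\code{"none"} for
#'   clinical-only replicates. Per-patient child RNG streams make the tissues
#'   identical whichever subset is materialised.
#' @param expression generate the bulk expression matrix.
#' @param seed overrides \code{config@seed}.
#' @param panel a \code{\link{MarkerPanel}} (default \code{\link{defaultPanel}}).
#' @return a \code{\link{SyntheticCohort}}.
#' @export
generateCohort <- function(config, tissues = TRUE, expression = TRUE,
                           seed = NULL, panel = defaultPanel()) {
  validObject(config)
  ct <- config@counts; sv <- config@survival
  if (is.null(seed)) seed <- config@seed
  seed <- as.integer(seed)
  set.seed(seed)
  n <- ct[["n_total"]]

  emptyClin <- data.frame(patient_id = character(0), ici_treated = integer(0),
    pfs_days = numeric(0), pfs_event = integer(0), os_days = numeric(0),
    os_event = integer(0), treatment_line = integer(0), regimen = character(0),
    histology = character(0), driver_status = character(0),
    ecog_ps = integer(0), pdl1_tps = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(new("SyntheticCohort", clinical = emptyClin,
               truth = data.frame(patient_id = character(0)),
               tissues = list(), geometry = list(), expression = NULL,
               expressionGroup = factor(), panel = panel, config = config))
  }

  ids <- sprintf("PT%03d", seq_len(n))
  nIci <- ct[["n_ici"]]
  ici <- logical(n); ici[.sampleFrom(seq_len(n), nIci)] <- TRUE

  ## driver status: configured EGFR/ALK counts inside the ICI arm, remainder
  ## distributed over the non-ICI arm
  driver <- rep("wild-type", n)
  iciIdx <- which(ici); nonIdx <- which(!ici)
  nIciEgfr <- min(.cnt(ct, "n_ici_egfr"), nIci, ct[["n_egfr"]])
  nIciAlk <- min(.cnt(ct, "n_ici_alk"), nIci - nIciEgfr, ct[["n_alk"]])
  pickIci <- .sampleFrom(iciIdx, nIciEgfr + nIciAlk)
  if (nIciEgfr > 0) driver[pickIci[seq_len(nIciEgfr)]] <- "EGFR"
  if (nIciAlk > 0) driver[pickIci[nIciEgfr + seq_len(nIciAlk)]] <- "ALK"
  nRestEgfr <- ct[["n_egfr"]] - nIciEgfr
  nRestAlk <- ct[["n_alk"]] - nIciAlk
  if (nRestEgfr + nRestAlk > length(nonIdx))
    stop("configuration error: driver counts exceed the non-ICI arm")
  pickNon <- .sampleFrom(nonIdx, nRestEgfr + nRestAlk)
  if (nRestEgfr > 0) driver[pickNon[seq_len(nRestEgfr)]] <- "EGFR"
  if (nRestAlk > 0) driver[pickNon[nRestEgfr + seq_len(nRestAlk)]] <- "ALK"

  isDriver <- driver %in% c("EGFR", "ALK")
  histology <- ifelse(runif(n) < ifelse(isDriver, 0.95, 0.62), "adenocarcinoma",
                      ifelse(runif(n) < 0.9, "squamous", "adenosquamous"))
  ecog <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.5, 0.1))
  line <- sample(1:2, n, replace = TRUE, prob = c(0.55, 0.45))
  regimen <- sample(c("monotherapy", "combination"), n, replace = TRUE)
  tps <- ifelse(runif(n) < 0.25, 0, round(100 * rbeta(n, 0.8, 1.2)))
  tps[sample.int(n, min(n, round(n * 16 / 103)))] <- NA

  ## outcome classes in the ICI arm: 2 early-censored, then responders drawn
  ## with odds tilted toward high TN CD8 density
  outcome <- rep(NA_character_, n)
  nEC <- ct[["n_earlycensor"]]
  ecIdx <- .sampleFrom(iciIdx, nEC)
  outcome[ecIdx] <- "early-censored"
  classIdx <- setdiff(iciIdx, ecIdx)

  ## latent TME parameters (favorable flag needs responder status, responder
  ## status needs CD8 -> draw CD8 first, then responders, then the rest)
  cd8Spec <- config@cells$densities$cd8
  cd8TN <- cd8Spec[["tn"]] * exp(rnorm(n, 0, cd8Spec[["sdlog"]]))
  lowCd8 <- cd8TN < cd8Spec[["tn"]]
  gam <- sv[["responder_cd8_logodds"]]
  nDcb <- ct[["n_dcb"]]
  if (length(classIdx)) {
    w <- exp(gam * as.numeric(!lowCd8[classIdx]))
    dcbIdx <- classIdx[sample.int(length(classIdx), min(nDcb, length(classIdx)),
                                  prob = w)]
    outcome[dcbIdx] <- "DCB"
    outcome[setdiff(classIdx, dcbIdx)] <- "non-DCB"
  }

  favorable <- logical(n)
  nFav <- .cnt(ct, "n_favorable"); nFavDcb <- min(.cnt(ct, "n_favorable_dcb"), nFav)
  dcbAll <- which(outcome %in% "DCB"); nonDcbAll <- which(outcome %in% "non-DCB")
  favD <- .sampleFrom(dcbAll, nFavDcb)
  favN <- .sampleFrom(nonDcbAll, max(nFav - length(favD), 0L))
  favorable[c(favD, favN)] <- TRUE

  lat <- .drawLatents(n, favorable, driver, config)
  lat$cd8_tn <- cd8TN
  ## favorable TMEs carry high tumor-nest CD8 density (tight draw), the
  ## substrate of their high functional Trm-like compartment
  favSpec <- config@cells$densities$cd8_favorable
  if (any(favorable) && !is.null(favSpec)) {
    lat$cd8_tn[favorable] <- favSpec[["tn"]] *
      exp(rnorm(sum(favorable), 0, favSpec[["sdlog"]]))
    lat$cd8_isa[favorable] <- favSpec[["isa"]] *
      exp(rnorm(sum(favorable), 0, favSpec[["sdlog"]]))
    lowCd8 <- lat$cd8_tn < cd8Spec[["tn"]]
  }

  ## survival: exponential PH on the planted class + low-CD8, rank-preserving
  ## rescale pinning exactly n_dcb ICI patients past the 1-year boundary
  pfs <- numeric(n); pfsEv <- integer(n)
  os <- numeric(n); osEv <- integer(n)
  cens <- sv[["censor_days"]]; bnd <- sv[["dcb_boundary"]]
  R <- as.numeric(outcome %in% "DCB")
  if (length(classIdx)) {
    lam <- sv[["lambda_pfs"]] * sv[["hr_pfs_dcb"]]^R[classIdx] *
      sv[["hr_tncd8"]]^as.numeric(lowCd8[classIdx])
    u <- rexp(length(classIdx), lam)
    nNon <- sum(outcome[classIdx] == "non-DCB")
    s <- sort(u)
    scale <- if (nNon > 0 && nNon < length(u)) bnd / ((s[nNon] + s[nNon + 1]) / 2)
             else if (nNon == 0) bnd / (0.99 * min(u))
             else bnd / (1.01 * max(u))
    tt <- u * scale
    pfs[classIdx] <- pmin(tt, cens)
    pfsEv[classIdx] <- as.integer(tt <= cens)
  }
  if (length(ecIdx)) {
    pfs[ecIdx] <- runif(length(ecIdx), 60, bnd - 1)
    pfsEv[ecIdx] <- 0L
  }
  lamOs <- sv[["lambda_os"]] * sv[["hr_os_dcb"]]^R
  vOs <- rexp(n, lamOs)
  if (length(nonIdx)) {
    pfsN <- rexp(length(nonIdx), sv[["lambda_pfs_nonici"]])
    pfs[nonIdx] <- pmin(pfsN, cens); pfsEv[nonIdx] <- as.integer(pfsN <= cens)
    vOs[nonIdx] <- rexp(length(nonIdx), sv[["lambda_os_nonici"]])
  }
  os <- pmin(vOs, cens); osEv <- as.integer(vOs <= cens)

  clinical <- data.frame(patient_id = ids, ici_treated = as.integer(ici),
    pfs_days = pfs, pfs_event = pfsEv, os_days = os,
    os_event = osEv, treatment_line = line, regimen = regimen,
    histology = histology, driver_status = driver, ecog_ps = ecog,
    pdl1_tps = tps, stringsAsFactors = FALSE)

  truth <- cbind(data.frame(patient_id = ids, outcome_class = outcome,
                            favorable = favorable, low_cd8_latent = lowCd8,
                            stringsAsFactors = FALSE), lat)

  tissueList <- list(); geomList <- list()
  tissueIdx <- if (isTRUE(tissues) || identical(tissues, "all")) seq_len(n)
               else if (identical(tissues, "ici")) iciIdx
               else integer(0)
  if (length(tissueIdx)) {
    for (i in tissueIdx) {
      childSeed <- .childSeed(seed, i)
      set.seed(childSeed)
      geom <- tissueGeometry(config@geometry)
      prof <- c(as.list(lat[i, ]), list(patient_id = ids[i],
                                        pdl1_tps = tps[i]))
      tissueList[[ids[i]]] <- generatePatientTissue(prof, geom, panel, config)
      geomList[[ids[i]]] <- geom
    }
  }

  exprMat <- NULL; exprGroup <- factor()
  if (expression) {
    set.seed(.childSeed(seed, 0L))
    ex <- config@expression
    nEg <- min(ex$n_egfr, sum(driver == "EGFR"))
    nWt <- min(ex$n_wt, sum(driver == "wild-type"))
    if (nEg >= 2 && nWt >= 2) {
      sEg <- .sampleFrom(ids[driver == "EGFR"], nEg)
      sWt <- .sampleFrom(ids[driver == "wild-type"], nWt)
      exprGroup <- factor(rep(c("EGFR-mut", "EGFR-wt"), c(nEg, nWt)),
                          levels = c("EGFR-mut", "EGFR-wt"))
      exprMat <- generateExpression(exprGroup, config = config)
      rownames(exprMat) <- c(sEg, sWt)
    }
  }

  new("SyntheticCohort", clinical = clinical, truth = truth,
      tissues = tissueList, geometry = geomList, expression = exprMat,
      expressionGroup = exprGroup, panel = panel, config = config)
}

#' Generate a bulk log2 expression matrix with planted group effects
#'
#' Log-scale Gaussian expression: per-gene baselines are uniform on the
#' configured range, noise is Gaussian, and genes carrying a planted effect
#' are shifted by the stated log2 amount in the first group level (set-level
#' effects are expanded over the packaged gene sets).
#'
#' @param group factor of sample group labels; effects apply to
#'   \code{levels(group)[1]}.
#' @param genes gene symbols (default the packaged 726-gene panel).
#' @param effects named numeric of per-gene log2 shifts.
#' @param setEffects named numeric of per-gene-set log2 shifts.
#' @param noiseSd Gaussian noise SD (log2 units).
#' @param config optional \code{\link{CohortConfig}} supplying all of the
#'   above.
#' @return numeric samples x genes matrix (sample names are generic when not
#'   set by the caller).
#' @export
generateExpression <- function(group, genes = defaultGenePanel(),
                               effects = NULL, setEffects = NULL,
                               noiseSd = 1, config = NULL) {
  if (!is.null(config)) {
    ex <- config@expression
    genes <- defaultGenePanel(ex$n_genes)
    effects <- ex$effects
    setEffects <- ex$set_effects
    noiseSd <- ex$noise_sd
  }
  group <- factor(group)
  ns <- length(group); ng <- length(genes)
  if (ng < 1L) stop("at least one gene is required")
  shift <- setNames(rep(0, ng), genes)
  if (!is.null(setEffects) && length(setEffects)) {
    sets <- defaultGeneSets()
    for (nm in names(setEffects)) {
      mem <- intersect(sets[[nm]], genes)
      shift[mem] <- shift[mem] + setEffects[[nm]]
    }
  }
  if (!is.null(effects) && length(effects)) {
    mem <- intersect(names(effects), genes)
    shift[mem] <- shift[mem] + effects[mem]
  }
  mu <- runif(ng, 4, 12)
  m <- matrix(rnorm(ns * ng, sd = noiseSd), ns, ng,
              dimnames = list(sprintf("S%03d", seq_len(ns)), genes))
  m <- sweep(m, 2L, mu, "+")
  inA <- group == levels(group)[1]
  if (any(inA)) m[inA, ] <- sweep(m[inA, , drop = FALSE], 2L, shift, "+")
  m
}
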
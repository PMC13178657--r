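#' @importFrom survival Surv coxph survfit survdiff coxph.control
NULL

#' Classify durable clinical benefit (DCB) from a PFS record
#'
#' A patient shows durable clinical benefit when progression-free survival
#' reaches one year (365 days), whether the record then ends in an event or in
#' censoring; progression before one year is non-DCB; censoring before one
#' year leaves the benefit status undeterminable (early-censored).
#'
#' @param time PFS in days (vectorised).
#' @param event 0/1 progression flag.
#' @param boundary the DCB boundary in days (default 365).
#' @return factor with levels \code{DCB}, \code{non-DCB}, \code{early-censored}.
#' @export
classifyDCB <- function(time, event, boundary = 365) {
  if (any(time < 0)) stop("survival times must be non-negative")
  out <- ifelse(time >= boundary, "DCB",
                ifelse(event == 1, "non-DCB", "early-censored"))
  factor(out, levels = c("DCB", "non-DCB", "early-censored"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event survival times (days) and 0/1 event flags.
#' @return data.frame with one row per distinct observed time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv} (the
#'   product-limit estimate; \code{S(0) = 1} implicitly). Censoring times are
#'   retained so curves can carry censoring tick marks.
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one record is required")
  fit <- survfit(Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = as.integer(fit$n.risk),
             n_event = as.integer(fit$n.event),
             n_censor = as.integer(fit$n.censor), surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected chi-square statistic with hypergeometric
#' variance, two-sided p.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 groups).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("at least two groups are required")
  if (sum(event) < 1L) stop("log-rank is undefined without events")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Partial-likelihood maximisation with the Efron approximation for tied event
#' times; per-covariate hazard ratios with Wald 95% confidence intervals and
#' p-values. Constant covariates and fits showing signs of monotone-likelihood
#' separation (unbounded coefficients) raise diagnostic errors.
#'
#' @param time,event survival data.
#' @param covariates data.frame of covariates (numeric, logical or factor);
#'   rows with missing covariates are dropped (missing data are not imputed).
#' @param maxCoef absolute log-HR beyond which the fit is declared separated.
#' @return list with \code{table} (data.frame: term, hr, lo, hi, p),
#'   \code{loglik}, \code{n}, \code{nevent}.
#' @export
coxFit <- function(time, event, covariates, maxCoef = 15) {
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(covariates) & !is.na(time) & !is.na(event)
  covariates <- covariates[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop(sprintf("covariate %s is constant", nm))
  }
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  ## convergence chatter is superseded by the explicit separation check below
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converged|infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (anyNA(beta) || any(abs(beta) > maxCoef))
    stop("Cox fit did not identify all coefficients (possible separation)")
  se <- sqrt(diag(fit$var))
  tab <- data.frame(term = names(beta),
                    hr = exp(beta),
                    lo = exp(beta - 1.96 * se),
                    hi = exp(beta + 1.96 * se),
                    p = 2 * pnorm(-abs(beta / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, loglik = fit$loglik[2], n = fit$n, nevent = fit$nevent)
}

#' Two-group, categorical and rank-correlation association tests
#'
#' \code{mann_whitney}: two-sided Mann-Whitney U via the normal approximation
#' with tie correction (\code{x}, \code{y} are the two samples).
#' \code{fisher}: exact two-sided Fisher test on the 2x2 table of two binary
#' vectors (or \code{x} may be a 2x2 matrix).
#' \code{spearman}: Spearman rank correlation with the t-approximation p.
#'
#' @param x,y inputs as described per kind.
#' @param kind the test.
#' @return list with \code{statistic}, \code{p} and, for spearman, \code{rho}.
#' @export
associationTest <- function(x, y = NULL,
                            kind = c("mann_whitney", "fisher", "spearman")) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else if (kind == "fisher") {
    tab <- if (is.matrix(x)) x else {
      if (!all(c(x, y) %in% 0:1)) stop("fisher requires binary 0/1 vectors or a 2x2 matrix")
      table(factor(x, levels = 0:1), factor(y, levels = 0:1))
    }
    if (!all(dim(tab) == c(2L, 2L))) stop("fisher requires a 2x2 table")
    ht <- fisher.test(tab)
    list(statistic = unname(ht$estimate), p = ht$p.value)
  } else {
    if (length(x) != length(y) || length(x) < 3L)
      stop("spearman requires paired vectors of length >= 3")
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      stop("spearman is undefined for constant ranks")
    rho <- cor(rank(x), rank(y))
    n <- length(x)
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    list(statistic = tstat, rho = rho, p = 2 * pt(-abs(tstat), n - 2))
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement:
#' \code{q_(i) = min over j >= i of m * p_(j) / j}. \code{NA}s propagate.
#'
#' @param p p-values in [0, 1].
#' @return q-values aligned with \code{p}.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hazard-ratio / p-value profile sweep over all TME features
#'
#' For every feature: split the cohort at the median (ties low), fit a
#' univariable Cox model for the low group (HR > 1 means low is unfavorable)
#' and a log-rank test on PFS. The favorable-TME cluster flag, when supplied,
#' is appended as an additional profile (HR for fTME vs the rest). Features
#' whose fit is degenerate (all-missing, one-sided split, no events, or
#' separation) are skipped with a warning.
#'
#' @param features a \code{\link{TMEFeatures}} or numeric matrix (rows must
#'   align with \code{time}/\code{event}).
#' @param time,event PFS data aligned with the feature rows.
#' @param ftme optional logical favorable-TME flag per patient.
#' @return data.frame with columns \code{feature}, \code{n}, \code{hr},
#'   \code{lo}, \code{hi}, \code{p_logrank}.
#' @export
profileSweep <- function(features, time, event, ftme = NULL) {
  m <- if (is(features, "TMEFeatures")) featureValues(features) else features
  oneRow <- function(name, indicator) {
    ok <- !is.na(indicator)
    if (sum(ok) < 4L || length(unique(indicator[ok])) < 2L) {
      warning(sprintf("profile %s skipped: degenerate split", name))
      return(NULL)
    }
    res <- tryCatch({
      cx <- coxFit(time[ok], event[ok],
                   data.frame(profile = as.integer(indicator[ok])))
      lr <- logrankTest(time[ok], event[ok], indicator[ok])
      data.frame(feature = name, n = sum(ok), hr = cx$table$hr,
                 lo = cx$table$lo, hi = cx$table$hi, p_logrank = lr$p,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("profile %s skipped: %s", name, conditionMessage(e)))
      NULL
    })
    res
  }
  rows <- lapply(colnames(m), function(f) {
    v <- m[, f]
    if (all(is.na(v))) {
      warning(sprintf("profile %s skipped: all values missing", f))
      return(NULL)
    }
    oneRow(f, dichotomize(v, "median") == "low")
  })
  if (!is.null(ftme)) rows <- c(rows, list(oneRow("ftme_cluster", ftme)))
  do.call(rbind, rows)
}
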
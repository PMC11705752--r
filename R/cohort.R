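# Relative first-exon usage in a tumour cohort, clustering, and
# survival stratification (Kaplan-Meier, log-rank, Cox).

.exonCountCols <- function(cohort) {
  cols <- grep("^count_", colnames(cohort), value = TRUE)
  if (length(cols) == 0L) stop("cohort table has no count_<exon> columns")
  cols
}

#' Relative first-exon usage fractions
#'
#' Converts per-tumour first-exon read counts to fractions of the total
#' first-exon reads. Tumours with fewer than `min_reads` total reads are
#' excluded (the boundary is inclusive: exactly `min_reads` is kept) and
#' the exclusion count reported.
#'
#' @param cohort data.frame with one `count_<exon>` column per first
#'   exon and a `tumour_id` column.
#' @param min_reads minimum total first-exon reads (default 10).
#' @return list with `fractions` (tumour-by-exon matrix of row-sum-1
#'   fractions, rownames tumour ids), `n_excluded`, `retained_ids`.
#' @export
firstExonFractions <- function(cohort, min_reads = 10L) {
  cols <- .exonCountCols(cohort)
  counts <- as.matrix(cohort[, cols, drop = FALSE])
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- rowSums(counts)
  keep <- total >= min_reads
  fr <- counts[keep, , drop = FALSE] / total[keep]
  colnames(fr) <- sub("^count_", "", cols)
  rownames(fr) <- cohort$tumour_id[keep]
  list(fractions = fr, n_excluded = sum(!keep),
       retained_ids = cohort$tumour_id[keep])
}

#' Cluster tumours by first-exon usage
#'
#' Default is hierarchical clustering with Ward linkage on Euclidean
#' distances between fraction vectors, cut at `k` groups; k-means is
#' available as an alternative. Results are deterministic under a fixed
#' seed (hierarchical clustering needs none). Returns the tumour
#' ordering used for heatmap display and a silhouette cohesion
#' diagnostic.
#'
#' @param fractions tumour-by-exon fraction matrix (as from
#'   [firstExonFractions()]`$fractions`); no missing values.
#' @param k number of clusters (>= 2, <= number of tumours).
#' @param method `"ward"` (hierarchical, ward.D2) or `"kmeans"`.
#' @param seed integer seed (used by k-means).
#' @return list with `labels` (named integer vector 1..k), `order`
#'   (display order of tumours), `silhouette` (mean silhouette width),
#'   `method`.
#' @export
clusterTumours <- function(fractions, k = 5L, method = c("ward", "kmeans"),
                           seed = 1L) {
  method <- match.arg(method)
  if (anyNA(fractions)) stop("fractions must not contain missing values")
  if (k < 2L) stop("'k' must be >= 2")
  if (k > nrow(fractions)) stop("'k' exceeds the number of tumours")
  d <- stats::dist(fractions)
  if (method == "ward") {
    hc <- stats::hclust(d, method = "ward.D2")
    labels <- stats::cutree(hc, k = k)
    ord <- hc$order
  } else {
    km <- .withSeed(seed, stats::kmeans(fractions, centers = k,
                                        nstart = 25L))
    labels <- km$cluster
    ord <- order(labels)
  }
  sil <- cluster::silhouette(labels, d)
  list(labels = labels, order = ord,
       silhouette = mean(sil[, "sil_width"]), method = method)
}

#' Stratify tumours by one first-exon fraction
#'
#' Labels a tumour `"high"` iff its fraction for the chosen exon is
#' strictly greater than the cutoff, else `"low"`.
#'
#' @param fractions tumour-by-exon fraction matrix.
#' @param exon exon name (a column of `fractions`).
#' @param cutoff fraction cutoff in (0, 1). Published strata cutoffs are
#'   generally not recoverable from figures, so this is a required
#'   analysis input; see [quantileCutoff()] for a data-driven helper.
#' @return named factor with levels `low`, `high`.
#' @export
stratifyTumours <- function(fractions, exon, cutoff) {
  if (!exon %in% colnames(fractions)) {
    stop(sprintf("unknown exon '%s'", exon))
  }
  if (cutoff <= 0 || cutoff >= 1) stop("'cutoff' must lie in (0, 1)")
  f <- fractions[, exon]
  factor(ifelse(f > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Quantile-based cutoff helper
#'
#' Convenience for choosing a stratification cutoff from the data (e.g.
#' the upper tertile). This is a helper for exploratory stratification
#' only; it does not reproduce any published cutoff.
#'
#' @param fractions tumour-by-exon fraction matrix.
#' @param exon exon name.
#' @param q quantile in (0, 1) (default 2/3, the upper tertile).
#' @return numeric cutoff.
#' @export
quantileCutoff <- function(fractions, exon, q = 2 / 3) {
  unname(stats::quantile(fractions[, exon], q, type = 7))
}

.endpointColumns <- function(cohort, endpoint) {
  tc <- paste0(endpoint, "_time"); ec <- paste0(endpoint, "_event")
  if (!all(c(tc, ec) %in% colnames(cohort))) {
    stop(sprintf("cohort table lacks columns %s / %s", tc, ec))
  }
  if (any(cohort[[tc]] <= 0)) stop("event/censoring times must be > 0")
  if (!all(cohort[[ec]] %in% c(0L, 1L))) {
    stop("event flags must be 0/1")
  }
  list(time = cohort[[tc]], event = cohort[[ec]])
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimate per group plus the log-rank chi-square
#' statistic with the standard hypergeometric variance.
#'
#' @param cohort cohort data.frame with `<endpoint>_time` and
#'   `<endpoint>_event` columns.
#' @param groups factor/character vector of group labels aligned with
#'   `cohort` rows (e.g. from [stratifyTumours()], matched by tumour id).
#' @param endpoint `"os"`, `"rfi"` or `"drfi"` (or any prefix with
#'   matching columns).
#' @return list with `curves` (data.frame per group: `time`, `n_risk`,
#'   `n_event`, `survival`), `chisq`, `df`, `p_value`, `n`, `n_events`.
#' @export
kmLogrank <- function(cohort, groups, endpoint = "os") {
  ep <- .endpointColumns(cohort, endpoint)
  groups <- factor(groups)
  if (length(groups) != nrow(cohort)) {
    stop("'groups' must align with the cohort rows")
  }
  if (any(table(groups) == 0L) || nlevels(groups) < 2L) {
    stop("need >= 2 non-empty groups")
  }
  if (sum(ep$event) == 0L) {
    stop("no events observed: log-rank test undefined")
  }
  d <- data.frame(time = ep$time, event = ep$event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit)
  strat <- if (is.null(sm$strata)) {
    rep(levels(groups)[1L], length(sm$time))
  } else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = strat, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1L
  list(curves = curves, chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = nrow(d), n_events = sum(d$event))
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times. Tumour size is dichotomized at 20 mm (`> 20` vs `<= 20`) when
#' the `tumour_size_mm` covariate is requested. Univariable mode fits
#' one model per covariate; multivariable mode fits them jointly.
#'
#' @param cohort cohort data.frame.
#' @param covariates character vector of covariate column names (factors
#'   and numerics are used as-is; `tumour_size_mm` becomes the binary
#'   `size_gt20`).
#' @param endpoint endpoint prefix (see [kmLogrank()]).
#' @param mode `"univariable"` or `"multivariable"`.
#' @return data.frame with one row per coefficient: `model`, `term`,
#'   `coef`, `hr`, `hr_lower`, `hr_upper`, `p_value`, `n`, `n_events`.
#' @export
coxFit <- function(cohort, covariates, endpoint = "os",
                   mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  ep <- .endpointColumns(cohort, endpoint)
  missingCov <- setdiff(covariates, colnames(cohort))
  if (length(missingCov) > 0L) {
    stop(sprintf("unknown covariate(s): %s",
                 paste(missingCov, collapse = ", ")))
  }
  d <- cohort[, covariates, drop = FALSE]
  if ("tumour_size_mm" %in% covariates) {
    d$size_gt20 <- factor(ifelse(d$tumour_size_mm > 20, ">20mm", "<=20mm"),
                          levels = c("<=20mm", ">20mm"))
    d$tumour_size_mm <- NULL
  }
  d$.time <- ep$time; d$.event <- ep$event
  terms <- setdiff(colnames(d), c(".time", ".event"))
  fitOne <- function(vars, label) {
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~", paste(vars, collapse = " + ")
    ))
    fit <- tryCatch(
      survival::coxph(fml, data = d, ties = "efron"),
      error = function(e) stop(sprintf("Cox fit failed (%s): %s", label,
                                       conditionMessage(e)))
    )
    if (any(!is.finite(fit$coefficients)) ||
        any(abs(fit$coefficients) > 15)) {
      stop(sprintf(
        "Cox fit did not converge or separated (%s): |coef| too large",
        label
      ))
    }
    sf <- summary(fit)
    data.frame(
      model = label, term = rownames(sf$coefficients),
      coef = sf$coefficients[, "coef"],
      hr = sf$conf.int[, "exp(coef)"],
      hr_lower = sf$conf.int[, "lower .95"],
      hr_upper = sf$conf.int[, "upper .95"],
      p_value = sf$coefficients[, "Pr(>|z|)"],
      n = sf$n, n_events = sf$nevent, row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  nEvents <- sum(ep$event)
  if (mode == "multivariable") {
    if (nEvents < length(terms)) {
      stop("fewer events than parameters: multivariable fit ill-posed")
    }
    fitOne(terms, "multivariable")
  } else {
    do.call(rbind, lapply(terms, function(v) {
      fitOne(v, paste0("univariable:", v))
    }))
  }
}
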
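# Differential methylation between sublines, site-by-site correlation
# structure, expression normalization, and methylation-expression
# correlation with BH correction.

# All permutations of 1..n as an (n!) x n index matrix.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation test
#'
#' Computes Spearman's rho with mid-ranks for ties. The two-sided p-value
#' is an exact permutation p (full enumeration of all `n!` orderings of
#' one variable) for `n <= exact_n`, and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @param exact_n largest n for which the exact permutation p is used
#'   (default 9).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearmanTest(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanTest <- function(x, y, exact_n = 9L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    Pm <- .permutations(n)
    stat <- matrix(ryc[Pm], nrow(Pm)) %*% rxc
    rho_perm <- as.vector(stat) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1. Inputs
#' outside (0, 1] are an error.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values (same length and order).
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Methylation differences between sublines and their parental line
#'
#' Subtracts the parental methylated fraction from the subline's at every
#' CpG site, so positive deltas mean methylation gained in the derived
#' subline. A delta is missing when either fraction is missing.
#'
#' @param matrix a [MethylationExperiment-class].
#' @param pairs data.frame with columns `subline` and `parental` naming
#'   sample columns.
#' @return Long data.frame: `chrom`, `pos`, `region_id`, `site_index`,
#'   `subline`, `parental`, `delta` (in `[-1, 1]`).
#' @export
deltaMethylation <- function(matrix, pairs) {
  stopifnot(is(matrix, "MethylationExperiment"),
            all(c("subline", "parental") %in% colnames(pairs)))
  f <- methFraction(matrix)
  unknown <- setdiff(unique(c(pairs$subline, pairs$parental)), colnames(f))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  }
  sites <- SummarizedExperiment::rowRanges(matrix)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(
      chrom = as.character(seqnames(sites)), pos = start(sites),
      region_id = mcols(sites)$region_id,
      site_index = mcols(sites)$site_index,
      subline = pairs$subline[i], parental = pairs$parental[i],
      delta = f[, pairs$subline[i]] - f[, pairs$parental[i]],
      row.names = NULL
    )
  }))
}

#' Site-by-site Spearman correlation of methylated fractions
#'
#' Spearman rho between every pair of CpG sites across samples, with
#' pairwise-complete handling. Pairs with fewer than `min_pairs` shared
#' samples or a zero-variance site are reported missing (`NA`), not 0.
#'
#' @param matrix a [MethylationExperiment-class].
#' @param min_pairs minimum shared samples per site pair (default 3).
#' @return symmetric site-by-site matrix of rho values with unit
#'   diagonal (where defined).
#' @export
siteCorrelationMatrix <- function(matrix, min_pairs = 3L) {
  f <- methFraction(matrix)
  rho <- suppressWarnings(
    stats::cor(t(f), method = "spearman", use = "pairwise.complete.obs")
  )
  npair <- crossprod(!is.na(t(f)))
  rho[npair < min_pairs] <- NA
  rho
}

#' Normalize target expression to ACTB
#'
#' Each target quantity is divided by the sample's (replicate-matched)
#' ACTB quantity and multiplied by a class-specific scale: 10000 for
#' first-exon targets, 100 for the 3' UTR. The scaling is presentational
#' (rank statistics downstream are unaffected). Replicate-level values
#' are retained alongside per-sample mean and SD.
#'
#' @param raw data.frame with columns `sample_id`, `target`, `quantity`
#'   and optionally `replicate`; ACTB rows have `target == "ACTB"`.
#' @param target_class named character vector mapping each non-ACTB
#'   target to `"first_exon"` or `"utr3"`.
#' @return list with `replicates` (normalized replicate-level values) and
#'   `summary` (per sample and target: mean, sd, n).
#' @export
normalizeExpression <- function(raw, target_class) {
  need <- c("sample_id", "target", "quantity")
  stopifnot(all(need %in% colnames(raw)))
  if (!"replicate" %in% colnames(raw)) raw$replicate <- 1L
  targets <- setdiff(unique(raw$target), "ACTB")
  if (!all(targets %in% names(target_class))) {
    stop(sprintf("no class given for target(s): %s",
                 paste(setdiff(targets, names(target_class)),
                       collapse = ", ")))
  }
  if (!all(target_class %in% c("first_exon", "utr3"))) {
    stop("target classes must be 'first_exon' or 'utr3'")
  }
  actb <- raw[raw$target == "ACTB", , drop = FALSE]
  tgt <- raw[raw$target != "ACTB", , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$replicate, sep = "\r")
  ref <- actb$quantity[match(key(tgt), key(actb))]
  if (anyNA(ref)) {
    miss <- unique(tgt$sample_id[is.na(ref)])
    stop(sprintf("no ACTB quantity for sample/replicate of: %s",
                 paste(miss, collapse = ", ")))
  }
  if (any(ref <= 0)) {
    stop(sprintf("ACTB quantity must be > 0 (sample %s)",
                 tgt$sample_id[which(ref <= 0)[1L]]))
  }
  scale <- ifelse(target_class[tgt$target] == "utr3", 100, 10000)
  tgt$expression <- tgt$quantity / ref * scale
  summ <- do.call(rbind, lapply(
    split(tgt, paste(tgt$sample_id, tgt$target, sep = "\r")),
    function(d) data.frame(sample_id = d$sample_id[1L],
                           target = d$target[1L],
                           mean = mean(d$expression),
                           sd = stats::sd(d$expression), n = nrow(d))
  ))
  rownames(summ) <- NULL
  list(replicates = tgt[, c("sample_id", "target", "replicate",
                            "expression")],
       summary = summ)
}

#' Correlate CpG methylation with target expression
#'
#' Spearman rho and two-sided p-value for every (CpG site, target) pair
#' over their shared samples (pairwise-complete, at least `min_shared`),
#' followed by Benjamini-Hochberg adjustment over the full site-by-target
#' family. Pairs with a constant vector are skipped and counted. The
#' summary reports the number of sites nominally significant
#' (`p < alpha`) for at least one target and the number still significant
#' after FDR correction.
#'
#' @param matrix a [MethylationExperiment-class].
#' @param expr long data.frame with columns `target`, `sample_id`,
#'   `expression` (replicate-level rows are averaged per sample).
#' @param alpha significance threshold (default 0.05).
#' @param min_shared minimum shared samples per pair (default 4).
#' @return list with `table` (site, target, rho, n, p_value, fdr),
#'   `n_sites_nominal`, `n_sites_fdr`, `n_pairs_skipped`.
#' @export
methylationExpressionCorrelation <- function(matrix, expr, alpha = 0.05,
                                             min_shared = 4L) {
  stopifnot(is(matrix, "MethylationExperiment"),
            all(c("target", "sample_id", "expression") %in% colnames(expr)))
  f <- methFraction(matrix)
  ag <- stats::aggregate(expression ~ target + sample_id, data = expr,
                         FUN = mean)
  targets <- sort(unique(ag$target))
  ew <- matrix(NA_real_, nrow = length(targets), ncol = ncol(f),
               dimnames = list(targets, colnames(f)))
  shared <- intersect(unique(ag$sample_id), colnames(f))
  for (tg in targets) {
    d <- ag[ag$target == tg & ag$sample_id %in% shared, , drop = FALSE]
    ew[tg, d$sample_id] <- d$expression
  }
  rows <- list(); skipped <- 0L
  for (site in rownames(f)) {
    for (tg in targets) {
      xs <- f[site, ]; ys <- ew[tg, ]
      ok <- stats::complete.cases(xs, ys)
      if (sum(ok) < min_shared) { skipped <- skipped + 1L; next }
      if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) {
        skipped <- skipped + 1L
        next
      }
      st <- spearmanTest(xs[ok], ys[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, target = tg, rho = st$rho, n = st$n,
        p_value = st$p_value, stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0L) {
    message(sprintf("%d (site, target) pairs skipped (too few samples or constant vector)",
                    skipped))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(list(table = NULL, n_sites_nominal = 0L, n_sites_fdr = 0L,
                n_pairs_skipped = skipped))
  }
  tab$fdr <- bhFDR(tab$p_value)
  nominal <- unique(tab$site[tab$p_value < alpha])
  byfdr <- unique(tab$site[tab$fdr < alpha])
  list(table = tab, n_sites_nominal = length(nominal),
       n_sites_fdr = length(byfdr), n_pairs_skipped = skipped)
}
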
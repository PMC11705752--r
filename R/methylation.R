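# Per-site methylated fractions, conversion QC, and read-level
# epiallele pattern analysis.

.siteIds <- function(sites) {
  paste0(as.character(seqnames(sites)), ":", start(sites))
}

#' Per-site methylated-read fractions
#'
#' For every CpG site and sample, the methylated fraction is
#' `#M / (#M + #U)` over all reads covering the site; `N` calls are
#' excluded from both numerator and denominator. Sites with coverage
#' below `min_coverage` in a sample are reported as missing (`NA`
#' fraction), never as zero.
#'
#' @param reads a [ReadCallSet-class].
#' @param min_coverage minimum number of informative (`M`+`U`) calls for
#'   a fraction to be reported (default 1).
#' @return A [MethylationExperiment-class]: assays `fraction` and
#'   `coverage`, rows the CpG sites (rownames `"chrom:pos"`), columns the
#'   samples.
#' @examples
#' spec <- epialleleMixtureSpec("r1", c(MU = 1), seed = 1)
#' me <- methylatedFraction(simulateReadCalls(spec, 50))
#' methFraction(me)
#' @export
methylatedFraction <- function(reads, min_coverage = 1L) {
  stopifnot(is(reads, "ReadCallSet"), min_coverage >= 1L)
  sites <- siteTable(reads)
  calls <- as.data.frame(readCalls(reads))
  samples <- sort(unique(calls$sample_id))
  nM <- matrix(0L, nrow = length(sites), ncol = length(samples),
               dimnames = list(.siteIds(sites), samples))
  nU <- nM
  siteRow <- split(seq_along(sites), mcols(sites)$region_id)
  for (rid in unique(calls$region_id)) {
    rows <- siteRow[[rid]]
    sub <- calls[calls$region_id == rid, , drop = FALSE]
    cm <- do.call(rbind, strsplit(sub$calls, "", fixed = TRUE))
    for (s in unique(sub$sample_id)) {
      m <- cm[sub$sample_id == s, , drop = FALSE]
      nM[rows, s] <- colSums(m == "M")
      nU[rows, s] <- colSums(m == "U")
    }
  }
  coverage <- nM + nU
  fraction <- ifelse(coverage >= min_coverage, nM / pmax(coverage, 1L), NA)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fraction = fraction, coverage = coverage),
    rowRanges = sites
  )
  methods::new("MethylationExperiment", se)
}

#' Bisulfite conversion QC from non-CpG context
#'
#' Cytosines outside CpG context are expected to be unmethylated, so any
#' unconverted (methylated-looking) call there estimates the conversion
#' failure rate. Returns `100 * unconverted / (converted + unconverted)`
#' per sample. Samples without tallies get an explicit unavailable
#' status (`NA` percentage), never zero.
#'
#' @param reads a [ReadCallSet-class].
#' @return data.frame with `sample_id`, `unconverted_percent`,
#'   `available`.
#' @export
conversionQC <- function(reads) {
  stopifnot(is(reads, "ReadCallSet"))
  samples <- sort(unique(as.character(readCalls(reads)$sample_id)))
  tal <- as.data.frame(conversionTallies(reads))
  out <- data.frame(sample_id = samples, unconverted_percent = NA_real_,
                    available = FALSE, stringsAsFactors = FALSE)
  if (nrow(tal) > 0L) {
    i <- match(out$sample_id, tal$sample_id)
    has <- !is.na(i)
    tot <- tal$converted[i[has]] + tal$unconverted[i[has]]
    out$unconverted_percent[has] <- 100 * tal$unconverted[i[has]] / tot
    out$available[has] <- tot > 0L
    out$unconverted_percent[has][tot == 0L] <- NA_real_
  }
  if (!all(out$available)) {
    message(sprintf("conversion QC unavailable for %d sample(s)",
                    sum(!out$available)))
  }
  out
}

#' Epiallele (read-level methylation pattern) frequencies
#'
#' Tabulates the joint methylation pattern across all CpG sites of a
#' region, per sample. Reads containing any `N` call are excluded from
#' pattern analysis (and counted in `n_reads_excluded`); frequencies are
#' computed over the remaining reads. The reported selection keeps the
#' union of the `top_k` patterns by count and all patterns with
#' frequency `>= min_frequency`; count ties are broken lexicographically
#' by pattern string. Truncation is presentational: the returned object
#' stores the full counts and all computations downstream (e.g.
#' [patternSharing()]) use them.
#'
#' @param reads a [ReadCallSet-class].
#' @param region region id.
#' @param top_k number of top patterns to mark as selected (default 10).
#' @param min_frequency frequency threshold for selection (default 0.01).
#' @return A [PatternFrequencyTable-class].
#' @export
epiallelePatterns <- function(reads, region, top_k = 10L,
                              min_frequency = 0.01) {
  stopifnot(is(reads, "ReadCallSet"))
  if (!region %in% mcols(siteTable(reads))$region_id) {
    stop(sprintf("unknown region '%s'", region))
  }
  calls <- as.data.frame(readCalls(reads))
  calls <- calls[calls$region_id == region, , drop = FALSE]
  samples <- sort(unique(calls$sample_id))
  tabs <- list(); reads_df <- list()
  for (s in samples) {
    cs <- calls$calls[calls$sample_id == s]
    hasN <- grepl("N", cs, fixed = TRUE)
    used <- cs[!hasN]
    reads_df[[s]] <- data.frame(sample_id = s,
                                n_reads_used = length(used),
                                n_reads_excluded = sum(hasN))
    if (length(used) == 0L) next
    tb <- table(used)
    cnt <- as.integer(tb)
    pat <- names(tb)
    ord <- order(-cnt, pat)  # by count desc, lexicographic tie-break
    sel <- rep(FALSE, length(cnt))
    sel[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
    freq <- cnt / length(used)
    sel <- sel | freq >= min_frequency
    tabs[[s]] <- data.frame(sample_id = s, pattern = pat, count = cnt,
                            frequency = freq, selected = sel,
                            stringsAsFactors = FALSE)[ord, , drop = FALSE]
  }
  tab <- if (length(tabs)) {
    do.call(rbind, c(tabs, make.row.names = FALSE))
  } else {
    data.frame(sample_id = character(), pattern = character(),
               count = integer(), frequency = numeric(),
               selected = logical())
  }
  methods::new("PatternFrequencyTable", region_id = as.character(region),
               table = DataFrame(tab),
               reads = DataFrame(do.call(rbind,
                                         c(reads_df,
                                           make.row.names = FALSE))))
}

#' Classify derived-sample epialleles as pre-existing or novel
#'
#' A pattern observed in a derived sample (e.g. a resistant subline) is
#' classified as pre-existing if its frequency in the parental sample is
#' at least `presence_threshold`, else novel. Also reports the fraction
#' of derived reads carried by pre-existing patterns — near 1 when
#' subpopulations merely expand or contract under selection, low when
#' patterns arise de novo (active methylation/demethylation).
#'
#' @param parental,derived [PatternFrequencyTable-class] objects for the
#'   same region (full counts are used, not the reporting selection).
#' @param presence_threshold minimum parental frequency counting as
#'   present (default 0.01).
#' @param derived_sample,parental_sample optional sample ids when the
#'   tables hold several samples (defaults to the only sample present).
#' @return list with `classification` (data.frame `pattern`, `frequency`,
#'   `parental_frequency`, `status`) and `carried_fraction`.
#' @export
patternSharing <- function(parental, derived, presence_threshold = 0.01,
                           parental_sample = NULL, derived_sample = NULL) {
  stopifnot(is(parental, "PatternFrequencyTable"),
            is(derived, "PatternFrequencyTable"))
  if (parental@region_id != derived@region_id) {
    stop(sprintf("region mismatch: '%s' vs '%s'",
                 parental@region_id, derived@region_id))
  }
  pickSample <- function(pft, s, what) {
    tb <- as.data.frame(patternFrequencies(pft))
    if (is.null(s)) {
      s <- unique(tb$sample_id)
      if (length(s) > 1L) {
        stop(sprintf("several %s samples present; specify one", what))
      }
    }
    tb[tb$sample_id == s, , drop = FALSE]
  }
  ptab <- pickSample(parental, parental_sample, "parental")
  dtab <- pickSample(derived, derived_sample, "derived")
  pf <- ptab$frequency[match(dtab$pattern, ptab$pattern)]
  pf[is.na(pf)] <- 0
  status <- ifelse(pf >= presence_threshold, "pre-existing", "novel")
  list(
    classification = data.frame(
      pattern = dtab$pattern, frequency = dtab$frequency,
      parental_frequency = pf, status = status, stringsAsFactors = FALSE
    ),
    carried_fraction = if (nrow(dtab)) {
      sum(dtab$frequency[status == "pre-existing"])
    } else NA_real_
  )
}

#' Write a MethylationExperiment as long and wide TSV
#'
#' @param x a [MethylationExperiment-class].
#' @param long_path,wide_path output paths (either may be `NULL`).
#' @return invisibly, the long-format data.frame.
#' @export
writeMethylationTSV <- function(x, long_path = NULL, wide_path = NULL) {
  sites <- SummarizedExperiment::rowRanges(x)
  f <- methFraction(x); cv <- methCoverage(x)
  long <- do.call(rbind, lapply(colnames(f), function(s) {
    data.frame(chrom = as.character(seqnames(sites)), pos = start(sites),
               region_id = mcols(sites)$region_id, sample_id = s,
               fraction = f[, s], coverage = cv[, s], row.names = NULL)
  }))
  if (!is.null(long_path)) {
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(wide_path)) {
    utils::write.table(
      data.frame(site = rownames(f), region_id = mcols(sites)$region_id, f,
                 check.names = FALSE),
      wide_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(long)
}
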
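#' Accessors for promoMethyl classes
#'
#' `readCalls()` returns the read-level call records of a
#' [ReadCallSet-class]; `siteTable()` its CpG site `GRanges`;
#' `conversionTallies()` its per-sample non-CpG context counts.
#' `patternFrequencies()` returns the (optionally truncated) pattern table
#' of a [PatternFrequencyTable-class] and `patternReadCounts()` its
#' per-sample used/excluded read counts. `regionRanges()` and `cpgSites()`
#' return the interval and CpG components of a [RegionSet-class].
#'
#' @param x the object.
#' @param ... further arguments passed to methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("readCalls", function(x, ...) standardGeneric("readCalls"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x, ...) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("conversionTallies",
  function(x, ...) standardGeneric("conversionTallies"))

#' @rdname accessors
#' @export
setGeneric("patternFrequencies",
  function(x, ...) standardGeneric("patternFrequencies"))

#' @rdname accessors
#' @export
setGeneric("patternReadCounts",
  function(x, ...) standardGeneric("patternReadCounts"))

#' @rdname accessors
#' @export
setGeneric("regionRanges", function(x, ...) standardGeneric("regionRanges"))

#' @rdname accessors
#' @export
setGeneric("cpgSites", function(x, ...) standardGeneric("cpgSites"))

#' @rdname accessors
#' @export
setMethod("readCalls", "ReadCallSet", function(x, ...) x@calls)

#' @rdname accessors
#' @export
setMethod("siteTable", "ReadCallSet", function(x, ...) x@sites)

#' @rdname accessors
#' @export
setMethod("conversionTallies", "ReadCallSet",
  function(x, ...) x@conversionTallies)

#' @param selectedOnly logical; if `TRUE` return only patterns retained
#'   for reporting (top-k / minimum-frequency rule), otherwise the full
#'   table used in all computations.
#' @rdname accessors
#' @export
setMethod("patternFrequencies", "PatternFrequencyTable",
  function(x, selectedOnly = FALSE, ...) {
    if (selectedOnly) x@table[x@table$selected, , drop = FALSE] else x@table
  })

#' @rdname accessors
#' @export
setMethod("patternReadCounts", "PatternFrequencyTable",
  function(x, ...) x@reads)

#' @rdname accessors
#' @export
setMethod("regionRanges", "RegionSet", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("cpgSites", "RegionSet", function(x, ...) x@cpg)

#' Methylated-fraction and coverage assay accessors
#'
#' Convenience wrappers around [SummarizedExperiment::assay()] for
#' [MethylationExperiment-class] objects.
#'
#' @param x a `MethylationExperiment`.
#' @return A numeric (fraction) or integer (coverage) site-by-sample
#'   matrix.
#' @export
methFraction <- function(x) SummarizedExperiment::assay(x, "fraction")

#' @rdname methFraction
#' @export
methCoverage <- function(x) SummarizedExperiment::assay(x, "coverage")

setMethod("show", "ReadCallSet", function(object) {
  cat(sprintf(
    "ReadCallSet: %d reads | %d CpG sites in %d regions | %d samples\n",
    nrow(object@calls), length(object@sites),
    length(unique(mcols(object@sites)$region_id)),
    length(unique(object@calls$sample_id))
  ))
  if (nrow(object@conversionTallies) > 0L) {
    cat(sprintf("  non-CpG conversion tallies for %d samples\n",
                nrow(object@conversionTallies)))
  }
  invisible(NULL)
})

setMethod("show", "PatternFrequencyTable", function(object) {
  cat(sprintf(
    "PatternFrequencyTable: region '%s' | %d patterns | %d samples | %d reads used (%d excluded)\n",
    object@region_id, length(unique(object@table$pattern)),
    nrow(object@reads), sum(object@reads$n_reads_used),
    sum(object@reads$n_reads_excluded)
  ))
  invisible(NULL)
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d regions | %d CpG positions\n",
              length(object@regions), length(object@cpg)))
  invisible(NULL)
})
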
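#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce resize start<- GRangesList
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
NULL

.CALL_ALPHABET <- c("M", "U", "N")

#' ReadCallSet: per-read CpG methylation calls for amplicon regions
#'
#' Container for read-level methylation calls from targeted bisulfite
#' sequencing. Each record is one sequencing read (one original DNA strand)
#' carrying one call per CpG site of its amplicon region, in site order:
#' `M` (methylated, bisulfite-protected C), `U` (unmethylated, converted C)
#' or `N` (no call at that site). Optional per-sample non-CpG context
#' tallies support bisulfite conversion QC.
#'
#' @slot calls `DataFrame` with columns `sample_id`, `region_id`,
#'   `read_id`, `calls` (string over `M`/`U`/`N`, one character per region
#'   CpG in `site_index` order).
#' @slot sites `GRanges` of width-1 CpG positions (the C of each CpG,
#'   1-based) with metadata columns `region_id` and `site_index` (0-based,
#'   contiguous within region in coordinate order).
#' @slot conversionTallies `DataFrame` with columns `sample_id`,
#'   `converted`, `unconverted` counting non-CpG context cytosines; may
#'   have zero rows when tallies are unavailable.
#'
#' @seealso [parseReadCalls()], [simulateReadCalls()],
#'   [methylatedFraction()], [epiallelePatterns()]
#' @export
setClass("ReadCallSet",
  slots = c(
    calls = "DataFrame",
    sites = "GRanges",
    conversionTallies = "DataFrame"
  )
)

.validReadCallSet <- function(object) {
  msg <- character()
  need <- c("sample_id", "region_id", "read_id", "calls")
  if (!all(need %in% colnames(object@calls))) {
    return(sprintf(
      "calls must have columns %s", paste(need, collapse = ", ")
    ))
  }
  sm <- mcols(object@sites)
  if (!all(c("region_id", "site_index") %in% colnames(sm))) {
    return("sites must carry metadata columns region_id and site_index")
  }
  if (any(width(object@sites) != 1L)) {
    msg <- c(msg, "all CpG sites must have width 1")
  }
  key <- paste(as.character(seqnames(object@sites)), start(object@sites))
  if (anyDuplicated(key)) {
    msg <- c(msg, "CpG site (chrom, pos) pairs must be unique")
  }
  ord <- order(factor(sm$region_id), start(object@sites))
  for (rid in unique(sm$region_id)) {
    idx <- which(sm$region_id[ord] == rid)
    si <- sm$site_index[ord][idx]
    if (!identical(as.integer(si), seq_along(si) - 1L)) {
      msg <- c(msg, sprintf(
        "site_index not contiguous in coordinate order for region '%s'", rid
      ))
    }
  }
  nsite <- table(sm$region_id)
  if (nrow(object@calls) > 0L) {
    bad <- nchar(object@calls$calls) !=
      as.integer(nsite[object@calls$region_id])
    if (any(bad, na.rm = TRUE)) {
      msg <- c(msg, sprintf(
        "%d call strings do not match their region's CpG count",
        sum(bad, na.rm = TRUE)
      ))
    }
    if (any(grepl("[^MUN]", object@calls$calls))) {
      msg <- c(msg, "call strings may only contain M, U, N")
    }
    dup <- anyDuplicated(paste(
      object@calls$sample_id, object@calls$region_id, object@calls$read_id
    ))
    if (dup) msg <- c(msg, "read_id must be unique within (sample, region)")
  }
  if (nrow(object@conversionTallies) > 0L &&
      !all(c("sample_id", "converted", "unconverted") %in%
           colnames(object@conversionTallies))) {
    msg <- c(msg, "conversionTallies needs sample_id, converted, unconverted")
  }
  if (length(msg)) msg else TRUE
}

setValidity("ReadCallSet", .validReadCallSet)

#' Construct a ReadCallSet
#'
#' @param calls data.frame/DataFrame of read records (`sample_id`,
#'   `region_id`, `read_id`, `calls`).
#' @param sites `GRanges` of CpG sites (see [ReadCallSet-class]) or a
#'   data.frame accepted by [siteGRanges()].
#' @param conversionTallies optional data.frame of per-sample non-CpG
#'   context counts (`sample_id`, `converted`, `unconverted`).
#' @return A [ReadCallSet-class] object.
#' @export
ReadCallSet <- function(calls, sites,
                        conversionTallies = DataFrame(
                          sample_id = character(),
                          converted = integer(), unconverted = integer()
                        )) {
  if (is.data.frame(sites)) sites <- siteGRanges(sites)
  calls <- as(as.data.frame(calls, stringsAsFactors = FALSE), "DataFrame")
  if (nrow(calls) > 0L) {
    calls$sample_id <- as.character(calls$sample_id)
    calls$region_id <- as.character(calls$region_id)
    calls$read_id <- as.character(calls$read_id)
    calls$calls <- as.character(calls$calls)
  }
  new("ReadCallSet",
    calls = calls, sites = sites,
    conversionTallies = as(
      as.data.frame(conversionTallies, stringsAsFactors = FALSE), "DataFrame"
    )
  )
}

#' MethylationExperiment: CpG site by sample methylated fractions
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with assays
#' `fraction` (methylated-read fraction per site and sample, `NA` where
#' coverage is below the minimum) and `coverage` (number of informative
#' `M`+`U` calls). Rows are CpG sites (`GRanges` with `region_id` and
#' `site_index`), columns are samples.
#'
#' @seealso [methylatedFraction()], [deltaMethylation()],
#'   [siteCorrelationMatrix()]
#' @export
setClass("MethylationExperiment",
  contains = "RangedSummarizedExperiment"
)

.validMethylationExperiment <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("fraction", "coverage") %in% an)) {
    return("assays 'fraction' and 'coverage' are required")
  }
  f <- SummarizedExperiment::assay(object, "fraction")
  cv <- SummarizedExperiment::assay(object, "coverage")
  if (any(cv < 0, na.rm = TRUE)) msg <- c(msg, "coverage must be >= 0")
  ok <- !is.na(f)
  if (any(f[ok] < 0 | f[ok] > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  # m * c must be (close to) an integer count of methylated reads
  if (any(abs(f[ok] * cv[ok] - round(f[ok] * cv[ok])) > 0.5)) {
    msg <- c(msg, "fraction * coverage must be within 0.5 of an integer")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MethylationExperiment", .validMethylationExperiment)

#' PatternFrequencyTable: epiallele pattern frequencies per sample
#'
#' Frequencies of read-level methylation patterns (epialleles) for one
#' amplicon region. The full, untruncated counts are stored; the `selected`
#' column marks the patterns retained for reporting (top-k by count or
#' above a minimum frequency; truncation is presentational only).
#'
#' @slot region_id the amplicon region the patterns belong to.
#' @slot table `DataFrame` with columns `sample_id`, `pattern`, `count`,
#'   `frequency`, `selected`.
#' @slot reads `DataFrame` with per-sample `n_reads_used` and
#'   `n_reads_excluded` (reads containing any `N` are excluded).
#' @seealso [epiallelePatterns()], [patternSharing()]
#' @export
setClass("PatternFrequencyTable",
  slots = c(region_id = "character", table = "DataFrame", reads = "DataFrame")
)

.validPatternFrequencyTable <- function(object) {
  msg <- character()
  if (!all(c("sample_id", "pattern", "count", "frequency", "selected") %in%
           colnames(object@table))) {
    return("table needs sample_id, pattern, count, frequency, selected")
  }
  for (s in unique(object@table$sample_id)) {
    sub <- object@table[object@table$sample_id == s, , drop = FALSE]
    used <- object@reads$n_reads_used[object@reads$sample_id == s]
    if (length(used) == 1L && used > 0L) {
      if (abs(sum(sub$frequency) - 1) > 1e-9) {
        msg <- c(msg, sprintf("frequencies for '%s' do not sum to 1", s))
      }
      if (sum(sub$count) != used) {
        msg <- c(msg, sprintf("counts for '%s' do not sum to n_reads_used", s))
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("PatternFrequencyTable", .validPatternFrequencyTable)

#' RegionSet: genomic regions with their CpG positions
#'
#' A set of non-overlapping genomic regions (e.g. the amplicon regions
#' under study, or an expression-matched background set around first
#' exons) together with the C-of-CpG positions they contain. Used as the
#' foreground/background unit of conservation analysis.
#'
#' @slot regions `GRanges` with metadata column `region_id`.
#' @slot cpg width-1 `GRanges` of C-of-CpG positions with `region_id`.
#' @seealso [buildBackgroundRegions()], [conservationCompare()],
#'   [deltaPhyloP()]
#' @export
setClass("RegionSet", slots = c(regions = "GRanges", cpg = "GRanges"))

.validRegionSet <- function(object) {
  msg <- character()
  if (!"region_id" %in% colnames(mcols(object@regions))) {
    return("regions must carry a region_id metadata column")
  }
  if (length(object@regions) > 1L) {
    hits <- findOverlaps(object@regions, drop.self = TRUE,
                         drop.redundant = TRUE)
    if (length(hits) > 0L) msg <- c(msg, "regions must be non-overlapping")
  }
  if (length(object@cpg) > 0L) {
    if (!"region_id" %in% colnames(mcols(object@cpg))) {
      msg <- c(msg, "cpg must carry a region_id metadata column")
    } else {
      hit <- findOverlaps(object@cpg, object@regions, select = "first")
      inside <- !is.na(hit) &
        mcols(object@regions)$region_id[hit] == mcols(object@cpg)$region_id
      if (!all(inside)) {
        msg <- c(msg, "every CpG position must fall inside its region")
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("RegionSet", .validRegionSet)

#' @param regions `GRanges` with a `region_id` metadata column.
#' @param cpg width-1 `GRanges` of C-of-CpG positions; if its `region_id`
#'   column is missing it is assigned by overlap with `regions`.
#' @return A [RegionSet-class].
#' @rdname RegionSet-class
#' @export
RegionSet <- function(regions, cpg = GRanges()) {
  if (length(cpg) > 0L && !"region_id" %in% colnames(mcols(cpg))) {
    hit <- findOverlaps(cpg, regions, select = "first")
    if (anyNA(hit)) stop("some CpG positions fall outside every region")
    mcols(cpg)$region_id <- mcols(regions)$region_id[hit]
  }
  new("RegionSet", regions = regions, cpg = cpg)
}
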
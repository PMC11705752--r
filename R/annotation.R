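# TFBS overlap of CpG sites, expression-matched background-region
# construction, and conservation comparison with delta-phyloP.

#' Read TFBS intervals from BED
#'
#' BED6(+1) with the transcription factor name in the `name` field and an
#' optional extra column carrying the cell type. Import converts the
#' 0-based half-open BED coordinates to 1-based closed `GRanges`.
#'
#' @param path BED file.
#' @return `GRanges` with metadata columns `tf` and (if present)
#'   `cell_type`.
#' @export
readTFBS <- function(path) {
  extra <- tryCatch(
    rtracklayer::import(path, format = "BED",
                        extraCols = c(cell_type = "character")),
    error = function(e) rtracklayer::import(path, format = "BED")
  )
  mcols(extra)$tf <- mcols(extra)$name
  extra
}

#' Overlap CpG sites with transcription factor binding sites
#'
#' A site overlaps an interval iff the C base lies inside it: with
#' 0-based half-open intervals `[start, end)` and a 1-based position
#' `pos`, that is `start < pos <= end`; on the 1-based closed `GRanges`
#' used internally it is plain interval containment of the width-1 site.
#'
#' @param sites width-1 `GRanges` of CpG sites (1-based C positions).
#' @param tfbs `GRanges` of binding-site intervals (e.g. [readTFBS()]);
#'   a metadata column `tf` (or `name`) labels the factor.
#' @return list with `annotation` (per site: `site`, `n_tfbs`, `tfs`
#'   comma-separated) and `n_sites_with_tfbs`.
#' @export
overlapTFBS <- function(sites, tfbs) {
  if (any(width(tfbs) < 1L)) stop("TFBS intervals must satisfy start < end")
  if (any(width(sites) != 1L)) stop("CpG sites must have width 1")
  tf <- mcols(tfbs)$tf
  if (is.null(tf)) tf <- mcols(tfbs)$name
  if (is.null(tf)) tf <- rep(NA_character_, length(tfbs))
  hits <- findOverlaps(sites, tfbs)
  bySite <- split(tf[S4Vectors::subjectHits(hits)],
                  factor(S4Vectors::queryHits(hits),
                         levels = seq_along(sites)))
  ann <- data.frame(
    site = .siteIds(sites),
    region_id = if ("region_id" %in% colnames(mcols(sites))) {
      mcols(sites)$region_id
    } else NA_character_,
    n_tfbs = lengths(bySite),
    tfs = vapply(bySite, function(z) paste(z, collapse = ","),
                 character(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(annotation = ann, n_sites_with_tfbs = sum(ann$n_tfbs > 0L))
}

#' Build an expression-matched background region set
#'
#' Constructs control regions around the first exons of genes whose mean
#' expression falls within the interquartile range of the target gene's
#' per-sample expression: (1) compute `[Q1, Q3]` of the target gene's
#' per-sample expression (quartiles by linear interpolation) and select
#' other genes whose mean expression lies inside it; (2) pad each
#' selected gene's first exons by `pad_bp` on both sides, merging padded
#' exons of the same gene that overlap; (3) subtract all protein-coding
#' (CDS) intervals, possibly splitting regions; (4) keep fragments
#' strictly longer than `min_len` bp containing at least `min_cpg` CpG
#' sites.
#'
#' @param gene_expr data.frame with columns `gene_id`, `sample_id`,
#'   `expression` (per-sample expression, e.g. fpkm).
#' @param target_gene gene whose expression IQR defines the match window
#'   (excluded from the background itself).
#' @param first_exons `GRanges` of first exons with metadata column
#'   `gene_id`.
#' @param cds `GRanges` of protein-coding sequence intervals.
#' @param cpg_positions width-1 `GRanges` of C-of-CpG positions.
#' @param pad_bp padding around first exons (default 750).
#' @param min_len fragments must be strictly longer than this (default
#'   400).
#' @param min_cpg minimum CpG count per fragment, inclusive (default 4).
#' @return A [RegionSet-class]; empty (with a warning) when no gene
#'   matches.
#' @export
buildBackgroundRegions <- function(gene_expr, target_gene, first_exons,
                                   cds, cpg_positions, pad_bp = 750L,
                                   min_len = 400L, min_cpg = 4L) {
  stopifnot(all(c("gene_id", "sample_id", "expression") %in%
                colnames(gene_expr)))
  tgt <- gene_expr$expression[gene_expr$gene_id == target_gene]
  if (length(tgt) == 0L) {
    stop(sprintf("target gene '%s' absent from expression table",
                 target_gene))
  }
  q <- stats::quantile(tgt, c(0.25, 0.75), type = 7, names = FALSE)
  means <- tapply(gene_expr$expression, gene_expr$gene_id, mean)
  keep <- names(means)[means >= q[1L] & means <= q[2L]]
  keep <- setdiff(keep, target_gene)
  emptyRS <- RegionSet(GRanges(region_id = character(0)))
  if (length(keep) == 0L) {
    warning("no gene matches the target expression window")
    return(emptyRS)
  }
  fe <- first_exons[mcols(first_exons)$gene_id %in% keep]
  if (length(fe) == 0L) {
    warning("selected genes have no first exons")
    return(emptyRS)
  }
  padded <- suppressWarnings(
    resize(fe, width(fe) + 2L * pad_bp, fix = "center")
  )
  start(padded) <- pmax(start(padded), 1L)
  # merge overlapping padded exons of the same gene before CDS masking
  merged <- unlist(GenomicRanges::GRangesList(
    lapply(split(padded, mcols(padded)$gene_id), reduce)
  ), use.names = FALSE)
  frags <- GenomicRanges::setdiff(reduce(merged), reduce(cds))
  frags <- frags[width(frags) > min_len]
  ncpg <- countOverlaps(frags, cpg_positions)
  frags <- frags[ncpg >= min_cpg]
  if (length(frags) == 0L) {
    warning("no fragment survives the length/CpG filters")
    return(emptyRS)
  }
  mcols(frags)$region_id <- sprintf("bg_%04d", seq_along(frags))
  cpg <- cpg_positions[countOverlaps(cpg_positions, frags) > 0L]
  mcols(cpg) <- NULL
  RegionSet(frags, cpg)
}

# Wilcoxon rank-sum with mid-ranks: exact for combined n <= exact_total
# with no ties, normal approximation with tie and continuity correction
# otherwise.
.rankSumTest <- function(a, b, exact_total = 10L) {
  noTies <- !anyDuplicated(c(a, b))
  exact <- (length(a) + length(b)) <= exact_total && noTies
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(W = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

.trackScores <- function(track, positions) {
  hit <- findOverlaps(positions, track, select = "first")
  mcols(track)$score[hit]
}

#' Compare conservation of C-of-CpG positions with their surroundings
#'
#' Splits the per-base conservation scores of a region set into the C
#' positions of CpG sites versus all other region positions and applies a
#' two-sided Wilcoxon rank-sum test (mid-ranks; exact for small tie-free
#' samples, normal approximation with tie and continuity correction
#' otherwise). By default positions are pooled across regions; a
#' stratified mode reports one test per region. Region bases without a
#' score are dropped and counted.
#'
#' @param track width-1 `GRanges` with a `score` column (a per-base
#'   phyloP-like track, see [readConservationTrack()]).
#' @param regions a [RegionSet-class].
#' @param mode `"pooled"` (default) or `"stratified"`.
#' @return list with `W`, `p_value`, `exact`, `n_cpg`, `n_other`,
#'   `n_unscored`, `cpg_scores`, `other_scores` and a `per_region`
#'   summary data.frame (median/mean per group per region; in stratified
#'   mode also per-region W and p).
#' @export
conservationCompare <- function(track, regions,
                                mode = c("pooled", "stratified")) {
  mode <- match.arg(mode)
  stopifnot(is(regions, "RegionSet"))
  reg <- regionRanges(regions)
  allpos <- GRanges(
    rep(as.character(seqnames(reg)), width(reg)),
    IRanges(unlist(lapply(seq_along(reg), function(i) {
      start(reg)[i]:end(reg)[i]
    })), width = 1L)
  )
  mcols(allpos)$region_id <- rep(mcols(reg)$region_id, width(reg))
  isC <- countOverlaps(allpos, cpgSites(regions)) > 0L
  score <- .trackScores(track, allpos)
  unscored <- is.na(score)
  keep <- !unscored
  a <- score[keep & isC]; b <- score[keep & !isC]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both the CpG and the background position group must be non-empty")
  }
  rid <- mcols(allpos)$region_id[keep]
  grp <- isC[keep]; sc <- score[keep]
  per <- do.call(rbind, lapply(unique(rid), function(r) {
    i <- rid == r
    d <- data.frame(
      region_id = r, n_cpg = sum(i & grp), n_other = sum(i & !grp),
      median_cpg = stats::median(sc[i & grp]),
      median_other = stats::median(sc[i & !grp]),
      mean_cpg = mean(sc[i & grp]), mean_other = mean(sc[i & !grp])
    )
    if (mode == "stratified" && d$n_cpg > 0L && d$n_other > 0L) {
      rt <- .rankSumTest(sc[i & grp], sc[i & !grp])
      d$W <- rt$W; d$p_value <- rt$p_value
    }
    d
  }))
  rt <- .rankSumTest(a, b)
  list(W = rt$W, p_value = rt$p_value, exact = rt$exact,
       n_cpg = length(a), n_other = length(b),
       n_unscored = sum(unscored), cpg_scores = a, other_scores = b,
       per_region = per, mode = mode)
}

#' Conservation relative to the regional mean (delta-phyloP)
#'
#' For every scored position of every region, `delta = score -
#' mean(region scores)`; by construction the deltas of a region average
#' to zero. The C-of-CpG versus other-position comparison is then re-run
#' on the deltas with the same Wilcoxon procedure, removing
#' between-region differences in baseline conservation. Regions with no
#' scored position are excluded with a warning.
#'
#' @inheritParams conservationCompare
#' @return list with `positions` (data.frame `chrom`, `pos`,
#'   `region_id`, `score`, `delta`, `is_cpg`), `cpg_delta` (deltas at C
#'   positions) and `comparison` (as from [conservationCompare()], on the
#'   deltas).
#' @export
deltaPhyloP <- function(track, regions) {
  stopifnot(is(regions, "RegionSet"))
  reg <- regionRanges(regions)
  rows <- list()
  for (i in seq_along(reg)) {
    pos <- start(reg)[i]:end(reg)[i]
    gr <- GRanges(as.character(seqnames(reg)[i]), IRanges(pos, width = 1L))
    sc <- .trackScores(track, gr)
    if (all(is.na(sc))) {
      warning(sprintf("region '%s' has no scored positions; excluded",
                      mcols(reg)$region_id[i]))
      next
    }
    mu <- mean(sc, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(reg)[i]), pos = pos,
      region_id = mcols(reg)$region_id[i], score = sc, delta = sc - mu,
      is_cpg = countOverlaps(gr, cpgSites(regions)) > 0L
    )
  }
  if (length(rows) == 0L) stop("no region has scored positions")
  df <- do.call(rbind, rows)
  scored <- df[!is.na(df$score), , drop = FALSE]
  a <- scored$delta[scored$is_cpg]
  b <- scored$delta[!scored$is_cpg]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both the CpG and the background position group must be non-empty")
  }
  rt <- .rankSumTest(a, b)
  list(positions = df, cpg_delta = a,
       comparison = list(W = rt$W, p_value = rt$p_value, exact = rt$exact,
                         n_cpg = length(a), n_other = length(b)))
}

#' Read a per-base conservation track
#'
#' bedGraph input is 0-based half-open and wig 1-based; both are
#' converted to 1-based width-1 positions (multi-base intervals are
#' expanded, each base inheriting the interval score).
#'
#' @param path bedGraph or wig file.
#' @param format `"bedGraph"` or `"wig"` (guessed from extension by
#'   default).
#' @return width-1 `GRanges` with a `score` column.
#' @export
readConservationTrack <- function(path,
                                  format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE)) {
      "wig"
    } else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  if (all(width(gr) == 1L)) return(gr)
  # expand multi-base intervals to per-base scores
  out <- GRanges(
    rep(as.character(seqnames(gr)), width(gr)),
    IRanges(unlist(lapply(seq_along(gr), function(i) {
      start(gr)[i]:end(gr)[i]
    })), width = 1L),
    score = rep(mcols(gr)$score, width(gr))
  )
  out
}

#' Write a conservation track as bedGraph
#'
#' @param track width-1 `GRanges` with a `score` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConservationTrack <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}
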
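# Reading and writing per-read CpG call data and CpG site tables.

#' Build a CpG site GRanges from a site table
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based position
#'   of the C of the CpG on the forward strand) and `region_id`.
#'   `site_index` is always (re)derived as the 0-based ordinal of the site
#'   within its region in coordinate order.
#' @return `GRanges` of width-1 sites with `region_id` and `site_index`.
#' @export
siteGRanges <- function(sites) {
  need <- c("chrom", "pos", "region_id")
  if (!all(need %in% colnames(sites))) {
    stop(sprintf("site table needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(sites$pos < 1)) stop("site positions must be >= 1 (1-based)")
  sites <- sites[order(sites$region_id, sites$pos), , drop = FALSE]
  GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
          region_id = as.character(sites$region_id),
          site_index = as.integer(
            stats::ave(sites$pos, sites$region_id, FUN = seq_along) - 1
          ))
}

#' Read a CpG site table from TSV or BED
#'
#' TSV files carry 1-based C positions (`chrom`, `pos`, `region_id`
#' columns). BED files are interpreted as 0-based half-open intervals of
#' the C base (width 1) with the region id in the `name` field; import
#' converts them to 1-based positions.
#'
#' @param path file path.
#' @param format `"tsv"` or `"bed"` (guessed from the extension by
#'   default).
#' @return `GRanges` as from [siteGRanges()].
#' @export
readSiteTable <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    bed <- rtracklayer::import(path, format = "BED")
    if (any(width(bed) != 1L)) {
      stop("BED site records must have width 1 (the C of the CpG)")
    }
    df <- data.frame(chrom = as.character(seqnames(bed)), pos = start(bed),
                     region_id = mcols(bed)$name)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  siteGRanges(df)
}

.regionSpans <- function(sites) {
  sp <- split(sites, mcols(sites)$region_id)
  gr <- unlist(GenomicRanges::GRangesList(lapply(sp, range)),
               use.names = FALSE)
  mcols(gr)$region_id <- names(sp)
  gr
}

#' Parse per-read CpG methylation calls
#'
#' Two dialects are supported. The native TSV has a header line and
#' columns `sample_id`, `region_id`, `read_id`, `calls` where `calls` is
#' one character per region CpG (`M`/`U`/`N`) in site order. The
#' bismark-style CpG context format has one line per cytosine call:
#' `read_id  strand-call  chrom  pos  call-char`, with `Z` (methylated
#' CpG) mapped to `M`, `z` to `U`, and sites of the region absent from a
#' read set to `N`. Bismark context files are per sample, so `sample_id`
#' must be supplied for that dialect.
#'
#' Reads whose positions fall outside every configured region are dropped
#' with a message reporting the count; a call at a position inside a
#' region that is not a configured CpG site is an error naming the
#' position.
#'
#' @param path input file.
#' @param sites CpG site `GRanges` (see [readSiteTable()]).
#' @param format `"native_tsv"` or `"bismark_cpg_context"`.
#' @param sample_id sample identifier (bismark dialect only).
#' @return A [ReadCallSet-class].
#' @export
parseReadCalls <- function(path, sites,
                           format = c("native_tsv", "bismark_cpg_context"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.data.frame(sites)) sites <- siteGRanges(sites)
  if (format == "native_tsv") {
    .parseNativeTSV(path, sites)
  } else {
    if (is.null(sample_id)) {
      stop("'sample_id' is required for bismark_cpg_context input")
    }
    .parseBismarkContext(path, sites, sample_id)
  }
}

.parseNativeTSV <- function(path, sites) {
  lines <- readLines(path)
  empty <- ReadCallSet(
    calls = data.frame(sample_id = character(), region_id = character(),
                       read_id = character(), calls = character()),
    sites = sites
  )
  if (length(lines) == 0L) return(empty)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("sample_id", "region_id", "read_id", "calls")
  if (!all(need %in% header)) {
    stop(sprintf("native TSV must have header columns %s",
                 paste(need, collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(empty)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1L]
    stop(sprintf("malformed line %d: expected %d fields, found %d",
                 bad + 1L, length(header), nfield[bad]))
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  df <- data.frame(mat[, need, drop = FALSE], stringsAsFactors = FALSE)
  nsite <- table(mcols(sites)$region_id)
  unknown <- !df$region_id %in% names(nsite)
  if (any(unknown)) {
    message(sprintf("dropping %d reads mapping to no configured region",
                    sum(unknown)))
    df <- df[!unknown, , drop = FALSE]
  }
  badlen <- which(nchar(df$calls) != as.integer(nsite[df$region_id]))
  if (length(badlen) > 0L) {
    stop(sprintf(
      "malformed line %d: call string length does not match region '%s'",
      badlen[1L] + 1L, df$region_id[badlen[1L]]
    ))
  }
  ReadCallSet(calls = df, sites = sites)
}

.parseBismarkContext <- function(path, sites, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "Bismark")]
  empty <- ReadCallSet(
    calls = data.frame(sample_id = character(), region_id = character(),
                       read_id = character(), calls = character()),
    sites = sites
  )
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 5L)) {
    stop(sprintf("malformed line %d: expected 5 fields",
                 which(nfield < 5L)[1L]))
  }
  mat <- do.call(rbind, lapply(parts, `[`, 1:5))
  df <- data.frame(read_id = mat[, 1L], chrom = mat[, 3L],
                   pos = as.integer(mat[, 4L]), call = mat[, 5L],
                   stringsAsFactors = FALSE)
  if (anyNA(df$pos)) {
    stop(sprintf("malformed line %d: non-integer position",
                 which(is.na(df$pos))[1L]))
  }
  if (any(!df$call %in% c("Z", "z"))) {
    stop(sprintf("malformed line %d: CpG context call must be Z or z",
                 which(!df$call %in% c("Z", "z"))[1L]))
  }
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
  hit <- findOverlaps(gr, sites, select = "first")
  spans <- .regionSpans(sites)
  inspan <- !is.na(findOverlaps(gr, spans, select = "first"))
  orphan <- is.na(hit) & inspan
  if (any(orphan)) {
    i <- which(orphan)[1L]
    stop(sprintf(
      "call at %s:%d is not a configured CpG site", df$chrom[i], df$pos[i]
    ))
  }
  # reads entirely outside configured regions are dropped with a count
  keep <- !is.na(hit)
  droppedReads <- setdiff(df$read_id[!keep], df$read_id[keep])
  if (length(droppedReads) > 0L) {
    message(sprintf("dropping %d reads mapping to no configured region",
                    length(droppedReads)))
  }
  df <- df[keep, , drop = FALSE]
  hit <- hit[keep]
  if (nrow(df) == 0L) return(empty)
  df$region_id <- mcols(sites)$region_id[hit]
  df$site_index <- mcols(sites)$site_index[hit]
  nsite <- table(mcols(sites)$region_id)
  recs <- lapply(split(df, paste(df$region_id, df$read_id, sep = "\r")),
    function(d) {
      rid <- d$region_id[1L]
      calls <- rep("N", as.integer(nsite[rid]))
      calls[d$site_index + 1L] <- ifelse(d$call == "Z", "M", "U")
      data.frame(sample_id = sample_id, region_id = rid,
                 read_id = d$read_id[1L],
                 calls = paste(calls, collapse = ""),
                 stringsAsFactors = FALSE)
    })
  ReadCallSet(calls = do.call(rbind, c(recs, make.row.names = FALSE)),
              sites = sites)
}

#' Write a ReadCallSet to the native TSV format
#'
#' @param x a [ReadCallSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadCalls <- function(x, path) {
  stopifnot(is(x, "ReadCallSet"))
  utils::write.table(
    as.data.frame(readCalls(x))[, c("sample_id", "region_id", "read_id",
                                    "calls")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a CpG site GRanges as a TSV site table
#'
#' @param sites site `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  utils::write.table(
    data.frame(chrom = as.character(seqnames(sites)), pos = start(sites),
               region_id = mcols(sites)$region_id,
               site_index = mcols(sites)$site_index),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
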
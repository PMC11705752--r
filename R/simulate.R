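# Synthetic-data generators emulating targeted bisulfite sequencing of
# alternative promoter regions, methylation-coupled expression,
# conservation tracks with depressed CpG scores, and tumour cohorts with
# cluster-structured first-exon usage and group-dependent hazards.

# Evaluate expr under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards (stage-level reproducibility).
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.checkProb <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
  p
}

#' Specify an epiallele mixture for read simulation
#'
#' Describes one amplicon region as a mixture of cellular subpopulations,
#' each carrying a fixed methylation pattern over the region's CpG sites.
#' Reads are generated by drawing a pattern by its mixture weight, then
#' applying bisulfite conversion failure (an unmethylated C read as
#' methylated, i.e. `U` flipped to `M`) and a symmetric per-call error.
#'
#' @param region_id region identifier.
#' @param patterns named numeric vector of mixture weights; names are
#'   pattern strings over `M`/`U` (or `0`/`1`), all of equal length.
#'   Weights must sum to 1 within 1e-9.
#' @param conversion_failure probability that an unmethylated C escapes
#'   conversion and is read as methylated.
#' @param call_error probability that any call is flipped (`M`<->`U`).
#' @param seed integer seed for the region's RNG stream.
#' @return A list of class `EpialleleMixtureSpec`.
#' @examples
#' epialleleMixtureSpec("r1", c(MM = 0.7, UU = 0.3), seed = 1)
#' @export
epialleleMixtureSpec <- function(region_id, patterns,
                                 conversion_failure = 0, call_error = 0,
                                 seed = 1L) {
  pats <- names(patterns)
  if (is.null(pats) || any(!nzchar(pats))) {
    stop("'patterns' must be a named vector (names are pattern strings)")
  }
  pats <- chartr("01", "UM", pats)
  if (any(grepl("[^MU]", pats))) {
    stop("pattern strings may only contain M/U (or 1/0)")
  }
  n_sites <- unique(nchar(pats))
  if (length(n_sites) != 1L) {
    stop("all pattern vectors must have the same length (n_sites)")
  }
  w <- as.numeric(patterns)
  if (any(w < 0 | w > 1) || abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must lie in [0, 1] and sum to 1 within 1e-9")
  }
  structure(
    list(
      region_id = as.character(region_id), n_sites = as.integer(n_sites),
      patterns = stats::setNames(w, pats),
      conversion_failure = .checkProb(conversion_failure,
                                      "conversion_failure"),
      call_error = .checkProb(call_error, "call_error"),
      seed = as.integer(seed)
    ),
    class = "EpialleleMixtureSpec"
  )
}

#' Synthetic CpG site table
#'
#' Lays out amplicon regions on a synthetic chromosome with evenly spaced
#' CpG sites, for use with the simulators when no real site table is
#' loaded.
#'
#' @param n_sites integer vector, number of CpG sites per region.
#' @param region_ids region identifiers (defaults to `region_1` ...).
#' @param chrom chromosome name.
#' @param region_gap distance between region starts in bp.
#' @param spacing distance between consecutive CpG sites in bp.
#' @return A `GRanges` of width-1 C positions with `region_id` and
#'   `site_index` metadata columns.
#' @export
syntheticSites <- function(n_sites,
                           region_ids = sprintf("region_%d",
                                                seq_along(n_sites)),
                           chrom = "chrS", region_gap = 10000L,
                           spacing = 40L) {
  stopifnot(length(n_sites) == length(region_ids), all(n_sites >= 1L))
  pos <- unlist(lapply(seq_along(n_sites), function(i) {
    1000L + (i - 1L) * region_gap + spacing * seq_len(n_sites[i])
  }))
  GRanges(chrom, IRanges(pos, width = 1L),
    region_id = rep(as.character(region_ids), n_sites),
    site_index = unlist(lapply(n_sites, function(k) seq_len(k) - 1L))
  )
}

#' Simulate per-read CpG methylation calls
#'
#' Draws reads from an epiallele mixture: each read picks one pattern by
#' its mixture weight, unmethylated sites are flipped to `M` with
#' probability `conversion_failure`, then every call is flipped with
#' probability `call_error`. Optionally simulates per-sample non-CpG
#' context tallies (binomial with the same conversion-failure rate) so
#' conversion QC can be exercised.
#'
#' @param spec an [epialleleMixtureSpec()].
#' @param n_reads number of reads to draw (>= 1).
#' @param sample_id sample identifier for the generated reads.
#' @param sites optional `GRanges` for the region's CpG sites; a
#'   [syntheticSites()] layout is generated when omitted.
#' @param n_noncpg number of non-CpG context cytosines to tally for
#'   conversion QC (0 = no tallies).
#' @return A [ReadCallSet-class].
#' @examples
#' spec <- epialleleMixtureSpec("r1", c(MM = 0.7, UU = 0.3), seed = 7)
#' rcs <- simulateReadCalls(spec, n_reads = 100)
#' @export
simulateReadCalls <- function(spec, n_reads, sample_id = "S1", sites = NULL,
                              n_noncpg = 0L) {
  stopifnot(inherits(spec, "EpialleleMixtureSpec"))
  if (!is.numeric(n_reads) || n_reads < 1) stop("'n_reads' must be >= 1")
  n_reads <- as.integer(n_reads)
  if (is.null(sites)) {
    sites <- syntheticSites(spec$n_sites, region_ids = spec$region_id)
  }
  .withSeed(spec$seed, {
    pats <- names(spec$patterns)
    pick <- sample.int(length(pats), n_reads, replace = TRUE,
                       prob = spec$patterns)
    # matrix of logical methylation states, reads x sites
    patmat <- do.call(rbind, strsplit(pats, "", fixed = TRUE)) == "M"
    meth <- patmat[pick, , drop = FALSE]
    if (spec$conversion_failure > 0) {
      fail <- !meth &
        matrix(stats::runif(length(meth)) < spec$conversion_failure,
               nrow = n_reads)
      meth[fail] <- TRUE
    }
    if (spec$call_error > 0) {
      flip <- matrix(stats::runif(length(meth)) < spec$call_error,
                     nrow = n_reads)
      meth <- xor(meth, flip)
    }
    callstr <- apply(meth, 1L, function(z) {
      paste(ifelse(z, "M", "U"), collapse = "")
    })
    tallies <- DataFrame(sample_id = character(), converted = integer(),
                         unconverted = integer())
    if (n_noncpg > 0L) {
      unconv <- stats::rbinom(1L, as.integer(n_noncpg),
                              spec$conversion_failure)
      tallies <- DataFrame(sample_id = sample_id,
                           converted = as.integer(n_noncpg) - unconv,
                           unconverted = unconv)
    }
    ReadCallSet(
      calls = data.frame(
        sample_id = sample_id, region_id = spec$region_id,
        read_id = sprintf("read_%06d", seq_len(n_reads)),
        calls = callstr, stringsAsFactors = FALSE
      ),
      sites = sites, conversionTallies = tallies
    )
  })
}

#' Combine ReadCallSets over samples/regions
#'
#' @param ... `ReadCallSet` objects sharing compatible site tables.
#' @return A single merged [ReadCallSet-class].
#' @export
combineReadCallSets <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "ReadCallSet")) {
    xs <- xs[[1L]]
  }
  stopifnot(all(vapply(xs, is, logical(1L), "ReadCallSet")))
  sites <- unique(do.call(c, lapply(xs, siteTable)))
  calls <- do.call(rbind, lapply(xs, readCalls))
  tal <- do.call(rbind, lapply(xs, conversionTallies))
  if (nrow(tal) > 0L) {
    tal <- DataFrame(stats::aggregate(
      cbind(converted, unconverted) ~ sample_id, data = as.data.frame(tal),
      FUN = sum
    ))
  }
  ReadCallSet(calls = calls, sites = sites, conversionTallies = tal)
}

#' Specify methylation-expression coupling for simulation
#'
#' @param exon_id identifier of the (first-exon) expression target.
#' @param linked_sites character vector of CpG site ids (`"chrom:pos"`,
#'   matching rownames of a [MethylationExperiment-class]); non-empty.
#' @param direction `"negative"` (methylation represses) or `"positive"`.
#' @param strength nonnegative coupling coefficient on the log-expression
#'   scale per unit methylated fraction.
#' @param noise_sd nonnegative Gaussian noise SD on the log scale.
#' @return A list of class `CouplingSpec`.
#' @export
couplingSpec <- function(exon_id, linked_sites,
                         direction = c("negative", "positive"),
                         strength = 1, noise_sd = 0.1) {
  direction <- match.arg(direction)
  if (length(linked_sites) < 1L) stop("'linked_sites' must be non-empty")
  if (strength < 0) stop("'strength' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(
    list(exon_id = as.character(exon_id),
         linked_sites = as.character(linked_sites),
         direction = direction, strength = strength, noise_sd = noise_sd),
    class = "CouplingSpec"
  )
}

#' Simulate expression coupled to methylation
#'
#' For each coupling, per-sample log-expression is
#' `baseline + sign * strength * mean(methylated fraction of the linked
#' sites) + N(0, noise_sd)`, with `sign = -1` for negative coupling.
#' Expression is reported on the natural scale (`exp` of the log value);
#' rank-based downstream statistics are unaffected by the transform.
#'
#' @param methylation a [MethylationExperiment-class] (rownames are
#'   `"chrom:pos"` site ids).
#' @param couplings list of [couplingSpec()] objects.
#' @param seed integer seed.
#' @param baseline baseline log-expression.
#' @return A long data.frame with columns `target`, `sample_id`,
#'   `expression`.
#' @export
simulateExpression <- function(methylation, couplings, seed = 1L,
                               baseline = 2) {
  stopifnot(is(methylation, "MethylationExperiment"))
  if (inherits(couplings, "CouplingSpec")) couplings <- list(couplings)
  f <- methFraction(methylation)
  .withSeed(seed, {
    do.call(rbind, lapply(couplings, function(cp) {
      missing <- setdiff(cp$linked_sites, rownames(f))
      if (length(missing) > 0L) {
        stop(sprintf("unknown linked site id(s): %s",
                     paste(missing, collapse = ", ")))
      }
      mbar <- colMeans(f[cp$linked_sites, , drop = FALSE], na.rm = TRUE)
      sgn <- if (cp$direction == "negative") -1 else 1
      logexpr <- baseline + sgn * cp$strength * mbar +
        stats::rnorm(length(mbar), 0, cp$noise_sd)
      data.frame(target = cp$exon_id, sample_id = names(mbar),
                 expression = exp(logexpr), row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate a per-base conservation track over regions
#'
#' Scores are drawn i.i.d. Normal(`base_score_mean`, 1) at every base of
#' every region; C-of-CpG positions are additionally shifted down by
#' `cpg_depression`, emulating locally reduced conservation at CpG sites.
#'
#' @param region_set a [RegionSet-class] whose `cpgSites()` mark the C
#'   positions.
#' @param base_score_mean mean phyloP-like score of non-CpG positions.
#' @param cpg_depression nonnegative downward shift applied at C-of-CpG
#'   positions.
#' @param seed integer seed.
#' @return A width-1 `GRanges` covering every region base with a `score`
#'   metadata column (a per-base conservation track).
#' @export
simulateConservation <- function(region_set, base_score_mean = 0,
                                 cpg_depression = 0, seed = 1L) {
  stopifnot(is(region_set, "RegionSet"))
  if (cpg_depression < 0) stop("'cpg_depression' must be >= 0")
  reg <- regionRanges(region_set)
  pos <- unlist(lapply(seq_along(reg), function(i) {
    start(reg)[i]:end(reg)[i]
  }))
  chrom <- rep(as.character(seqnames(reg)), width(reg))
  track <- GRanges(chrom, IRanges(pos, width = 1L))
  .withSeed(seed, {
    score <- stats::rnorm(length(track), base_score_mean, 1)
    hit <- findOverlaps(track, cpgSites(region_set), select = "first")
    score[!is.na(hit)] <- score[!is.na(hit)] - cpg_depression
    mcols(track)$score <- score
    track
  })
}

#' Specify a tumour cohort simulation
#'
#' @param n_tumours number of tumours.
#' @param cluster_profiles list of per-cluster first-exon fraction
#'   vectors (each nonnegative, summing to 1 within 1e-9); names become
#'   cluster labels. All vectors share the same exon names.
#' @param cluster_weights mixture weights over clusters (sum to 1).
#' @param depth a list describing the total first-exon read-depth
#'   distribution: `list(dist = "nbinom", mu =, size =)`,
#'   `list(dist = "poisson", lambda =)` or `list(dist = "fixed", value =)`.
#' @param hazard_by_group named numeric vector of exponential event
#'   hazards (events per unit time) per cluster/group.
#' @param censoring_rate exponential censoring rate.
#' @param seed integer seed.
#' @return A list of class `CohortSimSpec`.
#' @export
cohortSimSpec <- function(n_tumours, cluster_profiles, cluster_weights,
                          depth = list(dist = "nbinom", mu = 100, size = 5),
                          hazard_by_group, censoring_rate = 0.05,
                          seed = 1L) {
  stopifnot(n_tumours >= 1)
  if (is.null(names(cluster_profiles))) {
    names(cluster_profiles) <- sprintf("cluster_%d",
                                       seq_along(cluster_profiles))
  }
  for (p in cluster_profiles) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("each fraction profile must be nonnegative and sum to 1")
    }
  }
  if (abs(sum(cluster_weights) - 1) > 1e-9) {
    stop("cluster weights must sum to 1")
  }
  if (length(cluster_weights) != length(cluster_profiles)) {
    stop("one weight per cluster profile required")
  }
  if (!all(names(cluster_profiles) %in% names(hazard_by_group))) {
    stop("hazard_by_group must name every cluster")
  }
  structure(
    list(n_tumours = as.integer(n_tumours),
         cluster_profiles = cluster_profiles,
         cluster_weights = as.numeric(cluster_weights), depth = depth,
         hazard_by_group = hazard_by_group,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "CohortSimSpec"
  )
}

.drawDepth <- function(depth, n) {
  switch(depth$dist,
    nbinom = stats::rnbinom(n, mu = depth$mu, size = depth$size),
    poisson = stats::rpois(n, depth$lambda),
    fixed = rep(as.integer(depth$value), n),
    stop(sprintf("unknown depth distribution '%s'", depth$dist))
  )
}

#' Simulate a tumour cohort with first-exon counts and survival
#'
#' Each tumour draws a cluster by weight, a total first-exon read depth
#' from the configured count distribution, multinomial per-exon counts on
#' the cluster's fraction profile, an exponential event time with the
#' cluster's hazard and an independent exponential censoring time.
#' Endpoint columns follow the `<endpoint>_time` / `<endpoint>_event`
#' convention for overall survival (`os`), recurrence-free interval
#' (`rfi`) and distant recurrence-free interval (`drfi`); simulated
#' endpoints are independent draws from the same hazard model. Simple
#' clinical covariates (lymph-node status, histological grade, tumour
#' size in mm) are drawn independently of outcome unless listed in
#' `spec$hazard_by_group`.
#'
#' @param spec a [cohortSimSpec()].
#' @return A data.frame (cohort table) with `tumour_id`, `true_cluster`,
#'   one `count_<exon>` column per exon, `total_first_exon_reads`,
#'   clinical covariates and endpoint columns.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  .withSeed(spec$seed, {
    n <- spec$n_tumours
    labels <- names(spec$cluster_profiles)
    cl <- sample(labels, n, replace = TRUE, prob = spec$cluster_weights)
    depth <- .drawDepth(spec$depth, n)
    exons <- names(spec$cluster_profiles[[1L]])
    if (is.null(exons)) {
      exons <- sprintf("prom%s", LETTERS[seq_along(
        spec$cluster_profiles[[1L]])])
    }
    counts <- t(matrix(vapply(seq_len(n), function(i) {
      if (depth[i] == 0L) return(rep(0L, length(exons)))
      as.integer(stats::rmultinom(1L, depth[i],
                                  spec$cluster_profiles[[cl[i]]]))
    }, integer(length(exons))), nrow = length(exons)))
    colnames(counts) <- paste0("count_", exons)
    out <- data.frame(
      tumour_id = sprintf("T%05d", seq_len(n)), true_cluster = cl,
      counts, total_first_exon_reads = as.integer(depth),
      er_status = sample(c("positive", "negative"), n, replace = TRUE,
                         prob = c(0.85, 0.15)),
      lymph_node = stats::rbinom(n, 1L, 0.35),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.5, 0.3)),
      tumour_size_mm = round(stats::rlnorm(n, log(18), 0.4), 1),
      stringsAsFactors = FALSE
    )
    hz <- spec$hazard_by_group[cl]
    for (ep in c("os", "rfi", "drfi")) {
      evt <- stats::rexp(n, hz)
      cens <- stats::rexp(n, spec$censoring_rate)
      out[[paste0(ep, "_time")]] <- pmin(evt, cens)
      out[[paste0(ep, "_event")]] <- as.integer(evt <= cens)
    }
    out
  })
}
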
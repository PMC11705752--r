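# End-to-end orchestration from a single YAML config, plus a packaged
# synthetic fixture generator mirroring the study design scale
# (12 amplicon regions x 19 samples x 108 CpG sites).

.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

.writeProvenance <- function(path, hash, seed) {
  prov <- list(
    config_hash = hash, seed = seed,
    package = "promoMethyl",
    package_version = as.character(utils::packageVersion("promoMethyl"))
  )
  writeLines(yaml::as.yaml(prov), paste0(path, ".prov.yaml"))
  invisible(NULL)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Generate a packaged synthetic dataset
#'
#' Writes a complete, small synthetic input set mirroring the scale of
#' the study design: 12 amplicon regions with 9 CpG sites each (108
#' sites) on a synthetic chromosome, 19 samples (six cell lines as
#' parental/resistant/withdrawn sublines plus one late-withdrawal
#' sample), per-read methylation calls from epiallele mixtures with
#' bisulfite conversion failure and call error, first-exon expression
#' negatively coupled to the methylation of linked regions, a per-base
#' conservation track with depressed scores at C-of-CpG positions, a
#' TFBS interval set, and a simulated tumour cohort with
#' cluster-structured first-exon fractions and group-dependent hazards.
#' Truth tables (mixture methylation levels, coupling map) are written
#' alongside. A ready-to-run pipeline config referencing all files is
#' included.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; all per-stage streams derive from it.
#' @param n_reads reads per region and sample (default 60).
#' @param n_tumours cohort size (default 400).
#' @return list of generated file paths (named), including `config`.
#' @export
makeFixtures <- function(dir, seed = 1L, n_reads = 60L, n_tumours = 400L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  regions <- sprintf("region_%02d", 1:12)
  sites <- syntheticSites(rep(9L, 12L), region_ids = regions)
  lines <- c("CAMA1", "EFM19", "HCC1428", "MCF7", "T47D", "ZR751")
  samples <- c(as.vector(t(outer(lines, c("P", "FR", "FRF"), paste,
                                 sep = "_"))), "CAMA1_FRF_w17")
  # per (region, sample) weight of the fully methylated subpopulation
  grid <- expand.grid(region_id = regions, sample_id = samples,
                      stringsAsFactors = FALSE)
  grid$m_level <- .withSeed(seed, round(stats::rbeta(nrow(grid), 0.6, 1.4),
                                        3))
  mosaic <- paste(rep(c("M", "U"), length.out = 9L), collapse = "")
  rcsList <- list()
  for (i in seq_len(nrow(grid))) {
    m <- grid$m_level[i]
    w <- c(0.65 * (1 - m), 0.35 * (1 - m), m)
    names(w) <- c(strrep("U", 9L), mosaic, strrep("M", 9L))
    w <- w[w > 0]
    w <- w / sum(w)
    spec <- epialleleMixtureSpec(
      grid$region_id[i], w, conversion_failure = 0.015,
      call_error = 0.005, seed = seed + 13L * i
    )
    rcsList[[i]] <- simulateReadCalls(
      spec, n_reads, sample_id = grid$sample_id[i],
      sites = sites[mcols(sites)$region_id == grid$region_id[i]],
      n_noncpg = if (grid$region_id[i] == regions[1L]) 5000L else 0L
    )
  }
  rcs <- combineReadCallSets(rcsList)
  rcs@sites <- sites
  methods::validObject(rcs)
  paths <- list()
  paths$sites <- .writeTSV(
    data.frame(chrom = as.character(seqnames(sites)), pos = start(sites),
               region_id = mcols(sites)$region_id),
    file.path(dir, "sites.tsv")
  )
  paths$reads <- writeReadCalls(rcs, file.path(dir, "reads.tsv"))
  tal <- as.data.frame(conversionTallies(rcs))
  paths$conversion <- .writeTSV(tal, file.path(dir, "conversion.tsv"))
  paths$truth_mixtures <- .writeTSV(grid,
                                    file.path(dir, "truth_mixtures.tsv"))
  # expression coupled (negatively) to the methylation of linked regions
  me <- methylatedFraction(rcs)
  ids <- rownames(methFraction(me))
  byRegion <- split(ids, mcols(sites)$region_id)
  exons <- sprintf("prom%s", LETTERS[1:6])
  couplings <- lapply(seq_along(exons), function(j) {
    couplingSpec(exons[j], byRegion[[regions[2L * j - 1L]]],
                 direction = "negative", strength = 3, noise_sd = 0.3)
  })
  couplings <- c(couplings, list(
    couplingSpec("utr3", unlist(byRegion[regions[c(11L, 12L)]]),
                 direction = "negative", strength = 3, noise_sd = 0.3)
  ))
  expr <- simulateExpression(me, couplings, seed = seed + 101L)
  paths$expression <- .writeTSV(expr, file.path(dir, "expression.tsv"))
  paths$truth_couplings <- .writeTSV(
    do.call(rbind, lapply(couplings, function(cp) {
      data.frame(target = cp$exon_id,
                 linked_sites = paste(cp$linked_sites, collapse = ","),
                 direction = cp$direction, strength = cp$strength,
                 noise_sd = cp$noise_sd)
    })),
    file.path(dir, "truth_couplings.tsv")
  )
  # conservation track over padded region spans
  spans <- .regionSpans(sites)
  spans <- resize(spans, width(spans) + 80L, fix = "center")
  cpg <- sites; mcols(cpg) <- NULL
  rset <- RegionSet(spans, cpg)
  track <- simulateConservation(rset, base_score_mean = 1,
                                cpg_depression = 1.5, seed = seed + 202L)
  paths$track <- file.path(dir, "conservation.bedGraph")
  writeConservationTrack(track, paths$track)
  # TFBS intervals covering a subset of CpG sites plus decoys elsewhere
  tfnames <- c("CTCF", "GATA3", "TFAP2C", "MYC", "JUND", "RUNX1", "NR3C1",
               "ESR1")
  tfbs <- .withSeed(seed + 303L, {
    hit <- sample(seq_along(sites), size = 40L)
    on_sites <- GRanges(
      as.character(seqnames(sites)[hit]),
      IRanges(start(sites)[hit] - sample(3:12, 40L, replace = TRUE),
              width = sample(12:25, 40L, replace = TRUE)),
      name = sample(tfnames, 40L, replace = TRUE),
      score = 0L, strand = "+"
    )
    decoys <- GRanges("chrS",
                      IRanges(sample(200000:300000, 30L),
                              width = sample(10:25, 30L, replace = TRUE)),
                      name = sample(tfnames, 30L, replace = TRUE),
                      score = 0L, strand = "+")
    sort(c(on_sites, decoys))
  })
  paths$tfbs <- file.path(dir, "tfbs.bed")
  rtracklayer::export(tfbs, paths$tfbs, format = "BED")
  # tumour cohort: five first-exon usage archetypes with distinct hazards
  profiles <- list(
    promA_dominant = c(promA = 0.80, promB = 0.08, promC = 0.06,
                       promD = 0.03, promE = 0.02, promF = 0.01),
    promC_high = c(promA = 0.35, promB = 0.08, promC = 0.45,
                   promD = 0.06, promE = 0.04, promF = 0.02),
    promF_high = c(promA = 0.30, promB = 0.06, promC = 0.08,
                   promD = 0.06, promE = 0.05, promF = 0.45),
    mixed = c(promA = 0.40, promB = 0.20, promC = 0.15, promD = 0.10,
              promE = 0.10, promF = 0.05),
    promB_high = c(promA = 0.30, promB = 0.45, promC = 0.10,
                   promD = 0.05, promE = 0.05, promF = 0.05)
  )
  cspec <- cohortSimSpec(
    n_tumours = n_tumours, cluster_profiles = profiles,
    cluster_weights = c(0.35, 0.2, 0.15, 0.2, 0.1),
    depth = list(dist = "nbinom", mu = 120, size = 4),
    hazard_by_group = c(promA_dominant = 0.05, promC_high = 0.12,
                        promF_high = 0.08, mixed = 0.07,
                        promB_high = 0.10),
    censoring_rate = 0.05, seed = seed + 404L
  )
  cohort <- simulateCohort(cspec)
  paths$cohort <- .writeTSV(cohort, file.path(dir, "cohort.tsv"))
  config <- list(
    schema_version = 1L, seed = seed,
    paths = c(lapply(paths, normalizePath),
              list(out = file.path(normalizePath(dir), "results"))),
    thresholds = list(min_coverage = 1L, min_reads = 10L, alpha = 0.05,
                      top_k = 10L, min_frequency = 0.01,
                      presence_threshold = 0.01),
    pattern_region = regions[12L],
    pairs = data.frame(
      subline = paste(lines, "FR", sep = "_"),
      parental = paste(lines, "P", sep = "_")
    ),
    survival = list(exon = "promC", cutoff = 0.25, endpoint = "os",
                    covariates = c("lymph_node", "grade",
                                   "tumour_size_mm")),
    cluster_k = 5L
  )
  paths$config <- file.path(dir, "config.yaml")
  conf <- config
  conf$pairs <- as.list(conf$pairs)
  writeLines(yaml::as.yaml(conf), paths$config)
  paths
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML config file (see [makeFixtures()] for a template).
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  config <- yaml::read_yaml(path)
  if (is.null(config$paths)) stop("config lacks a 'paths' section")
  inputs <- setdiff(names(config$paths), "out")
  missing <- inputs[!vapply(config$paths[inputs],
                            function(p) file.exists(p), logical(1L))]
  if (length(missing) > 0L) {
    stop(sprintf("config input path(s) do not exist: %s (%s)",
                 paste(missing, collapse = ", "),
                 paste(unlist(config$paths[missing]), collapse = ", ")))
  }
  th <- config$thresholds
  if (!is.null(th$alpha) && (th$alpha <= 0 || th$alpha >= 1)) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.null(th$min_frequency) &&
      (th$min_frequency < 0 || th$min_frequency > 1)) {
    stop("min_frequency must lie in [0, 1]")
  }
  if (!is.null(config$pairs)) config$pairs <- as.data.frame(config$pairs)
  config
}

#' Run the full analysis pipeline from a config
#'
#' Stages run in dependency order: methylation quantification and
#' conversion QC, epiallele patterns, delta methylation, site-site and
#' methylation-expression correlation, TFBS overlap, conservation
#' comparison with delta-phyloP, and cohort fractions / clustering /
#' survival. Every output TSV gets a provenance sidecar
#' (`<file>.prov.yaml` with the config hash, seed and package version);
#' a rerun with an identical config is byte-identical. A stage failure
#' halts the run with the failing stage named.
#'
#' @param config path to a YAML config or a validated config list.
#' @return Invisibly, a list with `manifest` (data.frame `stage`,
#'   `file`, `md5`; also written to `<out>/manifest.tsv`) and the main
#'   in-memory stage results (`methylation`, `correlation`, `tfbs`,
#'   `conservation`, `cohort`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  out <- config$paths$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  th <- config$thresholds
  manifest <- list()
  emit <- function(stage, df, name) {
    path <- .writeTSV(df, file.path(out, name))
    .writeProvenance(path, hash, config$seed)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name, md5 = unname(tools::md5sum(path))
    )
    path
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sites <- readSiteTable(config$paths$sites)
  rcs <- runStage("methylation", function() {
    r <- parseReadCalls(config$paths$reads, sites, format = "native_tsv")
    if (!is.null(config$paths$conversion)) {
      tal <- utils::read.delim(config$paths$conversion)
      if (nrow(tal) > 0L) r@conversionTallies <- DataFrame(tal)
    }
    r
  })
  me <- methylatedFraction(rcs, min_coverage = th$min_coverage %||% 1L)
  long <- writeMethylationTSV(me)
  emit("methylation", long, "methylation_long.tsv")
  emit("methylation",
       data.frame(site = rownames(methFraction(me)), methFraction(me),
                  check.names = FALSE),
       "methylation_wide.tsv")
  emit("methylation", conversionQC(rcs), "conversion_qc.tsv")
  runStage("patterns", function() {
    reg <- config$pattern_region %||%
      unique(mcols(sites)$region_id)[1L]
    pft <- epiallelePatterns(rcs, reg, top_k = th$top_k %||% 10L,
                             min_frequency = th$min_frequency %||% 0.01)
    emit("patterns", as.data.frame(patternFrequencies(pft)),
         "patterns.tsv")
  })
  if (!is.null(config$pairs)) {
    runStage("delta", function() {
      emit("delta", deltaMethylation(me, config$pairs), "delta.tsv")
    })
  }
  runStage("site_correlation", function() {
    rho <- siteCorrelationMatrix(me)
    emit("site_correlation",
         data.frame(site = rownames(rho), rho, check.names = FALSE),
         "site_correlation.tsv")
    emit("site_correlation", data.frame(order = rownames(rho)),
         "site_order.tsv")
  })
  corSummary <- NULL
  if (!is.null(config$paths$expression)) {
    corSummary <- runStage("expression_correlation", function() {
      expr <- utils::read.delim(config$paths$expression)
      res <- suppressMessages(
        methylationExpressionCorrelation(me, expr,
                                         alpha = th$alpha %||% 0.05)
      )
      emit("expression_correlation", res$table,
           "methylation_expression_correlation.tsv")
      emit("expression_correlation",
           data.frame(n_sites_nominal = res$n_sites_nominal,
                      n_sites_fdr = res$n_sites_fdr),
           "correlation_summary.tsv")
      res
    })
  }
  tfbsSummary <- NULL
  if (!is.null(config$paths$tfbs)) {
    tfbsSummary <- runStage("tfbs", function() {
      ov <- overlapTFBS(sites, readTFBS(config$paths$tfbs))
      emit("tfbs", ov$annotation, "tfbs_overlap.tsv")
      ov
    })
  }
  consSummary <- NULL
  if (!is.null(config$paths$track)) {
    consSummary <- runStage("conservation", function() {
      track <- readConservationTrack(config$paths$track)
      spans <- .regionSpans(sites)
      cpg <- sites; mcols(cpg) <- NULL
      rset <- RegionSet(spans, cpg)
      cc <- conservationCompare(track, rset)
      dp <- deltaPhyloP(track, rset)
      emit("conservation", cc$per_region, "conservation_per_region.tsv")
      emit("conservation", dp$positions, "delta_phylop.tsv")
      emit("conservation",
           data.frame(test = c("phyloP", "delta_phyloP"),
                      W = c(cc$W, dp$comparison$W),
                      p_value = c(cc$p_value, dp$comparison$p_value)),
           "conservation_tests.tsv")
      list(raw = cc, delta = dp)
    })
  }
  survivalSummary <- NULL
  if (!is.null(config$paths$cohort)) {
    survivalSummary <- runStage("cohort", function() {
      cohort <- utils::read.delim(config$paths$cohort)
      fx <- firstExonFractions(cohort, min_reads = th$min_reads %||% 10L)
      emit("cohort",
           data.frame(tumour_id = rownames(fx$fractions), fx$fractions,
                      check.names = FALSE),
           "first_exon_fractions.tsv")
      cl <- clusterTumours(fx$fractions, k = config$cluster_k %||% 5L,
                           seed = config$seed)
      emit("cohort",
           data.frame(tumour_id = rownames(fx$fractions),
                      cluster = cl$labels),
           "clusters.tsv")
      sv <- config$survival
      res <- NULL
      if (!is.null(sv)) {
        retained <- cohort[match(rownames(fx$fractions),
                                 cohort$tumour_id), , drop = FALSE]
        groups <- stratifyTumours(fx$fractions, sv$exon, sv$cutoff)
        km <- kmLogrank(retained, groups, endpoint = sv$endpoint)
        emit("cohort", km$curves, "km_curves.tsv")
        emit("cohort",
             data.frame(chisq = km$chisq, df = km$df,
                        p_value = km$p_value, n = km$n,
                        n_events = km$n_events),
             "logrank.tsv")
        retained$strata <- groups
        cox_u <- coxFit(retained, c("strata", sv$covariates),
                        endpoint = sv$endpoint, mode = "univariable")
        cox_m <- coxFit(retained, c("strata", sv$covariates),
                        endpoint = sv$endpoint, mode = "multivariable")
        emit("cohort", rbind(cox_u, cox_m), "cox.tsv")
        res <- list(km = km, cox_uni = cox_u, cox_multi = cox_m)
      }
      list(fractions = fx, clusters = cl, survival = res)
    })
  }
  man <- do.call(rbind, manifest)
  .writeTSV(man, file.path(out, "manifest.tsv"))
  .writeProvenance(file.path(out, "manifest.tsv"), hash, config$seed)
  invisible(list(manifest = man, methylation = me,
                 correlation = corSummary, tfbs = tfbsSummary,
                 conservation = consSummary, cohort = survivalSummary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
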
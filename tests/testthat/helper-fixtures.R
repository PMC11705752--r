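# Shared in-code fixtures. The full synthetic dataset (12 regions x 19
# samples x 108 sites) is generated once per test run and reused.

.fixtureEnv <- new.env(parent = emptyenv())

sharedFixture <- function() {
  if (is.null(.fixtureEnv$paths)) {
    dir <- file.path(tempdir(), "promoMethyl-fixture")
    .fixtureEnv$paths <- makeFixtures(dir, seed = 20240806)
  }
  .fixtureEnv$paths
}

# Hand-build a MethylationExperiment from a fraction matrix.
# Fractions are rounded to 1/coverage so fraction * coverage is integral.
makeME <- function(fraction, coverage = 100L, sitesPerRegion = NULL) {
  nsite <- nrow(fraction)
  if (is.null(sitesPerRegion)) sitesPerRegion <- nsite
  sites <- syntheticSites(sitesPerRegion)
  fraction <- round(fraction * coverage) / coverage
  cov <- matrix(as.integer(coverage), nsite, ncol(fraction),
                dimnames = dimnames(fraction))
  ids <- paste0(as.character(GenomicRanges::seqnames(sites)), ":",
                GenomicRanges::start(sites))
  dimnames(fraction) <- list(ids, colnames(fraction))
  dimnames(cov) <- dimnames(fraction)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fraction = fraction, coverage = cov), rowRanges = sites
  )
  methods::new("MethylationExperiment", se)
}

# A tiny two-region site table used across parser tests
tinySites <- function() {
  siteGRanges(data.frame(
    chrom = "chr6",
    pos = c(100L, 150L, 200L, 500L, 560L),
    region_id = c("r1", "r1", "r1", "r2", "r2")
  ))
}

writeTempTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
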
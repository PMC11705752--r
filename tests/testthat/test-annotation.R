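# TFBS overlap, background-region construction and conservation
# comparison with delta-phyloP.

library(GenomicRanges)

test_that("TFBS overlap follows the 0-based half-open convention", {
  # interval [90, 110) in 0-based half-open = GRanges 91..110 (1-based)
  tfbs <- GRanges("chr1", IRanges(91, 110), tf = "CTCF")
  siteIn <- GRanges("chr1", IRanges(100, 100))
  siteBoundary <- GRanges("chr1", IRanges(110, 110))
  siteOut <- GRanges("chr1", IRanges(111, 111))
  expect_equal(overlapTFBS(siteIn, tfbs)$n_sites_with_tfbs, 1L)
  expect_equal(overlapTFBS(siteBoundary, tfbs)$n_sites_with_tfbs, 1L)
  expect_equal(overlapTFBS(siteOut, tfbs)$n_sites_with_tfbs, 0L)
  expect_error(overlapTFBS(siteIn, GRanges("chr1", IRanges(start = 6, end = 5))),
               "start < end")
})

test_that("TFBS overlap equals quadratic brute-force on random instances", {
  set.seed(15)
  for (rep in 1:100) {
    npos <- 20L; nint <- 30L
    pos <- sample(1:2000, npos)
    start0 <- sample(0:1990, nint)
    end0 <- start0 + sample(1:40, nint, replace = TRUE)
    sites <- GRanges("c", IRanges(pos, width = 1))
    tfbs <- GRanges("c", IRanges(start0 + 1L, end0),
                    tf = sprintf("TF%d", seq_len(nint)))
    got <- overlapTFBS(sites, tfbs)
    expect_equal(unname(got$annotation$n_tfbs),
                 unname(bruteOverlapCount(pos, start0, end0)))
  }
})

test_that("background regions follow the IQR/pad/mask/filter pipeline", {
  # target gene expression over 5 samples: quartiles of (10,20,30,40,50)
  # are Q1 = 20, Q3 = 40 by linear interpolation
  ge <- rbind(
    data.frame(gene_id = "TGT", sample_id = paste0("S", 1:5),
               expression = c(10, 20, 30, 40, 50)),
    data.frame(gene_id = "gIn", sample_id = "S1", expression = 25),
    data.frame(gene_id = "gIn2", sample_id = "S1", expression = 40),
    data.frame(gene_id = "gLow", sample_id = "S1", expression = 5),
    data.frame(gene_id = "gHigh", sample_id = "S1", expression = 90)
  )
  fe <- GRanges("chr1",
                IRanges(c(5000, 20000, 40000, 60000), width = 200),
                gene_id = c("gIn", "gIn2", "gLow", "gHigh"))
  # CDS that splits gIn's padded region [4250, 5949] into two fragments
  cds <- GRanges("chr1", IRanges(4600, 4799))
  cpg <- GRanges("chr1", IRanges(c(4300, 4350, 4400, 4450,  # left frag
                                   5000, 5100, 5200, 5300,  # right frag
                                   19500, 19600, 19700, 19800),
                                 width = 1))
  rs <- buildBackgroundRegions(ge, "TGT", fe, cds, cpg)
  reg <- regionRanges(rs)
  # hand-computed: gIn pads to [4250, 5949]; CDS masking leaves
  # [4250, 4599] (350 bp < 400, dropped) and [4800, 5949] (1150 bp, 4
  # CpGs, kept); gIn2 pads to [19250, 20949] (1700 bp, 4 CpGs, kept);
  # gLow/gHigh fall outside the expression window
  expect_equal(length(reg), 2L)
  expect_equal(start(reg), c(4800, 19250))
  expect_equal(end(reg), c(5949, 20949))
  # invariants: no CDS overlap; fragments inside padded first exons
  expect_equal(length(findOverlaps(reg, cds)), 0L)
  padded <- resize(fe, width(fe) + 1500, fix = "center")
  expect_true(all(countOverlaps(reg, padded, type = "within") >= 1L))
  expect_error(buildBackgroundRegions(ge, "nope", fe, cds, cpg), "absent")
})

test_that("boundary fragments are dropped per the strict length rule", {
  ge <- rbind(
    data.frame(gene_id = "TGT", sample_id = paste0("S", 1:4),
               expression = c(10, 20, 30, 40)),
    data.frame(gene_id = "g1", sample_id = "S1", expression = 25)
  )
  cpgAt <- function(pos) GRanges("chr1", IRanges(pos, width = 1))
  # fragment of exactly 400 bp: padded exon minus CDS leaves [1000, 1399]
  fe <- GRanges("chr1", IRanges(1000, 1399), gene_id = "g1")
  expect_warning(
    rs <- buildBackgroundRegions(ge, "TGT", fe, GRanges(),
                                 cpgAt(c(1010, 1020, 1030, 1040)),
                                 pad_bp = 0L),
    "no fragment"
  )
  expect_equal(length(regionRanges(rs)), 0L)  # 400 is not > 400
  # 500 bp but only 3 CpGs: dropped
  fe2 <- GRanges("chr1", IRanges(1000, 1499), gene_id = "g1")
  rs2 <- suppressWarnings(
    buildBackgroundRegions(ge, "TGT", fe2, GRanges(),
                           cpgAt(c(1010, 1020, 1030)), pad_bp = 0L)
  )
  expect_equal(length(regionRanges(rs2)), 0L)
  # 500 bp with 4 CpGs: kept
  rs3 <- buildBackgroundRegions(ge, "TGT", fe2, GRanges(),
                                cpgAt(c(1010, 1020, 1030, 1040)),
                                pad_bp = 0L)
  expect_equal(length(regionRanges(rs3)), 1L)
})

.toyRegionSet <- function(scores, cpgIdx, chrom = "c", startAt = 101L) {
  n <- length(scores)
  reg <- GRanges(chrom, IRanges(startAt, width = n), region_id = "r1")
  cpg <- GRanges(chrom, IRanges(startAt + cpgIdx - 1L, width = 1))
  rs <- RegionSet(reg, cpg)
  track <- GRanges(chrom, IRanges(startAt + seq_len(n) - 1L, width = 1),
                   score = scores)
  list(rs = rs, track = track)
}

test_that("rank-sum comparison matches exact enumeration", {
  # A = {1, 2} vs B = {3, 4}: rank-sum of A is 3, two-sided p = 1/3
  toy <- .toyRegionSet(c(1, 2, 3, 4), cpgIdx = c(1L, 2L))
  cc <- conservationCompare(toy$track, toy$rs)
  expect_equal(sort(cc$cpg_scores), c(1, 2))
  expect_equal(cc$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(cc$exact)
  # and against the enumeration oracle on random tie-free inputs
  set.seed(16)
  for (rep in 1:10) {
    sc <- sample(seq(0.1, 9.9, by = 0.1), 10)
    idx <- sort(sample(1:10, sample(2:5, 1)))
    toy <- .toyRegionSet(sc, idx)
    cc <- conservationCompare(toy$track, toy$rs)
    br <- bruteWilcox(sc[idx], sc[-idx])
    expect_equal(cc$p_value, br$p_value, tolerance = 1e-12)
    expect_equal(unname(cc$W), br$U)
  }
})

test_that("normal approximation is close to exact p at combined n = 10", {
  set.seed(17)
  sc <- sample(seq(0.1, 9.9, by = 0.1), 10)
  idx <- 1:4
  exact <- bruteWilcox(sc[idx], sc[-idx])$p_value
  wt <- suppressWarnings(wilcox.test(sc[idx], sc[-idx], exact = FALSE,
                                     correct = TRUE))
  expect_lt(abs(wt$p.value - exact), 1e-1)
  # identical groups: p = 1 under the approximation with ties
  toy <- .toyRegionSet(rep(c(1, 2), 5), cpgIdx = c(1L, 2L))
  cc <- conservationCompare(toy$track, toy$rs)
  expect_equal(cc$p_value, 1, tolerance = 0.05)
})

test_that("depressed CpG scores are detected with high power", {
  # smaller instance than the headline power run (kept in acceptance):
  # depression 2 with 20 C / 180 background positions
  sites <- syntheticSites(20L, spacing = 10L)
  spans <- range(sites)
  mcols(spans)$region_id <- "region_1"
  cpg <- sites; mcols(cpg) <- NULL
  rs <- RegionSet(spans, cpg)
  rej <- vapply(1:20, function(s) {
    tr <- simulateConservation(rs, 0, cpg_depression = 2, seed = s)
    conservationCompare(tr, rs)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("delta-phyloP centres every region at zero", {
  toy <- .toyRegionSet(c(0.2, 0.4, 0.6), cpgIdx = 1L)
  dp <- deltaPhyloP(toy$track, toy$rs)
  expect_equal(dp$cpg_delta, -0.2, tolerance = 1e-12)
  # algebraic identity: per-region mean of deltas is 0
  expect_lt(abs(mean(dp$positions$delta)), 1e-9)
  set.seed(18)
  sites <- syntheticSites(c(5L, 5L), region_ids = c("region_1", "region_2"))
  spans <- promoMethyl:::.regionSpans(sites)
  cpg <- sites; mcols(cpg) <- NULL
  rs <- RegionSet(spans, cpg)
  tr <- simulateConservation(rs, 1, 0.5, seed = 3)
  dp2 <- deltaPhyloP(tr, rs)
  for (r in unique(dp2$positions$region_id)) {
    expect_lt(abs(mean(dp2$positions$delta[dp2$positions$region_id == r])),
              1e-9)
  }
})

test_that("stratified mode reports one test per region", {
  sites <- syntheticSites(c(5L, 5L), region_ids = c("region_1", "region_2"))
  spans <- promoMethyl:::.regionSpans(sites)
  cpg <- sites; mcols(cpg) <- NULL
  rs <- RegionSet(spans, cpg)
  tr <- simulateConservation(rs, 0, 1, seed = 4)
  cc <- conservationCompare(tr, rs, mode = "stratified")
  expect_true(all(c("W", "p_value") %in% colnames(cc$per_region)))
  expect_equal(nrow(cc$per_region), 2L)
})

test_that("bedGraph round-trip preserves per-base scores", {
  sites <- syntheticSites(4L)
  spans <- range(sites)
  mcols(spans)$region_id <- "region_1"
  cpg <- sites; mcols(cpg) <- NULL
  rs <- RegionSet(spans, cpg)
  tr <- simulateConservation(rs, 0.5, 1, seed = 6)
  f <- tempfile(fileext = ".bedGraph")
  writeConservationTrack(tr, f)
  tr2 <- readConservationTrack(f)
  got <- promoMethyl:::.trackScores(tr2, tr)
  expect_equal(got, mcols(tr)$score, tolerance = 1e-6)
})
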
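# Delta methylation, Spearman machinery (with enumeration oracles),
# expression normalization and the BH correction layer.

test_that("delta methylation subtracts parental from subline", {
  f <- cbind(P = c(0.1, 0.5, 0.3), FR = c(0.9, 0.5, 0.1))
  me <- makeME(f, coverage = 10L)
  d <- deltaMethylation(me, data.frame(subline = "FR", parental = "P"))
  expect_equal(d$delta, c(0.8, 0.0, -0.2))
  expect_true(all(d$delta >= -1 & d$delta <= 1))
  expect_error(
    deltaMethylation(me, data.frame(subline = "XX", parental = "P")),
    "XX"
  )
})

test_that("a shifted region shows deltas near +1, others near 0", {
  mk <- function(w12, seed) {
    specs <- list(
      epialleleMixtureSpec("region_1", c(UUU = 1), seed = seed),
      epialleleMixtureSpec("region_2", w12, seed = seed + 1L)
    )
    sites <- syntheticSites(c(3L, 3L), region_ids = c("region_1",
                                                      "region_2"))
    combineReadCallSets(lapply(seq_along(specs), function(i) {
      simulateReadCalls(
        specs[[i]], 500L,
        sample_id = if (seed == 1) "P" else "FR",
        sites = sites[S4Vectors::mcols(sites)$region_id ==
                        specs[[i]]$region_id]
      )
    }))
  }
  rcs <- combineReadCallSets(mk(c(UUU = 1), 1L), mk(c(MMM = 1), 100L))
  me <- methylatedFraction(rcs)
  d <- deltaMethylation(me, data.frame(subline = "FR", parental = "P"))
  expect_true(all(abs(d$delta[d$region_id == "region_1"]) < 0.05))
  expect_true(all(d$delta[d$region_id == "region_2"] > 0.95))
})

test_that("site correlation matrix matches trivial and oracle cases", {
  f <- rbind(a = c(0.1, 0.2, 0.3, 0.4),
             b = c(0.1, 0.2, 0.3, 0.4),
             c = c(0.9, 0.5, 0.3, 0.1))
  colnames(f) <- paste0("S", 1:4)
  rho <- siteCorrelationMatrix(makeME(f, coverage = 10L))
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(rho["chrS:1040", "chrS:1080"], 1)   # identical vectors
  expect_equal(rho["chrS:1040", "chrS:1120"], -1)  # anti-monotone
  expect_true(isSymmetric(rho))
})

test_that("pairwise rho equals exhaustive rank enumeration at n = 5", {
  set.seed(14)
  for (rep in 1:5) {
    x <- round(runif(5), 2); y <- round(runif(5), 2)
    me <- makeME(rbind(x, y), coverage = 100L)
    rho <- siteCorrelationMatrix(me)
    expect_equal(rho[1, 2],
                 bruteSpearman(methFraction(me)[1, ],
                               methFraction(me)[2, ])$rho,
                 tolerance = 1e-12)
  }
})

test_that("zero-variance sites give missing correlation, not 0", {
  f <- rbind(a = c(0.5, 0.5, 0.5, 0.5), b = c(0.1, 0.2, 0.3, 0.4))
  colnames(f) <- paste0("S", 1:4)
  rho <- siteCorrelationMatrix(makeME(f, coverage = 10L))
  expect_true(is.na(rho[1, 2]))
})

test_that("spearmanTest agrees with enumeration for all n <= 6", {
  set.seed(7)
  for (n in 4:6) {
    for (rep in 1:6) {
      x <- rnorm(n); y <- rnorm(n)
      got <- spearmanTest(x, y)
      exp <- bruteSpearman(x, y)
      expect_equal(got$rho, exp$rho, tolerance = 1e-12)
      expect_equal(got$p_value, exp$p_value, tolerance = 1e-12)
    }
  }
  # and with ties (mid-ranks), still a valid permutation test
  x <- c(1, 1, 2, 3, 4); y <- c(2, 1, 1, 3, 3)
  got <- spearmanTest(x, y)
  exp <- bruteSpearman(x, y)
  expect_equal(got$rho, exp$rho, tolerance = 1e-12)
  expect_equal(got$p_value, exp$p_value, tolerance = 1e-12)
})

test_that("spearmanTest cross-checks cor.test and is monotone-invariant", {
  set.seed(8)
  x <- rnorm(19); y <- 0.6 * x + rnorm(19)
  got <- spearmanTest(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  # monotone transforms leave rho and p unchanged
  got2 <- spearmanTest(exp(x), 1 / (1 + exp(-y)))
  expect_equal(got2$rho, got$rho, tolerance = 1e-12)
  expect_equal(got2$p_value, got$p_value, tolerance = 1e-12)
})

test_that("expression normalization scales by ACTB and class factor", {
  raw <- data.frame(
    sample_id = rep("S1", 3),
    target = c("promA", "utr3", "ACTB"),
    quantity = c(2e-4, 0.05, 1)
  )
  ne <- normalizeExpression(raw, c(promA = "first_exon", utr3 = "utr3"))
  expect_equal(ne$replicates$expression[ne$replicates$target == "promA"],
               2.0)
  expect_equal(ne$replicates$expression[ne$replicates$target == "utr3"],
               5.0)
  raw$quantity[3] <- 0
  expect_error(normalizeExpression(raw, c(promA = "first_exon",
                                          utr3 = "utr3")),
               "ACTB")
})

test_that("class scaling does not change downstream Spearman rho", {
  set.seed(9)
  n <- 8
  raw <- data.frame(
    sample_id = rep(paste0("S", 1:n), each = 2),
    target = rep(c("promA", "ACTB"), n),
    quantity = abs(rnorm(2 * n)) + 0.1
  )
  meth <- runif(n)
  e1 <- normalizeExpression(raw, c(promA = "first_exon"))
  e2 <- normalizeExpression(raw, c(promA = "utr3"))
  r1 <- spearmanTest(meth, e1$summary$mean)
  r2 <- spearmanTest(meth, e2$summary$mean)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("bhFDR matches hand step-up computation and its properties", {
  expect_equal(bhFDR(0.03), 0.03)
  # hand computation: p_(i) * m / i, cummin from the top, here all 0.04
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  p <- runif(50)
  expect_true(all(bhFDR(p) >= p))
  expect_true(all(bhFDR(p) <= 1))
  expect_error(bhFDR(c(0.5, 0)), "0, 1")
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("methylation-expression correlation finds the coupled pairs", {
  set.seed(11)
  f <- matrix(round(runif(5 * 19), 2), nrow = 5,
              dimnames = list(NULL, paste0("S", 1:19)))
  me <- makeME(f)
  sites <- rownames(methFraction(me))
  expr <- rbind(
    simulateExpression(me, couplingSpec("exA", sites[1], strength = 6,
                                        noise_sd = 0.05), seed = 3),
    simulateExpression(me, couplingSpec("exB", sites[4],
                                        direction = "positive",
                                        strength = 0, noise_sd = 0.5),
                       seed = 4)
  )
  res <- methylationExpressionCorrelation(me, expr)
  tab <- res$table
  best <- tab[order(tab$fdr), ][1, ]
  expect_equal(best$site, sites[1])
  expect_equal(best$target, "exA")
  expect_lt(best$rho, 0)
  # strictly monotone pair gives rho = -1 and the minimal p for n = 19
  expect_true(any(tab$rho[tab$site == sites[1]] <= -0.9))
  # BH column is the BH adjustment of the p column over the full family
  expect_equal(tab$fdr, bhFDR(tab$p_value))
})

test_that("perfect anti-monotone coupling yields rho -1 at n = 19", {
  f <- matrix(round(seq(0.02, 0.92, by = 0.05), 2), nrow = 1,
              dimnames = list(NULL, paste0("S", 1:19)))
  me <- makeME(f)
  e <- simulateExpression(
    me, couplingSpec("ex", rownames(methFraction(me))[1], strength = 4,
                     noise_sd = 0), seed = 1
  )
  res <- methylationExpressionCorrelation(me, e)
  expect_equal(res$table$rho, -1)
  expect_equal(res$table$n, 19L)
})

test_that("exact permutation p at n = 5 equals 120-permutation enumeration", {
  set.seed(12)
  f <- matrix(round(runif(5), 2), nrow = 1,
              dimnames = list(NULL, paste0("S", 1:5)))
  me <- makeME(f)
  e <- data.frame(target = "ex", sample_id = paste0("S", 1:5),
                  expression = rnorm(5))
  res <- methylationExpressionCorrelation(me, e)
  exp <- bruteSpearman(methFraction(me)[1, ], e$expression)
  expect_equal(res$table$p_value, exp$p_value, tolerance = 1e-12)
})

test_that("site-site and site-expression rho agree on the same vectors", {
  set.seed(13)
  f <- matrix(round(runif(3 * 10), 2), nrow = 3,
              dimnames = list(NULL, paste0("S", 1:10)))
  me <- makeME(f)
  sites <- rownames(methFraction(me))
  # feed site 2's methylation in as an "expression" target
  e <- data.frame(target = "site2", sample_id = colnames(methFraction(me)),
                  expression = methFraction(me)[2, ])
  res <- methylationExpressionCorrelation(me, e)
  rhoMat <- siteCorrelationMatrix(me)
  expect_equal(res$table$rho[res$table$site == sites[1]],
               rhoMat[1, 2], tolerance = 1e-12)
})
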
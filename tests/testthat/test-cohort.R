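# First-exon usage fractions, clustering, stratification and survival.

.toyCohort <- function(counts, time, event, ids = NULL) {
  n <- nrow(counts)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_len(n))
  df <- data.frame(tumour_id = ids, counts, check.names = FALSE)
  df$os_time <- time
  df$os_event <- event
  df
}

test_that("fractions, retention boundary and row sums", {
  counts <- data.frame(count_promA = c(6L, 5L, 3L),
                       count_promB = c(3L, 4L, 3L),
                       count_promC = c(1L, 1L, 3L))
  ch <- .toyCohort(counts, time = c(1, 2, 3), event = c(1, 1, 0))
  fx <- firstExonFractions(ch, min_reads = 10L)
  # totals are 10, 10, 9: the first two retained (boundary inclusive)
  expect_equal(nrow(fx$fractions), 2L)
  expect_equal(fx$n_excluded, 1L)
  expect_equal(unname(fx$fractions[1, ]), c(0.6, 0.3, 0.1))
  expect_equal(unname(rowSums(fx$fractions)), rep(1, 2))
})

test_that("multinomial fractions recover cluster profiles", {
  prof <- list(
    a = c(promA = 0.7, promB = 0.2, promC = 0.1),
    b = c(promA = 0.1, promB = 0.3, promC = 0.6)
  )
  sp <- cohortSimSpec(600L, prof, c(0.5, 0.5),
                      depth = list(dist = "poisson", lambda = 80),
                      hazard_by_group = c(a = 0.1, b = 0.1), seed = 3)
  ch <- simulateCohort(sp)
  fx <- firstExonFractions(ch)
  for (g in names(prof)) {
    keep <- ch$true_cluster[match(rownames(fx$fractions),
                                  ch$tumour_id)] == g
    expect_true(all(abs(colMeans(fx$fractions[keep, ]) - prof[[g]]) <
                      0.02))
  }
})

test_that("clustering separates degenerate profiles perfectly", {
  fr <- rbind(
    matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE)
  )
  colnames(fr) <- c("promA", "promB", "promC")
  rownames(fr) <- sprintf("T%02d", 1:10)
  truth <- rep(1:2, each = 5)
  cl <- clusterTumours(fr, k = 2L)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  # permuting tumour order leaves the partition unchanged
  perm <- sample(10)
  cl2 <- clusterTumours(fr[perm, ], k = 2L)
  expect_equal(mclust::adjustedRandIndex(cl$labels[perm], cl2$labels), 1)
  expect_error(clusterTumours(fr, k = 11L), "exceeds")
})

test_that("low-noise cluster structure is recovered (ARI >= 0.9)", {
  prof <- list(
    a = c(promA = 0.85, promB = 0.10, promC = 0.05),
    b = c(promA = 0.10, promB = 0.80, promC = 0.10),
    c = c(promA = 0.05, promB = 0.15, promC = 0.80)
  )
  ari <- vapply(1:20, function(s) {
    sp <- cohortSimSpec(120L, prof, rep(1 / 3, 3),
                        depth = list(dist = "poisson", lambda = 200),
                        hazard_by_group = c(a = 0.1, b = 0.1, c = 0.1),
                        seed = s)
    ch <- simulateCohort(sp)
    fx <- firstExonFractions(ch)
    cl <- clusterTumours(fx$fractions, k = 3L)
    truth <- ch$true_cluster[match(rownames(fx$fractions), ch$tumour_id)]
    mclust::adjustedRandIndex(cl$labels, truth)
  }, numeric(1))
  expect_gte(min(ari), 0.9)
})

test_that("stratification uses a strict cutoff and is monotone", {
  fr <- matrix(c(0.2, 0.1, 0.05, 0.8, 0.9, 0.95), ncol = 2,
               dimnames = list(paste0("T", 1:3), c("promA", "promB")))
  g <- stratifyTumours(fr, "promA", 0.1)
  expect_equal(as.character(g), c("high", "low", "low"))  # f == cutoff: low
  expect_error(stratifyTumours(fr, "promZ", 0.1), "unknown exon")
  expect_error(stratifyTumours(fr, "promA", 1.5), "0, 1")
  cuts <- seq(0.02, 0.9, by = 0.02)
  nHigh <- vapply(cuts, function(ct) {
    sum(stratifyTumours(fr, "promA", ct) == "high")
  }, numeric(1))
  expect_true(all(diff(nHigh) <= 0))
})

test_that("log-rank matches the hand-worked 6-subject example", {
  counts <- data.frame(count_promA = rep(10L, 6))
  ch <- .toyCohort(counts, time = 1:6, event = rep(1L, 6))
  groups <- rep(c("A", "B"), each = 3)
  km <- kmLogrank(ch, groups, endpoint = "os")
  # observed - expected worked by hand over event times 1..6:
  # t=1: E_A = 3/6,  V = 9/36
  # t=2: E_A = 2/5,  V = 6/25
  # t=3: E_A = 1/4,  V = 3/16
  # t>=4: no A subjects at risk contribute
  O <- 3; E <- 3 / 6 + 2 / 5 + 1 / 4
  V <- 9 / 36 + 6 / 25 + 3 / 16
  expect_equal(km$chisq, (O - E)^2 / V, tolerance = 1e-12)
  expect_equal(km$p_value, pchisq((O - E)^2 / V, 1, lower.tail = FALSE))
  # identical groups: chi-square 0, p 1
  ch2 <- .toyCohort(data.frame(count_promA = rep(10L, 6)),
                    time = rep(c(2, 4, 6), 2), event = rep(1L, 6))
  km2 <- kmLogrank(ch2, groups, endpoint = "os")
  expect_equal(km2$chisq, 0, tolerance = 1e-12)
  expect_equal(km2$p_value, 1)
  # all censored: explicit error
  ch3 <- .toyCohort(data.frame(count_promA = rep(10L, 6)),
                    time = 1:6, event = rep(0L, 6))
  expect_error(kmLogrank(ch3, groups), "no events")
  expect_error(kmLogrank(ch, rep("A", 6)), "2 non-empty groups")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(19)
  time <- round(rexp(40, 0.2), 3)
  ch <- .toyCohort(data.frame(count_promA = rep(10L, 40)),
                   time = time, event = rep(1L, 40))
  km <- kmLogrank(ch, rep(c("g1", "g2"), 20), endpoint = "os")
  for (g in c("g1", "g2")) {
    cv <- km$curves[km$curves$group == g, ]
    keep <- rep(c("g1", "g2"), 20) == g
    expect_equal(cv$survival, bruteKM(time[keep], rep(1L, sum(keep))),
                 tolerance = 1e-12)
    # monotone, starting from at-risk = group size
    expect_true(all(diff(cv$survival) < 1e-12))
    expect_true(all(diff(cv$n_risk) <= 0))
  }
})

test_that("Cox coefficient equals grid-search likelihood maximization", {
  set.seed(20)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- round(rexp(n, 0.1 * exp(0.7 * x)), 6)
  while (anyDuplicated(time)) time <- time + runif(n, 0, 1e-6)
  ch <- .toyCohort(data.frame(count_promA = rep(10L, n)),
                   time = time, event = rep(1L, n))
  ch$x <- x
  fit <- coxFit(ch, "x", endpoint = "os", mode = "univariable")
  expect_lt(abs(fit$coef - bruteCoxCoef(time, rep(1L, n), x)), 1e-4)
})

test_that("null covariate CIs cover HR = 1 at nominal rate", {
  cover <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 120
    x <- rbinom(n, 1, 0.5)
    evt <- rexp(n, 0.1)
    cen <- rexp(n, 0.02)
    ch <- .toyCohort(data.frame(count_promA = rep(10L, n)),
                     time = pmin(evt, cen),
                     event = as.integer(evt <= cen))
    ch$x <- x
    fit <- coxFit(ch, "x", endpoint = "os")
    fit$hr_lower <= 1 && fit$hr_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("Cox estimates are invariant to time rescaling", {
  set.seed(21)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.5 * x))
  ch <- .toyCohort(data.frame(count_promA = rep(10L, n)),
                   time = time, event = rep(1L, n))
  ch$x <- x
  f1 <- coxFit(ch, "x", endpoint = "os")
  ch$os_time <- ch$os_time * 365.25
  f2 <- coxFit(ch, "x", endpoint = "os")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("multivariable fit dichotomizes size at 20 mm", {
  set.seed(22)
  n <- 300
  ch <- .toyCohort(data.frame(count_promA = rep(20L, n)),
                   time = rexp(n, 0.1), event = rbinom(n, 1, 0.8))
  ch$lymph_node <- rbinom(n, 1, 0.4)
  ch$grade <- sample(1:3, n, replace = TRUE)
  ch$tumour_size_mm <- runif(n, 5, 50)
  fit <- coxFit(ch, c("lymph_node", "grade", "tumour_size_mm"),
                endpoint = "os", mode = "multivariable")
  expect_true(any(grepl("size_gt20", fit$term)))
  expect_false(any(grepl("tumour_size_mm", fit$term)))
  expect_equal(nrow(fit), 3L)
})
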
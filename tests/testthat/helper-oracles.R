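# Independent brute-force oracles used to check the package's statistics.
# These are deliberately naive implementations sharing no code with R/.

# all permutations of 1..n (n! x n), plain recursion
permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  out <- NULL
  sub <- permMatrix(n - 1L)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Spearman rho and exact two-sided permutation p by full enumeration
bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rhoOf <- function(a, b) {
    ac <- a - mean(a); bc <- b - mean(b)
    sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  }
  rho <- rhoOf(rx, ry)
  P <- permMatrix(length(y))
  dist <- apply(P, 1L, function(ix) rhoOf(rx, ry[ix]))
  list(rho = rho, p_value = mean(abs(dist) >= abs(rho) - 1e-12))
}

# exact two-sided Wilcoxon rank-sum p by enumerating group assignments
bruteWilcox <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  U <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  obs <- U(seq_len(m))
  combs <- utils::combn(m + n, m)
  dist <- apply(combs, 2L, U)
  p <- 2 * min(mean(dist <= obs), mean(dist >= obs))
  list(U = obs, p_value = min(p, 1))
}

# quadratic all-pairs overlap scan; intervals given 0-based half-open,
# site positions 1-based: site s overlaps [st, en) iff st < s <= en
bruteOverlapCount <- function(pos, start0, end0) {
  vapply(pos, function(s) sum(start0 < s & s <= end0), numeric(1L))
}

# Efron = Breslow partial log-likelihood for untied event times,
# single covariate; maximized by golden-ratio-free grid + optimize
coxPartialLoglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

bruteCoxCoef <- function(time, event, x) {
  stats::optimize(function(b) coxPartialLoglik(b, time, event, x),
                  interval = c(-6, 6), maximum = TRUE,
                  tol = 1e-8)$maximum
}

# Kaplan-Meier product-limit estimate with no grouping (naive)
bruteKM <- function(time, event) {
  ut <- sort(unique(time[event == 1L]))
  s <- 1
  vapply(ut, function(t) {
    d <- sum(time == t & event == 1L)
    r <- sum(time >= t)
    s <<- s * (1 - d / r)
    s
  }, numeric(1L))
}
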
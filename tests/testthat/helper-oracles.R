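# Independent brute-force oracles used to cross-check package statistics.

# Benjamini-Hochberg step-up: q_i = min_{j: p_j >= p_i ranked} min(1, m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Lin's CCC from raw sums, population moments.
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# One-way ANOVA ICC from explicit sums, with the unbalanced k0.
icc_oracle <- function(subject, y) {
  subject <- as.character(subject)
  groups <- split(y, subject)
  a <- length(groups)
  n <- length(y)
  gbar <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gbar)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  k0 <- (n - sum(vapply(groups, length, 0L)^2) / n) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# Adjusted Rand index from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small metadata + panel fixture with an HV cohort only.
hv_fixture <- function(n = 40, p = 5, seed = 1) {
  set.seed(seed)
  md <- data.frame(
    sample_id = sprintf("S%03d", 1:n), subject_id = sprintf("P%03d", 1:n),
    cohort = "HV", subtype = "HV", age = runif(n, 20, 70),
    sex = rep(c("F", "M"), length.out = n), visit_index = 1L,
    stringsAsFactors = FALSE)
  md$sex_f <- as.numeric(md$sex == "F")
  panel <- matrix(rnorm(n * p, 8, 0.3), n, p,
                  dimnames = list(md$sample_id, sprintf("APT%04d", 1:p)))
  list(panel = panel, metadata = md)
}
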
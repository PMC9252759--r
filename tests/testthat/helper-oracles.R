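# Independent oracles used across the suite.  Each is a direct transcription
# of the defining formula, kept deliberately separate from the package code
# paths it checks.

# tie-free Spearman: 1 - 6 * sum(d^2) / (n (n^2 - 1))
oracle_spearman_tiefree <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# direct DCG-based nDCG for one predicted ordering (indices into obs)
oracle_ndcg_order <- function(obs, ord, k = length(obs)) {
  rel <- if (min(obs) < 0) obs - min(obs) else obs
  disc <- 1 / log2(seq_len(k) + 1)
  sum(rel[ord][seq_len(k)] * disc) / sum(sort(rel, decreasing = TRUE)[seq_len(k)] * disc)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# closed-form OLS via the normal equations
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# direct numerical maximization of the fractional/binary logit quasi-likelihood
oracle_logit_ml <- function(X, y) {
  X1 <- cbind(1, X)
  nll <- function(beta) {
    mu <- plogis(drop(X1 %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  optim(numeric(ncol(X1)), nll, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-14))$par
}

# Tukey boxplot statistics from first principles (type-7 quantiles)
oracle_boxplot <- function(v) {
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
  list(q25 = q[1], median = q[2], q75 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]))
}

# Wallace-rule melting temperature of a segment, transcribed directly
oracle_wallace <- function(segment) {
  chars <- strsplit(segment, "")[[1]]
  at <- sum(chars %in% c("A", "T"))
  gc <- sum(chars %in% c("G", "C"))
  2 * at + 4 * gc
}

# a valid 30-mer with a chosen protospacer (positions 5-24); PAM fixed to AGG
make_target <- function(protospacer, context = "ACGT", pam = "AGG", down = "ACG") {
  stopifnot(nchar(protospacer) == 20)
  paste0(context, protospacer, pam, down)
}

# small named schema over the five default ground-truth features
small_schema <- function() default_truth("fractional")$schema
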
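# Independent oracles and small fixture builders shared across tests.
# Each oracle is a direct, brute-force or closed-form computation kept
# deliberately separate from the package's own code paths.

# Closed-form ordinary regression of y on standardized x with a
# normal-theory Wald p, the single-variance-component limit of the
# mixed model.
ols_oracle <- function(y, x) {
  xs <- (x - mean(x)) / sd(x)
  X <- cbind(1, xs)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  rss <- sum((y - X %*% b)^2)
  s2 <- rss / (length(y) - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  z <- b[2] / se
  list(beta = b[2], se = se, p = 2 * pnorm(-abs(z)))
}

# Step-up BH oracle computed from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive two-sided Spearman permutation p for tiny n (recursive
# enumeration, rank-formula rho; independent of the package internals).
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  count <- 0L; total <- 0L
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(cor(rx, acc)) >= abs(obs) - 1e-12) count <<- count + 1L
      return(invisible())
    }
    for (i in seq_along(remaining))
      recurse(remaining[-i], c(acc, remaining[i]))
  }
  recurse(ry, numeric(0))
  count / total
}

# One-way fixed-effects ANOVA from raw sums of squares.
anova_oracle <- function(v, g) {
  g <- factor(g)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Exhaustive hypergeometric upper-tail p over all draws of the universe.
hyper_enum_oracle <- function(k, K, N, n) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Random bait/replicate presence tensor as a record data frame plus the
# logical truth array, for set-logic cross-checks.
random_presence_tensor <- function(n_prot = 8, baits = LETTERS[1:6],
                                   n_rep = 3, p_present = 0.3) {
  proteins <- sprintf("P%02d", seq_len(n_prot))
  arr <- array(runif(n_prot * length(baits) * n_rep) < p_present,
               dim = c(n_prot, length(baits), n_rep),
               dimnames = list(proteins, baits, NULL))
  rows <- list()
  for (p in seq_len(n_prot)) for (b in seq_along(baits)) for (r in seq_len(n_rep)) {
    present <- arr[p, b, r]
    rows[[length(rows) + 1L]] <- data.frame(
      protein = proteins[p], bait = baits[b], replicate = r,
      protein_probability = if (present) 0.999 else 0.5,
      peptide_probs = if (present) "0.99;0.99;0.98" else "0.99",
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), truth = arr)
}

# Direct set-logic oracle on the truth array.
specific_prey_oracle <- function(arr, required, min_required, forbidden) {
  proteins <- dimnames(arr)[[1]]
  keep <- vapply(proteins, function(p) {
    hits <- sum(vapply(required, function(b) any(arr[p, b, ]), logical(1)))
    banned <- any(vapply(forbidden, function(b) any(arr[p, b, ]), logical(1)))
    hits >= min_required && !banned
  }, logical(1))
  sort(proteins[keep])
}

# Kinship built from a random doubly standardized expression matrix.
random_kinship <- function(n_samples, n_genes = 5 * n_samples) {
  M <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  colnames(M) <- sprintf("S%03d", seq_len(n_samples))
  sample_kinship(iterative_standardize(M))
}

# Draw y = x*beta + u + e with u ~ N(0, sigma_g2 K) given a precomputed
# Cholesky-like factor of K.
draw_mixed <- function(x, beta, Lk, sigma_g2, sigma_e2) {
  n <- length(x)
  u <- sqrt(sigma_g2) * drop(Lk %*% rnorm(n))
  x * beta + u + rnorm(n, 0, sqrt(sigma_e2))
}

kinship_factor <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}
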
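# Mixed-model differential expression with expression-derived kinship.
#
# Model per gene: y = mu + x * beta + u + eps, u ~ N(0, sigma_g2 * K),
# eps ~ N(0, sigma_e2 * I), where K is the sample-sample covariance of the
# doubly standardized expression matrix. The variance ratio
# delta = sigma_e2 / sigma_g2 is profiled on the eigenbasis of K (one
# rotation shared by all genes), grid-then-Brent in log delta.

#' Iterative row/column standardization
#'
#' Alternates column z-scoring and row z-scoring until every row and
#' column simultaneously has mean below `tol` in absolute value and
#' variance within `10 * tol` of 1. Population variance (denominator `n`)
#' is used throughout: with the `n - 1` convention the two margin
#' constraints are mutually inconsistent for non-square matrices (the
#' total sum of squares would have to equal both `p(n-1)` and `n(p-1)`),
#' whereas with the population convention both equal `n * p` and the
#' alternation converges. This "doubly standardized" form puts genes and
#' samples on a common scale and is the input from which the sample
#' kinship is computed.
#'
#' @param M numeric matrix (genes x samples), at least 2 x 2, with no
#'   constant row or column.
#' @param tol convergence tolerance on margin means (variances use
#'   `10 * tol`).
#' @param max_iter maximum sweeps before failing with the worst margin.
#' @return matrix of the same dimensions with attribute `iterations`.
#' @export
iterative_standardize <- function(M, tol = 1e-6, max_iter = 100) {
  M <- as.matrix(M)
  if (nrow(M) < 2 || ncol(M) < 2) stop_input("need at least a 2 x 2 matrix")
  if (anyNA(M)) stop_input("matrix contains missing values")
  row_sd <- apply(M, 1, stats::sd)
  col_sd <- apply(M, 2, stats::sd)
  if (any(row_sd == 0) || any(col_sd == 0))
    stop_input("constant row or column: matrix cannot be doubly standardized")
  for (it in 0:max_iter) {
    stats <- margin_stats(M)
    if (stats$max_mean < tol && stats$max_var_dev < 10 * tol) {
      attr(M, "iterations") <- it
      attr(M, "state") <- "doubly_standardized"
      return(M)
    }
    if (it == max_iter)
      stop_input("iterative standardization did not converge in ", max_iter,
                 " sweeps; worst margin: ", stats$worst)
    M <- pop_scale_cols(M)             # columns: mean 0, population var 1
    M <- t(pop_scale_cols(t(M)))       # rows: mean 0, population var 1
  }
}

pop_scale_cols <- function(M) {
  ctr <- sweep(M, 2, colMeans(M))
  sweep(ctr, 2, sqrt(colMeans(ctr^2)), `/`)
}

pop_var_rows <- function(M) rowMeans((M - rowMeans(M))^2)

margin_stats <- function(M) {
  rm_ <- rowMeans(M); cm <- colMeans(M)
  rv <- pop_var_rows(M); cv <- pop_var_rows(t(M))
  devs <- c(row_mean = max(abs(rm_)), col_mean = max(abs(cm)),
            row_var = max(abs(rv - 1)), col_var = max(abs(cv - 1)))
  worst_mean <- which.max(c(devs["row_mean"], devs["col_mean"]))
  list(max_mean = max(devs["row_mean"], devs["col_mean"]),
       max_var_dev = max(devs["row_var"], devs["col_var"]),
       worst = names(devs)[which.max(devs)])
}

#' Rank-based inverse normal transform
#'
#' Maps a response to standard-normal quantiles through its ranks,
#' `qnorm((r - 0.5) / n)` with average ranks for ties, so that the
#' normality assumption of the mixed model holds for skewed assay
#' readouts such as propionate-incorporation activity.
#'
#' @param y numeric vector with at least 3 finite values; `NA`s are
#'   preserved in place.
#' @return transformed vector, mean approximately 0 and symmetric.
#' @export
rank_inverse_normal <- function(y) {
  ok <- is.finite(y)
  if (sum(ok) < 3) stop_input("need at least 3 finite values")
  v <- y[ok]
  if (max(v) == min(v)) stop_input("all values identical; transform undefined")
  r <- rank(v, ties.method = "average")
  out <- y
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}

#' Sample kinship from a doubly standardized expression matrix
#'
#' `K = M'M / p` over `p` genes: the sample-sample covariance structure of
#' the normalized expression data, used as the random-effect covariance.
#' The eigendecomposition is computed once and cached for reuse across a
#' genome-wide scan.
#'
#' @param M doubly standardized genes x samples matrix (see
#'   [iterative_standardize()]).
#' @return object of class `kinship`: list with `K`, eigenvalues `values`
#'   (floored at 0 within numerical tolerance) and eigenvectors `vectors`.
#' @export
sample_kinship <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop_input("need at least 2 genes")
  K <- crossprod(M) / nrow(M)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop_input("kinship is not positive semi-definite")
  e$values <- pmax(e$values, 0)
  structure(list(K = K, values = e$values, vectors = e$vectors,
                 samples = colnames(M)),
            class = "kinship")
}

as_kinship <- function(K) {
  if (inherits(K, "kinship")) return(K)
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8) stop_input("kinship matrix must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop_input("kinship is not positive semi-definite")
  e$values <- pmax(e$values, 0)
  structure(list(K = K, values = e$values, vectors = e$vectors,
                 samples = colnames(K)),
            class = "kinship")
}

# Profile restricted (or full) log-likelihood of delta on the eigenbasis.
# yt, Wt: rotated response and fixed-effect design; lam: eigenvalues.
reml_profile <- function(delta, yt, Wt, lam, reml = TRUE) {
  n <- length(yt); q <- ncol(Wt)
  d <- lam + delta
  w <- 1 / d
  A <- crossprod(Wt, Wt * w)
  b <- solve(A, crossprod(Wt, yt * w))
  r <- yt - Wt %*% b
  R <- sum(w * r^2)
  df <- if (reml) n - q else n
  ll <- -0.5 * (df * log(2 * pi) + df + df * log(R / df) + sum(log(d)))
  if (reml) ll <- ll - 0.5 * determinant(A, logarithm = TRUE)$modulus[1]
  list(ll = as.numeric(ll), beta = b, R = R, A = A, delta = delta)
}

#' Fit the mixed model for one gene
#'
#' Profiles the variance ratio `delta = sigma_e2 / sigma_g2` on the
#' eigenbasis of the kinship (rotate once, 41-point grid in
#' `log delta` over `[-10, 10]` refined by Brent's method), then reports
#' the fixed-effect slope of `x`, its standard error, and a two-sided Wald
#' p-value. REML is the default criterion for the variance profile;
#' maximum likelihood is available via `reml = FALSE`. Deterministic for
#' fixed inputs.
#'
#' @param y response vector (typically rank-inverse-normalized).
#' @param x gene expression vector used as the fixed effect; standardized
#'   internally when `standardize_x` so slopes are on an effect-size scale.
#' @param K [sample_kinship()] object or a PSD matrix.
#' @param reml profile the restricted likelihood (default) or ML.
#' @param standardize_x z-score `x` before fitting (default TRUE).
#' @return object of class `lmm_fit`: list with `beta`, `se`, `p`,
#'   `delta`, `sigma_g2`, `sigma_e2`, `loglik`, `at_bound` (TRUE when the
#'   optimizer settled at a grid boundary) and `n`.
#' @export
lmm_fit_one <- function(y, x, K, reml = TRUE, standardize_x = TRUE) {
  K <- as_kinship(K)
  n <- length(y)
  if (n < 5) stop_input("need at least 5 samples")
  if (length(x) != n || nrow(K$K) != n)
    stop_input("y, x and K must be conformable")
  if (standardize_x) x <- zscore(x)
  U <- K$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, cbind(intercept = 1, x = x))
  fit <- profile_delta(yt, Wt, K$values, reml = reml)
  finish_lmm_fit(fit, n, q = 2L, coef_index = 2L, reml = reml)
}

profile_delta <- function(yt, Wt, lam, reml = TRUE,
                          log_bounds = c(-10, 10), n_grid = 41L) {
  grid <- seq(log_bounds[1], log_bounds[2], length.out = n_grid)
  ll <- vapply(grid, function(g)
    reml_profile(exp(g), yt, Wt, lam, reml)$ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(g) reml_profile(exp(g), yt, Wt, lam, reml)$ll,
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  best_log <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  out <- reml_profile(exp(best_log), yt, Wt, lam, reml)
  out$at_bound <- i %in% c(1L, n_grid) &&
    abs(best_log - grid[i]) < diff(grid[1:2]) / 2
  out
}

finish_lmm_fit <- function(fit, n, q, coef_index, reml) {
  df <- if (reml) n - q else n
  sigma_g2 <- fit$R / df
  sigma_e2 <- fit$delta * sigma_g2
  cov_b <- sigma_g2 * solve(fit$A)
  beta <- fit$beta[coef_index]
  se <- sqrt(cov_b[coef_index, coef_index])
  z <- beta / se
  structure(list(beta = unname(beta), se = unname(se),
                 p = 2 * stats::pnorm(-abs(z)),
                 delta = fit$delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 loglik = fit$ll, at_bound = isTRUE(fit$at_bound), n = n),
            class = "lmm_fit")
}

#' Per-gene mixed-model scan
#'
#' Runs [lmm_fit_one()] for every gene of an expression matrix against one
#' response, reusing a single eigendecomposition of the kinship. Sample
#' identity between `y`, `X` and `K` is verified by name when names are
#' available, never by position alone.
#'
#' @param y named response vector.
#' @param X genes x samples expression matrix; each gene row is
#'   standardized before use as the fixed effect.
#' @param K kinship object (or matrix) on the same samples.
#' @param reml passed to the per-gene fits.
#' @param sort sort output by p-value (default TRUE).
#' @return data frame with one row per gene: `gene`, `beta`, `se`, `p`,
#'   `delta`, `sigma_g2`, `sigma_e2`, `neg_log10_p`, plus attribute
#'   `lambda_gc`, the genomic inflation factor of the scan.
#' @export
lmm_scan <- function(y, X, K, reml = TRUE, sort = TRUE) {
  X <- as.matrix(X)
  K <- as_kinship(K)
  if (!is.null(names(y)) && !is.null(colnames(X))) {
    if (!identical(names(y), colnames(X))) {
      bad <- union(setdiff(names(y), colnames(X)),
                   setdiff(colnames(X), names(y)))
      if (length(bad))
        stop_input("sample identifiers differ between response and ",
                   "expression: ", paste(utils::head(bad, 5), collapse = ", "))
      X <- X[, names(y), drop = FALSE]
    }
  }
  if (!is.null(K$samples) && !is.null(colnames(X)) &&
      !identical(K$samples, colnames(X)))
    stop_input("sample identifiers differ between kinship and expression")
  n <- length(y)
  U <- K$vectors
  yt <- drop(crossprod(U, y))
  ones_t <- drop(crossprod(U, rep(1, n)))
  Xs <- t(apply(X, 1, zscore))
  Xt <- Xs %*% U                       # each row is the rotated gene vector
  fits <- lapply(seq_len(nrow(X)), function(i) {
    Wt <- cbind(intercept = ones_t, x = Xt[i, ])
    f <- profile_delta(yt, Wt, K$values, reml = reml)
    finish_lmm_fit(f, n, q = 2L, coef_index = 2L, reml = reml)
  })
  out <- data.frame(
    gene = rownames(X) %||% paste0("gene", seq_len(nrow(X))),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    delta = vapply(fits, `[[`, numeric(1), "delta"),
    sigma_g2 = vapply(fits, `[[`, numeric(1), "sigma_g2"),
    sigma_e2 = vapply(fits, `[[`, numeric(1), "sigma_e2"),
    stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p)
  if (sort) out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "lambda_gc") <- genomic_inflation(out$p)
  out
}

#' Genomic inflation factor of a p-value set
#'
#' Median chi-square statistic of the observed p-values divided by the
#' median of the null chi-square(1) distribution; ~1 for a calibrated scan.
#'
#' @param p vector of p-values.
#' @return scalar inflation factor.
#' @export
genomic_inflation <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Restrict scan results to a gene set
#'
#' Subsets mixed-model fits to genes in a set (e.g. mitochondrially
#' localized enzymes), preserving order; warns on an empty intersection.
#'
#' @param fits data frame from [lmm_scan()].
#' @param gene_set character vector of gene identifiers.
#' @return the matching rows of `fits`.
#' @export
mito_filter <- function(fits, gene_set) {
  if (length(gene_set) == 0) stop_input("gene_set must be non-empty")
  out <- fits[fits$gene %in% gene_set, , drop = FALSE]
  if (nrow(out) == 0) warning("no scan gene found in the gene set")
  rownames(out) <- NULL
  out
}

#' Mixed-model prediction with BLUP random effects
#'
#' Fits `y = X b + u + eps` with `u ~ N(0, sigma_g2 K)`, estimating the
#' variance ratio by REML, then returns per-sample predictions
#' `X b + BLUP(u)` and the sample ranking by predicted response. With the
#' random-effect variance forced to zero (`delta_override = Inf`) the
#' prediction reduces to the ordinary least-squares fixed-effect fit; with
#' `K = I` and an intercept-only design the BLUP shrinks centered `y`
#' toward the mean by `sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param y response vector.
#' @param fixed matrix of covariate columns (an intercept is added).
#' @param K kinship object or PSD matrix.
#' @param delta_override optional fixed variance ratio (use `Inf` for the
#'   pure fixed-effect limit).
#' @param reml REML (default) or ML variance profile.
#' @return list with `prediction` (named per-sample), `ranking` (sample
#'   indices sorted by decreasing prediction), `beta`, `delta`,
#'   `sigma_g2`, `sigma_e2`.
#' @export
predict_blup <- function(y, fixed = NULL, K, delta_override = NULL,
                         reml = TRUE) {
  K <- as_kinship(K)
  n <- length(y)
  W <- cbind(intercept = rep(1, n), fixed)
  if (qr(W)$rank < ncol(W)) stop_input("singular fixed-effect design")
  U <- K$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  if (is.null(delta_override)) {
    fit <- profile_delta(yt, Wt, K$values, reml = reml)
  } else if (is.infinite(delta_override)) {
    b <- solve(crossprod(W), crossprod(W, y))
    pred <- drop(W %*% b)
    names(pred) <- names(y) %||% K$samples
    return(list(prediction = pred, ranking = order(pred, decreasing = TRUE),
                beta = drop(b), delta = Inf, sigma_g2 = 0,
                sigma_e2 = sum((y - pred)^2) / (n - ncol(W))))
  } else {
    fit <- reml_profile(delta_override, yt, Wt, K$values, reml)
  }
  df <- if (reml) n - ncol(W) else n
  sigma_g2 <- fit$R / df
  sigma_e2 <- fit$delta * sigma_g2
  resid_t <- yt - Wt %*% fit$beta
  u_t <- (K$values / (K$values + fit$delta)) * drop(resid_t)
  u <- drop(U %*% u_t)
  pred <- drop(W %*% fit$beta) + u
  names(pred) <- names(y) %||% K$samples
  list(prediction = pred, ranking = order(pred, decreasing = TRUE),
       beta = drop(fit$beta), delta = fit$delta,
       sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
}
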
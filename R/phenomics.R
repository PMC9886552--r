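# Phenomics: clinical severity score, mixed-type correlation matrix, and
# the phenome-wide linear-model screen ranking surrogate severity markers.

#' Clinical severity score (CSS)
#'
#' Sums five binary clinical indicators of methylmalonic aciduria severity:
#' early disease onset, neurological abnormalities, kidney impairment,
#' hematological abnormalities and failure to thrive. The score runs from 0
#' (none of the typical features) to 5 (all five present). Missing
#' components contribute 0 to the sum; a completeness count is attached so
#' downstream users can weigh partially scored individuals.
#'
#' @param components data frame with columns `early_onset`,
#'   `neurological_abnormalities`, `kidney_impairment`,
#'   `hematological_abnormalities`, `failure_to_thrive`, each coded
#'   0/1/`NA`, one row per individual.
#' @return integer vector of scores in `[0, 5]` with attribute
#'   `n_observed`, the number of non-missing components per individual.
#' @examples
#' compute_css(data.frame(early_onset = 1, neurological_abnormalities = 1,
#'   kidney_impairment = 0, hematological_abnormalities = 0,
#'   failure_to_thrive = 0))
#' @export
compute_css <- function(components) {
  comp_names <- c("early_onset", "neurological_abnormalities",
                  "kidney_impairment", "hematological_abnormalities",
                  "failure_to_thrive")
  if (!is.data.frame(components)) components <- as.data.frame(components)
  missing_cols <- setdiff(comp_names, names(components))
  if (length(missing_cols))
    stop_input("missing CSS components: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(components[comp_names])
  if (!all(m %in% c(0, 1, NA)))
    stop_input("CSS components must be coded 0/1/NA")
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0))
    stop_input("all CSS components missing for individual(s): ",
               paste(which(n_obs == 0), collapse = ", "))
  score <- as.integer(rowSums(m, na.rm = TRUE))
  attr(score, "n_observed") <- as.integer(n_obs)
  score
}

#' Binarize age at disease onset into the early-onset CSS component
#'
#' Neonatal presentation is the classic severe form; onset at or before
#' `threshold_days` (default 28, the neonatal period) is scored 1.
#'
#' @param onset_days numeric vector of onset ages in days; `NA` preserved.
#' @param threshold_days cutoff in days, inclusive.
#' @return 0/1/`NA` vector usable as the `early_onset` CSS component.
#' @export
early_onset_flag <- function(onset_days, threshold_days = 28) {
  ifelse(is.na(onset_days), NA_real_,
         as.numeric(onset_days <= threshold_days))
}

#' Mixed-type phenotype correlation matrix
#'
#' Spearman rank correlation between every pair of phenotype variables on
#' pairwise-complete observations. A single rank-based estimator is used
#' for all type combinations (for two binary variables it equals a
#' rank phi coefficient), giving one coherent matrix across continuous and
#' discrete traits. Cells with fewer than `min_pairs` complete pairs, or
#' involving a variable constant on the complete pairs, are `NA` (a warning
#' lists constant variables).
#'
#' @param table phenotype data frame; non-numeric columns and an
#'   `individual_id` column are ignored.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, min_pairs = 3) {
  vars <- phenotype_variables(table)
  p <- length(vars)
  if (p < 2) stop_input("need at least two numeric phenotype variables")
  m <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(m) <- 1
  constant_seen <- character(0)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      x <- table[[vars[i]]]
      y <- table[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_pairs) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        constant_seen <- union(constant_seen,
                               vars[c(i, j)][c(stats::sd(x[ok]) == 0,
                                               stats::sd(y[ok]) == 0)])
        next
      }
      m[i, j] <- m[j, i] <- stats::cor(x[ok], y[ok], method = "spearman")
    }
  }
  if (length(constant_seen))
    warning("constant variable(s) in pairwise-complete cells: ",
            paste(constant_seen, collapse = ", "))
  m
}

#' Phenome-wide association screen against a target variable
#'
#' Regresses every other phenotype variable on the target, one at a time,
#' replicating a surrogate-marker screen: strictly positive continuous
#' variables are log-transformed (`log(x + 1)` with a warning when zeros or
#' negatives are present), both sides are z-standardized, and an ordinary
#' least-squares slope with its two-sided p-value is recorded. P-values are
#' Benjamini-Hochberg adjusted across the screened set and results are
#' returned sorted by adjusted p. Because both sides are standardized the
#' effect size (ES) is a standardized slope, comparable across variables.
#'
#' @param table phenotype data frame.
#' @param target name of the target variable (e.g. `"PI_plus"` or `"CSS"`).
#' @param alpha significance level on adjusted p, recorded in the output
#'   attribute `n_significant`.
#' @param min_pairs variables with fewer complete pairs are skipped.
#' @return data frame with columns `variable`, `ES`, `p`, `p_adj`,
#'   `n_used`, sorted by `p_adj`; skipped variables in attribute `skipped`.
#' @export
association_screen <- function(table, target, alpha = 0.05, min_pairs = 3) {
  stopifnot(alpha > 0, alpha < 1)
  vars <- phenotype_variables(table)
  if (!target %in% vars) stop_input("target variable not found: ", target)
  tvals <- table[[target]]
  if (stats::sd(tvals, na.rm = TRUE) %in% c(0, NA))
    stop_input("target variable is constant")
  others <- setdiff(vars, target)
  skipped <- character(0)
  log1p_used <- character(0)
  transform_noting <- function(x, name) {
    if (!is_binary01(x) && min(x) <= 0) log1p_used <<- union(log1p_used, name)
    screen_transform(x, name)
  }
  rows <- lapply(others, function(v) {
    x <- table[[v]]
    ok <- is.finite(x) & is.finite(tvals)
    n <- sum(ok)
    if (n < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(tvals[ok]) == 0) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    xv <- transform_noting(x[ok], v)
    yv <- transform_noting(tvals[ok], target)
    fit <- stats::lm(xv ~ yv)
    sm <- summary(fit)$coefficients
    data.frame(variable = v, ES = unname(sm["yv", "Estimate"]),
               p = unname(sm["yv", "Pr(>|t|)"]), n_used = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_input("no variable had enough complete pairs")
  if (length(log1p_used))
    warning("non-positive values; used log1p for: ",
            paste(utils::head(log1p_used, 5), collapse = ", "),
            if (length(log1p_used) > 5) ", ...", call. = FALSE)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p_adj, res$p), c("variable", "ES", "p", "p_adj", "n_used")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "alpha") <- alpha
  attr(res, "n_significant") <- count_significant(res, alpha)
  res
}

# log then z-standardize; binary variables are standardized without log,
# variables with non-positive values fall back to log1p (warned about
# once per screen by the caller)
screen_transform <- function(x, name) {
  if (!is_binary01(x)) {
    x <- if (min(x) > 0) log(x) else log1p(pmax(x, -0.999))
  }
  zscore(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in input
#' order. Delegates to [stats::p.adjust()] after range validation.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_input("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(pvalues, method = "BH")
}

#' Count significant screen results
#'
#' @param results output of [association_screen()].
#' @param alpha threshold on the adjusted p-value.
#' @return number of variables with `p_adj < alpha`.
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) return(0L)
  sum(results$p_adj < alpha)
}

# numeric phenotype columns, excluding identifiers
phenotype_variables <- function(table) {
  vars <- names(table)[vapply(table, is.numeric, logical(1))]
  setdiff(vars, c("individual_id", "sample_id"))
}
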
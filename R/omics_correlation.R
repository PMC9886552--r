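# Transcript-protein and protein-protein correlation analyses, including
# the genotype-difference diagonal-distance statistic.

# Spearman rho with a two-sided p-value: exact permutation over all n!
# orderings for n <= exact_n, t-approximation otherwise.
spearman_test <- function(x, y, exact_n = 9L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= exact_n) {
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    null_rho <- as.vector(stats::cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Per-gene, per-group transcript-protein Spearman correlation
#'
#' For every gene present in both layers, Spearman correlation of
#' transcript against protein across the samples of each group, with a
#' two-sided p-value (exact permutation when a group has 9 or fewer
#' samples, t-approximation otherwise). Genes missing from either layer
#' are skipped and listed in attribute `skipped`.
#'
#' @param rna,protein genes x samples matrices with shared identifiers.
#' @param groups named character vector or factor mapping sample to group.
#' @param min_n groups with fewer samples are not scored (default 4).
#' @return data frame `gene`, `group`, `rho`, `p`, `n`.
#' @export
paired_spearman <- function(rna, protein, groups, min_n = 4) {
  shared <- match_layers(rna, protein)
  groups <- groups[shared$samples]
  rows <- list()
  for (g in unique(as.character(groups))) {
    idx <- which(as.character(groups) == g)
    if (length(idx) < min_n) next
    for (gene in shared$genes) {
      st <- spearman_test(shared$rna[gene, idx], shared$protein[gene, idx])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = g, rho = st$rho, p = st$p, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- shared$skipped
  out
}

match_layers <- function(rna, protein) {
  rna <- as.matrix(rna); protein <- as.matrix(protein)
  samples <- intersect(colnames(rna), colnames(protein))
  genes <- intersect(rownames(rna), rownames(protein))
  skipped <- union(setdiff(rownames(rna), genes),
                   setdiff(rownames(protein), genes))
  list(rna = rna[genes, samples, drop = FALSE],
       protein = protein[genes, samples, drop = FALSE],
       genes = genes, samples = samples, skipped = skipped)
}

#' Gene-level and sample-level cross-layer correlation summary
#'
#' Gene-level: per shared gene, Spearman rho of transcript versus protein
#' across all shared samples. Sample-level: per sample, Spearman rho
#' across all shared genes. Reports both vectors and their medians - the
#' two headline numbers of a proteogenomic concordance analysis.
#'
#' @param rna,protein genes x samples matrices.
#' @return list `gene_level` (named rho vector), `sample_level` (named rho
#'   vector), `median_gene`, `median_sample`, `n_pairs`, `n_samples`.
#' @export
cross_level_summary <- function(rna, protein) {
  shared <- match_layers(rna, protein)
  if (length(shared$genes) < 10) stop_input("fewer than 10 shared genes")
  gene_level <- vapply(shared$genes, function(g)
    stats::cor(shared$rna[g, ], shared$protein[g, ], method = "spearman"),
    numeric(1))
  sample_level <- vapply(shared$samples, function(s)
    stats::cor(shared$rna[, s], shared$protein[, s], method = "spearman"),
    numeric(1))
  list(gene_level = gene_level, sample_level = sample_level,
       median_gene = stats::median(gene_level, na.rm = TRUE),
       median_sample = stats::median(sample_level, na.rm = TRUE),
       n_pairs = length(shared$genes), n_samples = length(shared$samples))
}

#' Diagonal distance between group correlations
#'
#' Signed Euclidean distance of a (case, control) correlation pair from
#' the equal-correlation diagonal: `d = (rho_def - rho_ctrl) / sqrt(2)`.
#' Positive values mean the gene correlates more strongly in the
#' MMUT-deficient group than in controls.
#'
#' @param rho_def,rho_ctrl correlations in `[-1, 1]` (vectorized).
#' @return numeric distance(s).
#' @export
diagonal_distance <- function(rho_def, rho_ctrl) {
  if (any(!is.finite(rho_def)) || any(!is.finite(rho_ctrl)) ||
      any(abs(rho_def) > 1) || any(abs(rho_ctrl) > 1))
    stop_input("correlations must be finite and in [-1, 1]")
  (rho_def - rho_ctrl) / sqrt(2)
}

#' Two-sided test for a difference between two correlations
#'
#' Fisher z-transforms both correlations and compares them with the
#' normal statistic `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param rho1,rho2 correlations with `|rho| < 1`.
#' @param n1,n2 sample sizes (>= 4).
#' @return two-sided p-value.
#' @export
correlation_difference_test <- function(rho1, n1, rho2, n2) {
  if (any(n1 < 4) || any(n2 < 4)) stop_input("need n >= 4 per group")
  if (any(abs(rho1) >= 1) || any(abs(rho2) >= 1))
    stop_input("|rho| = 1 gives an infinite Fisher z; test undefined")
  z1 <- atanh(rho1); z2 <- atanh(rho2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Per-gene paired correlation table with diagonal distance
#'
#' Convenience wrapper producing, per shared gene, the transcript-protein
#' Spearman correlation in a case and a control group, the diagonal
#' distance, and two-sided p-values (per-group and for the difference).
#' Genes are retained only when both groups have at least `min_n` samples.
#'
#' @param rna,protein genes x samples matrices.
#' @param groups named sample-to-group mapping.
#' @param def_group,ctrl_group group labels to contrast.
#' @param min_n minimum samples per group.
#' @return data frame `gene`, `rho_def`, `rho_ctrl`, `d`, `p_def`,
#'   `p_ctrl`, `p_diff`, `n_def`, `n_ctrl`.
#' @export
paired_correlation_table <- function(rna, protein, groups,
                                     def_group = "MMUT-deficient",
                                     ctrl_group = "control", min_n = 4) {
  shared <- match_layers(rna, protein)
  groups <- as.character(groups[shared$samples])
  idx_def <- which(groups == def_group)
  idx_ctrl <- which(groups == ctrl_group)
  if (length(idx_def) < min_n || length(idx_ctrl) < min_n)
    stop_input("each group needs at least ", min_n, " samples")
  rows <- lapply(shared$genes, function(g) {
    sd_ <- spearman_test(shared$rna[g, idx_def], shared$protein[g, idx_def])
    sc <- spearman_test(shared$rna[g, idx_ctrl], shared$protein[g, idx_ctrl])
    if (is.na(sd_$rho) || is.na(sc$rho)) return(NULL)
    p_diff <- if (abs(sd_$rho) < 1 && abs(sc$rho) < 1)
      correlation_difference_test(sd_$rho, sd_$n, sc$rho, sc$n) else NA_real_
    data.frame(gene = g, rho_def = sd_$rho, rho_ctrl = sc$rho,
               d = diagonal_distance(sd_$rho, sc$rho),
               p_def = sd_$p, p_ctrl = sc$p, p_diff = p_diff,
               n_def = sd_$n, n_ctrl = sc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Anchor-protein correlation against partner proteins
#'
#' Spearman correlation (with p, same machinery as [paired_spearman()]) of
#' one anchor protein against each partner protein, within each sample
#' group - the analysis behind contrasting, e.g., MMUT against TCA-cycle
#' enzymes versus their cytosolic isoforms in cases and controls.
#'
#' @param protein genes x samples matrix.
#' @param anchor anchor gene name (must be present).
#' @param partners character vector of partner genes; missing partners are
#'   skipped and listed in attribute `skipped`.
#' @param groups named sample-to-group mapping.
#' @param min_n minimum samples per group.
#' @return data frame `partner`, `group`, `rho`, `p`, `n`.
#' @export
protein_pair_correlation <- function(protein, anchor, partners, groups,
                                     min_n = 4) {
  protein <- as.matrix(protein)
  if (!anchor %in% rownames(protein))
    stop_input("anchor protein not found: ", anchor)
  present <- intersect(partners, rownames(protein))
  skipped <- setdiff(partners, present)
  groups <- as.character(groups[colnames(protein)])
  rows <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_n) next
    for (p in present) {
      st <- spearman_test(protein[anchor, idx], protein[p, idx])
      rows[[length(rows) + 1L]] <- data.frame(
        partner = p, group = g, rho = st$rho, p = st$p, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
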
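# Rule-based variant prioritization: hard filters with an audit trail,
# biallelic diagnosis calls, allele-type census, mutational burden, and a
# robust-z expression-outlier screen.

NONSYN_CONSEQUENCES <- c("missense", "truncating", "splicing",
                         "inframe_deletion", "cnv")
VALID_CONSEQUENCES <- c(NONSYN_CONSEQUENCES, "synonymous", "other")
PATHOGENIC_CLASSES <- c("P", "LP")

#' Hard-filter variant records with a per-rule audit trail
#'
#' A record passes when all three rule blocks hold: (1) frequency -
#' maximum population allele frequency below `max_af`; (2) read support -
#' at least `min_fwd` forward and `min_rev` reverse reads and `min_cov`
#' total coverage (copy-number variants, which come from a separate
#' caller, bypass read support but not frequency); (3) relevance - at
#' least one of: a non-synonymous coding consequence, a
#' pathogenic/likely-pathogenic ClinVar or InterVar class, or a dbscSNV
#' ensemble splice score (ADA or RF) above `splice_cut`.
#'
#' @param records data frame with columns `individual_id`, `variant_id`,
#'   `gene`, `consequence`, `zygosity`, `population_max_af`, `fwd_reads`,
#'   `rev_reads`, `coverage`, `clinvar_class`, `intervar_class`,
#'   `dbscsnv_ada`, `dbscsnv_rf` (scores may be `NA`).
#' @param max_af,min_fwd,min_rev,min_cov,splice_cut rule thresholds.
#' @return `records` with appended logical columns `rule_frequency`,
#'   `rule_reads`, `rule_consequence`, `rule_pathogenic_class`,
#'   `rule_splice`, and `pass`.
#' @export
filter_variants <- function(records, max_af = 0.01, min_fwd = 2,
                            min_rev = 2, min_cov = 8, splice_cut = 0.6) {
  need <- c("individual_id", "variant_id", "gene", "consequence",
            "zygosity", "population_max_af", "fwd_reads", "rev_reads",
            "coverage", "clinvar_class", "intervar_class",
            "dbscsnv_ada", "dbscsnv_rf")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_input("records missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(records$consequence %in% VALID_CONSEQUENCES) |
                 !(records$zygosity %in% c("het", "hom")) |
                 records$population_max_af < 0 |
                 records$population_max_af > 1)
  if (length(bad))
    stop_input("malformed record at line(s): ",
               paste(utils::head(bad, 5), collapse = ", "))
  is_cnv <- records$consequence == "cnv"
  records$rule_frequency <- records$population_max_af < max_af
  records$rule_reads <- is_cnv |
    (records$fwd_reads >= min_fwd & records$rev_reads >= min_rev &
       records$coverage >= min_cov)
  records$rule_consequence <- records$consequence %in% NONSYN_CONSEQUENCES
  records$rule_pathogenic_class <-
    records$clinvar_class %in% PATHOGENIC_CLASSES |
    records$intervar_class %in% PATHOGENIC_CLASSES
  ada <- records$dbscsnv_ada; rf <- records$dbscsnv_rf
  records$rule_splice <- (!is.na(ada) & ada > splice_cut) |
    (!is.na(rf) & rf > splice_cut)
  records$pass <- records$rule_frequency & records$rule_reads &
    (records$rule_consequence | records$rule_pathogenic_class |
       records$rule_splice)
  records
}

#' Biallelic diagnosis calls
#'
#' Per (individual, gene): a homozygous call when any passing allele is
#' homozygous, otherwise a compound-heterozygous call when at least two
#' distinct passing heterozygous alleles hit the same gene. Phase is
#' unknown; compound heterozygosity assumes the two alleles are in trans.
#'
#' @param passing data frame from [filter_variants()]; only rows with
#'   `pass == TRUE` are used (a `pass` column is optional).
#' @return data frame `individual_id`, `gene`, `call_type`
#'   (`"homozygous"`/`"compound_het"`), `alleles` (`;`-joined variant
#'   ids), `n_alleles`.
#' @export
biallelic_calls <- function(passing) {
  if ("pass" %in% names(passing)) passing <- passing[passing$pass, ]
  if (nrow(passing) == 0)
    return(data.frame(individual_id = character(0), gene = character(0),
                      call_type = character(0), alleles = character(0),
                      n_alleles = integer(0)))
  grp <- split(passing, list(passing$individual_id, passing$gene),
               drop = TRUE)
  rows <- lapply(grp, function(blk) {
    hom <- blk[blk$zygosity == "hom", ]
    het_ids <- unique(blk$variant_id[blk$zygosity == "het"])
    if (nrow(hom) > 0) {
      data.frame(individual_id = blk$individual_id[1], gene = blk$gene[1],
                 call_type = "homozygous",
                 alleles = hom$variant_id[1],
                 n_alleles = 1L, stringsAsFactors = FALSE)
    } else if (length(het_ids) >= 2) {
      data.frame(individual_id = blk$individual_id[1], gene = blk$gene[1],
                 call_type = "compound_het",
                 alleles = paste(het_ids, collapse = ";"),
                 n_alleles = length(het_ids), stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(individual_id = character(0), gene = character(0),
                      call_type = character(0), alleles = character(0),
                      n_alleles = integer(0)))
  rownames(out) <- NULL
  out
}

#' Allele-type census of diagnosed individuals
#'
#' Counts disease alleles by consequence class: a homozygous call
#' contributes two alleles of its variant's consequence; every allele of
#' a compound-heterozygous call contributes one.
#'
#' @param calls data frame from [biallelic_calls()].
#' @param records the variant records the calls were derived from (for
#'   consequence lookup by `variant_id`).
#' @return named integer vector consequence -> allele count.
#' @export
allele_type_counts <- function(calls, records) {
  counts <- integer(0)
  bump <- function(cons, k) {
    counts[cons] <<- (if (cons %in% names(counts)) counts[[cons]] else 0L) + k
  }
  for (i in seq_len(nrow(calls))) {
    ids <- strsplit(calls$alleles[i], ";", fixed = TRUE)[[1]]
    mult <- if (calls$call_type[i] == "homozygous") 2L else 1L
    for (id in ids)
      bump(records$consequence[match(id, records$variant_id)], mult)
  }
  counts
}

#' Genes recurrently hit by biallelic variants across a cohort
#'
#' Mutational-burden gene list: genes with biallelic diagnosis calls in
#' at least `min_individuals` distinct individuals, ranked by the number
#' of individuals carrying them.
#'
#' @param calls data frame from [biallelic_calls()].
#' @param min_individuals inclusion threshold (default 2).
#' @return data frame `gene`, `n_individuals`, sorted decreasingly.
#' @export
mutational_burden <- function(calls, min_individuals = 2) {
  if (nrow(calls) == 0)
    return(data.frame(gene = character(0), n_individuals = integer(0)))
  tab <- tapply(calls$individual_id, calls$gene,
                function(x) length(unique(x)))
  out <- data.frame(gene = names(tab), n_individuals = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n_individuals >= min_individuals, ]
  out <- out[order(-out$n_individuals, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Robust-z expression-outlier screen
#'
#' Flags (sample, gene) entries whose expression falls below a robust
#' z-score threshold, `z = (value - median) / (1.4826 * MAD)` per gene -
#' a simple screen for aberrantly under-expressed genes (e.g. from
#' unrecognized splice or copy-number defects). Genes with zero MAD are
#' skipped with a warning.
#'
#' @param expr genes x samples numeric matrix (>= 20 samples).
#' @param z_threshold flag entries with `z < z_threshold` (default -3).
#' @return data frame `sample`, `gene`, `z`, sorted by `z`.
#' @export
expression_outlier <- function(expr, z_threshold = -3) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 20) stop_input("need at least 20 samples")
  rows <- list()
  skipped <- character(0)
  for (g in seq_len(nrow(expr))) {
    v <- expr[g, ]
    md <- stats::median(v)
    s <- stats::mad(v)        # 1.4826 * median absolute deviation
    if (s == 0) {
      skipped <- c(skipped, rownames(expr)[g] %||% as.character(g))
      next
    }
    z <- (v - md) / s
    hit <- which(z < z_threshold)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = colnames(expr)[hit] %||% as.character(hit),
        gene = rownames(expr)[g] %||% as.character(g),
        z = z[hit], stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("zero MAD, gene(s) skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), gene = character(0), z = numeric(0))
  out <- out[order(out$z), ]
  rownames(out) <- NULL
  out
}
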
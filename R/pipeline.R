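# End-to-end orchestration: simulate (or load) a cohort, run every
# analysis stage in dependency order, write flat-file outputs and a JSON
# run manifest with file digests.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Executes, in dependency order: clinical severity score and phenome
#' screen; doubly standardized expression, kinship and per-gene
#' mixed-model scans (RNA and protein) against rank-inverse-normalized
#' PI+; BLUP sample ranking from GLUD1/OGDH protein expression;
#' transcript-protein correlation summaries and the per-gene diagonal
#' distance table; isotopologue fractions, citrate M+5/M+4 ratios,
#' pool-size comparisons and reductive-fraction fits; IP-MS presence,
#' Venn, specificity, ANOVA and network; and variant triage with
#' biallelic calls, allele census, burden and expression outliers. Any
#' stage failure aborts with a stage-tagged error; outputs already
#' written are preserved.
#'
#' @param bundle a [simulate_cohort()] bundle (or the result of
#'   [read_cohort()]).
#' @param outdir output directory for all stage TSV/JSON files.
#' @param alpha significance threshold used by the screen, correlation
#'   and ANOVA stages.
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`; component `results` holds the in-memory stage
#'   outputs.
#' @export
run_pipeline <- function(bundle, outdir, alpha = 0.05) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- list()
  wt <- function(x, f, rows = FALSE) {
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = rows, col.names = TRUE)
    f
  }
  written <- character(0)

  stage("phenomics", {
    ph <- bundle$phenotypes
    ph$CSS <- compute_css(ph)
    res$phenotypes <- ph
    res$corr_matrix <- correlation_matrix(ph)
    res$screen_css <- association_screen(ph, "CSS", alpha)
    res$screen_pi_plus <- association_screen(ph, "PI_plus", alpha)
    written <- c(written, wt(res$corr_matrix, "phenotype_corr.tsv", TRUE),
                 wt(res$screen_css, "screen_CSS.tsv"),
                 wt(res$screen_pi_plus, "screen_PI_plus.tsv"))
  })

  stage("lmm", {
    y <- rank_inverse_normal(stats::setNames(res$phenotypes$PI_plus,
                                             res$phenotypes$individual_id))
    for (layer in c("rna", "protein")) {
      M <- log2(as.matrix(bundle[[layer]]))
      Ms <- iterative_standardize(M)
      K <- sample_kinship(Ms)
      fits <- lmm_scan(y, M, K)
      res[[paste0("lmm_", layer)]] <- fits
      written <- c(written, wt(fits, paste0("lmm_", layer, ".tsv")))
    }
    Mp <- log2(as.matrix(bundle$protein))
    Kp <- sample_kinship(iterative_standardize(Mp))
    covars <- t(apply(Mp[c("GLUD1", "OGDH"), , drop = FALSE], 1, zscore))
    res$blup <- predict_blup(y, fixed = t(covars), K = Kp)
    written <- c(written, wt(
      data.frame(sample = names(res$blup$prediction),
                 predicted_PI_plus = res$blup$prediction)[res$blup$ranking, ],
      "blup_ranking.tsv"))
  })

  stage("correlations", {
    groups <- ifelse(bundle$group_labels == "MMUT-deficient",
                     "MMUT-deficient", "control")
    names(groups) <- names(bundle$group_labels)
    rna <- log2(as.matrix(bundle$rna))
    protein <- log2(as.matrix(bundle$protein))
    res$cross_level <- cross_level_summary(rna, protein)
    res$paired <- paired_correlation_table(rna, protein, groups)
    written <- c(written, wt(res$paired, "paired_correlations.tsv"))
  })

  stage("tracing", {
    fr <- isotopologue_fractions(bundle$tracing$peaks,
                                 bundle$tracing$standards)
    res$fractions <- fr
    cit <- fr[fr$metabolite == "citrate", ]
    ratios <- vapply(split(cit, cit$sample), citrate_ratio, numeric(1))
    res$citrate_ratios <- data.frame(
      sample = names(ratios),
      condition = unname(bundle$tracing$condition[names(ratios)]),
      m5_m4_ratio = unname(ratios), stringsAsFactors = FALSE)
    pools <- stats::aggregate(area ~ sample + metabolite,
                              bundle$tracing$peaks, sum)
    names(pools)[3] <- "total"
    res$pool_tests <- pool_size_compare(pools, bundle$tracing$condition)
    fits <- lapply(split(cit, cit$sample), function(blk) {
      cond <- bundle$tracing$condition[blk$sample[1]]
      pars <- bundle$truth$tracing_params[[cond]]
      fit_reductive_fraction(blk$fraction[order(blk$isotopologue)],
                             a = pars$a, e = pars$e, turns = pars$turns)
    })
    res$r_fits <- data.frame(
      sample = names(fits),
      condition = unname(bundle$tracing$condition[names(fits)]),
      r_hat = vapply(fits, `[[`, numeric(1), "r_hat"),
      residual = vapply(fits, `[[`, numeric(1), "residual"),
      stringsAsFactors = FALSE)
    written <- c(written, wt(fr, "fractions.tsv"),
                 wt(res$citrate_ratios, "citrate_ratios.tsv"),
                 wt(res$pool_tests, "pool_tests.tsv"),
                 wt(res$r_fits, "reductive_fits.tsv"))
  })

  stage("ipms", {
    pm <- apply_id_thresholds(bundle$ipms$ids, roles = bundle$ipms$roles)
    required <- names(bundle$ipms$roles)[bundle$ipms$roles == "experimental"]
    forbidden <- names(bundle$ipms$roles)[bundle$ipms$roles == "negative_control"]
    res$presence <- pm
    res$specific <- specific_prey(pm, required, forbidden_baits = forbidden)
    res$venn <- venn_partition(pm, required)
    res$enrichment <- anova_enrichment(bundle$ipms$quant,
                                       bundle$ipms$quant_groups)
    res$network <- build_network(res$specific, res$enrichment, pm,
                                 baits = required, alpha = alpha)
    written <- c(written,
                 wt(as.data.frame(unclass(pm)), "ipms_presence.tsv", TRUE),
                 wt(data.frame(region = names(res$venn),
                               n = lengths(res$venn)), "ipms_venn.tsv"),
                 wt(res$enrichment, "ipms_enrichment.tsv"),
                 wt(res$network$edges, "ipms_network_edges.tsv"))
    write_graphml(res$network, file.path(outdir, "ipms_network.graphml"))
    written <- c(written, "ipms_network.graphml")
  })

  stage("variants", {
    filtered <- filter_variants(bundle$variants)
    res$variants_filtered <- filtered
    res$calls <- biallelic_calls(filtered)
    res$allele_counts <- allele_type_counts(res$calls, bundle$variants)
    res$burden <- mutational_burden(res$calls)
    res$outliers <- if (ncol(bundle$rna) >= 20)
      suppressWarnings(expression_outlier(log2(as.matrix(bundle$rna))))
    else NULL
    written <- c(written, wt(filtered, "variants_passing.tsv"),
                 wt(res$calls, "variant_calls.tsv"),
                 wt(res$burden, "variant_burden.tsv"))
  })

  manifest <- list(
    seed = bundle$truth$config$seed,
    alpha = alpha,
    n_samples = length(bundle$group_labels),
    n_genes = bundle$truth$config$n_genes,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = as.list(tools::md5sum(file.path(outdir, written))))
  names(manifest$outputs) <- written
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- res
  invisible(manifest)
}

#' Read a cohort bundle back from a directory
#'
#' Counterpart of [write_cohort()]; reads the TSV tables written there
#' into a `cohort_bundle` (the `truth` slot is reloaded from
#' `truth.json`).
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_bundle` list.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, rows = FALSE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_input("missing input file: ", f)
    utils::read.table(p, sep = "\t", header = TRUE, row.names = if (rows) 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  groups <- rd("groups.tsv")
  group_labels <- stats::setNames(groups$group, groups$sample)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  tr_std <- rd("tracing_standards.tsv")
  tr_peaks <- rd("tracing.tsv")
  condition <- stats::setNames(sub("_[0-9]+$", "", tr_std$sample[!duplicated(tr_std$sample)]),
                               tr_std$sample[!duplicated(tr_std$sample)])
  quant <- as.matrix(rd("ipms_quant.tsv", rows = TRUE))
  structure(list(
    phenotypes = rd("phenotypes.tsv"),
    rna = as.matrix(rd("rna.tsv", rows = TRUE)),
    protein = as.matrix(rd("protein.tsv", rows = TRUE)),
    variants = rd("variants.tsv"),
    tracing = list(peaks = tr_peaks, standards = tr_std,
                   condition = condition),
    ipms = list(ids = rd("ipms_ids.tsv"), quant = quant,
                quant_groups = sub("_[0-9]+$", "", colnames(quant)),
                roles = stats::setNames(
                  c(rep("experimental", 4), rep("negative_control", 2)),
                  c("MMUT", "MMAA", "MMAB", "MCEE", "EV", "VLCAD"))),
    group_labels = group_labels, truth = truth), class = "cohort_bundle")
}

#' Validate pipeline input tables
#'
#' Schema checks (required columns, value ranges) for every table of a
#' cohort bundle, with row-level diagnostics.
#'
#' @param bundle a `cohort_bundle`.
#' @return data frame `table`, `row`, `message`; zero rows when clean.
#' @export
validate_inputs <- function(bundle) {
  diags <- list()
  note <- function(tab, row, msg)
    diags[[length(diags) + 1L]] <<- data.frame(
      table = tab, row = row, message = msg, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(bundle$phenotypes))
    note("phenotypes", NA, "missing individual_id column")
  for (m in c("rna", "protein")) {
    bad <- which(bundle[[m]] < 0, arr.ind = TRUE)
    if (nrow(bad)) note(m, bad[1, 1], "negative abundance")
  }
  pk <- bundle$tracing$peaks
  bad <- which(pk$area < 0)
  for (i in utils::head(bad, 10)) note("tracing", i, "negative peak area")
  vr <- bundle$variants
  bad <- which(vr$population_max_af < 0 | vr$population_max_af > 1)
  for (i in utils::head(bad, 10))
    note("variants", i, "allele frequency outside [0, 1]")
  bad <- which(!vr$consequence %in% VALID_CONSEQUENCES)
  for (i in utils::head(bad, 10)) note("variants", i, "unknown consequence")
  pp <- bundle$ipms$ids$protein_probability
  bad <- which(pp < 0 | pp > 1)
  for (i in utils::head(bad, 10))
    note("ipms_ids", i, "protein probability outside [0, 1]")
  if (length(diags)) do.call(rbind, diags) else
    data.frame(table = character(0), row = integer(0),
               message = character(0))
}
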
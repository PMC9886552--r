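# Seeded synthetic cohort generator. Emulates the statistical structure
# the analysis stages assume: a latent disease-severity axis driving
# correlated mixed-type phenotypes (including PI/PI+ activity), genotype-
# group expression effects with tunable RNA-protein coupling, isotopologue
# spectra from the parameterized TCA labeling model, bait-specific prey
# enrichment over background, and variant records exercising every filter.

GROUP_LEVELS <- c("MMUT-deficient", "other-MMA", "unaffected")

#' Default genotype-group expression effects
#'
#' Log2 fold changes (MMUT-deficient versus all other samples) for the
#' marquee genes of MMUT deficiency: MMUT strongly down at both layers,
#' OGDH down (protein more than transcript), GLUD1 and ALDH2 up, PDK4 up
#' mainly at the transcript level.
#'
#' @return data frame `gene`, `rna_log2fc`, `protein_log2fc`.
#' @export
default_effect_table <- function() {
  data.frame(
    gene = c("MMUT", "OGDH", "GLUD1", "ALDH2", "PDK4"),
    rna_log2fc = c(-1.5, -0.3, 0.3, 0.5, 0.8),
    protein_log2fc = c(-1.5, -0.8, 0.8, 0.5, 0.2),
    stringsAsFactors = FALSE)
}

#' Default phenotype specifications
#'
#' Mixed-type phenotype variables loading on the latent severity axis:
#' in-vitro assays (PI, PI+, MMUT activity) decrease with severity,
#' biochemical markers (plasma methylmalonic acid, ammonia) increase,
#' blood pH and age at onset decrease, the five clinical-severity-score
#' components and treatment indicators are binary with positive loadings,
#' and a block of null variables carries no severity signal.
#'
#' @return data frame `name`, `type`, `category`, `loading`, `noise_sd`,
#'   `log_scale`.
#' @export
default_phenotype_specs <- function() {
  spec <- function(name, type, category, loading, noise_sd, log_scale)
    data.frame(name = name, type = type, category = category,
               loading = loading, noise_sd = noise_sd,
               log_scale = log_scale, stringsAsFactors = FALSE)
  rbind(
    spec("PI", "continuous", "in-vitro", -0.8, 0.6, TRUE),
    spec("PI_plus", "continuous", "in-vitro", -0.9, 0.5, TRUE),
    spec("MMUT_activity", "continuous", "in-vitro", -0.8, 0.6, TRUE),
    spec("onset_age_days", "continuous", "presentation", -0.7, 0.7, TRUE),
    spec("mma_plasma", "continuous", "clinical-chemistry", 0.8, 0.6, TRUE),
    spec("ammonia", "continuous", "clinical-chemistry", 0.7, 0.7, TRUE),
    spec("ph_blood", "continuous", "clinical-chemistry", -0.5, 0.9, FALSE),
    spec("early_onset", "binary", "presentation", 1.2, 1, FALSE),
    spec("neurological_abnormalities", "binary", "course", 1.0, 1, FALSE),
    spec("kidney_impairment", "binary", "course", 0.8, 1, FALSE),
    spec("hematological_abnormalities", "binary", "course", 0.8, 1, FALSE),
    spec("failure_to_thrive", "binary", "presentation", 1.0, 1, FALSE),
    spec("protein_restriction", "binary", "treatment", 1.0, 1, FALSE),
    spec("carnitine_supplement", "binary", "treatment", 0.8, 1, FALSE),
    spec(paste0("null_", 1:5), "continuous", "clinical-chemistry",
         0, 1, FALSE))
}

#' Cohort generator configuration
#'
#' @param n_case,n_control,n_other group sizes (MMUT-deficient, unaffected,
#'   other-MMA); all must be positive.
#' @param n_genes number of genes per expression layer (the effect-table
#'   genes plus fillers).
#' @param seed master seed; every layer derives a named sub-seed from it.
#' @param severity_sd standard deviation of the latent severity axis.
#' @param effect_table data frame `gene`, `rna_log2fc`, `protein_log2fc`.
#' @param rna_protein_coupling scalar or per-gene named vector in
#'   `[-1, 1]`: correlation between the transcript and protein noise of a
#'   gene.
#' @param phenotype_specs data frame as in [default_phenotype_specs()].
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 30, n_control = 10, n_other = 10,
                          n_genes = 200, seed = 1, severity_sd = 1,
                          effect_table = default_effect_table(),
                          rna_protein_coupling = 0.3,
                          phenotype_specs = default_phenotype_specs()) {
  counts <- c(n_case, n_control, n_other, n_genes)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop_input("n_case, n_control, n_other and n_genes must be positive integers")
  if (severity_sd <= 0) stop_input("severity_sd must be positive")
  if (!all(c("gene", "rna_log2fc", "protein_log2fc") %in% names(effect_table)))
    stop_input("effect_table needs columns gene, rna_log2fc, protein_log2fc")
  if (anyDuplicated(effect_table$gene))
    stop_input("duplicate gene in effect_table")
  if (any(abs(rna_protein_coupling) > 1))
    stop_input("rna_protein_coupling must be in [-1, 1]")
  if (any(phenotype_specs$noise_sd <= 0))
    stop_input("phenotype noise_sd must be positive")
  if (anyDuplicated(phenotype_specs$name))
    stop_input("duplicate phenotype spec name")
  structure(list(n_case = n_case, n_control = n_control, n_other = n_other,
                 n_genes = n_genes, seed = seed, severity_sd = severity_sd,
                 effect_table = effect_table,
                 rna_protein_coupling = rna_protein_coupling,
                 phenotype_specs = phenotype_specs),
            class = "cohort_config")
}

#' Simulate mixed-type phenotypes from a latent severity axis
#'
#' Continuous variables are `loading * severity + noise`, exponentiated
#' when `log_scale` (so assay-like variables are strictly positive and
#' log-normal); binary variables are Bernoulli draws from a logistic link
#' `plogis(loading * severity)`. Variables with zero loading are
#' independent of severity.
#'
#' @param latent_severity numeric vector, one value per individual.
#' @param specs data frame as in [default_phenotype_specs()].
#' @param individual_id optional identifiers (default `MMA001`, ...).
#' @return data frame with `individual_id` and one column per variable;
#'   the specs are attached as attribute `meta`.
#' @export
simulate_phenotypes <- function(latent_severity, specs,
                                individual_id = NULL) {
  if (anyDuplicated(specs$name)) stop_input("duplicate phenotype spec name")
  n <- length(latent_severity)
  ids <- individual_id %||% sprintf("MMA%03d", seq_len(n))
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (s$type == "continuous") {
      v <- s$loading * latent_severity + stats::rnorm(n, 0, s$noise_sd)
      if (isTRUE(s$log_scale)) v <- exp(v)
    } else if (s$type == "binary") {
      v <- stats::rbinom(n, 1, stats::plogis(s$loading * latent_severity))
    } else stop_input("unknown phenotype type: ", s$type)
    out[[s$name]] <- v
  }
  attr(out, "meta") <- specs
  out
}

#' Simulate coupled transcript and protein expression matrices
#'
#' Per gene, log2 transcript values are a log-normal base abundance plus
#' the configured group effect (applied to MMUT-deficient samples) plus
#' unit-variance noise. Log2 protein values couple to the standardized
#' transcript: `coupling * z(rna) + sqrt(1 - coupling^2) * noise`, plus
#' the protein group effect. Both layers are returned as raw (positive)
#' abundances, `2^log2`.
#'
#' @param group_labels named character vector sample -> group (levels as
#'   in `GROUP_LEVELS`).
#' @param effect_table data frame `gene`, `rna_log2fc`, `protein_log2fc`;
#'   every gene must exist in the generated layer.
#' @param coupling scalar or per-gene named coupling in `[-1, 1]`.
#' @param n_genes total genes (effect genes plus fillers `G0001`, ...).
#' @return list `rna`, `protein`: genes x samples matrices with attribute
#'   `layer` and `state = "raw"`.
#' @export
simulate_paired_omics <- function(group_labels, effect_table = default_effect_table(),
                                  coupling = 0.3, n_genes = 200) {
  if (length(group_labels) == 0) stop_input("group_labels must be non-empty")
  samples <- names(group_labels) %||% sprintf("MMA%03d", seq_along(group_labels))
  n <- length(samples)
  n_fill <- n_genes - nrow(effect_table)
  if (n_fill < 0) stop_input("n_genes smaller than the effect table")
  genes <- c(effect_table$gene, sprintf("G%04d", seq_len(n_fill)))
  if (!all(effect_table$gene %in% genes))
    stop_input("unknown gene in effect_table")
  cvec <- if (length(coupling) == 1) stats::setNames(rep(coupling, n_genes), genes)
          else coupling[genes]
  cvec[is.na(cvec)] <- 0.3
  rna_fc <- stats::setNames(rep(0, n_genes), genes)
  prot_fc <- rna_fc
  rna_fc[effect_table$gene] <- effect_table$rna_log2fc
  prot_fc[effect_table$gene] <- effect_table$protein_log2fc
  is_case <- as.numeric(group_labels == "MMUT-deficient")
  mu_rna <- stats::rnorm(n_genes, 7, 1.5)
  mu_prot <- stats::rnorm(n_genes, 10, 1.5)
  rna_log2 <- matrix(0, n_genes, n, dimnames = list(genes, samples))
  prot_log2 <- rna_log2
  for (g in seq_len(n_genes)) {
    z <- stats::rnorm(n)
    rna_log2[g, ] <- mu_rna[g] + rna_fc[g] * is_case + z
    zr <- zscore(rna_log2[g, ])
    eps <- stats::rnorm(n)
    cg <- cvec[g]
    prot_log2[g, ] <- mu_prot[g] + prot_fc[g] * is_case +
      cg * zr + sqrt(1 - cg^2) * eps
  }
  mk <- function(m, layer) {
    out <- 2^m
    attr(out, "layer") <- layer
    attr(out, "state") <- "raw"
    out
  }
  list(rna = mk(rna_log2, "rna"), protein = mk(prot_log2, "protein"))
}

# Allele records for one biallelic diagnosis passing every filter.
planted_alleles <- function(individual, gene, id_start) {
  consequences <- c("missense", "truncating", "splicing",
                    "inframe_deletion", "cnv")
  weights <- c(0.56, 0.35, 0.07, 0.01, 0.01)
  hom <- stats::runif(1) < 0.3
  k <- if (hom) 1L else 2L
  cons <- sample(consequences, k, replace = TRUE, prob = weights)
  fwd <- sample(5:30, k, replace = TRUE)
  rev <- sample(5:30, k, replace = TRUE)
  data.frame(
    individual_id = individual,
    variant_id = sprintf("var%05d", id_start + seq_len(k) - 1L),
    gene = gene, consequence = cons,
    zygosity = if (hom) "hom" else "het",
    population_max_af = stats::runif(k, 0, 0.005),
    fwd_reads = fwd, rev_reads = rev,
    coverage = fwd + rev + sample(0:10, k, replace = TRUE),
    clinvar_class = sample(c("P", "LP", "none"), k, replace = TRUE,
                           prob = c(0.4, 0.2, 0.4)),
    intervar_class = sample(c("P", "LP", "VUS"), k, replace = TRUE,
                            prob = c(0.3, 0.3, 0.4)),
    dbscsnv_ada = ifelse(cons == "splicing", stats::runif(k, 0.7, 1), NA),
    dbscsnv_rf = ifelse(cons == "splicing", stats::runif(k, 0.7, 1), NA),
    stringsAsFactors = FALSE)
}

# Noise allele violating exactly the named filter rule.
noise_allele <- function(individual, id, kind) {
  base <- data.frame(
    individual_id = individual, variant_id = sprintf("var%05d", id),
    gene = sample(sprintf("NOISE%02d", 1:20), 1),
    consequence = "missense", zygosity = "het",
    population_max_af = stats::runif(1, 0, 0.005),
    fwd_reads = 15L, rev_reads = 15L, coverage = 35L,
    clinvar_class = "none", intervar_class = "VUS",
    dbscsnv_ada = NA_real_, dbscsnv_rf = NA_real_,
    stringsAsFactors = FALSE)
  if (kind == "common") base$population_max_af <- stats::runif(1, 0.02, 0.3)
  if (kind == "low_reads") { base$fwd_reads <- 1L; base$coverage <- 5L }
  if (kind == "synonymous") base$consequence <- "synonymous"
  # unique gene per lone passing het: exercises the no-partner rule
  # without ever assembling an accidental compound het
  if (kind == "lone_het") base$gene <- sprintf("LONE%05d", id)
  base
}

simulate_variant_table <- function(group_labels) {
  ids <- names(group_labels)
  rows <- list()
  truth <- list()
  counter <- 1L
  other_genes <- c("ACSF3", "TCN2", "SUCLA2", "MMAB")
  other_ids <- ids[group_labels == "other-MMA"]
  diagnosed_other <- utils::head(other_ids, ceiling(length(other_ids) / 2))
  for (ind in ids) {
    grp <- group_labels[[ind]]
    if (grp == "MMUT-deficient") {
      blk <- planted_alleles(ind, "MMUT", counter)
    } else if (grp == "other-MMA" && ind %in% diagnosed_other) {
      blk <- planted_alleles(ind, sample(other_genes, 1,
                                         prob = c(0.7, 0.15, 0.1, 0.05)),
                             counter)
    } else blk <- NULL
    if (!is.null(blk)) {
      counter <- counter + nrow(blk)
      rows[[length(rows) + 1L]] <- blk
      truth[[length(truth) + 1L]] <- data.frame(
        individual_id = ind, gene = blk$gene[1],
        call_type = if (blk$zygosity[1] == "hom") "homozygous" else "compound_het",
        stringsAsFactors = FALSE)
    }
    for (kind in sample(c("common", "low_reads", "synonymous", "lone_het"),
                        stats::rpois(1, 2), replace = TRUE)) {
      rows[[length(rows) + 1L]] <- noise_allele(ind, counter, kind)
      counter <- counter + 1L
    }
  }
  list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
}

simulate_tracing_tables <- function(params_by_condition = list(
                                      control = tracing_params(r = 0.10, a = 0.45, e = 0.9, turns = 3),
                                      deficient = tracing_params(r = 0.35, a = 0.15, e = 0.9, turns = 3)),
                                    n_per_condition = 4, noise_sd = 0.02) {
  polarity_of <- c(glutamine = "pos", glutamate = "pos", oxoglutarate = "neg",
                   succinate = "neg", fumarate = "neg", malate = "neg",
                   citrate = "neg")
  pool_scale <- c(glutamate = 8, oxoglutarate = 1.5, succinate = 2,
                  fumarate = 1, malate = 3, citrate = 4)
  peaks <- list(); standards <- list(); condition <- character(0)
  for (cond in names(params_by_condition)) {
    sim <- simulate_labeling(params_by_condition[[cond]])
    pool_mult <- if (cond == "control") 1 else 0.5    # reduced TCA pools
    for (k in seq_len(n_per_condition)) {
      smp <- sprintf("%s_%d", cond, k)
      condition[smp] <- cond
      is_area <- c(pos = 1e5, neg = 1e5) * stats::runif(2, 0.8, 1.2)
      standards[[length(standards) + 1L]] <- data.frame(
        sample = smp, polarity = c("pos", "neg"), area = unname(is_area),
        stringsAsFactors = FALSE)
      for (met in names(sim)) {
        f <- pmax(sim[[met]] + stats::rnorm(length(sim[[met]]), 0, noise_sd), 0)
        f <- f / sum(f)
        pool <- pool_scale[met] * pool_mult * stats::runif(1, 0.85, 1.15)
        pol <- polarity_of[met]
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample = smp, metabolite = met,
          isotopologue = seq_along(f) - 1L,
          area = f * pool * is_area[[pol]], polarity = pol,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(peaks = do.call(rbind, peaks),
       standards = do.call(rbind, standards),
       condition = condition,
       params = lapply(params_by_condition, unclass))
}

simulate_ipms_tables <- function(n_background = 40, n_specific = 12,
                                 enrichment_fold = 8) {
  required <- c("MMUT", "MMAA", "MMAB", "MCEE")
  controls <- c("EV", "VLCAD")
  baits <- c(required, controls)
  reps <- 1:3
  specific <- c("OGDH", "DLST", "GOT2", "GLUD1", "SUCLA2",
                sprintf("PREY%03d", seq_len(max(0, n_specific - 5))))
  background <- sprintf("BG%03d", seq_len(n_background))
  mk_record <- function(protein, bait, rep, present) {
    if (present) {
      pp <- stats::runif(1, 0.992, 1)
      peps <- stats::runif(sample(2:6, 1), 0.96, 0.999)
    } else {
      # sub-threshold sighting: low protein probability or one peptide
      if (stats::runif(1) < 0.5) {
        pp <- stats::runif(1, 0.5, 0.98)
        peps <- stats::runif(2, 0.96, 0.999)
      } else {
        pp <- stats::runif(1, 0.992, 1)
        peps <- stats::runif(1, 0.96, 0.999)
      }
    }
    data.frame(protein = protein, bait = bait, replicate = rep,
               protein_probability = pp,
               peptide_probs = paste(round(peps, 4), collapse = ";"),
               stringsAsFactors = FALSE)
  }
  recs <- list()
  for (b in baits) for (r in reps) {
    recs[[length(recs) + 1L]] <- mk_record(b, b, r, b != "EV")  # bait itself
    for (p in specific) {
      if (b %in% required) {
        present <- r == 1 || stats::runif(1) < 0.8
        recs[[length(recs) + 1L]] <- mk_record(p, b, r, present)
      }
      # never any record in the negative controls for specific preys
    }
    for (p in background) {
      if (stats::runif(1) < 0.45)
        recs[[length(recs) + 1L]] <- mk_record(p, b, r, stats::runif(1) < 0.8)
    }
  }
  ids <- do.call(rbind, recs)
  # quantification: MMUT vs EV vs VLCAD triplicates
  quant_samples <- c(paste0("MMUT_", reps), paste0("EV_", reps),
                     paste0("VLCAD_", reps))
  quant_groups <- rep(c("MMUT", "EV", "VLCAD"), each = 3)
  proteins <- c(specific, background)
  quant <- matrix(0, length(proteins), length(quant_samples),
                  dimnames = list(proteins, quant_samples))
  for (p in proteins) {
    base <- 2^stats::rnorm(1, 20, 1)
    fold <- if (p %in% specific) enrichment_fold else 1
    mu <- ifelse(quant_groups == "MMUT", base * fold, base)
    quant[p, ] <- 2^(log2(mu) + stats::rnorm(length(mu), 0, 0.3))
  }
  list(ids = ids, quant = quant, quant_groups = quant_groups,
       roles = stats::setNames(c(rep("experimental", 4),
                                 rep("negative_control", 2)), baits),
       specific_preys = sort(specific))
}

#' Simulate a full synthetic cohort
#'
#' Generates every table the pipeline consumes - phenotypes, paired
#' RNA/protein expression, variant records, isotope-tracing peak tables,
#' and IP-MS identification/quantification tables - from one master seed,
#' with all generating parameters recorded in `truth`. The latent
#' severity axis is standard normal scaled by `severity_sd` with the
#' MMUT-deficient group shifted up by one standard deviation (other-MMA
#' by half); the generator is byte-deterministic for a fixed config.
#'
#' @param config a [cohort_config()] object.
#' @return list of class `cohort_bundle`: `phenotypes`, `rna`, `protein`,
#'   `variants`, `tracing` (list `peaks`, `standards`, `condition`),
#'   `ipms` (list `ids`, `quant`, `quant_groups`, `roles`),
#'   `group_labels`, `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 6,
                        c("severity", "phenotypes", "omics", "variants",
                          "tracing", "ipms"))
  n <- config$n_case + config$n_other + config$n_control
  ids <- sprintf("MMA%03d", seq_len(n))
  group_labels <- stats::setNames(
    rep(GROUP_LEVELS, c(config$n_case, config$n_other, config$n_control)),
    ids)
  shift <- c("MMUT-deficient" = 1, "other-MMA" = 0.5, "unaffected" = 0)
  severity <- with_seed(seeds["severity"],
    config$severity_sd * (stats::rnorm(n) + shift[group_labels]))
  names(severity) <- ids
  phenotypes <- with_seed(seeds["phenotypes"],
    simulate_phenotypes(severity, config$phenotype_specs, ids))
  omics <- with_seed(seeds["omics"],
    simulate_paired_omics(group_labels, config$effect_table,
                          config$rna_protein_coupling, config$n_genes))
  variants <- with_seed(seeds["variants"], simulate_variant_table(group_labels))
  tracing <- with_seed(seeds["tracing"], simulate_tracing_tables())
  ipms <- with_seed(seeds["ipms"], simulate_ipms_tables())
  truth <- list(
    config = unclass(config)[c("n_case", "n_control", "n_other", "n_genes",
                               "seed", "severity_sd", "rna_protein_coupling")],
    effect_table = config$effect_table,
    phenotype_specs = config$phenotype_specs,
    group_shift = as.list(shift),
    severity = as.list(severity),
    diagnoses = variants$truth,
    tracing_params = tracing$params,
    ipms_specific_preys = ipms$specific_preys,
    sub_seeds = as.list(seeds))
  structure(list(phenotypes = phenotypes, rna = omics$rna,
                 protein = omics$protein, variants = variants$records,
                 tracing = tracing[c("peaks", "standards", "condition")],
                 ipms = ipms[c("ids", "quant", "quant_groups", "roles")],
                 group_labels = group_labels, truth = truth),
            class = "cohort_bundle")
}

#' Write a cohort bundle to TSV/JSON files
#'
#' Writes `phenotypes.tsv`, `rna.tsv`, `protein.tsv`, `variants.tsv`,
#' `tracing.tsv`, `tracing_standards.tsv`, `ipms_ids.tsv`,
#' `ipms_quant.tsv`, `groups.tsv` and `truth.json` into `dir`.
#'
#' @param bundle a [simulate_cohort()] bundle.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rows = FALSE) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE,
                       row.names = rows, col.names = TRUE)
    p
  }
  paths <- c(
    wt(bundle$phenotypes, "phenotypes.tsv"),
    wt(as.data.frame(unclass(bundle$rna)), "rna.tsv", rows = TRUE),
    wt(as.data.frame(unclass(bundle$protein)), "protein.tsv", rows = TRUE),
    wt(bundle$variants, "variants.tsv"),
    wt(bundle$tracing$peaks, "tracing.tsv"),
    wt(bundle$tracing$standards, "tracing_standards.tsv"),
    wt(bundle$ipms$ids, "ipms_ids.tsv"),
    wt(as.data.frame(bundle$ipms$quant), "ipms_quant.tsv", rows = TRUE),
    wt(data.frame(sample = names(bundle$group_labels),
                  group = unname(bundle$group_labels),
                  condition_tracing = NA), "groups.tsv"))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(bundle$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(c(paths, truth_path))
}
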
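# Affinity-purification MS downstream logic: identification thresholds,
# bait-prey presence matrix, specificity/Venn filtering, ANOVA enrichment
# and the weighted interaction network.

#' Build a presence matrix from identification records
#'
#' A protein is called present in a (bait, replicate) run when its protein
#' identification probability exceeds `protein_prob` and at least
#' `min_peptides` of its peptides individually exceed `peptide_prob` -
#' the classic Scaffold-style acceptance rule.
#'
#' @param records data frame with columns `protein`, `bait`, `replicate`,
#'   `protein_probability`, and `peptide_probs` (per-record peptide
#'   probabilities as a `;`-separated string, or a list column).
#' @param protein_prob,min_peptides,peptide_prob acceptance thresholds.
#' @param roles optional named vector mapping bait to `"experimental"` or
#'   `"negative_control"`; stored as an attribute.
#' @return logical matrix proteins x runs with column names
#'   `"<bait>|<replicate>"`, class `presence_matrix`, attributes `bait`
#'   and `replicate` (per column) and `roles`.
#' @export
apply_id_thresholds <- function(records, protein_prob = 0.99,
                                min_peptides = 2, peptide_prob = 0.95,
                                roles = NULL) {
  need <- c("protein", "bait", "replicate", "protein_probability",
            "peptide_probs")
  if (!all(need %in% names(records)))
    stop_input("records must have columns: ", paste(need, collapse = ", "))
  pep <- records$peptide_probs
  if (!is.list(pep))
    pep <- lapply(strsplit(as.character(pep), ";", fixed = TRUE), as.numeric)
  if (any(unlist(pep) < 0 | unlist(pep) > 1, na.rm = TRUE) ||
      any(records$protein_probability < 0 | records$protein_probability > 1))
    stop_input("probabilities must be in [0, 1]")
  n_pass <- vapply(pep, function(p) sum(p > peptide_prob), integer(1))
  accepted <- records$protein_probability > protein_prob &
    n_pass >= min_peptides
  runs <- unique(records[c("bait", "replicate")])
  runs <- runs[order(runs$bait, runs$replicate), ]
  run_id <- paste(runs$bait, runs$replicate, sep = "|")
  proteins <- sort(unique(records$protein))
  m <- matrix(FALSE, length(proteins), nrow(runs),
              dimnames = list(proteins, run_id))
  hit <- records[accepted, ]
  if (nrow(hit))
    m[cbind(match(hit$protein, proteins),
            match(paste(hit$bait, hit$replicate, sep = "|"), run_id))] <- TRUE
  structure(m, class = c("presence_matrix", "matrix"),
            bait = runs$bait, replicate = runs$replicate, roles = roles)
}

pm_baits <- function(pm) unique(attr(pm, "bait"))

# proteins detected in >= min_reps replicates of a bait
detected_in_bait <- function(pm, bait, min_reps = 1) {
  cols <- which(attr(pm, "bait") == bait)
  if (length(cols) == 0) stop_input("unknown bait: ", bait)
  rownames(pm)[rowSums(pm[, cols, drop = FALSE]) >= min_reps]
}

#' Bait-specific prey selection
#'
#' Proteins detected in at least one replicate of at least `min_required`
#' of the required baits and in zero replicates of every forbidden bait -
#' e.g. preys pulled down by MMUT, MMAA, MMAB and MCEE but never by the
#' empty-vector or VLCAD controls.
#'
#' @param pm a [apply_id_thresholds()] presence matrix.
#' @param required_baits baits whose pull-downs count toward inclusion.
#' @param min_required minimum number of required baits detecting the
#'   protein (default: all of them).
#' @param forbidden_baits baits in which any detection excludes the
#'   protein.
#' @param min_replicates detections per required bait needed to count it
#'   (default 1).
#' @return character vector of prey proteins.
#' @export
specific_prey <- function(pm, required_baits,
                          min_required = length(required_baits),
                          forbidden_baits = character(0),
                          min_replicates = 1) {
  if (length(intersect(required_baits, forbidden_baits)))
    stop_input("required and forbidden baits must be disjoint")
  known <- pm_baits(pm)
  unknown <- setdiff(c(required_baits, forbidden_baits), known)
  if (length(unknown))
    stop_input("unknown bait name(s): ", paste(unknown, collapse = ", "))
  req_hits <- sapply(required_baits, function(b)
    rownames(pm) %in% detected_in_bait(pm, b, min_replicates))
  req_count <- rowSums(matrix(req_hits, nrow = nrow(pm)))
  ok <- req_count >= min_required
  for (b in forbidden_baits)
    ok <- ok & !(rownames(pm) %in% detected_in_bait(pm, b, 1))
  sort(rownames(pm)[ok])
}

#' Venn partition of detected proteins by bait membership
#'
#' Assigns every detected protein to exactly one of the `2^k - 1`
#' non-empty bait-membership regions, where membership means detection in
#' at least one replicate of that bait.
#'
#' @param pm presence matrix.
#' @param baits baits to partition over (<= 6; default all).
#' @return named list of protein vectors; region names join member baits
#'   with `"+"`.
#' @export
venn_partition <- function(pm, baits = pm_baits(pm)) {
  if (length(baits) > 6) stop_input("at most 6 baits supported")
  member <- sapply(baits, function(b)
    rownames(pm) %in% detected_in_bait(pm, b, 1))
  member <- matrix(member, nrow = nrow(pm), dimnames = list(rownames(pm), baits))
  detected <- rowSums(member) > 0
  keys <- apply(member[detected, , drop = FALSE], 1, function(z)
    paste(baits[z], collapse = "+"))
  split(rownames(pm)[detected], keys)
}

#' One-way ANOVA enrichment across bait groups
#'
#' Fixed-effects one-way F test of per-protein abundances across sample
#' groups (e.g. MMUT pull-downs versus two negative controls), with a
#' two-sided p-value and no multiplicity adjustment (a nominal threshold
#' is applied downstream). Proteins with zero variance everywhere and
#' equal group means get `F = 0, p = 1` by convention.
#'
#' @param quant numeric matrix proteins x samples of abundances.
#' @param groups factor/character vector of group per sample (>= 2
#'   replicates per group).
#' @return data frame `protein`, `F`, `p_anova`, one `mean_<group>`
#'   column per group.
#' @export
anova_enrichment <- function(quant, groups) {
  quant <- as.matrix(quant)
  groups <- factor(groups)
  if (length(groups) != ncol(quant))
    stop_input("one group label per sample column required")
  if (any(table(groups) < 2)) stop_input("need >= 2 replicates per group")
  res <- t(apply(quant, 1, function(v) {
    means <- tapply(v, groups, mean)
    if (all(tapply(v, groups, stats::var) == 0)) {
      if (max(means) - min(means) < 1e-12) return(c(0, 1, means))
      return(c(Inf, 0, means))
    }
    ft <- stats::oneway.test(v ~ groups, var.equal = TRUE)
    c(unname(ft$statistic), unname(ft$p.value), means)
  }))
  out <- data.frame(protein = rownames(quant), F = res[, 1],
                    p_anova = res[, 2], stringsAsFactors = FALSE)
  for (i in seq_along(levels(groups)))
    out[[paste0("mean_", levels(groups)[i])]] <- res[, 2 + i]
  rownames(out) <- NULL
  out
}

#' Weighted bait-prey interaction network
#'
#' One edge per (bait, significantly enriched prey) with weight
#' `-log10(p_anova)`, so stronger enrichment draws a thicker connector.
#' Nodes are annotated as `bait`, `exclusive_prey` (members of `preys`,
#' i.e. never seen in negative controls) or `shared_prey`.
#'
#' @param preys character vector of control-exclusive prey proteins (from
#'   [specific_prey()]).
#' @param enrichment data frame from [anova_enrichment()].
#' @param pm presence matrix used to attach preys to the baits that pulled
#'   them down.
#' @param baits experimental baits to draw edges from.
#' @param alpha nominal significance threshold on `p_anova`.
#' @return list `edges` (data frame `bait`, `prey`, `weight`, `p_anova`)
#'   and `nodes` (data frame `node`, `role`).
#' @export
build_network <- function(preys, enrichment, pm, baits = pm_baits(pm),
                          alpha = 0.05) {
  sig <- enrichment[enrichment$p_anova < alpha, ]
  edges <- list()
  for (b in baits) {
    hit <- intersect(detected_in_bait(pm, b, 1), sig$protein)
    if (length(hit))
      edges[[b]] <- data.frame(
        bait = b, prey = hit,
        weight = -log10(sig$p_anova[match(hit, sig$protein)]),
        p_anova = sig$p_anova[match(hit, sig$protein)],
        stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(bait = character(0), prey = character(0),
               weight = numeric(0), p_anova = numeric(0))
  rownames(edges) <- NULL
  node_names <- unique(c(baits, edges$prey))
  role <- ifelse(node_names %in% baits, "bait",
                 ifelse(node_names %in% preys, "exclusive_prey",
                        "shared_prey"))
  list(edges = edges,
       nodes = data.frame(node = node_names, role = role,
                          stringsAsFactors = FALSE))
}

#' Write a bait-prey network as GraphML
#'
#' @param network output of [build_network()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="role" for="node" attr.name="role" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="ipms" edgedefault="undirected">'), con)
  for (i in seq_len(nrow(network$nodes)))
    writeLines(sprintf('    <node id="%s"><data key="role">%s</data></node>',
                       esc(network$nodes$node[i]),
                       network$nodes$role[i]), con)
  for (i in seq_len(nrow(network$edges)))
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="weight">%.6g</data></edge>',
      esc(network$edges$bait[i]), esc(network$edges$prey[i]),
      network$edges$weight[i]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
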
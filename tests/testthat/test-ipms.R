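id_record <- function(protein, bait = "MMUT", rep = 1, pp = 0.999,
                      peps = c(0.96, 0.97)) {
  data.frame(protein = protein, bait = bait, replicate = rep,
             protein_probability = pp,
             peptide_probs = paste(peps, collapse = ";"),
             stringsAsFactors = FALSE)
}

test_that("identification thresholds implement the two-peptide 99% rule", {
  recs <- rbind(
    id_record("A", pp = 0.995, peps = c(0.96, 0.97)),   # present
    id_record("B", pp = 0.98, peps = c(0.99, 0.99)),    # protein prob fails
    id_record("C", pp = 0.995, peps = c(0.96, 0.90)),   # one passing peptide
    id_record("D", pp = 0.995, peps = 0.99))            # single peptide
  pm <- apply_id_thresholds(recs)
  expect_true(pm["A", "MMUT|1"])
  expect_false(pm["B", "MMUT|1"])
  expect_false(pm["C", "MMUT|1"])
  expect_false(pm["D", "MMUT|1"])
  expect_error(apply_id_thresholds(transform(recs, protein_probability = 2)),
               "0, 1")
})

test_that("specificity logic matches brute-force enumeration on random tensors", {
  set.seed(1)
  for (i in 1:10) {
    tensor <- random_presence_tensor()
    pm <- apply_id_thresholds(tensor$records)
    required <- LETTERS[1:4]; forbidden <- LETTERS[5:6]
    for (min_req in c(2, 3, 4)) {
      expect_equal(
        specific_prey(pm, required, min_req, forbidden),
        specific_prey_oracle(tensor$truth, required, min_req, forbidden))
    }
  }
})

test_that("a single control-replicate detection excludes a prey", {
  recs <- rbind(
    id_record("X", "MMUT", 1), id_record("X", "MMAA", 1),
    id_record("X", "EV", 3),                       # one control sighting
    id_record("Y", "MMUT", 1), id_record("Y", "MMAA", 1))
  pm <- apply_id_thresholds(recs)
  out <- specific_prey(pm, c("MMUT", "MMAA"), 2, "EV")
  expect_equal(out, "Y")
  expect_error(specific_prey(pm, c("MMUT", "ZZ"), 1, "EV"), "unknown bait")
  expect_error(specific_prey(pm, "MMUT", 1, "MMUT"), "disjoint")
})

test_that("specificity is monotone in its thresholds", {
  set.seed(2)
  tensor <- random_presence_tensor(n_prot = 12, p_present = 0.4)
  pm <- apply_id_thresholds(tensor$records)
  req <- LETTERS[1:4]
  base <- specific_prey(pm, req, 2, LETTERS[5])
  expect_true(all(specific_prey(pm, req, 3, LETTERS[5]) %in% base))
  expect_true(all(specific_prey(pm, req, 2, LETTERS[5:6]) %in% base))
})

test_that("venn regions partition the detected proteins", {
  set.seed(3)
  for (i in 1:5) {
    tensor <- random_presence_tensor()
    pm <- apply_id_thresholds(tensor$records)
    vp <- venn_partition(pm)
    # disjoint and exhaustive over detected proteins
    all_members <- unlist(vp, use.names = FALSE)
    expect_equal(anyDuplicated(all_members), 0)
    detected <- rownames(pm)[rowSums(pm) > 0]
    expect_setequal(all_members, detected)
    # region assignment equals direct membership computation
    for (region in names(vp)) {
      baits_in <- strsplit(region, "+", fixed = TRUE)[[1]]
      for (p in vp[[region]]) {
        member <- LETTERS[1:6][apply(tensor$truth[p, , ], 1, any)]
        expect_setequal(member, baits_in)
      }
    }
  }
  # a protein seen in only one bait lands in that singleton region
  recs <- id_record("solo", "MMUT", 1)
  expect_equal(venn_partition(apply_id_thresholds(recs))$MMUT, "solo")
})

test_that("anova enrichment matches the sum-of-squares oracle", {
  groups <- rep(c("MMUT", "EV", "VLCAD"), each = 3)
  # identical group composition: between-group variance is exactly zero
  flat <- matrix(rep(c(4, 5, 6), 3), 1, 9, dimnames = list("flat", NULL))
  res <- anova_enrichment(flat, groups)
  expect_equal(res$F, 0)
  expect_equal(res$p_anova, 1)
  # strong enrichment in the target group
  set.seed(4)
  strong <- matrix(c(rnorm(3, 10, 0.1), rnorm(6, 0, 0.1)), 1, 9,
                   dimnames = list("s", NULL))
  expect_lt(anova_enrichment(strong, groups)$p_anova, 0.001)
  # 50 random instances against the direct oracle
  for (i in 1:50) {
    v <- matrix(rnorm(9, sample(0:3, 1)), 1, 9, dimnames = list("p", NULL))
    res <- anova_enrichment(v, groups)
    oracle <- anova_oracle(v[1, ], groups)
    expect_equal(res$F, oracle$F, tolerance = 1e-8)
    expect_equal(res$p_anova, oracle$p, tolerance = 1e-8)
  }
  # degenerate equal-everything input uses the p = 1 convention
  const <- matrix(1, 1, 9, dimnames = list("c", NULL))
  expect_equal(anova_enrichment(const, groups)$p_anova, 1)
  expect_error(anova_enrichment(flat, rep(c("a", "b"), c(8, 1))),
               "2 replicates")
})

test_that("null anova p-values are uniform", {
  set.seed(5)
  quant <- matrix(rnorm(1000 * 9), 1000, 9,
                  dimnames = list(sprintf("P%04d", 1:1000), NULL))
  res <- anova_enrichment(quant, rep(c("a", "b", "c"), each = 3))
  ks <- suppressWarnings(ks.test(res$p_anova, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("network edges carry -log10 p weights for enriched preys only", {
  recs <- rbind(id_record("X", "MMUT", 1), id_record("Y", "MMUT", 1),
                id_record("Z", "MMAA", 1))
  pm <- apply_id_thresholds(recs)
  enr <- data.frame(protein = c("X", "Y", "Z"),
                    F = c(50, 20, 1), p_anova = c(0.01, 0.04, 0.5))
  net <- build_network(preys = "X", enr, pm, baits = c("MMUT", "MMAA"))
  expect_equal(nrow(net$edges), 2)            # Z not significant
  wx <- net$edges$weight[net$edges$prey == "X"]
  wy <- net$edges$weight[net$edges$prey == "Y"]
  expect_gt(wx, wy)                           # lower p, thicker connector
  expect_equal(wx, -log10(0.01))
  expect_equal(net$nodes$role[net$nodes$node == "X"], "exclusive_prey")
  expect_equal(net$nodes$role[net$nodes$node == "Y"], "shared_prey")
  # empty prey universe: no edges
  empty <- build_network(character(0),
                         data.frame(protein = "X", F = 1, p_anova = 0.9),
                         pm, baits = "MMUT")
  expect_equal(nrow(empty$edges), 0)
  # graphml export round-trips through a well-formed file
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  txt <- readLines(path)
  expect_true(any(grepl("graphml", txt)))
  expect_equal(sum(grepl("<edge ", txt)), 2)
})
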
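toy_peaks <- function(areas, sample = "s1", metabolite = "xmet",
                      polarity = "neg") {
  data.frame(sample = sample, metabolite = metabolite,
             isotopologue = seq_along(areas) - 1L, area = areas,
             polarity = polarity, stringsAsFactors = FALSE)
}
toy_standards <- function(area = 1, sample = "s1")
  data.frame(sample = sample, polarity = c("pos", "neg"), area = area)

test_that("fractions normalize to internal standards and sum to one", {
  fr <- isotopologue_fractions(toy_peaks(c(1, 1, 2)), toy_standards())
  expect_equal(fr$fraction, c(0.25, 0.25, 0.5))
  # scale invariance: doubling areas and the standard changes nothing
  fr2 <- isotopologue_fractions(toy_peaks(c(2, 2, 4)), toy_standards(2))
  expect_equal(fr2$fraction, fr$fraction)
  expect_error(isotopologue_fractions(toy_peaks(c(0, 0, 0)), toy_standards()),
               "all-zero")
  expect_error(isotopologue_fractions(toy_peaks(c(1, 2), polarity = "pos"),
                                      toy_standards()[2, ]),
               "internal standard")
  # known metabolites are padded to their carbon count
  fr3 <- isotopologue_fractions(toy_peaks(c(1, 1), metabolite = "citrate"),
                                toy_standards())
  expect_equal(nrow(fr3), 7)
  expect_equal(sum(fr3$fraction), 1)
})

test_that("citrate ratio divides the M+5 by the M+4 fraction", {
  f <- c(0.3, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1)
  expect_equal(citrate_ratio(f), 0.5)
  f0 <- c(0.5, 0.2, 0.1, 0.1, 0, 0.1, 0)
  expect_error(citrate_ratio(f0), "undefined")
  expect_error(citrate_ratio(c(0.5, 0.5)), "6-carbon")
})

test_that("single-turn labeling identities hold exactly", {
  ox <- simulate_labeling(tracing_params(r = 0, a = 0, e = 1, turns = 1))
  expect_equal(unname(ox$citrate["M+4"]), 1)
  expect_equal(unname(ox$succinate["M+4"]), 1)
  expect_equal(unname(ox$glutamate["M+5"]), 1)
  expect_equal(citrate_ratio(ox$citrate), 0)
  red <- simulate_labeling(tracing_params(r = 1, a = 0, e = 1, turns = 1))
  expect_equal(unname(red$citrate["M+5"]), 1)
  # full anaplerotic dilution wipes the four-carbon label
  dil <- simulate_labeling(tracing_params(r = 0, a = 1, e = 1, turns = 1))
  expect_equal(unname(dil$succinate["M+0"]), 1)
})

test_that("simulated spectra live on the simplex for random parameters", {
  set.seed(1)
  for (i in 1:25) {
    pars <- tracing_params(r = runif(1), a = runif(1), e = runif(1),
                           turns = sample(1:5, 1))
    sim <- simulate_labeling(pars)
    for (f in sim) {
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_true(all(f >= -1e-12))
    }
  }
  expect_error(tracing_params(r = 1.2), "\\[0, 1\\]")
  expect_error(tracing_params(turns = 0), "turns")
})

test_that("the citrate ratio rises with the reductive fraction and M+0 with dilution", {
  rs <- seq(0, 1, length.out = 21)
  ratios <- vapply(rs, function(r)
    citrate_ratio(simulate_labeling(tracing_params(r = r, a = 0.2, e = 0.9,
                                                   turns = 3))$citrate),
    numeric(1))
  expect_true(all(diff(ratios) > 0))
  as_ <- seq(0, 1, length.out = 11)
  m0 <- vapply(as_, function(a)
    simulate_labeling(tracing_params(r = 0.2, a = a, e = 0.9,
                                     turns = 3))$succinate["M+0"],
    numeric(1))
  expect_true(all(diff(m0) > 0))
})

test_that("reductive fraction is recovered from simulated citrate spectra", {
  for (r in seq(0, 1, by = 0.1)) {
    obs <- simulate_labeling(tracing_params(r = r, a = 0.3, e = 0.9,
                                            turns = 3))$citrate
    fit <- fit_reductive_fraction(obs, a = 0.3, e = 0.9, turns = 3)
    expect_lt(abs(fit$r_hat - r), 1e-3)
    expect_true(fit$identifiable)
  }
  # boundary case stays at the boundary
  obs0 <- simulate_labeling(tracing_params(r = 0, a = 0.3, e = 0.9,
                                           turns = 3))$citrate
  expect_lte(fit_reductive_fraction(obs0, 0.3, 0.9, 3)$r_hat, 0.01)
  # noisy recovery: mean error under fraction noise sd 0.02
  set.seed(2)
  r_hats <- vapply(1:50, function(i) {
    f <- simulate_labeling(tracing_params(r = 0.4, a = 0.3, e = 0.9,
                                          turns = 3))$citrate
    f <- pmax(f + rnorm(7, 0, 0.02), 0); f <- f / sum(f)
    fit_reductive_fraction(f, 0.3, 0.9, 3)$r_hat
  }, numeric(1))
  expect_lt(abs(mean(r_hats) - 0.4), 0.05)
})

test_that("pool comparisons reproduce the exact rank-sum enumeration", {
  pools <- data.frame(sample = paste0("s", 1:6),
                      metabolite = "succinate",
                      total = c(1, 2, 3, 10, 11, 12))
  cond <- setNames(rep(c("ctrl", "ko"), each = 3), paste0("s", 1:6))
  res <- pool_size_compare(pools, cond)
  # full enumeration of C(6,3) equally likely rank splits: the observed
  # extreme split has two-sided p = 2/20
  expect_equal(res$p, 0.1)
  # identical groups are maximally non-significant
  pools$total <- rep(c(5, 6, 7), 2)
  expect_equal(suppressWarnings(pool_size_compare(pools, cond)$p), 1)
  # label swap leaves p unchanged
  cond2 <- setNames(rep(c("ko", "ctrl"), each = 3), paste0("s", 1:6))
  pools$total <- c(1, 2, 3, 10, 11, 12)
  expect_equal(pool_size_compare(pools, cond2)$p,
               pool_size_compare(pools, cond)$p)
  expect_error(pool_size_compare(pools[-1, ], cond), "3 samples")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  uni <- sprintf("m%02d", 1:20)
  res <- metabolite_set_enrichment(uni[1:5], uni,
                                   list(tca = uni[1:5], other = uni[11:15]))
  expect_equal(res$p[res$pathway == "tca"], 1 / choose(20, 5),
               tolerance = 1e-9)
  expect_equal(res$p[res$pathway == "tca"], 6.4503e-5, tolerance = 1e-4)
  # a pathway disjoint from the significant set can only give p = 1 when
  # it could never overlap less than observed
  expect_equal(res$p[res$pathway == "other"], 1)
  # brute-force enumeration oracle on a universe of 15
  uni2 <- sprintf("u%02d", 1:15)
  set.seed(3)
  for (i in 1:5) {
    sig <- sample(uni2, 6)
    pw <- sample(uni2, 7)
    k <- length(intersect(sig, pw))
    res2 <- metabolite_set_enrichment(sig, uni2, list(pw = pw))
    expect_equal(res2$p, hyper_enum_oracle(k, 7, 15, 6), tolerance = 1e-9)
  }
  expect_error(metabolite_set_enrichment("x", character(0), list()), "empty")
  expect_error(metabolite_set_enrichment("zz", uni, list()), "subset")
})
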
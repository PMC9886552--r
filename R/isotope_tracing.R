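# [U-13C]glutamine isotopologue analytics: fractions from peak areas, the
# M+5/M+4 citrate ratio, a discrete-turn TCA label-propagation simulator,
# reductive-fraction fitting, pool comparisons and metabolite-set
# enrichment.

# carbon counts of the metabolites the simulator and ratio logic know about
METABOLITE_CARBONS <- c(glutamine = 5L, glutamate = 5L, oxoglutarate = 5L,
                        succinate = 4L, fumarate = 4L, malate = 4L,
                        citrate = 6L)

#' Isotopologue fractions from a peak-area table
#'
#' Normalizes raw areas to the sample's matching-polarity internal
#' standard, imputes missing isotopologues as zero area, and converts each
#' (sample, metabolite) block to fractions `f_i = A_i / sum(A_j)` over
#' M+0..M+n, where n is the metabolite's carbon count when known and the
#' largest observed index otherwise.
#'
#' @param peaks data frame with columns `sample`, `metabolite`,
#'   `isotopologue` (integer i of M+i), `area` (>= 0), `polarity`
#'   (`"pos"`/`"neg"`).
#' @param standards data frame with columns `sample`, `polarity`, `area`:
#'   the internal-standard area per sample and polarity.
#' @return data frame `sample`, `metabolite`, `isotopologue`, `fraction`;
#'   fractions within each (sample, metabolite) sum to 1.
#' @export
isotopologue_fractions <- function(peaks, standards) {
  need <- c("sample", "metabolite", "isotopologue", "area", "polarity")
  if (!all(need %in% names(peaks)))
    stop_input("peaks must have columns: ", paste(need, collapse = ", "))
  if (any(peaks$area < 0)) stop_input("negative peak area")
  key <- paste(standards$sample, standards$polarity)
  is_area <- standards$area[match(paste(peaks$sample, peaks$polarity), key)]
  if (anyNA(is_area))
    stop_input("missing internal standard for some (sample, polarity)")
  if (any(is_area <= 0)) stop_input("internal standard area must be positive")
  peaks$norm <- peaks$area / is_area
  out <- list()
  for (blk in split(peaks, list(peaks$sample, peaks$metabolite), drop = TRUE)) {
    met <- blk$metabolite[1]
    n_c <- METABOLITE_CARBONS[met]
    if (is.na(n_c)) n_c <- max(blk$isotopologue)
    if (any(blk$isotopologue > n_c))
      stop_input("isotopologue index above carbon count for ", met)
    f <- numeric(n_c + 1L)
    f[blk$isotopologue + 1L] <- f[blk$isotopologue + 1L] + blk$norm
    if (sum(f) == 0)
      stop_input("all-zero areas for metabolite '", met, "' in sample '",
                 blk$sample[1], "'")
    out[[length(out) + 1L]] <- data.frame(
      sample = blk$sample[1], metabolite = met,
      isotopologue = 0:n_c, fraction = f / sum(f), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' M+5/M+4 citrate ratio
#'
#' Index of reductive carboxylation: under [U-13C]glutamine, M+5 citrate
#' arises from the reductive route (oxoglutarate carboxylated directly to
#' citrate) whereas M+4 citrate arises from an oxidative turn, so the
#' ratio `f_5 / f_4` increases with the reductive preference.
#'
#' @param fractions numeric fraction vector for a 6-carbon metabolite
#'   (`f_0..f_6`, names optional), or a data frame from
#'   [isotopologue_fractions()] restricted to one (sample, metabolite).
#' @return scalar ratio.
#' @export
citrate_ratio <- function(fractions) {
  if (is.data.frame(fractions)) {
    f <- fractions$fraction[order(fractions$isotopologue)]
  } else f <- as.numeric(fractions)
  if (length(f) < 6) stop_input("need a 6-carbon isotopologue vector")
  f4 <- f[5]; f5 <- f[6]
  if (f4 == 0) stop_input("M+4 fraction is zero; ratio undefined")
  f5 / f4
}

#' Parameters of the TCA label-propagation simulator
#'
#' @param r reductive-flux fraction in `[0, 1]`: share of oxoglutarate
#'   carboxylated directly to citrate instead of turning oxidatively.
#' @param a unlabeled anaplerotic inflow fraction at succinyl-CoA in
#'   `[0, 1]` (e.g. from methylmalonyl-CoA); dilutes the labeled
#'   four-carbon pool.
#' @param e 13C enrichment of the glutamine source in `[0, 1]`.
#' @param turns number of discrete cycle turns (>= 1).
#' @return validated parameter list of class `tracing_params`.
#' @export
tracing_params <- function(r = 0.1, a = 0.3, e = 0.9, turns = 3L) {
  if (r < 0 || r > 1 || a < 0 || a > 1 || e < 0 || e > 1)
    stop_input("r, a and e must be in [0, 1]")
  turns <- as.integer(turns)
  if (turns < 1) stop_input("turns must be >= 1")
  structure(list(r = r, a = a, e = e, turns = turns),
            class = "tracing_params")
}

# Remove one carbon from a distribution over M+0..M+n: a random carbon is
# lost, so M+i -> M+(i-1) with probability i/n (fully labeled species lose
# a labeled carbon with certainty, matching oxidative decarboxylation of
# M+5 oxoglutarate to M+4 succinyl-CoA).
drop_one_carbon <- function(f) {
  n <- length(f) - 1L
  i <- 0:n
  out <- numeric(n)        # over M+0 .. M+(n-1)
  keep <- f * (1 - i / n)
  lose <- f * (i / n)
  out <- keep[1:n] + lose[2:(n + 1L)]
  out / sum(out)
}

# extend a distribution with k unlabeled carbons (M+i index unchanged)
add_unlabeled_carbons <- function(f, k) c(f, numeric(k))

#' Forward simulation of TCA labeling from [U-13C]glutamine
#'
#' Discrete-turn label propagation: glutamate and oxoglutarate start fully
#' labeled (M+5) at the source enrichment `e`. Each turn, the oxidative
#' branch (weight `1 - r`) decarboxylates oxoglutarate to the four-carbon
#' pool (M+5 -> M+4), which is diluted by the unlabeled anaplerotic inflow
#' `a` and read out as succinate, fumarate and malate; condensation with
#' unlabeled acetyl-CoA yields M+4 citrate. The reductive branch (weight
#' `r`) carboxylates M+5 oxoglutarate directly to M+5 citrate. For later
#' turns the citrate pool is decarboxylated back to oxoglutarate, diluting
#' label progressively. Reported distributions are averages over turns,
#' emulating sampling of a pool fed continuously across cycles.
#'
#' @param params a [tracing_params()] object.
#' @return named list of fraction vectors (`M+0..M+n`, summing to 1) for
#'   glutamate, oxoglutarate, succinate, fumarate, malate and citrate.
#' @export
simulate_labeling <- function(params) {
  stopifnot(inherits(params, "tracing_params"))
  r <- params$r; a <- params$a; e <- params$e
  fresh5 <- c(1 - e, 0, 0, 0, 0, e)          # glutamine-derived, M+0/M+5
  og <- fresh5
  acc <- list(og = 0, four = 0, cit = 0)
  for (t in seq_len(params$turns)) {
    four <- drop_one_carbon(og)              # oxoglutarate -> succinyl-CoA
    four <- (1 - a) * four + a * c(1, numeric(length(four) - 1L))
    cit_ox <- add_unlabeled_carbons(four, 2L)    # + unlabeled acetyl-CoA
    cit_red <- add_unlabeled_carbons(og, 1L)     # carboxylation, +CO2
    cit <- (1 - r) * cit_ox + r * cit_red
    acc$og <- acc$og + og
    acc$four <- acc$four + four
    acc$cit <- acc$cit + cit
    og <- drop_one_carbon(cit)               # recycle for the next turn
  }
  norm <- function(f) f / sum(f)
  og_out <- norm(acc$og / params$turns)
  four_out <- norm(acc$four / params$turns)
  cit_out <- norm(acc$cit / params$turns)
  label_names <- function(f) stats::setNames(f, paste0("M+", seq_along(f) - 1L))
  list(glutamate = label_names(fresh5),
       oxoglutarate = label_names(og_out),
       succinate = label_names(four_out),
       fumarate = label_names(four_out),
       malate = label_names(four_out),
       citrate = label_names(cit_out))
}

#' Estimate the reductive-flux fraction from an observed citrate spectrum
#'
#' Least-squares fit of the simulator's citrate isotopologue distribution
#' to an observed one over the reductive fraction `r`, on a coarse grid
#' refined by golden-section search. Flags non-identifiability when the
#' objective is nearly flat across the grid.
#'
#' @param observed numeric citrate fraction vector `f_0..f_6` (sums to 1).
#' @param a,e,turns remaining simulator parameters, assumed known.
#' @param flat_tol objective range below which the fit is flagged
#'   non-identifiable.
#' @return list `r_hat`, `residual` (sum of squared fraction errors),
#'   `identifiable` (logical).
#' @export
fit_reductive_fraction <- function(observed, a, e, turns = 3L,
                                   flat_tol = 1e-8) {
  observed <- as.numeric(observed)
  if (length(observed) != 7 || abs(sum(observed) - 1) > 1e-6)
    stop_input("observed must be a 7-element citrate fraction vector")
  obj <- function(r) {
    sim <- simulate_labeling(tracing_params(r = r, a = a, e = e,
                                            turns = turns))
    sum((sim$citrate - observed)^2)
  }
  grid <- seq(0, 1, by = 0.02)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-8)
  r_hat <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
  list(r_hat = min(max(r_hat, 0), 1),
       residual = min(opt$objective, vals[i]),
       identifiable = diff(range(vals)) > flat_tol)
}

#' Per-metabolite pool-size comparison between two conditions
#'
#' Two-sided Wilcoxon rank-sum test of per-sample metabolite totals
#' between two condition labels (exact for small groups without ties,
#' normal approximation otherwise, as in [stats::wilcox.test()]).
#'
#' @param pools data frame with columns `sample`, `metabolite`, `total`.
#' @param condition named vector mapping sample to one of two conditions.
#' @return data frame `metabolite`, `p`, `n1`, `n2`.
#' @export
pool_size_compare <- function(pools, condition) {
  cond <- condition[pools$sample]
  levs <- unique(stats::na.omit(as.character(cond)))
  if (length(levs) != 2) stop_input("need exactly two conditions")
  rows <- lapply(split(pools, pools$metabolite), function(blk) {
    g <- as.character(condition[blk$sample])
    x <- blk$total[g == levs[1]]; y <- blk$total[g == levs[2]]
    if (length(x) < 3 || length(y) < 3)
      stop_input("fewer than 3 samples per condition for ",
                 blk$metabolite[1])
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    data.frame(metabolite = blk$metabolite[1], p = p,
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric metabolite-set enrichment
#'
#' Upper-tail hypergeometric (over-representation) test of a significant
#' metabolite set against pathway definitions intersected with the
#' measured universe, with Benjamini-Hochberg adjustment across pathways.
#'
#' @param significant character vector, subset of `universe`.
#' @param universe character vector of all measured metabolites.
#' @param pathways named list of pathway member vectors.
#' @return data frame `pathway`, `overlap`, `pathway_size`, `p`, `p_adj`.
#' @export
metabolite_set_enrichment <- function(significant, universe, pathways) {
  if (length(universe) == 0) stop_input("empty universe")
  if (!all(significant %in% universe))
    stop_input("significant set must be a subset of the universe")
  N <- length(unique(universe))
  n_sig <- length(unique(significant))
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    K <- length(members)
    k <- length(intersect(members, significant))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n_sig, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, pathway_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
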
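# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# z-score a vector; constant input -> error unless allow_constant
zscore <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop_input("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

# Derive k reproducible 31-bit sub-seeds from one master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(seed, k, labels = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max, k)
  if (!is.null(labels)) names(s) <- labels
  s
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# All permutations of 1..n as an (n!) x n matrix; n must be small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- nrow(sub)
    idx <- row:(row + blk - 1L)
    out[idx, pos] <- n
    out[idx, setdiff(seq_len(n), pos)] <- sub
    row <- row + blk
  }
  out
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && all(x %in% c(0, 1))
}
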
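#' Random Gaussian energy tables
#'
#' I.i.d. normal one- and two-body energies, mean 0 and standard deviation
#' `scale`; a generic rugged design landscape for solver stress tests.
#'
#' @param n residue count.
#' @param alphabet design alphabet.
#' @param scale standard deviation of table entries (kcal/mol).
#' @param seed integer seed; the same seed reproduces identical tables.
#' @return `energy_tables`.
#' @export
make_random_tables <- function(n, alphabet = default_alphabet(), scale = 1, seed) {
  if (scale <= 0) abort_usage("scale must be positive")
  A <- length(alphabet)
  with_seed(seed, {
    ob <- matrix(stats::rnorm(n * A, sd = scale), n, A)
    tb <- array(0, dim = c(A, n, A, n))
    pr <- pair_index(n)
    for (k in seq_len(nrow(pr)))
      tb[, pr[k, 1L], , pr[k, 2L]] <- matrix(stats::rnorm(A * A, sd = scale), A, A)
    energy_tables(ob, tb, alphabet, conformation_id = sprintf("random-%d", seed))
  })
}

#' Planted-optimum energy tables
#'
#' Constructs tables whose unique global Potts minimum is a known sequence:
#' planted letters cost 0 one-body energy, every other letter costs at
#' least `gap`, and two-body entries are uniform noise small enough
#' (`< gap / (8 n)` at `noise_scale = 1`) that at the default weighting
#' `lambda = 0.01` the planted sequence beats every competitor by at least
#' `gap / 2`.  For small search spaces the margin is verified by exhaustive
#' enumeration at construction time.
#'
#' @inheritParams make_random_tables
#' @param planted_sequence the sequence to plant (default: random).
#' @param gap score-unit margin parameter (> 0).
#' @param noise_scale multiplier on the two-body noise band.
#' @param verify enumerate and check the margin when the space is small.
#' @return `energy_tables` with attribute `planted` (the sequence).
#' @export
make_planted_tables <- function(n, alphabet = default_alphabet(), planted_sequence = NULL,
                                gap = 2, noise_scale = 1, seed, verify = TRUE) {
  if (gap <= 0) abort_usage("gap must be positive")
  A <- length(alphabet)
  out <- with_seed(seed, {
    planted <- if (is.null(planted_sequence)) sample(alphabet, n, replace = TRUE)
               else as_residues(planted_sequence, alphabet)
    if (length(planted) != n) abort_usage("planted sequence length != n")
    pidx <- match(planted, alphabet)
    ob <- gap * (1 + matrix(stats::runif(n * A, 0, 0.5), n, A))
    ob[cbind(seq_len(n), pidx)] <- 0
    band <- noise_scale * gap / (8 * n)
    tb <- array(0, dim = c(A, n, A, n))
    pr <- pair_index(n)
    for (k in seq_len(nrow(pr)))
      tb[, pr[k, 1L], , pr[k, 2L]] <- matrix(stats::runif(A * A, -band, band), A, A)
    t <- energy_tables(ob, tb, alphabet, conformation_id = sprintf("planted-%d", seed))
    attr(t, "planted") <- planted
    t
  })
  if (verify && A^n <= 20000) {
    model <- potts_model(out, lambda = 0.01)
    sc <- enumerate_scores(model)
    best <- which.min(sc$score)
    if (!identical(idx_to_seq(sc$idx[best, ], alphabet), attr(out, "planted")))
      abort_numeric("planted construction failed: optimum is not the planted sequence")
    margin <- min(sc$score[-best]) - sc$score[best]
    if (margin < gap / 2)
      abort_numeric(sprintf("planted margin %.3g below gap/2", margin))
  }
  out
}

#' Degenerate energy tables with planted near-optimal alternates
#'
#' Builds a landscape with a unique global optimum plus `k_alternates`
#' planted sequences (single mutants of the optimum) lying exactly `window`
#' score units above it, while every other sequence is at least `2 * window`
#' worse.  Two-body entries are zero so the construction is exact at any
#' `lambda`.  Used to exercise the near-optimal-window harvesting rule.
#'
#' @inheritParams make_random_tables
#' @param k_alternates number of planted alternates (<= `n * (|alphabet|-1)`).
#' @param window score offset of the alternates (> 0).
#' @param verify enumerate and check the construction when the space is small.
#' @return `energy_tables` with attributes `planted` (optimal sequence) and
#'   `alternates` (list of planted near-optimal sequences).
#' @export
make_degenerate_tables <- function(n, alphabet = default_alphabet(), k_alternates,
                                   window = 5, seed, verify = TRUE) {
  if (window <= 0) abort_usage("window must be positive")
  A <- length(alphabet)
  if (k_alternates < 1 || k_alternates > n * (A - 1))
    abort_usage("k_alternates out of range for this n and alphabet")
  out <- with_seed(seed, {
    pidx <- sample.int(A, n, replace = TRUE)
    planted <- alphabet[pidx]
    mutants <- expand.grid(pos = seq_len(n), aa = seq_len(A))
    mutants <- mutants[mutants$aa != pidx[mutants$pos], ]
    pick <- mutants[sample.int(nrow(mutants), k_alternates), ]
    ob <- matrix(0, n, A)
    ob[cbind(seq_len(n), pidx)] <- 0
    other <- !(col(ob) == pidx[row(ob)])
    ob[other] <- 3 * window + matrix(stats::runif(n * A, 0, window), n, A)[other]
    ob[cbind(pick$pos, pick$aa)] <- window
    alts <- lapply(seq_len(nrow(pick)), function(r) {
      s <- planted
      s[pick$pos[r]] <- alphabet[pick$aa[r]]
      s
    })
    t <- energy_tables(ob, array(0, dim = c(A, n, A, n)), alphabet,
                       conformation_id = sprintf("degenerate-%d", seed))
    attr(t, "planted") <- planted
    attr(t, "alternates") <- alts
    t
  })
  if (verify && A^n <= 20000) {
    model <- potts_model(out, lambda = 0.01)
    sc <- enumerate_scores(model)
    best <- which.min(sc$score)
    stopifnot(identical(idx_to_seq(sc$idx[best, ], alphabet), attr(out, "planted")))
    inwin <- which(sc$score - sc$score[best] <= window + 1e-9 &
                   sc$score - sc$score[best] > 1e-9)
    keys <- sort(vapply(inwin, function(r) seq_key(idx_to_seq(sc$idx[r, ], alphabet)), ""))
    want <- sort(vapply(attr(out, "alternates"), seq_key, ""))
    if (!identical(keys, want))
      abort_numeric("degenerate construction failed enumeration check")
  }
  out
}
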
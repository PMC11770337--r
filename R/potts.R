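#' Energy tables for a fixed conformation
#'
#' Container for the one-body energies `E[i, alpha]` (residue against the
#' plastic surface, the peptide backbone and itself) and the two-body
#' energies `E[i, alpha, j, beta]` (side chain against side chain) of a
#' single frozen system conformation, in kcal/mol.  Two-body energies are
#' defined for unordered residue pairs; the constructor accepts entries for
#' `i < j` and keeps a symmetrized array so reads in either order agree.
#'
#' @param one_body numeric matrix `n x |alphabet|`.
#' @param two_body numeric array `|alphabet| x n x |alphabet| x n`; entries
#'   with `i < j` are authoritative, the rest are filled by symmetry and the
#'   `i = j` diagonal is forced to zero.
#' @param alphabet design alphabet.
#' @param conformation_id free-text identifier of the conformation.
#' @return object of class `energy_tables`.
#' @export
energy_tables <- function(one_body, two_body, alphabet = default_alphabet(),
                          conformation_id = "unnamed") {
  n <- nrow(one_body)
  A <- length(alphabet)
  if (ncol(one_body) != A) abort_usage("one_body width != alphabet size")
  if (!all(dim(two_body) == c(A, n, A, n))) abort_usage("two_body has wrong dimensions")
  if (!all(is.finite(one_body)) || !all(is.finite(two_body)))
    abort_data("energy tables must be finite")
  tb <- array(0, dim = c(A, n, A, n))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    tb[, i, , j] <- two_body[, i, , j]
    tb[, j, , i] <- t(two_body[, i, , j])
  }
  dimnames(one_body) <- NULL      # bare matrix: scalar reads must stay unnamed
  structure(list(n = n, alphabet = alphabet, one_body = one_body,
                 two_body = tb, conformation_id = conformation_id),
            class = "energy_tables")
}

#' @export
print.energy_tables <- function(x, ...) {
  cat(sprintf("energy_tables: n = %d residues, |alphabet| = %d, conformation '%s'\n",
              x$n, length(x$alphabet), x$conformation_id))
  invisible(x)
}

#' Read a one-body energy
#' @param tables `energy_tables`.
#' @param i residue index (1-based).
#' @param alpha amino-acid letter.
#' @export
one_body_at <- function(tables, i, alpha) {
  tables$one_body[i, match(alpha, tables$alphabet)]
}

#' Read a two-body energy (symmetrized)
#' @inheritParams one_body_at
#' @param j second residue index; must differ from `i`.
#' @param beta amino-acid letter at `j`.
#' @export
two_body_at <- function(tables, i, alpha, j, beta) {
  if (i == j) abort_usage("two-body energy requires i != j")
  tables$two_body[match(alpha, tables$alphabet), i,
                  match(beta, tables$alphabet), j]
}

#' Potts scoring model
#'
#' Couples energy tables with the intramolecular weighting `lambda`
#' (dimensionless, default 0.01) and a constant penalty offset `penalty`
#' (kcal/mol, default 0).  The score of a sequence is
#' `sum_i E[i, s_i] + lambda * sum_{i<j} E[i, s_i, j, s_j] + penalty`;
#' lower scores mean higher predicted plastic affinity.  The constant
#' offset cannot change the minimizer; it is kept because reported scores
#' are compared across (`lambda`, `penalty`) grid cells.
#'
#' @param tables `energy_tables`.
#' @param lambda non-negative scaling of two-body terms.
#' @param penalty constant score offset.
#' @return object of class `potts_model`.
#' @export
potts_model <- function(tables, lambda = 0.01, penalty = 0) {
  if (!inherits(tables, "energy_tables")) abort_usage("tables must be energy_tables")
  if (lambda < 0) abort_usage("lambda must be >= 0")
  structure(list(tables = tables, lambda = lambda, penalty = penalty),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("potts_model: n = %d, lambda = %g, penalty = %g\n",
              x$tables$n, x$lambda, x$penalty))
  invisible(x)
}

# Pair index helper: rows (i, j) for all i < j.
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
}

potts_score_idx <- function(model, idx) {
  tb <- model$tables
  ob <- sum(tb$one_body[cbind(seq_along(idx), idx)])
  pr <- pair_index(tb$n)
  twob <- if (nrow(pr) > 0L)
    sum(tb$two_body[cbind(idx[pr[, 1L]], pr[, 1L], idx[pr[, 2L]], pr[, 2L])])
  else 0
  ob + model$lambda * twob + model$penalty
}

#' Potts score of a sequence
#'
#' @param model `potts_model`.
#' @param seq sequence (string or character vector) of length `model$tables$n`.
#' @return score in kcal/mol (lower is better).
#' @export
#' @examples
#' tb <- make_random_tables(n = 4, alphabet = c("A", "C", "D"), scale = 1, seed = 1)
#' potts_score(potts_model(tb), c("A", "C", "A", "D"))
potts_score <- function(model, seq) {
  res <- as_residues(seq, model$tables$alphabet)
  if (length(res) != model$tables$n)
    abort_usage(sprintf("sequence length %d != table size %d", length(res), model$tables$n))
  potts_score_idx(model, match(res, model$tables$alphabet))
}

# Conditional one-body field: F[i, b] = E[i,b] + lambda * sum_{j != i} E[i,b,j,s_j].
# Changing residue i from a to b changes the score by F[i,b] - F[i,a];
# the solvers keep F incrementally up to date.
score_field <- function(model, idx) {
  tb <- model$tables
  n <- tb$n
  A <- length(tb$alphabet)
  F <- t(tb$one_body)              # A x n
  for (i in seq_len(n)) {
    acc <- numeric(A)
    for (j in seq_len(n)) if (j != i) acc <- acc + tb$two_body[, i, idx[j], j]
    F[, i] <- F[, i] + model$lambda * acc
  }
  F
}

# Update field after residue i changes a -> b.
score_field_update <- function(F, model, idx, i, a, b) {
  tb <- model$tables
  for (j in seq_len(tb$n)) if (j != i)
    F[, j] <- F[, j] + model$lambda * (tb$two_body[, j, b, i] - tb$two_body[, j, a, i])
  F
}

#' Write energy tables to tidy CSV with a JSON sidecar
#'
#' One row per table entry: columns `i, j, alpha, beta, energy`; one-body
#' rows leave `j` and `beta` empty.  Only `i < j` pairs are written.  The
#' sidecar `<path>.json` records `n`, the alphabet, the conformation id and
#' optionally the model weighting.
#'
#' @param tables `energy_tables`.
#' @param path CSV output path.
#' @param lambda,penalty optional model parameters recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_energy_tables <- function(tables, path, lambda = NULL, penalty = NULL) {
  n <- tables$n
  A <- tables$alphabet
  ob <- expand.grid(alpha = seq_along(A), i = seq_len(n))
  one <- data.frame(i = as.vector(ob$i), j = NA_integer_,
                    alpha = as.vector(A[ob$alpha]), beta = NA_character_,
                    energy = as.vector(tables$one_body[cbind(ob$i, ob$alpha)]),
                    row.names = NULL)
  pr <- pair_index(n)
  rows <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    g <- expand.grid(beta = seq_along(A), alpha = seq_along(A))
    rows[[k]] <- data.frame(i = i, j = j,
                            alpha = as.vector(A[g$alpha]), beta = as.vector(A[g$beta]),
                            energy = as.vector(tables$two_body[cbind(g$alpha, i, g$beta, j)]),
                            row.names = NULL)
  }
  out <- rbind(one, do.call(rbind, rows))
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  sidecar <- list(n = n, alphabet = A, conformation_id = tables$conformation_id)
  if (!is.null(lambda)) sidecar$lambda <- lambda
  if (!is.null(penalty)) sidecar$penalty <- penalty
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read energy tables written by [write_energy_tables()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return `energy_tables`; sidecar `lambda`/`penalty`, when present, are
#'   attached as attributes.
#' @export
read_energy_tables <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(i = "integer", j = "integer",
                                       alpha = "character", beta = "character",
                                       energy = "numeric"))
  n <- side$n
  A <- side$alphabet
  ob <- matrix(0, n, length(A))
  tb <- array(0, dim = c(length(A), n, length(A), n))
  is_one <- is.na(df$j)
  d1 <- df[is_one, ]
  ob[cbind(d1$i, match(d1$alpha, A))] <- d1$energy
  d2 <- df[!is_one, ]
  if (nrow(d2) > 0L)
    tb[cbind(match(d2$alpha, A), d2$i, match(d2$beta, A), d2$j)] <- d2$energy
  out <- energy_tables(ob, tb, alphabet = A, conformation_id = side$conformation_id)
  attr(out, "lambda") <- side$lambda
  attr(out, "penalty") <- side$penalty
  out
}
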
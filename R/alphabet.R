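#' Design alphabet
#'
#' The default design alphabet contains the 20 natural amino acids minus
#' proline (whose backbone constraint is incompatible with a fixed-backbone
#' design), in fixed alphabetical one-letter order.  All tables, QUBO
#' variables and policy outputs index amino acids in this order.
#'
#' @return character vector of 19 one-letter codes.
#' @export
#' @examples
#' default_alphabet()
default_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "Q", "R", "S", "T", "V", "W", "Y")
}

# Normalise a sequence given as a single string or a character vector of
# one-letter codes; validate against the alphabet.
as_residues <- function(seq, alphabet = default_alphabet()) {
  if (is.character(seq) && length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "")[[1]]
  if (!is.character(seq)) abort_usage("sequence must be a character vector or string")
  bad <- setdiff(unique(seq), alphabet)
  if (length(bad) > 0L)
    abort_usage(sprintf("letters not in alphabet: %s", paste(bad, collapse = ", ")))
  seq
}

seq_to_idx <- function(seq, alphabet = default_alphabet()) {
  match(as_residues(seq, alphabet), alphabet)
}

idx_to_seq <- function(idx, alphabet = default_alphabet()) alphabet[idx]

seq_key <- function(seq) paste(seq, collapse = "")

#' Random peptide sequence
#'
#' @param n peptide length.
#' @param alphabet design alphabet.
#' @param seed integer seed.
#' @return character vector of length `n`.
#' @export
random_sequence <- function(n, alphabet = default_alphabet(), seed) {
  with_seed(seed, sample(alphabet, n, replace = TRUE))
}

#' One-hot assignment matrix for a sequence
#'
#' Realizes the binary occupation variables of the Potts model: entry
#' `(i, alpha)` is 1 iff residue `i` carries amino acid `alpha`.
#'
#' @param seq sequence (string or character vector).
#' @param alphabet design alphabet.
#' @return integer matrix `n x length(alphabet)` with unit row sums.
#' @export
assignment_from_sequence <- function(seq, alphabet = default_alphabet()) {
  idx <- seq_to_idx(seq, alphabet)
  m <- matrix(0L, nrow = length(idx), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Validate a one-hot assignment matrix
#'
#' @param a binary matrix, residues in rows, amino acids in columns.
#' @return list with `feasible` (logical) and `bad_rows` (integer vector of
#'   rows whose sum differs from 1).
#' @export
validate_assignment <- function(a) {
  if (!is.matrix(a) || !all(a %in% c(0L, 1L)))
    abort_usage("assignment must be a binary matrix")
  rs <- rowSums(a)
  list(feasible = all(rs == 1L), bad_rows = which(rs != 1L))
}

#' Decode a one-hot assignment into a sequence
#'
#' @inheritParams validate_assignment
#' @param alphabet design alphabet (must match `ncol(a)`).
#' @return list with `feasible`; if feasible, `sequence`; otherwise
#'   `bad_rows` naming the offending rows.
#' @export
sequence_from_assignment <- function(a, alphabet = default_alphabet()) {
  if (ncol(a) != length(alphabet)) abort_usage("assignment width != alphabet size")
  v <- validate_assignment(a)
  if (!v$feasible) return(list(feasible = FALSE, bad_rows = v$bad_rows))
  list(feasible = TRUE, sequence = alphabet[apply(a, 1L, which.max)])
}
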
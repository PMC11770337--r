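#' Side-chain and terminal pKa set
#'
#' EMBOSS-style values; swappable for other conventions.
#'
#' @return list with named vectors `positive` (K, R, H, Nterm) and
#'   `negative` (D, E, C, Y, Cterm).
#' @export
default_pka_set <- function() {
  list(positive = c(K = 10.8, R = 12.5, H = 6.5, Nterm = 8.6),
       negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, Cterm = 3.6))
}

#' Net peptide charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains and both termini:
#' basic groups contribute `1 / (1 + 10^(pH - pKa))`, acidic groups
#' `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param seq sequence (string or character vector).
#' @param pH in [0, 14].
#' @param pkas pKa set (see [default_pka_set()]).
#' @return net charge in elementary units.
#' @export
net_charge <- function(seq, pH = 7, pkas = default_pka_set()) {
  if (pH < 0 || pH > 14) abort_usage("pH must be in [0, 14]")
  res <- as_residues(seq)
  pos_pka <- c(pkas$positive[match(res, names(pkas$positive), nomatch = 0)],
               pkas$positive[["Nterm"]])
  neg_pka <- c(pkas$negative[match(res, names(pkas$negative), nomatch = 0)],
               pkas$negative[["Cterm"]])
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point
#'
#' Bisection on [net_charge()] over pH 0..14; the termini guarantee both a
#' positive and a negative group, and the charge is strictly decreasing in
#' pH, so the root is unique.
#'
#' @inheritParams net_charge
#' @param tol charge tolerance at the returned pH.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pkas = default_pka_set(), tol = 1e-4) {
  lo <- 0; hi <- 14
  for (k in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pkas)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

residue_mass_table <- function(kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  if (kind == "average")
    c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
      G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
      M = 131.1926, N = 114.1038, Q = 128.1307, R = 156.1875, S = 87.0782,
      T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
  else
    c(A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
      G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
      M = 131.04049, N = 114.04293, Q = 128.05858, R = 156.10111, S = 87.03203,
      T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)
}

water_mass <- function(kind = c("average", "monoisotopic")) {
  if (match.arg(kind) == "average") 18.01528 else 18.010565
}

#' Peptide molecular mass
#'
#' Sum of residue masses plus one water.
#'
#' @inheritParams net_charge
#' @param kind `"average"` (default) or `"monoisotopic"` mass table.
#' @return mass in Da; the empty sequence returns the mass of water.
#' @export
molecular_mass <- function(seq, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  if (length(seq) == 1L && !nzchar(seq)) seq <- character(0)
  if (length(seq) == 0L) return(water_mass(kind))
  res <- as_residues(seq)
  tab <- residue_mass_table(kind)
  sum(tab[res]) + water_mass(kind)
}

kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Composition-based solubility proxy
#'
#' A simple, clearly labelled stand-in score (NOT the CamSol intrinsic
#' solubility method): minus the mean Kyte-Doolittle hydropathy plus half
#' the absolute per-residue net charge at pH 7.  Higher values indicate a
#' more soluble composition; the score depends only on composition, not on
#' residue order.
#'
#' @inheritParams net_charge
#' @return dimensionless score.
#' @export
solubility_proxy <- function(seq, pkas = default_pka_set()) {
  res <- as_residues(seq)
  -mean(kyte_doolittle()[res]) + 0.5 * abs(net_charge(res, 7, pkas)) / length(res)
}

#' Physicochemical profile of one or more peptides
#'
#' @param seqs character vector of sequences (strings).
#' @param pkas pKa set.
#' @return data.frame with `sequence`, `net_charge` (pH 7), `pI`, `mass`
#'   and `solubility_proxy` per peptide.
#' @export
property_profile <- function(seqs, pkas = default_pka_set()) {
  rows <- lapply(seqs, function(s) {
    r <- as_residues(s)
    data.frame(sequence = seq_key(r),
               net_charge = net_charge(r, 7, pkas),
               pI = isoelectric_point(r, pkas),
               mass = molecular_mass(r),
               solubility_proxy = solubility_proxy(r, pkas),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Amino-acid frequencies over a sequence set
#'
#' @param seqs non-empty character vector (or list) of sequences.
#' @param alphabet design alphabet.
#' @return list with `counts`, `freq` (sums to 1) and `total`.
#' @export
aa_frequency <- function(seqs, alphabet = default_alphabet()) {
  if (length(seqs) == 0L) abort_usage("empty sequence set")
  res <- unlist(lapply(seqs, as_residues, alphabet = alphabet))
  counts <- vapply(alphabet, function(a) sum(res == a), 0)
  list(counts = counts, freq = counts / sum(counts), total = sum(counts))
}

#' Welch two-sample t test (unequal variances)
#'
#' Two-tailed; Welch-Satterthwaite degrees of freedom.  When both samples
#' have zero variance and equal means, `p = 1` by convention.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort_usage("each sample needs n >= 2")
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-bin amino-acid preference table
#'
#' For each environment bin, reports the modal amino acid, but only when it
#' occurs in more than one third of the residues in that bin; modal ties
#' are suppressed (reported as none with a tie flag).
#'
#' @param env data.frame with columns `bin_key` and `aa` (one row per
#'   residue observation).
#' @param threshold minimum frequency for reporting (default 1/3,
#'   exclusive).
#' @return data.frame with `bin_key`, `aa` (NA when no preference),
#'   `count`, `total`, `tie`.
#' @export
environment_preference <- function(env, threshold = 1 / 3) {
  if (!all(c("bin_key", "aa") %in% names(env)))
    abort_usage("env needs columns bin_key and aa")
  rows <- lapply(split(env$aa, env$bin_key), function(aas) {
    tab <- sort(table(aas), decreasing = TRUE)
    total <- length(aas)
    tie <- length(tab) > 1L && tab[1L] == tab[2L]
    ok <- !tie && tab[1L] / total > threshold
    data.frame(aa = if (ok) names(tab)[1L] else NA_character_,
               count = as.integer(tab[1L]), total = total, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(bin_key = names(rows), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences (gaps removed).
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  fa <- tryCatch(bio3d::read.fasta(path),
                 error = function(e)
                   abort_data(sprintf("FASTA parse failed: %s", conditionMessage(e))))
  seqs <- apply(fa$ali, 1L, function(r) paste(r[r != "-" & !is.na(r)], collapse = ""))
  if (length(seqs) == 0L || all(!nzchar(seqs))) abort_data("FASTA contains no sequences")
  seqs
}

#' Write peptide sequences to FASTA
#'
#' @param seqs character vector of sequences.
#' @param path output file.
#' @param ids sequence identifiers.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path, ids = names(seqs)) {
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  ali <- do.call(rbind, lapply(seqs, function(s) as_residues(s)))
  bio3d::write.fasta(ids = ids, seqs = ali, file = path)
  invisible(path)
}
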
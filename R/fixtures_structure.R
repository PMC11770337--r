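# Ideal backbone internal coordinates (Angstrom / degrees).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5)

# Fully extended backbone (phi = psi = omega = 180) with one CB per
# non-glycine residue, lying in the z = 0 plane.
extended_backbone <- function(sequence) {
  n <- length(sequence)
  g <- BB_GEOM
  rows <- list()
  addr <- function(name, resno, resname, p)
    data.frame(name = name, resno = resno, resname = resname,
               x = p[1], y = p[2], z = p[3],
               element = substr(name, 1L, 1L), stringsAsFactors = FALSE)
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL", W = "TRP",
           Y = "TYR")
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(-cos(th), sin(th), 0)
  for (k in seq_len(n)) {
    r3 <- aa3[sequence[k]]
    rows[[length(rows) + 1L]] <- addr("N", k, r3, N)
    rows[[length(rows) + 1L]] <- addr("CA", k, r3, CA)
    rows[[length(rows) + 1L]] <- addr("C", k, r3, C)
    Nn <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, 180)   # psi = 180
    rows[[length(rows) + 1L]] <- addr("O", k, r3, place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, 0))
    if (sequence[k] != "G")
      rows[[length(rows) + 1L]] <- addr("CB", k, r3, ideal_cb(N, CA, C))
    if (k < n) {
      CAn <- place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, 180)  # omega = 180
      Cn <- place_atom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, 180)  # phi = 180
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  do.call(rbind, rows)
}

atomic_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  out <- unname(m[element])
  out[is.na(out)] <- 12.011
  out
}

#' Generate a toy peptide + slab conformation
#'
#' An ideal extended peptide backbone (with one united Cbeta per
#' non-glycine residue) laid parallel to a rectangular slab lattice of
#' CH2-like united carbons, with the peptide center of mass 4 Angstrom
#' above the slab top.  A small seeded jitter decorrelates repeated
#' fixtures without disturbing the geometry.
#'
#' @param n_res number of peptide residues.
#' @param sequence residue letters occupying the backbone (default
#'   all-alanine); only used to name residues and place Cbeta atoms.
#' @param slab_margin extra slab extent beyond the peptide footprint
#'   (Angstrom).
#' @param spacing slab lattice spacing (Angstrom).
#' @param layers slab layers.
#' @param height peptide center-of-mass height above the slab top.
#' @param jitter standard deviation of seeded coordinate noise on the
#'   peptide (Angstrom); 0 disables.
#' @param seed integer seed.
#' @return aligned `system_conformation`.
#' @export
make_toy_system <- function(n_res, sequence = rep("A", n_res), slab_margin = 6,
                            spacing = 2.0, layers = 3, height = 4.0,
                            jitter = 0.02, seed = 1L) {
  if (n_res < 1L) abort_usage("n_res must be >= 1")
  sequence <- as_residues(sequence)
  if (length(sequence) != n_res) abort_usage("sequence length != n_res")
  pep <- extended_backbone(sequence)
  with_seed(seed, {
    if (jitter > 0) {
      pep$x <- pep$x + stats::rnorm(nrow(pep), sd = jitter)
      pep$y <- pep$y + stats::rnorm(nrow(pep), sd = jitter)
      pep$z <- pep$z + stats::rnorm(nrow(pep), sd = jitter)
    }
    NULL
  })
  xr <- range(pep$x); yr <- range(pep$y)
  xs <- seq(xr[1] - slab_margin, xr[2] + slab_margin, by = spacing)
  ys <- seq(yr[1] - slab_margin, yr[2] + slab_margin, by = spacing)
  zs <- -spacing * (seq_len(layers) - 1L)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  slab <- data.frame(name = "C", resno = max(pep$resno) + seq_len(nrow(grid)),
                     resname = "PLS", x = grid$x, y = grid$y, z = grid$z,
                     element = "C", stringsAsFactors = FALSE)
  # shift peptide so its mass-weighted center sits `height` above the slab top
  m <- atomic_mass(pep$element)
  pep$z <- pep$z - sum(m * pep$z) / sum(m) + max(slab$z) + height
  atoms <- rbind(
    data.frame(serial = seq_len(nrow(pep)), name = pep$name, resno = pep$resno,
               resname = pep$resname, segment = "peptide",
               x = pep$x, y = pep$y, z = pep$z, element = pep$element,
               stringsAsFactors = FALSE),
    data.frame(serial = nrow(pep) + seq_len(nrow(slab)), name = slab$name,
               resno = slab$resno, resname = slab$resname, segment = "plastic",
               x = slab$x, y = slab$y, z = slab$z, element = slab$element,
               stringsAsFactors = FALSE))
  out <- system_conformation(atoms)
  out$surface <- surface_frame(out)
  out
}

# Midpoint sampler for possibly unbounded bin intervals.
sample_in_bin <- function(n, lo, hi) {
  if (!is.finite(lo)) lo <- hi - 4
  if (!is.finite(hi)) hi <- lo + 4
  stats::runif(n, lo, hi - 1e-6)
}

#' Synthetic side-chain environment dataset with planted preferences
#'
#' Draws descriptor triples uniformly inside every bin of the binning
#' config and labels them with amino acids: in planted bins the planted
#' letter appears with the requested probability (rest uniform over the
#' remaining alphabet), elsewhere labels are uniform.
#'
#' @param planted data.frame with columns `bin_key`, `aa`, `fraction`
#'   (`fraction` in (0, 1]).
#' @param n_per_bin samples per bin.
#' @param alphabet design alphabet.
#' @param bins binning config (see [default_environment_bins()]).
#' @param seed integer seed.
#' @return data.frame with `distance`, `angle`, `sasa`, `bin_key`, `aa`.
#' @export
make_env_dataset <- function(planted = NULL, n_per_bin = 50,
                             alphabet = default_alphabet(),
                             bins = default_environment_bins(), seed) {
  if (!is.null(planted) &&
      (any(planted$fraction <= 0) || any(planted$fraction > 1)))
    abort_usage("planted fractions must be in (0, 1]")
  with_seed(seed, {
    de <- bins$distance; ae <- bins$angle; se <- bins$sasa
    out <- list()
    for (di in seq_len(length(de) - 1L))
      for (ai in seq_len(length(ae) - 1L))
        for (si in seq_len(length(se) - 1L)) {
          d <- sample_in_bin(n_per_bin, de[di], de[di + 1L])
          a <- sample_in_bin(n_per_bin, ae[ai], ae[ai + 1L])
          s <- sample_in_bin(n_per_bin, se[si], se[si + 1L])
          key <- paste(sprintf("d[%g,%g)", de[di], de[di + 1L]),
                       sprintf("a[%g,%g)", ae[ai], ae[ai + 1L]),
                       sprintf("s[%g,%g)", se[si], se[si + 1L]), sep = "|")
          pl <- if (!is.null(planted)) planted[planted$bin_key == key, ] else NULL
          if (!is.null(pl) && nrow(pl) == 1L) {
            hit <- stats::runif(n_per_bin) < pl$fraction
            aa <- ifelse(hit, pl$aa,
                         sample(setdiff(alphabet, pl$aa), n_per_bin, replace = TRUE))
          } else {
            aa <- sample(alphabet, n_per_bin, replace = TRUE)
          }
          out[[length(out) + 1L]] <-
            data.frame(distance = d, angle = a, sasa = s, bin_key = key, aa = aa,
                       stringsAsFactors = FALSE)
        }
    do.call(rbind, out)
  })
}
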
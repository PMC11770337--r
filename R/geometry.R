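# --- vector helpers -------------------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) abort_numeric("zero-length vector")
  a / n
}

# Dihedral angle A-B-C-D in degrees, in (-180, 180].
dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Natural-extension-reference-frame placement: the atom D bonded to C with
# bond length `bond`, bond angle B-C-D `angle` (deg) and dihedral A-B-C-D
# `dihedral` (deg).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# --- descriptor operations ------------------------------------------------

#' Signed Cbeta height above the slab top
#'
#' @param conf aligned `system_conformation`.
#' @param residue_index 1-based peptide residue index (glycine, which has
#'   no Cbeta, raises a data error).
#' @return signed distance z(Cbeta) - z0 in Angstrom (negative below the
#'   slab top).
#' @export
cbeta_distance <- function(conf, residue_index) {
  cb <- residue_atom(conf, residue_index, "CB")
  cb[3] - conf_surface(conf)$z0
}

#' Angle between the Calpha-Cbeta vector and the surface normal
#'
#' @inheritParams cbeta_distance
#' @return angle in degrees, in [0, 180].
#' @export
ca_cb_angle <- function(conf, residue_index) {
  ca <- residue_atom(conf, residue_index, "CA")
  cb <- residue_atom(conf, residue_index, "CB")
  v <- cb - ca
  if (vnorm(v) < 1e-9) abort_data("Calpha and Cbeta coincide")
  cosang <- sum(vunit(v) * conf_surface(conf)$normal)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# van der Waals radii by element (Angstrom) used for SASA.
element_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over atomic spheres using a deterministic golden
#' spiral point set.
#'
#' @param xyz numeric matrix of atom coordinates (rows = atoms).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius (default 1.4 Angstrom, water).
#' @param n_points surface points per atom.
#' @param indices atoms for which to report SASA (default all).
#' @return numeric vector of SASA values (Angstrom^2) for `indices`.
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960,
                          indices = seq_len(nrow(xyz))) {
  pts <- sphere_points(n_points)
  er <- radii + probe
  out <- numeric(length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    ri <- er[i]
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < ri + er & seq_len(nrow(xyz)) != i)
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- colSums((t(sp) - xyz[j, ])^2)
      acc <- acc & dj >= er[j]^2
      if (!any(acc)) break
    }
    out[k] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  out
}

#' Bare-Cbeta solvent accessibility
#'
#' SASA of the beta carbon after deleting every other side-chain atom of the
#' same residue; all backbone, plastic and other residues' atoms remain as
#' occluders.  This measures how much room the side chain has, independent
#' of which amino acid currently occupies the site.
#'
#' @inheritParams cbeta_distance
#' @param probe probe radius (Angstrom).
#' @param n_points Shrake-Rupley points.
#' @return SASA in Angstrom^2.
#' @export
cbeta_bare_sasa <- function(conf, residue_index, probe = 1.4, n_points = 960) {
  at <- conf$atoms
  drop <- at$segment == "peptide" & at$resno == residue_index &
    !(at$name %in% c(backbone_atom_names(), "CB"))
  at <- at[!drop, , drop = FALSE]
  cb <- which(at$segment == "peptide" & at$resno == residue_index & at$name == "CB")
  if (length(cb) == 0L) abort_data(sprintf("residue %d has no CB", residue_index))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  shrake_rupley(xyz, element_radius(at$element), probe = probe,
                n_points = n_points, indices = cb[1L])
}

#' Default environment binning
#'
#' Half-open `[lo, hi)` bins for the three side-chain environment
#' descriptors; the final angle bin is closed at 180.
#'
#' @return list of numeric edge vectors (`distance` in Angstrom, `angle`
#'   in degrees, `sasa` in Angstrom^2).
#' @export
default_environment_bins <- function() {
  list(distance = c(-Inf, 0, 2, 4, 6, 8, Inf),
       angle = c(0, 60, 120, 180),
       sasa = c(0, 40, 80, Inf))
}

bin_label <- function(x, edges, prefix) {
  k <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  if (k < 1L || k >= length(edges)) abort_data(sprintf("%s value %g outside bins", prefix, x))
  sprintf("%s[%g,%g)", prefix, edges[k], edges[k + 1L])
}

#' Side-chain environment descriptor
#'
#' Computes the (Cbeta-surface distance, Calpha-Cbeta angle to the normal,
#' bare-Cbeta SASA) triple for one residue and assigns its bin.
#'
#' @inheritParams cbeta_distance
#' @param bins edge list as from [default_environment_bins()].
#' @return object of class `side_chain_environment` with fields
#'   `residue_index`, `distance`, `angle`, `sasa` and `bin` (named
#'   character triple plus combined `key`).
#' @export
environment_descriptor <- function(conf, residue_index,
                                   bins = default_environment_bins()) {
  d <- cbeta_distance(conf, residue_index)
  a <- ca_cb_angle(conf, residue_index)
  s <- cbeta_bare_sasa(conf, residue_index)
  b <- c(distance = bin_label(d, bins$distance, "d"),
         angle = bin_label(a, bins$angle, "a"),
         sasa = bin_label(s, bins$sasa, "s"))
  structure(list(residue_index = residue_index, distance = d, angle = a,
                 sasa = s, bin = b, key = paste(b, collapse = "|")),
            class = "side_chain_environment")
}

#' Environment descriptors for every residue of a peptide
#'
#' Glycine residues (no Cbeta in this model) are skipped and flagged.
#'
#' @param conf aligned `system_conformation`.
#' @param sequence the peptide sequence occupying the backbone (used only
#'   to flag glycine positions).
#' @param bins edge list.
#' @return data.frame with one row per non-glycine residue: columns
#'   `residue`, `distance`, `angle`, `sasa`, `bin_key`; skipped residues are
#'   listed in attribute `skipped`.
#' @export
environment_table <- function(conf, sequence = NULL,
                              bins = default_environment_bins()) {
  idx <- seq_len(conf$n_residues)
  skip <- integer(0)
  if (!is.null(sequence)) {
    res <- as_residues(sequence)
    skip <- which(res == "G")
    idx <- setdiff(idx, skip)
  }
  rows <- lapply(idx, function(i) {
    e <- environment_descriptor(conf, i, bins)
    data.frame(residue = i, distance = e$distance, angle = e$angle,
               sasa = e$sasa, bin_key = e$key, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skip
  out
}
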
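# Residue names recognised as plastic slab material in PDB input.
default_plastic_resnames <- function() c("PLS", "PE", "PET", "PP", "PS")

backbone_atom_names <- function() c("N", "CA", "C", "O")

#' System conformation: peptide + plastic slab
#'
#' A frozen set of atoms split into `peptide`, `plastic` and (optionally)
#' `solvent` segments, plus the surface frame (slab-top height `z0` and
#' unit surface normal) once the slab has been aligned to +z.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resno`,
#'   `resname`, `segment`, `x`, `y`, `z`, `element`.
#' @return object of class `system_conformation`.
#' @export
system_conformation <- function(atoms) {
  need <- c("serial", "name", "resno", "resname", "segment", "x", "y", "z", "element")
  if (!all(need %in% names(atoms))) abort_usage("atoms missing required columns")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    abort_data("non-finite coordinates")
  if (!any(atoms$segment == "plastic")) abort_data("no plastic atoms in structure")
  pep <- atoms[atoms$segment == "peptide", ]
  if (nrow(pep) == 0L) abort_data("no peptide atoms in structure")
  resnos <- sort(unique(as.integer(pep$resno)))
  if (!identical(resnos, seq_along(resnos)))
    abort_data("peptide residues must be contiguously numbered from 1")
  structure(list(atoms = atoms, n_residues = length(resnos), surface = NULL),
            class = "system_conformation")
}

#' @export
print.system_conformation <- function(x, ...) {
  cat(sprintf("system_conformation: %d peptide residues, %d peptide / %d plastic atoms\n",
              x$n_residues, sum(x$atoms$segment == "peptide"),
              sum(x$atoms$segment == "plastic")))
  invisible(x)
}

infer_element <- function(name) {
  e <- sub("^[0-9]*", "", name)
  e <- substr(e, 1L, 1L)
  toupper(e)
}

#' Read a peptide + slab structure from PDB
#'
#' Atoms are classified by residue name: names in `plastic_resnames` become
#' the plastic segment, common water names become solvent, everything else
#' is peptide.  Peptide residue numbers are renumbered contiguously from 1.
#'
#' @param path PDB file path.
#' @param plastic_resnames residue names treated as plastic.
#' @return `system_conformation`.
#' @export
read_structure <- function(path, plastic_resnames = default_plastic_resnames()) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort_data(sprintf("PDB parse failed: %s", conditionMessage(e))))
  at <- pdb$atom
  segment <- ifelse(at$resid %in% plastic_resnames, "plastic",
                    ifelse(at$resid %in% c("HOH", "WAT", "SOL", "TIP3"), "solvent", "peptide"))
  resno <- at$resno
  pepmask <- segment == "peptide"
  if (any(pepmask)) {
    key <- paste(at$chain[pepmask], at$resno[pepmask])
    resno[pepmask] <- match(key, unique(key))
  }
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(serial = at$eleno, name = at$elety, resno = resno,
                      resname = at$resid, segment = segment,
                      x = at$x, y = at$y, z = at$z, element = elem,
                      stringsAsFactors = FALSE)
  system_conformation(atoms)
}

#' Write a system conformation to PDB
#'
#' @param conf `system_conformation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(conf, path) {
  at <- conf$atoms
  chain <- c(peptide = "A", plastic = "B", solvent = "C")[at$segment]
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = chain, elesy = at$element)
  invisible(path)
}

plastic_heavy <- function(conf) {
  at <- conf$atoms
  at[at$segment == "plastic" & at$element != "H", , drop = FALSE]
}

#' Surface frame of an aligned conformation
#'
#' The slab top `z0` is the maximum z over plastic heavy atoms and the
#' normal is +z; the conformation must already be slab-aligned
#' (see [align_slab_to_z()]).
#'
#' @param conf `system_conformation`.
#' @return list with `z0` (Angstrom) and `normal` (unit vector).
#' @export
surface_frame <- function(conf) {
  ph <- plastic_heavy(conf)
  if (nrow(ph) == 0L) abort_data("no plastic heavy atoms")
  list(z0 = max(ph$z), normal = c(0, 0, 1))
}

#' Rigidly align the slab plane normal to +z
#'
#' Fits a plane to the plastic heavy atoms, applies the minimal rotation
#' (about the slab centroid) taking the fitted normal to +z, and flips the
#' system if the peptide ends up below the slab.  An already-aligned system
#' is returned unchanged (displacement < 1e-9).
#'
#' @param conf `system_conformation`.
#' @param planarity_tol maximum allowed thickness (standard deviation along
#'   the fitted normal, Angstrom) for the slab to count as planar.
#' @return aligned `system_conformation` with `surface` populated.
#' @export
align_slab_to_z <- function(conf, planarity_tol = 2.5) {
  at <- conf$atoms
  ph <- plastic_heavy(conf)
  if (nrow(ph) < 3L) abort_data("need at least 3 plastic heavy atoms to fit a plane")
  P <- as.matrix(ph[, c("x", "y", "z")])
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2L, ctr))
  normal <- sv$v[, 3L]
  if (stats::sd(sweep(P, 2L, ctr) %*% normal) > planarity_tol)
    abort_data("plastic slab is not planar within tolerance")
  X <- as.matrix(at[, c("x", "y", "z")])
  pep_ctr <- colMeans(X[at$segment == "peptide", , drop = FALSE])
  if (sum((pep_ctr - ctr) * normal) < 0) normal <- -normal
  z <- c(0, 0, 1)
  cosang <- sum(normal * z)
  if (cosang < 1 - 1e-12) {
    axis <- c(normal[2] * z[3] - normal[3] * z[2],
              normal[3] * z[1] - normal[1] * z[3],
              normal[1] * z[2] - normal[2] * z[1])
    s <- sqrt(sum(axis^2))
    if (s < 1e-12) {            # antiparallel: rotate 180 deg about x
      R <- diag(c(1, -1, -1))
    } else {
      axis <- axis / s
      K <- matrix(c(0, axis[3], -axis[2],
                    -axis[3], 0, axis[1],
                    axis[2], -axis[1], 0), 3, 3)
      ang <- atan2(s * 1, cosang)
      ang <- acos(max(-1, min(1, cosang)))
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    }
    X <- sweep(sweep(X, 2L, ctr) %*% t(R), 2L, ctr, `+`)
    at$x <- X[, 1L]; at$y <- X[, 2L]; at$z <- X[, 3L]
  }
  out <- system_conformation(at)
  out$surface <- surface_frame(out)
  out
}

residue_atom <- function(conf, residue_index, name) {
  at <- conf$atoms
  row <- at[at$segment == "peptide" & at$resno == residue_index & at$name == name, ]
  if (nrow(row) == 0L)
    abort_data(sprintf("residue %d has no atom '%s'", residue_index, name))
  c(row$x[1L], row$y[1L], row$z[1L])
}

conf_surface <- function(conf) {
  if (is.null(conf$surface)) surface_frame(conf) else conf$surface
}
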
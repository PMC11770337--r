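# Coulomb constant in kcal * Angstrom / (mol * e^2).
COULOMB_K <- 332.0636

#' Load a force-field parameter set
#'
#' Reads a tabular parameter file (columns `atom_type`, `charge` in e,
#' `eps` in kcal/mol, `rmin_half` in Angstrom, `gb_radius` in Angstrom).
#' The packaged default is a deliberately small united-atom parameter set:
#' a few atom types per residue carrying the residue's net charge, polarity
#' and bulk, not a transferable biomolecular force field.  Richer parameter
#' files with the same columns can be dropped in.
#'
#' @param path parameter file (default: packaged set).
#' @param dielectric_in,dielectric_out interior and solvent dielectric
#'   constants for the electrostatic and generalized-Born terms.
#' @param scale14 scaling of 1-4 bonded intra-residue Coulomb/LJ pairs
#'   (1-2 and 1-3 pairs are always excluded).
#' @return object of class `forcefield`.
#' @export
read_forcefield <- function(path = system.file("extdata", "forcefield.csv",
                                               package = "pottspep"),
                            dielectric_in = 1, dielectric_out = 78.5,
                            scale14 = 0.5) {
  if (!file.exists(path)) abort_usage(sprintf("no such force-field file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_type", "charge", "eps", "rmin_half", "gb_radius")
  if (!all(need %in% names(df))) abort_data("force-field file missing columns")
  if (any(df$eps < 0)) abort_data("negative LJ epsilon")
  if (any(df$gb_radius < 0)) abort_data("negative GB radius")
  rownames(df) <- df$atom_type
  structure(list(types = df, dielectric_in = dielectric_in,
                 dielectric_out = dielectric_out, scale14 = scale14,
                 k = COULOMB_K),
            class = "forcefield")
}

#' @rdname read_forcefield
#' @export
default_forcefield <- function() read_forcefield()

#' Load a rotamer library
#'
#' Chi-angle table (degrees), one row per rotamer, columns `aa`,
#' `chi1`..`chi4` (empty where the side chain has fewer torsions).  The
#' packaged library is a minimal set of three chi1 wells per rotatable
#' side chain.
#'
#' @param path rotamer file (default: packaged library).
#' @return named list mapping amino-acid letter to a numeric matrix of chi
#'   angles (rows = rotamers); residues without torsions map to a
#'   zero-column matrix.
#' @export
read_rotamer_library <- function(path = system.file("extdata", "rotamers.csv",
                                                    package = "pottspep")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$aa), function(d) {
    m <- as.matrix(d[, c("chi1", "chi2", "chi3", "chi4")])
    m[, colSums(!is.na(m)) > 0, drop = FALSE]
  })
  out
}

#' @rdname read_rotamer_library
#' @export
default_rotamer_library <- function() read_rotamer_library()

# Side-chain topology: per amino acid, the ordered united atoms with NeRF
# internal coordinates.  Cached per session.
sidechain_topology <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      df <- utils::read.csv(system.file("extdata", "sidechain_topology.csv",
                                        package = "pottspep"),
                            stringsAsFactors = FALSE)
      cache <<- split(df, df$aa)
    }
    cache
  }
})

# Number of chi torsions of an amino acid under the packaged topology.
n_chi <- function(aa) {
  topo <- sidechain_topology()[[aa]]
  if (is.null(topo)) 0L else sum(grepl("^chi", topo$dihedral))
}

# Resolve per-atom parameters from atom types.
resolve_params <- function(atoms, ff) {
  t <- ff$types[atoms$type, ]
  if (any(is.na(t$charge)))
    abort_data(sprintf("unknown atom type(s): %s",
                       paste(unique(atoms$type[is.na(t$charge)]), collapse = ", ")))
  atoms$charge <- t$charge
  atoms$eps <- t$eps
  atoms$rmin_half <- t$rmin_half
  atoms$gbr <- t$gb_radius
  atoms
}

# Atom type of a backbone or plastic atom.
builtin_atom_type <- function(segment, name) {
  ifelse(segment == "plastic", "C_PE",
         c(N = "N_BB", CA = "CA_BB", C = "C_BB", O = "O_BB")[name])
}

# Ideal Cbeta position from a residue's backbone N, CA, C.
ideal_cb <- function(N, CA, C) place_atom(C, N, CA, 1.53, 110.4, 122.55)

#' Build a side chain from chi angles
#'
#' Places the united side-chain atoms of amino acid `aa` on residue
#' `residue_index` of the conformation backbone, using NeRF internal
#' coordinates from the packaged topology and the supplied chi angles.
#'
#' @param conf `system_conformation` providing the backbone.
#' @param residue_index 1-based residue.
#' @param aa amino-acid letter.
#' @param chis numeric chi angles (degrees); length must equal the residue's
#'   torsion count.
#' @return data.frame of side-chain atoms with columns `name`, `type`,
#'   `x`, `y`, `z` (empty for glycine).
#' @export
build_sidechain <- function(conf, residue_index, aa, chis = numeric(0)) {
  topo <- sidechain_topology()[[aa]]
  if (is.null(topo)) {
    if (aa == "G") return(data.frame(name = character(0), type = character(0),
                                     x = numeric(0), y = numeric(0), z = numeric(0)))
    abort_usage(sprintf("amino acid '%s' absent from topology", aa))
  }
  if (length(chis) != sum(grepl("^chi", topo$dihedral)))
    abort_usage(sprintf("'%s' needs %d chi angles, got %d",
                        aa, sum(grepl("^chi", topo$dihedral)), length(chis)))
  N <- residue_atom(conf, residue_index, "N")
  CA <- residue_atom(conf, residue_index, "CA")
  C <- residue_atom(conf, residue_index, "C")
  chain <- list(N, CA)            # reference chain grows: N, CA, CB, X1, ...
  coords <- matrix(0, nrow(topo), 3L)
  for (r in seq_len(nrow(topo))) {
    dih <- topo$dihedral[r]
    if (dih == "cb") {
      p <- place_atom(C, N, CA, topo$bond[r], topo$angle[r], 122.55)
    } else {
      k <- as.integer(sub("chi", "", dih))
      m <- length(chain)
      p <- place_atom(chain[[m - 2L]], chain[[m - 1L]], chain[[m]],
                      topo$bond[r], topo$angle[r], chis[k])
    }
    coords[r, ] <- p
    chain[[length(chain) + 1L]] <- p
  }
  data.frame(name = topo$atom, type = topo$type,
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             stringsAsFactors = FALSE)
}
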
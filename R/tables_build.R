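# --- coarse-grained evaluation context ------------------------------------

# Backbone atoms of all residues, typed for the force field.
backbone_atoms <- function(conf) {
  at <- conf$atoms
  bb <- at[at$segment == "peptide" & at$name %in% backbone_atom_names(), ]
  data.frame(name = bb$name, type = builtin_atom_type("peptide", bb$name),
             segment = "peptide", resno = bb$resno,
             x = bb$x, y = bb$y, z = bb$z, stringsAsFactors = FALSE)
}

plastic_atoms <- function(conf) {
  pl <- conf$atoms[conf$atoms$segment == "plastic", ]
  data.frame(name = pl$name, type = "C_PE", segment = "plastic", resno = pl$resno,
             x = pl$x, y = pl$y, z = pl$z, stringsAsFactors = FALSE)
}

# Replace the side chains of every residue not in `active` by a single
# neutral, LJ-inert sphere (GB radius 3 Angstrom) at the ideal Cbeta site.
cg_spheres <- function(conf, active) {
  keep <- setdiff(seq_len(conf$n_residues), active)
  if (length(keep) == 0L)
    return(data.frame(name = character(0), type = character(0),
                      segment = character(0), resno = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  pos <- t(vapply(keep, function(j)
    ideal_cb(residue_atom(conf, j, "N"), residue_atom(conf, j, "CA"),
             residue_atom(conf, j, "C")), numeric(3)))
  data.frame(name = "CGS", type = "CG_SPHERE", segment = "cg", resno = keep,
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L], stringsAsFactors = FALSE)
}

#' Coarse-grained system for an active-residue context
#'
#' Plastic and backbone atoms plus one 3-Angstrom sphere per non-active
#' side chain; the active residues' side chains are supplied by the caller.
#'
#' @param conf `system_conformation`.
#' @param active residue indices whose side chains stay atomistic.
#' @param ff `forcefield`.
#' @return list with resolved `plastic`, `backbone`, `cg` atom sets.
#' @export
coarse_grained_context <- function(conf, active, ff = default_forcefield()) {
  list(plastic = resolve_params(plastic_atoms(conf), ff),
       backbone = resolve_params(backbone_atoms(conf), ff),
       cg = resolve_params(cg_spheres(conf, active), ff))
}

# Side chain of residue i as a typed atom set.
sidechain_set <- function(conf, i, aa, chis, ff) {
  sc <- build_sidechain(conf, i, aa, chis)
  if (nrow(sc) == 0L) return(cbind(sc, segment = character(0), resno = integer(0)))
  sc$segment <- "peptide"
  sc$resno <- i
  resolve_params(sc, ff)
}

# Bond separation (number of bonds) between side-chain atom `p` (1 = CB,
# 2 = first branch atom, ... along the linear united chain) of residue i and
# a backbone atom of residue `res_bb`.  Used for the 1-2/1-3 exclusion and
# 1-4 scaling of intra-peptide Coulomb/LJ terms.
bb_separation <- function(p, i, res_bb, name_bb) {
  same <- c(CA = 0L, N = 1L, C = 1L, O = 2L)
  prev <- c(C = 2L, O = 3L, CA = 3L, N = 4L)
  nxt <- c(N = 2L, CA = 3L, C = 4L, O = 5L)
  off <- if (res_bb == i) same[name_bb]
         else if (res_bb == i - 1L) prev[name_bb]
         else if (res_bb == i + 1L) nxt[name_bb]
         else 99L
  p + unname(off)
}

sep_to_weight <- function(sep, scale14) {
  ifelse(sep <= 2L, 0, ifelse(sep == 3L, scale14, 1))
}

# Weight matrices for a side chain against the backbone set and itself.
sc_bb_weights <- function(sc, bb, i, scale14) {
  p <- seq_len(nrow(sc))
  W <- matrix(1, nrow(sc), nrow(bb))
  for (c in seq_len(nrow(bb)))
    W[, c] <- sep_to_weight(bb_separation(p, i, bb$resno[c], bb$name[c]), scale14)
  W
}

sc_intra_weights <- function(sc, scale14) {
  p <- seq_len(nrow(sc))
  sep <- abs(outer(p, p, `-`))
  W <- sep_to_weight(sep, scale14)
  W[lower.tri(W, diag = TRUE)] <- 0          # count each pair once
  W
}

# Total GB energy of a set with itself: self-polarization plus each
# unordered pair once (no bonded exclusions in the GB term).
gb_set_energy <- function(a, Ra, ff) {
  if (nrow(a) == 0L) return(0)
  r <- cross_dist(a, a)
  fgb <- gb_f(r, outer(Ra, rep(1, length(Ra))), outer(rep(1, length(Ra)), Ra))
  -ff$k / 2 * (1 / ff$dielectric_in - 1 / ff$dielectric_out) *
    sum(outer(a$charge, a$charge) / fgb)
}

# One-body energy of a built side chain in a prepared context.
one_body_eval <- function(sc, ctx, i, ff) {
  if (nrow(sc) == 0L) return(energy_breakdown(0, 0, 0))
  bb <- ctx$backbone
  Wbb <- sc_bb_weights(sc, bb, i, ff$scale14)
  Win <- sc_intra_weights(sc, ff$scale14)
  elec <- coulomb_energy(sc, ctx$plastic, ff) +
    coulomb_energy(sc, bb, ff, weights = Wbb) +
    coulomb_energy(sc, sc, ff, weights = Win)
  lj <- lj_energy(sc, ctx$plastic, ff) +
    lj_energy(sc, bb, ff, weights = Wbb) +
    lj_energy(sc, sc, ff, weights = Win)
  all_atoms <- rbind(sc, ctx$backbone, ctx$plastic, ctx$cg)
  nsc <- nrow(sc); nbb <- nrow(bb)
  R <- born_radii(all_atoms, ff, indices = seq_len(nsc + nbb))
  Rsc <- R[seq_len(nsc)]; Rbb <- R[nsc + seq_len(nbb)]
  gb <- gb_pair_energy(sc, bb, Rsc, Rbb, ff) +
    gb_pair_energy(sc, ctx$plastic, Rsc,
                   rep(ctx$plastic$gbr[1] %||% 1, nrow(ctx$plastic)), ff) +
    gb_set_energy(sc, Rsc, ff)
  energy_breakdown(elec, lj, gb)
}

#' Select the lowest one-body-energy rotamer
#'
#' Evaluates every library rotamer of `aa` at residue `i` (all other side
#' chains coarse-grained), applies a discrete chi refinement (coordinate-wise
#' +/-10 degree scan, two sweeps) and keeps the lowest-energy candidate.
#' Ties break deterministically by library order.
#'
#' @param conf `system_conformation`.
#' @param residue_index residue (1-based).
#' @param aa amino-acid letter.
#' @param library rotamer library (see [read_rotamer_library()]).
#' @param ff `forcefield`.
#' @param ctx optional precomputed [coarse_grained_context()] for this
#'   residue (performance; computed when `NULL`).
#' @return list with `chis`, `energy` (kcal/mol) and `breakdown`.
#' @export
select_rotamer <- function(conf, residue_index, aa,
                           library = default_rotamer_library(),
                           ff = default_forcefield(), ctx = NULL) {
  rot <- library[[aa]]
  if (is.null(rot)) abort_usage(sprintf("amino acid '%s' absent from rotamer library", aa))
  nc <- n_chi(aa)
  if (is.null(ctx)) ctx <- coarse_grained_context(conf, residue_index, ff)
  ev <- function(chis) {
    sc <- sidechain_set(conf, residue_index, aa, chis, ff)
    one_body_eval(sc, ctx, residue_index, ff)
  }
  if (nc == 0L) {
    br <- ev(numeric(0))
    return(list(chis = numeric(0), energy = br$total, breakdown = br))
  }
  best <- NULL
  for (r in seq_len(nrow(rot))) {
    chis <- as.numeric(rot[r, seq_len(nc)])
    br <- ev(chis)
    if (is.null(best) || br$total < best$energy - 1e-12)
      best <- list(chis = chis, energy = br$total, breakdown = br)
  }
  for (sweep in 1:2) {
    for (k in seq_len(nc)) {
      for (dlt in c(-10, 10)) {
        chis <- best$chis
        chis[k] <- ((chis[k] + dlt + 180) %% 360) - 180
        br <- ev(chis)
        if (br$total < best$energy - 1e-12)
          best <- list(chis = chis, energy = br$total, breakdown = br)
      }
    }
  }
  best
}

#' One-body energy of amino acid `aa` at residue `i`
#'
#' Interaction of the residue's side chain (retained rotamer) with the
#' plastic slab, with itself (bonded exclusions applied to Coulomb/LJ; the
#' GB term has none) and with the full peptide backbone, in the
#' coarse-grained Born-radius context.  Backbone-backbone and
#' backbone-plastic terms are sequence-invariant and excluded by
#' construction.
#'
#' @inheritParams select_rotamer
#' @param chis chi angles; `NULL` selects the lowest-energy rotamer.
#' @return energy (kcal/mol) with attributes `breakdown` and `chis`.
#' @export
one_body_energy <- function(conf, residue_index, aa,
                            ff = default_forcefield(),
                            library = default_rotamer_library(), chis = NULL) {
  if (is.null(chis)) {
    sel <- select_rotamer(conf, residue_index, aa, library, ff)
    out <- sel$energy
    attr(out, "breakdown") <- sel$breakdown
    attr(out, "chis") <- sel$chis
    return(out)
  }
  ctx <- coarse_grained_context(conf, residue_index, ff)
  sc <- sidechain_set(conf, residue_index, aa, chis, ff)
  br <- one_body_eval(sc, ctx, residue_index, ff)
  out <- br$total
  attr(out, "breakdown") <- br
  attr(out, "chis") <- chis
  out
}

#' Two-body energy between side chains
#'
#' Coulomb + LJ + generalized-Born cross energy between the side-chain
#' atoms of `(i, aa_i)` and `(j, aa_j)`, both carrying their retained
#' one-body rotamers, with all other side chains coarse-grained.
#'
#' @inheritParams select_rotamer
#' @param i,j distinct residue indices.
#' @param aa_i,aa_j amino-acid letters.
#' @param chis_i,chis_j chi angles; `NULL` reselects via [select_rotamer()].
#' @param ctx optional precomputed pair [coarse_grained_context()].
#' @return energy in kcal/mol.
#' @export
two_body_energy <- function(conf, i, aa_i, j, aa_j,
                            ff = default_forcefield(),
                            library = default_rotamer_library(),
                            chis_i = NULL, chis_j = NULL, ctx = NULL) {
  if (i == j) abort_usage("two-body energy requires distinct residues")
  if (is.null(chis_i)) chis_i <- select_rotamer(conf, i, aa_i, library, ff)$chis
  if (is.null(chis_j)) chis_j <- select_rotamer(conf, j, aa_j, library, ff)$chis
  sc_i <- sidechain_set(conf, i, aa_i, chis_i, ff)
  sc_j <- sidechain_set(conf, j, aa_j, chis_j, ff)
  if (is.null(ctx)) ctx <- coarse_grained_context(conf, c(i, j), ff)
  two_body_eval(sc_i, sc_j, ctx, ff)
}

# Cross energy of two built side chains in a prepared pair context.
two_body_eval <- function(sc_i, sc_j, ctx, ff) {
  if (nrow(sc_i) == 0L || nrow(sc_j) == 0L) return(0)
  all_atoms <- rbind(sc_i, sc_j, ctx$backbone, ctx$plastic, ctx$cg)
  R <- born_radii(all_atoms, ff, indices = seq_len(nrow(sc_i) + nrow(sc_j)))
  Ri <- R[seq_len(nrow(sc_i))]
  Rj <- R[nrow(sc_i) + seq_len(nrow(sc_j))]
  coulomb_energy(sc_i, sc_j, ff) + lj_energy(sc_i, sc_j, ff) +
    gb_pair_energy(sc_i, sc_j, Ri, Rj, ff)
}

#' Build complete Potts energy tables for a conformation
#'
#' Selects the lowest-energy rotamer for every (residue, amino acid) pair,
#' tabulates all one-body energies and all `i < j` two-body energies using
#' the retained rotamers.  Deterministic for fixed inputs.
#'
#' @param conf aligned `system_conformation`.
#' @param ff `forcefield`.
#' @param library rotamer library.
#' @param alphabet design alphabet.
#' @param conformation_id identifier stored in the tables.
#' @return `energy_tables` with attribute `rotamers` (list of per-residue,
#'   per-amino-acid chi vectors).
#' @export
build_tables <- function(conf, ff = default_forcefield(),
                         library = default_rotamer_library(),
                         alphabet = default_alphabet(),
                         conformation_id = "conformation") {
  n <- conf$n_residues
  A <- length(alphabet)
  ob <- matrix(0, n, A)
  rots <- vector("list", n)
  for (i in seq_len(n)) {
    rots[[i]] <- vector("list", A)
    names(rots[[i]]) <- alphabet
    ctx_i <- coarse_grained_context(conf, i, ff)
    for (a in seq_len(A)) {
      sel <- select_rotamer(conf, i, alphabet[a], library, ff, ctx = ctx_i)
      ob[i, a] <- sel$energy
      rots[[i]][[a]] <- sel$chis
    }
  }
  sc_cache <- lapply(seq_len(n), function(i)
    lapply(seq_len(A), function(a)
      sidechain_set(conf, i, alphabet[a], rots[[i]][[a]], ff)))
  tb <- array(0, dim = c(A, n, A, n))
  pr <- pair_index(n)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    ctx_ij <- coarse_grained_context(conf, c(i, j), ff)
    for (a in seq_len(A)) for (b in seq_len(A))
      tb[a, i, b, j] <- two_body_eval(sc_cache[[i]][[a]], sc_cache[[j]][[b]],
                                      ctx_ij, ff)
  }
  out <- energy_tables(ob, tb, alphabet, conformation_id = conformation_id)
  attr(out, "rotamers") <- rots
  out
}

#' Direct (table-free) Potts score of a sequence
#'
#' Recomputes every one- and two-body term from atoms, in the same
#' coarse-graining and rotamer context the tables use.
#'
#' @inheritParams build_tables
#' @param seq sequence.
#' @param lambda,penalty model parameters.
#' @return score in kcal/mol.
#' @export
potts_score_direct <- function(conf, seq, ff = default_forcefield(),
                               library = default_rotamer_library(),
                               lambda = 0.01, penalty = 0) {
  res <- as_residues(seq)
  if (length(res) != conf$n_residues) abort_usage("sequence length != residue count")
  n <- length(res)
  sel <- lapply(seq_len(n), function(i) select_rotamer(conf, i, res[i], library, ff))
  total <- sum(vapply(sel, function(s) s$energy, 0))
  pr <- pair_index(n)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    total <- total + lambda *
      two_body_energy(conf, i, res[i], j, res[j], ff, library,
                      chis_i = sel[[i]]$chis, chis_j = sel[[j]]$chis)
  }
  total + penalty
}
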
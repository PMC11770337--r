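# Atom sets are data.frames with coordinates `x,y,z` and either resolved
# parameter columns (charge, eps, rmin_half, gbr) or a `type` column that
# is resolved against the force field on entry.
ensure_params <- function(atoms, ff) {
  if (!all(c("charge", "eps", "rmin_half", "gbr") %in% names(atoms)))
    atoms <- resolve_params(atoms, ff)
  atoms
}

cross_dist <- function(a, b) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  sqrt(pmax(d2, 0))
}

#' Coulomb energy between two atom sets
#'
#' `sum k q_i q_j / (eps_in r_ij)` over all cross pairs, no cutoff.
#'
#' @param a,b atom sets (disjoint).
#' @param ff `forcefield`.
#' @param weights optional pair weight matrix (`nrow(a) x nrow(b)`), used
#'   for bonded exclusions.
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(a, b, ff, weights = NULL) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  a <- ensure_params(a, ff); b <- ensure_params(b, ff)
  r <- cross_dist(a, b)
  w <- if (is.null(weights)) matrix(1, nrow(a), nrow(b)) else weights
  if (any(r < 1e-9 & w > 0)) abort_numeric("zero interatomic distance in Coulomb sum")
  e <- (ff$k / ff$dielectric_in) * outer(a$charge, b$charge) / pmax(r, 1e-9)
  sum(e * w)
}

#' Lennard-Jones energy between two atom sets
#'
#' Lorentz-Berthelot combination: `eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = rmin_half_i + rmin_half_j`;
#' `sum eps_ij ((rmin/r)^12 - 2 (rmin/r)^6)`.
#'
#' @inheritParams coulomb_energy
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(a, b, ff, weights = NULL) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  a <- ensure_params(a, ff); b <- ensure_params(b, ff)
  eps <- sqrt(outer(a$eps, b$eps))
  if (all(eps == 0)) return(0)
  r <- cross_dist(a, b)
  w <- if (is.null(weights)) matrix(1, nrow(a), nrow(b)) else weights
  if (any(r < 1e-9 & eps > 0 & w > 0)) abort_numeric("zero interatomic distance in LJ sum")
  rmin <- outer(a$rmin_half, b$rmin_half, `+`)
  q <- (rmin / pmax(r, 1e-9))^6
  sum(eps * (q^2 - 2 * q) * w)
}

# Pairwise-descreening integral: the volume integral of 1/(4 pi r^4) over a
# neighbor sphere of radius `a` whose center lies at distance `d`, clipped
# to the region outside the self sphere of radius `rho`.
descreen_integral <- function(d, a, rho) {
  U <- d + a
  L <- pmax(d - a, rho)
  out <- numeric(length(d))
  ok <- U > L & a > 0
  if (any(ok)) {
    f <- function(r, d, a) -1 / r - (1 / (2 * d)) * (log(r) - (d^2 - a^2) / (2 * r^2))
    out[ok] <- (f(U[ok], d[ok], a[ok]) - f(L[ok], d[ok], a[ok])) / 2
  }
  out
}

#' Effective Born radii by pairwise descreening
#'
#' Still-style pairwise sum: each atom starts from its intrinsic radius and
#' every other sphere in the system (including the 3-Angstrom side-chain
#' coarse-graining spheres) descreens it through the analytic
#' `1/r^4` volume integral.  An isolated atom returns its intrinsic radius.
#'
#' @param atoms full atom set of the (coarse-grained) system.
#' @param ff `forcefield`.
#' @param indices atoms for which radii are required (default all).
#' @param r_max cap on the effective radius for deeply buried atoms.
#' @return numeric vector of Born radii (Angstrom) for `indices`.
#' @export
born_radii <- function(atoms, ff, indices = seq_len(nrow(atoms)), r_max = 30) {
  atoms <- ensure_params(atoms, ff)
  if (any(atoms$gbr[indices] <= 0)) abort_numeric("non-positive intrinsic GB radius")
  d <- cross_dist(atoms[indices, , drop = FALSE], atoms)
  k <- length(indices)
  N <- nrow(atoms)
  self <- cbind(seq_len(k), indices)
  amat <- matrix(atoms$gbr, k, N, byrow = TRUE)
  active <- amat > 0
  active[self] <- FALSE
  if (any(d[active] < 1e-9)) abort_numeric("overlapping identical centers in Born sum")
  rho <- atoms$gbr[indices]
  contrib <- matrix(0, k, N)
  contrib[active] <- descreen_integral(d[active], amat[active],
                                       matrix(rho, k, N)[active])
  inv <- 1 / rho - rowSums(contrib)
  ifelse(inv <= 1 / r_max, r_max, 1 / inv)
}

gb_f <- function(r, Ri, Rj) sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))

#' Generalized-Born cross-term energy between two atom sets
#'
#' `-k (1/eps_in - 1/eps_out) sum q_i q_j / f_GB` with the Still smoothing
#' function `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`.
#'
#' @param a,b atom sets.
#' @param Ra,Rb Born radii aligned with `a` and `b`.
#' @param ff `forcefield`.
#' @return energy in kcal/mol.
#' @export
gb_pair_energy <- function(a, b, Ra, Rb, ff) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  a <- ensure_params(a, ff); b <- ensure_params(b, ff)
  if (any(Ra <= 0) || any(Rb <= 0)) abort_numeric("non-positive Born radius")
  r <- cross_dist(a, b)
  fgb <- gb_f(r, outer(Ra, rep(1, length(Rb))), outer(rep(1, length(Ra)), Rb))
  -ff$k * (1 / ff$dielectric_in - 1 / ff$dielectric_out) *
    sum(outer(a$charge, b$charge) / fgb)
}

# GB self-polarization energy of a set of atoms.
gb_self_energy <- function(a, Ra, ff) {
  if (nrow(a) == 0L) return(0)
  a <- ensure_params(a, ff)
  if (any(Ra <= 0)) abort_numeric("non-positive Born radius")
  -ff$k / 2 * (1 / ff$dielectric_in - 1 / ff$dielectric_out) * sum(a$charge^2 / Ra)
}

#' Energy breakdown container
#'
#' @param elec,lj,gb component energies (kcal/mol).
#' @return list with the components and their `total`.
#' @export
energy_breakdown <- function(elec, lj, gb) {
  list(elec = elec, lj = lj, gb = gb, total = elec + lj + gb)
}
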
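ff <- default_forcefield()
lib <- default_rotamer_library()

test_that("side chains are built at the requested chi angles", {
  conf <- get_toy_conf()
  sc <- build_sidechain(conf, 2, "K", c(-60, 180, 60, 180))
  expect_identical(sc$name, c("CB", "CG", "CD", "CE", "NZ"))
  N <- pottspep:::residue_atom(conf, 2, "N")
  CA <- pottspep:::residue_atom(conf, 2, "CA")
  chi1 <- pottspep:::dihedral_angle(N, CA, unlist(sc[1, c("x", "y", "z")]),
                                    unlist(sc[2, c("x", "y", "z")]))
  expect_equal(chi1, -60, tolerance = 1e-6)
  chi2 <- pottspep:::dihedral_angle(CA, unlist(sc[1, c("x", "y", "z")]),
                                    unlist(sc[2, c("x", "y", "z")]),
                                    unlist(sc[3, c("x", "y", "z")]))
  expect_equal(chi2, 180, tolerance = 1e-6)
  expect_identical(nrow(build_sidechain(conf, 1, "G")), 0L)
  expect_error(build_sidechain(conf, 1, "K", c(0, 0)), class = "pottspep_usage_error")
})

test_that("rotamer selection returns single-rotamer and chi-free cases directly", {
  conf <- get_toy_conf()
  single <- list(S = matrix(-60, 1, 1))
  sel <- select_rotamer(conf, 2, "S", library = single, ff = ff)
  # refinement may polish around the single rotamer but stays in its well
  expect_lte(sel$energy, one_body_energy(conf, 2, "S", ff, single, chis = -60))
  ala <- select_rotamer(conf, 2, "A", lib, ff)
  expect_identical(ala$chis, numeric(0))
  gly <- select_rotamer(conf, 2, "G", lib, ff)
  expect_identical(gly$energy, 0)
})

test_that("rotamer selection avoids a slab clash when an alternative exists", {
  conf <- get_toy_conf()
  # chi1 = -60 points the thiol toward the slab, +60 away from it
  two <- list(C = matrix(c(-60, 60), 2, 1))
  e_down <- one_body_energy(conf, 2, "C", ff, two, chis = -60)
  e_up <- one_body_energy(conf, 2, "C", ff, two, chis = 60)
  sel <- select_rotamer(conf, 2, "C", library = two, ff = ff)
  expect_lte(sel$energy, min(e_down, e_up))
  better <- if (e_down < e_up) -60 else 60
  expect_equal(abs(sel$chis - better) < 25, TRUE)  # refined around the winner
})

test_that("one-body energy components add up and decay far from the slab", {
  conf <- get_toy_conf()
  e <- one_body_energy(conf, 2, "S", ff, lib)
  br <- attr(e, "breakdown")
  expect_equal(as.numeric(e), br$elec + br$lj + br$gb, tolerance = 1e-9)
  # lift the peptide far above the slab: the plastic contribution vanishes
  at <- conf$atoms
  at$z[at$segment == "peptide"] <- at$z[at$segment == "peptide"] + 60
  far <- system_conformation(at); far$surface <- surface_frame(far)
  sc <- pottspep:::sidechain_set(far, 2, "V", c(180), ff)
  ctx <- coarse_grained_context(far, 2, ff)
  expect_lt(abs(lj_energy(sc, ctx$plastic, ff) +
                coulomb_energy(sc, ctx$plastic, ff)), 1e-3)
})

test_that("two-body energies are symmetric and decay for distant neutral pairs", {
  conf <- get_toy_conf()
  e12 <- two_body_energy(conf, 1, "K", 2, "E", ff, lib,
                         chis_i = c(180, 180, 180, 180), chis_j = c(180, 180))
  e21 <- two_body_energy(conf, 2, "E", 1, "K", ff, lib,
                         chis_i = c(180, 180), chis_j = c(180, 180, 180, 180))
  expect_equal(e12, e21, tolerance = 1e-12)
  expect_error(two_body_energy(conf, 2, "A", 2, "C", ff, lib),
               class = "pottspep_usage_error")
  long <- make_toy_system(10, seed = 3, slab_margin = 4)
  expect_lt(abs(two_body_energy(long, 1, "V", 10, "V", ff, lib,
                                chis_i = 180, chis_j = 180)), 1e-3)
})

test_that("two-body energy matches a direct atom-pair summation", {
  conf <- get_toy_conf()
  chis_i <- c(-60); chis_j <- c(60)
  sc_i <- pottspep:::sidechain_set(conf, 1, "S", chis_i, ff)
  sc_j <- pottspep:::sidechain_set(conf, 2, "T", chis_j, ff)
  ctx <- coarse_grained_context(conf, c(1, 2), ff)
  allat <- rbind(sc_i, sc_j, ctx$backbone, ctx$plastic, ctx$cg)
  R <- born_radii(allat, ff, indices = seq_len(nrow(sc_i) + nrow(sc_j)))
  manual <- 0
  pref <- -ff$k * (1 / ff$dielectric_in - 1 / ff$dielectric_out)
  for (x in seq_len(nrow(sc_i))) for (y in seq_len(nrow(sc_j))) {
    r <- sqrt(sum((unlist(sc_i[x, c("x", "y", "z")]) -
                   unlist(sc_j[y, c("x", "y", "z")]))^2))
    manual <- manual + ff$k * sc_i$charge[x] * sc_j$charge[y] / r
    eps <- sqrt(sc_i$eps[x] * sc_j$eps[y])
    rm <- sc_i$rmin_half[x] + sc_j$rmin_half[y]
    manual <- manual + eps * ((rm / r)^12 - 2 * (rm / r)^6)
    Ri <- R[x]; Rj <- R[nrow(sc_i) + y]
    fgb <- sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))
    manual <- manual + pref * sc_i$charge[x] * sc_j$charge[y] / fgb
  }
  got <- two_body_energy(conf, 1, "S", 2, "T", ff, lib,
                         chis_i = chis_i, chis_j = chis_j)
  expect_equal(got, manual, tolerance = 1e-9)
})

test_that("build_tables emits complete, deterministic tables that score correctly", {
  conf <- make_toy_system(3, seed = 5, slab_margin = 4)
  al <- c("A", "G", "S", "V")
  tb <- build_tables(conf, ff, lib, alphabet = al, conformation_id = "toy3")
  expect_identical(dim(tb$one_body), c(3L, 4L))
  expect_identical(dim(tb$two_body), c(4L, 3L, 4L, 3L))
  expect_true(all(is.finite(tb$one_body)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_energy_tables(tb, f1)
  write_energy_tables(build_tables(conf, ff, lib, alphabet = al,
                                   conformation_id = "toy3"), f2)
  expect_identical(readLines(f1), readLines(f2))
  m <- potts_model(tb, lambda = 0.01)
  for (seed in 1:3) {
    s <- random_sequence(3, al, seed = seed)
    expect_equal(potts_score(m, s),
                 potts_score_direct(conf, s, ff, lib, lambda = 0.01),
                 tolerance = 1e-9)
  }
})
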
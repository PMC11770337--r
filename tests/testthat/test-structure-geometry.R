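# Hand-built conformation: 2-residue stub above a 3x3 single-layer slab.
flat_conf <- function(cb2 = c(6, 0, 13), z0 = 10) {
  slab <- expand.grid(x = c(0, 4, 8), y = c(0, 4, 8))
  atoms <- rbind(
    data.frame(serial = 1:6, name = c("N", "CA", "C", "O", "CB", "N"),
               resno = c(1, 1, 1, 1, 1, 2), resname = "ALA", segment = "peptide",
               x = c(0, 1.5, 2.5, 3.0, 1.5, 4.0),
               y = c(0, 0, 1, 2, 0, 1),
               z = c(12, 11, 12, 12, 12, 12), element = c("N", "C", "C", "O", "C", "N"),
               stringsAsFactors = FALSE),
    data.frame(serial = 7, name = "CA", resno = 2, resname = "ALA",
               segment = "peptide", x = 6, y = 0, z = 12, element = "C",
               stringsAsFactors = FALSE),
    data.frame(serial = 8, name = "CB", resno = 2, resname = "ALA",
               segment = "peptide", x = cb2[1], y = cb2[2], z = cb2[3],
               element = "C", stringsAsFactors = FALSE),
    data.frame(serial = 9:17, name = "C", resno = 3:11, resname = "PLS",
               segment = "plastic", x = slab$x, y = slab$y, z = z0,
               element = "C", stringsAsFactors = FALSE))
  conf <- system_conformation(atoms)
  conf$surface <- surface_frame(conf)
  conf
}

test_that("surface frame takes the top plastic heavy atom and ignores hydrogens", {
  conf <- flat_conf()
  expect_identical(surface_frame(conf)$z0, 10)
  expect_identical(surface_frame(conf)$normal, c(0, 0, 1))
  at <- conf$atoms
  at$z[at$segment == "plastic"] <- at$z[at$segment == "plastic"] + 3
  shifted <- system_conformation(at)
  expect_identical(surface_frame(shifted)$z0, 13)
  at2 <- rbind(conf$atoms,
               data.frame(serial = 99, name = "H", resno = 12, resname = "PLS",
                          segment = "plastic", x = 0, y = 0, z = 25, element = "H",
                          stringsAsFactors = FALSE))
  expect_identical(surface_frame(system_conformation(at2))$z0, 10)
})

test_that("Cbeta distance is the signed height above the slab top", {
  conf <- flat_conf(cb2 = c(6, 0, 13))
  expect_equal(cbeta_distance(conf, 2), 3)
  conf0 <- flat_conf(cb2 = c(6, 0, 10))
  expect_equal(cbeta_distance(conf0, 2), 0)
  at <- conf$atoms
  at$z <- at$z + 2                               # whole-system translation
  c2 <- system_conformation(at); c2$surface <- surface_frame(c2)
  expect_equal(cbeta_distance(c2, 2), 3)
})

test_that("Calpha-Cbeta angle hits 0, 90 and 180 on constructed cases", {
  expect_equal(ca_cb_angle(flat_conf(cb2 = c(6, 0, 13)), 2), 0)
  expect_equal(ca_cb_angle(flat_conf(cb2 = c(7, 0, 12)), 2), 90)
  expect_equal(ca_cb_angle(flat_conf(cb2 = c(6, 0, 11)), 2), 180)
  # Cbeta on top of Calpha is a degenerate geometry
  expect_error(ca_cb_angle(flat_conf(cb2 = c(6, 0, 12)), 2),
               class = "pottspep_data_error")
})

test_that("structure round-trips through PDB at coordinate precision", {
  conf <- get_toy_conf()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(conf, f)
  c2 <- read_structure(f)
  expect_identical(c2$n_residues, conf$n_residues)
  expect_identical(c2$atoms$segment, conf$atoms$segment)
  expect_lt(max(abs(as.matrix(conf$atoms[, c("x", "y", "z")]) -
                    as.matrix(c2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("peptide-only structures are rejected", {
  conf <- get_toy_conf()
  pep <- conf$atoms[conf$atoms$segment == "peptide", ]
  expect_error(system_conformation(pep), class = "pottspep_data_error")
})

test_that("alignment is the identity on aligned systems and undoes rotations", {
  conf <- get_toy_conf()
  a0 <- align_slab_to_z(conf)
  expect_lt(max(abs(as.matrix(conf$atoms[, c("x", "y", "z")]) -
                    as.matrix(a0$atoms[, c("x", "y", "z")]))), 1e-9)
  # rotate 90 degrees about x: z-spread should become the original y-spread
  at <- conf$atoms
  y <- at$y; z <- at$z
  at$y <- -z; at$z <- y
  rot <- align_slab_to_z(system_conformation(at))
  pl0 <- conf$atoms$segment == "plastic"
  expect_equal(diff(range(rot$atoms$z[pl0])), diff(range(conf$atoms$z[pl0])),
               tolerance = 1e-6)
})

test_that("descriptors are invariant under rigid motion before alignment", {
  conf <- get_toy_conf()
  th <- 0.61
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)), 3, 3)
  at <- conf$atoms
  X <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, c(-7, 3, 12), `+`)
  at$x <- X[, 1]; at$y <- X[, 2]; at$z <- X[, 3]
  moved <- align_slab_to_z(system_conformation(at))
  for (i in c(1, 3)) {
    expect_equal(cbeta_distance(moved, i), cbeta_distance(conf, i), tolerance = 1e-6)
    expect_equal(ca_cb_angle(moved, i), ca_cb_angle(conf, i), tolerance = 1e-6)
    # denser point set so the discretization error stays below the 2% band
    s0 <- cbeta_bare_sasa(conf, i, n_points = 5000)
    expect_lt(abs(cbeta_bare_sasa(moved, i, n_points = 5000) - s0) / max(s0, 1), 0.02)
  }
})

test_that("Shrake-Rupley matches the closed form and a dense-sampling oracle", {
  # isolated carbon sphere: SASA = 4 pi (1.7 + 1.4)^2
  xyz <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(shrake_rupley(xyz, 1.7), 4 * pi * 3.1^2, tolerance = 1e-9)
  # fully buried: octahedral cage of large spheres
  cage <- rbind(c(0, 0, 0), 2.2 * rbind(diag(3), -diag(3)))
  expect_equal(shrake_rupley(cage, c(1.7, rep(2.5, 6)), indices = 1L)[1], 0)
  # two-sphere partial occlusion vs an independent random-point oracle
  xyz2 <- rbind(c(0, 0, 0), c(2.4, 0, 0))
  got <- shrake_rupley(xyz2, c(1.7, 1.7), indices = 1L)
  set.seed(99)
  p <- matrix(stats::rnorm(3 * 1e4), ncol = 3)
  p <- 3.1 * p / sqrt(rowSums(p^2))
  frac <- mean(sqrt(rowSums(sweep(p, 2, xyz2[2, ])^2)) >= 3.1)
  expect_lt(abs(got - 4 * pi * 3.1^2 * frac) / got, 0.02)
  # SASA never exceeds the free-sphere area and shrinks as occluders are added
  expect_lte(got, 4 * pi * 3.1^2)
  xyz3 <- rbind(xyz2, c(-2.4, 0, 0))
  expect_lt(shrake_rupley(xyz3, rep(1.7, 3), indices = 1L), got)
})

test_that("environment binning follows the half-open convention", {
  conf <- flat_conf(cb2 = c(6, 0, 13))    # d = 3.0, angle = 0
  e <- environment_descriptor(conf, 2)
  expect_equal(e$distance, 3)
  expect_identical(unname(e$bin["distance"]), "d[2,4)")
  expect_identical(unname(e$bin["angle"]), "a[0,60)")
  # exact edge belongs to the upper bin
  conf_edge <- flat_conf(cb2 = c(6, 0, 14))  # d = 4.0
  expect_identical(unname(environment_descriptor(conf_edge, 2)$bin["distance"]),
                   "d[4,6)")
  # closed top angle bin
  conf180 <- flat_conf(cb2 = c(6, 0, 11))
  expect_identical(unname(environment_descriptor(conf180, 2)$bin["angle"]),
                   "a[120,180)")
})

test_that("environment tables skip glycine and cover all other residues", {
  conf <- get_toy_conf()
  tab <- environment_table(conf, sequence = c("A", "G", "K", "A"))
  expect_identical(attr(tab, "skipped"), 2L)
  expect_identical(tab$residue, c(1L, 3L, 4L))
})
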
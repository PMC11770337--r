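ff <- default_forcefield()
atom <- function(x, y, z, type) data.frame(x = x, y = y, z = z, type = type,
                                           stringsAsFactors = FALSE)

test_that("Coulomb energy has the closed form, antisymmetry and 1/r decay", {
  a <- atom(0, 0, 0, "N_POS")       # +1 e
  b <- atom(1, 0, 0, "N_POS")
  expect_equal(coulomb_energy(a, b, ff), 332.0636, tolerance = 1e-9)
  neg <- atom(1, 0, 0, "C_CRX")     # -1 e
  expect_equal(coulomb_energy(a, neg, ff), -332.0636, tolerance = 1e-9)
  b2 <- atom(2, 0, 0, "N_POS")
  expect_equal(coulomb_energy(a, b2, ff), coulomb_energy(a, b, ff) / 2,
               tolerance = 1e-12)
  expect_error(coulomb_energy(a, atom(0, 0, 0, "N_POS"), ff),
               class = "pottspep_numeric_error")
})

test_that("LJ energy equals -eps at the combined rmin and matches brute force", {
  a <- atom(0, 0, 0, "C_ALI")
  rmin <- 2 * ff$types["C_ALI", "rmin_half"]
  b <- atom(rmin, 0, 0, "C_ALI")
  expect_equal(lj_energy(a, b, ff), -ff$types["C_ALI", "eps"], tolerance = 1e-9)
  far <- atom(500, 0, 0, "C_ALI")
  expect_lt(abs(lj_energy(a, far, ff)), 1e-12)
  # 10-atom fixture vs direct double-loop summation
  set.seed(4)
  A <- data.frame(x = runif(5, 0, 4), y = runif(5, 0, 4), z = runif(5, 0, 4),
                  type = sample(c("C_ALI", "O_HYD", "S_THI"), 5, TRUE))
  B <- data.frame(x = runif(5, 5, 9), y = runif(5, 0, 4), z = runif(5, 0, 4),
                  type = sample(c("C_ALI", "N_POS"), 5, TRUE))
  Ar <- pottspep:::resolve_params(A, ff); Br <- pottspep:::resolve_params(B, ff)
  manual <- 0
  for (i in 1:5) for (j in 1:5) {
    r <- sqrt(sum((unlist(Ar[i, c("x", "y", "z")]) - unlist(Br[j, c("x", "y", "z")]))^2))
    e <- sqrt(Ar$eps[i] * Br$eps[j]); rm <- Ar$rmin_half[i] + Br$rmin_half[j]
    manual <- manual + e * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  expect_equal(lj_energy(A, B, ff), manual, tolerance = 1e-9)
})

test_that("Born radii: isolated atoms keep their intrinsic radius, burial grows it", {
  a <- pottspep:::resolve_params(atom(0, 0, 0, "C_ALI"), ff)
  expect_equal(born_radii(a, ff), ff$types["C_ALI", "gb_radius"], tolerance = 1e-12)
  cage <- pottspep:::resolve_params(
    rbind(atom(0, 0, 0, "C_ALI"),
          atom(3, 0, 0, "C_ALI"), atom(-3, 0, 0, "C_ALI"),
          atom(0, 3, 0, "C_ALI"), atom(0, -3, 0, "C_ALI"),
          atom(0, 0, 3, "C_ALI"), atom(0, 0, -3, "C_ALI")), ff)
  expect_gt(born_radii(cage, ff, indices = 1L), ff$types["C_ALI", "gb_radius"])
})

test_that("pairwise descreening matches a Monte Carlo volume integral", {
  # 5-atom cluster; oracle integrates 1/(4 pi r^4) over each neighbor sphere
  set.seed(8)
  pts <- rbind(c(0, 0, 0), c(3.1, 0, 0), c(-2.9, 0.5, 0), c(0, 3.4, 0.4),
               c(0.5, -3.0, 1.0))
  atoms <- pottspep:::resolve_params(
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], type = "C_ALI"), ff)
  rho <- atoms$gbr[1]
  mc <- 0
  for (j in 2:5) {
    aj <- atoms$gbr[j]
    u <- matrix(runif(3 * 2e5, -aj, aj), ncol = 3)
    u <- u[rowSums(u^2) <= aj^2, , drop = FALSE]
    r <- sqrt(rowSums(sweep(u, 2, -pts[j, ])^2))   # distance to atom 1 at origin
    vol <- 4 / 3 * pi * aj^3
    mc <- mc + vol * mean(ifelse(r > rho, 1 / (4 * pi * r^4), 0))
  }
  inv_direct <- 1 / rho - mc
  got <- born_radii(atoms, ff, indices = 1L)
  expect_lt(abs(1 / got - inv_direct) / abs(inv_direct), 0.05)
})

test_that("GB cross term has the Still self-limit and vanishes without contrast", {
  a <- pottspep:::resolve_params(atom(0, 0, 0, "N_POS"), ff)
  b <- pottspep:::resolve_params(atom(0.0, 0, 0, "N_POS"), ff)
  # r = 0 limit: f_GB = sqrt(R_i R_j) = 2
  got <- gb_pair_energy(a, b, 2, 2, ff)
  expect_equal(got, -332.0636 * (1 - 1 / 78.5) / 2, tolerance = 1e-9)
  ff0 <- read_forcefield(dielectric_in = 78.5, dielectric_out = 78.5)
  expect_equal(gb_pair_energy(a, b, 2, 2, ff0), 0, tolerance = 1e-12)
  expect_error(gb_pair_energy(a, b, -1, 2, ff), class = "pottspep_numeric_error")
})

test_that("GB matches hand-computed f_GB values on a 3-atom case", {
  a <- pottspep:::resolve_params(rbind(atom(0, 0, 0, "N_POS"),
                                       atom(2, 0, 0, "C_CRX")), ff)
  b <- pottspep:::resolve_params(atom(0, 3, 0, "N_POS"), ff)
  Ra <- c(1.6, 1.9); Rb <- 2.1
  hand <- 0
  pref <- -332.0636 * (1 - 1 / 78.5)
  for (i in 1:2) {
    r <- sqrt(sum((unlist(a[i, c("x", "y", "z")]) - c(0, 3, 0))^2))
    fgb <- sqrt(r^2 + Ra[i] * Rb * exp(-r^2 / (4 * Ra[i] * Rb)))
    hand <- hand + pref * a$charge[i] * b$charge[1] / fgb
  }
  expect_equal(gb_pair_energy(a, b, Ra, Rb, ff), hand, tolerance = 1e-9)
})

test_that("f_GB approaches r as Born radii shrink (screened-Coulomb limit)", {
  r <- 3.7
  for (R in c(1e-2, 1e-3, 1e-4))
    expect_equal(pottspep:::gb_f(r, R, R), r, tolerance = 1e-4)
})

test_that("energies are invariant under whole-system translation", {
  set.seed(12)
  A <- data.frame(x = runif(4), y = runif(4), z = runif(4),
                  type = c("N_POS", "C_ALI", "O_HYD", "C_CRX"))
  B <- data.frame(x = runif(3) + 4, y = runif(3), z = runif(3),
                  type = c("C_ALI", "N_POS", "S_THI"))
  sh <- function(d, v) { d$x <- d$x + v[1]; d$y <- d$y + v[2]; d$z <- d$z + v[3]; d }
  v <- c(11, -7, 3)
  expect_equal(coulomb_energy(A, B, ff), coulomb_energy(sh(A, v), sh(B, v), ff),
               tolerance = 1e-9)
  expect_equal(lj_energy(A, B, ff), lj_energy(sh(A, v), sh(B, v), ff),
               tolerance = 1e-9)
  all1 <- pottspep:::resolve_params(rbind(A, B), ff)
  all2 <- pottspep:::resolve_params(rbind(sh(A, v), sh(B, v)), ff)
  expect_equal(born_radii(all1, ff), born_radii(all2, ff), tolerance = 1e-9)
})

test_that("energy breakdown books its own total", {
  br <- energy_breakdown(-1.5, 2.25, -0.5)
  expect_equal(br$total, br$elec + br$lj + br$gb, tolerance = 1e-12)
})
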
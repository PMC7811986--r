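# Finite-volume assembly and the complex-symmetric solve.

tt1 <- function() const_tissue_table()

test_that("stencil assembly matches hand-computed coefficients", {
  # 4-voxel bar, sigma = 1 S/m, 1 mm spacing: interior coupling sigma*A/d
  ph <- make_bar_phantom(c(4, 1, 1), spacing = 1)
  sys <- assemble_system(ph, tt1(), contact_scenario("LH-RH", 0, 1, "INTERN"))
  expect_identical(sys$n, 2L)
  Y <- 1 * 1e-3  # sigma * (s^2 * 1e-6) / (s * 1e-3)
  M <- as.matrix(sys$R)
  expect_equal(M, rbind(c(2 * Y, -Y), c(-Y, 2 * Y)))
  expect_equal(sys$b, complex(real = c(Y, 0)))
  # harmonic-mean face admittance between sigma = 1 and sigma = 3
  labels <- array(contactdose:::.TISSUE_IDS[["muscle"]], c(4, 1, 1))
  labels[3:4, , ] <- contactdose:::.TISSUE_IDS[["bone"]]
  ph2 <- make_bar_phantom(c(4, 1, 1), spacing = 1, labels = labels)
  tt <- const_tissue_table(sigma = c(muscle = 1, bone = 3))
  sys2 <- assemble_system(ph2, tt, contact_scenario("LH-RH", 0, 1, "INTERN"))
  M2 <- as.matrix(sys2$R)
  expect_equal(M2[1, 2], -2 * 1 * 3 / (1 + 3) * 1e-3)  # 1.5e-3 coupling
  # at f = 0 the assembled matrix is real and symmetric
  expect_null(sys2$I)
  expect_true(Matrix::isSymmetric(sys2$R))
})

test_that("homogeneous bar gives the exact affine potential profile", {
  ph <- make_bar_phantom(c(21, 2, 2), spacing = 5)
  sol <- solve_potential(assemble_system(ph, tt1(),
                                         contact_scenario("LH-RH", 0, 1, "INTERN")))
  prof <- Re(sol$potential[, 1, 1])
  expect_lt(max(abs(prof - seq(1, 0, length.out = 21))), 1e-8)
  # orientation invariance: the same bar along z gives the same profile
  phz <- make_bar_phantom(c(2, 2, 21), spacing = 5, axis = 3)
  solz <- solve_potential(assemble_system(phz, tt1(),
                                          contact_scenario("LH-RH", 0, 1, "INTERN")))
  expect_equal(Re(solz$potential[1, 1, ]), prof, tolerance = 1e-10)
})

test_that("two-layer bar matches the series voltage-divider closed form", {
  n <- c(21, 2, 2)
  ids <- contactdose:::.TISSUE_IDS
  labels <- array(ids[["muscle"]], n)
  labels[12:21, , ] <- ids[["fat"]]
  ph <- make_bar_phantom(n, spacing = 5, labels = labels)
  tt <- const_tissue_table(sigma = c(muscle = 1, fat = 0.2))
  sol <- solve_potential(assemble_system(ph, tt,
                                         contact_scenario("LH-RH", 0, 1, "INTERN")))
  sol <- derive_fields(sol)
  # independent series-resistance closed form, face by face: faces 1..10 at
  # sigma = 1, the interface face at the harmonic mean, faces 12..20 at 0.2
  A <- 4 * 25e-6; d <- 5e-3
  rface <- function(s) d / (s * A)
  faces <- c(rep(rface(1), 10), rface(2 * 1 * 0.2 / 1.2), rep(rface(0.2), 9))
  I_exp <- 1 / sum(faces)
  ib <- body_current(sol, 4)
  expect_equal(as.numeric(Mod(as.complex(ib))), I_exp, tolerance = 1e-10)
  # interface potential equals the voltage-divider value
  phi_if <- Re(sol$potential[11, 1, 1])
  expect_equal(phi_if, 1 - I_exp * sum(faces[1:10]), tolerance = 1e-10)
  # |J| continuous across the interface while |E| jumps by sigma1/sigma2
  Jx <- Mod(sol$J[[1]][, 1, 1]); Ex <- Mod(sol$E[[1]][, 1, 1])
  expect_equal(Jx[9], Jx[13], tolerance = 1e-6)
  expect_equal(Ex[13] / Ex[9], 1 / 0.2, tolerance = 1e-6)
})

test_that("sparse solves agree with a dense complex direct oracle", {
  n <- c(12, 12, 12)
  ids <- contactdose:::.TISSUE_IDS
  mix <- c(ids[["muscle"]], ids[["fat"]], ids[["bone"]], ids[["heart_blood"]])
  pat <- array(0L, n)
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    pat[i, j, k] <- mix[(i + 2 * j + 3 * k) %% 4 + 1]
  }
  ph <- make_bar_phantom(n, spacing = 3, labels = pat)
  sys <- assemble_system(ph, default_tt(), contact_scenario("LH-RH", 50, 10, "INTERN"))
  A <- as_dense_matrix(sys)
  x_dense <- solve(A, sys$b)
  sol_direct <- solve_potential(sys, method = "direct")
  sol_cocg <- solve_potential(sys, method = "cocg", tolerance = 1e-12,
                              max_iter = 300)
  x_direct <- sol_direct$potential[sys$unknown_lin]
  x_cocg <- sol_cocg$potential[sys$unknown_lin]
  scale <- max(Mod(x_dense))
  expect_lt(max(Mod(x_direct - x_dense)) / scale, 1e-8)
  expect_lt(max(Mod(x_cocg - x_dense)) / scale, 1e-8)
})

test_that("solution is linear in the touch voltage", {
  ph <- make_bar_phantom(c(15, 3, 3), spacing = 4)
  tt <- default_tt()
  s1 <- solve_potential(assemble_system(ph, tt, contact_scenario("LH-RH", 50, 1, "INTERN")))
  s2 <- solve_potential(assemble_system(ph, tt, contact_scenario("LH-RH", 50, 2, "INTERN")))
  dom <- !is.na(s1$potential)
  rel <- Mod(s2$potential[dom] - 2 * s1$potential[dom]) / max(Mod(s2$potential[dom]))
  expect_lt(max(rel), 1e-10)
})

test_that("swapping source and sink reflects the potential and preserves |Z|", {
  n <- c(17, 3, 3)
  ids <- contactdose:::.TISSUE_IDS
  labels <- array(ids[["muscle"]], n)
  labels[9:17, , ] <- ids[["fat"]]
  ph <- make_bar_phantom(n, spacing = 4, labels = labels)
  tt <- const_tissue_table(sigma = c(muscle = 0.35, fat = 0.04))
  fwd <- derive_fields(solve_potential(assemble_system(
    ph, tt, contact_scenario("LH-RH", 0, 10, "INTERN"))))
  # swap: drive RH as source at the same voltage
  ph_swap <- ph
  ph_swap$pads <- ph$pads[c("RH", "LH")]
  names(ph_swap$pads) <- c("LH", "RH")
  rev <- derive_fields(solve_potential(assemble_system(
    ph_swap, tt, contact_scenario("LH-RH", 0, 10, "INTERN"))))
  dom <- !is.na(fwd$potential)
  expect_lt(max(Mod(rev$potential[dom] - (10 - fwd$potential[dom]))), 1e-8)
  z1 <- Mod(total_impedance(10, as.complex(body_current(fwd, 3))))
  z2 <- Mod(total_impedance(10, as.complex(body_current(rev, 3))))
  expect_lt(abs(z1 - z2) / z1, 1e-8)
})

test_that("uniform-conductivity fields are divergence-free away from sources", {
  ph <- make_bar_phantom(c(15, 6, 6), spacing = 4)
  sol <- derive_fields(solve_potential(assemble_system(
    ph, tt1(), contact_scenario("LH-RH", 0, 1, "INTERN"))))
  # discrete Laplacian over interior voxels must vanish (flux conservation)
  d <- dim(ph$labels)
  p0 <- Re(sol$potential)
  core <- function(di) p0[(2 + di[1]):(d[1] - 1 + di[1]),
                          (2 + di[2]):(d[2] - 1 + di[2]),
                          (2 + di[3]):(d[3] - 1 + di[3])]
  div <- -6 * core(c(0, 0, 0))
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    div <- div + core(e) + core(-e)
  }
  expect_lt(max(abs(div)), 1e-9)
})

test_that("non-convergence raises an error carrying the residual history", {
  ph <- make_bar_phantom(c(25, 4, 4), spacing = 4)
  sys <- assemble_system(ph, default_tt(), contact_scenario("LH-RH", 50, 1, "INTERN"))
  expect_error(solve_potential(sys, method = "cocg", tolerance = 0,
                               max_iter = 2),
               "did not converge")
  expect_error(assemble_system(ph, default_tt()[2:3, ],
                               contact_scenario("LH-RH", 50, 1, "INTERN")),
               "entry for tissue")
})
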
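# Dose quantities: body current, impedance, the myocardial percentile field,
# the trans-cardiac line integrals, and the HCF normalization.

test_that("body current matches slab closed forms and conserves across planes", {
  # homogeneous bar: sigma=1 S/m, A=1 cm^2, L=10 cm, U=1 V -> I = 1 mA
  ph <- make_bar_phantom(c(21, 2, 2), spacing = 5)
  sol <- derive_fields(solve_potential(assemble_system(
    ph, const_tissue_table(), contact_scenario("LH-RH", 0, 1, "INTERN"))))
  ib <- body_current(sol, 4)
  expect_equal(as.numeric(Mod(as.complex(ib))), 1e-3, tolerance = 1e-3)
  expect_lt(attr(ib, "spread"), 0.01)
  expect_length(attr(ib, "per_plane"), 4L)
})

test_that("impedance via Ohm's law and the TOTAL/INTERN ordering", {
  expect_equal(total_impedance(1, 1e-3 + 0i), 1000 + 0i)
  expect_error(total_impedance(1, 0 + 0i), "zero")
  ph <- small_phantom()
  tt <- default_tt()
  z_int <- local({
    s <- solve_scenario(ph, tt, contact_scenario("LH-RH", 50, 25, "INTERN"))
    Mod(total_impedance(25, as.complex(body_current(s, 4))))
  })
  z_tot <- local({
    s <- solve_scenario(ph, tt, contact_scenario("LH-RH", 50, 25, "TOTAL"))
    Mod(total_impedance(25, as.complex(body_current(s, 4))))
  })
  expect_gt(z_tot, z_int)  # added series skin layer
})

test_that("|Z| of the TOTAL body model is non-increasing with frequency", {
  ph <- small_phantom()
  tt <- default_tt()
  freqs <- c(50, 1e3, 1e4, 1e5)
  zm <- vapply(freqs, function(f) {
    s <- solve_scenario(ph, tt, contact_scenario("LH-RH", f, 25, "TOTAL"))
    Mod(total_impedance(25, as.complex(body_current(s, 4))))
  }, numeric(1))
  expect_true(all(diff(zm) < 0))
  # the drop is dominated by the skin layer shorting out above 10 kHz
  expect_lt(zm[4] / zm[1], 0.5)
})

test_that("myocardial percentile field follows the stated convention", {
  # uniform field over the shell
  expect_equal(e99_heart(fake_field_solution(rep(7.5, 500))), 7.5)
  # 100 voxels with |E| = 1..100: linear order-statistic interpolation
  expect_equal(e99_heart(fake_field_solution(1:100)), 99.01)
  # scaling equivariance
  x <- exp(sin(1:321))
  expect_equal(e99_heart(fake_field_solution(3 * x)),
               3 * e99_heart(fake_field_solution(x)))
  # matches the independent sorted oracle
  expect_equal(e99_heart(fake_field_solution(x)), oracle_q99(x))
  s <- fake_field_solution(1:10); s$E <- NULL
  expect_error(e99_heart(s), "not derived")
})

test_that("trans-cardiac line integrals recover uniform and gradient fields", {
  ids <- contactdose:::.TISSUE_IDS
  n <- c(30, 30, 30)
  mk_sol <- function(phi_fun = NULL, E_const = NULL) {
    labels <- array(ids[["heart_muscle"]], n)
    axes <- list(a1 = rbind(c(20, 58, 58), c(96, 58, 58)),
                 a2 = rbind(c(58, 20, 58), c(58, 96, 58)),
                 a3 = rbind(c(58, 58, 20), c(58, 58, 96)))
    ph <- structure(list(labels = labels, spacing = 4, origin = c(0, 0, 0),
                         tissue_map = stats::setNames(names(ids), as.character(ids)),
                         sites = list(), site_areas = numeric(),
                         heart_axes = axes, heart_center = c(58, 58, 58),
                         config = NULL, pads = list()),
                    class = "voxel_phantom")
    sol <- structure(list(potential = NULL, residual = 0, iterations = 1L,
                          method = "direct", frequency = 0,
                          scenario = contact_scenario("LH-RH", 0, 1, "INTERN"),
                          phantom = ph, sig_grid = array(1 + 0i, n),
                          E = NULL, J = NULL), class = "field_solution")
    if (!is.null(E_const)) {
      sol$E <- lapply(E_const, function(v) array(complex(real = v), n))
    } else {
      phi <- array(0, n)
      for (k in 1:n[3]) phi[, , k] <- phi_fun((k - 1) * 4)
      sol$potential <- array(complex(real = phi), n)
      sol <- derive_fields(sol)
    }
    sol
  }
  # uniform field aligned with axis 1
  s1 <- mk_sol(E_const = list(4.2, 0, 0))
  expect_equal(as.numeric(sam_field(s1)), 4.2, tolerance = 1e-9)
  # uniform field at equal angles to all three axes: norm recovered
  s2 <- mk_sol(E_const = as.list(rep(5 / sqrt(3), 3)))
  expect_equal(as.numeric(sam_field(s2)), 5, tolerance = 1e-9)
  # quadratic potential in z (E linear in z): the axis voltage equals the
  # endpoint potential difference (gradient-theorem oracle) within 0.1%
  phi_fun <- function(z_mm) 1e-3 * z_mm^2 + 0.05 * z_mm
  s3 <- mk_sol(phi_fun = phi_fun)
  pa <- attr(sam_field(s3), "per_axis")
  v3 <- pa$voltage[pa$axis == "a3"]
  v_expected <- abs(phi_fun(96) - phi_fun(20))
  expect_equal(v3, v_expected, tolerance = 1e-3)
})

test_that("HCF table implements the reference-normalized ratio", {
  dose <- tibble::tibble(
    path = c("LH-BF", "X-Y", "LH-BF", "X-Y"),
    frequency = c(50, 50, 1000, 1000),
    i_body_a = c(1, 4, 1, 1),
    e99_heart = c(1, 2, 1, 1),
    e_sam = c(1, 2, 1, 1)
  )
  h <- hcf_table(dose)
  expect_identical(h$f99[h$path == "LH-BF"], c(1, 1))  # exactly 1.0
  expect_identical(h$f99[h$path == "X-Y" & h$frequency == 50], 0.5)
  expect_identical(h$f99[h$path == "X-Y" & h$frequency == 1000], 1)
  expect_identical(h$f_sam[h$path == "X-Y" & h$frequency == 50], 0.5)
  # wide layout mirrors paths-as-rows, frequencies-as-columns
  w <- hcf_wide(h)
  expect_identical(names(w), c("path", "f_50", "f_1000"))
  # missing reference frequency is an error
  expect_error(hcf_table(dose[dose$frequency == 50 | dose$path != "LH-BF", ]),
               "missing at frequencies")
})

test_that("plane placement fails when no plane separates the electrodes", {
  ph <- make_bar_phantom(c(9, 3, 3), spacing = 4)
  ph$pads$RH$dirichlet <- ph$pads$LH$dirichlet  # degenerate: same slice
  sol <- structure(list(potential = array(0 + 0i, c(9, 3, 3)),
                        sig_grid = array(1 + 0i, c(9, 3, 3)),
                        scenario = contact_scenario("LH-RH", 0, 1, "INTERN"),
                        phantom = ph), class = "field_solution")
  expect_error(body_current(sol, 2), "separates")
})

test_that("electrode proximity to the heart increases myocardial field inhomogeneity", {
  # the anterior-thorax electrode sits directly over the heart; its relative
  # field dispersion over the myocardium exceeds the distributed
  # longitudinal reference path
  at <- sol_default("AT-LH", 50)
  bf <- sol_default("LH-BF", 50)
  expect_gt(iqr_over_median(at), iqr_over_median(bf))
})
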
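# Body-model regime classification, skin-slice properties, slab impedance,
# and the skin-property fit.

test_that("regime classification matches the frequency/voltage table", {
  expect_identical(select_body_model(50, 100), "TOTAL")
  expect_identical(select_body_model(5e4, 50), "INTERN")
  expect_identical(select_body_model(50, 400), "INTERN")
  expect_identical(select_body_model(5e3, 100), "CASE_BY_CASE")
  # boundary conventions
  expect_identical(select_body_model(1e3, 100), "TOTAL")
  expect_identical(select_body_model(1e4, 100), "CASE_BY_CASE")
  expect_identical(select_body_model(50, 220), "TOTAL")
  expect_identical(select_body_model(1e4 + 1, 100), "INTERN")
  expect_warning(out <- select_body_model(50, 10), "below 25 V")
  expect_identical(out, "TOTAL")
})

test_that("skin-slice properties reproduce the tabulated voltages exactly", {
  got <- skin_props(c(25, 50, 100, 220))
  expect_identical(got$sigma, c(0.14e-3, 0.19e-3, 0.27e-3, 0.85e-3))
  expect_identical(got$eps_r, c(2.4e4, 3.9e4, 6.4e4, 13.2e4))
  # strict monotonicity over the interpolated range
  v <- seq(25, 220, length.out = 80)
  sp <- skin_props(v)
  expect_true(all(diff(sp$sigma) > 0))
  expect_true(all(diff(sp$eps_r) > 0))
  # conductivity rises by a factor that rounds to 6 between 25 and 220 V
  expect_identical(round(0.85e-3 / 0.14e-3), 6)
  expect_error(skin_props(24.9), "no extrapolation")
  expect_error(skin_props(221), "no extrapolation")
})

test_that("slab impedance: DC resistance, capacitive shorting, hand oracle", {
  # DC slab resistance L/(sigma A)
  z0 <- two_layer_impedance(list(sigma = 1, eps_r = 1), thickness = 2,
                            area = 0.01, z_intern = 0, frequency = 0)
  expect_equal(z0, 0.2 + 0i)
  # f -> infinity: capacitive short, Z -> z_intern
  zi <- 500 + 0i
  zhi <- two_layer_impedance(skin_props(25), 2, 0.01, zi, 1e12)
  expect_equal(Mod(zhi), Mod(zi), tolerance = 1e-4)
  # independent complex-arithmetic oracle at 25 V, 50 Hz
  sk <- skin_props(25)
  sig_star <- complex(real = 0.14e-3,
                      imaginary = 2 * pi * 50 * 8.854e-12 * 2.4e4)
  z_oracle <- 0.002 / (0.01 * sig_star) + 500
  expect_equal(two_layer_impedance(sk, 2, 0.01, 500, 50), z_oracle,
               tolerance = 1e-12)
  # |Z| non-increasing in frequency for fixed real internal impedance
  f <- 10^seq(0, 6, length.out = 50)
  zm <- Mod(two_layer_impedance(sk, 2, 0.01, 500, f))
  expect_true(all(diff(zm) <= 1e-9))
  # above 10 kHz the slab contributes < 20% of a 500 Ohm internal impedance
  z20k <- two_layer_impedance(sk, 2, 0.01, 0, 2e4)
  expect_lt(Mod(z20k), 0.2 * 500)
  expect_error(two_layer_impedance(sk, 2, 0, 500, 50), "area")
})

test_that("skin fit recovers parameters and orders voltages correctly", {
  freqs <- c(25, 50, 100, 200, 400, 600, 800, 1000)
  truth <- skin_props(c(25, 100, 220))
  ref <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    z <- Mod(two_layer_impedance(truth[i, ], 2, 0.01, 500, freqs))
    tibble::tibble(frequency_hz = freqs,
                   touch_voltage_v = truth$touch_voltage[i], z_ohm = z)
  }))
  fit <- fit_skin_properties(ref, 500, 2, 0.01)
  expect_equal(fit$sigma, truth$sigma, tolerance = 0.01)
  expect_equal(fit$eps_r, truth$eps_r, tolerance = 0.01)
  # increasing voltage targets (decreasing |Z|) give increasing sigma
  expect_true(all(diff(fit$sigma) > 0))
  # tidy/glance surfaces
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(glance(fit),
               c("n_voltages", "rel_rms_residual", "thickness_mm", "area_m2"))
  expect_lt(glance(fit)$rel_rms_residual, 1e-3)
})

test_that("skin fit under multiplicative noise meets the established tolerance", {
  # tolerance established by Monte-Carlo: median relative recovery error
  # over replicates stays under 15% at 5% noise with 8 frequencies
  freqs <- c(25, 50, 100, 200, 400, 600, 800, 1000)
  true_sigma <- 0.27e-3; true_eps <- 6.4e4
  z_true <- Mod(two_layer_impedance(list(sigma = true_sigma, eps_r = true_eps),
                                    2, 0.01, 500, freqs))
  set.seed(20260919)
  errs <- t(replicate(40, {
    z_noisy <- pmax(z_true * (1 + 0.05 * rnorm(length(freqs))), 1)
    ref <- tibble::tibble(frequency_hz = freqs, touch_voltage_v = 100,
                          z_ohm = z_noisy)
    fit <- fit_skin_properties(ref, 500, 2, 0.01)
    c(abs(fit$sigma - true_sigma) / true_sigma,
      abs(fit$eps_r - true_eps) / true_eps)
  }))
  expect_lt(median(errs[, 1]), 0.15)
  expect_lt(median(errs[, 2]), 0.15)
})

test_that("impedance curves round-trip and are validated", {
  cur <- tibble::tibble(frequency_hz = c(50, 100), touch_voltage_v = 50,
                        z_ohm = c(2000, 1500))
  path <- withr::local_tempfile(fileext = ".csv")
  write_impedance_curve(cur, path)
  back <- read_impedance_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(cur))
  bad <- cur; bad$z_ohm[1] <- -1
  write_impedance_curve(bad, path)
  expect_error(read_impedance_curve(path), "magnitudes")
})
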
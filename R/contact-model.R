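# Two-body-model contact framework: regime classification by frequency and
# touch voltage, the voltage-dependent skin-slice dielectric table, the
# series slab impedance of the contact layer, and least-squares fitting of
# skin-slice properties to reference |Z| curves.

# Skin-slice properties by touch voltage (validated range 25-220 V).
# Conductivity in S/m, permittivity dimensionless; both increase with
# touch voltage (partial skin breakdown).
.SKIN_TABLE <- data.frame(
  touch_voltage = c(25, 50, 100, 220),
  sigma = c(0.14e-3, 0.19e-3, 0.27e-3, 0.85e-3),
  eps_r = c(2.4e4, 3.9e4, 6.4e4, 13.2e4)
)

#' Body-model regime for a contact-current scenario
#'
#' Classifies an exposure by frequency and touch voltage into the body model
#' that must be used: `TOTAL` (skin layer included), `INTERN` (skin
#' negligible: high frequency or skin breakdown above 220 V), or
#' `CASE_BY_CASE` (1-10 kHz band at intact-skin voltages, to be assessed
#' individually). Interval conventions at the printed boundaries: f = 1 kHz
#' is still `TOTAL`, f = 10 kHz is still `CASE_BY_CASE`, and U_t = 220 V
#' belongs to the intact-skin row.
#'
#' @param frequency Frequency in Hz (>= 0).
#' @param touch_voltage Touch voltage in V (> 0). Values below 25 V are
#'   outside the validated range and trigger a warning but are classified.
#' @return One of `"TOTAL"`, `"CASE_BY_CASE"`, `"INTERN"` (vectorized over
#'   the longer of the two inputs).
#' @export
select_body_model <- function(frequency, touch_voltage) {
  stopifnot(all(frequency >= 0), all(touch_voltage > 0))
  n <- max(length(frequency), length(touch_voltage))
  frequency <- rep_len(frequency, n)
  touch_voltage <- rep_len(touch_voltage, n)
  if (any(touch_voltage < 25)) {
    warning("touch voltage below 25 V is outside the validated range; ",
            "classification returned anyway")
  }
  dplyr::case_when(
    touch_voltage > 220 ~ "INTERN",
    frequency <= 1e3 ~ "TOTAL",
    frequency <= 1e4 ~ "CASE_BY_CASE",
    TRUE ~ "INTERN"
  )
}

#' Skin-slice dielectric properties at a touch voltage
#'
#' Returns the conductivity and relative permittivity of the 2-mm contact
#' skin slice. At the four tabulated voltages (25, 50, 100, 220 V) the
#' tabulated values are returned exactly; between them both properties are
#' interpolated linearly in log(voltage). No extrapolation: outside
#' `[25, 220]` V an error is raised.
#'
#' @param touch_voltage Touch voltage(s) in V, within `[25, 220]`.
#' @return Tibble with columns `touch_voltage`, `sigma` (S/m), `eps_r`.
#' @examples
#' skin_props(c(25, 100, 220))
#' @export
skin_props <- function(touch_voltage) {
  if (any(touch_voltage < 25 | touch_voltage > 220)) {
    stop("touch voltage outside the tabulated range [25, 220] V; ",
         "no extrapolation is performed")
  }
  lv <- log(touch_voltage)
  lt <- log(.SKIN_TABLE$touch_voltage)
  tibble::tibble(
    touch_voltage = as.numeric(touch_voltage),
    sigma = stats::approx(lt, .SKIN_TABLE$sigma, xout = lv)$y,
    eps_r = stats::approx(lt, .SKIN_TABLE$eps_r, xout = lv)$y
  )
}

#' Series impedance of the contact skin slice plus internal impedance
#'
#' The contact layer is a parallel-RC slab: Z_skin(f) =
#' thickness / (area * (sigma + j*2*pi*f*eps0*eps_r)); the total is
#' Z_skin + z_intern. |Z| is non-increasing in frequency for fixed real
#' z_intern (the capacitive branch shorts the slab at high f).
#'
#' @param skin One-row output of [skin_props()] (or any list with `sigma`,
#'   `eps_r`).
#' @param thickness Slab thickness in mm (default 2 mm).
#' @param area Contact area in m^2 (> 0).
#' @param z_intern Internal body impedance in Ohm (complex allowed).
#' @param frequency Frequencies in Hz.
#' @return Complex impedance(s) in Ohm.
#' @export
two_layer_impedance <- function(skin, thickness = 2, area, z_intern, frequency) {
  if (!is.numeric(area) || any(area <= 0)) stop("contact area must be positive")
  if (any(thickness <= 0)) stop("slab thickness must be positive")
  sig_star <- complex(real = skin$sigma,
                      imaginary = 2 * pi * frequency * EPS0 * skin$eps_r)
  (thickness * 1e-3) / (area * sig_star) + z_intern
}

#' Fit skin-slice properties to a reference impedance curve
#'
#' Recovers per-voltage (sigma, eps_r) of the contact slab by least-squares
#' on the relative error of |Z| against reference points, using the slab
#' model of [two_layer_impedance()]. Only the magnitude is fitted (reference
#' sources report |Z|); the per-frequency residual profile is returned so
#' the frequency anchoring of the permittivity can be inspected.
#'
#' @param reference Data frame with columns `frequency_hz`, `touch_voltage_v`,
#'   `z_ohm` (impedance magnitude, Ohm). At least 2 frequencies <= 1 kHz per
#'   voltage level are required; points above 1 kHz are ignored (the slab
#'   table is an ELF model).
#' @param z_intern_by_freq Function `f(frequency_hz) -> complex z_intern`,
#'   or a single number used at all frequencies.
#' @param thickness Slab thickness in mm.
#' @param area Contact area in m^2.
#' @return An object of class `skin_fit`: tibble of per-voltage estimates
#'   (`touch_voltage`, `sigma`, `eps_r`, `rel_rms_residual`, `converged`)
#'   plus a `residuals` attribute with the per-point residual profile.
#'   [tidy()][generics::tidy] and `glance()` methods are provided.
#' @export
fit_skin_properties <- function(reference, z_intern_by_freq, thickness = 2, area) {
  stopifnot(all(c("frequency_hz", "touch_voltage_v", "z_ohm") %in% names(reference)))
  if (any(reference$z_ohm <= 0) || any(reference$frequency_hz < 0)) {
    stop("reference curve needs frequencies >= 0 and |Z| > 0")
  }
  zfun <- if (is.function(z_intern_by_freq)) z_intern_by_freq else {
    zi <- z_intern_by_freq
    function(f) rep_len(zi, length(f))
  }
  ref <- dplyr::filter(reference, .data$frequency_hz <= 1e3)
  fits <- dplyr::group_by(ref, .data$touch_voltage_v)
  fits <- dplyr::group_split(fits)
  resid_rows <- list()
  rows <- purrr::map(fits, function(g) {
    if (nrow(g) < 2L) {
      stop("need >= 2 reference frequencies <= 1 kHz at U_t = ",
           g$touch_voltage_v[1], " V")
    }
    zi <- zfun(g$frequency_hz)
    obj <- function(logp) {
      sk <- list(sigma = exp(logp[1]), eps_r = exp(logp[2]))
      zm <- Mod(two_layer_impedance(sk, thickness, area, zi, g$frequency_hz))
      sum(((zm - g$z_ohm) / g$z_ohm)^2)
    }
    # start from the slab resistance implied by the lowest-frequency point
    z0 <- max(g$z_ohm[which.min(g$frequency_hz)] - Mod(zi[which.min(g$frequency_hz)]),
              1e-3)
    sigma0 <- (thickness * 1e-3) / (area * z0)
    fmax <- max(g$frequency_hz)
    eps0_guess <- sigma0 / (2 * pi * max(fmax, 50) * EPS0)
    opt <- stats::optim(log(c(sigma0, eps0_guess)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    sigma_hat <- exp(opt$par[1]); eps_hat <- exp(opt$par[2])
    if (!is.finite(sigma_hat) || sigma_hat <= 0) {
      stop("skin fit failed at U_t = ", g$touch_voltage_v[1],
           " V (non-positive sigma)")
    }
    sk <- list(sigma = sigma_hat, eps_r = eps_hat)
    zm <- Mod(two_layer_impedance(sk, thickness, area, zi, g$frequency_hz))
    rel <- (zm - g$z_ohm) / g$z_ohm
    resid_rows[[length(resid_rows) + 1L]] <<- tibble::tibble(
      touch_voltage = g$touch_voltage_v[1], frequency = g$frequency_hz,
      rel_residual = rel)
    tibble::tibble(
      touch_voltage = g$touch_voltage_v[1],
      sigma = sigma_hat, eps_r = eps_hat,
      rel_rms_residual = sqrt(mean(rel^2)),
      converged = opt$convergence == 0L
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$touch_voltage)
  if (any(!out$converged)) {
    stop("skin fit did not converge at U_t = ",
         paste(out$touch_voltage[!out$converged], collapse = ", "), " V; ",
         "residuals: ", paste(signif(out$rel_rms_residual[!out$converged], 3),
                              collapse = ", "))
  }
  structure(out, class = c("skin_fit", class(out)),
            residuals = dplyr::bind_rows(resid_rows),
            thickness = thickness, area = area)
}

#' @export
tidy.skin_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("touch_voltage", "sigma", "eps_r",
                                 "rel_rms_residual")])
}

#' @export
glance.skin_fit <- function(x, ...) {
  tibble::tibble(
    n_voltages = nrow(x),
    rel_rms_residual = sqrt(mean(x$rel_rms_residual^2)),
    thickness_mm = attr(x, "thickness"),
    area_m2 = attr(x, "area")
  )
}

#' Tidiers (broom-style) for fitted objects
#'
#' @param x Fitted object.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Read / write reference impedance curves
#'
#' Delimited text with header `frequency_hz, touch_voltage_v, z_ohm`.
#'
#' @param path File path.
#' @export
read_impedance_curve <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("frequency_hz", "touch_voltage_v", "z_ohm") %in% names(out)))
  if (any(out$frequency_hz < 0) || any(out$z_ohm <= 0)) {
    stop("impedance curve needs frequencies >= 0 and magnitudes > 0")
  }
  out
}

#' @rdname read_impedance_curve
#' @param curve Impedance-curve data frame to write.
#' @export
write_impedance_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
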
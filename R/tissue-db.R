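# Frequency-dependent dielectric properties of the phantom tissues.
#
# Each tissue carries either constant (sigma, eps_r) or a Cole-Cole
# dispersion: eps^(w) = eps_inf + sum_k d_eps_k / (1 + (j w tau_k)^(1-a_k))
# plus the DC conduction term sigma_dc / (j w eps0).  Conductivity and
# relative permittivity follow as
#   sigma(w) = sigma_dc - w * eps0 * Im(chi(w)),
#   eps_r(w) = eps_inf + Re(chi(w)),
# so sigma(0) = sigma_dc exactly and eps_r(0) = eps_inf + sum d_eps.

#' Vacuum permittivity used throughout the package
#'
#' Fixed at 8.854e-12 F/m. DC is encoded as `frequency = 0`, never a sentinel.
#' @export
EPS0 <- 8.854e-12

#' Create a tissue dispersion model
#'
#' @param tissue Tissue name.
#' @param mode `"constant"` (frequency-independent `sigma_dc`, `eps_inf`) or
#'   `"cole_cole"` (one or more relaxation terms).
#' @param sigma_dc DC conductivity in S/m (must be positive).
#' @param eps_inf High-frequency relative permittivity (>= 1).
#' @param terms Data frame with columns `delta_eps`, `tau` (seconds) and
#'   `alpha` (in `[0, 1)`), one row per Cole-Cole term. Ignored in constant
#'   mode; at least one row is required in `cole_cole` mode.
#' @return An object of class `dispersion_model`.
#' @examples
#' m <- dispersion_model("blood", "cole_cole", sigma_dc = 0.7, eps_inf = 4e3,
#'                       terms = data.frame(delta_eps = 3.5e3, tau = 8.4e-7, alpha = 0.1))
#' evaluate_dispersion(m, c(0, 50, 1e5))
#' @export
dispersion_model <- function(tissue, mode = c("constant", "cole_cole"),
                             sigma_dc, eps_inf, terms = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(tissue), length(tissue) == 1L)
  if (!is.numeric(sigma_dc) || sigma_dc <= 0) {
    stop("`sigma_dc` must be positive for tissue '", tissue, "'")
  }
  if (!is.numeric(eps_inf) || eps_inf < 1) {
    stop("`eps_inf` must be >= 1 for tissue '", tissue, "'")
  }
  if (mode == "cole_cole") {
    if (is.null(terms) || nrow(terms) < 1L) {
      stop("cole_cole mode requires at least one dispersion term ('", tissue, "')")
    }
    terms <- as.data.frame(terms)[, c("delta_eps", "tau", "alpha")]
    if (any(terms$delta_eps < 0) || any(terms$tau <= 0) ||
        any(terms$alpha < 0) || any(terms$alpha >= 1)) {
      stop("invalid Cole-Cole terms for '", tissue,
           "': need delta_eps >= 0, tau > 0, alpha in [0, 1)")
    }
  } else {
    terms <- data.frame(delta_eps = numeric(), tau = numeric(), alpha = numeric())
  }
  structure(
    list(tissue = tissue, mode = mode, sigma_dc = sigma_dc,
         eps_inf = eps_inf, terms = terms),
    class = "dispersion_model"
  )
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("<dispersion_model> ", x$tissue, " [", x$mode, "] sigma_dc = ",
      format(x$sigma_dc), " S/m, eps_inf = ", format(x$eps_inf), sep = "")
  if (nrow(x$terms)) cat(", ", nrow(x$terms), " Cole-Cole term(s)", sep = "")
  cat("\n")
  invisible(x)
}

# chi(w) = sum_k d_eps_k / (1 + (j w tau_k)^(1-a_k)); complex, vectorized in f
.cole_cole_chi <- function(model, frequency) {
  w <- 2 * pi * frequency
  chi <- complex(real = rep(0, length(w)), imaginary = 0)
  for (k in seq_len(nrow(model$terms))) {
    tk <- model$terms[k, ]
    chi <- chi + tk$delta_eps / (1 + (1i * w * tk$tau)^(1 - tk$alpha))
  }
  chi
}

#' Evaluate conductivity and relative permittivity at given frequencies
#'
#' @param model A [dispersion_model()].
#' @param frequency Frequencies in Hz (>= 0; 0 means DC).
#' @return A tibble with columns `frequency`, `sigma` (S/m), `eps_r`.
#' @export
evaluate_dispersion <- function(model, frequency) {
  stopifnot(inherits(model, "dispersion_model"))
  if (any(frequency < 0)) stop("frequency must be >= 0")
  if (model$mode == "constant" || nrow(model$terms) == 0L) {
    sigma <- rep(model$sigma_dc, length(frequency))
    eps_r <- rep(model$eps_inf, length(frequency))
  } else {
    chi <- .cole_cole_chi(model, frequency)
    sigma <- model$sigma_dc - 2 * pi * frequency * EPS0 * Im(chi)
    eps_r <- model$eps_inf + Re(chi)
  }
  tibble::tibble(frequency = as.numeric(frequency), sigma = sigma, eps_r = eps_r)
}

#' Complex conductivity sigma* = sigma + j*2*pi*f*eps0*eps_r
#'
#' The material coefficient of the electro-quasi-static operator
#' div(sigma* grad phi) = 0. Purely real at DC (`frequency = 0`).
#'
#' @inheritParams evaluate_dispersion
#' @return Complex vector (S/m), one element per frequency.
#' @export
complex_conductivity <- function(model, frequency) {
  ev <- evaluate_dispersion(model, frequency)
  complex(real = ev$sigma, imaginary = 2 * pi * ev$frequency * EPS0 * ev$eps_r)
}

#' Bundled tissue dielectric table for the synthetic phantom
#'
#' Literature-style Cole-Cole parameters for the ~10 tissues of the synthetic
#' phantom. Two values are pinned to the contact-dosimetry setup: the skin
#' conductivity at ELF is 0.2 mS/m and the electrode bulk material is a
#' constant 1.0 S/m. Skeletal muscle is isotropic at its longitudinal
#' conductivity value (no tensor support). All entries can be overridden via
#' [read_tissue_table()] or by editing the returned tibble.
#'
#' @return A tibble with columns `tissue`, `mode`, `sigma_dc`, `eps_inf` and a
#'   list-column `terms` of per-tissue Cole-Cole term data frames.
#' @export
default_tissue_table <- function() {
  term <- function(delta_eps, tau, alpha) {
    list(data.frame(delta_eps = delta_eps, tau = tau, alpha = alpha))
  }
  no_term <- list(data.frame(delta_eps = numeric(), tau = numeric(), alpha = numeric()))
  tibble::tibble(
    tissue = c("muscle", "fat", "bone", "blood", "heart_muscle", "lung",
               "skin", "heart_blood", "vessel_blood", "electrode_bulk"),
    mode = c(rep("cole_cole", 9L), "constant"),
    sigma_dc = c(0.35, 0.04, 0.02, 0.70, 0.08, 0.07, 2.0e-4, 0.70, 0.70, 1.0),
    eps_inf = c(2e4, 2e3, 300, 4e3, 3e4, 1e4, 1.1e3, 4e3, 4e3, 1),
    terms = c(
      term(7e6, 2.3e-3, 0.10),     # muscle (longitudinal value)
      term(5e5, 2.3e-3, 0.20),     # fat
      term(2.5e4, 1.6e-3, 0.20),   # cortical bone
      term(3.5e3, 8.4e-7, 0.10),   # blood
      term(8e6, 3.2e-3, 0.15),     # ventricular myocardium
      term(2.5e6, 2.3e-3, 0.15),   # inflated lung
      term(3e4, 1.6e-5, 0.10),     # dry skin envelope; 0.2 mS/m at ELF
      term(3.5e3, 8.4e-7, 0.10),   # heart lumen blood
      term(3.5e3, 8.4e-7, 0.10),   # vessel blood
      no_term                      # electrode bulk, 1.0 S/m
    )
  )
}

.row_to_model <- function(row) {
  dispersion_model(row$tissue, row$mode, row$sigma_dc, row$eps_inf, row$terms[[1]])
}

#' Look up complex conductivities for a set of tissues
#'
#' @param table A tissue table as returned by [default_tissue_table()].
#' @param tissues Character vector of tissue names (must exist in `table`).
#' @param frequency Single frequency in Hz.
#' @return Named complex vector of sigma* (S/m), one entry per tissue.
#' @export
tissue_sigma_star <- function(table, tissues, frequency) {
  stopifnot(length(frequency) == 1L, frequency >= 0)
  miss <- setdiff(tissues, table$tissue)
  if (length(miss)) stop("no dielectric entry for tissue(s): ", paste(miss, collapse = ", "))
  out <- vapply(tissues, function(tn) {
    row <- table[table$tissue == tn, ]
    complex_conductivity(.row_to_model(row[1, ]), frequency)
  }, complex(1))
  stats::setNames(out, tissues)
}

#' Validate a tissue table over the quasi-static band
#'
#' Checks, on a log-spaced grid over `[0, 1 MHz]`, that every tissue has
#' sigma(f) > 0 and non-decreasing and eps_r(f) >= 1 and non-increasing
#' (standard dispersion behaviour).
#'
#' @param table Tissue table.
#' @param n_grid Number of frequency grid points.
#' @return Invisibly `TRUE`; errors describe the offending tissue.
#' @export
validate_tissue_table <- function(table, n_grid = 60L) {
  freqs <- c(0, 10^seq(0, 6, length.out = n_grid - 1L))
  for (i in seq_len(nrow(table))) {
    m <- .row_to_model(table[i, ])
    ev <- evaluate_dispersion(m, freqs)
    if (any(ev$sigma <= 0)) stop("sigma(f) <= 0 for tissue '", m$tissue, "'")
    if (any(ev$eps_r < 1)) stop("eps_r(f) < 1 for tissue '", m$tissue, "'")
    if (any(diff(ev$sigma) < -1e-12 * max(ev$sigma))) {
      stop("sigma(f) decreasing for tissue '", m$tissue, "'")
    }
    if (any(diff(ev$eps_r) > 1e-12 * max(ev$eps_r))) {
      stop("eps_r(f) increasing for tissue '", m$tissue, "'")
    }
  }
  invisible(TRUE)
}

#' Read / write a tissue table as structured text (JSON)
#'
#' One record per tissue: name, mode, `sigma_dc`, `eps_inf`, term list.
#' Invariants are validated on load.
#'
#' @param path File path.
#' @return `read_tissue_table()` returns a validated tissue tibble.
#' @export
read_tissue_table <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- purrr::map(recs, function(r) {
    terms <- if (length(r$terms)) {
      purrr::map_dfr(r$terms, ~ data.frame(delta_eps = .x$delta_eps,
                                           tau = .x$tau, alpha = .x$alpha))
    } else {
      data.frame(delta_eps = numeric(), tau = numeric(), alpha = numeric())
    }
    tibble::tibble(tissue = r$tissue, mode = r$mode, sigma_dc = r$sigma_dc,
                   eps_inf = r$eps_inf, terms = list(terms))
  })
  table <- dplyr::bind_rows(rows)
  validate_tissue_table(table)
  table
}

#' @rdname read_tissue_table
#' @param table Tissue table to write.
#' @export
write_tissue_table <- function(table, path) {
  recs <- purrr::pmap(table, function(tissue, mode, sigma_dc, eps_inf, terms) {
    list(tissue = tissue, mode = mode, sigma_dc = sigma_dc, eps_inf = eps_inf,
         terms = purrr::pmap(terms, function(delta_eps, tau, alpha) {
           list(delta_eps = delta_eps, tau = tau, alpha = alpha)
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
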
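# Shared fixtures, all built in code. Expensive objects (phantom builds,
# full-phantom solves) are memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

all_tissue_names <- function() {
  unname(contactdose:::.TISSUE_IDS)
  names(contactdose:::.TISSUE_IDS)
}

# constant-property tissue table covering every label the phantom can emit
const_tissue_table <- function(sigma = NULL, eps = 1) {
  tn <- all_tissue_names()
  sig <- stats::setNames(rep(1, length(tn)), tn)
  if (!is.null(sigma)) sig[names(sigma)] <- sigma
  no_term <- data.frame(delta_eps = numeric(), tau = numeric(), alpha = numeric())
  tibble::tibble(tissue = tn, mode = "constant", sigma_dc = unname(sig),
                 eps_inf = eps, terms = replicate(length(tn), no_term,
                                                  simplify = FALSE))
}

# rectangular bar along `axis` with Dirichlet end slices (LH source, RH sink);
# `labels` may override the default all-muscle fill
make_bar_phantom <- function(n = c(21, 2, 2), spacing = 5, axis = 1,
                             labels = NULL) {
  ids <- contactdose:::.TISSUE_IDS
  if (is.null(labels)) labels <- array(ids[["muscle"]], n)
  ph <- structure(list(
    labels = labels, spacing = spacing, origin = c(0, 0, 0),
    tissue_map = stats::setNames(names(ids), as.character(ids)),
    sites = list(), site_areas = numeric(), heart_axes = NULL,
    heart_center = NULL, config = NULL, pads = list()),
    class = "voxel_phantom")
  slice_lin <- function(k) which(slice.index(labels, axis) == k & labels > 0L)
  pad <- function(site, lin) list(site = site, mode = "INTERN",
                                  touch_voltage = NULL, skin_sigma = NA,
                                  skin_eps_r = NA, pad_voxels = lin,
                                  dirichlet = lin, n_skin_layers = 0L)
  ph$pads$LH <- pad("LH", slice_lin(1L))
  ph$pads$RH <- pad("RH", slice_lin(n[axis]))
  ph
}

# circular cylinder along z between full end electrodes
make_cylinder_phantom <- function(radius = 20, length = 100, spacing = 2) {
  ids <- contactdose:::.TISSUE_IDS
  nz <- round(length / spacing) + 1L
  nxy <- 2L * ceiling(radius / spacing) + 3L
  cs <- ((1:nxy) - (nxy + 1) / 2) * spacing
  disc <- outer(cs^2, cs^2, "+") <= radius^2
  labels <- array(0L, c(nxy, nxy, nz))
  for (k in 1:nz) labels[, , k][disc] <- ids[["muscle"]]
  ph <- make_bar_phantom(c(nxy, nxy, nz), spacing, axis = 3, labels = labels)
  ph
}

small_phantom_config <- function(spacing = 5, ...) {
  phantom_config(spacing = spacing, scale = 0.5, vessel_radius = 16,
                 neck_radius = 16, ...)
}

small_phantom <- function() memo("small_phantom",
                                 build_phantom(small_phantom_config()))

default_phantom <- function() memo("default_phantom",
                                   build_phantom(phantom_config()))

default_tt <- function() memo("default_tt", default_tissue_table())

# independent sort-based percentile oracle (linear interpolation between
# closest order statistics)
oracle_q99 <- function(x, p = 0.99) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
}

# reference HCF campaign on the default phantom: LH-BF (reference) + LH-RH
# at the five standard frequencies, Intern-BM
acceptance_campaign <- function() memo("acceptance_campaign", {
  run_campaign(campaign(phantom = default_phantom(),
                        paths = c("LH-BF", "LH-RH"),
                        frequencies = c(0, 50, 1e3, 1e4, 1e5),
                        touch_voltages = 100, purpose = "hcf",
                        tissues = default_tt()))
})

fake_field_solution <- function(emag_values) {
  # wraps a plain vector of |E| magnitudes as a heart-only field solution
  ids <- contactdose:::.TISSUE_IDS
  n <- length(emag_values)
  labels <- array(ids[["heart_muscle"]], c(n, 1, 1))
  ph <- structure(list(labels = labels, spacing = 1, origin = c(0, 0, 0),
                       tissue_map = stats::setNames(names(ids), as.character(ids)),
                       sites = list(), site_areas = numeric(),
                       heart_axes = NULL, heart_center = NULL, config = NULL,
                       pads = list()), class = "voxel_phantom")
  E <- list(array(complex(real = emag_values), c(n, 1, 1)),
            array(0 + 0i, c(n, 1, 1)), array(0 + 0i, c(n, 1, 1)))
  structure(list(potential = array(0 + 0i, c(n, 1, 1)), residual = 0,
                 iterations = 1L, method = "direct", precond = NULL,
                 frequency = 0,
                 scenario = contact_scenario("LH-RH", 0, 1, "INTERN"),
                 phantom = ph, sig_grid = array(1 + 0i, c(n, 1, 1)),
                 E = E, J = E, history = 0),
            class = "field_solution")
}

# memoized full-phantom field solutions (shared across test files)
sol_default <- function(label, f = 50, tt = default_tt(), tol = 1e-9,
                        phantom = NULL, key_extra = "") {
  key <- paste0("sol_", label, "_", f, "_", tol, "_", key_extra)
  memo(key, {
    ph <- if (is.null(phantom)) default_phantom() else phantom
    solve_scenario(ph, tt, contact_scenario(label, f, 100, "INTERN"),
                   tolerance = tol, max_iter = 600)
  })
}

iqr_over_median <- function(sol) {
  hm <- which(sol$phantom$labels == contactdose:::.TISSUE_IDS[["heart_muscle"]])
  em <- sqrt(Mod(sol$E[[1]][hm])^2 + Mod(sol$E[[2]][hm])^2 +
               Mod(sol$E[[3]][hm])^2)
  stats::IQR(em) / stats::median(em)
}
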
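# Electro-quasi-static finite-volume solver.
#
# div(sigma*(x) grad phi) = 0 on the tissue+pad voxel domain, with Dirichlet
# values on the energized pad boundaries and homogeneous Neumann at the
# body-air surface (air is excluded: conduction-dominated regime below
# 1 MHz). 7-point stencil; face admittances are harmonic means of the
# adjacent complex conductivities (flux continuity across interfaces, which
# an arithmetic mean would violate for thin resistive layers such as the
# contact skin slice). The complex-symmetric system is solved directly
# (sparse, via the equivalent real block form; Cholesky when purely real)
# below a size threshold and otherwise by conjugate-orthogonal CG
# preconditioned with a sparse Cholesky factor of the real part.

#' Describe one contact-current solve
#'
#' @param path Path label (e.g. `"LH-BF"`) or [current_path()] object.
#' @param frequency Frequency in Hz (0 = DC).
#' @param touch_voltage Touch voltage in V (source boundary value).
#' @param mode `"TOTAL"` or `"INTERN"` (see [select_body_model()]).
#' @return A list of class `contact_scenario`.
#' @export
contact_scenario <- function(path, frequency, touch_voltage = 100,
                             mode = c("INTERN", "TOTAL")) {
  mode <- match.arg(mode)
  if (is.character(path)) path <- current_path(path)
  stopifnot(frequency >= 0, touch_voltage > 0)
  structure(list(path = path, frequency = frequency,
                 touch_voltage = touch_voltage, mode = mode),
            class = "contact_scenario")
}

# complex conductivity grid: one value per voxel label at `frequency`
.sigma_star_grid <- function(phantom, tissues, frequency) {
  labels <- phantom$labels
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  tn <- phantom$tissue_map[as.character(present)]
  if (anyNA(tn)) stop("unmaterialized label id(s): ",
                      paste(present[is.na(tn)], collapse = ", "))
  sig_by_id <- stats::setNames(complex(length(present)), as.character(present))
  slice_id <- .TISSUE_IDS[["skin_slice"]]
  for (i in seq_along(present)) {
    if (present[i] == slice_id) {
      pads <- Filter(function(p) p$mode == "TOTAL", phantom$pads)
      if (!length(pads)) stop("skin_slice label present but no TOTAL pad recorded")
      p <- pads[[1]]
      sig_by_id[i] <- complex(real = p$skin_sigma,
                              imaginary = 2 * pi * frequency * EPS0 * p$skin_eps_r)
    } else {
      sig_by_id[i] <- tissue_sigma_star(tissues, tn[i], frequency)
    }
  }
  grid <- array(0 + 0i, dim(labels))
  nz <- labels > 0L
  grid[nz] <- sig_by_id[as.character(labels[nz])]
  grid
}

.AXIS_STRIDE <- function(d) c(1L, d[1], d[1] * d[2])

# face arrays along `axis`: linear index of the lower voxel of each interior
# face plus the (complex) face admittance; zero admittance marks invalid faces
.face_admittance <- function(sig, axis, spacing) {
  d <- dim(sig)
  idx <- lapply(d, seq_len)
  lo <- hi <- idx
  lo[[axis]] <- seq_len(d[axis] - 1L)
  hi[[axis]] <- seq_len(d[axis] - 1L) + 1L
  A <- as.vector(sig[lo[[1]], lo[[2]], lo[[3]]])
  B <- as.vector(sig[hi[[1]], hi[[2]], hi[[3]]])
  valid <- (Mod(A) > 0) & (Mod(B) > 0)
  Y <- rep(0 + 0i, length(A))
  Y[valid] <- 2 * A[valid] * B[valid] / (A[valid] + B[valid]) * (spacing * 1e-3)
  # embed in full-size array so `which()` gives full-grid linear indices
  full <- array(0 + 0i, d)
  full[lo[[1]], lo[[2]], lo[[3]]] <- Y
  from <- which(Mod(full) > 0)
  list(from = from, to = from + .AXIS_STRIDE(d)[axis], Y = full[from])
}

#' Assemble the finite-volume system for a scenario
#'
#' Electrodes must already be placed ([place_path_electrodes()]); every
#' label present needs a dielectric entry. Dirichlet rows (energized pad
#' boundaries) are eliminated: the returned system is over interior voxels
#' only and is diagonally dominant for purely real conductivities.
#'
#' @param phantom Phantom with pads placed.
#' @param tissues Tissue table ([default_tissue_table()]).
#' @param scenario A [contact_scenario()].
#' @return An object of class `eqs_system` with sparse real/imaginary parts
#'   `R`, `I`, right-hand side `b`, the unknown index map and the
#'   conductivity grid.
#' @export
assemble_system <- function(phantom, tissues, scenario) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(scenario, "contact_scenario"))
  d <- dim(phantom$labels)
  src_sites <- scenario$path$source_sites
  snk_sites <- scenario$path$sink_sites
  for (site in c(src_sites, snk_sites)) {
    if (is.null(phantom$pads[[site]])) {
      stop("no electrode pad placed at site '", site, "'")
    }
  }
  sig <- .sigma_star_grid(phantom, tissues, scenario$frequency)

  dir_lin <- integer(); dir_val <- numeric()
  for (site in src_sites) {
    dir_lin <- c(dir_lin, phantom$pads[[site]]$dirichlet)
    dir_val <- c(dir_val, rep(scenario$touch_voltage,
                              length(phantom$pads[[site]]$dirichlet)))
  }
  for (site in snk_sites) {
    dir_lin <- c(dir_lin, phantom$pads[[site]]$dirichlet)
    dir_val <- c(dir_val, rep(0, length(phantom$pads[[site]]$dirichlet)))
  }
  if (!length(dir_lin)) stop("empty electrode set")
  dir_grid <- array(0, d); dir_grid[dir_lin] <- dir_val
  is_dir <- array(FALSE, d); is_dir[dir_lin] <- TRUE

  domain <- Mod(sig) > 0
  unknown_lin <- which(domain & !is_dir)
  n <- length(unknown_lin)
  umap <- array(0L, d); umap[unknown_lin] <- seq_len(n)

  diag_acc <- complex(n)
  b <- complex(n)
  ii <- jj <- vector("list", 3L); xx <- vector("list", 3L)
  for (ax in 1:3) {
    f <- .face_admittance(sig, ax, phantom$spacing)
    uf <- umap[f$from]; ut <- umap[f$to]
    both <- uf > 0L & ut > 0L
    fd <- uf > 0L & ut == 0L & is_dir[f$to]
    df <- uf == 0L & ut > 0L & is_dir[f$from]
    # unknown-unknown faces
    w <- which(both)
    add <- rowsum_complex(c(f$Y[w], f$Y[w]), c(uf[w], ut[w]), n)
    diag_acc <- diag_acc + add
    ii[[ax]] <- c(uf[w], ut[w]); jj[[ax]] <- c(ut[w], uf[w])
    xx[[ax]] <- c(-f$Y[w], -f$Y[w])
    # unknown-Dirichlet faces
    w <- which(fd)
    diag_acc <- diag_acc + rowsum_complex(f$Y[w], uf[w], n)
    b <- b + rowsum_complex(f$Y[w] * dir_grid[f$to[w]], uf[w], n)
    w <- which(df)
    diag_acc <- diag_acc + rowsum_complex(f$Y[w], ut[w], n)
    b <- b + rowsum_complex(f$Y[w] * dir_grid[f$from[w]], ut[w], n)
  }
  ii <- c(unlist(ii), seq_len(n))
  jj <- c(unlist(jj), seq_len(n))
  xx <- c(unlist(xx), diag_acc)
  Rm <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(xx), dims = c(n, n))
  Im_ <- if (scenario$frequency > 0) {
    Matrix::sparseMatrix(i = ii, j = jj, x = Im(xx), dims = c(n, n))
  } else NULL
  structure(
    list(R = Rm, I = Im_, b = b, n = n, dims = d,
         unknown_lin = unknown_lin, dir_lin = dir_lin, dir_val = dir_val,
         sig_grid = sig, phantom = phantom, scenario = scenario),
    class = "eqs_system"
  )
}

# complex-aware rowsum onto 1..n
rowsum_complex <- function(x, group, n) {
  out <- complex(n)
  if (!length(x)) return(out)
  re <- rowsum(Re(x), group)
  im <- rowsum(Im(x), group)
  g <- as.integer(rownames(re))
  out[g] <- complex(real = re[, 1], imaginary = im[, 1])
  out
}

#' Dense complex matrix of an assembled system (small systems only)
#'
#' @param system An `eqs_system`.
#' @return Dense complex matrix (for direct-oracle comparisons).
#' @export
as_dense_matrix <- function(system) {
  if (system$n > 6000) stop("system too large for a dense matrix")
  M <- as.matrix(system$R)
  if (!is.null(system$I)) M <- M + 1i * as.matrix(system$I)
  M
}

#' Solve the assembled potential problem
#'
#' Deterministic for identical inputs and settings: the direct route uses a
#' sparse factorization, the iterative route is conjugate-orthogonal CG on
#' the complex-symmetric system, preconditioned with a sparse Cholesky
#' factor of the real part (optionally reused across frequencies via
#' `precond`). `"auto"` solves directly below `direct_limit` unknowns and
#' at DC (purely real SPD system), iteratively otherwise.
#'
#' @param system An `eqs_system`.
#' @param tolerance Relative residual target ||Ax-b||/||b||.
#' @param max_iter Iteration cap for the Krylov route.
#' @param method `"auto"`, `"direct"` or `"cocg"`.
#' @param direct_limit Unknown-count threshold for the direct route (the DC
#   real-arithmetic fast path is always direct).
#' @param precond Optional Cholesky factor (from a previous solve with
#'   `keep_precond = TRUE`) to reuse.
#' @param keep_precond Keep the factor in the returned object (large; only
#'   worth it when further solves on the same electrode layout follow).
#' @return A `field_solution` with the complex potential grid, residual and
#'   iteration count.
#' @export
solve_potential <- function(system, tolerance = 1e-9, max_iter = 400,
                            method = c("auto", "direct", "cocg"),
                            direct_limit = 3000L, precond = NULL,
                            keep_precond = FALSE) {
  method <- match.arg(method)
  n <- system$n
  real_sys <- is.null(system$I) || all(system$I@x == 0)
  if (method == "auto") {
    method <- if (real_sys || n <= direct_limit) "direct" else "cocg"
  }
  iterations <- NA_integer_
  Ch <- precond
  if (method == "direct") {
    if (real_sys) {
      if (is.null(Ch)) Ch <- Matrix::Cholesky(methods::as(system$R, "symmetricMatrix"), super = TRUE)
      x <- as.vector(Matrix::solve(Ch, Re(system$b), system = "A"))
      x <- complex(real = x, imaginary = 0)
    } else {
      blk <- rbind(cbind(system$R, -system$I), cbind(system$I, system$R))
      xr <- as.vector(Matrix::solve(blk, c(Re(system$b), Im(system$b))))
      x <- complex(real = xr[1:n], imaginary = xr[(n + 1):(2 * n)])
    }
    res <- .rel_residual(system, x)
    iterations <- 1L
    history <- res
  } else {
    if (is.null(Ch)) Ch <- Matrix::Cholesky(methods::as(system$R, "symmetricMatrix"), super = TRUE)
    out <- .cocg(system, Ch, tolerance, max_iter)
    x <- out$x; res <- out$residual; iterations <- out$iterations
    history <- out$history
    if (res > tolerance) {
      stop("solver did not converge: relative residual ", signif(res, 4),
           " after ", iterations, " iterations (history: ",
           paste(signif(utils::tail(history, 8), 3), collapse = ", "), ")")
    }
  }
  if (res > max(tolerance, 1e-7) && method == "direct") {
    warning("direct solve residual ", signif(res, 3), " above tolerance")
  }
  phi <- array(NA_complex_, system$dims)
  phi[system$unknown_lin] <- x
  phi[system$dir_lin] <- system$dir_val
  structure(
    list(potential = phi, residual = res, iterations = iterations,
         method = method, precond = if (keep_precond) Ch else NULL,
         frequency = system$scenario$frequency, scenario = system$scenario,
         phantom = system$phantom, sig_grid = system$sig_grid,
         E = NULL, J = NULL, history = history),
    class = "field_solution"
  )
}

.amul <- function(system, x) {
  xr <- Re(x); xi <- Im(x)
  if (is.null(system$I)) {
    complex(real = as.vector(system$R %*% xr),
            imaginary = as.vector(system$R %*% xi))
  } else {
    complex(
      real = as.vector(system$R %*% xr - system$I %*% xi),
      imaginary = as.vector(system$R %*% xi + system$I %*% xr)
    )
  }
}

.rel_residual <- function(system, x) {
  sqrt(sum(Mod(system$b - .amul(system, x))^2)) / sqrt(sum(Mod(system$b)^2))
}

# conjugate-orthogonal CG for complex symmetric A, SPD preconditioner factor Ch
.cocg <- function(system, Ch, tolerance, max_iter) {
  b <- system$b
  bnorm <- sqrt(sum(Mod(b)^2))
  x <- complex(system$n)
  r <- b
  msolve <- function(v) {
    z <- Matrix::solve(Ch, cbind(Re(v), Im(v)), system = "A")
    complex(real = z[, 1], imaginary = z[, 2])
  }
  z <- msolve(r)
  p <- z
  rz <- sum(r * z)
  history <- numeric()
  for (it in seq_len(max_iter)) {
    q <- .amul(system, p)
    alpha <- rz / sum(p * q)
    x <- x + alpha * p
    r <- r - alpha * q
    res <- sqrt(sum(Mod(r)^2)) / bnorm
    history <- c(history, res)
    if (res <= tolerance) {
      return(list(x = x, residual = .rel_residual(system, x),
                  iterations = it, history = history))
    }
    z <- msolve(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    p <- z + beta * p
    rz <- rz_new
  }
  list(x = x, residual = .rel_residual(system, x), iterations = max_iter,
       history = history)
}

#' Derive electric field and current density from a potential solution
#'
#' E = -grad(phi) via central differences at interior voxels and one-sided
#' differences at the tissue-air surface; J = sigma* E voxelwise. Components
#' are complex phasors (V/m, A/m^2).
#'
#' @param solution A `field_solution` from [solve_potential()].
#' @return The solution with `E` and `J` lists of three component arrays.
#' @export
derive_fields <- function(solution) {
  phi <- solution$potential
  d <- dim(phi)
  h <- solution$phantom$spacing * 1e-3
  dom <- !is.na(phi)
  phi0 <- phi; phi0[!dom] <- 0 + 0i
  E <- vector("list", 3L)
  for (ax in 1:3) {
    up <- array(0 + 0i, d); dn <- array(0 + 0i, d)
    has_up <- .shift3(dom, ax, -1L)   # neighbor at +1 exists
    has_dn <- .shift3(dom, ax, +1L)   # neighbor at -1 exists
    idx <- lapply(d, seq_len)
    iu <- idx; iu[[ax]] <- c(2:d[ax], d[ax])
    idn <- idx; idn[[ax]] <- c(1L, 1:(d[ax] - 1L))
    up <- phi0[iu[[1]], iu[[2]], iu[[3]]]
    dn <- phi0[idn[[1]], idn[[2]], idn[[3]]]
    Ea <- array(0 + 0i, d)
    cc <- dom & has_up & has_dn
    Ea[cc] <- -(up[cc] - dn[cc]) / (2 * h)
    fw <- dom & has_up & !has_dn
    Ea[fw] <- -(up[fw] - phi0[fw]) / h
    bw <- dom & !has_up & has_dn
    Ea[bw] <- -(phi0[bw] - dn[bw]) / h
    Ea[!dom] <- NA_complex_
    E[[ax]] <- Ea
  }
  solution$E <- E
  solution$J <- lapply(E, function(Ea) {
    Ja <- Ea * solution$sig_grid
    Ja[!dom] <- NA_complex_
    Ja
  })
  solution
}

#' One-call scenario solve
#'
#' Places the path electrodes, assembles, solves and derives fields.
#'
#' @inheritParams assemble_system
#' @param tolerance,max_iter,method,direct_limit,precond,keep_precond Passed
#'   to [solve_potential()].
#' @return A `field_solution` with derived fields.
#' @export
solve_scenario <- function(phantom, tissues, scenario, tolerance = 1e-9,
                           max_iter = 400, method = "auto",
                           direct_limit = 3000L, precond = NULL,
                           keep_precond = FALSE) {
  ph <- place_path_electrodes(phantom, scenario$path, scenario$mode,
                              scenario$touch_voltage)
  sys <- assemble_system(ph, tissues, scenario)
  sol <- solve_potential(sys, tolerance = tolerance, max_iter = max_iter,
                         method = method, direct_limit = direct_limit,
                         precond = precond, keep_precond = keep_precond)
  derive_fields(sol)
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> path ", x$scenario$path$label, " @ ",
      format(x$frequency, big.mark = ","), " Hz, ", x$scenario$mode,
      " mode, U_t = ", x$scenario$touch_voltage, " V\n",
      "residual ", signif(x$residual, 3), " after ", x$iterations,
      " iteration(s) [", x$method, "]\n", sep = "")
  invisible(x)
}

#' @export
glance.field_solution <- function(x, ...) {
  tibble::tibble(
    path = x$scenario$path$label, frequency = x$frequency,
    touch_voltage = x$scenario$touch_voltage, mode = x$scenario$mode,
    residual = x$residual, iterations = x$iterations, method = x$method
  )
}
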
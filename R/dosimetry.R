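# Dose post-processing: total body current (cross-section surface
# integrals), body impedance via Ohm's law, the 99th-percentile myocardial
# field, the three-axis trans-cardiac line-integral field estimate, and the
# heart-current-factor statistics normalized on LH-BF.

# planes (axis, slice k: faces between k and k+1) that separate source from
# sink Dirichlet sets; returns the axis and n evenly spaced slice indices
.separating_planes <- function(solution, n_planes) {
  ph <- solution$phantom
  d <- dim(ph$labels)
  src <- unlist(lapply(solution$scenario$path$source_sites,
                       function(s) ph$pads[[s]]$dirichlet))
  snk <- unlist(lapply(solution$scenario$path$sink_sites,
                       function(s) ph$pads[[s]]$dirichlet))
  si <- arrayInd(src, d); ki <- arrayInd(snk, d)
  best <- NULL
  for (ax in 1:3) {
    lo_src <- min(si[, ax]); hi_src <- max(si[, ax])
    lo_snk <- min(ki[, ax]); hi_snk <- max(ki[, ax])
    if (hi_src < lo_snk) {
      gap <- c(hi_src, lo_snk - 1L); sign <- +1
    } else if (hi_snk < lo_src) {
      gap <- c(hi_snk, lo_src - 1L); sign <- -1
    } else next
    if (is.null(best) || diff(gap) > diff(best$gap)) {
      best <- list(axis = ax, gap = gap, sign = sign)
    }
  }
  if (is.null(best)) stop("no coordinate plane separates source from sink pads")
  ks <- unique(round(seq(best$gap[1], best$gap[2],
                         length.out = n_planes + 2L)[-c(1L, n_planes + 2L)]))
  list(axis = best$axis, ks = ks, sign = best$sign)
}

# current crossing the plane of faces between slices k and k+1 along `axis`
.plane_current <- function(solution, axis, k) {
  sig <- solution$sig_grid
  phi <- solution$potential
  d <- dim(sig)
  idx <- lapply(d, seq_len)
  ia <- idx; ia[[axis]] <- k
  ib <- idx; ib[[axis]] <- k + 1L
  sA <- sig[ia[[1]], ia[[2]], ia[[3]]]; sB <- sig[ib[[1]], ib[[2]], ib[[3]]]
  pA <- phi[ia[[1]], ia[[2]], ia[[3]]]; pB <- phi[ib[[1]], ib[[2]], ib[[3]]]
  valid <- Mod(sA) > 0 & Mod(sB) > 0 & !is.na(pA) & !is.na(pB)
  if (!any(valid)) stop("cross-section plane misses the body (axis ", axis,
                        ", slice ", k, ")")
  Y <- 2 * sA[valid] * sB[valid] / (sA[valid] + sB[valid]) *
    (solution$phantom$spacing * 1e-3)
  sum(Y * (pA[valid] - pB[valid]))
}

#' Total body current from cross-section surface integrals
#'
#' Evaluates the conduction current through `n_planes` full cross-section
#' planes placed between the source and sink electrodes (the numerical
#' analogue of measuring I_Body with several surface integrals) and returns
#' their mean. The maximum pairwise spread across planes is attached as a
#' conservation diagnostic (`attr(, "spread")`, relative to |I|).
#'
#' @param solution A solved `field_solution`.
#' @param n_planes Number of planes (>= 1).
#' @return Complex current in A with attributes `spread` and `per_plane`.
#' @export
body_current <- function(solution, n_planes = 4L) {
  stopifnot(n_planes >= 1L)
  pl <- .separating_planes(solution, n_planes)
  vals <- vapply(pl$ks, function(k) .plane_current(solution, pl$axis, k),
                 complex(1))
  vals <- vals * pl$sign
  i_mean <- mean(vals)
  spread <- if (length(vals) > 1L) {
    max(abs(outer(Mod(vals), Mod(vals), "-"))) / Mod(i_mean)
  } else 0
  structure(i_mean, spread = spread, per_plane = vals, axis = pl$axis)
}

#' Total body impedance via Ohm's law
#'
#' @param touch_voltage Touch voltage in V (real by convention; the phase is
#'   carried by the current).
#' @param i_body Complex body current in A.
#' @return Complex impedance in Ohm.
#' @export
total_impedance <- function(touch_voltage, i_body) {
  if (Mod(i_body) == 0) stop("zero body current")
  touch_voltage / i_body
}

#' 99th percentile of |E| over the ventricular myocardium
#'
#' Per-voxel phasor magnitude |E| = sqrt(|Ex|^2 + |Ey|^2 + |Ez|^2) over all
#' ventricular-myocardium voxels (lumen blood, vessels and other tissues are
#' excluded); the percentile uses linear interpolation between the closest
#' order statistics (`stats::quantile` type 7).
#'
#' @param solution A `field_solution` with derived fields.
#' @param prob Percentile (default 0.99).
#' @return Field magnitude in V/m.
#' @export
e99_heart <- function(solution, prob = 0.99) {
  if (is.null(solution$E)) stop("fields not derived; call derive_fields()")
  hm <- which(solution$phantom$labels == .TISSUE_IDS[["heart_muscle"]])
  if (!length(hm)) stop("phantom has no ventricular-myocardium voxels")
  emag <- sqrt(Mod(solution$E[[1]][hm])^2 + Mod(solution$E[[2]][hm])^2 +
                 Mod(solution$E[[3]][hm])^2)
  unname(stats::quantile(emag, prob, type = 7, names = FALSE))
}

# trilinear interpolation of a complex array at continuous 1-based indices
.trilinear <- function(arr, pts) {
  d <- dim(arr)
  if (any(pts < 1) || any(pts[, 1] > d[1]) || any(pts[, 2] > d[2]) ||
      any(pts[, 3] > d[3])) {
    stop("sample point outside the voxel grid")
  }
  i0 <- pmin(floor(pts[, 1]), d[1] - 1L); fx <- pts[, 1] - i0
  j0 <- pmin(floor(pts[, 2]), d[2] - 1L); fy <- pts[, 2] - j0
  k0 <- pmin(floor(pts[, 3]), d[3] - 1L); fz <- pts[, 3] - k0
  val <- complex(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    lin <- (i0 + dx) + (j0 + dy - 1L) * d[1] + (k0 + dz - 1L) * d[1] * d[2]
    val <- val + w * arr[lin]
  }
  val
}

#' Trans-cardiac line-integral field estimate
#'
#' For each of the three orthogonal heart axes (base-apex, front-back,
#' top-bottom), integrates E . dl at <= 1 mm sampling (trilinear field
#' interpolation), divides the voltage magnitude by the axis length, and
#' combines the three orthogonal estimates as a Euclidean norm (the unique
#' rotation-consistent combination of orthogonal component estimates).
#'
#' @param solution A `field_solution` with derived fields.
#' @return Field estimate in V/m with attribute `per_axis` (a tibble of the
#'   three axis voltages and field components).
#' @export
sam_field <- function(solution) {
  if (is.null(solution$E)) stop("fields not derived; call derive_fields()")
  ph <- solution$phantom
  if (is.null(ph$heart_axes)) stop("phantom has no heart axes defined")
  rows <- purrr::imap(ph$heart_axes, function(seg, nm) {
    p0 <- seg[1, ]; p1 <- seg[2, ]
    L <- sqrt(sum((p1 - p0)^2))           # mm
    tdir <- (p1 - p0) / L
    n_steps <- max(2L, ceiling(L))        # <= 1 mm local resolution
    tt <- seq(0, 1, length.out = n_steps + 1L)
    pts_mm <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                    p0[2] + tt * (p1[2] - p0[2]),
                    p0[3] + tt * (p1[3] - p0[3]))
    pts <- sweep(pts_mm, 2, ph$origin, "-") / ph$spacing + 1
    et <- .trilinear(solution$E[[1]], pts) * tdir[1] +
      .trilinear(solution$E[[2]], pts) * tdir[2] +
      .trilinear(solution$E[[3]], pts) * tdir[3]
    if (anyNA(et)) stop("heart axis '", nm, "' exits the tissue domain")
    dl <- (L / n_steps) * 1e-3            # m
    V <- sum((et[-1] + et[-length(et)]) / 2) * dl
    tibble::tibble(axis = nm, length_mm = L, voltage = Mod(V),
                   e_component = Mod(V) / (L * 1e-3))
  })
  per_axis <- dplyr::bind_rows(rows)
  structure(sqrt(sum(per_axis$e_component^2)), per_axis = per_axis)
}

#' Full dose report for one solved scenario
#'
#' @param solution A solved `field_solution` (fields are derived on demand).
#' @param n_planes Cross-section planes for the body-current integral.
#' @return One-row tibble: path, frequency, mode, touch voltage, |I_Body|
#'   and phase, |Z| and phase, E99Heart, E_Sam, the cross-plane conservation
#'   spread, and solver diagnostics.
#' @export
compute_dose <- function(solution, n_planes = 4L) {
  if (is.null(solution$E)) solution <- derive_fields(solution)
  ib <- body_current(solution, n_planes)
  z <- total_impedance(solution$scenario$touch_voltage, as.complex(ib))
  es <- sam_field(solution)
  tibble::tibble(
    path = solution$scenario$path$label,
    frequency = solution$frequency,
    touch_voltage = solution$scenario$touch_voltage,
    mode = solution$scenario$mode,
    i_body_a = Mod(as.complex(ib)),
    i_body_phase_deg = Arg(as.complex(ib)) * 180 / pi,
    z_total_ohm = Mod(z),
    z_phase_deg = Arg(z) * 180 / pi,
    e99_heart = e99_heart(solution),
    e_sam = as.numeric(es),
    current_spread = attr(ib, "spread"),
    residual = solution$residual,
    iterations = solution$iterations
  )
}

#' Heart-current-factor table
#'
#' F(p, f) = [E(p, f) / |I_Body(p, f)|] * [|I_Body(ref, f)| / E(ref, f)]
#' with E = E99Heart for the 99th-percentile statistic (`f99`) and
#' E = E_Sam for the line-integral statistic (`f_sam`). The reference path
#' row is exactly 1.0 at every frequency by construction, and the table is
#' invariant to the touch voltage by solver linearity.
#'
#' @param dose Dose tibble from [compute_dose()] rows (one per path x
#'   frequency; the reference path must be present at every frequency).
#' @param reference Reference path label (default `"LH-BF"`).
#' @return An `hcf_table` tibble: `path`, `frequency`, `f99` and (when
#'   `e_sam` is available) `f_sam`.
#' @export
hcf_table <- function(dose, reference = "LH-BF") {
  stopifnot(all(c("path", "frequency", "i_body_a", "e99_heart") %in% names(dose)))
  ref <- dplyr::filter(dose, .data$path == reference)
  missing_f <- setdiff(unique(dose$frequency), ref$frequency)
  if (nrow(ref) == 0L || length(missing_f)) {
    stop("reference path '", reference, "' missing at frequencies: ",
         paste(missing_f, collapse = ", "))
  }
  ref <- dplyr::transmute(ref, frequency = .data$frequency,
                          ref_e99_per_i = .data$e99_heart / .data$i_body_a,
                          ref_esam_per_i = if ("e_sam" %in% names(ref))
                            .data$e_sam / .data$i_body_a else NA_real_)
  out <- dplyr::left_join(dose, ref, by = "frequency")
  out <- dplyr::mutate(
    out,
    f99 = (.data$e99_heart / .data$i_body_a) / .data$ref_e99_per_i,
    f_sam = if ("e_sam" %in% names(dose))
      (.data$e_sam / .data$i_body_a) / .data$ref_esam_per_i else NA_real_
  )
  out <- dplyr::select(out, "path", "frequency", "f99", dplyr::any_of("f_sam"))
  structure(out, class = c("hcf_table", class(out)), reference = reference)
}

#' Pivot an HCF table to the paths-by-frequency layout
#'
#' @param x An `hcf_table`.
#' @param statistic `"f99"` or `"f_sam"`.
#' @return Wide tibble: one row per path, one column per frequency.
#' @export
hcf_wide <- function(x, statistic = c("f99", "f_sam")) {
  statistic <- match.arg(statistic)
  tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(x), "path", "frequency",
                  dplyr::all_of(statistic)),
    names_from = "frequency", values_from = dplyr::all_of(statistic),
    names_prefix = "f_"
  )
}

#' Write dose reports and HCF tables
#'
#' CSV (long form) plus JSON with the same content; HCF tables are written
#' in the paths-as-rows / frequencies-as-columns layout.
#'
#' @param dose Dose tibble.
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @return Invisibly the written paths.
#' @export
write_dose_report <- function(dose, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(dose, csv, row.names = FALSE)
  jsonlite::write_json(dose, js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}

#' @rdname write_dose_report
#' @param x An `hcf_table`.
#' @export
write_hcf_table <- function(x, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(hcf_wide(x, "f99"), csv, row.names = FALSE)
  if ("f_sam" %in% names(x) && !all(is.na(x$f_sam))) {
    utils::write.csv(hcf_wide(x, "f_sam"),
                     paste0(path, "_sam.csv"), row.names = FALSE)
  }
  invisible(csv)
}
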
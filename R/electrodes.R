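# Electrode pads.  A pad is grown outward (into air) from a registered
# surface patch.  In Total-BM mode the innermost ~2 mm of the pad is the
# skin slice carrying the voltage-dependent contact properties and the skin
# under the patch is removed; in Intern-BM mode the whole pad is electrode
# bulk (1.0 S/m) sitting directly on the subcutaneous tissue.  The outermost
# pad layer is the energized (Dirichlet) boundary.

#' Place a contact electrode on the phantom
#'
#' @param phantom A `voxel_phantom` with registered sites.
#' @param site One of the seven sites (see [ELECTRODE_SITES]).
#' @param mode `"TOTAL"` (skin-slice contact layer included) or `"INTERN"`
#'   (skin removed at the contact, electrode on subcutaneous tissue).
#' @param touch_voltage Touch voltage in V. Required in TOTAL mode and must
#'   lie within the tabulated `[25, 220]` V (no extrapolation of the
#'   skin-slice properties).
#' @return The phantom with updated labels and a `pads[[site]]` record
#'   (pad voxels, Dirichlet boundary voxels, skin-slice properties).
#' @export
place_electrode <- function(phantom, site, mode = c("TOTAL", "INTERN"),
                            touch_voltage = NULL) {
  mode <- match.arg(mode)
  if (is.null(phantom$sites[[site]])) stop("site '", site, "' is not registered")
  id <- .TISSUE_IDS
  labels <- phantom$labels
  d <- dim(labels)
  s <- phantom$spacing
  n_skin_layers <- max(1L, as.integer(round(2 / s)))
  n_layers <- n_skin_layers + phantom$config$pad_bulk_layers

  skin_sigma <- skin_eps <- NA_real_
  if (mode == "TOTAL") {
    if (is.null(touch_voltage)) stop("TOTAL mode requires a touch voltage")
    if (touch_voltage < 25 || touch_voltage > 220) {
      stop("TOTAL mode touch voltage must lie in [25, 220] V (no extrapolation)")
    }
    sp <- skin_props(touch_voltage)
    skin_sigma <- sp$sigma; skin_eps <- sp$eps_r
  }

  patch <- phantom$sites[[site]]
  # remove the skin under the patch (both modes): relabel to the underlying
  # subcutaneous tissue, walking inward as many shells as the skin has
  n_skin_shells <- max(1L, round(phantom$config$skin_mm / s))
  set <- patch
  for (k in seq_len(n_skin_shells)) {
    sk <- set[labels[set] == id[["skin"]]]
    labels[sk] <- id[["fat"]]
    nxt <- integer()
    for (ax in 1:3) for (dr in c(-1L, 1L)) {
      nb <- .neighbor_lin(set, d, ax, dr)
      nxt <- c(nxt, nb$to[labels[nb$to] > 0L])
    }
    set <- unique(nxt)
  }

  # grow the pad into air, layer by layer
  grown <- patch
  layers <- vector("list", n_layers)
  occupied <- array(FALSE, d); occupied[patch] <- TRUE
  for (k in seq_len(n_layers)) {
    cand <- integer()
    for (ax in 1:3) for (dr in c(-1L, 1L)) {
      nb <- .neighbor_lin(grown, d, ax, dr)
      cand <- c(cand, nb$to)
    }
    cand <- unique(cand)
    cand <- cand[labels[cand] == 0L & !occupied[cand]]
    if (!length(cand)) stop("electrode pad at '", site, "' cannot grow into air")
    layers[[k]] <- cand
    occupied[cand] <- TRUE
    grown <- cand
  }
  for (k in seq_len(n_layers)) {
    lab_id <- if (mode == "TOTAL" && k <= n_skin_layers) id[["skin_slice"]] else id[["electrode_bulk"]]
    labels[layers[[k]]] <- lab_id
  }

  phantom$labels <- labels
  phantom$pads[[site]] <- list(
    site = site, mode = mode, touch_voltage = touch_voltage,
    skin_sigma = skin_sigma, skin_eps_r = skin_eps,
    pad_voxels = unlist(layers), dirichlet = layers[[n_layers]],
    n_skin_layers = if (mode == "TOTAL") n_skin_layers else 0L,
    skin_slice_thickness_mm = if (mode == "TOTAL") n_skin_layers * s else 0
  )
  phantom
}

#' Place all electrodes of a current path
#'
#' @param phantom A `voxel_phantom`.
#' @param path A path label or [current_path()] object.
#' @param mode Body-model mode, `"TOTAL"` or `"INTERN"`.
#' @param touch_voltage Touch voltage in V (drives the skin-slice properties
#'   in TOTAL mode; the source boundary value in the solve).
#' @return Phantom with all source and sink pads placed.
#' @export
place_path_electrodes <- function(phantom, path, mode = c("TOTAL", "INTERN"),
                                  touch_voltage = 100) {
  mode <- match.arg(mode)
  if (is.character(path)) path <- current_path(path)
  for (site in c(path$source_sites, path$sink_sites)) {
    phantom <- place_electrode(phantom, site, mode,
                               touch_voltage = if (mode == "TOTAL") touch_voltage else NULL)
  }
  phantom
}

#' Shift an electrode site's patch (sensitivity analysis)
#'
#' Regrows the surface patch of `site` from an anchor shifted by
#' `offset_mm` (a length-3 vector, any direction). If the shifted anchor is
#' farther than `max_snap_mm` from the body surface the shift is rejected
#' with an error of class `electrode_off_surface`.
#'
#' @param phantom A `voxel_phantom` (without pads placed).
#' @param site Site to move.
#' @param offset_mm Numeric length-3 offset in mm.
#' @param max_snap_mm Maximum allowed snap distance to the surface.
#' @return Phantom with the site's patch recomputed.
#' @export
shift_electrode_site <- function(phantom, site, offset_mm, max_snap_mm = 25) {
  stopifnot(length(offset_mm) == 3)
  cfg <- phantom$config
  anchors <- .default_anchors(cfg)
  if (!is.null(cfg$anchors)) anchors[names(cfg$anchors)] <- cfg$anchors
  anchor <- anchors[[site]] + offset_mm
  body <- phantom$labels > 0L
  surface <- body & !.erode6(body)
  surf_lin <- which(surface)
  ijk <- arrayInd(surf_lin, dim(body))
  w <- sweep((ijk - 1) * phantom$spacing, 2, phantom$origin, "+")
  d2 <- (w[, 1] - anchor[1])^2 + (w[, 2] - anchor[2])^2 + (w[, 3] - anchor[3])^2
  if (min(d2) > max_snap_mm^2) {
    stop(structure(class = c("electrode_off_surface", "error", "condition"),
                   list(message = paste0("offset moves electrode '", site,
                                         "' off the body surface"),
                        call = sys.call())))
  }
  p <- .grow_patch(body, surface, anchor, prod(cfg$patch_size),
                   phantom$spacing, phantom$origin)
  phantom$sites[[site]] <- p$lin
  phantom$site_areas[site] <- p$area
  phantom
}
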
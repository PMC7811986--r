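# Label-volume IO: NIfTI voxel label maps with a JSON sidecar carrying the
# tissue map, spacing, origin and heart axes.

.sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write a phantom's label volume to NIfTI (+ JSON sidecar)
#'
#' The `.nii`/`.nii.gz` file stores the integer label grid with the voxel
#' spacing in its header; the sidecar stores the tissue map, origin, heart
#' axes and electrode patch registry so that [load_label_volume()] can
#' reconstruct the full phantom.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly `path`.
#' @export
write_label_volume <- function(phantom, path) {
  img <- RNifti::asNifti(phantom$labels,
                         pixdim = rep(phantom$spacing, 3), datatype = "int16")
  RNifti::writeNifti(img, path)
  sidecar <- list(
    spacing_mm = phantom$spacing,
    origin_mm = phantom$origin,
    tissue_map = as.list(phantom$tissue_map),
    heart_axes = lapply(phantom$heart_axes, function(m) list(p0 = m[1, ], p1 = m[2, ])),
    sites = lapply(phantom$sites, function(v) as.integer(v)),
    site_areas = as.list(phantom$site_areas)
  )
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a labeled voxel volume as a phantom
#'
#' Reads a NIfTI label map (own or third-party). Labels must be covered by
#' the tissue map (from the sidecar or the `tissue_map` argument); unmapped
#' ids raise an error listing them. A disconnected tissue set is a warning,
#' not an error (real anatomical models may contain floating voxels). Heart
#' axes must come from the sidecar or the `heart_axes` argument when the
#' trans-cardiac line integrals are to be evaluated.
#'
#' @param path `.nii`/`.nii.gz` file.
#' @param tissue_map Named character vector `label_id -> tissue_name`
#'   (overrides the sidecar).
#' @param heart_axes Optional list of three 2x3 matrices (world mm).
#' @return A `voxel_phantom` (validated with `connected_warn_only = TRUE`).
#' @export
load_label_volume <- function(path, tissue_map = NULL, heart_axes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(img), dim(img))
  spacing <- RNifti::pixdim(img)[1]
  sidecar <- .sidecar_path(path)
  sc <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(tissue_map)) {
    if (is.null(sc$tissue_map)) stop("no tissue map: supply `tissue_map` or a sidecar")
    tissue_map <- unlist(sc$tissue_map)
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  unmapped <- setdiff(as.character(present), names(tissue_map))
  if (length(unmapped)) {
    stop("label id(s) without tissue mapping: ", paste(unmapped, collapse = ", "))
  }
  if (!is.null(sc$spacing_mm)) spacing <- as.numeric(sc$spacing_mm)
  origin <- if (!is.null(sc$origin_mm)) as.numeric(sc$origin_mm) else c(0, 0, 0)
  if (is.null(heart_axes) && !is.null(sc$heart_axes)) {
    heart_axes <- lapply(sc$heart_axes, function(a) rbind(unlist(a$p0), unlist(a$p1)))
  }
  sites <- if (!is.null(sc$sites)) lapply(sc$sites, as.integer) else list()
  site_areas <- if (!is.null(sc$site_areas)) unlist(sc$site_areas) else numeric()
  ph <- structure(
    list(labels = labels, spacing = spacing, origin = origin,
         tissue_map = tissue_map, sites = sites, site_areas = site_areas,
         heart_axes = heart_axes, heart_center = NULL, config = NULL,
         pads = list()),
    class = "voxel_phantom"
  )
  validate_phantom(ph, connected_warn_only = TRUE)
  ph
}

#' Export field-solution volumes for external viewers
#'
#' Writes |E| and |J| magnitude volumes (and optionally the real/imaginary
#' parts of the potential) as NIfTI files next to `prefix`.
#'
#' @param solution A solved `field_solution` with derived fields.
#' @param prefix Path prefix; files `<prefix>_Emag.nii.gz` etc. are created.
#' @param potential Also write `phi_re` / `phi_im` volumes.
#' @return Invisibly the written paths.
#' @export
export_field_volumes <- function(solution, prefix, potential = FALSE) {
  s <- solution$phantom$spacing
  wr <- function(a, tag) {
    a[is.na(a)] <- 0
    p <- paste0(prefix, "_", tag, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(a, pixdim = rep(s, 3)), p)
    p
  }
  emag <- sqrt(Mod(solution$E[[1]])^2 + Mod(solution$E[[2]])^2 + Mod(solution$E[[3]])^2)
  jmag <- sqrt(Mod(solution$J[[1]])^2 + Mod(solution$J[[2]])^2 + Mod(solution$J[[3]])^2)
  paths <- c(wr(emag, "Emag"), wr(jmag, "Jmag"))
  if (potential) {
    paths <- c(paths, wr(Re(solution$potential), "phi_re"),
               wr(Im(solution$potential), "phi_im"))
  }
  invisible(paths)
}
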
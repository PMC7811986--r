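# Synthetic parametric voxel body phantom.
#
# Geometric primitives on a uniform grid: trunk as an elliptic cylinder with
# concentric skin/fat layers, limbs as cylinders, heart as an ellipsoidal
# myocardium shell around a blood-filled lumen, two lung ellipsoids,
# spine/long bones as cylinders, and blood-vessel tubes connecting the arms
# and the lower trunk to the heart lumen (the subclavian / aorta / vena-cava
# analogues that carry the current-channeling effect).
#
# Coordinate convention: world coordinates are voxel-center positions in mm;
# axes (x, y, z) = (left -> right, posterior -> anterior, inferior ->
# superior). Voxel [1,1,1] has world coordinate `origin`.

.TISSUE_IDS <- c(muscle = 1L, fat = 2L, bone = 3L, lung = 4L,
                 heart_muscle = 5L, heart_blood = 6L, vessel_blood = 7L,
                 skin = 8L, skin_slice = 9L, electrode_bulk = 10L)

#' Phantom configuration with documented defaults
#'
#' All linear dimensions in mm. The default is a reduced-stature (~1.1 m)
#' body: the minimal closed anatomy that reproduces the current-channeling
#' mechanism at desk scale. `scale` multiplies every linear dimension
#' (not the voxel spacing).
#'
#' @param spacing Isotropic voxel spacing in mm, within `[1, 5]`.
#' @param scale Global geometric scale factor.
#' @param vessel_channels Rasterize the blood-vessel tubes (`TRUE`) or leave
#'   the underlying tissue in place (`FALSE`).
#' @param ... Named overrides of any default listed in the function body
#'   (e.g. `trunk_a`, `heart_wall`, `vessel_radius`, `anchors`).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(spacing = 4, scale = 1, vessel_channels = TRUE, ...) {
  if (spacing < 1 || spacing > 5) stop("spacing must be within [1, 5] mm")
  cfg <- list(
    spacing = spacing,
    vessel_channels = vessel_channels,
    trunk_a = 100, trunk_b = 65, trunk_height = 380,
    leg_length = 340, leg_radius = 36, leg_offset = 55,
    arm_length = 240, arm_radius = 24, arm_overlap = 20, shoulder_drop = 45,
    skin_mm = 4, fat_mm = 4,
    spine_radius = 16, spine_y = -35,
    leg_bone_radius = 12, arm_bone_radius = 8,
    lung_semi = c(42, 52, 120), lung_dx = 50, lung_dy = 8, lung_dz = 235,
    heart_dx = -18, heart_dy = 12, heart_dz = 250,
    heart_outer = c(48, 40, 56), heart_wall = 20,
    vessel_radius = 9, neck_radius = 5,
    patch_size = c(100, 100),   # nominal electrode patch, mm x mm
    pad_bulk_layers = 2L,
    margin_mm = 24,
    anchors = NULL              # optional named list of site anchor overrides
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown phantom config option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  lin <- c("trunk_a", "trunk_b", "trunk_height", "leg_length", "leg_radius",
           "leg_offset", "arm_length", "arm_radius", "arm_overlap",
           "shoulder_drop", "skin_mm", "fat_mm", "spine_radius", "spine_y",
           "leg_bone_radius", "arm_bone_radius", "lung_semi", "lung_dx",
           "lung_dy", "lung_dz", "heart_dx", "heart_dy", "heart_dz",
           "heart_outer", "heart_wall", "vessel_radius", "neck_radius", "patch_size",
           "margin_mm")
  if (scale != 1) cfg[lin] <- lapply(cfg[lin], function(v) v * scale)
  structure(cfg, class = "phantom_config")
}

# one-voxel shift with FALSE padding; dir = +1 / -1 along axis 1..3
.shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1L) }
  else         { idx_dst[[axis]] <- 1:(d[axis] - 1L); idx_src[[axis]] <- 2:d[axis] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

.erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dr in c(-1L, 1L)) out <- out & .shift3(mask, ax, dr)
  out
}

# linear indices of the 6-neighbours of linear indices `lin` along (axis, dir),
# dropping steps that leave the grid
.neighbor_lin <- function(lin, d, axis, dir) {
  ijk <- arrayInd(lin, d)
  ijk[, axis] <- ijk[, axis] + dir
  keep <- ijk[, axis] >= 1L & ijk[, axis] <= d[axis]
  ijk <- ijk[keep, , drop = FALSE]
  list(from = lin[keep],
       to = ijk[, 1] + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2])
}

# voxels within radius r of the segment p0-p1 (world mm); returns linear idx
.tube_lin <- function(p0, p1, r, xs, ys, zs) {
  d <- c(length(xs), length(ys), length(zs))
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  ir <- which(xs >= lo[1] & xs <= hi[1])
  jr <- which(ys >= lo[2] & ys <= hi[2])
  kr <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ir) || !length(jr) || !length(kr)) return(integer())
  g <- expand.grid(i = ir, j = jr, k = kr)
  px <- xs[g$i] - p0[1]; py <- ys[g$j] - p0[2]; pz <- zs[g$k] - p0[3]
  v <- p1 - p0; vv <- sum(v^2)
  t <- pmin(pmax((px * v[1] + py * v[2] + pz * v[3]) / vv, 0), 1)
  d2 <- (px - t * v[1])^2 + (py - t * v[2])^2 + (pz - t * v[3])^2
  keep <- d2 <= r^2
  g <- g[keep, , drop = FALSE]
  g$i + (g$j - 1L) * d[1] + (g$k - 1L) * d[1] * d[2]
}

.default_anchors <- function(cfg) {
  trunk_z0 <- cfg$leg_length
  trunk_top <- trunk_z0 + cfg$trunk_height
  shoulder_z <- trunk_top - cfg$shoulder_drop
  arm_tip <- cfg$trunk_a - cfg$arm_overlap + cfg$arm_length
  heart_z <- trunk_z0 + cfg$heart_dz
  list(
    LH = c(arm_tip, 0, shoulder_z),
    RH = c(-arm_tip, 0, shoulder_z),
    LF = c(cfg$leg_offset, 0, 0),
    RF = c(-cfg$leg_offset, 0, 0),
    PT = c(cfg$heart_dx, -cfg$trunk_b, heart_z + 10),
    AT = c(cfg$heart_dx, cfg$trunk_b, heart_z + 10),
    SEAT = c(0, -cfg$trunk_b, trunk_z0 + 25)
  )
}

# grow a surface patch from the surface voxel nearest `anchor` (world mm)
# until the accumulated exposed-face area reaches `target_area` (mm^2).
# BFS over 26-adjacent surface voxels, distance-ordered within layers.
.grow_patch <- function(body, surface, anchor, target_area, spacing, origin) {
  d <- dim(body)
  surf_lin <- which(surface)
  ijk <- arrayInd(surf_lin, d)
  wx <- origin[1] + (ijk[, 1] - 1) * spacing
  wy <- origin[2] + (ijk[, 2] - 1) * spacing
  wz <- origin[3] + (ijk[, 3] - 1) * spacing
  dist2 <- (wx - anchor[1])^2 + (wy - anchor[2])^2 + (wz - anchor[3])^2
  # exposed-face count per surface voxel
  nfaces <- integer(length(surf_lin))
  surf_map <- array(0L, d); surf_map[surf_lin] <- seq_along(surf_lin)
  for (ax in 1:3) for (dr in c(-1L, 1L)) {
    nb <- .neighbor_lin(surf_lin, d, ax, dr)
    exposed <- !body[nb$to]
    nfaces[surf_map[nb$from[exposed]]] <- nfaces[surf_map[nb$from[exposed]]] + 1L
    # faces on the grid boundary count as exposed too
    off_grid <- setdiff(seq_along(surf_lin), surf_map[nb$from])
    nfaces[off_grid] <- nfaces[off_grid] + 1L
  }
  area_vox <- nfaces * spacing^2
  seed <- which.min(dist2)
  visited <- logical(length(surf_lin))
  frontier <- seed
  visited[seed] <- TRUE
  picked <- integer()
  acc <- 0
  repeat {
    ord <- frontier[order(dist2[frontier], frontier)]
    for (v in ord) {
      picked <- c(picked, v)
      acc <- acc + area_vox[v]
      if (acc >= target_area) break
    }
    if (acc >= target_area) break
    nxt <- integer()
    fl <- surf_lin[frontier]
    nb_ijk <- arrayInd(fl, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- nb_ijk
      q[, 1] <- q[, 1] + dx; q[, 2] <- q[, 2] + dy; q[, 3] <- q[, 3] + dz
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      ql <- q[ok, 1] + (q[ok, 2] - 1L) * d[1] + (q[ok, 3] - 1L) * d[1] * d[2]
      sidx <- surf_map[ql]
      sidx <- sidx[sidx > 0L]
      nxt <- c(nxt, sidx[!visited[sidx]])
      visited[sidx] <- TRUE
    }
    if (!length(nxt)) break  # ran out of surface
    frontier <- unique(nxt)
  }
  list(lin = surf_lin[picked], area = acc)
}

#' Build the synthetic voxel body phantom
#'
#' Deterministic for a fixed configuration: no randomness anywhere. The
#' returned phantom carries the label grid, the tissue map, the seven
#' registered electrode surface patches, and the three orthogonal
#' trans-cardiac axes used by the line-integral dose estimate.
#'
#' @param config A [phantom_config()].
#' @return An object of class `voxel_phantom`.
#' @examples
#' ph <- build_phantom(phantom_config(spacing = 5, scale = 0.5))
#' table(ph$tissue_map[as.character(ph$labels[ph$labels > 0])])
#' @export
build_phantom <- function(config = phantom_config()) {
  cfg <- config
  s <- cfg$spacing
  id <- .TISSUE_IDS
  trunk_z0 <- cfg$leg_length
  trunk_top <- trunk_z0 + cfg$trunk_height
  shoulder_z <- trunk_top - cfg$shoulder_drop
  arm_x0 <- cfg$trunk_a - cfg$arm_overlap
  arm_x1 <- arm_x0 + cfg$arm_length
  m <- cfg$margin_mm
  xs <- seq(-(arm_x1 + m), arm_x1 + m, by = s)
  ys <- seq(-(cfg$trunk_b + m), cfg$trunk_b + m, by = s)
  zs <- seq(-m, trunk_top + m, by = s)
  d <- c(length(xs), length(ys), length(zs))
  origin <- c(xs[1], ys[1], zs[1])

  body <- array(FALSE, d)
  # trunk: elliptic cylinder
  exy <- outer((xs / cfg$trunk_a)^2, (ys / cfg$trunk_b)^2, "+") <= 1
  kz <- which(zs >= trunk_z0 & zs <= trunk_top)
  body[, , kz] <- body[, , kz] | array(exy, c(d[1], d[2], length(kz)))
  # legs: circular cylinders along z
  for (sx in c(1, -1)) {
    cyl <- outer((xs - sx * cfg$leg_offset)^2, ys^2, "+") <= cfg$leg_radius^2
    kz <- which(zs >= 0 & zs <= trunk_z0)
    body[, , kz] <- body[, , kz] | array(cyl, c(d[1], d[2], length(kz)))
  }
  # arms: circular cylinders along x at shoulder height
  arm_yz <- outer(ys^2, (zs - shoulder_z)^2, "+") <= cfg$arm_radius^2
  for (sx in c(1, -1)) {
    ix <- which(sign(xs) * sx > 0 & abs(xs) >= arm_x0 & abs(xs) <= arm_x1)
    w <- which(arm_yz)
    if (length(ix) && length(w)) {
      jj <- (w - 1L) %% d[2] + 1L
      kk <- (w - 1L) %/% d[2] + 1L
      off <- (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
      body[as.vector(outer(ix, off, "+"))] <- TRUE
    }
  }

  labels <- array(0L, d)
  labels[body] <- id[["muscle"]]

  # skin and subcutaneous fat as erosion shells (thickness in mm -> shells)
  n_skin <- max(1L, round(cfg$skin_mm / s))
  n_fat <- max(1L, round(cfg$fat_mm / s))
  cur <- body
  for (k in seq_len(n_skin)) {
    shell <- cur & !.erode6(cur)
    labels[shell] <- id[["skin"]]
    cur <- cur & !shell
  }
  for (k in seq_len(n_fat)) {
    shell <- cur & !.erode6(cur)
    labels[shell] <- id[["fat"]]
    cur <- cur & !shell
  }

  put_if <- function(lin, new_id, over) {
    lin <- lin[labels[lin] %in% id[over]]
    labels[lin] <<- id[[new_id]]
  }
  # bones
  spine <- .tube_lin(c(0, cfg$spine_y, trunk_z0), c(0, cfg$spine_y, trunk_top - 20),
                     cfg$spine_radius, xs, ys, zs)
  put_if(spine, "bone", "muscle")
  for (sx in c(1, -1)) {
    put_if(.tube_lin(c(sx * cfg$leg_offset, 0, 10), c(sx * cfg$leg_offset, 0, trunk_z0),
                     cfg$leg_bone_radius, xs, ys, zs), "bone", "muscle")
    put_if(.tube_lin(c(sx * (arm_x0 + 10), 0, shoulder_z), c(sx * (arm_x1 - 14), 0, shoulder_z),
                     cfg$arm_bone_radius, xs, ys, zs), "bone", "muscle")
  }
  # lungs
  lung_z <- trunk_z0 + cfg$lung_dz
  for (sx in c(1, -1)) {
    ctr <- c(sx * cfg$lung_dx, cfg$lung_dy, lung_z)
    e3 <- outer(outer(((xs - ctr[1]) / cfg$lung_semi[1])^2,
                      ((ys - ctr[2]) / cfg$lung_semi[2])^2, "+"),
                ((zs - ctr[3]) / cfg$lung_semi[3])^2, "+") <= 1
    put_if(which(e3), "lung", "muscle")
  }
  # heart: myocardium shell + blood lumen
  hc <- c(cfg$heart_dx, cfg$heart_dy, trunk_z0 + cfg$heart_dz)
  inner <- cfg$heart_outer - cfg$heart_wall
  if (any(inner < 2 * s)) stop("config leaves tissue 'heart_blood' empty (wall too thick)")
  e_out <- outer(outer(((xs - hc[1]) / cfg$heart_outer[1])^2,
                       ((ys - hc[2]) / cfg$heart_outer[2])^2, "+"),
                 ((zs - hc[3]) / cfg$heart_outer[3])^2, "+") <= 1
  e_in <- outer(outer(((xs - hc[1]) / inner[1])^2,
                      ((ys - hc[2]) / inner[2])^2, "+"),
                ((zs - hc[3]) / inner[3])^2, "+") <= 1
  put_if(which(e_out & !e_in), "heart_muscle", c("muscle", "lung", "bone"))
  put_if(which(e_in), "heart_blood", c("muscle", "lung", "bone", "heart_muscle"))

  # vessel channels: arm -> subclavian analogue -> lumen; lumen -> aorta /
  # vena-cava analogue -> lower trunk
  if (isTRUE(cfg$vessel_channels)) {
    vr <- cfg$vessel_radius
    seg <- function(p0, p1) put_if(.tube_lin(p0, p1, vr, xs, ys, zs),
                                   "vessel_blood",
                                   c("muscle", "lung", "heart_muscle", "bone", "fat"))
    # The great-vessel trunks terminate immediately above the heart base and
    # below the apex (2 mm clearance, no wall puncture at the poles): they
    # import the remote arch potential to the base's doorstep and collect
    # the apex exit current into the caval trunk, which concentrates the
    # through-wall current at the poles -- the channeling mechanism. The
    # lumen joins the tree through a narrow lateral root (pulmonary-vein
    # analogue) at the equator, where the wall current is small.
    clearance <- 2
    arch <- c(hc[1], hc[2], hc[3] + cfg$heart_outer[3] + clearance + vr)
    below <- c(hc[1], hc[2], hc[3] - cfg$heart_outer[3] - clearance - vr)
    for (sx in c(1, -1)) {
      seg(c(sx * (arm_x0 + 70), 0, shoulder_z), arch)
    }
    nr <- cfg$neck_radius
    side_x <- hc[1] - cfg$heart_outer[1] - clearance - nr
    side_lo <- c(side_x, hc[2], below[3])
    side_hi <- c(side_x, hc[2], hc[3] - 10)
    put_if(.tube_lin(side_lo, side_hi, nr, xs, ys, zs), "vessel_blood",
           c("muscle", "lung", "heart_muscle", "bone", "fat"))
    put_if(.tube_lin(side_hi, c(hc[1] - inner[1] * 0.1, hc[2], hc[3] - 10),
                     nr, xs, ys, zs), "vessel_blood",
           c("muscle", "lung", "heart_muscle", "bone", "fat"))
    # descending aorta / vena-cava analogues beside the heart and the
    # inferior trunk continuing from below the apex to the lower trunk
    desc <- c(hc[1] + cfg$heart_outer[1] + 4 + vr, hc[2] - 30,
              hc[3] + cfg$heart_outer[3] + 10)
    iliac <- c(0, 0, trunk_z0 + 20)
    seg(arch, desc)
    seg(desc, iliac)
    seg(below, side_lo)
    seg(below, iliac)
  }

  # every anatomical tissue must be present
  for (tn in c("muscle", "fat", "bone", "lung", "heart_muscle", "heart_blood",
               if (isTRUE(cfg$vessel_channels)) "vessel_blood", "skin")) {
    if (!any(labels == id[[tn]])) {
      stop("configuration leaves required tissue '", tn, "' empty")
    }
  }

  tissue_map <- stats::setNames(names(id), as.character(id))
  body <- labels > 0L
  surface <- body & !.erode6(body)
  anchors <- .default_anchors(cfg)
  if (!is.null(cfg$anchors)) anchors[names(cfg$anchors)] <- cfg$anchors
  target <- prod(cfg$patch_size)
  sites <- list(); site_areas <- numeric()
  for (site in ELECTRODE_SITES) {
    p <- .grow_patch(body, surface, anchors[[site]], target, s, origin)
    sites[[site]] <- p$lin
    site_areas[site] <- p$area
  }

  ax_margin <- 6
  half <- cfg$heart_outer - ax_margin
  heart_axes <- list(
    base_apex = rbind(hc - c(0, 0, half[3]), hc + c(0, 0, half[3])),
    front_back = rbind(hc - c(0, half[2], 0), hc + c(0, half[2], 0)),
    top_bottom = rbind(hc - c(half[1], 0, 0), hc + c(half[1], 0, 0))
  )

  structure(
    list(labels = labels, spacing = s, origin = origin, tissue_map = tissue_map,
         sites = sites, site_areas = site_areas, heart_axes = heart_axes,
         heart_center = hc, config = cfg, pads = list()),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("<voxel_phantom> ", paste(d, collapse = " x "), " grid @ ", x$spacing,
      " mm, ", sum(x$labels > 0L), " tissue voxels\n", sep = "")
  tab <- table(x$tissue_map[as.character(x$labels[x$labels > 0L])])
  print(tab)
  invisible(x)
}

#' Tissue volumes of a phantom
#'
#' @param phantom A `voxel_phantom`.
#' @return Tibble with `tissue`, `n_voxels`, `volume_cm3`.
#' @export
tissue_volumes <- function(phantom) {
  lab <- phantom$labels[phantom$labels > 0L]
  tab <- table(phantom$tissue_map[as.character(lab)])
  tibble::tibble(
    tissue = names(tab),
    n_voxels = as.integer(tab),
    volume_cm3 = as.integer(tab) * (phantom$spacing / 10)^3
  )
}

#' Validate phantom invariants
#'
#' Checks: every non-air label is mapped; the tissue voxel set is a single
#' 6-connected component; the lumen is fully enclosed by myocardium /
#' vessel blood; vessel channels (when present) are 6-connected with the
#' lumen and reach both arms and the lower trunk; electrode patches are
#' mutually disjoint with face area within 30% of the nominal patch area;
#' heart axes are pairwise orthogonal and inside the heart bounding box.
#'
#' @param phantom A `voxel_phantom`.
#' @param connected_warn_only If `TRUE`, a disconnected tissue set gives a
#'   warning instead of an error (loaded real-world label maps may contain
#'   floating voxels).
#' @return Invisibly `TRUE`.
#' @export
validate_phantom <- function(phantom, connected_warn_only = FALSE) {
  labels <- phantom$labels
  d <- dim(labels)
  id <- .TISSUE_IDS
  present <- setdiff(unique(as.vector(labels)), 0L)
  unmapped <- setdiff(as.character(present), names(phantom$tissue_map))
  if (length(unmapped)) stop("unmapped label id(s): ", paste(unmapped, collapse = ", "))

  body_lin <- which(labels > 0L)
  vert <- array(0L, d); vert[body_lin] <- seq_along(body_lin)
  edges <- list()
  for (ax in 1:3) {
    nb <- .neighbor_lin(body_lin, d, ax, 1L)
    keep <- labels[nb$to] > 0L
    edges[[ax]] <- cbind(vert[nb$from[keep]], vert[nb$to[keep]])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(body_lin) - igraph::vcount(g)))
  ncomp <- igraph::components(g)$no
  if (ncomp != 1L) {
    msg <- paste0("tissue voxel set has ", ncomp, " 6-connected components")
    if (connected_warn_only) warning(msg) else stop(msg)
  }

  lumen <- which(labels == id[["heart_blood"]])
  if (length(lumen)) {
    ok_ids <- id[c("heart_muscle", "heart_blood", "vessel_blood")]
    for (ax in 1:3) for (dr in c(-1L, 1L)) {
      nb <- .neighbor_lin(lumen, d, ax, dr)
      bad <- !(labels[nb$to] %in% ok_ids)
      if (any(bad)) stop("heart lumen not enclosed: ", sum(bad),
                         " lumen voxel face(s) touch ",
                         paste(unique(phantom$tissue_map[as.character(labels[nb$to[bad]])]),
                               collapse = "/"))
    }
  }

  vess <- which(labels == id[["vessel_blood"]])
  if (length(vess)) {
    sub_lin <- c(vess, lumen)
    sv <- array(0L, d); sv[sub_lin] <- seq_along(sub_lin)
    edges <- list()
    for (ax in 1:3) {
      nb <- .neighbor_lin(sub_lin, d, ax, 1L)
      keep <- sv[nb$to] > 0L
      edges[[ax]] <- cbind(sv[nb$from[keep]], sv[nb$to[keep]])
    }
    gg <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0L, length(sub_lin) - igraph::vcount(gg)))
    if (igraph::components(gg)$no != 1L) {
      stop("vessel channels are not 6-connected with the heart lumen")
    }
    ijk <- arrayInd(vess, d)
    wx <- phantom$origin[1] + (ijk[, 1] - 1) * phantom$spacing
    wz <- phantom$origin[3] + (ijk[, 3] - 1) * phantom$spacing
    cfg <- phantom$config
    if (!is.null(cfg)) {
      if (!any(wx > cfg$trunk_a) || !any(wx < -cfg$trunk_a)) {
        stop("vessel channels do not reach both arms")
      }
      if (!any(wz < cfg$leg_length + 0.2 * cfg$trunk_height)) {
        stop("vessel channels do not reach the lower trunk")
      }
    }
  }

  # electrode patches: disjoint, area within 30% of nominal
  all_sites <- unlist(phantom$sites)
  if (anyDuplicated(all_sites)) stop("electrode surface patches overlap")
  if (!is.null(phantom$config)) {
    nominal <- prod(phantom$config$patch_size)
    bad <- abs(phantom$site_areas - nominal) > 0.3 * nominal
    if (any(bad)) stop("electrode patch area off nominal by > 30%: ",
                       paste(names(phantom$site_areas)[bad], collapse = ", "))
  }

  ax <- phantom$heart_axes
  if (!is.null(ax)) {
    dirs <- lapply(ax, function(seg) {
      v <- seg[2, ] - seg[1, ]; v / sqrt(sum(v^2))
    })
    for (i in 1:2) for (j in (i + 1):3) {
      if (abs(sum(dirs[[i]] * dirs[[j]])) > 1e-9) {
        stop("heart axes are not pairwise orthogonal")
      }
    }
    hm <- which(labels %in% id[c("heart_muscle", "heart_blood")])
    ijk <- arrayInd(hm, d)
    lo <- phantom$origin + (apply(ijk, 2, min) - 1) * phantom$spacing - phantom$spacing
    hi <- phantom$origin + (apply(ijk, 2, max) - 1) * phantom$spacing + phantom$spacing
    for (seg in ax) {
      if (any(t(seg) < lo - 1e-9) || any(t(seg) > hi + 1e-9)) {
        stop("a heart axis leaves the heart bounding box")
      }
    }
  }
  invisible(TRUE)
}
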
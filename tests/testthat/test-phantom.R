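# Synthetic phantom generator, electrode placement, and label-volume IO.

test_that("default phantom has the full anatomy and passes all invariants", {
  ph <- default_phantom()
  expect_true(validate_phantom(ph))
  present <- sort(unique(as.vector(ph$labels)))
  anatomical <- c("muscle", "fat", "bone", "lung", "heart_muscle",
                  "heart_blood", "vessel_blood", "skin")
  expect_true(all(contactdose:::.TISSUE_IDS[anatomical] %in% present))
  expect_length(ph$tissue_map, 10L)  # incl. skin_slice + electrode_bulk
  expect_length(ph$sites, 7L)
  # patch areas within 30% of the nominal patch size
  nominal <- prod(ph$config$patch_size)
  expect_true(all(abs(ph$site_areas - nominal) <= 0.3 * nominal))
})

test_that("phantom build is pure and voxel counts match a brute-force oracle", {
  cfg <- small_phantom_config()
  a <- build_phantom(cfg)
  b <- build_phantom(cfg)
  expect_identical(a$labels, b$labels)
  # independent rasterization of the body outline (scalar membership test
  # per voxel centre, written without the builder's outer-product machinery)
  d <- dim(a$labels)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  x <- a$origin[1] + (g$i - 1) * a$spacing
  y <- a$origin[2] + (g$j - 1) * a$spacing
  z <- a$origin[3] + (g$k - 1) * a$spacing
  trunk_z0 <- cfg$leg_length; trunk_top <- trunk_z0 + cfg$trunk_height
  shoulder_z <- trunk_top - cfg$shoulder_drop
  arm_x0 <- cfg$trunk_a - cfg$arm_overlap
  arm_x1 <- arm_x0 + cfg$arm_length
  in_trunk <- (x / cfg$trunk_a)^2 + (y / cfg$trunk_b)^2 <= 1 &
    z >= trunk_z0 & z <= trunk_top
  in_leg <- ((x - cfg$leg_offset)^2 + y^2 <= cfg$leg_radius^2 |
               (x + cfg$leg_offset)^2 + y^2 <= cfg$leg_radius^2) &
    z >= 0 & z <= trunk_z0
  in_arm <- y^2 + (z - shoulder_z)^2 <= cfg$arm_radius^2 &
    abs(x) >= arm_x0 & abs(x) <= arm_x1
  expect_identical(sum(a$labels > 0L), sum(in_trunk | in_leg | in_arm))
})

test_that("vessels-off variant differs only at vessel voxels", {
  on <- small_phantom()
  off <- build_phantom(small_phantom_config(vessel_channels = FALSE))
  vid <- contactdose:::.TISSUE_IDS[["vessel_blood"]]
  diff_vox <- which(on$labels != off$labels)
  expect_true(length(diff_vox) > 0)
  expect_true(all(on$labels[diff_vox] == vid))
  expect_false(any(off$labels == vid))
  # lumen stays enclosed in both variants
  expect_true(validate_phantom(off))
})

test_that("halving the voxel spacing changes tissue volumes by < 10%", {
  v4 <- tissue_volumes(build_phantom(phantom_config(spacing = 4)))
  v2 <- tissue_volumes(build_phantom(phantom_config(spacing = 2)))
  m <- dplyr::inner_join(v4, v2, by = "tissue", suffix = c("_4", "_2"))
  expect_identical(nrow(m), 8L)
  expect_true(all(abs(m$volume_cm3_4 - m$volume_cm3_2) / m$volume_cm3_2 < 0.1))
})

test_that("electrode placement: skin removal, slice thickness, commutation", {
  ph <- small_phantom()
  ids <- contactdose:::.TISSUE_IDS
  intern <- place_electrode(ph, "LH", "INTERN")
  expect_false(any(intern$labels[ph$sites$LH] == ids[["skin"]]))
  expect_error(place_electrode(ph, "LH", "TOTAL"), "touch voltage")
  expect_error(place_electrode(ph, "LH", "TOTAL", touch_voltage = 300),
               "no extrapolation")
  tot <- place_electrode(ph, "LH", "TOTAL", touch_voltage = 220)
  expect_true(any(tot$labels == ids[["skin_slice"]]))
  expect_true(any(tot$labels == ids[["electrode_bulk"]]))
  expect_equal(tot$pads$LH$skin_sigma, 0.85e-3)
  # slice thickness within 2 mm +- half a voxel along the patch normal
  # (assessed at a spacing fine enough to resolve the slice)
  ph4 <- memo("small4_phantom", build_phantom(small_phantom_config(spacing = 4)))
  tot4 <- place_electrode(ph4, "LH", "TOTAL", touch_voltage = 100)
  expect_lte(abs(tot4$pads$LH$skin_slice_thickness_mm - 2), ph4$spacing / 2)
  # placement order does not matter
  ab <- place_electrode(place_electrode(ph, "RH", "INTERN"), "LH", "INTERN")
  ba <- place_electrode(place_electrode(ph, "LH", "INTERN"), "RH", "INTERN")
  expect_identical(ab$labels, ba$labels)
})

test_that("label volumes round-trip through NIfTI with sidecar metadata", {
  ph <- small_phantom()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(ph, path)
  back <- load_label_volume(path)
  expect_identical(array(back$labels, dim(back$labels)), ph$labels)
  expect_identical(back$spacing, ph$spacing)
  expect_equal(back$origin, ph$origin)
  expect_equal(lapply(back$heart_axes, unname),
               lapply(ph$heart_axes, unname))
  expect_setequal(names(back$sites), names(ph$sites))
  # unmapped labels are reported by id
  expect_error(load_label_volume(path, tissue_map = c(`1` = "muscle")),
               "without tissue mapping")
  expect_error(load_label_volume("/nonexistent.nii"), "no such file")
})

test_that("configuration errors are caught and named", {
  expect_error(phantom_config(spacing = 0.5), "spacing")
  expect_error(phantom_config(bogus_dimension = 3), "unknown phantom config")
  expect_error(build_phantom(phantom_config(heart_wall = 100)), "heart_blood")
})

test_that("electrode site shifting snaps to the surface or flags the point", {
  ph <- small_phantom()
  moved <- shift_electrode_site(ph, "AT", c(0, 0, 10))
  expect_true(length(moved$sites$AT) > 0)
  expect_false(identical(sort(moved$sites$AT), sort(ph$sites$AT)))
  expect_error(shift_electrode_site(ph, "AT", c(0, 500, 0)),
               class = "electrode_off_surface")
})
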
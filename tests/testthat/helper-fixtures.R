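# Shared fixtures, built once per test run and cached. Phantom generation is
# deterministic, so caching only saves time.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- builder()
  }
  .fixture_cache[[name]]
}

# straight tube r = 0.5 mm, L = 10 mm at a working resolution
tube_005 <- function() fixture("tube_005", function() {
  make_tube_phantom(0.5, 10, spacing_mm = 0.05)
})

# the native micro-CT voxel scale (20 um)
tube_002 <- function() fixture("tube_002", function() {
  make_tube_phantom(0.5, 10, spacing_mm = 0.02)
})

tube_002_tilted <- function() fixture("tube_002_tilted", function() {
  make_tube_phantom(0.5, 6, spacing_mm = 0.02,
                    axis_direction = c(0, sin(pi / 6), cos(pi / 6)))
})

venturi_004 <- function() fixture("venturi_004", function() {
  make_venturi_phantom(0.8, 0.4, spacing_mm = 0.04)
})

mouse_008 <- function() fixture("mouse_008", function() {
  make_mouse_airway_phantom(mouse_airway_config(), spacing_mm = 0.08)
})

mouse_008_scaled <- function() fixture("mouse_008_scaled", function() {
  make_mouse_airway_phantom(mouse_airway_config(scale = 0.8), spacing_mm = 0.08)
})

mouse_geometry <- function() fixture("mouse_geometry", function() {
  ph <- mouse_008()
  lm <- setNames(
    lapply(seq_len(nrow(ph$landmarks)),
           function(i) as.numeric(ph$landmarks[i, c("x_mm", "y_mm", "z_mm")])),
    ph$landmarks$name
  )
  cl <- extract_centerline(ph$mask,
                           (lm$nostril_left + lm$nostril_right) / 2,
                           lm$arytenoid)
  segs <- partition_segments(cl, ph$landmarks)
  list(phantom = ph, landmarks = lm, centerline = cl, segments = segs)
})

# open-ended tube mask (lumen touches the z faces) for the 3D flow solver
open_tube_mask <- function(radius_mm, length_mm, spacing_mm) {
  key <- sprintf("open_tube_%g_%g_%g", radius_mm, length_mm, spacing_mm)
  fixture(key, function() {
    ph <- suppressWarnings(make_tube_phantom(radius_mm, length_mm, spacing_mm))
    m <- ph$mask$voxels
    zs <- which(apply(m, 3, any))
    binary_mask(m[, , zs], ph$mask$spacing_mm,
                ph$mask$origin_mm + c(0, 0, (zs[1] - 1) * spacing_mm))
  })
}

axial_centerline <- function(mask) {
  d <- dim(mask$voxels)
  z0 <- mask$origin_mm[3]
  z1 <- mask$origin_mm[3] + (d[3] - 1) * mask$spacing_mm[3]
  centerline_from_points(cbind(0, 0, seq(z0, z1, length.out = 200)))
}

# solved 16 voxel/diameter Poiseuille case, reused across flow tests
poiseuille_16 <- function() fixture("poiseuille_16", function() {
  mask <- open_tube_mask(0.5, 6, 1 / 16)
  sol <- solve_flow_3d(mask, "z-", "z+",
                       bc = flow_bc(flow_ml_s = 0.006),
                       fluid = fluid_properties(),
                       grid_tolerance = 1e-5, max_iterations = 4000,
                       peak_factor = 2.2)
  list(mask = mask, sol = sol, q_ml_s = 0.006, radius_mm = 0.5, length_mm = 6)
})

mean_slice_pressure <- function(sol, mask, k) {
  mean(sol$pressure_pa[, , k][mask$voxels[, , k]])
}
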
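straight_profile <- function(radius_mm, length_mm, n = 401) {
  tibble::tibble(s_mm = seq(0, length_mm, length.out = n),
                 area_mm2 = pi * radius_mm^2)
}

test_that("the quasi-1D solver reproduces Hagen-Poiseuille exactly on a tube", {
  prof <- straight_profile(0.5, 10)
  sol <- solve_flow_1d(prof, flow_bc(flow_ml_s = 5.28), fluid_properties())
  dp <- sol$pressure_pa[1] - sol$pressure_pa[nrow(sol)]
  # closed form computed independently
  mu <- 1.825e-5
  dp_hp <- 8 * mu * 0.01 * 5.28e-6 / (pi * (0.5e-3)^4)
  expect_equal(dp, dp_hp, tolerance = 0.005)
  # mean velocity is Q/A everywhere
  expect_equal(sol$velocity_m_s,
               rep(5.28e-6 / (pi * 0.25e-6), nrow(sol)), tolerance = 1e-12)
})

test_that("zero flow gives a uniform pressure field at the inlet value", {
  prof <- straight_profile(0.5, 10)
  expect_error(solve_flow_1d(prof, flow_bc(flow_ml_s = 0)), "flow_ml_s > 0")
  # vanishing-flow limit: pressures collapse onto the inlet value
  sol <- solve_flow_1d(prof, flow_bc(inlet_pressure_pa = 3, flow_ml_s = 1e-12))
  expect_equal(sol$pressure_pa, rep(3, nrow(sol)), tolerance = 1e-6)
  expect_lt(max(sol$velocity_m_s), 1e-8)
})

test_that("with negligible viscosity a symmetric venturi recovers inlet pressure", {
  vp <- make_venturi_phantom(0.8, 0.4, spacing_mm = 0.05)
  prof <- vp$truth$area_profile_true
  inviscid <- fluid_properties(density_kg_m3 = 1.204, viscosity_pa_s = 1e-300)
  sol <- solve_flow_1d(prof, flow_bc(flow_ml_s = 5.28), inviscid)
  # A(exit) = A(inlet): Bernoulli conserves the energy head
  expect_equal(sol$pressure_pa[nrow(sol)], sol$pressure_pa[1], tolerance = 1e-9)
  # pressure minimum at the throat
  expect_equal(sol$s_mm[which.min(sol$pressure_pa)],
               prof$s_mm[which.min(prof$area_mm2)], tolerance = 0.1)
})

test_that("non-positive areas are a singular-geometry error", {
  bad <- tibble::tibble(s_mm = c(0, 1, 2), area_mm2 = c(1, 0, 1))
  expect_error(solve_flow_1d(bad), "singular geometry")
  unordered <- tibble::tibble(s_mm = c(0, 2, 1), area_mm2 = 1)
  expect_error(solve_flow_1d(unordered), "strictly increasing")
})

test_that("pressure is non-increasing along a non-expanding duct", {
  # tube then taper to a throat: area never increases
  s <- seq(0, 8, by = 0.02)
  a <- ifelse(s < 4, pi * 0.64, pi * (0.8 - 0.05 * (s - 4))^2)
  sol <- solve_flow_1d(tibble::tibble(s_mm = s, area_mm2 = a),
                       flow_bc(flow_ml_s = 5.28))
  expect_true(all(diff(sol$pressure_pa) <= 1e-12))
})

test_that("the viscous pressure drop is linear in the flow rate", {
  prof <- straight_profile(0.5, 10)
  dp_at <- function(q) {
    sol <- solve_flow_1d(prof, flow_bc(flow_ml_s = q))
    sol$pressure_pa[1] - sol$pressure_pa[nrow(sol)]
  }
  expect_equal(dp_at(2) / dp_at(1), 2, tolerance = 1e-9)
  expect_equal(dp_at(5.28) / dp_at(2.64), 2, tolerance = 1e-9)
})

test_that("flow summaries telescope segment drops to pmax exactly", {
  g <- mouse_geometry()
  prof <- g$phantom$truth$area_profile_true
  sol <- solve_flow_1d(prof, flow_bc(flow_ml_s = 5.28))
  fs <- summarize_flow(sol, g$segments)
  expect_equal(fs$p_nasal_pa + fs$p_hard_pa + fs$p_soft_pa, fs$pmax_pa,
               tolerance = 1e-12)
  expect_lt(fs$pmax_pa, 0) # inspiratory pressures are negative
  expect_s3_class(fs, "flow_summary")
})
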
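test_that("grid reaction field reproduces the Born ion and vanishes without contrast", {
  grid <- grid_spec(spacing = 0.5, padding = 6)
  bc <- born_check(q = 1, radius = 2, d_in = 2.25, d_solv = 78.5, grid = grid)
  expect_equal(bc$analytic, born_analytic(1, 2, 2.25, 78.5), tolerance = 1e-12)
  expect_lt(bc$rel_error, 0.05)
  expect_lt(bc$grid, 0)  # negative for a net charge in a more polar solvent

  ion <- point_system(rbind(c(0, 0, 0)), charge = 1, radius = 2)
  same <- reaction_field_energy(ion, d_in = 2.25, d_solv = 2.2500001,
                                rho = 1, grid = grid)
  expect_lt(abs(as.numeric(same)), 0.05)
})

test_that("reaction field is quadratic in charge scaling", {
  grid <- grid_spec(spacing = 0.6, padding = 4 * 0.6)
  ion <- point_system(rbind(c(0, 0, 0)), charge = 0.5, radius = 1.8)
  e1 <- as.numeric(reaction_field_energy(ion, rho = 1, grid = grid))
  ion$atoms$charge <- 1.0
  e2 <- as.numeric(reaction_field_energy(ion, rho = 1, grid = grid))
  expect_equal(e2 / e1, 4, tolerance = 1e-3)
})

test_that("grid solve tracks the two-term Kirkwood expansion for an off-center dipole", {
  # big neutral sphere defines the cavity; two charges sit well inside it
  xyz <- rbind(c(0, 0, 0), c(0.6, 0, 0), c(-0.6, 0, 0))
  sys <- point_system(xyz, charge = c(0, 1, -0.3), radius = 0.3)
  sys$atoms$boundary_radius <- c(2.0, 0.3, 0.3)
  grid <- grid_spec(spacing = 0.4, padding = 6)
  num <- as.numeric(reaction_field_energy(sys, d_in = 2.25, d_solv = 78.5,
                                          rho = 1, grid = grid))
  ana <- kirkwood_two_term(c(1, -0.3), xyz[2:3, , drop = FALSE], a = 2.0,
                           d_in = 2.25, d_solv = 78.5)
  expect_equal(num, ana, tolerance = 0.08)
})

test_that("solute translation by a non-lattice offset leaves RF unchanged", {
  grid <- grid_spec(spacing = 0.6, padding = 4 * 0.6)
  ion <- point_system(rbind(c(0, 0, 0)), charge = 1, radius = 1.8)
  e0 <- as.numeric(reaction_field_energy(ion, rho = 1, grid = grid))
  moved <- ion
  moved$atoms$x <- 0.237; moved$atoms$y <- -1.911; moved$atoms$z <- 0.533
  e1 <- as.numeric(reaction_field_energy(moved, rho = 1, grid = grid))
  expect_lt(abs(e1 - e0) / abs(e0), 0.02)
})

test_that("binding reaction-field change vanishes for separated partners and penalizes burial", {
  # separated: charged atom 30 A from a small neutral cluster
  far <- point_system(rbind(c(0, 0, 0), c(2.5, 0, 0), c(30, 0, 0)),
                      charge = c(0, 0, 1), radius = 1.7)
  grid <- grid_spec(spacing = 1.0, padding = 4)
  d_far <- delta_reaction_field(far, receptor = 1:2, ligand = 3, grid = grid)
  expect_lt(abs(d_far), 0.5)

  # buried: the same charge enclosed by a neutral cage loses solvation
  cage <- rbind(expand.grid(x = c(-2.6, 2.6), y = c(-2.6, 2.6),
                            z = c(-2.6, 2.6)))
  near <- point_system(rbind(as.matrix(cage), c(0, 0, 0)),
                       charge = c(rep(0, 8), 1), radius = 2.0)
  d_near <- delta_reaction_field(near, receptor = 1:8, ligand = 9,
                                 grid = grid)
  expect_gt(d_near, 0)
})

test_that("solver errors carry diagnostics", {
  ion <- point_system(rbind(c(0, 0, 0)), charge = 1, radius = 1.8)
  tight <- grid_spec(spacing = 0.6, padding = 2.4, max_iterations = 2,
                     tolerance = 1e-12)
  expect_error(reaction_field_energy(ion, rho = 1, grid = tight),
               "did not converge.*residual")
  expect_error(grid_spec(spacing = 0.5, padding = 1), "padding")
})

test_that("surface area matches sphere formulas: single, disjoint, overlapping", {
  one <- point_system(rbind(c(0, 0, 0)), charge = 0, radius = 1.5)
  a1 <- as.numeric(molecular_surface_area(one, probe = 1.4, rho = 1.1,
                                          n_points = 960))
  expect_equal(a1, 4 * pi * (1.5 * 1.1 + 1.4)^2, tolerance = 0.005)

  two_far <- point_system(rbind(c(0, 0, 0), c(100, 0, 0)), charge = c(0, 0),
                          radius = 1.5)
  a2 <- as.numeric(molecular_surface_area(two_far, probe = 1.4, rho = 1.1,
                                          n_points = 960))
  expect_equal(a2, 2 * a1, tolerance = 1e-9)

  # overlapping unit spheres (probe 0, rho 1) vs spherical-cap closed form
  d <- 1.2
  two_near <- point_system(rbind(c(0, 0, 0), c(d, 0, 0)), charge = c(0, 0),
                           radius = 1)
  a3 <- as.numeric(molecular_surface_area(two_near, probe = 0, rho = 1,
                                          n_points = 2000))
  expect_equal(a3, two_sphere_area(1, d), tolerance = 0.01)
})

test_that("surface change on binding is zero when separated, negative on contact", {
  sep <- point_system(rbind(c(0, 0, 0), c(50, 0, 0)), charge = c(0, 0),
                      radius = 1.6)
  expect_equal(delta_msa(sep, 1, 2), 0)
  near <- point_system(rbind(c(0, 0, 0), c(3, 0, 0)), charge = c(0, 0),
                       radius = 1.6)
  expect_lt(delta_msa(near, 1, 2), 0)
})
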
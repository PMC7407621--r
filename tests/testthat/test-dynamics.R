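test_that("restraint layers follow the k*d^2 convention and exact gradients", {
  ref <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(6, 0, 0))  # free, buffer, outer
  rm_ <- restraint_model(ref, center = c(0, 0, 0), sphere_radius = 5,
                         free_fraction = 0.85, buffer_k = 10, outer_k = 200)
  # atom at its reference position: zero energy and force
  r0 <- restraint_energy_forces(ref, rm_)
  expect_equal(r0$energy, 0)
  expect_equal(max(abs(r0$forces)), 0)
  # buffer atom displaced 0.5 A with k = 10 -> 10 * 0.25 = 2.5
  x <- ref; x[2, 2] <- 0.5
  expect_equal(restraint_energy_forces(x, rm_)$energy, 2.5)
  # outer atom displaced 0.1 A with k = 200 -> 2.0
  x <- ref; x[3, 3] <- 0.1
  expect_equal(restraint_energy_forces(x, rm_)$energy, 2.0, tolerance = 1e-12)
  expect_error(restraint_energy_forces(ref[1:2, ], rm_), "differ in length")
})

test_that("restraint forces match finite differences and are conservative", {
  set.seed(21)
  n <- 6
  ref <- matrix(runif(3 * n, -4, 4), n, 3)
  rm_ <- restraint_model(ref, center = c(0, 0, 0), sphere_radius = 4,
                         free_fraction = 0.6, buffer_k = 7, outer_k = 90,
                         wall_k = 12, wall_atoms = 1:n)
  x <- ref + matrix(rnorm(3 * n, 0, 0.8), n, 3)
  out <- restraint_energy_forces(x, rm_)
  h <- 1e-6
  for (i in c(1, 3, n)) for (k in 1:3) {
    xp <- x; xp[i, k] <- xp[i, k] + h
    xm <- x; xm[i, k] <- xm[i, k] - h
    num <- -(restraint_energy_forces(xp, rm_)$energy -
               restraint_energy_forces(xm, rm_)$energy) / (2 * h)
    expect_lt(abs(out$forces[i, k] - num), 1e-5 * max(1, abs(num)))
  }
  # closed-loop work along a random closed path, by fine trapezoidal
  # integration of F . dx, vanishes because the force is a gradient
  t <- seq(0, 2 * pi, length.out = 30001)
  amp <- matrix(rnorm(3 * n, 0, 0.5), n, 3)
  work <- 0
  prev <- NULL
  for (ti in t) {
    xi <- x + amp * sin(ti) + 0.3 * amp * sin(2 * ti)
    Fi <- restraint_energy_forces(xi, rm_)$forces
    if (!is.null(prev))
      work <- work + sum(0.5 * (Fi + prev$F) * (xi - prev$x))
    prev <- list(x = xi, F = Fi)
  }
  expect_lt(abs(work), 1e-6)
})

test_that("default equilibration schedule mirrors the droplet protocol", {
  sch <- build_equilibration_schedule()
  expect_equal(sch[[1]]$target_temperature, 1)
  expect_equal(sch[[1]]$timestep, 0.1)
  expect_equal(sch[[1]]$restraint_k_evb_region, 200)
  n <- length(sch)
  expect_equal(sch[[n - 1]]$restraint_k_evb_region, 0.5, tolerance = 1e-9)
  expect_equal(sch[[n]]$target_temperature, 300)
  ks <- vapply(sch, `[[`, 0, "restraint_k_evb_region")
  expect_true(all(diff(ks) <= 0))
  one <- list(protocol_stage(100))
  expect_identical(build_equilibration_schedule(list(stages = one)), one)
  expect_error(build_equilibration_schedule(list(min_duration = -5)),
               "positive")
})

test_that("propagation is stationary with zero forces and seed-deterministic", {
  # two free particles, no interactions, zero velocities: nothing moves
  s <- evb_state(2, charges = c(0, 0), eps = c(0, 0), sigma = c(1, 1))
  topo <- evb_topology(c("A", "B"), c(10, 10), s, s, h12 = 0)
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  st <- protocol_stage(500, timestep = 1, target_temperature = 0,
                       thermostat = "none")
  tr <- propagate(topo, xyz, 0, st, seed = 1,
                  velocities = matrix(0, 2, 3), sample_every = 100)
  expect_equal(tr$xyz_final, xyz, tolerance = 1e-14, ignore_attr = TRUE)

  # bit-identical trajectories under the same seed, different under another
  sys <- make_toy_reaction_system(toy_system_spec(n_bath_particles = 4, seed = 2))
  st <- protocol_stage(300, target_temperature = 300, thermostat = "langevin")
  t1 <- propagate(sys$topology, sys$conformation, 0.5, st, seed = 42,
                  restraint = sys$restraint)
  t2 <- propagate(sys$topology, sys$conformation, 0.5, st, seed = 42,
                  restraint = sys$restraint)
  t3 <- propagate(sys$topology, sys$conformation, 0.5, st, seed = 43,
                  restraint = sys$restraint)
  expect_identical(t1$coords, t2$coords)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("unthermostatted harmonic dimer conserves total energy", {
  s <- evb_state(2, bonds = data.frame(i = 1, j = 2, form = "harmonic",
                                       k = 5, r0 = 1.5, D = NA, a = NA),
                 charges = c(0, 0), eps = c(0, 0), sigma = c(1, 1))
  topo <- evb_topology(c("A", "B"), c(10, 10), s, s, h12 = 0)
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0))  # stretched 0.3 A
  st <- protocol_stage(10000, timestep = 0.5, target_temperature = 0,
                       thermostat = "none")
  tr <- propagate(topo, xyz, 0, st, velocities = matrix(0, 2, 3),
                  sample_every = 20)
  etot <- tr$epot + tr$kinetic
  expect_lt(max(etot) - min(etot), 1e-3)
})

test_that("Langevin sampling satisfies equipartition on an LJ droplet", {
  n <- 20
  set.seed(31)
  s <- evb_state(n, charges = rep(0, n), eps = rep(0.15, n),
                 sigma = rep(3.1, n))
  topo <- evb_topology(paste0("W", 1:n), rep(18, n), s, s, h12 = 0)
  xyz <- random_conformation(n, seed = 8, spread = 5)
  rm_ <- restraint_model(xyz, center = c(0, 0, 0), sphere_radius = 7,
                         free_fraction = 0.99, buffer_k = 0, outer_k = 0,
                         wall_k = 10, wall_atoms = 1:n)
  st <- protocol_stage(60000, timestep = 1, target_temperature = 300,
                       thermostat = "langevin", friction = 0.02)
  tr <- propagate(topo, xyz, 0, st, seed = 77, restraint = rm_,
                  sample_every = 20, burn_in = 10000)
  kT <- physical_constants$kB_kcal * 300
  ke_per_dof <- mean(tr$kinetic) / tr$ndof
  expect_lt(abs(ke_per_dof - kT / 2) / (kT / 2), 0.05)
})

test_that("integration blow-ups raise an integration error", {
  # absurd timestep on a stiff harmonic bond diverges to overflow
  s <- evb_state(2, bonds = data.frame(i = 1, j = 2, form = "harmonic",
                                       k = 100, r0 = 1, D = NA, a = NA),
                 charges = c(0, 0), eps = c(0, 0), sigma = c(1, 1))
  topo <- evb_topology(c("A", "B"), c(1, 1), s, s, h12 = 0)
  st <- protocol_stage(2e5, timestep = 40, target_temperature = 300,
                       thermostat = "none")
  expect_error(propagate(topo, rbind(c(0, 0, 0), c(2.5, 0, 0)), 0, st,
                         seed = 1), "integration error")
})
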
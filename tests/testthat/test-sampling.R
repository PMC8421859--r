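test_that("the umbrella grid is an inclusive arithmetic sequence", {
  w <- make_windows(13, 26, 0.25)
  expect_equal(nrow(w), 53)
  expect_equal(w$index, 0:52)
  expect_equal(w$rg0[1], 13)
  expect_equal(w$rg0[53], 26)
  expect_equal(window_frame_count(w), 10000)

  expect_equal(nrow(make_windows(13, 13, 0.25)), 1)
  w3 <- make_windows(0, 1, 0.5)
  expect_equal(w3$rg0, c(0, 0.5, 1))
  expect_error(make_windows(13, 26, 0), "positive")
  expect_error(make_windows(26, 13, 0.25), "exceed")
})

test_that("initial velocities follow the Maxwell-Boltzmann statistics", {
  ch <- two_bead_chain(mass = 50)
  expect_true(all(init_velocities(ch, 0) == 0))
  expect_error(init_velocities(ch, -1), "non-negative")

  set.seed(99)
  kBT <- 0.0019872041 * 300 * 4.184e-4
  draws <- replicate(1e5, sum(rnorm(3, sd = sqrt(kBT / 50))^2))
  # oracle: mean squared speed over many draws approaches 3 kBT / m
  expect_equal(mean(draws), 3 * kBT / 50, tolerance = 0.02)
  # the implementation draws from the same law
  v <- init_velocities(ch, 300, seed = 1)
  v2 <- init_velocities(ch, 300, seed = 1)
  expect_identical(v, v2)
  big <- init_velocities(helix_chain(60), 300, seed = 2)
  m <- build_cg_from_pdb(make_ideal_helix(60))$masses
  expect_equal(mean(rowSums(big^2) * m) / (3 * 0.0019872041 * 300 * 4.184e-4),
               1, tolerance = 0.15)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  ch <- helix_chain(6)
  ff <- default_forcefield()
  cfg <- integrator_config(seed = 11)
  t1 <- run_md(ch, ff, cfg, nsteps = 500, record_every = 50)
  t2 <- run_md(ch, ff, cfg, nsteps = 500, record_every = 50)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$final_coords, t2$final_coords)
  t3 <- run_md(ch, ff, integrator_config(seed = 12), nsteps = 500,
               record_every = 50)
  expect_false(identical(t1$final_coords, t3$final_coords))
})

test_that("with zero friction the integrator conserves energy (NVE)", {
  ch <- two_bead_chain()
  cfg <- integrator_config(friction = 0, seed = 8)
  v0 <- init_velocities(ch, 300, seed = 8)
  tr <- run_md(ch, harmonic_pair_ff(), cfg, nsteps = 20000, record_every = 100,
               velocities = v0)
  etot <- tr$series$epot + tr$series$ekin
  expect_lt((max(etot) - min(etot)) / 20000, 1e-4)
})

test_that("zero-temperature dynamics at a minimum stays put", {
  ch <- two_bead_chain(r = 4)
  cfg <- integrator_config(temperature = 1e-12, friction = 0, seed = 1)
  v0 <- matrix(0, 2, 3)
  tr <- run_md(ch, harmonic_pair_ff(r0 = 4), cfg, nsteps = 1000,
               record_every = 100, velocities = v0)
  expect_equal(tr$final_coords, ch$coords, tolerance = 1e-10)
})

test_that("a thermostatted harmonic pair satisfies equipartition", {
  ch <- two_bead_chain(r = 4, mass = 100)
  k <- 20
  cfg <- integrator_config(timestep = 2, temperature = 300, friction = 0.02,
                           seed = 4)
  tr <- run_md(ch, harmonic_pair_ff(k = k, r0 = 4), cfg, nsteps = 3e5,
               record_every = 10)
  r <- 2 * tr$series$rg                      # bond length of the symmetric pair
  keep <- tr$series$step > 2e4               # discard equilibration
  kBT <- 0.0019872041 * 300
  expect_equal(stats::var(r[keep]), kBT / k, tolerance = 0.05)
  expect_equal(mean(tr$series$temp_inst[keep]), 300, tolerance = 0.03)
})

test_that("the kinetic temperature of a 10-bead chain tracks the thermostat", {
  ch <- build_cg_from_pdb(make_ideal_helix(10, "ADKLGEMRFV"))
  ch <- assign_default_charges(ch)
  ff <- default_forcefield()
  cfg <- integrator_config(temperature = 300, friction = 0.02, seed = 5)
  tr <- run_md(ch, ff, cfg, nsteps = 6e4, record_every = 20)
  keep <- tr$series$step > 1e4
  expect_equal(mean(tr$series$temp_inst[keep]), 300, tolerance = 0.03)
})

test_that("an Rg restraint keeps the reaction coordinate near its target", {
  ch <- assign_default_charges(helix_chain(12))
  ff <- default_forcefield()
  rg_start <- rg_chain(ch)
  rg0 <- rg_start + 1
  k <- 50
  restr <- list(list(type = "rg", bead_idx = ch$ca_idx,
                     masses = ch$masses[ch$ca_idx], k = k, rg0 = rg0))
  cfg <- integrator_config(temperature = 300, friction = 0.02, seed = 6)
  tr <- run_md(ch, ff, cfg, nsteps = 5e4, restraints = restr,
               record_every = 50)
  keep <- tr$series$step > 1e4
  sigma <- sqrt(0.0019872041 * 300 / k)
  # the unrestrained PMF tilts the window mean, but never beyond ~3 sigma
  expect_lt(abs(mean(tr$series$rg[keep]) - rg0), 3 * sigma)
})

test_that("the Rg-bias gradient matches finite differences", {
  ch <- helix_chain(8)
  idx <- ch$ca_idx
  m <- ch$masses[idx]
  efun <- function(x) {
    r <- cgcam:::rg_bias_cpp(x, as.integer(idx), m, 50, 10)
    list(energy = r$energy, forces = r$forces)
  }
  set.seed(17)
  x0 <- ch$coords + matrix(rnorm(length(ch$coords), sd = 0.2), ncol = 3)
  expect_lt(force_fd_error(efun, x0), 1e-5)
})

test_that("annealing follows the schedule and reduces to constant T when flat", {
  ch <- assign_default_charges(helix_chain(8))
  ff <- default_forcefield()
  sched <- anneal_schedule(450, 280, 2000)
  tr <- simulated_annealing(ch, sched, ff, integrator_config(seed = 3),
                            record_every = 200)
  expect_equal(tr$series$temperature[1], 450 - (450 - 280) * 0.1)
  expect_equal(tr$series$temperature[10], 280)
  expect_false(any(is.na(tr$series$qw)))
  expect_true(all(tr$series$qw > 0 & tr$series$qw <= 1.0001))

  flat <- anneal_schedule(300, 300, 1000)
  ta <- simulated_annealing(ch, flat, ff, integrator_config(seed = 9),
                            record_every = 100)
  tc <- run_md(ch, ff, integrator_config(seed = 9), nsteps = 1000,
               record_every = 100, reference = ch)
  expect_equal(ta$series$rg, tc$series$rg)

  expect_error(anneal_schedule(280, 450), "cool")
  # different seeds diverge
  tb <- simulated_annealing(ch, flat, ff, integrator_config(seed = 10),
                            record_every = 100)
  expect_false(identical(ta$series$rg, tb$series$rg))
})

test_that("slow cooling drives a two-bead system into its energy minimum", {
  ch <- two_bead_chain(r = 5.5, mass = 50)
  sched <- anneal_schedule(200, 1, 20000)
  tr <- simulated_annealing(ch, sched, harmonic_pair_ff(k = 10, r0 = 4),
                            integrator_config(friction = 0.05, seed = 2),
                            reference = NULL, record_every = 1000)
  r_final <- sqrt(sum((tr$final_coords[2, ] - tr$final_coords[1, ])^2))
  expect_equal(r_final, 4, tolerance = 0.05)
})

test_that("window seeding picks the closest frame with earliest-frame ties", {
  ch <- helix_chain(6)
  traj <- structure(list(
    series = data.frame(step = c(1000, 2000, 3000), rg = c(14, 18, 22)),
    frames = list(matrix(1, 2, 3), matrix(2, 2, 3), matrix(3, 2, 3))),
    class = "cgcam_trajectory")
  w <- make_windows(13, 26, 0.25)
  sel <- select_window_seeds(traj, data.frame(index = 0, rg0 = 17.9))
  expect_equal(sel$info$rg, 18)
  # exact tie at 16: frames at 14 and 18 are equidistant; earliest wins
  sel2 <- select_window_seeds(traj, data.frame(index = 0, rg0 = 16))
  expect_equal(sel2$info$frame, 1)
  # total over all windows
  sel3 <- select_window_seeds(traj, w)
  expect_equal(nrow(sel3$info), 53)
  expect_true(all(sel3$info$frame %in% 1:3))
  empty <- structure(list(series = data.frame(), frames = list()),
                     class = "cgcam_trajectory")
  expect_error(select_window_seeds(empty, w), "no recorded frames")
})

test_that("umbrella samples carry the window metadata and replica seeds differ", {
  ch <- assign_default_charges(helix_chain(8))
  ff <- default_forcefield()
  w <- make_windows(9, 9.5, 0.5, k = 20, steps = 400, replicas = 2,
                    record_every = 100)
  us <- run_umbrella(ch, ff, w, integrator_config(seed = 100))
  expect_equal(nrow(us$samples), 2 * 2 * 4)
  expect_setequal(unique(us$samples$rg0), c(9, 9.5))
  s1 <- us$samples$rg[us$samples$window == 0 & us$samples$replica == 1]
  s2 <- us$samples$rg[us$samples$window == 0 & us$samples$replica == 2]
  expect_false(identical(s1, s2))
})

test_that("divergent dynamics abort with a diagnostic", {
  ch <- two_bead_chain(r = 4)
  bad_ff <- function(x) list(energy = NaN, forces = matrix(NaN, 2, 3))
  expect_error(run_md(ch, bad_ff, integrator_config(seed = 1), nsteps = 10,
                      record_every = 10), "non-finite")
})
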
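#' Umbrella-window grid along the radius of gyration
#'
#' Inclusive arithmetic grid of restraint centers. The production protocol
#' (13.00-26.00 A at 0.25 A spacing) yields 53 windows; with 5 replicas of
#' 2,000,000 steps recorded every 1,000 steps, each window accumulates
#' 10,000 frames.
#'
#' @param rg_min,rg_max grid end points (A)
#' @param spacing grid spacing (A, > 0)
#' @param k restraint force constant (kcal/mol/A^2)
#' @param steps steps per replica
#' @param replicas independent replicas per window
#' @param record_every recording interval (steps)
#' @return a `cgcam_windows` data.frame with columns `index` (0-based),
#'   `rg0`, `k`, `steps`, `replicas`, `record_every`
#' @export
make_windows <- function(rg_min = 13, rg_max = 26, spacing = 0.25, k = 50,
                         steps = 2e6, replicas = 5, record_every = 1000) {
  if (spacing <= 0) stop("window spacing must be positive")
  if (rg_min > rg_max) stop("rg_min must not exceed rg_max")
  if (k <= 0) stop("restraint force constant must be positive")
  rg0 <- seq(rg_min, rg_max, by = spacing)
  structure(data.frame(index = seq_along(rg0) - 1L, rg0 = rg0, k = k,
                       steps = steps, replicas = replicas,
                       record_every = record_every),
            class = c("cgcam_windows", "data.frame"))
}

#' Frames accumulated per window
#'
#' @param windows a [make_windows()] grid
#' @return frames per window (replicas x steps / record interval)
#' @export
window_frame_count <- function(windows) {
  with(windows[1, ], replicas * steps / record_every)
}

#' Integrator configuration
#'
#' @param timestep integration step (fs); the coarse-grained potential is
#'   smooth, so a step maps to more physical time than its nominal value
#' @param temperature thermostat target (K)
#' @param friction Langevin friction (1/fs)
#' @param seed RNG seed (same seed, same trajectory)
#' @param box cubic box edge (A)
#' @param periodic minimum-image convention for nonbonded terms
#' @return an `integrator_config`
#' @export
integrator_config <- function(timestep = 2, temperature = 300,
                              friction = 0.005, seed = 1, box = 400,
                              periodic = TRUE) {
  if (timestep <= 0) stop("timestep must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (friction < 0) stop("friction must be non-negative")
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, seed = seed, box = box,
                 periodic = periodic),
            class = "integrator_config")
}

#' Draw Maxwell-Boltzmann initial velocities
#'
#' Each velocity component is Gaussian with variance `kB T / m`, so the
#' average squared speed per bead is `3 kB T / m`. At `T -> 0` all
#' velocities vanish.
#'
#' @param chain a `cg_chain`
#' @param temperature temperature (K, >= 0)
#' @param seed optional RNG seed
#' @return n_beads x 3 velocity matrix (A/fs)
#' @export
init_velocities <- function(chain, temperature, seed = NULL) {
  if (temperature < 0) stop("temperature must be non-negative")
  if (any(chain$masses <= 0)) stop("bead masses must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(chain$coords)
  sdv <- sqrt(.kB * temperature * .kcal2akma / chain$masses)
  matrix(rnorm(3 * n), n, 3) * sdv
}

.kinetic_energy <- function(v, m) {
  0.5 * sum(m * rowSums(v^2)) / .kcal2akma     # kcal/mol
}

#' Instantaneous kinetic temperature
#' @param v velocity matrix (A/fs)
#' @param m bead masses (amu)
#' @return temperature (K)
#' @export
kinetic_temperature <- function(v, m) {
  2 * .kinetic_energy(v, m) / (3 * length(m) * .kB)
}

# evaluate restraints: list of rg-bias specs; returns energy + forces
.eval_restraints <- function(coords, restraints) {
  e <- 0
  f <- NULL
  for (r in restraints) {
    if (!identical(r$type, "rg")) stop("unknown restraint type: ", r$type)
    b <- rg_bias_cpp(coords, as.integer(r$bead_idx), as.numeric(r$masses),
                     r$k, r$rg0)
    e <- e + b$energy
    f <- if (is.null(f)) b$forces else f + b$forces
  }
  list(energy = e, forces = f)
}

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration in the NVT ensemble (with zero friction
#' it reduces to velocity Verlet, i.e. NVE). The force field may be a
#' `cg_forcefield` (compiled kernels) or any function
#' `f(coords) -> list(energy, forces)` for toy systems. Optional harmonic
#' radius-of-gyration restraints are added with their analytic gradient at
#' every step. Trajectories are reproducible bit-for-bit for a given seed.
#'
#' @param chain a `cg_chain`
#' @param forcefield a `cg_forcefield` or an energy/force function
#' @param config an [integrator_config()]
#' @param nsteps number of steps
#' @param restraints list of restraint specs
#'   (`list(type = "rg", bead_idx, masses, k, rg0)`); the chain's own
#'   `$restraints` (e.g. from calcium approach II) are appended automatically
#' @param record_every recording interval (steps)
#' @param record_coords keep frame coordinates (needed for window seeding)
#' @param velocities initial velocities; drawn from Maxwell-Boltzmann at the
#'   target temperature when `NULL`
#' @param temperature_schedule optional function `step -> temperature`
#'   overriding the constant target (used by simulated annealing)
#' @param reference optional reference `cg_chain`: per-frame Qw is recorded
#' @return a `cgcam_trajectory`: `series` data.frame (step, time_fs,
#'   temperature, epot, erestr, ekin, temp_inst, rg, qw) and `frames`
#' @export
run_md <- function(chain, forcefield, config = integrator_config(),
                   nsteps = 10000, restraints = list(), record_every = 1000,
                   record_coords = FALSE, velocities = NULL,
                   temperature_schedule = NULL, reference = NULL) {
  stopifnot(inherits(chain, "cg_chain"))
  if (nsteps < 1) stop("nsteps must be positive")
  restraints <- c(restraints, chain$restraints)
  if (inherits(forcefield, "cg_forcefield")) {
    spec <- ff_spec(chain, forcefield)
    evalf <- function(x) ff_eval_cpp(x, spec)
  } else if (is.function(forcefield)) {
    evalf <- forcefield
  } else stop("forcefield must be a cg_forcefield or a function")

  if (!is.null(config$seed)) set.seed(config$seed)
  m <- chain$masses
  dt <- config$timestep
  gam <- config$friction
  c1 <- exp(-gam * dt)
  x <- chain$coords
  temp_at <- if (is.null(temperature_schedule)) {
    function(step) config$temperature
  } else temperature_schedule
  v <- if (is.null(velocities)) init_velocities(chain, temp_at(0)) else
    velocities
  inv_m <- .kcal2akma / m
  ref_ca <- if (!is.null(reference)) {
    reference$coords[reference$ca_idx, , drop = FALSE]
  } else NULL

  ev <- evalf(x)
  rs <- .eval_restraints(x, restraints)
  f <- ev$forces
  if (!is.null(rs$forces)) f <- f + rs$forces

  nrec <- floor(nsteps / record_every)
  series <- data.frame(step = integer(nrec), time_fs = numeric(nrec),
                       temperature = numeric(nrec), epot = numeric(nrec),
                       erestr = numeric(nrec), ekin = numeric(nrec),
                       temp_inst = numeric(nrec), rg = numeric(nrec),
                       qw = rep(NA_real_, nrec))
  frames <- if (record_coords) vector("list", nrec) else NULL
  irec <- 0L
  nb <- nrow(x)

  for (step in seq_len(nsteps)) {
    Tt <- temp_at(step)
    a <- f * inv_m
    v <- v + (0.5 * dt) * a
    x <- x + (0.5 * dt) * v
    if (gam > 0) {
      sdv <- sqrt((1 - c1^2) * .kB * Tt * .kcal2akma / m)
      v <- c1 * v + matrix(rnorm(3 * nb), nb, 3) * sdv
    }
    x <- x + (0.5 * dt) * v
    ev <- evalf(x)
    rs <- .eval_restraints(x, restraints)
    f <- ev$forces
    if (!is.null(rs$forces)) f <- f + rs$forces
    if (!all(is.finite(f)) || !is.finite(ev$energy)) {
      dump <- tempfile(pattern = "cgcam-diverged-", fileext = ".rds")
      saveRDS(list(step = step, coords = x, velocities = v), dump)
      stop("non-finite energy or force at step ", step,
           "; diagnostic frame written to ", dump)
    }
    v <- v + (0.5 * dt) * (f * inv_m)
    if (step %% record_every == 0L) {
      irec <- irec + 1L
      ca <- x[chain$ca_idx, , drop = FALSE]
      series$step[irec] <- step
      series$time_fs[irec] <- step * dt
      series$temperature[irec] <- Tt
      series$epot[irec] <- ev$energy
      series$erestr[irec] <- rs$energy
      series$ekin[irec] <- .kinetic_energy(v, m)
      series$temp_inst[irec] <- kinetic_temperature(v, m)
      series$rg[irec] <- radius_of_gyration(ca, chain$masses[chain$ca_idx])
      if (!is.null(ref_ca)) series$qw[irec] <- qw(ca, ref_ca)
      if (record_coords) frames[[irec]] <- x
    }
  }
  structure(list(series = series, frames = frames, final_coords = x,
                 final_velocities = v, config = config, nsteps = nsteps),
            class = "cgcam_trajectory")
}

#' Annealing schedule
#'
#' @param t_start,t_end start and end temperatures (K, start > end)
#' @param steps total steps
#' @param profile cooling profile (only `"linear"` implemented)
#' @return an `anneal_schedule`
#' @export
anneal_schedule <- function(t_start = 450, t_end = 280, steps = 2e6,
                            profile = "linear") {
  if (t_start < t_end) stop("annealing must cool: t_start >= t_end")
  if (steps <= 0) stop("steps must be positive")
  profile <- match.arg(profile, "linear")
  structure(list(t_start = t_start, t_end = t_end, steps = steps,
                 profile = profile), class = "anneal_schedule")
}

#' Simulated annealing
#'
#' Cools the system from the schedule's start temperature (default 450 K, a
#' denatured state) to its end temperature (280 K) with a linear profile
#' while recording per-frame Qw against the reference structure.
#'
#' @param chain a `cg_chain`
#' @param schedule an [anneal_schedule()]
#' @param forcefield a `cg_forcefield` or function
#' @param config an [integrator_config()]
#' @param reference reference chain for Qw (default: the starting chain)
#' @param ... passed to [run_md()]
#' @return a `cgcam_trajectory`
#' @export
simulated_annealing <- function(chain, schedule = anneal_schedule(),
                                forcefield, config = integrator_config(),
                                reference = chain, ...) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  sched <- function(step) {
    frac <- min(1, step / schedule$steps)
    schedule$t_start + (schedule$t_end - schedule$t_start) * frac
  }
  config$temperature <- schedule$t_start
  run_md(chain, forcefield, config, nsteps = schedule$steps,
         temperature_schedule = sched, reference = reference, ...)
}

#' Select initial structures for umbrella windows
#'
#' For each window, the recorded frame whose Rg is closest to the window's
#' equilibrium value; exact ties go to the earliest frame.
#'
#' @param traj a `cgcam_trajectory` run with `record_coords = TRUE`
#' @param windows a [make_windows()] grid
#' @return list with `frames` (one coordinate matrix per window) and `info`
#'   (window, rg0, chosen frame, its rg)
#' @export
select_window_seeds <- function(traj, windows) {
  stopifnot(inherits(traj, "cgcam_trajectory"))
  if (is.null(traj$frames) || length(traj$frames) == 0 ||
      nrow(traj$series) == 0)
    stop("trajectory has no recorded frames")
  rg <- traj$series$rg
  sel <- vapply(windows$rg0, function(r0) which.min(abs(rg - r0)), integer(1))
  list(frames = traj$frames[sel],
       info = data.frame(window = windows$index, rg0 = windows$rg0,
                         frame = sel, rg = rg[sel]))
}

#' Run Rg-restrained umbrella sampling
#'
#' Independent replicas per window share the window's initial structure and
#' differ in their velocity seeds; seeds are derived deterministically from
#' the master seed and the (window, replica) index. The restraint acts on
#' the mass-weighted radius of gyration of the Calpha beads.
#'
#' @param chain a `cg_chain`
#' @param forcefield a `cg_forcefield` or function
#' @param windows a [make_windows()] grid
#' @param config an [integrator_config()]; its seed is the master seed
#' @param seeds optional [select_window_seeds()] result giving per-window
#'   initial coordinates (default: the chain's own coordinates)
#' @param progress print per-window progress
#' @return a `cgcam_umbrella`: `samples` data.frame (window, rg0, k, replica,
#'   step, rg, epot) directly consumable by [estimate_pmf()]
#' @export
run_umbrella <- function(chain, forcefield, windows = make_windows(),
                         config = integrator_config(), seeds = NULL,
                         progress = FALSE) {
  stopifnot(inherits(chain, "cg_chain"))
  master <- config$seed
  out <- vector("list", nrow(windows) * windows$replicas[1])
  z <- 0L
  for (w in seq_len(nrow(windows))) {
    wrow <- windows[w, ]
    ch <- chain
    if (!is.null(seeds)) ch$coords <- seeds$frames[[w]]
    restr <- list(list(type = "rg", bead_idx = ch$ca_idx,
                       masses = ch$masses[ch$ca_idx], k = wrow$k,
                       rg0 = wrow$rg0))
    for (r in seq_len(wrow$replicas)) {
      cfg <- config
      cfg$seed <- master + 7919L * wrow$index + r
      tr <- run_md(ch, forcefield, cfg, nsteps = wrow$steps,
                   restraints = restr, record_every = wrow$record_every)
      z <- z + 1L
      out[[z]] <- data.frame(window = wrow$index, rg0 = wrow$rg0, k = wrow$k,
                             replica = r, step = tr$series$step,
                             rg = tr$series$rg, epot = tr$series$epot)
    }
    if (progress)
      message(sprintf("window %d/%d (rg0 = %.2f) done", w, nrow(windows),
                      wrow$rg0))
  }
  structure(list(samples = do.call(rbind, out), windows = windows,
                 config = config), class = "cgcam_umbrella")
}
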
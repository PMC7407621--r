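#' Layered positional-restraint droplet model
#'
#' Emulates a restrained spherical solvent droplet: atoms whose reference
#' position lies in the inner \code{free_fraction} of the sphere move freely,
#' atoms in the outer shell are held by a \code{buffer_k} harmonic positional
#' restraint, and atoms outside the sphere by a stiff \code{outer_k} restraint.
#' A half-harmonic radial wall at the droplet surface keeps the listed bath
#' atoms from evaporating. The restraint energy convention is \code{k * d^2},
#' so quoted force constants in kcal/mol/A^2 apply verbatim.
#'
#' @param reference_coordinates n x 3 matrix of reference positions (A).
#' @param center sphere center (length-3, A).
#' @param sphere_radius droplet radius (A).
#' @param free_fraction fraction of the radius that is unrestrained (default 0.85).
#' @param buffer_k,outer_k layer force constants (kcal/mol/A^2; defaults 10, 200).
#' @param wall_k radial wall constant for bath atoms (kcal/mol/A^2).
#' @param wall_atoms indices subject to the radial wall (default none).
#' @param k_atom optional per-atom additional positional restraint constants
#'   (length n), used for the equilibration-schedule restraints on the
#'   reactive region.
#' @return Object of class \code{restraint_model}.
#' @export
restraint_model <- function(reference_coordinates, center = c(0, 0, 0),
                            sphere_radius, free_fraction = 0.85,
                            buffer_k = 10, outer_k = 200,
                            wall_k = 10, wall_atoms = integer(0),
                            k_atom = NULL) {
  ref <- as.matrix(reference_coordinates)
  stopifnot(ncol(ref) == 3, sphere_radius > 0,
            free_fraction > 0, free_fraction < 1,
            buffer_k >= 0, outer_k >= 0, wall_k >= 0)
  if (!is.null(k_atom) && length(k_atom) != nrow(ref))
    stop("k_atom must have one entry per atom")
  structure(list(reference = ref, center = as.numeric(center),
                 radius = sphere_radius, free_fraction = free_fraction,
                 buffer_k = buffer_k, outer_k = outer_k,
                 wall_k = wall_k, wall_atoms = as.integer(wall_atoms),
                 k_atom = if (is.null(k_atom)) numeric(0) else as.numeric(k_atom)),
            class = "restraint_model")
}

restraint_clist <- function(r) {
  list(reference = r$reference, center = r$center, radius = r$radius,
       free_fraction = r$free_fraction, buffer_k = r$buffer_k,
       outer_k = r$outer_k, wall_k = r$wall_k, wall_atoms = r$wall_atoms,
       k_atom = r$k_atom)
}

#' Restraint energy and forces
#'
#' @param conformation n x 3 coordinate matrix (A).
#' @param restraint a \code{\link{restraint_model}}.
#' @return list with \code{energy} (kcal/mol) and \code{forces}
#'   (n x 3, kcal/mol/A; the exact negative gradient).
#' @export
restraint_energy_forces <- function(conformation, restraint) {
  xyz <- as.matrix(conformation)
  if (nrow(xyz) != nrow(restraint$reference))
    stop("conformation and reference coordinates differ in length")
  cpp_restraint(xyz, restraint_clist(restraint))
}

#' A single dynamics protocol stage
#'
#' @param duration stage length (fs, > 0).
#' @param timestep integration timestep (fs, > 0).
#' @param target_temperature thermostat target (K, >= 0).
#' @param restraint_k_evb_region positional restraint on reactive-region
#'   atoms during this stage (kcal/mol/A^2).
#' @param thermostat \code{"langevin"} (default), \code{"berendsen"}, or
#'   \code{"none"}.
#' @param friction Langevin friction (1/fs).
#' @param coupling_time Berendsen coupling time (fs).
#' @param seed optional integer RNG seed for the stage.
#' @return Object of class \code{protocol_stage}.
#' @export
protocol_stage <- function(duration, timestep = 1, target_temperature = 300,
                           restraint_k_evb_region = 0,
                           thermostat = c("langevin", "berendsen", "none"),
                           friction = 0.01, coupling_time = 100, seed = NULL) {
  thermostat <- match.arg(thermostat)
  if (duration <= 0) stop("stage duration must be positive")
  if (timestep <= 0) stop("stage timestep must be positive")
  if (target_temperature < 0) stop("stage temperature must be non-negative")
  structure(list(duration = duration, timestep = timestep,
                 target_temperature = target_temperature,
                 restraint_k_evb_region = restraint_k_evb_region,
                 thermostat = thermostat, friction = friction,
                 coupling_time = coupling_time, seed = seed),
            class = "protocol_stage")
}

#' Build the droplet equilibration schedule
#'
#' The default mirrors the simulation protocol the package emulates: a long
#' low-temperature minimization-like stage (1 K, 0.1 fs steps, 200
#' kcal/mol/A^2 positional restraints), a series of heating stages ramping
#' the temperature to 300 K while decaying the reactive-region restraint
#' from 200 to 0.5 kcal/mol/A^2, and a final unrestrained production-ready
#' stage at 300 K. Durations default to desk-scale values and are fully
#' configurable.
#'
#' @param config optional list overriding defaults: \code{min_duration},
#'   \code{ramp_stages}, \code{ramp_duration}, \code{production_duration},
#'   \code{final_temperature}, \code{timestep}, \code{thermostat},
#'   \code{stages} (a list of \code{\link{protocol_stage}}s returned as-is).
#' @return list of \code{\link{protocol_stage}} objects.
#' @export
build_equilibration_schedule <- function(config = list()) {
  if (!is.null(config$stages)) {
    stopifnot(all(vapply(config$stages, inherits, TRUE, "protocol_stage")))
    return(config$stages)
  }
  getd <- function(nm, d) if (is.null(config[[nm]])) d else config[[nm]]
  min_dur  <- getd("min_duration", 300)
  n_ramp   <- getd("ramp_stages", 5)
  ramp_dur <- getd("ramp_duration", 200)
  prod_dur <- getd("production_duration", 500)
  t_final  <- getd("final_temperature", 300)
  dt       <- getd("timestep", 1)
  thermo   <- getd("thermostat", "langevin")
  if (min_dur <= 0 || ramp_dur <= 0 || prod_dur <= 0)
    stop("stage durations must be positive")
  if (t_final < 0) stop("final temperature must be non-negative")
  stages <- list(protocol_stage(min_dur, timestep = 0.1,
                                target_temperature = 1,
                                restraint_k_evb_region = 200,
                                thermostat = thermo))
  temps <- seq(1, t_final, length.out = n_ramp + 1)[-1]
  # geometric restraint decay 200 -> 0.5 across the ramp
  ks <- exp(seq(log(200), log(0.5), length.out = n_ramp + 1))[-1]
  for (s in seq_len(n_ramp)) {
    stages[[length(stages) + 1L]] <-
      protocol_stage(ramp_dur, timestep = dt, target_temperature = temps[s],
                     restraint_k_evb_region = ks[s], thermostat = thermo)
  }
  stages[[length(stages) + 1L]] <-
    protocol_stage(prod_dur, timestep = dt, target_temperature = t_final,
                   restraint_k_evb_region = 0, thermostat = thermo)
  stages
}

thermostat_code <- function(stage) {
  switch(stage$thermostat, none = 0L, langevin = 1L, berendsen = 2L)
}

#' Propagate the system on an EVB surface
#'
#' Integrates the equations of motion with a velocity-Verlet (leapfrog
#' equivalent) scheme on either a mapping potential (a fixed lambda blend of
#' the diabatic surfaces) or the adiabatic ground surface, with a Langevin
#' (BAOAB) or Berendsen thermostat. Identical seeds reproduce trajectories
#' bit-for-bit.
#'
#' @param topology an \code{\link{evb_topology}}.
#' @param conformation starting n x 3 coordinates (A).
#' @param potential_spec a lambda in [0,1] (mapping surface) or
#'   \code{"ground"}.
#' @param stage a \code{\link{protocol_stage}}.
#' @param seed integer RNG seed (overrides \code{stage$seed}).
#' @param restraint optional \code{\link{restraint_model}}; the stage's
#'   reactive-region restraint constant is layered on top of it.
#' @param velocities optional starting velocities (A/fs); default drawn from
#'   the Maxwell-Boltzmann distribution at the stage temperature.
#' @param frozen_atoms indices never integrated (held fixed).
#' @param sample_every sampling stride in steps.
#' @param burn_in number of initial steps discarded from sampling.
#' @return list of class \code{evb_trajectory}: \code{coords}
#'   (nsamples x 3n), energy series \code{e1, e2, e_ground, e_map, epot,
#'   kinetic, gap}, \code{xyz_final}, \code{vel_final}, \code{ndof},
#'   \code{lambda}.
#' @export
propagate <- function(topology, conformation, potential_spec, stage,
                      seed = NULL, restraint = NULL, velocities = NULL,
                      frozen_atoms = integer(0), sample_every = 10,
                      burn_in = 0) {
  xyz <- check_conformation(topology, conformation)
  stopifnot(inherits(stage, "protocol_stage"))
  surface <- if (identical(potential_spec, "ground")) -1 else {
    if (!is.numeric(potential_spec) || potential_spec < 0 || potential_spec > 1)
      stop("potential_spec must be 'ground' or a lambda in [0,1]")
    potential_spec
  }
  if (is.null(seed)) seed <- stage$seed
  if (!is.null(seed)) set.seed(seed)
  n <- topology$n_atoms
  if (is.null(velocities)) {
    sv <- sqrt(physical_constants$kB_kcal * stage$target_temperature *
                 4.184e-4 / topology$masses)
    velocities <- matrix(rnorm(3 * n), n, 3) * sv
  }
  # stage restraint on reactive atoms, layered onto any droplet model
  if (stage$restraint_k_evb_region > 0) {
    k_atom <- numeric(n)
    k_atom[topology$evb_region] <- stage$restraint_k_evb_region
    if (is.null(restraint)) {
      restraint <- restraint_model(xyz, center = colMeans(xyz),
                                   sphere_radius = 1e6, free_fraction = 0.99,
                                   buffer_k = 0, outer_k = 0, wall_k = 0,
                                   k_atom = k_atom)
    } else {
      ka <- if (length(restraint$k_atom)) restraint$k_atom else numeric(n)
      restraint$k_atom <- ka + k_atom
    }
  }
  nsteps <- max(1L, as.integer(round(stage$duration / stage$timestep)))
  tparam <- if (stage$thermostat == "langevin") stage$friction else stage$coupling_time
  out <- tryCatch(
    cpp_propagate(xyz, as.matrix(velocities), topology$masses,
                  state_clist(topology$state1), state_clist(topology$state2),
                  topology$h12, surface,
                  if (is.null(restraint)) NULL else restraint_clist(restraint),
                  as.integer(frozen_atoms), nsteps, stage$timestep,
                  stage$target_temperature, thermostat_code(stage), tparam,
                  as.integer(sample_every), as.integer(burn_in)),
    error = function(e) stop("integration error: ", conditionMessage(e),
                             call. = FALSE))
  out$gap <- out$e1 - out$e2
  out$lambda <- if (surface < 0) NA_real_ else surface
  out$timestep <- stage$timestep
  class(out) <- "evb_trajectory"
  out
}

#' Run a full equilibration schedule
#'
#' Applies the stages of \code{\link{build_equilibration_schedule}} in order,
#' carrying coordinates and velocities between stages.
#'
#' @inheritParams propagate
#' @param stages list of \code{\link{protocol_stage}}s.
#' @param seed base seed; stage s uses \code{seed + s}.
#' @return list with \code{xyz}, \code{vel} (final state) and
#'   \code{stage_trajectories}.
#' @export
run_schedule <- function(topology, conformation, stages, seed = 1,
                         restraint = NULL, potential_spec = 0,
                         frozen_atoms = integer(0)) {
  xyz <- check_conformation(topology, conformation)
  vel <- NULL
  trajs <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    tr <- propagate(topology, xyz, potential_spec, stages[[s]],
                    seed = seed + s, restraint = restraint,
                    velocities = vel, frozen_atoms = frozen_atoms,
                    sample_every = 50)
    xyz <- tr$xyz_final
    vel <- tr$vel_final
    trajs[[s]] <- tr
  }
  list(xyz = xyz, vel = vel, stage_trajectories = trajs)
}
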
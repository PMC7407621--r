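#' Specification for a toy proton-transfer system in a droplet
#'
#' Describes a donor-hydrogen-acceptor triad (Morse-bonded proton in each
#' diabatic state) immersed in a small Lennard-Jones bath confined to a
#' spherical droplet by a half-harmonic wall. The product-state shift alpha
#' is calibrated at generation time so a rigid 1D scan of the proton along
#' the donor-acceptor axis has a minimum-energy difference equal to
#' \code{target_dG_rxn}.
#'
#' @param n_bath_particles number of bath particles (default 8).
#' @param droplet_radius droplet radius (A, default 6).
#' @param da_distance donor-acceptor distance (A, default 2.8, inside the
#'   range observed for proton-transfer Michaelis complexes).
#' @param morse_D,morse_a,morse_r0 Morse parameters of the transferable
#'   proton bond (kcal/mol, 1/A, A), identical in both states by default.
#' @param scaffold_k harmonic constant holding the donor-acceptor pair
#'   together (kcal/mol/A^2).
#' @param charges_state1,charges_state2 triad partial charges (D, H, A) in
#'   each state (e).
#' @param target_dG_rxn reaction free energy the 1D scan must reproduce
#'   (kcal/mol).
#' @param coupling_h12 off-diagonal coupling (kcal/mol).
#' @param charged_bath give bath particles alternating +/- 0.2 e charges
#'   (exercises the electrostatic group analysis).
#' @param seed integer seed for bath placement.
#' @return list of class \code{toy_system_spec}.
#' @export
toy_system_spec <- function(n_bath_particles = 8, droplet_radius = 6,
                            da_distance = 2.8,
                            morse_D = 80, morse_a = 1.5, morse_r0 = 1.0,
                            scaffold_k = 40,
                            charges_state1 = c(-0.2, 0.2, -0.4),
                            charges_state2 = c(-0.4, 0.2, -0.2),
                            target_dG_rxn = 0, coupling_h12 = 1,
                            charged_bath = FALSE, seed = 1) {
  stopifnot(droplet_radius > 0, da_distance > 0, morse_D > 0, morse_a > 0,
            morse_r0 > 0, scaffold_k > 0, coupling_h12 >= 0,
            n_bath_particles >= 0)
  structure(as.list(environment()), class = "toy_system_spec")
}

# triad-only topology for a given product-state shift
triad_topology <- function(spec, alpha2) {
  bonds1 <- data.frame(i = 1, j = 2, form = "morse",
                       D = spec$morse_D, a = spec$morse_a, r0 = spec$morse_r0,
                       k = NA)
  bonds1 <- rbind(bonds1, data.frame(i = 1, j = 3, form = "harmonic",
                                     D = NA, a = NA, r0 = spec$da_distance,
                                     k = spec$scaffold_k))
  bonds2 <- data.frame(i = 3, j = 2, form = "morse",
                       D = spec$morse_D, a = spec$morse_a, r0 = spec$morse_r0,
                       k = NA)
  bonds2 <- rbind(bonds2, data.frame(i = 1, j = 3, form = "harmonic",
                                     D = NA, a = NA, r0 = spec$da_distance,
                                     k = spec$scaffold_k))
  eps <- c(0.15, 0.01, 0.15); sig <- c(2.9, 1.0, 2.9)
  s1 <- evb_state(3, bonds = bonds1, charges = spec$charges_state1,
                  eps = eps, sigma = sig, alpha_shift = 0)
  s2 <- evb_state(3, bonds = bonds2, charges = spec$charges_state2,
                  eps = eps, sigma = sig, alpha_shift = alpha2)
  evb_topology(c("D", "H", "A"), c(16, 1, 16), s1, s2, spec$coupling_h12,
               evb_region = 1:3)
}

#' Rigid 1D proton scan of a triad topology
#'
#' Brute-force oracle: the donor and acceptor sit at their default
#' positions and the proton is scanned along the axis; adiabatic ground
#' energies are returned together with the two well minima and the barrier
#' between them.
#'
#' @param topology a 3-atom (or larger; only atoms 1-3 move) EVB topology
#'   with the triad as atoms (D, H, A).
#' @param da_distance donor-acceptor separation used for the scan (A).
#' @param n_points scan resolution.
#' @return list with \code{x, e_ground, e1, e2, dG_rxn} (right minus left
#'   minimum), \code{barrier} (saddle minus left minimum).
#' @export
triad_scan <- function(topology, da_distance, n_points = 401) {
  x <- seq(0.45, da_distance - 0.45, length.out = n_points)
  n <- topology$n_atoms
  eg <- e1 <- e2 <- numeric(length(x))
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[3, ] <- c(da_distance, 0, 0)
  if (n > 3) xyz[4:n, 1] <- 1e4 + seq_len(n - 3) * 10  # park bath far away
  for (i in seq_along(x)) {
    xyz[2, ] <- c(x[i], 0, 0)
    de <- diabatic_energies(topology, xyz)
    ap <- adiabatic_state(de["e1"], de["e2"], topology$h12)
    e1[i] <- de["e1"]; e2[i] <- de["e2"]; eg[i] <- ap$e_ground
  }
  imax <- which.max(eg[x > 0.8 & x < da_distance - 0.8])
  ibar <- which(x > 0.8 & x < da_distance - 0.8)[imax]
  left <- min(eg[seq_len(ibar)])
  right <- min(eg[ibar:length(eg)])
  list(x = x, e_ground = eg, e1 = e1, e2 = e2,
       dG_rxn = right - left, barrier = eg[ibar] - left)
}

#' Generate a toy reactive EVB system
#'
#' Builds the donor-hydrogen-acceptor triad plus Lennard-Jones bath
#' described by a \code{\link{toy_system_spec}}. The product-state shift is
#' iteratively calibrated against \code{\link{triad_scan}} so the scan's
#' minimum-energy difference matches \code{target_dG_rxn} to better than
#' 0.01 kcal/mol; generation fails if the resulting adiabatic barrier is
#' not positive. Bath particles are placed by rejection sampling inside the
#' droplet (deterministic in the spec seed).
#'
#' @param spec a \code{\link{toy_system_spec}}.
#' @return list with \code{topology}, \code{conformation} (n x 3),
#'   \code{restraint} (droplet wall for the bath), \code{indices}
#'   (donor/hydrogen/acceptor), \code{scan} (the calibration scan), and
#'   \code{spec}.
#' @export
make_toy_reaction_system <- function(spec = toy_system_spec()) {
  stopifnot(inherits(spec, "toy_system_spec"))
  # calibrate alpha on the isolated triad
  alpha2 <- 0
  for (it in 1:8) {
    sc <- triad_scan(triad_topology(spec, alpha2), spec$da_distance)
    err <- spec$target_dG_rxn - sc$dG_rxn
    if (abs(err) < 0.005) break
    alpha2 <- alpha2 + err
  }
  scan <- triad_scan(triad_topology(spec, alpha2), spec$da_distance)
  if (scan$barrier <= 0 || scan$barrier <= scan$dG_rxn)
    stop("generation error: calibrated triad has no forward barrier")
  nb <- spec$n_bath_particles
  n <- 3 + nb
  # assemble full system
  set.seed(spec$seed)
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- c(-spec$da_distance / 2, 0, 0)
  xyz[2, ] <- c(-spec$da_distance / 2 + spec$morse_r0, 0, 0)
  xyz[3, ] <- c(spec$da_distance / 2, 0, 0)
  if (nb > 0) {
    placed <- 0
    tries <- 0
    while (placed < nb) {
      tries <- tries + 1
      if (tries > 20000)
        stop("generation error: cannot place bath particles without overlap")
      p <- stats::runif(3, -1, 1) * spec$droplet_radius
      if (sqrt(sum(p^2)) > spec$droplet_radius * 0.9) next
      dmin <- min(sqrt(rowSums(sweep(xyz[seq_len(3 + placed), , drop = FALSE],
                                     2, p)^2)))
      if (dmin < 2.6) next
      placed <- placed + 1
      xyz[3 + placed, ] <- p
    }
  }
  tri <- triad_topology(spec, alpha2)
  pad <- function(v, fill) c(v, rep(fill, nb))
  qb <- if (spec$charged_bath && nb > 0)
    rep_len(c(0.2, -0.2), nb) - (nb %% 2) * 0  else rep(0, nb)
  if (spec$charged_bath && nb %% 2 == 1) qb[nb] <- 0  # keep the bath neutral
  mk_state <- function(s) {
    evb_state(n, bonds = NULL, charges = c(s$charges[1:3], qb),
              eps = pad(s$eps[1:3], 0.15), sigma = pad(s$sigma[1:3], 3.1),
              alpha_shift = s$alpha)
  }
  s1 <- mk_state(tri$state1); s2 <- mk_state(tri$state2)
  s1$bonds <- tri$state1$bonds; s1$excl <- tri$state1$excl
  s2$bonds <- tri$state2$bonds; s2$excl <- tri$state2$excl
  topo <- evb_topology(c("D", "H", "A", if (nb) sprintf("W%d", seq_len(nb))),
                       c(16, 1, 16, rep(18, nb)), s1, s2, spec$coupling_h12,
                       evb_region = 1:3)
  restraint <- restraint_model(xyz, center = c(0, 0, 0),
                               sphere_radius = spec$droplet_radius,
                               free_fraction = 0.85, buffer_k = 0,
                               outer_k = 0, wall_k = 10,
                               wall_atoms = if (nb) 3 + seq_len(nb) else integer(0))
  list(topology = topo, conformation = xyz, restraint = restraint,
       indices = c(donor = 1L, hydrogen = 2L, acceptor = 3L),
       scan = scan, alpha = alpha2, spec = spec)
}

#' One-dimensional harmonic-diabat model system
#'
#' A frozen anchor atom plus one mobile particle bound by a harmonic bond
#' whose rest length differs between the two diabatic states: the classic
#' two-parabola Marcus picture realised as a radial coordinate. With equal
#' force constants k and minima separated by d, the reorganization energy
#' is \code{k d^2} (with the package's \code{k d^2} energy convention).
#'
#' @param k1,k2 force constants (kcal/mol/A^2).
#' @param r1,r2 state rest lengths (A).
#' @param alpha product-state shift (kcal/mol).
#' @param h12 coupling (kcal/mol).
#' @param mass particle mass (amu).
#' @return list with \code{topology}, \code{conformation}, \code{frozen}
#'   (the anchor index), and closed-form \code{lambda_R}.
#' @export
make_harmonic_diabat_system <- function(k1 = 3, k2 = 3, r1 = 2, r2 = 4,
                                        alpha = 0, h12 = 0.5, mass = 10) {
  s1 <- evb_state(2, bonds = data.frame(i = 1, j = 2, form = "harmonic",
                                        k = k1, r0 = r1, D = NA, a = NA),
                  alpha_shift = 0, eps = c(0, 0), sigma = c(1, 1))
  s2 <- evb_state(2, bonds = data.frame(i = 1, j = 2, form = "harmonic",
                                        k = k2, r0 = r2, D = NA, a = NA),
                  alpha_shift = alpha, eps = c(0, 0), sigma = c(1, 1))
  topo <- evb_topology(c("X", "P"), c(1e6, mass), s1, s2, h12,
                       evb_region = 1:2)
  xyz <- rbind(c(0, 0, 0), c(r1, 0, 0))
  list(topology = topo, conformation = xyz, frozen = 1L,
       lambda_R = if (k1 == k2) k1 * (r2 - r1)^2 else NA_real_)
}

#' Simulate a noisy Michaelis-Menten rate profile
#'
#' \code{v = kcat E0 S / (KM + S)} with multiplicative Gaussian noise of
#' the given relative standard deviation, seeded.
#'
#' @param kcat turnover number (1/s).
#' @param KM Michaelis constant (mM).
#' @param E0 enzyme concentration (M).
#' @param conc_grid substrate concentrations (mM).
#' @param relative_noise relative noise sd (>= 0).
#' @param seed integer seed.
#' @return data.frame with \code{substrate_mM} and \code{rate_M_per_s}.
#' @export
simulate_kinetics_dataset <- function(kcat, KM, E0,
                                      conc_grid = seq(0.5, 6, length.out = 12),
                                      relative_noise = 0.05, seed = 1) {
  stopifnot(kcat > 0, KM > 0, E0 > 0)
  if (relative_noise < 0) stop("relative_noise must be non-negative")
  set.seed(seed)
  v <- kcat * E0 * conc_grid / (KM + conc_grid)
  v <- v * (1 + rnorm(length(conc_grid), 0, relative_noise))
  data.frame(substrate_mM = conc_grid, rate_M_per_s = v)
}

#' Generate a variant table with planted geometry-barrier structure
#'
#' Emulates a screening table in which activation barriers are linearly
#' related to the donor-acceptor distance (and, with opposite sign, to the
#' donor-hydrogen-acceptor angle) plus Gaussian noise. Distances are drawn
#' uniformly from the plausible Michaelis-complex range 2.64-4.25 A; kcat
#' values are derived from the barriers by the inverse Eyring relation so
#' kinetics and thermodynamics are mutually consistent.
#'
#' @param n_variants number of records (>= 3).
#' @param barrier_range barriers spanned over the distance range
#'   (kcal/mol, length 2, increasing).
#' @param geometry_slope barrier change per A of donor-acceptor distance
#'   (kcal/mol/A); its sign sets the sign of the planted correlation.
#' @param noise sd of the barrier noise (kcal/mol).
#' @param seed integer seed.
#' @param distance_range donor-acceptor distance range (A).
#' @return a \code{variant_table} with geometry and barrier columns filled.
#' @export
make_variant_table <- function(n_variants, barrier_range = c(15, 19),
                               geometry_slope = NULL, noise = 0.3, seed = 1,
                               distance_range = c(2.64, 4.25)) {
  if (n_variants < 3) stop("need at least 3 variants")
  if (diff(distance_range) <= 0 || diff(barrier_range) == 0)
    stop("degenerate range")
  set.seed(seed)
  if (is.null(geometry_slope))
    geometry_slope <- diff(barrier_range) / diff(distance_range)
  d <- stats::runif(n_variants, distance_range[1], distance_range[2])
  intercept <- if (geometry_slope >= 0)
    barrier_range[1] - geometry_slope * distance_range[1]
  else barrier_range[2] - geometry_slope * distance_range[1]
  dg <- intercept + geometry_slope * d + rnorm(n_variants, 0, noise)
  # angle shrinks as the donor-acceptor pair stretches
  ang <- 170 - 22 * (d - distance_range[1]) + rnorm(n_variants, 0, 1.5)
  ang <- pmin(pmax(ang, 0), 180)
  kcat <- kcat_from_barrier(dg)
  KM <- exp(rnorm(n_variants, log(3), 0.4))
  out <- data.frame(name = sprintf("VAR-%03d", seq_len(n_variants)),
                    mutations = NA_character_,
                    kcat = kcat, kcat_err = NA_real_,
                    KM = KM, KM_err = NA_real_,
                    efficiency = kcat / (KM * 1e-3),
                    efficiency_err = NA_real_,
                    TM = round(rnorm(n_variants, 78, 1.5), 1),
                    dG_act_exp = dg,
                    dG_act_calc = dg + rnorm(n_variants, 0, noise / 2),
                    dG_act_calc_sem = rep(round(noise / 3, 2), n_variants),
                    DA_distance = d, DHA_angle = ang,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}
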
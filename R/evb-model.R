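#' Define a diabatic valence-bond state
#'
#' A diabatic state is one bonding pattern of the reactive system: its own
#' bonded terms (harmonic or Morse bonds, harmonic angles), its own partial
#' charges and Lennard-Jones parameters, the pairs excluded from the
#' intrastate nonbonded sum (the pairs bonded in this state), and a constant
#' gas-phase shift added to the state energy. The shift on the product state
#' is the calibration parameter that positions the reaction free energy.
#'
#' Energy conventions: harmonic bond/angle terms are \code{k * d^2} (not
#' \code{k/2 * d^2}), so force constants quoted in kcal/mol/A^2 are used
#' verbatim; Morse bonds are \code{D * (1 - exp(-a (r - r0)))^2}.
#'
#' @param n_atoms number of atoms in the topology this state belongs to.
#' @param bonds data.frame with columns \code{i, j, form} (\code{"harmonic"}
#'   or \code{"morse"}) and parameters: \code{k, r0} for harmonic (kcal/mol/A^2, A),
#'   \code{D, a, r0} for Morse (kcal/mol, 1/A, A). May be \code{NULL}.
#' @param angles data.frame with columns \code{i, j, k} (j central),
#'   \code{k_theta} (kcal/mol/rad^2) and \code{theta0} (degrees). May be \code{NULL}.
#' @param charges numeric vector of partial charges (e), length \code{n_atoms}.
#' @param eps,sigma Lennard-Jones parameters per atom (kcal/mol, A).
#' @param alpha_shift constant energy offset for this state (kcal/mol).
#' @return An object of class \code{evb_state}.
#' @export
evb_state <- function(n_atoms, bonds = NULL, angles = NULL,
                      charges = rep(0, n_atoms),
                      eps = rep(0, n_atoms), sigma = rep(1, n_atoms),
                      alpha_shift = 0) {
  stopifnot(n_atoms >= 1, length(charges) == n_atoms,
            length(eps) == n_atoms, length(sigma) == n_atoms)
  if (!is.finite(alpha_shift)) stop("alpha_shift must be finite")
  bond_m <- matrix(0, 0, 6)
  excl <- matrix(0L, 0, 2)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    idx <- cbind(bonds$i, bonds$j)
    if (any(idx < 1 | idx > n_atoms)) stop("bond atom index out of range")
    if (any(bonds$i == bonds$j)) stop("bond must join two distinct atoms")
    form <- ifelse(bonds$form == "morse", 1, 0)
    p <- matrix(0, nrow(bonds), 3)
    for (b in seq_len(nrow(bonds))) {
      if (form[b] == 1) {
        if (any(c(bonds$D[b], bonds$a[b], bonds$r0[b]) <= 0))
          stop("Morse parameters D, a, r0 must all be positive")
        p[b, ] <- c(bonds$D[b], bonds$a[b], bonds$r0[b])
      } else {
        p[b, 1:2] <- c(bonds$k[b], bonds$r0[b])
      }
    }
    bond_m <- cbind(bonds$i, bonds$j, form, p)
    excl <- cbind(as.integer(bonds$i), as.integer(bonds$j))
  }
  angle_m <- matrix(0, 0, 5)
  if (!is.null(angles) && nrow(angles) > 0) {
    idx <- cbind(angles$i, angles$j, angles$k)
    if (any(idx < 1 | idx > n_atoms)) stop("angle atom index out of range")
    angle_m <- cbind(angles$i, angles$j, angles$k,
                     angles$k_theta, angles$theta0 * pi / 180)
  }
  structure(list(n_atoms = n_atoms, bonds = bond_m, angles = angle_m,
                 charges = as.numeric(charges), eps = as.numeric(eps),
                 sigma = as.numeric(sigma), excl = excl,
                 alpha = as.numeric(alpha_shift)),
            class = "evb_state")
}

#' Assemble a two-state EVB topology
#'
#' Couples two diabatic states over an identical atom set with a constant
#' off-diagonal element H12. Atoms are partitioned into the reactive (EVB)
#' region and the classical environment region.
#'
#' @param atom_names character vector.
#' @param masses atomic masses (amu).
#' @param state1,state2 \code{\link{evb_state}} objects (reactant, product).
#' @param h12 coupling constant in kcal/mol, must be >= 0.
#' @param evb_region integer indices of the reactive atoms.
#' @return An object of class \code{evb_topology}.
#' @export
evb_topology <- function(atom_names, masses, state1, state2, h12,
                         evb_region = seq_along(atom_names)) {
  n <- length(atom_names)
  stopifnot(length(masses) == n, inherits(state1, "evb_state"),
            inherits(state2, "evb_state"))
  if (state1$n_atoms != n || state2$n_atoms != n)
    stop("both diabatic states must cover the identical atom set")
  if (h12 < 0) stop("coupling h12 must be non-negative")
  evb_region <- sort(unique(as.integer(evb_region)))
  if (any(evb_region < 1 | evb_region > n)) stop("evb_region index out of range")
  env_region <- setdiff(seq_len(n), evb_region)
  structure(list(atom_names = atom_names, masses = as.numeric(masses),
                 state1 = state1, state2 = state2, h12 = as.numeric(h12),
                 evb_region = evb_region, environment_region = env_region,
                 n_atoms = n),
            class = "evb_topology")
}

#' @export
print.evb_topology <- function(x, ...) {
  cat("Two-state EVB topology:", x$n_atoms, "atoms (",
      length(x$evb_region), "reactive,", length(x$environment_region),
      "environment ), H12 =", x$h12, "kcal/mol\n")
  invisible(x)
}

check_conformation <- function(topology, conformation) {
  xyz <- as.matrix(conformation)
  if (!is.numeric(xyz) || ncol(xyz) != 3)
    stop("conformation must be an n x 3 numeric matrix of coordinates (A)")
  if (nrow(xyz) != topology$n_atoms)
    stop("conformation has ", nrow(xyz), " atoms; topology has ", topology$n_atoms)
  if (!all(is.finite(xyz))) stop("conformation contains non-finite coordinates")
  xyz
}

state_clist <- function(s) {
  list(bonds = s$bonds, angles = s$angles, charges = s$charges,
       eps = s$eps, sigma = s$sigma,
       excl = if (nrow(s$excl)) s$excl else matrix(0L, 0, 2),
       alpha = s$alpha)
}

#' Diabatic state energies of a conformation
#'
#' Evaluates both diabatic potential energies: bonded terms plus the
#' intrastate nonbonded sum (Lennard-Jones + Coulomb with that state's
#' charges and exclusions) plus the state's constant shift.
#'
#' @param topology an \code{\link{evb_topology}}.
#' @param conformation n x 3 coordinate matrix (A).
#' @return Named numeric vector \code{c(e1 =, e2 =)} in kcal/mol.
#' @export
diabatic_energies <- function(topology, conformation) {
  xyz <- check_conformation(topology, conformation)
  r <- cpp_diabatic(xyz, state_clist(topology$state1), state_clist(topology$state2))
  c(e1 = r$e1, e2 = r$e2)
}

#' Adiabatic ground state of the 2x2 EVB Hamiltonian
#'
#' The ground-state energy is the lower eigenvalue
#' \code{Eg = (e1+e2)/2 - sqrt((e1-e2)^2 + 4 h12^2)/2}, and the mixing
#' weights are the squared components of the corresponding eigenvector.
#'
#' @param e1,e2 diabatic energies (kcal/mol).
#' @param h12 coupling (kcal/mol, >= 0).
#' @return An \code{energy_pair} list with \code{e1, e2, e_ground, gap}
#'   (\code{= e1 - e2}), and mixing weights \code{c1_sq, c2_sq}.
#' @export
adiabatic_state <- function(e1, e2, h12) {
  if (h12 < 0) stop("coupling h12 must be non-negative")
  de <- e1 - e2
  disc <- sqrt(de^2 + 4 * h12^2)
  eg <- 0.5 * (e1 + e2) - 0.5 * disc
  c1s <- if (disc < 1e-300) 0.5 else 0.5 * (1 - de / disc)
  structure(list(e1 = e1, e2 = e2, e_ground = eg, gap = de,
                 c1_sq = c1s, c2_sq = 1 - c1s),
            class = "energy_pair")
}

#' Analytic forces on the adiabatic ground surface
#'
#' With constant coupling the gradient of the ground-state energy follows
#' from the chain rule over the two diabatic gradients, weighted by the
#' mixing weights (Hellmann-Feynman).
#'
#' @inheritParams diabatic_energies
#' @return n x 3 matrix of forces (kcal/mol/A).
#' @export
adiabatic_forces <- function(topology, conformation) {
  xyz <- check_conformation(topology, conformation)
  r <- cpp_evb_eval(xyz, state_clist(topology$state1), state_clist(topology$state2),
                    topology$h12, -1, TRUE)
  r$forces
}

#' Full EVB evaluation at a conformation
#'
#' @inheritParams diabatic_energies
#' @param surface mapping parameter lambda in [0,1], or \code{"ground"} for
#'   the adiabatic surface.
#' @param forces logical, also compute forces on the requested surface.
#' @return list with \code{e1, e2, e_ground, gap, c1_sq, epot, forces}.
#' @export
evb_eval <- function(topology, conformation, surface = "ground", forces = TRUE) {
  xyz <- check_conformation(topology, conformation)
  s <- if (identical(surface, "ground")) -1 else {
    if (!is.numeric(surface) || surface < 0 || surface > 1)
      stop("surface must be 'ground' or a lambda in [0,1]")
    surface
  }
  cpp_evb_eval(xyz, state_clist(topology$state1), state_clist(topology$state2),
               topology$h12, s, forces)
}

#' Mapping potential between the diabatic states
#'
#' The sampling potential for window m is the linear blend
#' \code{(1 - lambda) e1 + lambda e2}; its force is the same blend of the
#' diabatic forces.
#'
#' @param e1,e2 diabatic energies (kcal/mol).
#' @param lambda_m blend parameter in [0, 1].
#' @return list with \code{energy} and \code{weights = c(w1, w2)}.
#' @export
mapping_potential <- function(e1, e2, lambda_m) {
  if (!is.numeric(lambda_m) || lambda_m < 0 || lambda_m > 1)
    stop("lambda_m must lie in [0, 1]")
  list(energy = (1 - lambda_m) * e1 + lambda_m * e2,
       weights = c(w1 = 1 - lambda_m, w2 = lambda_m))
}
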
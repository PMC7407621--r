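# Shared miniature systems built in code at test time.

# 4-atom two-state fixture with printed parameters; state2 differs from
# state1 only by a +3 kcal/mol shift.
fixture_topology <- function(alpha2 = 3) {
  bonds <- data.frame(i = 1, j = 2, form = "harmonic", k = 10, r0 = 1.5,
                      D = NA, a = NA)
  angles <- data.frame(i = 1, j = 2, k = 3, k_theta = 5, theta0 = 100)
  q <- c(0.3, -0.2, 0.1, -0.2)
  eps <- c(0.1, 0.2, 0.15, 0.05)
  sig <- c(2.5, 3.0, 2.8, 3.2)
  s1 <- evb_state(4, bonds = bonds, angles = angles, charges = q,
                  eps = eps, sigma = sig, alpha_shift = 0)
  s2 <- evb_state(4, bonds = bonds, angles = angles, charges = q,
                  eps = eps, sigma = sig, alpha_shift = alpha2)
  evb_topology(paste0("A", 1:4), c(12, 16, 14, 1), s1, s2, h12 = 2,
               evb_region = 1:2)
}

fixture_coords <- function() {
  rbind(c(0, 0, 0), c(1.2, 0.3, -0.2), c(2.0, 1.0, 0.5), c(-0.8, 1.1, 0.4))
}

# independent term-by-term energy evaluation used as the hand-sum oracle
oracle_state_energy <- function(xyz, q, eps, sig, kbond, r0bond, kang,
                                theta0_deg, alpha) {
  dist <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e <- alpha
  e <- e + kbond * (dist(1, 2) - r0bond)^2
  v1 <- xyz[1, ] - xyz[2, ]; v2 <- xyz[3, ] - xyz[2, ]
  th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  e <- e + kang * (th - theta0_deg * pi / 180)^2
  for (i in 1:3) for (j in (i + 1):4) {
    if (i == 1 && j == 2) next               # bonded exclusion
    r <- dist(i, j)
    e <- e + 332.0636 * q[i] * q[j] / r
    epsij <- sqrt(eps[i] * eps[j]); sij <- (sig[i] + sig[j]) / 2
    e <- e + 4 * epsij * ((sij / r)^12 - (sij / r)^6)
  }
  e
}

# small random reactive topology for force-oracle property tests
random_topology <- function(n = 5, seed = 1) {
  set.seed(seed)
  bonds1 <- data.frame(i = 1, j = 2, form = "morse", D = 60, a = 1.4,
                       r0 = 1.1, k = NA)
  bonds2 <- data.frame(i = 2, j = 3, form = "harmonic", k = 15, r0 = 1.3,
                       D = NA, a = NA)
  q1 <- round(runif(n, -0.3, 0.3), 2); q1 <- q1 - mean(q1)
  q2 <- rev(q1)
  eps <- runif(n, 0.05, 0.2); sig <- runif(n, 2.2, 3.2)
  s1 <- evb_state(n, bonds = bonds1, charges = q1, eps = eps, sigma = sig)
  s2 <- evb_state(n, bonds = bonds2, charges = q2, eps = eps, sigma = sig,
                  alpha_shift = 1.5)
  evb_topology(paste0("X", 1:n), runif(n, 4, 20), s1, s2, h12 = 3,
               evb_region = 1:3)
}

random_conformation <- function(n = 5, seed = 1, spread = 2.5) {
  set.seed(seed)
  # rejection-sample until no two atoms closer than 1 A
  repeat {
    xyz <- matrix(runif(3 * n, -spread, spread), n, 3)
    d <- as.matrix(dist(xyz))
    if (min(d[upper.tri(d)]) > 1.0) return(xyz)
  }
}

ground_energy_of <- function(topology, xyz) {
  de <- diabatic_energies(topology, xyz)
  adiabatic_state(de[["e1"]], de[["e2"]], topology$h12)$e_ground
}

# hand-built window_samples object for estimator unit tests
fake_window <- function(lambda, e1, e2, replicate_id = 1) {
  structure(list(lambda = lambda, e1 = e1, e2 = e2,
                 e_ground = pmin(e1, e2), e_map = (1 - lambda) * e1 + lambda * e2,
                 gap = e1 - e2, coords = NULL, replicate_id = replicate_id,
                 seed = 0, temperature = 300),
            class = "window_samples")
}
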
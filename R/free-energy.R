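#' Run the EVB mapping windows
#'
#' Samples the system on a series of mapping potentials
#' \code{(1 - lambda) e1 + lambda e2} on an even lambda grid over [0, 1],
#' one pass per replicate. Within a replicate the windows are run
#' sequentially, carrying coordinates and velocities from window to window
#' as in the standard FEP/US protocol; replicate i uses seed
#' \code{seed + i}, so the whole scan is deterministic.
#'
#' @param topology an \code{\link{evb_topology}}.
#' @param start_conformations a single n x 3 matrix or a list of matrices,
#'   one per replicate (recycled if shorter than \code{n_replicates}).
#' @param n_windows number of lambda windows (>= 2; the paper-scale value is
#'   51, the desk-scale default 11).
#' @param steps_per_window integration steps per window.
#' @param seed integer base seed.
#' @param n_replicates number of independent replicates.
#' @param temperature sampling temperature (K).
#' @param timestep integration step (fs).
#' @param restraint optional \code{\link{restraint_model}}.
#' @param frozen_atoms indices held fixed.
#' @param sample_every sampling stride (steps).
#' @param burn_fraction fraction of each window discarded as equilibration.
#' @param friction Langevin friction (1/fs).
#' @return list of \code{window_samples} objects, each with fields
#'   \code{lambda, e1, e2, e_ground, e_map, gap, coords, replicate_id, seed,
#'   temperature}.
#' @export
run_evb_windows <- function(topology, start_conformations, n_windows = 11,
                            steps_per_window = 5000, seed = 1,
                            n_replicates = 1, temperature = 300,
                            timestep = 1, restraint = NULL,
                            frozen_atoms = integer(0), sample_every = 10,
                            burn_fraction = 0.2, friction = 0.02) {
  if (n_windows < 2) stop("need at least two mapping windows")
  lambdas <- seq(0, 1, length.out = n_windows)
  if (is.matrix(start_conformations)) start_conformations <- list(start_conformations)
  out <- list()
  for (r in seq_len(n_replicates)) {
    xyz <- start_conformations[[(r - 1L) %% length(start_conformations) + 1L]]
    vel <- NULL
    for (m in seq_len(n_windows)) {
      stage <- protocol_stage(steps_per_window * timestep, timestep = timestep,
                              target_temperature = temperature,
                              thermostat = "langevin", friction = friction)
      tr <- tryCatch(
        propagate(topology, xyz, lambdas[m], stage,
                  seed = seed + r + 1000L * m, restraint = restraint,
                  velocities = vel, frozen_atoms = frozen_atoms,
                  sample_every = sample_every,
                  burn_in = as.integer(burn_fraction * steps_per_window)),
        error = function(e)
          stop("integration error in window ", m, " replicate ", r, ": ",
               conditionMessage(e), call. = FALSE))
      xyz <- tr$xyz_final
      vel <- tr$vel_final
      out[[length(out) + 1L]] <- structure(
        list(lambda = lambdas[m], e1 = tr$e1, e2 = tr$e2,
             e_ground = tr$e_ground, e_map = tr$e_map, gap = tr$gap,
             coords = tr$coords, replicate_id = r,
             seed = seed + r + 1000L * m, temperature = temperature),
        class = "window_samples")
    }
  }
  out
}

window_lambdas <- function(windows) vapply(windows, `[[`, 0, "lambda")
window_replicates <- function(windows) vapply(windows, `[[`, 0, "replicate_id")

# log of mean(exp(x)) with overflow guard
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Cumulative FEP free energies along the lambda grid
#'
#' Adjacent-window exponential (Zwanzig) averaging:
#' \code{dG(m -> m+1) = -kT ln < exp(-beta (eps_{m+1} - eps_m)) >_m},
#' evaluated in both directions and averaged; the forward-backward
#' difference is reported as hysteresis. Samples from windows sharing a
#' lambda (replicates) are pooled.
#'
#' @param windows list of \code{window_samples}.
#' @param temperature K (> 0).
#' @return list with \code{lambda}, \code{dG_lambda} (cumulative, zero at
#'   lambda = 0), \code{dG_forward}, \code{dG_backward}, \code{hysteresis}.
#' @export
fep_cumulative <- function(windows, temperature = 300) {
  stopifnot(temperature > 0)
  if (!length(windows)) stop("no windows supplied")
  lam <- window_lambdas(windows)
  grid <- sort(unique(lam))
  kT <- physical_constants$kB_kcal * temperature
  beta <- 1 / kT
  e1 <- lapply(grid, function(l) unlist(lapply(windows[lam == l], `[[`, "e1")))
  e2 <- lapply(grid, function(l) unlist(lapply(windows[lam == l], `[[`, "e2")))
  if (any(vapply(e1, length, 0L) == 0)) stop("empty window in lambda grid")
  M <- length(grid)
  eps <- function(m, l) (1 - l) * e1[[m]] + l * e2[[m]]
  dgf <- dgb <- numeric(M - 1)
  for (m in seq_len(M - 1)) {
    du_f <- eps(m, grid[m + 1]) - eps(m, grid[m])
    dgf[m] <- -kT * log_mean_exp(-beta * du_f)
    du_b <- eps(m + 1, grid[m]) - eps(m + 1, grid[m + 1])
    dgb[m] <- kT * log_mean_exp(-beta * du_b)
  }
  dg <- 0.5 * (dgf + dgb)
  list(lambda = grid, dG_lambda = c(0, cumsum(dg)),
       dG_forward = dgf, dG_backward = dgb, hysteresis = dgf - dgb)
}

#' Free-energy profile on the energy-gap coordinate
#'
#' Umbrella reweighting of the mapping-window samples onto the gap
#' coordinate \code{x = e1 - e2} (reactant basin at negative x):
#' \code{g(x_b) = dG(lambda_m) - kT ln < 1_b exp(-beta (Eg - eps_m)) >_m},
#' combined over windows per bin with sample-count weights (default) or
#' inverse-variance weights. Bins with fewer than \code{min_samples} total
#' samples are masked (NA), never interpolated.
#'
#' @param windows list of \code{window_samples}.
#' @param dG_lambda result of \code{\link{fep_cumulative}} (or NULL to
#'   compute it internally).
#' @param temperature K.
#' @param n_bins number of gap bins (>= 10).
#' @param min_samples mask threshold per bin.
#' @param weighting \code{"count"} or \code{"invvar"}.
#' @return object of class \code{free_energy_profile} with \code{gap_bins}
#'   (centers), \code{g} (kcal/mol, minimum at 0), \code{samples_per_bin},
#'   \code{dG_lambda}.
#' @export
gap_profile <- function(windows, dG_lambda = NULL, temperature = 300,
                        n_bins = 50, min_samples = 10,
                        weighting = c("count", "invvar")) {
  weighting <- match.arg(weighting)
  if (n_bins < 10) stop("need at least 10 gap bins")
  if (is.null(dG_lambda)) dG_lambda <- fep_cumulative(windows, temperature)
  kT <- physical_constants$kB_kcal * temperature
  beta <- 1 / kT
  lam <- window_lambdas(windows)
  grid <- dG_lambda$lambda
  gaps_all <- unlist(lapply(windows, `[[`, "gap"))
  rng <- range(gaps_all)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- 0.5 * (edges[-1] + edges[-length(edges)])
  gsum <- wsum <- ntot <- matrix(0, length(grid), n_bins)
  gval <- matrix(NA_real_, length(grid), n_bins)
  for (mi in seq_along(grid)) {
    ws <- windows[lam == grid[mi]]
    gap <- unlist(lapply(ws, `[[`, "gap"))
    eg  <- unlist(lapply(ws, `[[`, "e_ground"))
    e1  <- unlist(lapply(ws, `[[`, "e1"))
    e2  <- unlist(lapply(ws, `[[`, "e2"))
    em  <- (1 - grid[mi]) * e1 + grid[mi] * e2
    u <- -beta * (eg - em)
    b <- findInterval(gap, edges, rightmost.closed = TRUE)
    b[b < 1] <- 1; b[b > n_bins] <- n_bins
    N <- length(gap)
    u0 <- max(u)
    w <- exp(u - u0)
    for (bb in unique(b)) {
      sel <- b == bb
      ntot[mi, bb] <- sum(sel)
      sw <- sum(w[sel])
      gval[mi, bb] <- dG_lambda$dG_lambda[mi] - kT * (u0 + log(sw / N))
      # delta-method variance of the log-average, for invvar weighting
      wsum[mi, bb] <- if (weighting == "invvar") {
        vw <- stats::var(w[sel]) / max(1, sum(sel))
        mw <- (sw / sum(sel))^2
        v <- kT^2 * vw / max(mw, 1e-300)
        1 / max(v, 1e-12)
      } else ntot[mi, bb]
    }
  }
  npb <- colSums(ntot)
  g <- rep(NA_real_, n_bins)
  for (bb in seq_len(n_bins)) {
    if (npb[bb] < min_samples) next
    sel <- !is.na(gval[, bb]) & wsum[, bb] > 0
    if (!any(sel)) next
    g[bb] <- sum(gval[sel, bb] * wsum[sel, bb]) / sum(wsum[sel, bb])
  }
  if (all(is.na(g))) stop("coverage error: all gap bins under-sampled")
  g <- g - min(g, na.rm = TRUE)
  structure(list(gap_bins = centers, g = g, samples_per_bin = npb,
                 dG_lambda = dG_lambda, temperature = temperature),
            class = "free_energy_profile")
}

# barrier extraction for one profile
profile_extrema <- function(profile) {
  keep <- !is.na(profile$g)
  x <- profile$gap_bins[keep]
  g <- profile$g[keep]
  n <- length(g)
  if (n < 3) stop("no barrier: profile has too few sampled bins")
  ismax <- vapply(2:(n - 1), function(i) g[i] >= g[i - 1] && g[i] >= g[i + 1],
                  TRUE)
  cand <- which(ismax) + 1L
  # genuine interior maxima: something lower on both sides
  cand <- cand[vapply(cand, function(i)
    any(g[seq_len(i - 1)] < g[i]) && any(g[(i + 1):n] < g[i]), TRUE)]
  if (!length(cand)) stop("no barrier: free-energy profile is monotone")
  ts <- cand[order(abs(x[cand]), -g[cand])][1]  # nearest x = 0, ties higher g
  g_r <- min(g[seq_len(ts - 1)])
  g_p <- min(g[(ts + 1):n])
  list(dG_act = g[ts] - g_r, dG_rxn = g_p - g_r, x_ts = x[ts])
}

#' Activation and reaction free energies with replicate statistics
#'
#' Locates the transition-state maximum (the masked-profile maximum nearest
#' the diabatic crossing at x = 0) and the flanking minima on each
#' replicate profile, then reports the mean and standard error of the mean
#' across replicates.
#'
#' @param profiles_per_replicate a single \code{free_energy_profile} or a
#'   list of them (one per replicate).
#' @return object of class \code{barrier_result}: \code{dG_act, dG_rxn,
#'   sem_act, sem_rxn, n_replicates, per_replicate}.
#' @export
extract_barriers <- function(profiles_per_replicate) {
  if (inherits(profiles_per_replicate, "free_energy_profile"))
    profiles_per_replicate <- list(profiles_per_replicate)
  ex <- lapply(profiles_per_replicate, profile_extrema)
  act <- vapply(ex, `[[`, 0, "dG_act")
  rxn <- vapply(ex, `[[`, 0, "dG_rxn")
  n <- length(act)
  res <- structure(list(dG_act = mean(act), dG_rxn = mean(rxn),
                        sem_act = if (n > 1) sd(act) / sqrt(n) else 0,
                        sem_rxn = if (n > 1) sd(rxn) / sqrt(n) else 0,
                        n_replicates = n,
                        single_replicate = n == 1,
                        per_replicate = data.frame(dG_act = act, dG_rxn = rxn)),
                   class = "barrier_result")
  if (n == 1)
    warning("single replicate: standard errors reported as 0", call. = FALSE)
  res
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("dG_act = %.2f +/- %.2f kcal/mol; dG_rxn = %.2f +/- %.2f kcal/mol (n = %d)\n",
              x$dG_act, x$sem_act, x$dG_rxn, x$sem_rxn, x$n_replicates))
  invisible(x)
}

#' Full desk-scale EVB free-energy pipeline
#'
#' Convenience wrapper: runs the mapping windows, builds a gap-coordinate
#' profile per replicate, and extracts barrier statistics.
#'
#' @inheritParams run_evb_windows
#' @param n_bins,min_samples passed to \code{\link{gap_profile}}.
#' @return list with \code{windows}, \code{profiles}, \code{barriers}.
#' @export
evb_free_energy <- function(topology, start_conformations, n_windows = 11,
                            steps_per_window = 5000, n_replicates = 5,
                            seed = 1, temperature = 300, timestep = 1,
                            restraint = NULL, frozen_atoms = integer(0),
                            n_bins = 50, min_samples = 10, ...) {
  windows <- run_evb_windows(topology, start_conformations,
                             n_windows = n_windows,
                             steps_per_window = steps_per_window,
                             seed = seed, n_replicates = n_replicates,
                             temperature = temperature, timestep = timestep,
                             restraint = restraint,
                             frozen_atoms = frozen_atoms, ...)
  reps <- window_replicates(windows)
  profiles <- lapply(sort(unique(reps)), function(r)
    gap_profile(windows[reps == r], temperature = temperature,
                n_bins = n_bins, min_samples = min_samples))
  list(windows = windows, profiles = profiles,
       barriers = extract_barriers(profiles))
}

#' Calibrate the gas-phase shift and coupling against reference barriers
#'
#' Adjusts the product-state shift alpha (which moves the reaction free
#' energy essentially one-for-one) and the coupling H12 (which lowers the
#' activation barrier) by alternating secant updates until the simulated
#' (dG_act, dG_rxn) match the targets within tolerance. The internal
#' simulations reuse a fixed seed so the objective is deterministic.
#'
#' @param reference_system list with \code{topology},
#'   \code{start_conformation}, and optional run settings
#'   (\code{n_windows, steps_per_window, n_replicates, temperature,
#'   frozen_atoms, restraint, seed, n_bins, min_samples}).
#' @param target_dG_act,target_dG_rxn reference barriers (kcal/mol).
#' @param tolerance convergence tolerance (kcal/mol, default 0.1).
#' @param max_iter maximum alternating iterations (default 20).
#' @return list with \code{alpha}, \code{h12}, \code{dG_act}, \code{dG_rxn},
#'   \code{converged}, \code{trace} (data.frame of iterates).
#' @export
calibrate_reference <- function(reference_system, target_dG_act,
                                target_dG_rxn, tolerance = 0.1,
                                max_iter = 20) {
  if (!is.finite(target_dG_act) || !is.finite(target_dG_rxn))
    stop("calibration targets must be finite")
  if (target_dG_act < 0 || target_dG_act < target_dG_rxn)
    stop("calibration error: infeasible targets (need dG_act >= max(0, dG_rxn))")
  rs <- reference_system
  topo <- rs$topology
  getd <- function(nm, d) if (is.null(rs[[nm]])) d else rs[[nm]]
  runit <- function(alpha, h12) {
    t2 <- topo
    t2$state2$alpha <- alpha
    t2$h12 <- max(h12, 0)
    fe <- suppressWarnings(evb_free_energy(t2, rs$start_conformation,
                          n_windows = getd("n_windows", 11),
                          steps_per_window = getd("steps_per_window", 2000),
                          n_replicates = getd("n_replicates", 1),
                          seed = getd("seed", 7712),
                          temperature = getd("temperature", 300),
                          restraint = rs$restraint,
                          frozen_atoms = getd("frozen_atoms", integer(0)),
                          n_bins = getd("n_bins", 40),
                          min_samples = getd("min_samples", 5)))
    c(act = fe$barriers$dG_act, rxn = fe$barriers$dG_rxn)
  }
  alpha <- topo$state2$alpha
  h12 <- topo$h12
  cur <- runit(alpha, h12)
  trace <- data.frame(iter = 0, alpha = alpha, h12 = h12,
                      dG_act = cur["act"], dG_rxn = cur["rxn"])
  prev <- NULL
  for (it in seq_len(max_iter)) {
    if (abs(cur["act"] - target_dG_act) <= tolerance &&
        abs(cur["rxn"] - target_dG_rxn) <= tolerance) {
      return(list(alpha = alpha, h12 = h12, dG_act = unname(cur["act"]),
                  dG_rxn = unname(cur["rxn"]), converged = TRUE,
                  trace = trace))
    }
    # secant slope for dG_rxn in alpha (first-order slope is 1)
    s_rxn <- 1
    s_act <- -1
    if (!is.null(prev)) {
      if (abs(alpha - prev$alpha) > 1e-8) {
        s <- (cur["rxn"] - prev$rxn) / (alpha - prev$alpha)
        if (is.finite(s) && abs(s) > 0.2) s_rxn <- s
      }
      if (abs(h12 - prev$h12) > 1e-8) {
        s <- (cur["act"] - prev$act) / (h12 - prev$h12)
        if (is.finite(s) && abs(s) > 0.2) s_act <- s
      }
    }
    prev <- list(alpha = alpha, h12 = h12,
                 act = cur["act"], rxn = cur["rxn"])
    alpha <- alpha + (target_dG_rxn - cur["rxn"]) / s_rxn
    h12 <- max(0, h12 + (target_dG_act - cur["act"]) / s_act)
    cur <- runit(alpha, h12)
    trace <- rbind(trace, data.frame(iter = it, alpha = alpha, h12 = h12,
                                     dG_act = cur["act"], dG_rxn = cur["rxn"]))
  }
  stop("calibration error: not converged after ", max_iter,
       " iterations; final residuals ",
       sprintf("(%.3f, %.3f)", cur["act"] - target_dG_act,
               cur["rxn"] - target_dG_rxn))
}

#' Reorganization energy from the endpoint windows
#'
#' Marcus reorganization energy estimated from the mean energy gap in the
#' two endpoint ensembles:
#' \code{lambda_R = ( <e2 - e1>_{lambda=0} - <e2 - e1>_{lambda=1} ) / 2}.
#'
#' @param windows list of \code{window_samples} including lambda = 0 and 1.
#' @return reorganization energy (kcal/mol).
#' @export
reorganization_energy <- function(windows) {
  lam <- window_lambdas(windows)
  if (!any(lam == 0) || !any(lam == 1))
    stop("reorganization energy needs both endpoint windows (lambda 0 and 1)")
  m0 <- mean(unlist(lapply(windows[lam == 0], function(w) w$e2 - w$e1)))
  m1 <- mean(unlist(lapply(windows[lam == 1], function(w) w$e2 - w$e1)))
  lr <- 0.5 * (m0 - m1)
  if (lr < 0)
    warning("negative reorganization energy estimate (", signif(lr, 3),
            " kcal/mol): endpoint ensembles look swapped or under-sampled")
  lr
}
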
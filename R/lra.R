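#' Linear response approximation free-energy estimate
#'
#' \code{dG_LRA = ( <dU>_A + <dU>_B ) / 2}, where the perturbation energy
#' \code{dU = U_B - U_A} is averaged over both endpoint ensembles. Exact
#' when dU is Gaussian with equal variance in the two ensembles.
#'
#' @param samples_A,samples_B endpoint ensembles: either numeric vectors of
#'   precomputed dU values, or frame matrices (rows = frames, columns =
#'   flattened xyz) to which \code{deltaU_evaluator} is applied.
#' @param deltaU_evaluator function mapping one n x 3 conformation to
#'   \code{U_B - U_A}; ignored when the ensembles are numeric dU vectors.
#' @return list with \code{dG} (kcal/mol), \code{mean_A}, \code{mean_B},
#'   \code{se} (standard error from the two ensemble means).
#' @export
lra_estimate <- function(samples_A, samples_B, deltaU_evaluator = NULL) {
  du <- function(s) {
    if (is.numeric(s) && is.null(dim(s))) return(as.numeric(s))
    if (is.null(deltaU_evaluator))
      stop("deltaU_evaluator required when ensembles are conformations")
    s <- as.matrix(s)
    vapply(seq_len(nrow(s)), function(i)
      deltaU_evaluator(matrix(s[i, ], ncol = 3, byrow = TRUE)), 0)
  }
  duA <- du(samples_A)
  duB <- du(samples_B)
  if (!length(duA) || !length(duB)) stop("empty ensemble")
  seA <- if (length(duA) > 1) sd(duA) / sqrt(length(duA)) else 0
  seB <- if (length(duB) > 1) sd(duB) / sqrt(length(duB)) else 0
  list(dG = 0.5 * (mean(duA) + mean(duB)),
       mean_A = mean(duA), mean_B = mean(duB),
       se = 0.5 * sqrt(seA^2 + seB^2))
}

#' Select the reactant and transition-state ensembles from mapping windows
#'
#' The reactant ensemble is the lambda = 0 window; the transition-state
#' proxy is the window whose pooled mean energy gap is nearest zero (the
#' diabatic crossing).
#'
#' @param windows list of \code{window_samples}.
#' @return list with \code{rs} and \code{ts} (lists of windows) and
#'   \code{lambda_ts}.
#' @export
lra_windows <- function(windows) {
  lam <- window_lambdas(windows)
  if (!any(lam == 0)) stop("no lambda = 0 window for the reactant ensemble")
  grid <- sort(unique(lam))
  mg <- vapply(grid, function(l)
    mean(unlist(lapply(windows[lam == l], `[[`, "gap"))), 0)
  lts <- grid[which.min(abs(mg))]
  list(rs = windows[lam == 0], ts = windows[lam == lts], lambda_ts = lts)
}

# per-frame Coulomb interaction between group atoms (fixed env charges) and
# EVB atoms carrying dq; coords is frames x 3n
group_coulomb_series <- function(coords, group_idx, evb_idx, q_env, dq) {
  out <- numeric(nrow(coords))
  for (g in group_idx) {
    if (q_env[g] == 0) next
    gx <- coords[, 3 * (g - 1) + 1]; gy <- coords[, 3 * (g - 1) + 2]
    gz <- coords[, 3 * (g - 1) + 3]
    for (ei in seq_along(evb_idx)) {
      e <- evb_idx[ei]
      if (is.matrix(dq)) dqe <- dq[, ei] else dqe <- dq[ei]
      r <- sqrt((gx - coords[, 3 * (e - 1) + 1])^2 +
                (gy - coords[, 3 * (e - 1) + 2])^2 +
                (gz - coords[, 3 * (e - 1) + 3])^2)
      out <- out + physical_constants$coulomb * q_env[g] * dqe / r
    }
  }
  out
}

#' Per-group electrostatic contributions to the activation barrier
#'
#' For each disjoint group of environment atoms, computes the Coulomb
#' interaction between the group and the reactive region evaluated with the
#' transition-state minus reactant-state EVB charges, averages it over the
#' reactant and transition-state ensembles with the linear response
#' approximation, and scales the result by the assumed dielectric constant
#' (default 4 for a buried, hydrophobic site).
#'
#' @param traj_RS,traj_TS \code{window_samples} (or lists of them) for the
#'   reactant window and the window nearest the transition state.
#' @param topology the \code{\link{evb_topology}}.
#' @param groups named list of disjoint integer index vectors; all indices
#'   must lie in the environment region.
#' @param dielectric_scale divisor applied uniformly (default 4).
#' @param ts_charges \code{"adiabatic"} (default: per-frame mixing-weighted
#'   blend \code{c1^2 q1 + c2^2 q2}) or a fixed lambda in [0,1] for a
#'   linear blend.
#' @param small_threshold contributions with \code{|ddG| <} this value
#'   (kcal/mol) are flagged \code{small} (default 2).
#' @return data.frame with \code{group_id, ddG_elec, small,
#'   dielectric_scale}.
#' @export
group_electrostatic_contributions <- function(traj_RS, traj_TS, topology,
                                              groups, dielectric_scale = 4,
                                              ts_charges = "adiabatic",
                                              small_threshold = 2) {
  stopifnot(dielectric_scale > 0)
  aslist <- function(x) if (inherits(x, "window_samples")) list(x) else x
  traj_RS <- aslist(traj_RS); traj_TS <- aslist(traj_TS)
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx))
    stop("definition error: groups must be disjoint")
  if (!all(all_idx %in% topology$environment_region))
    stop("group atoms must lie in the environment region")
  evb_idx <- topology$evb_region
  q1 <- topology$state1$charges[evb_idx]
  q2 <- topology$state2$charges[evb_idx]
  q_env <- topology$state1$charges
  frame_dq <- function(w) {
    if (identical(ts_charges, "adiabatic")) {
      ap <- mapply(function(e1, e2)
        adiabatic_state(e1, e2, topology$h12)$c1_sq, w$e1, w$e2)
      outer(ap, q1) + outer(1 - ap, q2) - rep(1, length(ap)) %o% q1
    } else {
      lb <- as.numeric(ts_charges)
      matrix((1 - lb) * q1 + lb * q2 - q1, nrow(w$coords),
             length(evb_idx), byrow = TRUE)
    }
  }
  # per group: LRA over the two ensembles
  res <- lapply(seq_along(groups), function(gi) {
    duA <- unlist(lapply(traj_RS, function(w)
      group_coulomb_series(w$coords, groups[[gi]], evb_idx, q_env,
                           frame_dq(w))))
    duB <- unlist(lapply(traj_TS, function(w)
      group_coulomb_series(w$coords, groups[[gi]], evb_idx, q_env,
                           frame_dq(w))))
    lra_estimate(duA, duB)$dG / dielectric_scale
  })
  ddg <- unlist(res)
  data.frame(group_id = names(groups), ddG_elec = ddg,
             small = abs(ddg) < small_threshold,
             dielectric_scale = dielectric_scale,
             stringsAsFactors = FALSE)
}
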
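state_to_list <- function(s) {
  bonds <- lapply(seq_len(nrow(s$bonds)), function(b) {
    r <- s$bonds[b, ]
    if (r[3] == 1) list(i = unname(r[1]), j = unname(r[2]), form = "morse",
                        D = unname(r[4]), a = unname(r[5]), r0 = unname(r[6]))
    else list(i = unname(r[1]), j = unname(r[2]), form = "harmonic",
              k = unname(r[4]), r0 = unname(r[5]))
  })
  angles <- lapply(seq_len(nrow(s$angles)), function(a) {
    r <- s$angles[a, ]
    list(i = unname(r[1]), j = unname(r[2]), k = unname(r[3]),
         k_theta = unname(r[4]), theta0 = unname(r[5]) * 180 / pi)
  })
  list(bonds = bonds, angles = angles, charges = s$charges, eps = s$eps,
       sigma = s$sigma, alpha_shift = s$alpha)
}

state_from_list <- function(l, n_atoms) {
  bonds <- if (length(l$bonds)) do.call(rbind, lapply(l$bonds, function(b)
    data.frame(i = b$i, j = b$j, form = b$form,
               k = if (is.null(b$k)) NA else b$k,
               D = if (is.null(b$D)) NA else b$D,
               a = if (is.null(b$a)) NA else b$a,
               r0 = b$r0))) else NULL
  angles <- if (length(l$angles)) do.call(rbind, lapply(l$angles, function(a)
    data.frame(i = a$i, j = a$j, k = a$k, k_theta = a$k_theta,
               theta0 = a$theta0))) else NULL
  evb_state(n_atoms, bonds = bonds, angles = angles,
            charges = unlist(l$charges), eps = unlist(l$eps),
            sigma = unlist(l$sigma), alpha_shift = l$alpha_shift)
}

#' Write an EVB system definition to a YAML configuration file
#'
#' Serializes the atoms, the two diabatic states (bond/angle terms,
#' charges, Lennard-Jones parameters, gas-phase shift), the coupling, the
#' region partition, and optionally the starting coordinates. The format
#' round-trips exactly through \code{\link{read_evb_config}}.
#'
#' @param topology an \code{\link{evb_topology}}.
#' @param file output path.
#' @param conformation optional n x 3 coordinate matrix stored alongside.
#' @return the file path, invisibly.
#' @export
write_evb_config <- function(topology, file, conformation = NULL) {
  cfg <- list(
    atoms = list(names = topology$atom_names, masses = topology$masses),
    evb_region = topology$evb_region,
    coupling_h12 = topology$h12,
    state1 = state_to_list(topology$state1),
    state2 = state_to_list(topology$state2))
  if (!is.null(conformation))
    cfg$coordinates <- apply(as.matrix(conformation), 1, function(r)
      as.list(unname(r)), simplify = FALSE)
  yaml::write_yaml(cfg, file, precision = 12)
  invisible(file)
}

#' Read an EVB system definition from a YAML configuration file
#'
#' @param file path written by \code{\link{write_evb_config}} (or hand
#'   authored to the same schema).
#' @return list with \code{topology} and \code{conformation} (NULL when
#'   the file stores no coordinates).
#' @export
read_evb_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  n <- length(cfg$atoms$names)
  topo <- evb_topology(unlist(cfg$atoms$names), unlist(cfg$atoms$masses),
                       state_from_list(cfg$state1, n),
                       state_from_list(cfg$state2, n),
                       cfg$coupling_h12,
                       evb_region = unlist(cfg$evb_region))
  conf <- if (!is.null(cfg$coordinates))
    do.call(rbind, lapply(cfg$coordinates, unlist)) else NULL
  list(topology = topo, conformation = conf)
}
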
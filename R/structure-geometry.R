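#' Parse a PDB-format structure or multi-model trajectory
#'
#' Accepts raw PDB text (or a file path) containing ATOM/HETATM records,
#' optionally split into MODEL/ENDMDL blocks. Coordinate fields are
#' validated up front so malformed fixed-width records are reported with
#' their line number; the actual record parsing is done by bio3d.
#'
#' @param pdb_text a character scalar of PDB text, a character vector of
#'   lines, or a path to a .pdb file.
#' @return object of class \code{structure_ensemble}: \code{atoms}
#'   (data.frame with elety, resid, chain, resno), \code{coords}
#'   (n_frames x 3n matrix, A), \code{n_atoms}, \code{n_frames}.
#' @export
parse_structure <- function(pdb_text) {
  lines <- if (length(pdb_text) == 1 && !grepl("\n", pdb_text) &&
               file.exists(pdb_text)) readLines(pdb_text)
           else unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("parse error: no ATOM/HETATM records found")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error at line ", i, ": record shorter than coordinate fields")
    for (f in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, f[1], f[2])))
      if (is.na(v))
        stop("parse error at line ", i, ": non-numeric coordinate field '",
             trimws(substr(ln, f[1], f[2])), "'")
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  multi <- any(grepl("^MODEL", lines))
  pdb <- bio3d::read.pdb(tf, multi = multi, verbose = FALSE)
  coords <- if (is.matrix(pdb$xyz)) unclass(pdb$xyz) else
    matrix(as.numeric(pdb$xyz), nrow = 1)
  structure(list(atoms = pdb$atom[, c("elety", "resid", "chain", "resno")],
                 coords = coords, n_atoms = nrow(pdb$atom),
                 n_frames = nrow(coords)),
            class = "structure_ensemble")
}

#' Write a structure ensemble as (multi-model) PDB text
#'
#' Round-trips with \code{\link{parse_structure}} on coordinates (to the
#' PDB's 3-decimal precision), atom names, residues and chains.
#'
#' @param x a \code{structure_ensemble}, or an n x 3 matrix (single frame),
#'   or an n_frames x 3n matrix of frames.
#' @param file optional path; when NULL the text is returned invisibly.
#' @param atoms optional data.frame like \code{structure_ensemble$atoms}
#'   when \code{x} is a bare matrix.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_structure <- function(x, file = NULL, atoms = NULL) {
  if (inherits(x, "structure_ensemble")) {
    coords <- x$coords
    atoms <- x$atoms
  } else {
    x <- as.matrix(x)
    coords <- if (ncol(x) == 3) matrix(t(x), nrow = 1) else x
  }
  n <- ncol(coords) / 3
  if (is.null(atoms))
    atoms <- data.frame(elety = sprintf("C%d", seq_len(n)), resid = "LIG",
                        chain = "A", resno = 1L, stringsAsFactors = FALSE)
  chain <- ifelse(is.na(atoms$chain), " ", atoms$chain)
  fmt_model <- function(fr) {
    vapply(seq_len(n), function(i) {
      nm <- atoms$elety[i]
      nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
              i, nm4, atoms$resid[i], chain[i], atoms$resno[i],
              coords[fr, 3 * i - 2], coords[fr, 3 * i - 1],
              coords[fr, 3 * i], 1, 0)
    }, "")
  }
  if (nrow(coords) == 1) {
    out <- c(fmt_model(1), "END")
  } else {
    out <- unlist(lapply(seq_len(nrow(coords)), function(fr)
      c(sprintf("MODEL     %4d", fr), fmt_model(fr), "ENDMDL")))
    out <- c(out, "END")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Donor-acceptor distance and donor-hydrogen-acceptor angle
#'
#' @param frame n x 3 coordinate matrix (A).
#' @param donor_idx,hydrogen_idx,acceptor_idx three distinct atom indices.
#' @return named numeric vector \code{c(distance =, angle =)}: the
#'   donor-acceptor distance (A) and the D-H...A angle at the hydrogen
#'   (degrees, in [0, 180]).
#' @export
donor_acceptor_geometry <- function(frame, donor_idx, hydrogen_idx,
                                    acceptor_idx) {
  idx <- c(donor_idx, hydrogen_idx, acceptor_idx)
  if (anyDuplicated(idx)) stop("donor, hydrogen and acceptor must be distinct")
  frame <- as.matrix(frame)
  if (any(idx < 1 | idx > nrow(frame))) stop("atom index out of range")
  d <- frame[donor_idx, ]; h <- frame[hydrogen_idx, ]; a <- frame[acceptor_idx, ]
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosang <- min(1, max(-1, cosang))
  c(distance = sqrt(sum((d - a)^2)), angle = acos(cosang) * 180 / pi)
}

frames_matrix <- function(trajectory) {
  if (inherits(trajectory, "structure_ensemble")) return(trajectory$coords)
  if (is.list(trajectory) && !is.null(trajectory$coords))
    return(trajectory$coords)
  if (is.list(trajectory))
    return(do.call(rbind, lapply(trajectory, function(f) as.numeric(t(f)))))
  as.matrix(trajectory)
}

#' Ensemble donor-acceptor geometry statistics
#'
#' Measures the donor-acceptor distance and D-H...A angle on every frame and
#' aggregates to mean and standard deviation.
#'
#' @param trajectory frames as an n_frames x 3n matrix, a
#'   \code{structure_ensemble}, an \code{evb_trajectory}, or a list of
#'   n x 3 matrices.
#' @param indices length-3 integer vector (donor, hydrogen, acceptor).
#' @return object of class \code{geometry_summary}: \code{mean_DA_distance,
#'   sd_DA, mean_DHA_angle, sd_DHA, n_frames}, plus the per-frame series.
#' @export
ensemble_geometry <- function(trajectory, indices) {
  fm <- frames_matrix(trajectory)
  if (!nrow(fm)) stop("empty trajectory")
  meas <- t(vapply(seq_len(nrow(fm)), function(i)
    donor_acceptor_geometry(matrix(fm[i, ], ncol = 3, byrow = TRUE),
                            indices[1], indices[2], indices[3]),
    c(distance = 0, angle = 0)))
  structure(list(mean_DA_distance = mean(meas[, "distance"]),
                 sd_DA = if (nrow(fm) > 1) sd(meas[, "distance"]) else 0,
                 mean_DHA_angle = mean(meas[, "angle"]),
                 sd_DHA = if (nrow(fm) > 1) sd(meas[, "angle"]) else 0,
                 n_frames = nrow(fm),
                 distances = meas[, "distance"], angles = meas[, "angle"]),
            class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("D-A %.2f +/- %.2f A; D-H...A %.1f +/- %.1f deg (%d frames)\n",
              x$mean_DA_distance, x$sd_DA, x$mean_DHA_angle, x$sd_DHA,
              x$n_frames))
  invisible(x)
}

#' RMSD after optimal (Kabsch) superposition
#'
#' Centers both coordinate sets, finds the rotation minimizing the RMSD by
#' singular value decomposition (proper rotation enforced), and returns the
#' residual root-mean-square deviation.
#'
#' @param a,b n x 3 coordinate matrices with equal atom counts.
#' @return RMSD in A.
#' @export
rmsd_superposed <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("frames have unequal atom counts")
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ac %*% rot - bc)^2)))
}

#' Greedy RMSD-neighbor (Daura) clustering
#'
#' Computes all pairwise superposed RMSDs, repeatedly takes the frame with
#' the most neighbors within the cutoff as a cluster representative,
#' removes that cluster, and iterates. Ties are broken towards the lowest
#' frame index, making the partition deterministic.
#'
#' @param frames n_frames x 3n matrix, list of n x 3 matrices, or a
#'   \code{structure_ensemble}.
#' @param rmsd_cutoff neighbor cutoff (A, > 0).
#' @return list of clusters, each \code{list(representative =, members =)}
#'   with members sorted; cluster sizes are non-increasing and the clusters
#'   partition the frame set.
#' @export
daura_cluster <- function(frames, rmsd_cutoff) {
  if (rmsd_cutoff <= 0) stop("rmsd_cutoff must be positive")
  fm <- frames_matrix(frames)
  nf <- nrow(fm)
  if (!nf) stop("no frames to cluster")
  asfr <- function(i) matrix(fm[i, ], ncol = 3, byrow = TRUE)
  rm <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf)
      rm[i, j] <- rm[j, i] <- rmsd_superposed(asfr(i), asfr(j))
  }
  remaining <- seq_len(nf)
  clusters <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(rm[i, remaining] <= rmsd_cutoff), 0L)  # includes self
    center <- remaining[which.max(counts)]       # which.max -> lowest index tie-break
    members <- remaining[rm[center, remaining] <= rmsd_cutoff]
    clusters[[length(clusters) + 1L]] <-
      list(representative = center, members = sort(members))
    remaining <- setdiff(remaining, members)
  }
  clusters
}
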
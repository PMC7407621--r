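pdb_snippet <- paste(
  "ATOM      1  OD1 ASP A 229      10.000  20.000  30.000  1.00  0.00",
  "ATOM      2  H   LIG A 300      11.000  20.000  30.000  1.00  0.00",
  "HETATM    3  N1  LIG A 300      12.000  20.500  30.000  1.00  0.00",
  sep = "\n")

test_that("PDB parsing reads coordinates and flags malformed records", {
  s <- parse_structure(pdb_snippet)
  expect_equal(s$n_atoms, 3)
  expect_equal(s$n_frames, 1)
  expect_equal(as.numeric(s$coords[1, 1:3]), c(10, 20, 30))
  expect_equal(s$atoms$elety[1], "OD1")
  expect_equal(s$atoms$resno[3], 300)

  bad <- sub("11.000", "xx.abc", pdb_snippet)
  expect_error(parse_structure(bad), "line 2")
  expect_error(parse_structure("REMARK nothing"), "no ATOM")
})

test_that("write-then-parse round-trips coordinates, names and models", {
  s <- parse_structure(pdb_snippet)
  txt <- write_structure(s)
  back <- parse_structure(paste(txt, collapse = "\n"))
  expect_equal(back$coords, s$coords, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$atoms$elety, s$atoms$elety)

  # multi-model trajectory round-trip
  set.seed(14)
  coords <- matrix(round(rnorm(4 * 9, 0, 5), 3), 4, 9)
  txt <- write_structure(coords)
  back <- parse_structure(paste(txt, collapse = "\n"))
  expect_equal(back$n_frames, 4)
  expect_equal(back$coords, coords, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("donor-acceptor geometry matches vector algebra", {
  f <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  g <- donor_acceptor_geometry(f, 1, 2, 3)
  expect_equal(unname(g["distance"]), 2.0)
  expect_equal(unname(g["angle"]), 180.0)
  f <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(unname(donor_acceptor_geometry(f, 1, 2, 3)["angle"]), 90.0)
  expect_error(donor_acceptor_geometry(f, 1, 1, 3), "distinct")

  # random triplets against an independent implementation
  set.seed(15)
  for (i in 1:200) {
    f <- matrix(rnorm(9, 0, 3), 3, 3)
    g <- donor_acceptor_geometry(f, 1, 2, 3)
    d_or <- sqrt(sum((f[1, ] - f[3, ])^2))
    u <- f[1, ] - f[2, ]; v <- f[3, ] - f[2, ]
    a_or <- atan2(sqrt(sum(pracma::cross(u, v)^2)), sum(u * v)) * 180 / pi
    expect_equal(unname(g["distance"]), d_or, tolerance = 1e-9)
    expect_equal(unname(g["angle"]), a_or, tolerance = 1e-9)
    expect_true(g["angle"] >= 0 && g["angle"] <= 180)
  }
})

test_that("ensemble geometry aggregates per-frame measures", {
  f1 <- c(0, 0, 0, 1, 0, 0, 2, 0, 0)
  gs <- ensemble_geometry(rbind(f1, f1, f1), indices = 1:3)
  expect_equal(gs$sd_DA, 0)
  expect_equal(gs$mean_DA_distance, 2)
  expect_equal(gs$n_frames, 3)

  f2 <- c(0, 0, 0, 1, 0, 0, 4, 0, 0)
  gs <- ensemble_geometry(rbind(f1, f2), indices = 1:3)
  expect_equal(gs$mean_DA_distance, 3.0)

  # brute-force recomputation over random frames
  set.seed(16)
  fm <- matrix(rnorm(100 * 9, 0, 2), 100, 9)
  gs <- ensemble_geometry(fm, indices = 1:3)
  dd <- apply(fm, 1, function(r) sqrt(sum((r[1:3] - r[7:9])^2)))
  expect_equal(gs$mean_DA_distance, mean(dd), tolerance = 1e-12)
  expect_equal(gs$sd_DA, sd(dd), tolerance = 1e-12)
  expect_error(ensemble_geometry(fm[0, , drop = FALSE], 1:3), "empty")
})

test_that("superposed RMSD is a congruence-invariant metric", {
  set.seed(17)
  a <- matrix(rnorm(15, 0, 2), 5, 3)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  b <- a %*% R + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  expect_lt(rmsd_superposed(a, b), 1e-8)          # congruent -> 0
  c_ <- a + matrix(rnorm(15, 0, 0.3), 5, 3)
  expect_equal(rmsd_superposed(a, c_), rmsd_superposed(c_, a),
               tolerance = 1e-10)                  # symmetric
  expect_gt(rmsd_superposed(a, c_), 0)
  # agreement with the independent bio3d implementation (which prints 3 d.p.)
  expect_equal(rmsd_superposed(a, c_),
               bio3d::rmsd(as.numeric(t(a)), as.numeric(t(c_)), fit = TRUE),
               tolerance = 5e-3)
  expect_error(rmsd_superposed(a, a[1:3, ]), "unequal")
})

# independent greedy clustering oracle written against plain distance
# matrices (no shared code with the implementation)
oracle_daura <- function(rm, cutoff) {
  remaining <- seq_len(nrow(rm))
  out <- list()
  while (length(remaining)) {
    best <- NULL; bestn <- -1
    for (i in remaining) {
      ni <- sum(rm[i, remaining] <= cutoff)
      if (ni > bestn) { bestn <- ni; best <- i }
    }
    memb <- remaining[rm[best, remaining] <= cutoff]
    out[[length(out) + 1]] <- list(representative = best,
                                   members = sort(memb))
    remaining <- setdiff(remaining, memb)
  }
  out
}

test_that("Daura clustering matches the brute-force oracle and partitions frames", {
  # n identical frames -> one cluster of size n
  f <- matrix(rnorm(9), 1, 9)
  cl <- daura_cluster(f[rep(1, 6), ], rmsd_cutoff = 0.1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, 1:6)

  # cutoff below the minimum pairwise RMSD -> all singletons
  set.seed(18)
  fm <- matrix(rnorm(5 * 9, 0, 4), 5, 9)
  cl <- daura_cluster(fm, rmsd_cutoff = 1e-6)
  expect_length(cl, 5)

  # 8 frames in two planted blobs: equals the oracle partition
  base1 <- matrix(rnorm(12, 0, 3), 4, 3)
  base2 <- base1 + 6
  frames <- rbind(
    t(vapply(1:5, function(i) as.numeric(t(base1 + rnorm(12, 0, 0.05))), numeric(12))),
    t(vapply(1:3, function(i) as.numeric(t(base2 + rnorm(12, 0, 0.05))), numeric(12))))
  cl <- daura_cluster(frames, rmsd_cutoff = 1.0)
  rm_ <- matrix(0, 8, 8)
  for (i in 1:7) for (j in (i + 1):8)
    rm_[i, j] <- rm_[j, i] <- rmsd_superposed(matrix(frames[i, ], 4, 3, byrow = TRUE),
                                              matrix(frames[j, ], 4, 3, byrow = TRUE))
  orc <- oracle_daura(rm_, 1.0)
  expect_equal(lapply(cl, `[[`, "members"), lapply(orc, `[[`, "members"))

  # partition + non-increasing sizes over random inputs
  for (s in 1:5) {
    set.seed(30 + s)
    fm <- matrix(rnorm(7 * 9, 0, 2), 7, 9)
    cl <- daura_cluster(fm, rmsd_cutoff = runif(1, 0.5, 3))
    memb <- sort(unlist(lapply(cl, `[[`, "members")))
    expect_equal(memb, 1:7)
    sizes <- lengths(lapply(cl, `[[`, "members"))
    expect_true(all(diff(sizes) <= 0))
  }
  expect_error(daura_cluster(fm, -1), "positive")
})
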
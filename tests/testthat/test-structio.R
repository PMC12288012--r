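test_that("multi-model PDB files parse into frames x atoms, deterministically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.600   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.100   1.400   0.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  tr <- read_structures(f)
  expect_equal(n_frames(tr), 2)
  expect_equal(n_atoms(tr), 3)
  expect_equal(tr$atoms$atom_name, c("N", "CA", "C"))
  expect_equal(tr$atoms$residue_index, c(0L, 0L, 0L))
  expect_equal(tr$coords[2, 2, 1], 1.6)
  tr2 <- read_structures(f)
  expect_identical(tr$coords, tr2$coords)
})

test_that("trajectories round-trip through the multi-model PDB writer to format precision", {
  ens <- generate_ensemble(synthetic_spec(n_residues = 5, n_frames = 12, seed = 3,
                                          driver_indices = c(0L, 2L)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(ens$trajectory, f)
  back <- read_structures(f)
  expect_equal(n_frames(back), 12)
  expect_equal(n_atoms(back), 10)
  expect_lt(max(abs(back$coords - ens$trajectory$coords)), 1e-3)
  expect_equal(back$atoms$atom_name, ens$trajectory$atoms$atom_name)
  expect_equal(back$atoms$residue_index, ens$trajectory$atoms$residue_index)
})

test_that("atom selection follows chemistry, composes, and errors on empty matches", {
  tr <- gly_ala_traj()
  cb <- select_atoms(tr, "CB")
  expect_equal(n_atoms(cb), 1)           # glycine has no CB
  expect_equal(cb$atoms$residue_name, "ALA")
  two_step <- select_atoms(select_atoms(tr, c("CA", "CB")), "CA")
  direct <- select_atoms(tr, "CA")
  expect_identical(two_step$coords, direct$coords)
  all_names <- select_atoms(tr, unique(tr$atoms$atom_name))
  expect_identical(all_names$coords, tr$coords)
  expect_error(select_atoms(tr, "ZZ"), class = "rc_empty_selection")
})

test_that("alignment recovers rigid-body transforms and preserves internal geometry", {
  ref <- gly_ala_traj()
  R <- rot_z(0.8) %*% rot_y(-0.4)
  moved <- ref$coords[1, , ] %*% t(R)
  moved <- sweep(moved, 2, c(-5, 3, 12), `+`)
  tr <- make_traj(array(moved, dim = c(1, 7, 3)),
                  atom_name = ref$atoms$atom_name,
                  residue_index = ref$atoms$residue_index,
                  residue_name = ref$atoms$residue_name)
  fitted <- align_frames(tr, ref, recentre = FALSE)
  expect_lt(sqrt(mean((fitted$coords - ref$coords)^2)), 1e-8)

  # identity: aligning the reference to itself leaves coordinates unchanged
  self <- align_frames(ref, ref, recentre = FALSE)
  expect_lt(max(abs(self$coords - ref$coords)), 1e-12)

  # internal geometry is untouched by superposition
  noisy <- make_traj(array(ref$coords[1, , ] + matrix(rnorm(21, sd = 0.2), 7, 3),
                           dim = c(1, 7, 3)),
                     atom_name = ref$atoms$atom_name,
                     residue_index = ref$atoms$residue_index)
  ali <- align_frames(noisy, ref)
  expect_lt(max(abs(dist(ali$coords[1, , ]) - dist(noisy$coords[1, , ]))), 1e-9)

  expect_error(align_frames(tr, ref, backbone = "CB"),
               class = "rc_underdetermined_superposition")
})

test_that("least-squares superposition beats a brute-force rotation grid and reduces RMSD", {
  ref <- random_traj(1, 6, seed = 11)
  set.seed(12)
  nf <- 20
  coords <- array(0, dim = c(nf, 6, 3))
  for (f in seq_len(nf)) {
    R <- rot_z(runif(1, 0, 2 * pi)) %*% rot_y(runif(1, 0, pi))
    coords[f, , ] <- (ref$coords[1, , ] + matrix(rnorm(18, sd = 0.3), 6, 3)) %*% t(R) +
      matrix(rep(rnorm(3, sd = 5), each = 6), 6, 3)
  }
  tr <- make_traj(coords, atom_name = ref$atoms$atom_name)
  ali <- align_frames(tr, ref, backbone = "CA", recentre = FALSE)
  refc <- ref$coords[1, , ]

  rmsd_to_ref <- function(m) sqrt(mean(rowSums((m - refc)^2)))
  for (f in seq_len(nf)) {
    before <- rmsd_to_ref(sweep(coords[f, , ], 2,
                                colMeans(coords[f, , ]) - colMeans(refc)))
    expect_lte(rmsd_to_ref(ali$coords[f, , ]), before + 1e-9)
  }

  # brute-force oracle on one frame: no rotation on a 30-degree Euler grid
  # does better than the closed-form fit
  mobc <- sweep(coords[1, , ], 2, colMeans(coords[1, , ]))
  refq <- sweep(refc, 2, colMeans(refc))
  grid_best <- Inf
  for (a in seq(0, 2 * pi, by = pi / 6)) {
    for (b in seq(0, pi, by = pi / 6)) {
      for (cc in seq(0, 2 * pi, by = pi / 6)) {
        Rg <- rot_z(a) %*% rot_y(b) %*% rot_z(cc)
        grid_best <- min(grid_best, sqrt(mean(rowSums((mobc %*% t(Rg) - refq)^2))))
      }
    }
  }
  fit_rmsd <- sqrt(mean(rowSums((sweep(ali$coords[1, , ], 2,
                                       colMeans(ali$coords[1, , ])) - refq)^2)))
  expect_lte(fit_rmsd, grid_best + 1e-9)
})

test_that("RMSD matches closed forms and an explicit per-atom loop", {
  tr <- random_traj(8, 5, seed = 21)
  ref <- get_frame(tr, 1)
  r0 <- compute_rmsd(tr, ref)
  expect_identical(r0$values[1], 0)  # reference against itself

  shifted <- tr
  shifted$coords[, , 1] <- shifted$coords[, , 1] + 1
  expect_equal(compute_rmsd(shifted, ref)$values[1], 1.0, tolerance = 1e-12)

  # brute-force per-atom loop oracle
  loop <- sapply(seq_len(n_frames(tr)), function(f) {
    s <- 0
    for (a in seq_len(n_atoms(tr))) {
      s <- s + sum((tr$coords[f, a, ] - ref$coords[1, a, ])^2)
    }
    sqrt(s / n_atoms(tr))
  })
  expect_equal(r0$values, loop, tolerance = 1e-12)
  expect_error(compute_rmsd(tr, ref, atom_names = "CB"),
               class = "rc_empty_selection")
})

test_that("residue-pair distances resolve selectors and satisfy closed forms", {
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  tr <- make_traj(coords, atom_name = c("CA", "CA"),
                  residue_index = c(0L, 1L),
                  residue_name = c("ARG", "LEU"))
  d <- compute_pair_distance(tr, 0L, 1L)
  expect_equal(d$values, 5.0)          # 3-4-5 triangle
  expect_equal(compute_pair_distance(tr, 0L, 0L)$values, 0.0)
  # author-numbering selectors, with and without residue-name prefix
  expect_equal(compute_pair_distance(tr, "R1", "L2")$values, 5.0)
  expect_equal(compute_pair_distance(tr, "A:1", "2")$values, 5.0)
  expect_error(compute_pair_distance(tr, "R99", "L2"),
               class = "rc_selector_resolution")
  expect_error(compute_pair_distance(tr, 0L, 1L, atom_name = "CB"),
               class = "rc_selector_resolution")
})

test_that("frame sampling is deterministic, ordered, and approximately uniform", {
  tr <- random_traj(1000, 2, seed = 5)
  all_of_it <- sample_frames(tr, 1000, seed = 9)
  expect_identical(all_of_it$frame_ids, tr$frame_ids)  # identity, ascending
  s1 <- sample_frames(tr, 100, seed = 42)
  s2 <- sample_frames(tr, 100, seed = 42)
  expect_identical(s1$frame_ids, s2$frame_ids)
  expect_false(is.unsorted(s1$frame_ids))
  expect_error(sample_frames(tr, 1001, seed = 1),
               class = "rc_request_exceeds_supply")

  hits <- integer(1000)
  for (seed in 1:1000) {
    ids <- sample_frames(tr, 100, seed = seed)$frame_ids
    hits[ids] <- hits[ids] + 1L
  }
  freq <- hits / 1000
  expect_true(all(abs(freq - 0.1) <= 0.03))
})
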
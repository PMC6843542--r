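test_that("mean energy is the arithmetic mean", {
  expect_equal(mean_energy(c(1, 2, 3)), 2)
  expect_equal(mean_energy(rep(7.5, 40)), 7.5)
  e <- withr::with_seed(9, runif(1000))
  acc <- 0
  for (v in e) acc <- acc + v             # independent summation oracle
  expect_equal(mean_energy(e), acc / 1000, tolerance = 1e-12)
  expect_equal(mean_energy(xy_series(1:3, c(1, 2, 3))), 2)
  expect_error(mean_energy(numeric(0)), "empty")
})

test_that("frame RMSD evaluates the unaligned formula", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(frame_rmsd(a, a), 0)
  # single atom displaced by a 3-4-5 triangle
  expect_equal(frame_rmsd(matrix(0, 1, 3),
                          matrix(c(3, 4, 0), 1, 3)), 5)
  # two atoms both displaced 1 A along x
  b <- matrix(0, 2, 3); b2 <- b; b2[, 1] <- 1
  expect_equal(frame_rmsd(b, b2), 1)
  expect_error(frame_rmsd(matrix(0, 2, 3), matrix(0, 3, 3)), "atom count")
})

test_that("RMSD is a symmetric non-negative deviation with translation laws", {
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(24), 8, 3)
      expect_equal(frame_rmsd(a, b), frame_rmsd(b, a))
      expect_gte(frame_rmsd(a, b), 0)
      expect_equal(frame_rmsd(a, b), oracle_rmsd(a, b), tolerance = 1e-12)
      # translating both frames leaves RMSD unchanged
      t <- matrix(rnorm(3), 8, 3, byrow = TRUE)
      expect_equal(frame_rmsd(a + t, b + t), frame_rmsd(a, b), tolerance = 1e-12)
      # translating one copy of a frame by d gives RMSD exactly d
      d <- c(1, 2, 2)  # |d| = 3
      expect_equal(frame_rmsd(a, a + matrix(d, 8, 3, byrow = TRUE)), 3,
                   tolerance = 1e-12)
    }
  })
})

test_that("rmsd_series handles static, rigidly translated and random trajectories", {
  fs <- make_trajectory(n_atoms = 12, n_frames = 6, step_sd = 0, seed = 1)
  expect_true(all(rmsd_series(fs)$y == 0))

  base <- fs$coords[[1]]
  shifted <- frame_series(0:5, lapply(0:5, function(k) base + 2 * (k > 0)))
  r <- rmsd_series(shifted)
  expect_equal(r$y[1], 0)
  expect_equal(r$y[-1], rep(sqrt(12), 5), tolerance = 1e-12)  # 2 A on 3 axes

  walk <- make_trajectory(n_atoms = 10, n_frames = 8, step_sd = 0.7, seed = 3)
  r <- rmsd_series(walk)
  ref <- walk$coords[[1]]
  for (f in seq_along(walk$coords)) {
    expect_equal(r$y[f], oracle_rmsd(walk$coords[[f]], ref), tolerance = 1e-12)
  }
})

test_that("minimum distance matches the all-pairs oracle and is label-symmetric", {
  two <- frame_series(0, list(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)),
                      groups = c("A", "B"))
  expect_equal(min_distance_series(two, "A", "B")$y, 3)
  expect_equal(min_distance_series(two, "B", "A")$y,
               min_distance_series(two, "A", "B")$y)

  fs <- make_trajectory(n_atoms = 20, n_frames = 4, step_sd = 0.5,
                        groups = rep(c("pep", "lip"), each = 10), seed = 8)
  md <- min_distance_series(fs, "pep", "lip")
  for (f in seq_along(fs$coords)) {
    m <- fs$coords[[f]]
    expect_equal(md$y[f], oracle_min_dist(m[1:10, ], m[11:20, ]),
                 tolerance = 1e-12)
  }
  expect_error(min_distance_series(fs, "pep", "nope"), "unknown group")
})

test_that("XYZ trajectories round-trip through the reader", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame time = 0.0",
               "C 0.0 0.0 0.0", "N 1.0 0.0 0.0",
               "2", "frame time = 0.5",
               "C 0.5 0.0 0.0", "N 1.5 0.5 0.0"), p)
  fs <- read_xyz(p)
  expect_identical(length(fs$times), 2L)
  expect_equal(fs$times, c(0, 0.5))
  expect_identical(fs$groups, c("C", "N"))
  expect_equal(fs$coords[[2]][1, ], c(0.5, 0, 0))
})

test_that("Kabsch-aligned RMSD removes rigid rotations the plain metric keeps", {
  withr::with_seed(5, {
    a <- matrix(rnorm(30), 10, 3)
    th <- 0.8
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    b <- a %*% rot + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
    expect_gt(frame_rmsd(a, b), 1)
    expect_lt(kabsch_rmsd(a, b), 1e-9)
  })
})
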
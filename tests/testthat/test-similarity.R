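test_that("hamming distance counts differing positions", {
  alph <- state_alphabet(c("0", "1"))
  a <- state_profile(c(0L, 0L, 1L), alph, "a")
  b <- state_profile(c(0L, 1L, 1L), alph, "b")
  expect_equal(hamming(a, a), 0)
  expect_equal(hamming(a, b), 1)
  expect_equal(hamming(b, a), 1)
  ## complement of a binary profile is at distance L
  comp <- state_profile(1L - a$states, alph, "c")
  expect_equal(hamming(a, comp), 3)
  expect_error(hamming(a, state_profile(c(0L, 1L), alph)), "length")
  alph2 <- state_alphabet(c("x", "y"))
  expect_error(hamming(a, state_profile(c(0L, 1L, 1L), alph2)), "alphabet")
})

test_that("hamming satisfies the triangle inequality on random triples", {
  set.seed(71)
  for (rep in 1:20) {
    l <- sample(5:40, 1)
    s <- sample(2:6, 1)
    x <- sample(0:(s - 1), l, TRUE)
    y <- sample(0:(s - 1), l, TRUE)
    z <- sample(0:(s - 1), l, TRUE)
    expect_lte(hamming(x, y), hamming(x, z) + hamming(z, y))
  }
})

test_that("cosine distance is scale-invariant with known values", {
  a <- frequency_profile(c(1, 1))
  b <- frequency_profile(c(1, 0))
  expect_equal(cosine_distance(a, frequency_profile(c(2, 2))), 0,
               tolerance = 1e-12)
  expect_equal(cosine_distance(frequency_profile(c(1, 0)),
                               frequency_profile(c(0, 1))), 1)
  expect_equal(cosine_distance(a, b), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_distance(a, b), cosine_distance(b, a))
  expect_error(cosine_distance(a, frequency_profile(c(0, 0))), "all-zero")
})

test_that("Kabsch superposition is exact on rigid transforms", {
  set.seed(72)
  p <- matrix(rnorm(45), ncol = 3)
  expect_equal(kabsch_rmsd(p, p)$rmsd, 0, tolerance = 1e-12)
  for (rep in 1:10) {
    q <- apply_rigid(p)
    sup <- kabsch_rmsd(p, q)
    expect_lt(sup$rmsd, 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    ## invariance of the rmsd under a further rigid move of either side
    expect_lt(abs(kabsch_rmsd(apply_rigid(p), q)$rmsd - sup$rmsd), 1e-9)
  }
  expect_error(kabsch_rmsd(p[1:2, ], p[1:2, ]), "3 points")
  ## degenerate colinear sets still return a proper solution
  lin <- cbind(1:5, 0, 0)
  sup <- kabsch_rmsd(lin, apply_rigid(lin))
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("unit square vs doubled square gives rmsd sqrt(2)/2", {
  p <- matrix(c(-0.5, -0.5, 0, -0.5, 0.5, 0, 0.5, -0.5, 0, 0.5, 0.5, 0),
              ncol = 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(p, 2 * p)$rmsd, sqrt(2) / 2, tolerance = 1e-9)
})

test_that("Kabsch agrees with a rotation-grid oracle on 5-point sets", {
  ## exhaustive search over a dense Euler-angle grid can only do worse
  ## than the analytic optimum, and comes within 1e-3 of it
  set.seed(73)
  p <- matrix(rnorm(15), ncol = 3)
  q <- matrix(rnorm(15), ncol = 3)
  sup <- kabsch_rmsd(p, q)
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  euler_rmsd <- function(a, b, c) {
    rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    sqrt(mean(rowSums((p0 %*% (rz1 %*% ry %*% rz2) - q0)^2)))
  }
  ## coarse Euler grid, then two local refinements around the best cell
  ctr <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  steps <- 9
  best <- Inf
  for (level in 1:3) {
    ga <- seq(ctr[1] - span[1], ctr[1] + span[1], length.out = 2 * steps + 1)
    gb <- seq(ctr[2] - span[2], ctr[2] + span[2], length.out = steps + 1)
    gc <- seq(ctr[3] - span[3], ctr[3] + span[3], length.out = 2 * steps + 1)
    for (a in ga) for (b in gb) for (c in gc) {
      v <- euler_rmsd(a, b, c)
      if (v < best) {
        best <- v
        ctr <- c(a, b, c)
      }
    }
    span <- span / steps
  }
  expect_gte(best, sup$rmsd - 1e-9)   # analytic optimum is a lower bound
  expect_lt(best - sup$rmsd, 1e-3)    # and the refined grid approaches it
})

test_that("maxsub scores identity, displacement and bounds correctly", {
  set.seed(74)
  m <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(maxsub(m, m), 1, tolerance = 1e-12)
  ## one of 10 residues displaced 50 A: the other 9 superimpose exactly
  m2 <- m
  m2[4, ] <- m2[4, ] + c(50, 0, 0)
  expect_equal(maxsub(m2, m), 0.9, tolerance = 1e-9)
  ## random pairs stay within [0, 1]
  for (rep in 1:5) {
    a <- matrix(rnorm(36, sd = 4), ncol = 3)
    b <- matrix(rnorm(36, sd = 4), ncol = 3)
    v <- maxsub(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_error(maxsub(m, m[1:5, ]), "length")
})

test_that("maxsub never decreases as a residue deviation shrinks", {
  set.seed(75)
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  offsets <- c(6, 4, 2, 0.5, 0)
  scores <- vapply(offsets, function(off) {
    m <- base
    m[7, ] <- m[7, ] + c(off, 0, 0)
    maxsub(m, base)
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("distance matrices are consistent with their kernels", {
  set.seed(76)
  ps <- random_profiles(12, 18, 4)
  hm <- hamming_matrix(ps)
  for (rep in 1:5) {
    i <- sample(12, 1)
    j <- sample(12, 1)
    expect_equal(hm[i, j], hamming(ps$states[i, ], ps$states[j, ]))
  }
  fm <- matrix(rpois(8 * 5, 4) + 1, 8, 5)
  rownames(fm) <- paste0("f", 1:8)
  cm <- cosine_distance_matrix(fm)
  expect_equal(cm[2, 6], cosine_distance(fm[2, ], fm[6, ]),
               tolerance = 1e-12)
  f <- withr::local_tempfile()
  write_distance_matrix(hm, f)
  back <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(hm))
})
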
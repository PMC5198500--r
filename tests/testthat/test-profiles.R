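test_that("SS-SA composite encoding covers 30 states with H/E/C collapse", {
  ann <- protein_annotation(c("H", "C"), c(0, 1))
  p <- ss_sa_profile(ann)
  expect_equal(length(p$alphabet$states), 30)
  expect_equal(p$states, c(0L, 29L))  # (H, bin 0) first, (C, top bin) last
  ## 8-class collapse: G,I -> H; B -> E; T,S,- -> C
  ann2 <- protein_annotation(c("G", "I", "B", "T", "S", "-"), rep(0.5, 6))
  p2 <- ss_sa_profile(ann2, n_sa_bins = 2)
  expect_equal(p2$states %/% 2, c(0L, 0L, 1L, 2L, 2L, 2L))
  expect_error(ss_sa_profile(ann, n_sa_bins = 1), "n_sa_bins")
  bad <- protein_annotation(c("H"), c(0.5))
  bad$rsa <- 1.2
  expect_error(ss_sa_profile(bad), "residue 1")
})

test_that("composite state encodings are bijective", {
  ann <- protein_annotation(rep(c("H", "E", "C"), each = 10),
                            rep(seq(0.05, 0.95, by = 0.1), 3))
  p <- ss_sa_profile(ann)
  expect_equal(sort(p$states), 0:29)  # every composite state hit once
  expect_equal(encode_states(p$alphabet,
                             decode_states(p$alphabet, p$states)),
               p$states)
})

test_that("pseudo-secondary structure separates ideal helix and strand", {
  ph <- ca_ss_nc_profile(helix_trace(20))
  ss <- substr(decode_states(ph$alphabet, ph$states), 1, 1)
  expect_true(all(ss[1:17] == "H"))   # d(i, i+3) ~ 5.05 A < 6.0
  expect_true(all(ss[18:20] == "C"))  # terminal default
  pe <- ca_ss_nc_profile(extended_trace(20))
  sse <- substr(decode_states(pe$alphabet, pe$states), 1, 1)
  expect_true(all(sse[1:18] == "E"))  # d(i, i+2) = 7.6 A > 6.2
  expect_true(all(sse[19:20] == "C"))
  expect_error(ca_ss_nc_profile(helix_trace(4)), ">= 5")
})

test_that("contact numbers bin to zero for an isolated sparse trace", {
  tr <- cbind(seq(0, 80, by = 20), 0, 0)  # mutual distances >= 20 A
  p <- ca_ss_nc_profile(tr, contact_radius = 10)
  expect_true(all(p$states %% 10 == 0))  # nc bin 0 everywhere
})

test_that("contact-map profile follows the strict 8.5 A / |i-j| > 11 rule", {
  l <- 30
  tr <- extended_trace(l) * 0  # all points coincident, then move pairs
  tr <- matrix(0, l, 3)
  tr[, 1] <- (1:l) * 100  # far apart baseline
  ## place residues 1 and 13 at 8.4 A: state 1; 2 and 14 at 8.5: state 0
  tr[13, ] <- tr[1, ] + c(8.4, 0, 0)
  tr[14, ] <- tr[2, ] + c(8.5, 0, 0)
  p <- ca_cm_profile(tr)
  pairs <- attr(p, "pairs")
  expect_equal(p$states[pairs[, 1] == 1 & pairs[, 2] == 13], 1L)
  expect_equal(p$states[pairs[, 1] == 2 & pairs[, 2] == 14], 0L)
  ## separation 11 is not a profile position at all
  expect_false(any(pairs[, 2] - pairs[, 1] < 12))
})

test_that("contact-map enumeration matches exhaustive pair counting", {
  ## L = 14: exactly (1,13), (1,14), (2,14)
  p <- ca_cm_profile(template_trace(14, seed = 1))
  expect_equal(attr(p, "pairs"),
               cbind(i = c(1L, 1L, 2L), j = c(13L, 14L, 14L)),
               ignore_attr = TRUE)
  for (l in c(13, 20, 37, 60)) {
    exhaustive <- sum(outer(1:l, 1:l, function(i, j) j - i >= 12))
    expect_equal(length(ca_cm_profile(template_trace(l, seed = l))$states),
                 exhaustive)
    expect_equal(exhaustive, (l - 12) * (l - 11) / 2)
  }
  expect_error(ca_cm_profile(template_trace(12, seed = 1)), "length")
})

test_that("RNA P contact map uses the 15.5 A cutoff with strict inequality", {
  l <- 30
  tr <- matrix(0, l, 3)
  tr[, 1] <- (1:l) * 100
  tr[13, ] <- tr[1, ] + c(15.4, 0, 0)
  tr[14, ] <- tr[2, ] + c(15.5, 0, 0)
  p <- rna_p_cm_profile(tr)
  pairs <- attr(p, "pairs")
  expect_equal(p$states[pairs[, 1] == 1 & pairs[, 2] == 13], 1L)
  expect_equal(p$states[pairs[, 1] == 2 & pairs[, 2] == 14], 0L)
  ## all P atoms mutually farther than 15.5 A -> all-zero profile
  p0 <- rna_p_cm_profile(matrix(c((1:l) * 100, rep(0, 2 * l)), l, 3))
  expect_true(all(p0$states == 0L))
})

test_that("RNA annotation profiles use the documented composite encodings", {
  ra <- rna_annotation(c("stem", "loop", "loop"),
                       c("cWW", NA, "tHS"),
                       c("BI-anti", "other", "BII-syn"))
  lw <- rna_ss_lw_profile(ra)
  expect_equal(length(lw$alphabet$states), 30)
  expect_equal(lw$states[1], 0L)                      # (stem, label 0)
  expect_equal(lw$states[2], 15L + 14L)               # (loop, "Other")
  ta <- rna_ss_ta_profile(ra)
  expect_equal(length(ta$alphabet$states), 10)
  expect_equal(ta$states, c(0L, 5L + 4L, 5L + 3L))
  expect_error(rna_annotation("stem", "cXX"), "cWW")
  expect_error(rna_ss_ta_profile(rna_annotation("stem", "cWW")), "torsion")
})

test_that("profiles are invariant under rigid-body transformation", {
  set.seed(99)
  tr <- template_trace(30, seed = 9)
  lib <- tiny_library(5, 4, seed = 2)
  for (rep in 1:5) {
    tr2 <- apply_rigid(tr)
    expect_equal(ca_cm_profile(tr2)$states, ca_cm_profile(tr)$states)
    expect_equal(ca_ss_nc_profile(tr2)$states, ca_ss_nc_profile(tr)$states)
    expect_equal(fragbag_profile(tr2, lib)$counts,
                 fragbag_profile(tr, lib)$counts, tolerance = 0)
  }
})

test_that("fragbag assigns windows to nearest fragments and counts them", {
  lib <- tiny_library(6, 5, seed = 3)
  ## a trace that IS a rigid transform of fragment 4 -> count vector e_4
  tr <- apply_rigid(lib$fragments[[4]])
  expect_equal(fragbag_profile(tr, lib)$counts,
               c(0, 0, 0, 1, 0, 0))
  ## window count conservation: L - w + 1
  tr2 <- template_trace(21, seed = 4)
  lib11 <- tiny_library(8, 11, seed = 5)
  expect_equal(sum(fragbag_profile(tr2, lib11)$counts), 11)
  expect_error(fragbag_profile(template_trace(8, seed = 1), lib11),
               "window")
})

test_that("fragbag counts are permutation-covariant in the library", {
  set.seed(12)
  lib <- tiny_library(6, 4, seed = 6)
  tr <- template_trace(25, seed = 7)
  perm <- sample(6)
  lib_p <- fragment_library(lib$fragments[perm])
  c0 <- fragbag_profile(tr, lib)$counts
  cp <- fragbag_profile(tr, lib_p)$counts
  expect_equal(cp, c0[perm])
})
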
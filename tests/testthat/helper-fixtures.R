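## Shared fixtures and independent oracles used across the suite.

## ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, 100 deg/residue
helix_trace <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1))
}

## fully extended colinear chain with 3.8 A virtual bonds
extended_trace <- function(n, bond = 3.8) {
  cbind(bond * (seq_len(n) - 1), 0, 0)
}

## uniformly random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(x, rot = random_rotation(),
                        shift = stats::rnorm(3, sd = 20)) {
  x %*% rot + matrix(shift, nrow(x), 3, byrow = TRUE)
}

## random profile_set (plain uniform states, no planted structure)
random_profiles <- function(n, l, s, ids = sprintf("r%03d", seq_len(n))) {
  m <- matrix(sample(0:(s - 1), n * l, replace = TRUE), nrow = n)
  rownames(m) <- ids
  profile_set(m, state_alphabet(as.character(0:(s - 1)), "rand"), ids)
}

## explicit O(N^2 * L) pairwise match-count jury oracle
oracle_jury_scores <- function(states) {
  n <- nrow(states)
  vapply(seq_len(n), function(m) {
    sum(t(states) == states[m, ])
  }, numeric(1))
}

## brute-force cosine-sum jury oracle (explicit double loop)
oracle_cosine_scores <- function(m) {
  n <- nrow(m)
  u <- m / sqrt(rowSums(m^2))
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) s <- s + sum(u[i, ] * u[j, ])
    s
  }, numeric(1))
}

## direct unweighted average-linkage (UPGMA) oracle: recomputes every
## cluster-to-cluster distance as the mean over original member pairs and
## always merges the globally closest pair (lowest-index tie-break).
## Returns the cophenetic distance matrix, which identifies the dendrogram.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  act <- seq_len(n)
  sets <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  dd <- d
  diag(dd) <- Inf
  while (length(act) > 1) {
    sub <- dd[act, act, drop = FALSE]
    v <- min(sub)
    idx <- which(sub == v, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    a <- act[idx[1]]
    b <- act[idx[2]]
    coph[sets[[a]], sets[[b]]] <- v
    coph[sets[[b]], sets[[a]]] <- v
    newset <- c(sets[[a]], sets[[b]])
    for (x in setdiff(act, c(a, b))) {
      dd[a, x] <- dd[x, a] <- mean(d[newset, sets[[x]], drop = FALSE])
    }
    sets[[a]] <- newset
    act <- setdiff(act, b)
  }
  coph
}

cophenetic_of_tree <- function(tree) {
  hc <- as.hclust(tree)
  as.matrix(stats::cophenetic(hc))
}

## minimal fixed-column DSSP fixture writer
write_dssp_fixture <- function(path, aa, ss, acc) {
  mk <- function(i, a, s, ac) {
    paste0(formatC(i, width = 5), formatC(i, width = 5), " A ", a, "  ", s,
           strrep(" ", 17), formatC(ac, width = 4))
  }
  lines <- c("==== Secondary Structure Definition ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             mapply(mk, seq_along(aa), aa, ss, acc))
  writeLines(lines, path)
  path
}

## small random fragment library
tiny_library <- function(n_frag, w, seed = 1) {
  set.seed(seed)
  fragment_library(lapply(seq_len(n_frag),
                          function(i) matrix(stats::rnorm(3 * w, sd = 3),
                                             ncol = 3)),
                   name = "tiny")
}
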
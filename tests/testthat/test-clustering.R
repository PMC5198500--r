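test_that("hash clustering recovers noise-free planted groups exactly", {
  g <- generate_profile_set(60, 40, 4, 3, 0, seed = 2)
  sol <- hash_cluster(g$profiles, 3, 100)
  expect_equal(sol$coverage, 100)
  expect_length(sol$clusters, 3)
  expect_equal(rand_index(cluster_labels(sol, names(g$labels)), g$labels), 1)
  expect_equal(sol$params$positions_dropped, 0)
  ## centroids are members of their clusters
  for (cl in sol$clusters) expect_true(cl$centroid %in% cl$members)
})

test_that("hash with K = N on all-distinct keys returns singletons untouched", {
  set.seed(81)
  ps <- random_profiles(20, 30, 5)
  sol <- hash_cluster(ps, 20, 100)
  expect_equal(sol$coverage, 100)
  expect_true(all(lengths(lapply(sol$clusters, `[[`, "members")) == 1))
  expect_equal(sol$params$positions_dropped, 0)
  expect_error(hash_cluster(ps, 21, 100), "exceeds")
})

test_that("hash solutions keep coverage arithmetic exact and clusters disjoint", {
  g <- generate_profile_set(120, 50, 4, 4, 0.08, seed = 9)
  sol <- hash_cluster(g$profiles, 4, 70)
  members <- unname(unlist(lapply(sol$clusters, `[[`, "members")))
  expect_equal(anyDuplicated(members), 0)
  expect_equal(sol$coverage, 100 * length(members) / 120)
  expect_equal(sort(c(members, sol$unassigned)), sort(g$profiles$ids))
})

test_that("coarsening keys never shrinks the largest micro-cluster", {
  set.seed(82)
  g <- generate_profile_set(80, 25, 3, 3, 0.15, seed = 5)
  ps <- g$profiles
  keys <- make_hash_keys(ps)
  ref <- ps$states[match(keys$reference_id, ps$ids), ]
  ent <- key_entropy(keys)
  ord <- order(-ent, seq_along(ent))
  active <- rep(TRUE, profile_length(ps))
  prev_max <- 0
  for (k in seq_len(15)) {
    grp <- group_by_key(make_hash_keys(
      profile_set(ps$states[, active, drop = FALSE], ps$alphabet, ps$ids),
      reference = ref[active]))
    cur_max <- max(lengths(grp$members))
    expect_gte(cur_max, prev_max)
    prev_max <- cur_max
    active[ord[k]] <- FALSE
  }
})

test_that("rpart handles degenerate and planted inputs per contract", {
  ## all profiles identical: one populated cluster, K-1 empty, coverage 100
  alph <- state_alphabet(c("a", "b"))
  psi <- profile_set(matrix(1L, 8, 10), alph, paste0("m", 1:8))
  sol <- rpart_cluster(psi, 3, 100)
  expect_equal(sol$coverage, 100)
  sizes <- lengths(lapply(sol$clusters, `[[`, "members"))
  expect_equal(sizes, c(8L, 0L, 0L))
  ## D_max = 40 -> initial radius 10
  st <- rbind(rep(0L, 50), rep(0L, 50), c(rep(1L, 40), rep(0L, 10)))
  ps40 <- profile_set(st, alph, c("a", "b", "c"))
  sol40 <- rpart_cluster(ps40, 2, 100)
  expect_equal(sol40$params$d_max, 40)
  expect_equal(sol40$params$initial_radius, 10)
  ## planted fixture: centroids land in three distinct planted clusters
  g <- generate_profile_set(150, 60, 4, 3, 0.04, seed = 13)
  solp <- rpart_cluster(g$profiles, 3, 90)
  cents <- vapply(solp$clusters, `[[`, character(1), "centroid")
  expect_equal(sort(unique(g$labels[cents])), 1:3)
  expect_gte(rand_index(cluster_labels(solp, names(g$labels)), g$labels),
             0.95)
  expect_error(rpart_cluster(g$profiles, 151, 90), "exceeds")
})

test_that("tree with k_micro >= N on distinct profiles equals direct average linkage", {
  set.seed(83)
  for (rep in 1:5) {
    n <- sample(8:40, 1)
    ps <- random_profiles(n, sample(20:40, 1), sample(3:6, 1))
    if (anyDuplicated(ps$states)) next
    tr <- tree_cluster(ps, k_micro = 1000)
    expect_length(tr$leaves, n)
    coph <- cophenetic_of_tree(tr)[ps$ids, ps$ids]
    oracle <- oracle_upgma_cophenetic(hamming_matrix(ps))
    dimnames(oracle) <- list(ps$ids, ps$ids)
    expect_equal(coph, oracle, tolerance = 1e-9)
  }
})

test_that("in-package average linkage matches hclust on tie-free distances", {
  set.seed(84)
  for (rep in 1:5) {
    n <- sample(6:40, 1)
    x <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(x))
    lk <- average_linkage(d)
    expect_true(all(diff(lk$height) >= -1e-12))
    mine <- structure(list(merge = lk$merge, height = lk$height,
                           order = lk$order,
                           labels = as.character(seq_len(n)),
                           method = "average"), class = "hclust")
    ref <- hclust(as.dist(d), method = "average")
    ref$labels <- as.character(seq_len(n))
    expect_equal(as.matrix(cophenetic(mine)), as.matrix(cophenetic(ref)),
                 tolerance = 1e-9)
  }
})

test_that("tree cut at the planted count recovers conformer labels", {
  tpl <- template_trace(40, seed = 4)
  ens <- generate_ensemble(tpl, 3, 30, 8, 0.3, seed = 15)
  ps <- cm_profiles(ens$models)
  tr <- tree_cluster(ps, k_micro = 40)
  labs <- cut_dendrogram(tr, 3)
  expect_equal(rand_index(labs[names(ens$labels)], ens$labels), 1)
  ## leaf sizes conserve the number of models
  expect_equal(sum(vapply(tr$leaves, `[[`, integer(1), "size")),
               length(ens$labels))
})

test_that("dendrogram cutting follows merge heights", {
  ## chain of 3 leaves merged at heights 1 then 5: k = 2 splits at height 5
  d <- matrix(c(0, 1, 5, 1, 0, 5.2, 5, 5.2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  lk <- average_linkage(d)
  expect_equal(lk$height, c(1, 5.1))
  leaves <- lapply(c("a", "b", "c"), function(id)
    list(centroid = id, members = id, size = 1L))
  tree <- profclust:::pc_tree(lk, leaves, ids = c("a", "b", "c"),
                              distance = "hamming", weighted = FALSE)
  labs <- cut_dendrogram(tree, 2)
  expect_equal(labs[["a"]], labs[["b"]])
  expect_false(labs[["a"]] == labs[["c"]])
  expect_equal(length(unique(cut_dendrogram(tree, 1))), 1)
  expect_equal(length(unique(cut_dendrogram(tree, 3))), 3)
  expect_error(cut_dendrogram(tree, 4), "k must be")
})

test_that("k-medoids recovers well-separated groups from any seed", {
  g <- generate_profile_set(40, 30, 4, 2, 0.02, seed = 6)
  for (s in 1:10) {
    sol <- kmedoids_cluster(g$profiles, 2, seed = s)
    expect_equal(rand_index(cluster_labels(sol, names(g$labels)),
                            g$labels), 1)
  }
  ## K = N: every item its own medoid, zero cost
  ps <- random_profiles(7, 15, 4)
  soln <- kmedoids_cluster(ps, 7, seed = 1)
  expect_true(all(lengths(lapply(soln$clusters, `[[`, "members")) == 1))
  ## determinism for a fixed seed
  a <- kmedoids_cluster(g$profiles, 2, seed = 3)
  b <- kmedoids_cluster(g$profiles, 2, seed = 3)
  expect_identical(cluster_labels(a), cluster_labels(b))
  expect_error(kmedoids_cluster(ps, 8, seed = 1), "exceeds")
})

test_that("rand index matches pair enumeration and is symmetric", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  ## {12|34} vs all singletons: 4 of 6 pairs agree
  expect_equal(rand_index(c(1, 1, 2, 2), 1:4), 4 / 6)
  set.seed(85)
  a <- sample(3, 30, TRUE)
  b <- sample(4, 30, TRUE)
  expect_equal(rand_index(a, b), rand_index(b, a))
  expect_error(rand_index(1:3, 1:4), "length")
})

test_that("selection evaluation applies the MaxSub-gap and top-centroid rules", {
  g <- generate_profile_set(30, 20, 3, 3, 0, seed = 3)
  sol <- hash_cluster(g$profiles, 3, 100)
  quality <- stats::setNames(rep(0.3, 30), names(g$labels))
  quality[sol$clusters[[1]]$centroid] <- 0.50
  best_id <- setdiff(sol$clusters[[2]]$members,
                     sol$clusters[[2]]$centroid)[1]
  quality[best_id] <- 0.65
  ev <- evaluate_selection(sol, quality, mode = "maxsub_gap", top_n = 1,
                           gap = 0.2)
  expect_true(ev$good)  # 0.65 - 0.50 = 0.15 < 0.2
  ev2 <- evaluate_selection(sol, quality, mode = "maxsub_gap", top_n = 1,
                            gap = 0.1)
  expect_false(ev2$good)
  ## top model = best model: good for any gap >= 0
  jr <- jury_rank(g$profiles)
  q2 <- stats::setNames(rep(0.1, 30), names(g$labels))
  q2[jr$reference_id] <- 0.9
  expect_true(evaluate_selection(jr, q2, gap = 0)$good)
  ## rmsd mode takes the minimum over the selected centroids
  q3 <- stats::setNames(rep(7.0, 30), names(g$labels))
  cents <- vapply(sol$clusters, `[[`, character(1), "centroid")
  q3[cents] <- c(6.1, 4.6, 7.0)
  expect_equal(evaluate_selection(sol, q3, mode = "rmsd_to_native",
                                  top_n = 3)$value, 4.6)
  expect_error(evaluate_selection(sol, q3[-1], mode = "rmsd_to_native"),
               "quality")
})

test_that("cluster TSV export lists members, centroids and unassigned", {
  g <- generate_profile_set(20, 15, 3, 2, 0.1, seed = 8)
  sol <- hash_cluster(g$profiles, 2, 60)
  f <- withr::local_tempfile()
  write_clusters(sol, f, header = "# hdr")
  tab <- utils::read.delim(f, skip = 1)
  expect_equal(sort(tab$model_id), sort(names(g$labels)))
  expect_equal(sum(tab$is_centroid),
               sum(vapply(sol$clusters,
                          function(c) length(c$members) > 0, logical(1))))
})
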
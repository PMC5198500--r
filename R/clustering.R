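## Clustering heuristics over hashed profiles: entropy-driven key
## coarsening (hash_cluster), reference-based partitioning
## (rpart_cluster), approximate hierarchical clustering over micro-cluster
## centroids (tree_cluster) and a k-medoids baseline, plus partition
## comparison and model-quality evaluation utilities.

cluster_solution <- function(clusters, n, unassigned, params, method) {
  cov <- 100 * sum(lengths(lapply(clusters, `[[`, "members"))) / n
  structure(list(clusters = clusters, coverage = cov,
                 unassigned = unassigned, params = params,
                 n_models = n, method = method),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  sizes <- vapply(x$clusters, function(c) length(c$members), integer(1))
  cat("Cluster solution (", x$method, "): ", sum(sizes > 0),
      " non-empty clusters over ", x$n_models, " models; coverage ",
      format(x$coverage, digits = 4), "%\n", sep = "")
  cat("Cluster sizes:", paste(utils::head(sort(sizes, decreasing = TRUE),
                                          10), collapse = ", "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.cluster_solution <- function(object, ...) {
  print(object)
  if (length(object$unassigned)) {
    cat("Unassigned:", length(object$unassigned), "models\n")
  }
  invisible(object)
}

#' Cluster membership labels of a solution
#'
#' @param solution a \code{"cluster_solution"}.
#' @param ids model ids defining the output order (default: all assigned
#'   plus unassigned ids).
#' @return Named integer vector; unassigned models get label 0.
#' @export
cluster_labels <- function(solution, ids = NULL) {
  if (is.null(ids)) {
    ids <- c(unlist(lapply(solution$clusters, `[[`, "members")),
             solution$unassigned)
  }
  labels <- stats::setNames(integer(length(ids)), ids)
  for (k in seq_along(solution$clusters)) {
    labels[solution$clusters[[k]]$members] <- k
  }
  labels
}

## member with the maximal within-group 1D-jury score
group_centroid <- function(profiles, idx) {
  if (length(idx) == 1) return(profiles$ids[idx])
  jury_rank(subset_profiles(profiles, idx))$reference_id
}

## ---- Hash(K, F) ----------------------------------------------------------

#' Hashing-based clustering by key coarsening (Hash(K, F))
#'
#' Slices the data into micro-clusters of identical consensus-referenced
#' hash keys, then coarsens key granularity until the K largest groups
#' hold at least F percent of the models: positions are removed from the
#' key in order of decreasing bit entropy (the most variable positions
#' first, ties to the lowest position index), regrouping after each
#' removal.  If the target is never reached the best coverage seen is
#' returned.  Cluster centroids are the members with maximal within-group
#' 1D-jury score.
#'
#' @param profiles a \code{\link{profile_set}} with N >= K models.
#' @param K target cluster count.
#' @param F target coverage percentage in (0, 100]; compared with a
#'   0.5-point tolerance.
#' @return A \code{"cluster_solution"}; \code{params} records the dropped
#'   key positions.
#' @export
hash_cluster <- function(profiles, K, F = 100) {
  n <- n_models(profiles)
  check_kf(K, F, n)
  keys <- make_hash_keys(profiles)
  ent <- key_entropy(keys)
  drop_order <- order(-ent, seq_along(ent))
  bits <- keys$bits
  active <- rep(TRUE, ncol(bits))
  best <- NULL
  n_dropped <- 0
  repeat {
    idx <- group_rows(bits[, active, drop = FALSE])
    sizes <- lengths(idx)
    top <- order(-sizes, seq_along(sizes))[seq_len(min(K, length(idx)))]
    cov <- 100 * sum(sizes[top]) / n
    if (is.null(best) || cov > best$cov + 1e-9) {
      best <- list(cov = cov, groups = idx[top], dropped = n_dropped)
    }
    if (cov >= F - 0.5) break
    remaining <- drop_order[active[drop_order]]
    if (!length(remaining) || ent[remaining[1]] == 0) break
    active[remaining[1]] <- FALSE
    n_dropped <- n_dropped + 1
  }
  clusters <- lapply(best$groups, function(g) {
    list(members = profiles$ids[g],
         centroid = group_centroid(profiles, g))
  })
  assigned <- unlist(lapply(best$groups, identity))
  cluster_solution(clusters, n,
                   unassigned = profiles$ids[setdiff(seq_len(n), assigned)],
                   params = list(K = K, F = F,
                                 positions_dropped = best$dropped,
                                 reference_id = keys$reference_id),
                   method = "hash")
}

## row indices grouped by identical bit pattern, first-appearance order
group_rows <- function(bits) {
  if (!ncol(bits)) return(list(seq_len(nrow(bits))))
  ks <- key_strings(bits)
  grp <- match(ks, unique(ks))
  idx <- split(seq_along(grp), grp)
  idx[order(as.integer(names(idx)))]
}

check_kf <- function(K, F, n) {
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of models (", n, ")")
  if (F <= 0 || F > 100) stop("F must be in (0, 100]")
  invisible(NULL)
}

## ---- Rpart(K, F) ---------------------------------------------------------

#' Reference-based partitioning (Rpart(K, F))
#'
#' Represents all profiles as binary hash keys against the 1D-jury
#' reference and grows up to K spheres of the current clustering radius in
#' Hamming-key space: the first is centred on the reference; each next
#' centre is the unassigned model of highest (global) 1D-jury score among
#' those within twice the pass radius of the original reference (falling
#' back to all unassigned models when that shell is empty, so K clusters
#' stay reachable).  Because every unassigned model lies beyond the pass
#' radius from the original reference, resetting a new sphere's radius to
#' its centre's reference distance can never tighten it below the pass
#' radius; the pass radius itself is used throughout, which keeps
#' well-separated equidistant clusters from being swallowed by one
#' sphere.  An outer integer bisection over the radius -- started at one
#' quarter of the maximum key distance -- finds the smallest radius whose
#' K spheres cover at least F percent of the data (best coverage seen is
#' returned when F is unreachable).
#'
#' @param profiles a \code{\link{profile_set}} with N >= K models.
#' @param K target cluster count (empty trailing clusters are reported,
#'   not an error).
#' @param F target coverage percentage in (0, 100]; 0.5-point tolerance.
#' @return A \code{"cluster_solution"}; \code{params} records
#'   \code{d_max}, \code{initial_radius} and the selected
#'   \code{final_radius}.
#' @export
rpart_cluster <- function(profiles, K, F = 100) {
  n <- n_models(profiles)
  check_kf(K, F, n)
  jr <- jury_rank(profiles)
  scores <- unname(jr$scores)
  ref_row <- match(jr$reference_id, profiles$ids)
  keys <- make_hash_keys(profiles, reference = jr$reference_id)
  bits <- keys$bits
  bnum <- matrix(as.numeric(bits), n, ncol(bits))
  rs <- rowSums(bnum)
  d0 <- as.integer(rs)  # Hamming distance of every key to the reference key
  d_max <- max(d0)
  r_init <- as.integer(ceiling(d_max / 4))

  ham_to <- function(pattern) {
    ## Hamming distance of every key to a given bit pattern
    as.integer(rs + sum(pattern) - 2 * as.numeric(bnum %*% pattern))
  }

  run_pass <- function(r) {
    assign <- integer(n)
    unassigned <- rep(TRUE, n)
    cur_pattern <- as.numeric(bits[ref_row, ])
    refs <- integer(0)
    cur_ref <- ref_row
    for (k in seq_len(K)) {
      if (!any(unassigned)) break
      d <- ham_to(cur_pattern)
      sel <- unassigned & (d <= r)
      sel[cur_ref] <- sel[cur_ref] | unassigned[cur_ref]
      assign[sel] <- k
      unassigned[sel] <- FALSE
      refs[k] <- cur_ref
      if (!any(unassigned)) break
      cand <- which(unassigned & (d0 < 2 * r))
      if (!length(cand)) cand <- which(unassigned)
      cur_ref <- cand[which.max(scores[cand])]
      cur_pattern <- as.numeric(bits[cur_ref, ])
    }
    list(assign = assign, refs = refs,
         cov = 100 * sum(assign > 0) / n, r = r)
  }

  lo <- 0L
  hi <- d_max
  r <- min(max(r_init, lo), hi)
  best_ok <- NULL   # smallest radius reaching F
  best_any <- NULL  # highest coverage seen
  n_passes <- 0
  repeat {
    res <- run_pass(r)
    n_passes <- n_passes + 1
    if (is.null(best_any) || res$cov > best_any$cov + 1e-9) best_any <- res
    if (res$cov >= F - 0.5) {
      if (is.null(best_ok) || res$r < best_ok$r) best_ok <- res
      hi <- r - 1L
    } else {
      lo <- r + 1L
    }
    if (lo > hi) break
    r <- (lo + hi) %/% 2L
  }
  res <- if (!is.null(best_ok)) best_ok else best_any
  clusters <- lapply(seq_len(K), function(k) {
    g <- which(res$assign == k)
    if (!length(g)) return(list(members = character(0),
                                centroid = NA_character_))
    list(members = profiles$ids[g], centroid = group_centroid(profiles, g))
  })
  cluster_solution(clusters, n,
                   unassigned = profiles$ids[res$assign == 0],
                   params = list(K = K, F = F, d_max = d_max,
                                 initial_radius = r_init,
                                 final_radius = res$r,
                                 passes = n_passes,
                                 reference_id = jr$reference_id),
                   method = "rpart")
}

## ---- Tree ----------------------------------------------------------------

#' Approximate hierarchical clustering over micro-cluster centroids (Tree)
#'
#' Seeds micro-clusters with \code{\link{rpart_cluster}} or
#' \code{\link{hash_cluster}} at a large K (\code{k_micro}, default 1000)
#' and full coverage, computes the 1D-jury centroid of each micro-cluster,
#' and applies traditional unweighted average-linkage agglomeration to the
#' centroid-to-centroid distances (Hamming on state profiles, cosine on
#' frequency profiles, or Kabsch RMSD on coordinates).  When the ensemble
#' is much larger than \code{k_micro} the overall work is linear in the
#' number of models plus quadratic only in \code{k_micro}.  With
#' \code{k_micro >= N} and all profiles distinct every model is its own
#' leaf and the result equals full average-linkage hierarchical
#' clustering.
#'
#' @param profiles a \code{\link{profile_set}} (Hamming or RMSD distance)
#'   or a frequency-profile matrix/list (cosine distance; hashing operates
#'   on its \code{\link{quantize_frequency}} discretisation).
#' @param distance \code{"hamming"}, \code{"cosine"} or \code{"rmsd"}.
#' @param k_micro target number of micro-clusters (default 1000).
#' @param seeding micro-clustering heuristic, \code{"rpart"} (default) or
#'   \code{"hash"}.
#' @param models a \code{\link{model_set}}, required for
#'   \code{distance = "rmsd"} (centroid structures are superimposed).
#' @param atom backbone atom for RMSD traces.
#' @param weighted use micro-cluster sizes as linkage weights (default
#'   FALSE: unweighted over centroids).
#' @return A \code{"profclust_tree"} (see \code{\link{cut_dendrogram}}).
#' @export
tree_cluster <- function(profiles,
                         distance = c("hamming", "cosine", "rmsd"),
                         k_micro = 1000, seeding = c("rpart", "hash"),
                         models = NULL, atom = "CA", weighted = FALSE) {
  distance <- match.arg(distance)
  seeding <- match.arg(seeding)
  freq <- NULL
  if (distance == "cosine") {
    if (inherits(profiles, "profile_set")) {
      stop("tree_cluster: cosine distance requires frequency profiles")
    }
    freq <- freq_matrix(profiles)
    seed_profiles <- quantize_frequency(freq)
  } else {
    if (!inherits(profiles, "profile_set")) {
      stop("tree_cluster: ", distance,
           " distance requires a profile_set (state profiles)")
    }
    seed_profiles <- profiles
  }
  if (distance == "rmsd" && !inherits(models, "model_set")) {
    stop("tree_cluster: rmsd distance requires a model_set with coordinates")
  }
  n <- n_models(seed_profiles)
  kk <- min(k_micro, n)
  sol <- if (seeding == "rpart") rpart_cluster(seed_profiles, kk, 100)
         else hash_cluster(seed_profiles, kk, 100)
  groups <- Filter(function(c) length(c$members) > 0, sol$clusters)
  members <- lapply(groups, `[[`, "members")
  ## any model of the seeding pass that stayed unassigned becomes a
  ## singleton leaf so that leaves always partition the models
  members <- c(members, as.list(sol$unassigned))
  ## canonical leaf order (first member's input position) so that linkage
  ## tie-breaks do not depend on the seeding heuristic's discovery order
  members <- members[order(vapply(members, function(m)
    match(m[1], seed_profiles$ids), integer(1)))]

  leaves <- lapply(members, function(mem) {
    cent <- if (length(mem) == 1) {
      mem
    } else if (distance == "cosine") {
      jury_rank_frequency(freq[mem, , drop = FALSE])$reference_id
    } else {
      idx <- match(mem, seed_profiles$ids)
      group_centroid(seed_profiles, idx)
    }
    list(centroid = cent, members = mem, size = length(mem))
  })
  cent_ids <- vapply(leaves, `[[`, character(1), "centroid")
  d <- switch(distance,
    hamming = hamming_matrix(subset_profiles(seed_profiles,
                                             match(cent_ids,
                                                   seed_profiles$ids))),
    cosine = cosine_distance_matrix(freq[cent_ids, , drop = FALSE]),
    rmsd = rmsd_matrix(extract_traces(
      model_set(models$models[cent_ids]), atom), ids = cent_ids))
  sizes <- vapply(leaves, `[[`, integer(1), "size")
  linkage <- average_linkage(d, weights = if (weighted) sizes else NULL)
  pc_tree(linkage, leaves, ids = seed_profiles$ids, distance = distance,
          weighted = weighted)
}

## ---- k-medoids baseline --------------------------------------------------

#' K-medoids clustering (PAM-style baseline)
#'
#' Alternating assignment/update k-medoids over an explicit distance
#' matrix -- the metric-space analogue of K-means used as a baseline
#' comparator (RMSD and Hamming admit no coordinate mean).  Deterministic
#' for a fixed seed; ties in assignment and medoid updates resolve to the
#' lowest index.
#'
#' @param x a \code{\link{profile_set}} (\code{distance = "hamming"}), a
#'   frequency matrix/list (\code{"cosine"}), a \code{\link{model_set}}
#'   (\code{"rmsd"}), or a precomputed square distance matrix with
#'   dimnames (\code{distance} ignored).
#' @param K number of medoids, \code{K <= N}.
#' @param distance \code{"hamming"}, \code{"cosine"} or \code{"rmsd"}.
#' @param seed integer seed for the initial medoid draws.
#' @param max_iter iteration cap per restart (default 100).
#' @param nstart number of seeded random restarts; the solution of lowest
#'   total within-cluster distance is kept (default 10, the usual guard
#'   against poor local optima of alternating k-medoids).
#' @param atom backbone atom for RMSD traces.
#' @return A \code{"cluster_solution"} with coverage 100 and medoid
#'   centroids.
#' @export
kmedoids_cluster <- function(x, K, distance = c("hamming", "cosine", "rmsd"),
                             seed = 1, max_iter = 100, nstart = 10,
                             atom = "CA") {
  distance <- match.arg(distance)
  if (is.matrix(x) && nrow(x) == ncol(x) && !is.null(rownames(x)) &&
      identical(rownames(x), colnames(x))) {
    d <- x
  } else if (inherits(x, "profile_set")) {
    d <- hamming_matrix(x)
  } else if (inherits(x, "model_set")) {
    d <- rmsd_matrix(extract_traces(x, atom), ids = x$ids)
  } else {
    d <- cosine_distance_matrix(x)
  }
  n <- nrow(d)
  ids <- rownames(d)
  check_kf(K, 100, n)
  one_run <- function(run_seed) {
    med <- with_seed(run_seed, sort(sample.int(n, K)))
    for (it in seq_len(max_iter)) {
      assign <- max.col(-d[, med, drop = FALSE], ties.method = "first")
      new_med <- vapply(seq_len(K), function(k) {
        mem <- which(assign == k)
        if (!length(mem)) return(med[k])
        mem[which.min(colSums(d[mem, mem, drop = FALSE]))]
      }, integer(1))
      if (identical(new_med, med)) break
      med <- new_med
    }
    assign <- max.col(-d[, med, drop = FALSE], ties.method = "first")
    list(med = med, assign = assign,
         cost = sum(d[cbind(seq_len(n), med[assign])]))
  }
  runs <- lapply(seq_len(max(1, nstart)) - 1L, function(s) one_run(seed + s))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  med <- best$med
  assign <- best$assign
  clusters <- lapply(seq_len(K), function(k) {
    list(members = ids[assign == k], centroid = ids[med[k]])
  })
  cluster_solution(clusters, n, unassigned = character(0),
                   params = list(K = K, distance = distance, seed = seed),
                   method = "kmedoids")
}

## ---- partition comparison and MQA evaluation -----------------------------

#' Rand index between two partitions
#'
#' Fraction of item pairs on which the two labelings agree (co-clustered
#' in both or separated in both); 1 for identical partitions.
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   items.
#' @return Numeric in [0, 1].
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("rand_index: label vectors differ in length (",
         length(labels_a), " vs ", length(labels_b), ")")
  }
  n <- length(labels_a)
  if (n < 2) return(1)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(tab^2)
  sum_a <- sum(rowSums(tab)^2)
  sum_b <- sum(colSums(tab)^2)
  total <- choose(n, 2)
  disagree <- (sum_a + sum_b) / 2 - sum_ij
  (total - disagree) / total
}

#' Evaluate a model selection against per-model quality values
#'
#' For clustering solutions the selected models are the centroids of the
#' \code{top_n} largest clusters; for jury rankings the single top-ranked
#' model.  In \code{"maxsub_gap"} mode the selection is flagged good when
#' its best quality is within \code{gap} of the best quality in the whole
#' set (e.g. within 0.2 MaxSub of the best model); in
#' \code{"rmsd_to_native"} mode the returned value is the minimum quality
#' (RMSD to native) over the selected centroids.
#'
#' @param solution a \code{"cluster_solution"} or \code{"jury_result"}.
#' @param quality named numeric vector of per-model quality values
#'   covering all referenced ids.
#' @param mode \code{"maxsub_gap"} or \code{"rmsd_to_native"}.
#' @param top_n number of largest-cluster centroids considered (default 5).
#' @param gap quality gap for \code{"maxsub_gap"} (default 0.2).
#' @return List with \code{selected}, \code{value} (best or minimum
#'   quality over the selection) and, in gap mode, \code{best_overall}
#'   and logical \code{good}.
#' @export
evaluate_selection <- function(solution, quality,
                               mode = c("maxsub_gap", "rmsd_to_native"),
                               top_n = 5, gap = 0.2) {
  mode <- match.arg(mode)
  if (inherits(solution, "jury_result")) {
    selected <- solution$reference_id
  } else if (inherits(solution, "cluster_solution")) {
    sizes <- vapply(solution$clusters, function(c) length(c$members),
                    integer(1))
    keep <- order(-sizes, seq_along(sizes))
    keep <- keep[sizes[keep] > 0]
    keep <- keep[seq_len(min(top_n, length(keep)))]
    selected <- vapply(solution$clusters[keep], `[[`, character(1),
                       "centroid")
  } else {
    stop("evaluate_selection: need a cluster_solution or jury_result")
  }
  miss <- setdiff(selected, names(quality))
  if (length(miss)) {
    stop("evaluate_selection: no quality value for model '", miss[1], "'")
  }
  q <- quality[selected]
  if (mode == "maxsub_gap") {
    best_overall <- max(quality)
    list(mode = mode, selected = selected, value = max(q),
         best_overall = best_overall,
         good = max(q) >= best_overall - gap)
  } else {
    list(mode = mode, selected = selected, value = min(q))
  }
}

#' Write a cluster solution as TSV
#'
#' Columns: model_id, cluster_id (0 = unassigned), is_centroid.
#'
#' @param solution a \code{"cluster_solution"}.
#' @param path output file.
#' @param header optional comment line(s).
#' @return Invisibly, \code{path}.
#' @export
write_clusters <- function(solution, path, header = NULL) {
  rows <- list()
  for (k in seq_along(solution$clusters)) {
    cl <- solution$clusters[[k]]
    if (!length(cl$members)) next
    rows[[length(rows) + 1]] <-
      data.frame(model_id = cl$members, cluster_id = k,
                 is_centroid = cl$members == cl$centroid,
                 stringsAsFactors = FALSE)
  }
  if (length(solution$unassigned)) {
    rows[[length(rows) + 1]] <-
      data.frame(model_id = solution$unassigned, cluster_id = 0,
                 is_centroid = FALSE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
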
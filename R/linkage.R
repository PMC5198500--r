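## In-package average-linkage agglomerator (Lance-Williams updates with a
## cached row-minimum search and a deterministic lowest-index tie-break),
## plus the dendrogram container produced by tree_cluster and its cutting.

#' Average-linkage agglomerative clustering of a distance matrix
#'
#' Bottom-up agglomeration under the (optionally weighted) average-linkage
#' Lance-Williams update.  With unit weights this is unweighted average
#' linkage over the items (each leaf counts once, as used for
#' micro-cluster centroids); passing micro-cluster sizes as \code{weights}
#' gives the size-weighted variant.  The next merge is always the globally
#' closest active pair, with ties broken towards the lowest item indices,
#' so results are fully deterministic; merge heights are non-decreasing.
#'
#' @param d square symmetric distance matrix.
#' @param weights optional per-item weights (default all 1).
#' @return List with \code{merge} (hclust convention), \code{height} and
#'   \code{order}.
#' @export
average_linkage <- function(d, weights = NULL) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (k == 1) {
    return(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                order = 1L))
  }
  w <- if (is.null(weights)) rep(1, k) else as.numeric(weights)
  storage.mode(d) <- "double"
  diag(d) <- Inf
  active <- rep(TRUE, k)
  id <- -seq_len(k)
  merge <- matrix(0L, k - 1, 2)
  height <- numeric(k - 1)
  rowmin <- apply(d, 1, min)
  rowarg <- apply(d, 1, which.min)  # first minimum -> lowest index
  for (m in seq_len(k - 1)) {
    act_all <- which(active)
    i <- act_all[which.min(rowmin[act_all])]
    j <- rowarg[i]
    height[m] <- d[i, j]
    merge[m, ] <- c(id[i], id[j])
    act <- act_all[act_all != i & act_all != j]
    newd <- (w[i] * d[i, act] + w[j] * d[j, act]) / (w[i] + w[j])
    d[i, act] <- newd
    d[act, i] <- newd
    d[i, i] <- Inf
    d[j, ] <- Inf
    d[, j] <- Inf
    active[j] <- FALSE
    w[i] <- w[i] + w[j]
    id[i] <- m
    if (length(act)) {
      rowmin[i] <- min(d[i, act])
      rowarg[i] <- act[which.min(d[i, act])]
      for (x in act) {
        if (rowarg[x] == i || rowarg[x] == j) {
          rowmin[x] <- min(d[x, ])
          rowarg[x] <- which.min(d[x, ])
        } else if (d[x, i] < rowmin[x] ||
                   (d[x, i] == rowmin[x] && i < rowarg[x])) {
          rowmin[x] <- d[x, i]
          rowarg[x] <- i
        }
      }
    }
  }
  list(merge = merge, height = height, order = tree_leaf_order(merge))
}

## leaf order by depth-first traversal of the merge tree (iterative)
tree_leaf_order <- function(merge) {
  m <- nrow(merge)
  if (!m) return(1L)
  ord <- integer(m + 1)
  pos <- 0L
  stack <- integer(2 * m + 1)
  stack[1] <- m
  top <- 1L
  while (top > 0L) {
    node <- stack[top]
    top <- top - 1L
    if (node < 0) {
      pos <- pos + 1L
      ord[pos] <- -node
    } else {
      top <- top + 1L
      stack[top] <- merge[node, 2]
      top <- top + 1L
      stack[top] <- merge[node, 1]
    }
  }
  ord
}

pc_tree <- function(linkage, leaves, ids, distance, weighted) {
  structure(list(merge = linkage$merge, height = linkage$height,
                 order = linkage$order,
                 labels = vapply(leaves, `[[`, character(1), "centroid"),
                 leaves = leaves, ids = ids, distance = distance,
                 weighted = weighted),
            class = "profclust_tree")
}

#' @export
print.profclust_tree <- function(x, ...) {
  cat("Approximate hierarchical clustering:", length(x$leaves),
      "micro-cluster leaves over", length(x$ids), "models;",
      x$distance, "distance, average linkage\n")
  if (length(x$height)) {
    cat("Merge heights:", format(min(x$height), digits = 4), "..",
        format(max(x$height), digits = 4), "\n")
  }
  invisible(x)
}

#' @export
as.hclust.profclust_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = x$distance),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges; each surviving subtree is one
#' cluster and every model inherits the label of its micro-cluster leaf.
#'
#' @param tree a \code{"profclust_tree"} from \code{\link{tree_cluster}}.
#' @param k number of clusters, \code{1 <= k <= } number of leaves.
#' @return Named integer vector of cluster labels for all models, in the
#'   model order of the profile set the tree was built from.
#' @export
cut_dendrogram <- function(tree, k) {
  nl <- length(tree$leaves)
  if (k < 1 || k > nl) {
    stop("cut_dendrogram: k must be in 1..", nl, " (got ", k, ")")
  }
  leaf_lab <- if (nl == 1) 1L else stats::cutree(as.hclust(tree), k = k)
  labels <- integer(length(tree$ids))
  names(labels) <- tree$ids
  for (l in seq_len(nl)) {
    labels[tree$leaves[[l]]$members] <- leaf_lab[l]
  }
  labels
}

#' Export a dendrogram as Newick
#'
#' Leaf labels are \code{centroidID_size}; branch lengths derive from the
#' average-linkage merge heights.  An optional '#'-prefixed header line
#' (skipped by \code{\link{read_newick_line}}) can carry run metadata.
#'
#' @param tree a \code{"profclust_tree"}.
#' @param path output file.
#' @param header optional comment line(s) written before the tree.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path, header = NULL) {
  labs <- vapply(tree$leaves, function(l) paste0(l$centroid, "_", l$size),
                 character(1))
  nl <- length(labs)
  if (nl == 1) {
    nwk <- paste0("(", labs[1], ":0);")
  } else {
    hc <- as.hclust(tree)
    hc$labels <- labs
    if (requireNamespace("ape", quietly = TRUE)) {
      ph <- ape::as.phylo(hc)
      nwk <- ape::write.tree(ph)
    } else {
      nwk <- hclust_to_newick(hc)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(nwk, con)
  invisible(path)
}

## minimal newick serialiser used when ape is unavailable
hclust_to_newick <- function(hc) {
  node_str <- function(node, parent_h) {
    if (node < 0) {
      paste0(hc$labels[-node], ":", format(parent_h, digits = 10))
    } else {
      h <- hc$height[node]
      paste0("(", node_str(hc$merge[node, 1], h / 2), ",",
             node_str(hc$merge[node, 2], h / 2), "):",
             format(max(parent_h - h, 0) , digits = 10))
    }
  }
  m <- nrow(hc$merge)
  h <- hc$height[m]
  paste0("(", node_str(hc$merge[m, 1], h / 2), ",",
         node_str(hc$merge[m, 2], h / 2), ");")
}

#' Read the Newick line of a file written by \code{\link{write_newick}}
#'
#' Skips '#' comment lines and returns the first Newick string.
#'
#' @param path file.
#' @return Character scalar Newick string.
#' @export
read_newick_line <- function(path) {
  lines <- readLines(path)
  lines[!grepl("^#", lines) & nzchar(lines)][1]
}
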
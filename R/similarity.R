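## Distance kernels between profiles and between 3D structures.

#' Hamming distance between two state profiles
#'
#' Number of positions at which two equal-length state vectors differ.
#'
#' @param a,b state profiles (see \code{\link{state_profile}}) or plain
#'   integer/character vectors of equal length.
#' @return Integer count in \code{0..L}.
#' @examples
#' hamming(c(0L, 0L, 1L), c(0L, 1L, 1L))
#' @export
hamming <- function(a, b) {
  av <- profile_states(a)
  bv <- profile_states(b)
  if (length(av) != length(bv)) {
    stop("hamming: profiles have different lengths (", length(av), " vs ",
         length(bv), ")")
  }
  check_same_alphabet(a, b)
  sum(av != bv)
}

#' Cosine distance between two frequency profiles
#'
#' \code{1 - a.b / (|a||b|)}; scale-invariant, in \code{[0, 1]} for
#' non-negative count vectors.
#'
#' @param a,b frequency profiles (\code{\link{frequency_profile}}) or
#'   numeric vectors of equal dimension; neither may be all-zero.
#' @return Numeric distance.
#' @examples
#' cosine_distance(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(a, b) {
  av <- freq_counts(a)
  bv <- freq_counts(b)
  if (length(av) != length(bv)) {
    stop("cosine_distance: dimension mismatch (", length(av), " vs ",
         length(bv), ")")
  }
  na <- sqrt(sum(av^2))
  nb <- sqrt(sum(bv^2))
  if (na == 0) stop("cosine_distance: first vector is all-zero")
  if (nb == 0) stop("cosine_distance: second vector is all-zero")
  1 - sum(av * bv) / (na * nb)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping \code{p}
#' onto \code{q}.  Reflections are excluded by the usual determinant sign
#' correction so that physical chirality is preserved.
#'
#' @param p,q numeric matrices of matching dimension (n x 3, n >= 3), one
#'   point per row, coordinates in Angstrom.
#' @return An object of class \code{"superposition"}: a list with
#'   \code{rotation} (3 x 3, det = +1), \code{translation} (length-3) and
#'   \code{rmsd} (Angstrom).  The transform maps row vectors of \code{p} as
#'   \code{p \%*\% rotation + translation}.
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' kabsch_rmsd(p, p)$rmsd  # 0
#' @export
kabsch_rmsd <- function(p, q) {
  p <- as_coord_matrix(p)
  q <- as_coord_matrix(q)
  if (nrow(p) != nrow(q)) {
    stop("kabsch_rmsd: point counts differ (", nrow(p), " vs ", nrow(q), ")")
  }
  if (nrow(p) < 3) stop("kabsch_rmsd: need at least 3 points")
  cp <- colMeans(p)
  cq <- colMeans(q)
  p0 <- sweep(p, 2, cp)
  q0 <- sweep(q, 2, cq)
  h <- crossprod(p0, q0)
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  dev <- p0 %*% rot - q0
  res <- list(
    rotation = rot,
    translation = as.numeric(cq - cp %*% rot),
    rmsd = sqrt(mean(rowSums(dev^2)))
  )
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: rmsd =", format(x$rmsd, digits = 6), "Angstrom\n")
  invisible(x)
}

## deviations of each point of p from q after superimposing p[idx,] on q[idx,]
superpose_deviations <- function(p, q, idx) {
  sup <- kabsch_rmsd(p[idx, , drop = FALSE], q[idx, , drop = FALSE])
  aligned <- p %*% sup$rotation +
    matrix(sup$translation, nrow(p), 3, byrow = TRUE)
  sqrt(rowSums((aligned - q)^2))
}

#' MaxSub structure similarity score
#'
#' Size of the largest subset of residues of \code{model} superimposable on
#' \code{reference} within a distance threshold, scored as
#' \code{sum_{i in M} 1 / (1 + (d_i/d0)^2) / L}.  Every contiguous window of
#' \code{seed_len} residues seeds an iterative extension: the threshold grows
#' linearly to \code{d0} over \code{refine_iters} rounds, re-superimposing on
#' the selected subset each round; the best-scoring subset over all seeds is
#' kept.
#'
#' @param model,reference n x 3 coordinate matrices of equal length
#'   \code{L >= seed_len}.
#' @param d0 distance threshold in Angstrom (default 3.5).
#' @param seed_len length of the contiguous seed segments (default 4).
#' @param refine_iters number of threshold-growing refinement rounds
#'   (default 4).
#' @return Score in \code{[0, 1]}; 1 for identical structures.
#' @export
maxsub <- function(model, reference, d0 = 3.5, seed_len = 4,
                   refine_iters = 4) {
  model <- as_coord_matrix(model)
  reference <- as_coord_matrix(reference)
  l <- nrow(model)
  if (nrow(reference) != l) {
    stop("maxsub: length mismatch (", l, " vs ", nrow(reference), ")")
  }
  if (l < seed_len) stop("maxsub: structures shorter than seed_len")
  if (seed_len < 3) stop("maxsub: seed_len must be >= 3")
  best <- 0
  for (s in seq_len(l - seed_len + 1)) {
    m <- s:(s + seed_len - 1)
    for (j in seq_len(refine_iters)) {
      dev <- superpose_deviations(model, reference, m)
      thr <- d0 * j / refine_iters
      sel <- which(dev < thr)
      if (length(sel) < 3) break
      m <- sel
    }
    dev <- superpose_deviations(model, reference, m)
    keep <- m[dev[m] < d0]
    if (length(keep)) {
      sc <- sum(1 / (1 + (dev[keep] / d0)^2)) / l
      if (sc > best) best <- sc
    }
  }
  best
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("expected an n x 3 coordinate matrix")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  storage.mode(x) <- "double"
  x
}

#' Full pairwise Hamming distance matrix of a profile set
#'
#' Computed per state via cross-products of indicator matrices, so large
#' sets stay in BLAS rather than an R-level double loop.
#'
#' @param profiles a \code{\link{profile_set}}.
#' @return Symmetric integer N x N matrix with model ids as dimnames.
#' @export
hamming_matrix <- function(profiles) {
  x <- profiles$states
  n <- nrow(x)
  l <- ncol(x)
  match_counts <- matrix(0, n, n)
  for (s in unique(as.vector(x))) {
    ind <- matrix(as.numeric(x == s), n, ncol(x))
    match_counts <- match_counts + tcrossprod(ind)
  }
  d <- l - match_counts
  d <- round(d)
  dimnames(d) <- list(profiles$ids, profiles$ids)
  d
}

#' Pairwise cosine distance matrix of frequency profiles
#'
#' @param x a numeric matrix (one profile per row) or list of
#'   \code{\link{frequency_profile}} objects.
#' @return Symmetric N x N matrix of \code{1 - cosine} distances.
#' @export
cosine_distance_matrix <- function(x) {
  m <- freq_matrix(x)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("cosine_distance_matrix: all-zero vector for model ",
         rownames(m)[which(nrm == 0)[1]])
  }
  u <- m / nrm
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Pairwise Kabsch RMSD matrix over backbone traces
#'
#' @param traces list of n x 3 coordinate matrices of equal length.
#' @param ids optional character ids used as dimnames.
#' @return Symmetric N x N matrix of RMSDs (Angstrom).
#' @export
rmsd_matrix <- function(traces, ids = names(traces)) {
  n <- length(traces)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- kabsch_rmsd(traces[[i]], traces[[j]])$rmsd
      }
    }
  }
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' Write a square pairwise distance matrix as TSV
#'
#' Row and column ids are preserved; used for inspection and by oracle
#' tests on small sets.
#'
#' @param d square numeric matrix with dimnames.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
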
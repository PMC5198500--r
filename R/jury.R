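## 1D-jury: linear-time implicit all-pairs consensus ranking.  The score of
## a model is the sum over profile positions of the number of models (self
## included) sharing its state there, i.e. the sum over all models of
## pairwise position-match counts -- computed in O(N*L) from the per-position
## state frequency table instead of an O(N^2) loop over pairs.

#' Per-position state frequency table
#'
#' \code{counts[p, s]} = number of models whose state at position p is
#' s - 1 (0-based state s); each row sums to N.  One pass over the data.
#'
#' @param profiles a \code{\link{profile_set}}.
#' @return Object of class \code{"state_frequency_table"}: list with
#'   \code{counts} (L x S integer matrix) and \code{n_models}.
#' @export
state_frequency_table <- function(profiles) {
  x <- profiles$states
  s <- alphabet_size(profiles$alphabet)
  counts <- vapply(0:(s - 1), function(st) .colSums(x == st, nrow(x),
                                                    ncol(x)),
                   numeric(ncol(x)))
  counts <- matrix(as.integer(counts), ncol = s,
                   dimnames = list(NULL, profiles$alphabet$states))
  structure(list(counts = counts, n_models = nrow(x)),
            class = "state_frequency_table")
}

#' @export
print.state_frequency_table <- function(x, ...) {
  cat("State frequency table:", nrow(x$counts), "positions x",
      ncol(x$counts), "states over", x$n_models, "models\n")
  invisible(x)
}

jury_result <- function(scores, ids) {
  ord <- order(-scores, seq_along(scores))  # ties broken by input order
  structure(list(scores = stats::setNames(scores, ids),
                 ranking = ids[ord],
                 reference_id = ids[ord[1]]),
            class = "jury_result")
}

#' @export
print.jury_result <- function(x, ...) {
  cat("1D-jury ranking of", length(x$scores), "models\n")
  cat("Reference (top):", x$reference_id, " score =",
      format(x$scores[[x$reference_id]], digits = 8), "\n")
  top <- utils::head(x$ranking, 5)
  cat("Top:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.jury_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' 1D-jury consensus ranking of state profiles
#'
#' \code{score(m) = sum_p counts[p, state_m(p)]}: the total number of
#' position-wise agreements of model m with all models (itself included),
#' in O(N*L) time and O(L*S + N) memory.  Equivalently
#' \code{score(m) = N*L - sum_m' Hamming(m, m')}.  The top-scoring model
#' (ties to earliest input order) is the consensus reference.
#'
#' @param profiles a \code{\link{profile_set}}.
#' @return Object of class \code{"jury_result"}: \code{scores} (named, in
#'   input order), \code{ranking} (ids by descending score) and
#'   \code{reference_id}.
#' @examples
#' ps <- profile_set(rbind(c(0L,0L), c(0L,0L), c(0L,1L)),
#'                   state_alphabet(c("a","b")))
#' jury_rank(ps)$scores  # 5, 5, 4
#' @export
jury_rank <- function(profiles) {
  x <- profiles$states
  n <- nrow(x)
  l <- ncol(x)
  counts <- state_frequency_table(profiles)$counts
  ## linear (column-major) index of counts[p, state + 1] is p + state * L
  idx <- as.vector(x * l + rep(seq_len(l), each = n))
  scores <- .rowSums(matrix(counts[idx], n, l), n, l)
  jury_result(scores, profiles$ids)
}

#' 1D-jury ranking of frequency profiles
#'
#' Generalisation to fixed-dimension frequency (bag-of-fragments)
#' profiles: \code{score(m)} is the sum of cosine similarities of model m
#' to all models (self included), computed in O(N*D) as the dot product of
#' the unit-normalised vector with the accumulated sum of all unit
#' vectors.
#'
#' @param vectors numeric matrix (one profile per row) or list of
#'   \code{\link{frequency_profile}} objects; no all-zero rows.
#' @return A \code{"jury_result"} with real-valued scores.
#' @export
jury_rank_frequency <- function(vectors) {
  m <- freq_matrix(vectors)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("jury_rank_frequency: all-zero vector for model ",
         rownames(m)[which(nrm == 0)[1]])
  }
  u <- m / nrm
  total <- colSums(u)
  scores <- as.numeric(u %*% total)
  jury_result(scores, rownames(m))
}

#' Write a jury ranking as TSV
#'
#' Columns: rank, model_id, jury_score.
#'
#' @param jury a \code{"jury_result"}.
#' @param path output file.
#' @param header optional comment line(s) written before the table.
#' @return Invisibly, \code{path}.
#' @export
write_ranking <- function(jury, path, header = NULL) {
  tab <- data.frame(rank = seq_along(jury$ranking),
                    model_id = jury$ranking,
                    jury_score = unname(jury$scores[jury$ranking]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
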
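## Consensus-referenced binary profile hashing: each model's key marks the
## positions where its profile disagrees with the 1D-jury reference
## profile, so the key popcount equals the Hamming distance to the
## reference and models sharing a key form a micro-cluster.

#' Binary hash keys against a reference profile
#'
#' Bit p of model m's key is 0 iff model m's state at position p equals
#' the reference state (1 otherwise); the reference's own key is all
#' zeros, and the number of ones in any key equals the model's Hamming
#' distance from the reference profile.  Keys are exact bit patterns --
#' equality is exact, no locality-sensitive approximation.
#'
#' @param profiles a \code{\link{profile_set}}.
#' @param reference a \code{\link{state_profile}} (same length and
#'   alphabet), an integer state vector, or a model id present in
#'   \code{profiles}; defaults to the 1D-jury reference.
#' @return Object of class \code{"hash_keys"}: \code{bits} (N x L logical
#'   matrix), \code{ids}, \code{reference_id}.
#' @export
make_hash_keys <- function(profiles, reference = NULL) {
  x <- profiles$states
  ref_id <- NA_character_
  if (is.null(reference)) {
    ref_id <- jury_rank(profiles)$reference_id
    ref <- x[match(ref_id, profiles$ids), ]
  } else if (inherits(reference, "state_profile")) {
    if (!identical(reference$alphabet$states, profiles$alphabet$states)) {
      stop("make_hash_keys: reference uses a different alphabet")
    }
    ref <- reference$states
    ref_id <- reference$model_id
  } else if (is.character(reference) && length(reference) == 1 &&
             reference %in% profiles$ids) {
    ref_id <- reference
    ref <- x[match(reference, profiles$ids), ]
  } else {
    ref <- as.integer(reference)
  }
  if (length(ref) != ncol(x)) {
    stop("make_hash_keys: reference length ", length(ref),
         " does not match profile length ", ncol(x))
  }
  bits <- x != matrix(ref, nrow(x), ncol(x), byrow = TRUE)
  rownames(bits) <- profiles$ids
  structure(list(bits = bits, ids = profiles$ids, reference_id = ref_id),
            class = "hash_keys")
}

#' @export
print.hash_keys <- function(x, ...) {
  cat("Hash keys:", nrow(x$bits), "models x", ncol(x$bits),
      "bit positions; reference:", x$reference_id, "\n")
  invisible(x)
}

## compact string form of each key (packed bits, hex), used for exact
## grouping
key_strings <- function(bits) {
  l <- ncol(bits)
  pad <- (-l) %% 8
  apply(bits, 1L, function(r) {
    paste(packBits(c(r, rep(FALSE, pad)), type = "raw"), collapse = "")
  })
}

#' Quantize a frequency profile into discrete count bins
#'
#' Maps each per-dimension count to its bin index via ascending integer
#' bin edges (bin 0 holds zero counts; edges must start at 1).  The
#' default edges 1, 2, 4, 8 give bins 0, 1, 2-3, 4-7, >= 8.  Quantization
#' is monotone in the count.  This makes frequency (bag-of-fragments)
#' profiles hashable by \code{\link{make_hash_keys}}.
#'
#' @param x a \code{\link{frequency_profile}}, a numeric matrix (one
#'   profile per row) or a list of frequency profiles.
#' @param bin_edges ascending integer edges starting at 1.
#' @return A \code{\link{state_profile}} (single profile) or
#'   \code{\link{profile_set}} (matrix/list input).
#' @export
quantize_frequency <- function(x, bin_edges = c(1, 2, 4, 8)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("quantize_frequency: bin_edges must be strictly ascending")
  }
  if (bin_edges[1] != 1) {
    stop("quantize_frequency: bin_edges must start at 1 (bin 0 = zero count)")
  }
  alph <- state_alphabet(paste0("q", seq_len(length(bin_edges) + 1) - 1),
                         "quantized")
  if (inherits(x, "frequency_profile")) {
    return(state_profile(findInterval(x$counts, bin_edges), alph,
                         x$model_id))
  }
  m <- freq_matrix(x)
  states <- matrix(findInterval(m, bin_edges), nrow(m), ncol(m))
  rownames(states) <- rownames(m)
  profile_set(states, alph, rownames(m))
}

#' Group models into micro-clusters by identical hash key
#'
#' Exact bit-pattern grouping: group order follows first appearance,
#' member order follows input order; groups partition all models.
#'
#' @param keys a \code{"hash_keys"} object (see
#'   \code{\link{make_hash_keys}}).
#' @return Object of class \code{"micro_cluster_index"}: \code{members}
#'   (list of character id vectors), \code{patterns} (packed key strings),
#'   \code{reference_id}.
#' @export
group_by_key <- function(keys) {
  ks <- key_strings(keys$bits)
  grp <- match(ks, unique(ks))
  members <- split(keys$ids, grp)
  members <- members[order(as.integer(names(members)))]
  names(members) <- NULL
  structure(list(members = members,
                 patterns = unique(ks),
                 reference_id = keys$reference_id),
            class = "micro_cluster_index")
}

#' @export
print.micro_cluster_index <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("Micro-cluster index:", length(x$members), "groups over",
      sum(sizes), "models; largest group =", max(sizes), "\n")
  invisible(x)
}

#' Per-position entropy of hash keys
#'
#' Shannon entropy (bits) of the 0/1 split at each key position across
#' all models, with 0 log 0 = 0; constant positions score 0 and balanced
#' positions 1.  High-entropy positions are the most variable and are the
#' ones removed first when coarsening keys in \code{\link{hash_cluster}}.
#'
#' @param keys a \code{"hash_keys"} object.
#' @return Numeric vector of length L.
#' @export
key_entropy <- function(keys) {
  f <- colMeans(keys$bits)
  plogp <- function(p) ifelse(p > 0, -p * log2(p), 0)
  unname(plogp(f) + plogp(1 - f))
}

#' Export hash keys as TSV
#'
#' Columns: model_id, bitstring (e.g. "0100110...").
#'
#' @param keys a \code{"hash_keys"} object.
#' @param path output file.
#' @param header optional comment line(s).
#' @return Invisibly, \code{path}.
#' @export
write_keys <- function(keys, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines("model_id\tbitstring", con)
  bitstr <- apply(keys$bits, 1, function(r) paste(as.integer(r),
                                                  collapse = ""))
  writeLines(paste(keys$ids, bitstr, sep = "\t"), con)
  invisible(path)
}
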
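## Core containers: alphabets, state profiles, profile sets, frequency
## profiles.  State indices are stored 0-based (0..S-1) so that composite
## encodings read as ss_index * n_bins + bin; labels are used at the I/O
## boundary only.

#' Discrete state alphabet
#'
#' @param states character vector of unique state labels (length >= 2).
#' @param name short alphabet name.
#' @return Object of class \code{"state_alphabet"}.
#' @export
state_alphabet <- function(states, name = "custom") {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("state_alphabet: duplicate state labels")
  if (length(states) < 2) stop("state_alphabet: need at least 2 states")
  structure(list(name = name, states = states), class = "state_alphabet")
}

#' @export
print.state_alphabet <- function(x, ...) {
  cat("Alphabet '", x$name, "': ", length(x$states), " states\n", sep = "")
  invisible(x)
}

alphabet_size <- function(a) length(a$states)

#' Encode state labels as 0-based indices
#'
#' @param alphabet a \code{\link{state_alphabet}}.
#' @param labels character vector of state labels.
#' @return Integer vector in \code{0..S-1}.
#' @export
encode_states <- function(alphabet, labels) {
  idx <- match(as.character(labels), alphabet$states)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown state label(s) ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(alphabet$states, collapse = ", "))
  }
  idx - 1L
}

#' Decode 0-based state indices to labels
#'
#' @param alphabet a \code{\link{state_alphabet}}.
#' @param states integer vector in \code{0..S-1}.
#' @return Character vector of labels.
#' @export
decode_states <- function(alphabet, states) {
  s <- as.integer(states)
  if (any(s < 0 | s >= alphabet_size(alphabet))) {
    stop("state index out of range 0..", alphabet_size(alphabet) - 1)
  }
  alphabet$states[s + 1L]
}

binary_alphabet <- function() state_alphabet(c("0", "1"), "binary")

#' Single-model state profile
#'
#' @param states integer vector of 0-based state indices.
#' @param alphabet a \code{\link{state_alphabet}}.
#' @param model_id model identifier.
#' @return Object of class \code{"state_profile"}.
#' @export
state_profile <- function(states, alphabet, model_id = "model") {
  states <- as.integer(states)
  if (!length(states)) stop("state_profile: empty profile")
  if (any(states < 0 | states >= alphabet_size(alphabet))) {
    stop("state_profile: state index outside 0..",
         alphabet_size(alphabet) - 1)
  }
  structure(list(model_id = model_id, alphabet = alphabet, states = states),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat("State profile '", x$model_id, "': L = ", length(x$states),
      ", alphabet '", x$alphabet$name, "' (S = ",
      alphabet_size(x$alphabet), ")\n", sep = "")
  invisible(x)
}

profile_states <- function(x) {
  if (inherits(x, "state_profile")) return(x$states)
  if (is.character(x)) return(x)
  as.integer(x)
}

check_same_alphabet <- function(a, b) {
  if (inherits(a, "state_profile") && inherits(b, "state_profile") &&
      !identical(a$alphabet$states, b$alphabet$states)) {
    stop("profiles use different alphabets ('", a$alphabet$name, "' vs '",
         b$alphabet$name, "')")
  }
  invisible(NULL)
}

#' Aligned set of state profiles
#'
#' N equal-length profiles over a shared alphabet, stored as an N x L
#' integer matrix of 0-based states.
#'
#' @param x a list of \code{\link{state_profile}} objects, or an integer
#'   matrix (one model per row, 0-based states).
#' @param alphabet required when \code{x} is a matrix.
#' @param ids model ids; defaults to the profiles' own ids or rownames.
#' @return Object of class \code{"profile_set"} with elements
#'   \code{states}, \code{alphabet}, \code{ids}.
#' @export
profile_set <- function(x, alphabet = NULL, ids = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!length(x)) stop("profile_set: empty profile list")
    lens <- vapply(x, function(p) length(p$states), integer(1))
    if (length(unique(lens)) != 1) {
      bad <- which(lens != lens[1])[1]
      stop("profile_set: profile '", x[[bad]]$model_id, "' has length ",
           lens[bad], ", expected ", lens[1])
    }
    alphabet <- x[[1]]$alphabet
    for (p in x) {
      if (!identical(p$alphabet$states, alphabet$states)) {
        stop("profile_set: profile '", p$model_id,
             "' uses a different alphabet")
      }
    }
    if (is.null(ids)) ids <- vapply(x, `[[`, character(1), "model_id")
    states <- do.call(rbind, lapply(x, `[[`, "states"))
  } else {
    states <- as.matrix(x)
    storage.mode(states) <- "integer"
    if (is.null(alphabet)) stop("profile_set: alphabet required for matrix input")
    if (is.null(ids)) ids <- rownames(states)
    if (is.null(ids)) ids <- paste0("m", seq_len(nrow(states)))
    if (any(states < 0 | states >= alphabet_size(alphabet))) {
      stop("profile_set: state index outside alphabet range")
    }
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("profile_set: duplicate model ids")
  if (length(ids) != nrow(states)) stop("profile_set: ids/rows mismatch")
  rownames(states) <- ids
  structure(list(states = states, alphabet = alphabet, ids = ids),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set: N = ", nrow(x$states), " models, L = ", ncol(x$states),
      ", alphabet '", x$alphabet$name, "' (S = ",
      alphabet_size(x$alphabet), ")\n", sep = "")
  invisible(x)
}

#' Number of models / profile length accessors
#' @param x a \code{\link{profile_set}}.
#' @return Integer.
#' @export
n_models <- function(x) nrow(x$states)

#' @rdname n_models
#' @export
profile_length <- function(x) ncol(x$states)

#' Extract one model's profile from a set
#'
#' @param x a \code{\link{profile_set}}.
#' @param id model id or integer row index.
#' @return A \code{\link{state_profile}}.
#' @export
get_profile <- function(x, id) {
  i <- if (is.character(id)) match(id, x$ids) else as.integer(id)
  if (is.na(i) || i < 1 || i > nrow(x$states)) {
    stop("get_profile: unknown model '", id, "'")
  }
  state_profile(x$states[i, ], x$alphabet, x$ids[i])
}

subset_profiles <- function(x, idx) {
  profile_set(x$states[idx, , drop = FALSE], x$alphabet, x$ids[idx])
}

#' Fixed-dimension fragment frequency profile
#'
#' Non-negative count vector of library-fragment assignments over all
#' backbone windows of one structure (bag-of-fragments encoding).
#'
#' @param counts non-negative integer vector of dimension D.
#' @param model_id model identifier.
#' @return Object of class \code{"frequency_profile"}.
#' @export
frequency_profile <- function(counts, model_id = "model") {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("frequency_profile: counts must be finite and non-negative")
  }
  structure(list(model_id = model_id, counts = counts),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("Frequency profile '", x$model_id, "': D = ", length(x$counts),
      ", total windows = ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

freq_counts <- function(x) {
  if (inherits(x, "frequency_profile")) return(x$counts)
  as.numeric(x)
}

## matrix (one row per model) from a list of frequency profiles or a matrix
freq_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("m", seq_len(nrow(m)))
    return(m)
  }
  if (is.list(x)) {
    dims <- vapply(x, function(f) length(freq_counts(f)), integer(1))
    if (length(unique(dims)) != 1) {
      stop("frequency profiles have differing dimensions")
    }
    m <- do.call(rbind, lapply(x, freq_counts))
    ids <- if (!is.null(names(x))) names(x) else
      vapply(x, function(f) if (inherits(f, "frequency_profile"))
        f$model_id else "", character(1))
    if (any(ids == "")) ids <- paste0("m", seq_along(x))
    rownames(m) <- ids
    return(m)
  }
  stop("expected a matrix or list of frequency profiles")
}
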
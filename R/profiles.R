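## 1D structural profiles: projections of 3D coordinates (or external
## per-residue annotations) into discrete state vectors, and the
## bag-of-fragments frequency projection.

## ---- SS-SA (DSSP-based secondary structure x solvent accessibility) ------

## 8-class DSSP secondary structure collapsed to helix/strand/coil
collapse_ss3 <- function(ss) {
  out <- rep("C", length(ss))
  out[ss %in% c("H", "G", "I")] <- "H"
  out[ss %in% c("E", "B")] <- "E"
  out
}

ss_sa_alphabet <- function(n_sa_bins) {
  state_alphabet(paste0(rep(c("H", "E", "C"), each = n_sa_bins),
                        rep(seq_len(n_sa_bins) - 1, 3)),
                 paste0("ss-sa", n_sa_bins))
}

#' Secondary structure / solvent accessibility profile (SS-SA)
#'
#' Collapses the 8-class DSSP secondary structure to \{H, E, C\}
#' (H,G,I -> H; E,B -> E; else C) and bins relative solvent accessibility
#' into \code{n_sa_bins} equal-width bins on [0, 1] (rsa = 1 falls in the
#' top bin).  The composite state is \code{ss_index * n_sa_bins + sa_bin}
#' with ss order H, E, C, for an alphabet of \code{3 * n_sa_bins} states
#' (30 at the default 10 accessibility bins).
#'
#' @param annotation a protein \code{\link{protein_annotation}} (per-residue
#'   DSSP \code{ss} and \code{rsa}).
#' @param n_sa_bins number of accessibility bins, 2..10 (default 10).
#' @param model_id id for the resulting profile.
#' @return A \code{\link{state_profile}}.
#' @export
ss_sa_profile <- function(annotation, n_sa_bins = 10, model_id = "model") {
  stopifnot(inherits(annotation, "residue_annotation"))
  if (annotation$kind != "protein") {
    stop("ss_sa_profile: protein annotation required")
  }
  if (n_sa_bins < 2 || n_sa_bins > 10) {
    stop("ss_sa_profile: n_sa_bins must be in 2..10")
  }
  rsa <- annotation$rsa
  bad <- which(rsa < 0 | rsa > 1)
  if (length(bad)) {
    stop("ss_sa_profile: rsa outside [0, 1] at residue ", bad[1])
  }
  ss3 <- collapse_ss3(annotation$ss)
  ss_idx <- match(ss3, c("H", "E", "C")) - 1L
  sa_bin <- pmin(floor(rsa * n_sa_bins), n_sa_bins - 1L)
  state_profile(ss_idx * n_sa_bins + sa_bin, ss_sa_alphabet(n_sa_bins),
                model_id)
}

## ---- CA(SS)-NC(SA): pseudo-secondary structure x contact number ----------

#' Pseudo-secondary-structure / contact-number profile (CA(SS)-NC(SA))
#'
#' A coordinate-only analogue of SS-SA usable for CA-only models.  Residue
#' i is labelled H when d(CA_i, CA_{i+3}) < 6.0 A, else E when
#' d(CA_i, CA_{i+2}) > 6.2 A, else C (chain-terminal residues default to
#' C); these thresholds separate ideal helix (d(i,i+3) ~ 5.1 A) from
#' extended (d(i,i+2) = 7.6 A) geometry and are configurable.  The contact
#' number is the count of CA atoms within \code{contact_radius}, excluding
#' chain neighbours |i-j| <= 2, capped into \code{n_nc_bins} unit-width
#' bins (0, 1, ..., >= n_nc_bins-1).  Composite state =
#' \code{ss_index * n_nc_bins + nc_bin}.
#'
#' @param trace L x 3 CA trace, L >= 5 (see \code{\link{extract_trace}}).
#' @param contact_radius contact-number radius in Angstrom (default 10).
#' @param n_nc_bins number of contact-number bins (default 10).
#' @param d_helix,d_strand distance thresholds (Angstrom) for the H and E
#'   assignments.
#' @return A \code{\link{state_profile}} over \code{3 * n_nc_bins} states.
#' @export
ca_ss_nc_profile <- function(trace, contact_radius = 10.0, n_nc_bins = 10,
                             d_helix = 6.0, d_strand = 6.2) {
  trace <- as_coord_matrix(trace)
  l <- nrow(trace)
  if (l < 5) stop("ca_ss_nc_profile: trace must have >= 5 residues")
  d <- as.matrix(stats::dist(trace))
  ss <- rep("C", l)
  i2 <- seq_len(l - 2)
  ss[i2][d[cbind(i2, i2 + 2)] > d_strand] <- "E"
  i3 <- seq_len(l - 3)
  ss[i3][d[cbind(i3, i3 + 3)] < d_helix] <- "H"
  near <- d < contact_radius
  sep <- abs(outer(seq_len(l), seq_len(l), "-"))
  near[sep <= 2] <- FALSE
  nc <- rowSums(near)
  nc_bin <- pmin(nc, n_nc_bins - 1L)
  ss_idx <- match(ss, c("H", "E", "C")) - 1L
  alph <- state_alphabet(paste0(rep(c("H", "E", "C"), each = n_nc_bins),
                                rep(seq_len(n_nc_bins) - 1, 3)),
                         paste0("ca-ss-nc", n_nc_bins))
  state_profile(ss_idx * n_nc_bins + nc_bin, alph,
                model_id = attr(trace, "model_id") %||% "model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- binary contact-map profiles -----------------------------------------

## ordered long-range pair positions (i, j), i < j, j - i >= min_sep,
## enumerated row-major (by i, then j)
cm_pairs <- function(l, min_sep) {
  if (l <= min_sep) {
    stop("contact-map profile requires length > ", min_sep,
         " (got L = ", l, ")")
  }
  i <- rep(seq_len(l - min_sep),
           times = (l - min_sep):1)
  j <- unlist(lapply(seq_len(l - min_sep), function(a) (a + min_sep):l))
  cbind(i, j)
}

#' Binary contact-map profile (CA-CM)
#'
#' The upper triangle of the long-range binary contact map as a 1D binary
#' profile: positions are ordered pairs (i, j) with sequence separation
#' |i-j| > min_sep - 1 enumerated row-major, and the state is 1 iff
#' d(CA_i, CA_j) < cutoff (strict).  Profile length is
#' \code{(L - min_sep) (L - min_sep + 1) / 2}.
#'
#' @param trace L x 3 CA trace with L > \code{min_sep}.
#' @param cutoff contact distance cutoff in Angstrom (default 8.5).
#' @param min_sep minimum sequence separation j - i (default 12, i.e.
#'   |i-j| > 11).
#' @return A binary \code{\link{state_profile}} with attribute
#'   \code{"pairs"} giving the (i, j) enumeration.
#' @export
ca_cm_profile <- function(trace, cutoff = 8.5, min_sep = 12) {
  trace <- as_coord_matrix(trace)
  pr <- cm_pairs(nrow(trace), min_sep)
  d <- sqrt(rowSums((trace[pr[, 1], , drop = FALSE] -
                     trace[pr[, 2], , drop = FALSE])^2))
  p <- state_profile(as.integer(d < cutoff), binary_alphabet(),
                     model_id = attr(trace, "model_id") %||% "model")
  attr(p, "pairs") <- pr
  p
}

#' RNA backbone phosphorus contact-map profile (RNA-P-CM)
#'
#' Identical to \code{\link{ca_cm_profile}} with the RNA phosphorus-atom
#' contact cutoff of 15.5 Angstrom.
#'
#' @param trace L x 3 P-atom trace.
#' @param cutoff contact cutoff (default 15.5 A).
#' @param min_sep minimum separation (default 12).
#' @return A binary \code{\link{state_profile}}.
#' @export
rna_p_cm_profile <- function(trace, cutoff = 15.5, min_sep = 12) {
  ca_cm_profile(trace, cutoff = cutoff, min_sep = min_sep)
}

#' Contact-map profiles for every model of a set
#'
#' @param ms a \code{\link{model_set}} or list of traces.
#' @param atom backbone atom name ("CA" or "P").
#' @param cutoff,min_sep as in \code{\link{ca_cm_profile}}.
#' @return A \code{\link{profile_set}}.
#' @export
cm_profiles <- function(ms, atom = "CA", cutoff = 8.5, min_sep = 12) {
  traces <- if (inherits(ms, "model_set")) extract_traces(ms, atom) else ms
  l <- nrow(traces[[1]])
  pr <- cm_pairs(l, min_sep)
  states <- t(vapply(traces, function(tr) {
    d2 <- rowSums((tr[pr[, 1], , drop = FALSE] -
                   tr[pr[, 2], , drop = FALSE])^2)
    as.integer(d2 < cutoff^2)
  }, integer(nrow(pr))))
  ids <- if (inherits(ms, "model_set")) ms$ids else
    (names(traces) %||% paste0("m", seq_along(traces)))
  rownames(states) <- ids
  profile_set(states, binary_alphabet(), ids)
}

## ---- RNA annotation-based profiles ---------------------------------------

#' Default Leontis-Westhof 15-class base-pair label set
#'
#' Cis/trans Watson-Crick, Hoogsteen and Sugar-edge pairings plus
#' bifurcated, water-inserted and a catch-all "Other" for unpaired
#' residues.  The set is configurable at annotation ingestion.
#'
#' @return Character vector of 15 labels.
#' @export
lw_labels <- function() {
  c("cWW", "tWW", "cWH", "tWH", "cWS", "tWS", "cHH", "tHH", "cHS", "tHS",
    "cSS", "tSS", "bifurcated", "water-inserted", "Other")
}

#' Default RNA backbone torsion-state labels
#'
#' Combinations of epsilon-zeta BI/BII backbone states with chi syn/anti,
#' plus a catch-all other state.
#'
#' @return Character vector of 5 labels.
#' @export
torsion_labels <- function() {
  c("BI-anti", "BII-anti", "BI-syn", "BII-syn", "other")
}

#' RNA secondary-structure / Leontis-Westhof profile (RNA-SS-LW)
#'
#' Combines the stem/loop secondary-structure state (N_SS = 2) with the
#' coarse-grained 15-class Leontis-Westhof base-pair type; unpaired
#' residues carry the "Other" class.  Composite state =
#' \code{ss2_index * 15 + lw_index}, alphabet size 30.
#'
#' @param annotation an RNA \code{\link{rna_annotation}}.
#' @param model_id id for the profile.
#' @return A \code{\link{state_profile}} over 30 states.
#' @export
rna_ss_lw_profile <- function(annotation, model_id = "model") {
  stopifnot(inherits(annotation, "residue_annotation"))
  if (annotation$kind != "rna") stop("rna_ss_lw_profile: RNA annotation required")
  labels <- annotation$lw_labels
  nl <- length(labels)
  ss2 <- match(annotation$ss2, c("stem", "loop")) - 1L
  lw <- match(annotation$lw_class, labels) - 1L
  alph <- state_alphabet(paste0(rep(c("stem", "loop"), each = nl), ".",
                                rep(labels, 2)), "rna-ss-lw")
  state_profile(ss2 * nl + lw, alph, model_id)
}

#' RNA secondary-structure / torsion-angle profile (RNA-SS-TA)
#'
#' Combines the stem/loop state (N_SS = 2) with 5 backbone torsion states
#' (N_TA = 5): composite state = \code{ss2_index * 5 + torsion_index},
#' alphabet size 10.
#'
#' @param annotation an RNA \code{\link{rna_annotation}} with torsion
#'   states.
#' @param model_id id for the profile.
#' @return A \code{\link{state_profile}} over 10 states.
#' @export
rna_ss_ta_profile <- function(annotation, model_id = "model") {
  stopifnot(inherits(annotation, "residue_annotation"))
  if (annotation$kind != "rna") stop("rna_ss_ta_profile: RNA annotation required")
  if (is.null(annotation$torsion_state) || anyNA(annotation$torsion_state)) {
    stop("rna_ss_ta_profile: missing torsion state")
  }
  labels <- annotation$ta_labels
  ss2 <- match(annotation$ss2, c("stem", "loop")) - 1L
  ta <- match(annotation$torsion_state, labels) - 1L
  alph <- state_alphabet(paste0(rep(c("stem", "loop"),
                                    each = length(labels)), ".",
                                rep(labels, 2)), "rna-ss-ta")
  state_profile(ss2 * length(labels) + ta, alph, model_id)
}

## ---- bag-of-fragments ----------------------------------------------------

#' Backbone fragment library
#'
#' @param fragments list of w x 3 coordinate matrices, all of one window
#'   length w.
#' @param name library name.
#' @return Object of class \code{"fragment_library"}.
#' @export
fragment_library <- function(fragments, name = "library") {
  if (!length(fragments)) stop("fragment_library: empty library")
  fragments <- lapply(fragments, as_coord_matrix)
  w <- nrow(fragments[[1]])
  if (any(vapply(fragments, nrow, integer(1)) != w)) {
    stop("fragment_library: fragments differ in window length")
  }
  structure(list(name = name, window_length = w, fragments = fragments),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("Fragment library '", x$name, "': D = ", length(x$fragments),
      " fragments of length ", x$window_length, "\n", sep = "")
  invisible(x)
}

#' Bag-of-fragments frequency profile (FragBag)
#'
#' Slides a window of the library's fragment length along the backbone
#' trace; each of the L - w + 1 windows is assigned to the library
#' fragment of minimum Kabsch superposition RMSD (ties to the lowest
#' fragment index) and the winner's count is incremented.  The resulting
#' fixed-dimension count vector is length-independent, so structures of
#' different sizes become comparable.
#'
#' @param trace L x 3 backbone trace with L >= window length.
#' @param library a \code{\link{fragment_library}}.
#' @return A \code{\link{frequency_profile}} of dimension = library size,
#'   with counts summing to L - w + 1.
#' @export
fragbag_profile <- function(trace, library) {
  trace <- as_coord_matrix(trace)
  w <- library$window_length
  l <- nrow(trace)
  if (l < w) {
    stop("fragbag_profile: trace length ", l, " below window length ", w)
  }
  d <- length(library$fragments)
  counts <- numeric(d)
  for (s in seq_len(l - w + 1)) {
    win <- trace[s:(s + w - 1), , drop = FALSE]
    rms <- vapply(library$fragments,
                  function(f) kabsch_rmsd(win, f)$rmsd, numeric(1))
    k <- which.min(rms)  # ties -> lowest index
    counts[k] <- counts[k] + 1
  }
  frequency_profile(counts,
                    model_id = attr(trace, "model_id") %||% "model")
}
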
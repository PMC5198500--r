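## Per-residue annotation ingestion (DSSP output, RNA annotation tables),
## user-defined profile TSVs and fragment-library files.

#' Per-residue protein annotation (DSSP-style)
#'
#' @param ss character vector of 8-class DSSP secondary structure codes.
#' @param rsa numeric vector of relative solvent accessibilities in [0, 1].
#' @return Object of class \code{"residue_annotation"}.
#' @export
protein_annotation <- function(ss, rsa) {
  if (length(ss) != length(rsa)) stop("protein_annotation: length mismatch")
  if (any(rsa < 0 | rsa > 1)) {
    stop("protein_annotation: rsa outside [0, 1] at residue ",
         which(rsa < 0 | rsa > 1)[1])
  }
  structure(list(kind = "protein", ss = as.character(ss),
                 rsa = as.numeric(rsa)),
            class = "residue_annotation")
}

#' Per-residue RNA annotation
#'
#' @param ss2 character vector over \{"stem", "loop"\}.
#' @param lw_class Leontis-Westhof base-pair class per residue; unpaired
#'   residues (NA or empty) receive \code{"Other"}.
#' @param torsion_state optional backbone torsion state per residue.
#' @param lw_labels accepted 15-class LW label set (default
#'   \code{\link{lw_labels}()}).
#' @param ta_labels accepted torsion-state label set (default
#'   \code{\link{torsion_labels}()}).
#' @return Object of class \code{"residue_annotation"}.
#' @export
rna_annotation <- function(ss2, lw_class, torsion_state = NULL,
                           lw_labels = profclust::lw_labels(),
                           ta_labels = torsion_labels()) {
  ss2 <- as.character(ss2)
  if (!all(ss2 %in% c("stem", "loop"))) {
    stop("rna_annotation: ss2 must be 'stem' or 'loop'")
  }
  lw_class <- as.character(lw_class)
  lw_class[is.na(lw_class) | lw_class == ""] <- "Other"
  bad <- setdiff(unique(lw_class), lw_labels)
  if (length(bad)) {
    stop("rna_annotation: unknown LW label(s) ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(lw_labels, collapse = ", "))
  }
  if (!is.null(torsion_state)) {
    torsion_state <- as.character(torsion_state)
    if (length(torsion_state) != length(ss2)) {
      stop("rna_annotation: torsion_state length mismatch")
    }
    badt <- setdiff(unique(torsion_state[!is.na(torsion_state)]), ta_labels)
    if (length(badt)) {
      stop("rna_annotation: unknown torsion label(s) ",
           paste(badt, collapse = ", "))
    }
  }
  structure(list(kind = "rna", ss2 = ss2, lw_class = lw_class,
                 torsion_state = torsion_state, lw_labels = lw_labels,
                 ta_labels = ta_labels),
            class = "residue_annotation")
}

#' @export
print.residue_annotation <- function(x, ...) {
  cat("Residue annotation (", x$kind, "): ",
      length(if (x$kind == "protein") x$ss else x$ss2), " residues\n",
      sep = "")
  invisible(x)
}

## Theoretical maximum accessible surface areas (A^2) per residue type,
## Tien et al. scale; used to normalise DSSP ACC to relative accessibility.
max_asa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Read a DSSP output file
#'
#' Fixed-column parse of standard DSSP output: the per-residue secondary
#' structure code (column 17) and the accessibility value ACC (columns
#' 35-38), normalised to relative accessibility by the Tien et al.
#' theoretical max-ASA scale and clipped to [0, 1].  Chain-break rows
#' ('!') are skipped without emitting a record.
#'
#' @param path DSSP output file.
#' @return A protein \code{\link{protein_annotation}}.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("read_dssp: malformed DSSP file (no residue header)")
  body <- lines[(hdr[1] + 1):length(lines)]
  ss <- character(0)
  rsa <- numeric(0)
  for (k in seq_along(body)) {
    line <- body[k]
    if (nchar(line) < 38) {
      stop("read_dssp: truncated residue line at line ", hdr[1] + k)
    }
    aa <- substr(line, 14, 14)
    if (aa == "!") next  # chain break
    code <- substr(line, 17, 17)
    acc <- suppressWarnings(as.numeric(substr(line, 35, 38)))
    if (is.na(acc)) {
      stop("read_dssp: unreadable ACC field at line ", hdr[1] + k)
    }
    aa3 <- aa1to3[toupper(aa)]
    mx <- if (!is.na(aa3)) max_asa[[aa3]] else mean(max_asa)
    ss <- c(ss, if (code == " ") "-" else code)
    rsa <- c(rsa, min(1, acc / mx))
  }
  protein_annotation(ss, rsa)
}

#' Read an RNA annotation table
#'
#' Tab-separated table with header columns \code{residue}, \code{ss2},
#' \code{lw_class} and optionally \code{torsion_state}; rows ordered by
#' residue.  Empty or NA \code{lw_class} entries denote unpaired residues
#' and map to \code{"Other"}.
#'
#' @param path TSV file.
#' @param lw_labels,ta_labels accepted label sets.
#' @return An RNA \code{\link{rna_annotation}}.
#' @export
read_rna_annotation <- function(path, lw_labels = profclust::lw_labels(),
                                ta_labels = torsion_labels()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "ss2", "lw_class")
  if (!all(need %in% names(tab))) {
    stop("read_rna_annotation: need columns ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$residue), ]
  rna_annotation(tab$ss2, tab$lw_class,
                 torsion_state = if ("torsion_state" %in% names(tab))
                   tab$torsion_state else NULL,
                 lw_labels = lw_labels, ta_labels = ta_labels)
}

## ---- user profile TSV ----------------------------------------------------

#' Read user-defined state profiles from TSV
#'
#' Format: a header line \code{alphabet<TAB>label1<TAB>label2...} declaring
#' the state alphabet, then one row per model: \code{id<TAB>s1<TAB>...<TAB>sL}
#' of state labels.  All rows must share one length and every label must
#' belong to the declared alphabet.
#'
#' @param path TSV file.
#' @return A \code{\link{profile_set}}.
#' @seealso \code{\link{write_profiles}} for the inverse.
#' @export
read_user_profiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2) stop("read_user_profiles: no profile rows in '",
                              path, "'")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "alphabet" || length(hdr) < 3) {
    stop("read_user_profiles: first line must declare the alphabet ",
         "('alphabet<TAB>label...')")
  }
  alph <- state_alphabet(hdr[-1], "user")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop("read_user_profiles: row ", bad + 1, " has ", lens[bad] - 1,
         " states, expected ", lens[1] - 1)
  }
  ids <- vapply(rows, `[[`, character(1), 1)
  states <- t(vapply(seq_along(rows), function(r) {
    labels <- rows[[r]][-1]
    idx <- match(labels, alph$states)
    if (anyNA(idx)) {
      col <- which(is.na(idx))[1]
      stop("read_user_profiles: unknown label '", labels[col],
           "' at row ", r + 1, ", column ", col + 1)
    }
    idx - 1L
  }, integer(lens[1] - 1)))
  profile_set(states, alph, ids)
}

#' Write a profile set as user-profile TSV
#'
#' Inverse of \code{\link{read_user_profiles}}: round-trips exactly.
#'
#' @param profiles a \code{\link{profile_set}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("alphabet", profiles$alphabet$states),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(profiles$states))) {
    writeLines(paste(c(profiles$ids[i],
                       decode_states(profiles$alphabet,
                                     profiles$states[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

## ---- fragment library files ----------------------------------------------

#' Read a fragment library file
#'
#' Concatenated xyz blocks: each fragment starts with a header line
#' \code{"> name"} followed by one \code{x y z} line per backbone point;
#' all fragments must share one window length.
#'
#' @param path library file.
#' @param name library name (defaults to the file name).
#' @return A \code{\link{fragment_library}}.
#' @export
read_fragment_library <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("read_fragment_library: no fragment headers")
  ends <- c(starts[-1] - 1, length(lines))
  frags <- lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1):ends[k]]
    co <- do.call(rbind, lapply(block, function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
    if (ncol(co) != 3 || anyNA(co)) {
      stop("read_fragment_library: malformed fragment block ", k)
    }
    co
  })
  fragment_library(frags, name = name)
}

#' @rdname read_fragment_library
#' @param library a \code{\link{fragment_library}} to write.
#' @export
write_fragment_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(library$fragments)) {
    writeLines(paste0("> frag", k), con)
    f <- library$fragments[[k]]
    writeLines(apply(f, 1, function(r) paste(format(r, trim = TRUE,
                                                    digits = 12),
                                             collapse = " ")), con)
  }
  invisible(path)
}
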
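## Model ingestion (PDB via bio3d, plain xyz tables), trace extraction and
## the synthetic ensemble / profile-set generators used throughout the
## test-suite and worked examples.

#' Single 3D model
#'
#' One conformation of a macromolecule: ordered residues, each carrying a
#' named-atom coordinate table.  Residue identity is positional
#' (\code{seq_index} 1..L in file order); author numbering is retained in
#' \code{resno} but never used for alignment, so that all models of a set
#' align by position.
#'
#' @param atom data.frame with columns \code{elety} (atom name),
#'   \code{resid} (residue name), \code{resno}, \code{seq_index}, \code{x},
#'   \code{y}, \code{z}.
#' @param id model identifier.
#' @param kind \code{"protein"} or \code{"rna"}.
#' @return Object of class \code{"pc_model"}.
#' @export
pc_model <- function(atom, id = "model", kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  need <- c("elety", "resid", "resno", "seq_index", "x", "y", "z")
  if (!all(need %in% names(atom))) {
    stop("pc_model: atom table must have columns ",
         paste(need, collapse = ", "))
  }
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z))) {
    stop("pc_model: non-finite coordinates in model '", id, "'")
  }
  if (is.unsorted(atom$seq_index)) {
    stop("pc_model: seq_index must be non-decreasing")
  }
  structure(list(id = id, kind = kind, atom = atom), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("Model '", x$id, "' (", x$kind, "): ",
      length(unique(x$atom$seq_index)), " residues, ", nrow(x$atom),
      " atoms\n", sep = "")
  invisible(x)
}

n_residues <- function(model) length(unique(model$atom$seq_index))

#' Ordered set of models of one molecule
#'
#' @param models list of \code{\link{pc_model}} objects.
#' @param fixed_length require all models to share residue count (the mode
#'   needed by fixed-length profile comparison); default TRUE.
#' @return Object of class \code{"model_set"} with \code{models} and
#'   \code{ids}.
#' @export
model_set <- function(models, fixed_length = TRUE) {
  if (!length(models)) stop("model_set: no models")
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("model_set: duplicate model ids")
  if (fixed_length) {
    lens <- vapply(models, n_residues, integer(1))
    if (length(unique(lens)) != 1) {
      bad <- which(lens != lens[1])[1]
      stop("model_set: model '", ids[bad], "' has ", lens[bad],
           " residues, expected ", lens[1])
    }
  }
  names(models) <- ids
  structure(list(models = models, ids = ids), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set:", length(x$models), "models,",
      n_residues(x$models[[1]]), "residues each (first model)\n")
  invisible(x)
}

## ---- PDB ingestion -------------------------------------------------------

## one pc_model from a bio3d pdb object (single-model coordinates in xyz row)
model_from_bio3d <- function(atom, xyz_row, id, kind, atom_subset) {
  ok <- atom$type == "ATOM"
  ## altloc: keep the first altloc seen for each (chain, resno, insert, elety)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "",
                                              atom$insert), atom$elety)
  ok <- ok & !duplicated(key)
  if (!is.null(atom_subset)) ok <- ok & atom$elety %in% atom_subset
  idx <- which(ok)
  if (!length(idx)) stop("no matching ATOM records in model '", id, "'")
  co <- matrix(xyz_row, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  rkey <- paste(atom$chain[idx], atom$resno[idx],
                ifelse(is.na(atom$insert[idx]), "", atom$insert[idx]))
  seq_index <- match(rkey, unique(rkey))
  pc_model(data.frame(elety = atom$elety[idx], resid = atom$resid[idx],
                      resno = atom$resno[idx], seq_index = seq_index,
                      x = co[, 1], y = co[, 2], z = co[, 3],
                      stringsAsFactors = FALSE),
           id = id, kind = kind)
}

#' Read models from a PDB file or a directory of PDB files
#'
#' A multi-MODEL PDB file yields one model per MODEL record (ids = MODEL
#' number); a directory yields one model per \code{.pdb}/\code{.ent} file
#' (ids = filename without extension, lexicographic order).  All-atom and
#' reduced (e.g. CA-only or P-only) files are accepted.  For each atom the
#' first alternate location is kept; insertion codes are honoured in
#' residue ordering; residues are indexed positionally.
#'
#' @param path PDB file or directory.
#' @param atom_subset optional character vector of atom names to retain
#'   (e.g. \code{"CA"}).
#' @param kind \code{"protein"} or \code{"rna"}.
#' @param fixed_length require equal residue counts across models.
#' @return A \code{\link{model_set}}.
#' @export
read_models <- function(path, atom_subset = NULL,
                        kind = c("protein", "rna"), fixed_length = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_models: cannot read '", path, "'")
  models <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(pdb|ent)$",
                             full.names = TRUE))
    if (!length(files)) stop("read_models: no PDB files in '", path, "'")
    for (f in files) {
      pdb <- bio3d::read.pdb(f, verbose = FALSE)
      id <- sub("\\.(pdb|ent)$", "", basename(f))
      models[[length(models) + 1]] <-
        model_from_bio3d(pdb$atom, pdb$xyz[1, ], id, kind, atom_subset)
    }
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nm <- nrow(pdb$xyz)
    if (is.null(nm) || nm == 0) stop("read_models: zero models in '", path, "'")
    for (i in seq_len(nm)) {
      models[[i]] <- model_from_bio3d(pdb$atom, pdb$xyz[i, ],
                                      as.character(i), kind, atom_subset)
    }
  }
  model_set(models, fixed_length = fixed_length)
}

#' Write a model set as a multi-model PDB file
#'
#' Models are emitted as consecutive MODEL/ENDMDL blocks in set order;
#' coordinates at the PDB format's 3-decimal precision.
#'
#' @param ms a \code{\link{model_set}} whose models share an atom layout.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_models <- function(ms, path) {
  a1 <- ms$models[[1]]$atom
  xyz <- do.call(rbind, lapply(ms$models, function(m) {
    as.numeric(t(as.matrix(m$atom[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a1$resno,
                   resid = a1$resid, elety = a1$elety)
  invisible(path)
}

## ---- plain xyz tables ----------------------------------------------------

#' Read models from a whitespace-delimited xyz table
#'
#' Lightweight alternative to PDB: columns \code{model_id},
#' \code{residue_index}, \code{x}, \code{y}, \code{z}; one backbone atom
#' per residue.
#'
#' @param path input file (header optional, detected by column names).
#' @param atom name given to the single atom per residue (default "CA").
#' @param kind \code{"protein"} or \code{"rna"}.
#' @return A \code{\link{model_set}}.
#' @export
read_xyz_table <- function(path, atom = "CA", kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1)
  if (grepl("model_id", first)) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("model_id", "residue_index",
                                           "x", "y", "z"),
                             stringsAsFactors = FALSE)
  }
  models <- lapply(split(tab, factor(tab$model_id,
                                     levels = unique(tab$model_id))),
                   function(d) {
    d <- d[order(d$residue_index), ]
    pc_model(data.frame(elety = atom, resid = if (kind == "protein") "ALA"
                        else "A",
                        resno = d$residue_index,
                        seq_index = seq_len(nrow(d)),
                        x = d$x, y = d$y, z = d$z,
                        stringsAsFactors = FALSE),
             id = as.character(d$model_id[1]), kind = kind)
  })
  model_set(unname(models))
}

#' @rdname read_xyz_table
#' @param ms a \code{\link{model_set}} of single-atom-per-residue models.
#' @export
write_xyz_table <- function(ms, path) {
  rows <- lapply(ms$models, function(m) {
    data.frame(model_id = m$id, residue_index = m$atom$seq_index,
               x = m$atom$x, y = m$atom$y, z = m$atom$z,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- traces --------------------------------------------------------------

#' Extract the trace of one named backbone atom
#'
#' @param model a \code{\link{pc_model}}.
#' @param atom_name atom to extract (\code{"CA"} for protein traces,
#'   \code{"P"} for RNA backbone phosphorus).
#' @return L x 3 coordinate matrix in residue order, with attributes
#'   \code{model_id} and \code{atom}.
#' @export
extract_trace <- function(model, atom_name = "CA") {
  a <- model$atom[model$atom$elety == atom_name, ]
  res <- unique(model$atom$seq_index)
  miss <- setdiff(res, a$seq_index)
  if (length(miss)) {
    stop("extract_trace: residue ", miss[1], " of model '", model$id,
         "' has no atom '", atom_name, "'")
  }
  a <- a[!duplicated(a$seq_index), ]
  a <- a[order(a$seq_index), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  attr(m, "model_id") <- model$id
  attr(m, "atom") <- atom_name
  m
}

#' Extract traces for every model of a set
#'
#' @param ms a \code{\link{model_set}}.
#' @param atom_name backbone atom name.
#' @return Named list of L x 3 matrices.
#' @export
extract_traces <- function(ms, atom_name = "CA") {
  lapply(ms$models, extract_trace, atom_name = atom_name)
}

## ---- synthetic generators ------------------------------------------------

#' Compact template backbone trace
#'
#' Deterministic serpentine slab -- consecutive 3.8-Angstrom virtual bonds
#' folded into anti-parallel rows and stacked layers, plus a small smooth
#' jitter -- giving a compact globule-like trace rich in the long-range
#' (|i-j| > 11) contacts that contact-map profiles record.
#'
#' @param n_residues trace length.
#' @param seed integer seed for the jitter.
#' @param row_length residues per row (default 10).
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
template_trace <- function(n_residues, seed = 1, row_length = 10) {
  i <- seq_len(n_residues) - 1L
  row <- i %/% row_length
  pos <- i %% row_length
  pos <- ifelse(row %% 2 == 0, pos, row_length - 1 - pos)  # serpentine
  layer <- row %/% 5
  rowin <- row %% 5
  base <- cbind(pos * 3.8, rowin * 4.8, layer * 5.5)
  with_seed(seed, {
    jit <- matrix(stats::rnorm(3 * n_residues, sd = 0.3), ncol = 3)
    ## smooth the jitter so bonds stay near-ideal
    jit <- apply(jit, 2, function(v) stats::filter(c(v[1], v, v[length(v)]),
                                                   rep(1 / 3, 3))[2:(length(v) + 1)])
    base + jit
  })
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c + s * ux + (1 - c) * tcrossprod(u)
}

## one smooth deformation of a trace: random rigid hinge at an interior
## residue plus a low-frequency sinusoidal displacement
deform_trace <- function(trace, magnitude) {
  l <- nrow(trace)
  h <- sample(seq(max(2, floor(l * 0.25)), min(l - 1, ceiling(l * 0.75))), 1)
  tail_idx <- (h + 1):l
  lever <- mean(sqrt(rowSums(sweep(trace[tail_idx, , drop = FALSE], 2,
                                   trace[h, ])^2)))
  angle <- min(pi, magnitude / max(lever, 1e-6))
  rot <- rotation_about_axis(stats::rnorm(3), angle * sample(c(-1, 1), 1))
  out <- trace
  out[tail_idx, ] <- sweep(sweep(trace[tail_idx, , drop = FALSE], 2,
                                 trace[h, ]) %*% rot, 2, trace[h, ], "+")
  dirv <- stats::rnorm(3)
  dirv <- dirv / sqrt(sum(dirv^2))
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- magnitude / 2
  out + outer(amp * sin(2 * pi * seq_len(l) / l + phase), dirv)
}

#' Synthetic decoy ensemble with planted conformational clusters
#'
#' Emulates an ensemble drawn from a few distinct conformers: each of
#' \code{n_clusters} base conformers is an independent smooth deformation
#' (random rigid hinge plus low-frequency sinusoidal bend, overall
#' magnitude \code{conformer_shift}) of the template; each cluster member
#' adds i.i.d. Gaussian coordinate noise of sd \code{noise_sigma}.
#' Deterministic for a fixed seed.
#'
#' @param template L x 3 template trace (e.g. \code{\link{template_trace}}).
#' @param n_clusters number of planted conformers (>= 1).
#' @param per_cluster members per conformer (>= 1).
#' @param conformer_shift deformation magnitude between conformers
#'   (Angstrom).
#' @param noise_sigma per-coordinate Gaussian noise sd (Angstrom, >= 0).
#' @param seed integer seed.
#' @param atom atom name for the generated single-atom models.
#' @param kind \code{"protein"} or \code{"rna"}.
#' @return List of class \code{"pc_ensemble"}: \code{models} (a
#'   \code{\link{model_set}}), \code{labels} (named integer vector of true
#'   cluster labels), \code{bases} (list of base conformer traces).
#' @export
generate_ensemble <- function(template, n_clusters, per_cluster,
                              conformer_shift, noise_sigma, seed,
                              atom = "CA", kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (n_clusters < 1 || per_cluster < 1) {
    stop("generate_ensemble: n_clusters and per_cluster must be >= 1")
  }
  if (noise_sigma < 0) stop("generate_ensemble: noise_sigma must be >= 0")
  template <- as_coord_matrix(template)
  l <- nrow(template)
  with_seed(seed, {
    bases <- lapply(seq_len(n_clusters), function(c)
      deform_trace(template, conformer_shift))
    models <- vector("list", n_clusters * per_cluster)
    labels <- integer(n_clusters * per_cluster)
    k <- 0
    for (c in seq_len(n_clusters)) {
      for (m in seq_len(per_cluster)) {
        k <- k + 1
        co <- bases[[c]] +
          matrix(stats::rnorm(3 * l, sd = noise_sigma), ncol = 3)
        id <- sprintf("c%02d_m%04d", c, m)
        models[[k]] <- pc_model(data.frame(
          elety = atom, resid = if (kind == "protein") "ALA" else "A",
          resno = seq_len(l), seq_index = seq_len(l),
          x = co[, 1], y = co[, 2], z = co[, 3], stringsAsFactors = FALSE),
          id = id, kind = kind)
        labels[k] <- c
      }
    }
    ms <- model_set(models)
    names(labels) <- ms$ids
    structure(list(models = ms, labels = labels, bases = bases),
              class = "pc_ensemble")
  })
}

#' @export
print.pc_ensemble <- function(x, ...) {
  cat("Synthetic ensemble:", length(x$labels), "models,",
      length(x$bases), "planted conformers\n")
  invisible(x)
}

#' Synthetic categorical profile set with planted key structure
#'
#' Draws \code{n_clusters} random archetype profiles over \code{n_states}
#' states; each member copies its archetype and independently resamples
#' each position to a uniformly random \emph{other} state with probability
#' \code{flip_prob} (so the expected member-archetype Hamming distance is
#' \code{length * flip_prob}).  Deterministic for a fixed seed.
#'
#' @param n number of profiles.
#' @param length profile length L.
#' @param n_states alphabet size S (>= 2).
#' @param n_clusters number of archetypes (<= n).
#' @param flip_prob per-position flip probability in [0, 1).
#' @param seed integer seed.
#' @return List: \code{profiles} (a \code{\link{profile_set}}),
#'   \code{labels} (named integer vector), \code{archetypes} (matrix).
#' @export
generate_profile_set <- function(n, length, n_states, n_clusters,
                                 flip_prob, seed) {
  if (n_states < 2) stop("generate_profile_set: n_states must be >= 2")
  if (flip_prob < 0 || flip_prob >= 1) {
    stop("generate_profile_set: flip_prob must be in [0, 1)")
  }
  if (n_clusters > n) {
    stop("generate_profile_set: n_clusters (", n_clusters,
         ") exceeds n (", n, ")")
  }
  with_seed(seed, {
    arch <- matrix(sample(0:(n_states - 1), n_clusters * length,
                          replace = TRUE), nrow = n_clusters)
    labels <- sort(rep_len(seq_len(n_clusters), n))
    states <- arch[labels, , drop = FALSE]
    flips <- matrix(stats::runif(n * length) < flip_prob, nrow = n)
    nflip <- sum(flips)
    if (nflip) {
      shift <- sample(n_states - 1, nflip, replace = TRUE)
      states[flips] <- (states[flips] + shift) %% n_states
    }
    ids <- sprintf("p%04d", seq_len(n))
    rownames(states) <- ids
    names(labels) <- ids
    list(profiles = profile_set(states,
                                state_alphabet(as.character(0:(n_states - 1)),
                                               "synthetic")),
         labels = labels, archetypes = arch)
  })
}
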
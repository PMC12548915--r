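# Compound featurization: canonical SMILES, ECFP substructure sets with
# bit -> atom-environment provenance, and edge-attributed molecular graphs.
# Chemistry perception is delegated to RDKit through the bundled batch
# featurizer script (inst/python/featurize.py); results are cached per input
# SMILES string for the lifetime of the R session.

.cypdfi <- new.env(parent = emptyenv())
.cypdfi$cache <- new.env(parent = emptyenv())
.cypdfi$vocab_sizes <- NULL
.cypdfi$vocab_version <- NULL

#' @keywords internal
.python_bin <- function() {
  bin <- Sys.which("python")
  if (bin == "") bin <- Sys.which("python3")
  if (bin == "") stop("no 'python' interpreter found on PATH", call. = FALSE)
  bin
}

#' @keywords internal
.featurizer_script <- function() {
  path <- system.file("python", "featurize.py", package = "cypdfi")
  if (path == "") {
    # during development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "python", "featurize.py", package = "cypdfi")
  }
  if (path == "") stop("bundled featurize.py not found", call. = FALSE)
  path
}

# Run the batch featurizer for SMILES strings missing from the cache.
.featurize_fill_cache <- function(smiles) {
  smiles <- unique(smiles)
  missing <- smiles[!vapply(smiles, exists, logical(1), envir = .cypdfi$cache)]
  if (length(missing) == 0L) return(invisible(NULL))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(missing, fin, auto_unbox = FALSE)
  status <- system2(.python_bin(), c(shQuote(.featurizer_script()),
                                     shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(fout)) {
    stop("featurizer subprocess failed (exit status ", status, ")", call. = FALSE)
  }
  res <- jsonlite::read_json(fout)
  .cypdfi$vocab_sizes <- lapply(res$vocab_sizes, as.integer)
  .cypdfi$vocab_version <- res$vocab_version
  for (i in seq_along(missing)) {
    assign(missing[[i]], res$records[[i]], envir = .cypdfi$cache)
  }
  invisible(NULL)
}

.featurize_record <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .featurize_fill_cache(smiles)
  rec <- get(smiles, envir = .cypdfi$cache)
  if (!isTRUE(rec$ok)) {
    stop(errorCondition(
      sprintf("featurization failed for SMILES '%s': %s", smiles, rec$error),
      smiles = smiles, class = c("cypdfi_featurize_error", "error")))
  }
  rec
}

#' Feature vocabulary sizes used by the molecular graph encoder
#'
#' Returns the named integer vector of category counts for the nine atom
#' feature channels and three bond feature channels.  The vocabulary is fixed
#' in code (and versioned) so that saved model checkpoints remain loadable.
#'
#' @return Named list of integer vocabulary sizes.
#' @export
feature_vocab_sizes <- function() {
  if (is.null(.cypdfi$vocab_sizes)) .featurize_fill_cache("C")
  .cypdfi$vocab_sizes
}

#' @rdname feature_vocab_sizes
#' @export
feature_vocab_version <- function() {
  if (is.null(.cypdfi$vocab_version)) .featurize_fill_cache("C")
  .cypdfi$vocab_version
}

#' Canonicalize SMILES strings
#'
#' Maps every parseable SMILES to a unique canonical form.  Multi-fragment
#' inputs (e.g. salts) are reduced to their largest organic fragment before
#' canonicalization; a message is emitted when that happens.
#'
#' @param smiles Character vector of SMILES strings.
#' @param quiet Suppress the fragment-reduction message.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # identical outputs
#' }
#' @export
canonicalize_smiles <- function(smiles, quiet = FALSE) {
  stopifnot(is.character(smiles))
  .featurize_fill_cache(smiles)
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    rec <- .featurize_record(smiles[[i]])
    if (isTRUE(rec$fragment_reduced) && !quiet) {
      message(sprintf("multi-fragment input '%s' reduced to largest organic fragment '%s'",
                      smiles[[i]], rec$canonical))
    }
    out[[i]] <- rec$canonical
  }
  out
}

#' Compute the substructure set of a compound
#'
#' The substructure set of a compound is the set of on-bit indices of its
#' 1024-bit radius-2 binary extended-connectivity (Morgan) fingerprint,
#' together with the provenance of each bit: the circular atom environments
#' (center atom, radius) that set it.  Each on bit is treated downstream as
#' one "substructure" key in the compound-CYP cross-attention.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `substructure_set` with fields `bits` (strictly
#'   increasing integers in `[0, 1023]`), `n` (number of on bits),
#'   `atom_environments` (named list, bit -> integer matrix with columns
#'   `center` (1-based atom index) and `radius`), and `smiles` (canonical
#'   form).
#' @export
compute_substructures <- function(smiles) {
  rec <- .featurize_record(smiles)
  bits <- sort(as.integer(unlist(rec$bits)))
  envs <- lapply(rec$bit_envs, function(e) {
    m <- do.call(rbind, lapply(e, function(x) as.integer(unlist(x))))
    m[, 1] <- m[, 1] + 1L  # 0-based atom -> 1-based
    colnames(m) <- c("center", "radius")
    m
  })
  structure(list(bits = bits, n = length(bits),
                 atom_environments = envs[as.character(bits)],
                 smiles = rec$canonical),
            class = "substructure_set")
}

#' @export
print.substructure_set <- function(x, ...) {
  cat(sprintf("<substructure_set> %s\n  %d on bits of 1024 (radius-2 ECFP)\n",
              x$smiles, x$n))
  invisible(x)
}

#' Build the molecular graph of a compound
#'
#' One node per heavy atom with nine categorical features (atomic number,
#' chirality, degree, formal charge, hydrogen count, radical electrons,
#' hybridization, aromaticity, ring membership) and two directed edges per
#' bond with three categorical features (bond type, stereo, conjugation).
#' Hydrogens are implicit.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecular_graph` with fields `n_atoms`,
#'   `node_features` (`n x 9` integer matrix of 1-based vocabulary codes),
#'   `edges` (`m x 2` integer matrix of directed edges, 1-based), and
#'   `edge_features` (`m x 3` integer matrix, rows aligned with `edges`).
#' @export
build_molecular_graph <- function(smiles) {
  rec <- .featurize_record(smiles)
  nf <- do.call(rbind, lapply(rec$atoms, function(a) as.integer(unlist(a))))
  nf <- nf + 1L  # 1-based codes
  colnames(nf) <- c("atomic_num", "chirality", "degree", "formal_charge",
                    "num_hs", "radical_electrons", "hybridization",
                    "aromatic", "in_ring")
  if (length(rec$bonds) > 0L) {
    b <- do.call(rbind, lapply(rec$bonds, function(x) as.integer(unlist(x))))
    u <- b[, 1] + 1L; v <- b[, 2] + 1L
    edges <- cbind(c(u, v), c(v, u))
    ef <- rbind(b[, 3:5, drop = FALSE], b[, 3:5, drop = FALSE]) + 1L
  } else {
    edges <- matrix(integer(0), ncol = 2)
    ef <- matrix(integer(0), ncol = 3)
  }
  colnames(edges) <- c("from", "to")
  colnames(ef) <- c("bond_type", "bond_stereo", "conjugated")
  structure(list(n_atoms = nrow(nf), node_features = nf,
                 edges = edges, edge_features = ef,
                 smiles = rec$canonical),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s\n  %d atoms, %d directed edges\n",
              x$smiles, x$n_atoms, nrow(x$edges)))
  invisible(x)
}

#' Map fingerprint bits to the atoms of their circular environments
#'
#' For each requested bit, returns the union of atoms covered by every
#' circular environment that set the bit (the center atom plus all atoms
#' within the environment radius).  Used to highlight the molecular regions
#' behind highly attended substructures.
#'
#' @param s A `substructure_set` from [compute_substructures()].
#' @param smiles The compound's SMILES (used to rebuild bond topology).
#' @param bits Integer vector of bit indices; must be a subset of `s$bits`.
#' @return Named list, bit -> sorted integer vector of 1-based atom indices.
#' @export
map_bits_to_atoms <- function(s, smiles, bits) {
  stopifnot(inherits(s, "substructure_set"))
  bits <- as.integer(bits)
  unknown <- setdiff(bits, s$bits)
  if (length(unknown) > 0L) {
    stop(sprintf("bit(s) %s not present in the compound's substructure set",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  g <- build_molecular_graph(smiles)
  adj <- vector("list", g$n_atoms)
  if (nrow(g$edges) > 0L) {
    for (i in seq_len(nrow(g$edges))) {
      adj[[g$edges[i, 1]]] <- c(adj[[g$edges[i, 1]]], g$edges[i, 2])
    }
  }
  ball <- function(center, radius) {
    seen <- center
    frontier <- center
    r <- 0L
    while (r < radius && length(frontier) > 0L) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, frontier)
      r <- r + 1L
    }
    seen
  }
  out <- lapply(bits, function(b) {
    envs <- s$atom_environments[[as.character(b)]]
    sort(unique(unlist(lapply(seq_len(nrow(envs)), function(i)
      ball(envs[i, "center"], envs[i, "radius"])))))
  })
  names(out) <- as.character(bits)
  out
}

#' Featurize a batch of compounds
#'
#' Computes (and caches) the substructure set and molecular graph of every
#' compound in one featurizer invocation.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Named list (by input SMILES): each element has `canonical`,
#'   `substructures` and `graph`.
#' @export
featurize_compounds <- function(smiles) {
  stopifnot(is.character(smiles))
  .featurize_fill_cache(smiles)
  out <- lapply(smiles, function(s) {
    list(canonical = canonicalize_smiles(s, quiet = TRUE),
         substructures = compute_substructures(s),
         graph = build_molecular_graph(s))
  })
  names(out) <- smiles
  out
}
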
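# Drug featurization: SMILES -> three binary fingerprints.
#
# MACCS keys come from OpenBabel (ChemmineOB), whose 166 SMARTS-defined keys
# use the same numbering as every other MACCS implementation. The hashed
# topological-torsion (HashTT) and MinHashed atom-pair (MAP4) fingerprints
# are computed here directly on the molecular graph: torsions are linear
# paths of four bonded heavy atoms labelled by (element, pi electrons,
# branching); MAP4 shingles pair circular substructures of radius 1 and 2
# bonds around two atoms with their topological distance, then MinHash the
# shingle set.

#' Parse and canonicalize a SMILES string
#'
#' Parses `smiles` with OpenBabel, canonicalizes it, and extracts the heavy-
#' atom molecular graph used by the hashed fingerprints. Multi-fragment
#' inputs (salts, mixtures) are reduced to their largest fragment by heavy
#' atom count before canonicalization.
#'
#' @param smiles A single non-empty SMILES string.
#' @param id Optional drug identifier carried along with the molecule.
#' @return An object of class `synfuse_molecule`: a list with elements
#'   `id`, `smiles` (canonical form), `atoms` (data frame of element symbols)
#'   and `bonds` (data frame with columns `from`, `to`, `order`).
#' @examples
#' mol <- parse_smiles("OCC")
#' mol$smiles  # canonical form, identical to parse_smiles("CCO")$smiles
#' @export
parse_smiles <- function(smiles, id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_invalid_smiles(as.character(smiles), "empty or non-string input")
  }
  smiles <- trimws(smiles)
  canon <- .canonical_smiles(smiles)
  if (is.na(canon)) stop_invalid_smiles(smiles, "unparsable by OpenBabel")
  # Salts / mixtures: keep the largest fragment, then re-canonicalize.
  if (grepl(".", canon, fixed = TRUE)) {
    frags <- strsplit(canon, ".", fixed = TRUE)[[1]]
    sizes <- vapply(frags, function(f) {
      g <- tryCatch(.mol_graph(f), error = function(e) NULL)
      if (is.null(g)) -1L else nrow(g$atoms)
    }, integer(1))
    if (all(sizes < 0L)) stop_invalid_smiles(smiles, "no parsable fragment")
    canon <- .canonical_smiles(frags[[which.max(sizes)]])
  }
  g <- .mol_graph(canon)
  structure(list(id = id, smiles = canon, atoms = g$atoms, bonds = g$bonds),
            class = "synfuse_molecule")
}

#' @export
print.synfuse_molecule <- function(x, ...) {
  cat(sprintf("<molecule%s> %s (%d heavy atoms, %d bonds)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

.canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- sub("[\t ].*$", "", sub("\n$", "", out))
  if (!nzchar(out)) return(NA_character_)
  out
}

# Heavy-atom graph of a single-fragment SMILES via an SDF round trip.
# OpenBabel kekulizes on output, so bond orders are 1/2/3.
.mol_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) stop("no atoms parsed")
  elements <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || length(bb) == 0L || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    bb <- as.data.frame(bb)
    bonds <- data.frame(from = as.integer(bb[[1]]), to = as.integer(bb[[2]]),
                        order = pmin(as.integer(bb[[3]]), 3L))
  }
  list(atoms = data.frame(element = elements, stringsAsFactors = FALSE),
       bonds = bonds)
}

.assert_molecule <- function(mol) {
  if (!inherits(mol, "synfuse_molecule")) {
    stop_domain("expected a 'synfuse_molecule'; see parse_smiles()")
  }
  mol
}

.fp_vector <- function(values, kind) {
  values <- as.integer(values)
  attr(values, "kind") <- kind
  values
}

#' MACCS keys fingerprint
#'
#' Computes the 166 MACCS structural keys of a molecule as a binary vector.
#' Toolkits conventionally store MACCS in a wider array whose leading bit is
#' unused; only keys 1 through 166 are returned, so `length(fp) == 166` and
#' position `i` is MACCS key `i`.
#'
#' @param mol A `synfuse_molecule` from [parse_smiles()].
#' @return Integer 0/1 vector of length 166 with attribute `kind = "maccs"`.
#' @examples
#' fp <- compute_maccs(parse_smiles("c1ccccc1"))
#' which(fp == 1)  # aromatic/ring keys 162, 163, 165
#' @export
compute_maccs <- function(mol) {
  .assert_molecule(mol)
  ref <- ChemmineOB::forEachMol("SMILES", mol$smiles, identity)
  bits <- ChemmineOB::fingerprint_OB(ref, "MACCS")
  .fp_vector(bits[seq_len(166L)], "maccs")
}

# Per-atom pi-electron counts derived from kekulized bond orders.
.atom_pi <- function(mol) {
  pi <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0L) {
    extra <- mol$bonds$order - 1L
    for (k in seq_len(nrow(mol$bonds))) {
      pi[mol$bonds$from[k]] <- pi[mol$bonds$from[k]] + extra[k]
      pi[mol$bonds$to[k]] <- pi[mol$bonds$to[k]] + extra[k]
    }
  }
  pi
}

.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Hashed topological-torsion fingerprint
#'
#' Enumerates every linear path of four consecutively bonded heavy atoms,
#' labels each atom by (element, pi electrons, number of attached heavy-atom
#' branches outside the path), orients each path canonically, and hashes the
#' resulting fragment strings into `n_bits` presence/absence buckets.
#'
#' Molecules with fewer than four heavy atoms have no torsion fragment; an
#' all-zero vector is returned with a `degenerate_molecule_warning`.
#'
#' @param mol A `synfuse_molecule`.
#' @param n_bits Fingerprint length (>= 64); default 512.
#' @return Integer 0/1 vector of length `n_bits`, attribute `kind = "hashtt"`.
#' @export
compute_hashtt <- function(mol, n_bits = 512L) {
  .assert_molecule(mol)
  n_bits <- as.integer(n_bits)
  if (is.na(n_bits) || n_bits < 64L) stop_domain("n_bits must be >= 64")
  vec <- integer(n_bits)
  n <- nrow(mol$atoms)
  if (n < 4L) {
    warn_degenerate_molecule(
      sprintf("molecule %s has %d heavy atoms; no 4-atom torsion path exists",
              mol$smiles, n))
    return(.fp_vector(vec, "hashtt"))
  }
  adj <- .adjacency(mol)
  deg <- lengths(adj)
  pi <- .atom_pi(mol)
  elem <- mol$atoms$element
  lab <- function(x, excl) paste(elem[x], pi[x], deg[x] - excl, sep = ",")
  frags <- character(0)
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds$from[k]; cc <- mol$bonds$to[k]
    for (a in setdiff(adj[[b]], cc)) {
      for (d in setdiff(adj[[cc]], c(b, a))) {
        fwd <- paste(lab(a, 1L), lab(b, 2L), lab(cc, 2L), lab(d, 1L), sep = "|")
        rev <- paste(lab(d, 1L), lab(cc, 2L), lab(b, 2L), lab(a, 1L), sep = "|")
        frags <- c(frags, if (fwd <= rev) fwd else rev)
      }
    }
  }
  frags <- unique(frags)
  if (length(frags) == 0L) {
    warn_degenerate_molecule(
      sprintf("molecule %s has no 4-atom torsion path", mol$smiles))
    return(.fp_vector(vec, "hashtt"))
  }
  vec[(.hash_strings(frags) %% n_bits) + 1L] <- 1L
  .fp_vector(vec, "hashtt")
}

# Canonical circular-substructure strings of radius 0..2 for every atom:
# radius 0 is (element, degree, pi); radius r appends the sorted multiset of
# (bond order, neighbour's radius r-1 string).
.circular_reps <- function(mol, adj, radius = 2L) {
  deg <- lengths(adj)
  pi <- .atom_pi(mol)
  n <- nrow(mol$atoms)
  border <- matrix(0L, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    border[mol$bonds$from[k], mol$bonds$to[k]] <- mol$bonds$order[k]
    border[mol$bonds$to[k], mol$bonds$from[k]] <- mol$bonds$order[k]
  }
  reps <- vector("list", radius + 1L)
  reps[[1]] <- paste(mol$atoms$element, deg, pi, sep = ",")
  for (r in seq_len(radius)) {
    prev <- reps[[r]]
    reps[[r + 1L]] <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (length(nb) == 0L) return(prev[i])
      parts <- sort(paste0(border[i, nb], prev[nb]))
      paste0(prev[i], "(", paste(parts, collapse = ";"), ")")
    }, character(1))
  }
  reps
}

#' MinHashed atom-pair fingerprint
#'
#' For every unordered heavy-atom pair, circular substructures of radius 1
#' and 2 bonds around the two atoms are combined with the topological
#' distance between them into shingle strings. The shingle set is MinHashed
#' with `dims` fixed universal hash functions and the integer signature is
#' folded modulo `dims` into a binary presence vector, so the same molecule
#' always yields the same bits.
#'
#' @param mol A `synfuse_molecule`.
#' @param dims Fingerprint length (>= 64); default 512.
#' @return Integer 0/1 vector of length `dims`, attribute `kind = "map4"`.
#' @export
compute_map4 <- function(mol, dims = 512L) {
  .assert_molecule(mol)
  dims <- as.integer(dims)
  if (is.na(dims) || dims < 64L) stop_domain("dims must be >= 64")
  vec <- integer(dims)
  n <- nrow(mol$atoms)
  if (n < 2L) {
    warn_degenerate_molecule(
      sprintf("molecule %s has a single heavy atom; no atom pair exists",
              mol$smiles))
    return(.fp_vector(vec, "map4"))
  }
  adj <- .adjacency(mol)
  reps <- .circular_reps(mol, adj, radius = 2L)
  g <- igraph::graph_from_data_frame(
    mol$bonds[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  dist <- igraph::distances(g)
  shingles <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dist[i, j]
      if (!is.finite(d)) next
      for (r in 2:3) { # radius 1 and 2 strings
        si <- reps[[r]][i]; sj <- reps[[r]][j]
        if (si > sj) { tmp <- si; si <- sj; sj <- tmp }
        shingles <- c(shingles, paste(si, d, sj, sep = "|"))
      }
    }
  }
  shingles <- unique(shingles)
  if (length(shingles) == 0L) {
    warn_degenerate_molecule(
      sprintf("molecule %s yields no atom-pair shingle", mol$smiles))
    return(.fp_vector(vec, "map4"))
  }
  sig <- .minhash_signature(.hash_strings(shingles), dims)
  vec[(sig %% dims) + 1L] <- 1L
  .fp_vector(vec, "map4")
}

#' Featurize a drug table into all three fingerprints
#'
#' Computes the HashTT, MAP4 and MACCS fingerprints for every drug in a
#' two-column table. Results are cached by canonical SMILES, so duplicate
#' structures under different identifiers share one computation and receive
#' identical vectors. Invalid SMILES are collected and reported together.
#'
#' @param drugs Data frame (or coercible) with columns `id` and `smiles`.
#' @param n_bits HashTT length; default 512.
#' @param dims MAP4 length; default 512.
#' @return Named list keyed by drug id; each element is a list with entries
#'   `hashtt`, `map4`, `maccs`.
#' @export
featurize_drug_table <- function(drugs, n_bits = 512L, dims = 512L) {
  drugs <- as.data.frame(drugs)
  if (nrow(drugs) == 0L) return(structure(list(), names = character(0)))
  if (!all(c("id", "smiles") %in% names(drugs))) {
    stop_domain("drug table needs columns 'id' and 'smiles'")
  }
  ids <- as.character(drugs$id)
  if (anyDuplicated(ids)) stop_domain("drug ids must be unique")
  mols <- vector("list", nrow(drugs))
  bad <- character(0)
  for (i in seq_len(nrow(drugs))) {
    mol <- tryCatch(parse_smiles(drugs$smiles[i], id = ids[i]),
                    invalid_smiles_error = function(e) NULL)
    mols[i] <- list(mol)
    if (is.null(mol)) bad <- c(bad, ids[i])
  }
  if (length(bad) > 0L) {
    stop_invalid_smiles(bad, "unparsable SMILES for these drug ids")
  }
  cache <- new.env(parent = emptyenv())
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(mols)) {
    key <- mols[[i]]$smiles
    if (is.null(cache[[key]])) {
      cache[[key]] <- list(
        hashtt = compute_hashtt(mols[[i]], n_bits = n_bits),
        map4 = compute_map4(mols[[i]], dims = dims),
        maccs = compute_maccs(mols[[i]])
      )
    }
    out[[i]] <- cache[[key]]
  }
  out
}

#' Assemble fingerprint matrices from a featurized drug table
#'
#' Converts the per-drug list returned by [featurize_drug_table()] into one
#' drugs-by-bits matrix per fingerprint kind, with drug ids as row names;
#' this is the layout consumed by the model.
#'
#' @param featurized Output of [featurize_drug_table()].
#' @return Named list of matrices `hashtt`, `map4`, `maccs`.
#' @export
fingerprint_matrices <- function(featurized) {
  kinds <- c("hashtt", "map4", "maccs")
  out <- lapply(kinds, function(k) {
    m <- do.call(rbind, lapply(featurized, function(f) as.integer(f[[k]])))
    rownames(m) <- names(featurized)
    m
  })
  names(out) <- kinds
  out
}
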
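# SMILES handling: canonicalization through OpenBabel, molecular graphs,
# Bemis-Murcko scaffolds and hashed circular (Morgan-style) fingerprints.
#
# OpenBabel (via ChemmineOB) is used for SMILES parsing and canonical SMILES
# generation.  Scaffold pruning and fingerprinting operate on the bond graph
# extracted from the V2000 molfile that OpenBabel writes; ring membership
# comes from igraph bridge detection (an atom is in a ring iff it has an
# incident non-bridge edge).

ob_convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
    error = function(e) "")
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every spelling of a molecule to one canonical string (OpenBabel
#' canonical SMILES).  Canonicalization is idempotent.  Unparseable strings
#' are an error by default; with `on_error = "drop"` they come back as `NA`
#' so callers can drop and count them.
#'
#' @param smiles character vector of SMILES.
#' @param on_error `"error"` or `"drop"` (unparseable entries become `NA`).
#' @return character vector of canonical SMILES, same length as the input.
#' @export
canonicalize_smiles <- function(smiles, on_error = c("error", "drop")) {
  on_error <- match.arg(on_error)
  smiles <- as.character(smiles)
  n <- length(smiles)
  if (n == 0) return(character(0))
  out <- rep(NA_character_, n)
  todo <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  if (length(todo) > 0) {
    # Batch conversion with index titles so failed lines can be realigned:
    # OpenBabel silently omits unparseable records from its output.
    input <- paste(sprintf("%s\tidx%d", trimws(smiles[todo]), todo),
                   collapse = "\n")
    res <- ob_convert("SMI", "CAN", input)
    if (nzchar(res)) {
      lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      for (p in parts) {
        if (length(p) >= 2 && grepl("^idx[0-9]+$", p[2])) {
          i <- as.integer(sub("idx", "", p[2]))
          if (nzchar(p[1])) out[i] <- p[1]
        }
      }
    }
  }
  # a bad record can abort the rest of the batch; retry leftovers singly
  retry <- which(!is.na(smiles) & nzchar(trimws(smiles)) & is.na(out))
  for (i in retry) {
    res <- ob_convert("SMI", "CAN", trimws(smiles[i]))
    if (nzchar(res)) out[i] <- strsplit(res, "\t|\n")[[1]][1]
  }
  failed <- which(!is.na(smiles) & nzchar(trimws(smiles)) & is.na(out))
  if (length(failed) > 0 && on_error == "error") {
    stop("unparseable SMILES: ",
         paste(unique(smiles[head(failed, 10)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Parse a SMILES into an atom/bond graph via an OpenBabel V2000 molfile.
# Returns NULL for unparseable input.  Hydrogens stay implicit.
smiles_to_graph <- function(smiles) {
  sdf <- ob_convert("SMI", "SDF", trimws(smiles))
  if (!nzchar(sdf)) return(NULL)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)
  atom_lines <- lines[4 + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- NULL
  if (!is.na(n_bonds) && n_bonds > 0) {
    bond_lines <- lines[4 + n_atoms + seq_len(n_bonds)]
    bonds <- cbind(from = as.integer(substr(bond_lines, 1, 3)),
                   to = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  }
  list(elements = elements, bonds = bonds, n_atoms = n_atoms)
}

# Atoms that belong to a ring: endpoints of edges that are not bridges.
ring_atoms <- function(graph) {
  if (is.null(graph$bonds) || nrow(graph$bonds) == 0) return(integer(0))
  g <- igraph::make_graph(edges = as.vector(t(graph$bonds[, 1:2])),
                          n = graph$n_atoms, directed = FALSE)
  br <- igraph::bridges(g)
  non_bridge <- setdiff(seq_len(nrow(graph$bonds)), as.integer(br))
  sort(unique(as.vector(graph$bonds[non_bridge, 1:2])))
}

# Serialize an induced subgraph back to a V2000 molfile (no coordinates)
# and let OpenBabel emit its canonical SMILES.
subgraph_to_canonical <- function(graph, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(graph$n_atoms), keep)
  bonds <- graph$bonds
  if (!is.null(bonds)) {
    sel <- bonds[, 1] %in% keep & bonds[, 2] %in% keep
    bonds <- bonds[sel, , drop = FALSE]
  }
  n_a <- length(keep)
  n_b <- if (is.null(bonds)) 0L else nrow(bonds)
  atom_block <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    graph$elements[keep])
  bond_block <- character(0)
  if (n_b > 0) {
    bond_block <- sprintf("%3d%3d%3d  0  0  0  0",
                          idx[bonds[, 1]], idx[bonds[, 2]], bonds[, 3])
  }
  mol <- paste(c("", " ligandblend", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b),
                 atom_block, bond_block, "M  END", "$$$$", ""),
               collapse = "\n")
  out <- ob_convert("SDF", "CAN", mol)
  if (!nzchar(out)) return(NA_character_)
  strsplit(out, "\t|\n")[[1]][1]
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The scaffold is the ring systems plus the linker atoms connecting them,
#' with all side chains removed: non-ring atoms are pruned iteratively from
#' the terminals inward, ring atoms are never pruned, and atoms attached to
#' the retained core by a double or triple bond (e.g. exocyclic carbonyl
#' oxygens on linkers) are restored.  Acyclic molecules have the empty
#' scaffold `""`, which all acyclic molecules share.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for unparseable input).
#' @export
murcko_scaffold <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s)) return(NA_character_)
    graph <- smiles_to_graph(s)
    if (is.null(graph)) return(NA_character_)
    rings <- ring_atoms(graph)
    if (length(rings) == 0) return("")
    keep <- rep(TRUE, graph$n_atoms)
    protected <- seq_len(graph$n_atoms) %in% rings
    repeat {
      deg <- integer(graph$n_atoms)
      active <- graph$bonds[keep[graph$bonds[, 1]] & keep[graph$bonds[, 2]], ,
                            drop = FALSE]
      tab <- table(factor(as.vector(active[, 1:2]),
                          levels = seq_len(graph$n_atoms)))
      deg <- as.integer(tab)
      prune <- which(keep & !protected & deg <= 1)
      if (length(prune) == 0) break
      keep[prune] <- FALSE
    }
    # restore atoms multiply-bonded to the core (exocyclic =O, =N, etc.)
    restore <- graph$bonds[, "order"] >= 2 &
      (keep[graph$bonds[, 1]] | keep[graph$bonds[, 2]])
    keep[as.vector(graph$bonds[restore, 1:2])] <- TRUE
    subgraph_to_canonical(graph, which(keep))
  }, character(1), USE.NAMES = FALSE)
}

# ---- circular (Morgan-style) fingerprints --------------------------------

# Deterministic 31-bit integer hash of an integer vector (FNV-1a style).
hash_ints <- function(v) {
  h <- 2166136261
  for (x in v) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(x %% 2147483647))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

element_number <- function(el) {
  tab <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
           Cl = 17, Br = 35, I = 53)
  out <- unname(tab[el])
  out[is.na(out)] <- 99L
  as.integer(out)
}

#' Hashed circular fingerprint of a molecule
#'
#' Morgan-style fingerprint: each atom starts from an invariant of
#' (element, heavy degree, summed bond orders, ring membership); the
#' invariant is then iteratively re-hashed together with the sorted
#' (bond order, neighbour identifier) list out to `radius` bonds.  The
#' fingerprint is the set of all identifiers seen at radii `0..radius`,
#' compared with [tanimoto()].
#'
#' @param smiles one SMILES string.
#' @param radius neighbourhood radius in bonds (default 2, ECFP4-like).
#' @return sorted integer vector of substructure identifiers, or `NULL` for
#'   unparseable input.
#' @export
morgan_fingerprint <- function(smiles, radius = 2) {
  graph <- smiles_to_graph(smiles)
  if (is.null(graph)) return(NULL)
  n <- graph$n_atoms
  nbrs <- vector("list", n)
  if (!is.null(graph$bonds) && nrow(graph$bonds) > 0) {
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[b, 1]; j <- graph$bonds[b, 2]
      o <- graph$bonds[b, 3]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  in_ring <- seq_len(n) %in% ring_atoms(graph)
  deg <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bond_sum <- vapply(nbrs, function(x) if (is.null(x)) 0L else sum(x[, 2]),
                     numeric(1))
  ids <- mapply(function(el, d, bs, r) hash_ints(c(el, d, bs, r)),
                element_number(graph$elements), deg, bond_sum,
                as.integer(in_ring))
  seen <- ids
  for (r in seq_len(radius)) {
    new_ids <- integer(n)
    for (a in seq_len(n)) {
      if (is.null(nbrs[[a]])) { new_ids[a] <- hash_ints(c(r, ids[a])); next }
      env <- nbrs[[a]]
      pairs <- cbind(env[, 2], ids[env[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      new_ids[a] <- hash_ints(c(r, ids[a], as.vector(t(pairs[ord, , drop = FALSE]))))
    }
    ids <- new_ids
    seen <- c(seen, ids)
  }
  sort(unique(seen))
}

#' Tanimoto similarity of two fingerprints
#'
#' @param fp_a,fp_b integer identifier sets from [morgan_fingerprint()].
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) == 0 && length(fp_b) == 0) return(1)
  inter <- length(intersect(fp_a, fp_b))
  inter / (length(fp_a) + length(fp_b) - inter)
}
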
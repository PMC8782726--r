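# Substructure sentences: molecules as "sentences" whose "words" are
# per-atom circular-environment identifiers (Morgan-style), radii 0..R,
# emitted in atom order with radii interleaved. The identifiers are stable
# FNV-1a hashes of iteratively refined atom invariants, so a fixed canonical
# SMILES always yields the same sentence.

#' Substructure sentence of a molecule
#'
#' @param mol a `mol_graph` (from [mol_graphs()]) or a single SMILES string.
#' @param radius maximum environment radius R (tokens are emitted for every
#'   radius 0..R). Default 1, the usual choice for substructure embeddings.
#' @return character vector of `n_heavy_atoms * (R + 1)` environment
#'   identifiers, ordered atom1-r0, atom1-r1, ..., atom2-r0, ...
#' @examples
#' \donttest{
#' s <- mol_sentence("c1ccccc1", radius = 1)
#' length(s)           # 12
#' length(unique(s))   # 2: all carbons are equivalent
#' }
#' @export
mol_sentence <- function(mol, radius = 1L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    .fatal_config("sentence radius must be a non-negative integer")
  radius <- as.integer(radius)
  if (is.character(mol)) mol <- mol_graphs(mol)[[1]]
  if (is.null(mol)) .fatal_input("cannot build sentence: molecule failed to parse")

  heavy <- which(mol$symbol != "H")
  n <- length(heavy)
  if (n == 0L) return(character(0))

  # neighbour lists over heavy atoms, with bond labels
  nbr <- vector("list", mol$n_atoms)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    o <- mol$bonds$order[b]
    # aromatic bond label when both ends are aromatic: makes environments
    # independent of the kekule structure chosen by the engine
    lab <- if (mol$aromatic[a1] && mol$aromatic[a2]) "a" else as.character(o)
    if (mol$symbol[a2] != "H") nbr[[a1]] <- rbind(nbr[[a1]], c(a2, lab))
    if (mol$symbol[a1] != "H") nbr[[a2]] <- rbind(nbr[[a2]], c(a1, lab))
  }

  # radius-0 invariant: element, charge, total H count, heavy degree,
  # bond-order sum, aromaticity
  heavy_deg <- vapply(seq_len(mol$n_atoms), function(a) {
    if (is.null(nbr[[a]])) 0L else nrow(nbr[[a]])
  }, integer(1))
  inv <- paste(mol$symbol, mol$charge, mol$nH, heavy_deg, mol$bondsum,
               as.integer(mol$aromatic), sep = ",")
  inv <- .fnv1a32(inv)

  tokens <- matrix("", nrow = radius + 1L, ncol = n)
  tokens[1L, ] <- inv[heavy]
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      nxt <- inv
      for (a in seq_len(mol$n_atoms)) {
        if (mol$symbol[a] == "H") next
        nb <- nbr[[a]]
        if (is.null(nb)) {
          env <- inv[a]  # isolated heavy atom: environment cannot grow
        } else {
          parts <- paste0(nb[, 2], ":", inv[as.integer(nb[, 1])])
          env <- paste(c(inv[a], sort(parts)), collapse = "|")
        }
        nxt[a] <- env
      }
      inv <- .fnv1a32(nxt)
      tokens[r + 1L, ] <- inv[heavy]
    }
  }
  as.vector(tokens)  # column-major: atom-major, radii interleaved
}

#' Sentences for a whole compound set
#'
#' @param records compound set with `status == "ok"` rows, or a character
#'   vector of SMILES.
#' @param radius environment radius, as in [mol_sentence()].
#' @return named list of sentences (NULL for records that fail to parse).
#' @export
mol_sentences <- function(records, radius = 1L) {
  if (is.character(records)) {
    smiles <- records
    ids <- names(records)
    if (is.null(ids)) ids <- as.character(seq_along(smiles))
  } else {
    smiles <- ifelse(records$status == "ok", records$canonical_smiles, NA)
    ids <- records$id
  }
  graphs <- mol_graphs(smiles)
  out <- lapply(graphs, function(g) {
    if (is.null(g)) NULL else mol_sentence(g, radius)
  })
  names(out) <- ids
  out
}
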
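# The 2D channel: pharmacophore-pair fingerprint. Atoms are typed into six
# pharmacophoric classes; every unordered pair of typed atoms, together with
# the binned topological (bond-path) distance between them, is hashed into a
# fixed-size sparse bit vector. Captures the graph relationship between
# functional fragments without any 3D information.

.pharm_types <- c("donor", "acceptor", "aromatic", "hydrophobe",
                  "pos_ionizable", "neg_ionizable")

#' 2D pharmacophore fingerprint scheme
#'
#' @param size folded fingerprint length (positions), default 2048.
#' @param bins upper edges of the topological distance bins in bond lengths;
#'   default bins 1..7 plus an open-ended >= 8 bin.
#' @return a `pharm2d_scheme` list.
#' @export
pharm2d_scheme <- function(size = 2048L, bins = 1:7) {
  structure(list(size = as.integer(size), bins = as.integer(bins)),
            class = "pharm2d_scheme")
}

# Rule-based pharmacophore typing on the annotated graph. Returns a list of
# integer atom-index vectors, one per type.
pharm_type_atoms <- function(g) {
  n <- g$n_atoms
  sym <- g$symbol
  heavy <- sym != "H"

  # adjacency and carbonyl lookup used by several rules
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    a1 <- g$bonds$a1[b]; a2 <- g$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  dbl_to_O <- logical(n)  # atom has a double bond to oxygen
  for (b in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[b] == 2L) {
      if (sym[g$bonds$a2[b]] == "O") dbl_to_O[g$bonds$a1[b]] <- TRUE
      if (sym[g$bonds$a1[b]] == "O") dbl_to_O[g$bonds$a2[b]] <- TRUE
    }
  }

  donor <- heavy & sym %in% c("N", "O") & g$nH > 0L & g$charge >= 0L
  acceptor <- heavy & (
    (sym == "O" & g$charge <= 0L) |
    # N with an available lone pair: not pyrrole-type (aromatic N-H),
    # not quaternary/positively charged
    (sym == "N" & g$charge <= 0L & g$bondsum < 4L & !(g$aromatic & g$nH > 0L))
  )
  aromatic <- heavy & g$aromatic

  hetero <- sym %in% c("N", "O", "P", "S")
  hydrophobe <- logical(n)
  for (a in which(heavy)) {
    if (sym[a] == "C" && !g$aromatic[a]) {
      nbs <- adj[[a]]
      if (!any(hetero[nbs])) hydrophobe[a] <- TRUE
    } else if (sym[a] %in% c("Cl", "Br", "I")) {
      hydrophobe[a] <- TRUE
    }
  }

  # basic amine N (not amide, not aromatic) or formally positive atom
  pos <- heavy & g$charge > 0L
  for (a in which(heavy & sym == "N" & !g$aromatic & g$charge == 0L)) {
    if (g$bondsum[a] <= 3L && !any(dbl_to_O[adj[[a]]]) && !dbl_to_O[a])
      pos[a] <- TRUE
  }

  # carboxylic acid O-H (or formally negative atom)
  neg <- heavy & g$charge < 0L
  for (a in which(sym == "O" & g$nH > 0L)) {
    if (any(sym[adj[[a]]] == "C" & dbl_to_O[adj[[a]]])) neg[a] <- TRUE
  }

  list(donor = which(donor), acceptor = which(acceptor),
       aromatic = which(aromatic), hydrophobe = which(hydrophobe),
       pos_ionizable = which(pos), neg_ionizable = which(neg))
}

# Topological (bond-path) distance matrix over all atoms.
topo_distances <- function(g) {
  if (nrow(g$bonds) == 0L)
    return(matrix(0, g$n_atoms, g$n_atoms))
  ig <- igraph::graph_from_edgelist(
    as.matrix(g$bonds[, c("a1", "a2")]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_atoms - igraph::vcount(ig)))
  igraph::distances(ig)
}

#' 2D pharmacophore-pair fingerprint
#'
#' @param mol a `mol_graph` or single SMILES string.
#' @param scheme a [pharm2d_scheme()].
#' @return integer vector of on-bit positions (0-based, sorted, unique) with
#'   attributes `size` and `kind = "pharm2d"`. A molecule with no typed
#'   features yields an empty fingerprint (similarity against it is 0).
#' @examples
#' \donttest{
#' fp <- pharm2d_fingerprint("c1ccccc1O")  # phenol: donor/acceptor/aromatic
#' length(fp) > 0
#' }
#' @export
pharm2d_fingerprint <- function(mol, scheme = pharm2d_scheme()) {
  if (is.character(mol)) mol <- mol_graphs(mol)[[1]]
  if (is.null(mol)) .fatal_input("cannot fingerprint: molecule failed to parse")

  typed <- pharm_type_atoms(mol)
  feats <- data.frame(
    type = rep(names(typed), lengths(typed)),
    atom = unlist(typed, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(feats) < 2L) {
    bits <- integer(0)
  } else {
    dmat <- topo_distances(mol)
    nb <- length(scheme$bins)
    keys <- character(0)
    for (i in seq_len(nrow(feats) - 1L)) {
      for (j in seq(i + 1L, nrow(feats))) {
        d <- dmat[feats$atom[i], feats$atom[j]]
        if (!is.finite(d) || d < 1) next  # same atom or disconnected
        bin <- findInterval(d, c(scheme$bins, Inf))  # 1..nb, nb+1 = open bin
        if (bin > nb) bin <- nb + 1L
        t1 <- feats$type[i]; t2 <- feats$type[j]
        if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
        keys <- c(keys, paste(t1, t2, bin, sep = "|"))
      }
    }
    keys <- unique(keys)
    bits <- if (length(keys)) sort(unique(.fnv1a32_mod(keys, scheme$size)))
            else integer(0)
  }
  structure(bits, size = scheme$size, kind = "pharm2d")
}
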
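# Low-level interface to the SMILES engine (OpenBabel via ChemmineR/ChemmineOB).
# Everything downstream works from canonical SMILES produced here, so the
# canonicalisation dialect is pinned to the installed OpenBabel version
# (recorded in run manifests by engine_versions()).

#' @importFrom ChemmineOB convertFormat
NULL

ob_quiet <- function(expr) {
  # OpenBabel writes parse diagnostics straight to stderr; silence them so
  # expected parse failures don't pollute logs/test output.
  err <- tempfile()
  con <- file(err, open = "wt")
  sink(con, type = "message")
  on.exit({
    sink(type = "message")
    close(con)
    unlink(err)
  }, add = TRUE)
  expr
}

#' Canonicalise SMILES strings
#'
#' Vectorised canonicalisation through the pinned SMILES engine. Unparsable
#' entries yield `NA` rather than an error, so one bad library line never
#' aborts a screen.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' \donttest{
#' ob_canonical(c("OCC", "c1ccccc1", "not_a_smiles"))
#' }
#' @export
ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  todo <- which(!bad)
  # Batch conversion aborts at the first unparsable entry, so convert in
  # chunks: everything before a failure is kept, the failing entry is marked
  # NA, and the remainder is retried.
  while (length(todo) > 0L) {
    inp <- paste0(gsub("[\t\n ]+", "", smiles[todo]), " T", seq_along(todo),
                  collapse = "\n")
    res <- ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", inp))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    got <- integer(0)
    if (length(lines) > 0) {
      parts <- strsplit(lines, "[ \t]+")
      got <- as.integer(sub("^T", "", vapply(parts, function(p) p[length(p)], "")))
      can <- vapply(parts, `[[`, "", 1L)
      out[todo[got]] <- can
    }
    done <- if (length(got)) max(got) else 0L
    # entry done+1 failed (or everything converted)
    if (done + 1L > length(todo)) break
    todo <- todo[seq(done + 2L, length.out = length(todo) - done - 1L)]
  }
  out
}

# Ordered atom tokens of a SMILES string: symbol + aromatic flag per atom.
# Atom order matches the engine's SMILES -> SDF atom order, which lets us
# attach aromaticity (lost in the kekulised SDF) back onto the graph.
smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sym <- character(0)
  arom <- logical(0)
  i <- 1L
  two_letter <- c("Cl", "Br")
  arom_sym <- c("b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste0(chars[(i + 1):(j - 1)], collapse = "")
      body <- sub("^[0-9]+", "", body)  # isotope
      m <- regmatches(body, regexpr("^([A-Za-z][a-z]?)", body))[1]
      if (!is.na(m) && nzchar(m)) {
        first <- substr(m, 1L, 1L)
        if (first %in% letters) {  # aromatic bracket atom: c, n, o, s, se, as, p
          if (!m %in% c("se", "as")) m <- first
          sym <- c(sym, paste0(toupper(substr(m, 1, 1)), substr(m, 2, 10)))
          arom <- c(arom, TRUE)
        } else {
          # two-letter element only if the second char is a valid lowercase
          # element continuation (e.g. Cl, Br, Na, Si), not an H-count
          if (nchar(m) == 2L && substr(m, 2, 2) == "H" ) m <- first
          sym <- c(sym, m)
          arom <- c(arom, FALSE)
        }
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1]) %in% two_letter) {
      sym <- c(sym, paste0(ch, chars[i + 1])); arom <- c(arom, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      sym <- c(sym, ch); arom <- c(arom, FALSE)
      i <- i + 1L
    } else if (ch %in% arom_sym) {
      sym <- c(sym, toupper(ch)); arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L  # bonds, ring closures, branches, dots
    }
  }
  data.frame(symbol = sym, aromatic = arom, stringsAsFactors = FALSE)
}

# Elements present in a SMILES (heavy atoms only).
smiles_elements <- function(smiles) {
  a <- smiles_atoms(smiles)
  setdiff(unique(a$symbol), "H")
}

# Heavy-atom count from the atom tokens.
smiles_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- smiles_atoms(s)
    sum(a$symbol != "H")
  }, integer(1), USE.NAMES = FALSE)
}

# MDL old-style charge codes as parsed by ChemmineR (atom-block column C6).
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Default valences for implicit-H assignment on the kekulised graph.
.valences <- list(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
                  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L)

#' Parse molecules into annotated graphs
#'
#' Converts canonical SMILES into per-molecule graph structures: elements,
#' formal charges, implicit hydrogen counts, aromatic flags, bond list and
#' (optionally) 3D coordinates. This is the substrate for substructure
#' sentences, pharmacophore typing and the 3D feature map.
#'
#' 3D coordinates come from the package's own deterministic embedding:
#' classical multidimensional scaling of the bond-length-scaled topological
#' distance matrix. The construction is per molecule (independent of what
#' else is in the batch) and bit-reproducible, which the radial-shell 3D
#' descriptor requires; force-field geometries are deliberately not used
#' because the available builder is stochastic.
#'
#' @param smiles character vector of valid canonical SMILES.
#' @param coords3d logical; add deterministic 3D coordinates.
#' @return a list of `mol_graph` objects (NULL where conversion failed), each
#'   with fields `symbol`, `aromatic`, `charge`, `nH`, `degree`, `bonds`
#'   (data.frame a1, a2, order), and `xyz` when requested.
#' @export
mol_graphs <- function(smiles, coords3d = FALSE) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (length(ok) == 0L) return(out)
  sdf <- ob_quiet(suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(smiles[ok], paste0("M", ok)))))
  # bond-less molecules (single heavy atom) come back as "invalid" SDFs and
  # are dropped by the converter; map the survivors back by name
  have <- vapply(ChemmineR::SDFset2SDF(sdf), function(x)
    unname(ChemmineR::header(x)["Molecule_Name"]), "")
  for (k in seq_along(ok)) {
    i <- ok[k]
    j <- match(paste0("M", i), have)
    g <- if (!is.na(j)) {
      tryCatch(.graph_from_sdf(sdf[[j]], smiles[i]),
               error = function(e) NULL)
    } else NULL
    if (is.null(g))
      g <- tryCatch(.graph_single_atom(smiles[i]),
                    error = function(e) NULL)
    if (coords3d && !is.null(g))
      g$xyz <- tryCatch(.embed3d(g), error = function(e) NULL)
    out[i] <- list(g)
  }
  out
}

# Deterministic 3D embedding: classical MDS of the topological distance
# matrix scaled by a mean bond length of 1.5 Angstrom. Rotation/reflection
# indeterminacy is irrelevant downstream (the 3D descriptor only uses
# distances from the feature centroid).
.embed3d <- function(g, bond_length = 1.5) {
  n <- g$n_atoms
  if (n == 1L) return(matrix(0, 1L, 3L))
  d <- topo_distances(g)
  if (any(!is.finite(d))) {
    fin <- d[is.finite(d)]
    d[!is.finite(d)] <- if (length(fin)) max(fin) + 2 else 2
  }
  xyz <- suppressWarnings(stats::cmdscale(d * bond_length,
                                          k = min(3L, n - 1L)))
  if (!is.matrix(xyz) || nrow(xyz) != n) return(NULL)
  if (ncol(xyz) < 3L)
    xyz <- cbind(xyz, matrix(0, n, 3L - ncol(xyz)))
  unname(xyz)
}

# Fallback for bond-less molecules: build the one-atom graph from the SMILES
# tokens directly.
.graph_single_atom <- function(smiles) {
  toks <- smiles_atoms(smiles)
  if (nrow(toks) != 1L) return(NULL)
  sym <- toks$symbol
  charge <- 0L
  m <- regmatches(smiles, regexpr("[+-]\\d?", smiles))
  if (length(m) && nzchar(m)) {
    charge <- if (nchar(m) > 1L) as.integer(substring(m, 2)) else 1L
    if (substr(m, 1, 1) == "-") charge <- -charge
  }
  v <- .valences[[sym]]
  nH <- 0L
  if (!is.null(v)) {
    v <- if (sym %in% c("C", "B")) v - abs(charge) else v + charge
    nH <- max(0L, min(v))
  }
  hm <- regmatches(smiles, regexpr("H\\d?", smiles))
  if (length(hm) && nzchar(hm))
    nH <- if (nchar(hm) > 1L) as.integer(substring(hm, 2)) else 1L
  g <- list(smiles = smiles, symbol = sym, aromatic = FALSE,
            charge = charge, nH = nH, degree = 0L, bondsum = 0L,
            bonds = data.frame(a1 = integer(0), a2 = integer(0),
                               order = integer(0)),
            n_atoms = 1L)
  class(g) <- "mol_graph"
  g
}

.graph_from_sdf <- function(sdf1, smiles) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  nat <- nrow(ab)
  symbol <- gsub("_.*$", "", rownames(ab))
  charge <- .mdl_charge[as.character(ab[, "C6"])]
  charge[is.na(charge)] <- 0L
  names(charge) <- NULL

  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    bonds <- bonds[bonds$a1 >= 1L & bonds$a2 >= 1L, , drop = FALSE]
  }

  # aromatic flags from the SMILES tokens (engine preserves atom order)
  toks <- smiles_atoms(smiles)
  aromatic <- if (nrow(toks) == nat && all(toks$symbol == symbol)) {
    toks$aromatic
  } else {
    rep(FALSE, nat)
  }

  bondsum <- integer(nat)
  degree <- integer(nat)
  for (b in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]; o <- bonds$order[b]
    bondsum[a1] <- bondsum[a1] + o; bondsum[a2] <- bondsum[a2] + o
    degree[a1] <- degree[a1] + 1L; degree[a2] <- degree[a2] + 1L
  }

  nH <- integer(nat)
  for (a in seq_len(nat)) {
    v <- .valences[[symbol[a]]]
    if (is.null(v)) next
    # lone-pair elements gain valence with positive charge, lose with negative
    v <- v + charge[a]
    if (symbol[a] %in% c("C", "B")) v <- .valences[[symbol[a]]] - abs(charge[a])
    v <- v[v >= bondsum[a]]
    if (length(v)) nH[a] <- min(v) - bondsum[a]
  }
  # explicit hydrogens also count
  if (any(symbol == "H") && nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      if (symbol[bonds$a2[b]] == "H") nH[bonds$a1[b]] <- nH[bonds$a1[b]] + 1L
      if (symbol[bonds$a1[b]] == "H") nH[bonds$a2[b]] <- nH[bonds$a2[b]] + 1L
    }
  }

  g <- list(smiles = smiles, symbol = symbol, aromatic = aromatic,
            charge = charge, nH = nH, degree = degree, bondsum = bondsum,
            bonds = bonds, n_atoms = nat)
  class(g) <- "mol_graph"
  g
}

#' Engine and package versions for run manifests
#' @return named list of version strings.
#' @export
engine_versions <- function() {
  list(
    r = as.character(getRversion()),
    triscreen = as.character(utils::packageVersion("triscreen")),
    ChemmineR = as.character(utils::packageVersion("ChemmineR")),
    ChemmineOB = as.character(utils::packageVersion("ChemmineOB"))
  )
}
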
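# The 3D channel: a conformer feature-map fingerprint. Each conformer places
# pharmacophore feature points at typed-atom positions; their Gaussian-
# weighted radial distribution around the feature centroid, split by feature
# type, forms a fixed-length vector. Conformer vectors are mean-aggregated
# and unit-normalised.

#' 3D feature-map scheme
#'
#' @param n_shells number of radial shells around the feature-point centroid.
#' @param shell_width shell width in Angstrom (the last shell is open-ended).
#' @param sigma Gaussian width (Angstrom) for soft shell assignment.
#' @return a `shape3d_scheme`; the vector length is
#'   `6 feature types * n_shells` (48 by default).
#' @export
shape3d_scheme <- function(n_shells = 8L, shell_width = 0.5, sigma = 0.5) {
  structure(list(n_shells = as.integer(n_shells), shell_width = shell_width,
                 sigma = sigma, dim = 6L * as.integer(n_shells)),
            class = "shape3d_scheme")
}

# Deterministic per-molecule seed: global seed XOR a stable hash of the
# compound id, so results do not depend on library ordering.
.mol_seed <- function(seed, id) {
  h <- strtoi(substr(.fnv1a32(as.character(id)), 1, 7), 16L)
  bitwXor(as.integer(seed), h)
}

# Rotate the part of the molecule on the a2 side of rotatable bond (a1, a2)
# by `angle` around the bond axis. Used to sample torsional conformers from
# the deterministic base geometry.
.rotate_torsion <- function(xyz, bonds, a1, a2, angle) {
  n <- nrow(xyz)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    if ((bonds$a1[b] == a1 && bonds$a2[b] == a2) ||
        (bonds$a1[b] == a2 && bonds$a2[b] == a1)) next
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
  }
  side <- logical(n)
  queue <- a2
  side[a2] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!side[nb]) { side[nb] <- TRUE; queue <- c(queue, nb) }
  }
  if (side[a1]) return(xyz)  # ring bond: rotation not applicable

  axis <- xyz[a2, ] - xyz[a1, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) return(xyz)
  axis <- axis / nrm
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + sa * K + (1 - ca) * (K %*% K)
  idx <- which(side)
  shifted <- sweep(xyz[idx, , drop = FALSE], 2, xyz[a1, ])
  xyz[idx, ] <- sweep(shifted %*% t(Rm), 2, xyz[a1, ], `+`)
  xyz
}

.rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0L) return(g$bonds[0, ])
  ig <- igraph::graph_from_edgelist(
    as.matrix(g$bonds[, c("a1", "a2")]), directed = FALSE)
  bridges <- igraph::bridges(ig)
  bridge_idx <- as.integer(bridges)
  cand <- g$bonds[bridge_idx, , drop = FALSE]
  cand <- cand[cand$order == 1L, , drop = FALSE]
  # both ends must carry another heavy neighbour for the torsion to matter
  keep <- g$degree[cand$a1] > 1L & g$degree[cand$a2] > 1L
  cand[keep, , drop = FALSE]
}

.feature_map_vector <- function(xyz, typed, scheme) {
  atoms <- unlist(typed, use.names = FALSE)
  if (length(atoms) == 0L) return(NULL)
  pts <- xyz[atoms, , drop = FALSE]
  centroid <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
  shell_centers <- (seq_len(scheme$n_shells) - 0.5) * scheme$shell_width
  v <- numeric(scheme$dim)
  type_of <- rep(seq_along(typed), lengths(typed))
  for (k in seq_along(atoms)) {
    w <- exp(-0.5 * ((d[k] - shell_centers) / scheme$sigma)^2)
    # distances beyond the shell range accumulate in the outermost shell
    if (d[k] > scheme$n_shells * scheme$shell_width)
      w[scheme$n_shells] <- w[scheme$n_shells] +
        (1 - exp(-0.5 * ((d[k] - shell_centers[scheme$n_shells]) / scheme$sigma)^2))
    off <- (type_of[k] - 1L) * scheme$n_shells
    v[off + seq_len(scheme$n_shells)] <- v[off + seq_len(scheme$n_shells)] + w
  }
  v
}

#' 3D conformer feature-map fingerprint
#'
#' Generates a deterministic base 3D geometry, samples up to `n_conf`
#' torsional conformers from it with a per-molecule seed, accumulates each
#' conformer's Gaussian-weighted pharmacophore feature points into a
#' feature-type x radial-shell histogram, averages over conformers and
#' normalises to unit Euclidean norm.
#'
#' @param mol a `mol_graph` with 3D coordinates (`mol_graphs(..., coords3d
#'   = TRUE)`) or a single SMILES string.
#' @param n_conf conformers to sample (>= 1); the base geometry is always
#'   conformer 1.
#' @param seed global seed; combined with the compound id into a
#'   per-molecule stream so results are independent of library order.
#' @param scheme a [shape3d_scheme()].
#' @param id compound identifier used for per-molecule seeding.
#' @return unit-norm numeric vector of length `scheme$dim`, or NULL when the
#'   molecule has no typed feature points or no 3D geometry (the 3D channel
#'   is then recorded as missing, not zero).
#' @export
shape3d_fingerprint <- function(mol, n_conf = 5L, seed = 1L,
                                scheme = shape3d_scheme(), id = NULL) {
  if (n_conf < 1L) .fatal_config("n_conf must be >= 1")
  if (is.character(mol)) {
    if (is.null(id)) id <- mol
    mol <- mol_graphs(mol, coords3d = TRUE)[[1]]
  }
  if (is.null(mol) || is.null(mol$xyz)) return(NULL)
  if (is.null(id)) id <- mol$smiles

  typed <- pharm_type_atoms(mol)
  if (sum(lengths(typed)) == 0L) return(NULL)

  base <- .feature_map_vector(mol$xyz, typed, scheme)
  if (is.null(base)) return(NULL)
  acc <- base
  nconf_done <- 1L

  if (n_conf > 1L) {
    rot <- .rotatable_bonds(mol)
    if (nrow(rot) > 0L) {
      # Park-Miller stream, deterministic in (seed, id); double arithmetic
      # keeps every intermediate below 2^53 so the stream is exact
      rng <- as.numeric(.mol_seed(seed, id)) %% 2147483646 + 1
      for (cidx in seq_len(n_conf - 1L)) {
        xyz <- mol$xyz
        for (b in seq_len(nrow(rot))) {
          rng <- (rng * 48271) %% 2147483647
          angle <- (rng %% 360) * pi / 180
          xyz <- .rotate_torsion(xyz, mol$bonds, rot$a1[b], rot$a2[b], angle)
        }
        v <- .feature_map_vector(xyz, typed, scheme)
        if (!is.null(v)) { acc <- acc + v; nconf_done <- nconf_done + 1L }
      }
    }
  }

  v <- acc / nconf_done
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(NULL)
  structure(v / nrm, kind = "shape3d")
}
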
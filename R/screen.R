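# End-to-end screening: representations for a library and a reference panel,
# per-reference scoring, aggregation, outlier flagging and ranking.

#' Compute all three representations for a compound set
#'
#' @param records standardised compound set (only `status == "ok"` rows are
#'   represented).
#' @param model an `embedding_model` for the 1D channel.
#' @param cfg a [screening_config()].
#' @param quiet suppress progress messages.
#' @return named list (by compound ID) of lists with `embed1d`, `pharm2d`,
#'   `shape3d` (NULL where a channel is unavailable).
#' @export
represent_library <- function(records, model, cfg = screening_config(),
                              quiet = TRUE) {
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) .fatal_input("no valid molecules to represent")
  smiles <- ok$canonical_smiles

  if (!quiet) message("building substructure sentences (radius ",
                      cfg$radius, ") ...")
  graphs2d <- mol_graphs(smiles)
  if (!quiet) message("generating 3D geometries ...")
  graphs3d <- mol_graphs(smiles, coords3d = TRUE)

  out <- vector("list", nrow(ok))
  names(out) <- ok$id
  n_oov_only <- 0L
  for (i in seq_len(nrow(ok))) {
    g <- graphs2d[[i]]
    rep_i <- list(embed1d = NULL, pharm2d = NULL, shape3d = NULL)
    if (!is.null(g)) {
      sent <- mol_sentence(g, cfg$radius)
      v <- withCallingHandlers(
        embed_molecule(model, sent),
        warning = function(w) {
          n_oov_only <<- n_oov_only + 1L
          invokeRestart("muffleWarning")
        })
      if (sqrt(sum(v^2)) > 1e-12) {
        rep_i$embed1d <- structure(v, kind = "embed1d")
      }
      rep_i$pharm2d <- pharm2d_fingerprint(g, cfg$pharm2d)
      if (length(rep_i$pharm2d) == 0L) rep_i$pharm2d <- NULL
    }
    g3 <- graphs3d[[i]]
    if (!is.null(g3)) {
      rep_i$shape3d <- shape3d_fingerprint(g3, n_conf = cfg$n_conf,
                                           seed = cfg$seed,
                                           scheme = cfg$shape3d, id = ok$id[i])
    }
    out[[i]] <- rep_i
  }
  if (!quiet && n_oov_only > 0L)
    message(n_oov_only, " molecule(s) had no in-vocabulary substructure token")
  out
}

# Concatenated per-channel unit-normalised representation, for the outlier
# statistic. Missing channels contribute zeros.
.concat_representation <- function(rep_i, dim1d, size2d, dim3d) {
  v1 <- numeric(dim1d)
  if (!is.null(rep_i$embed1d)) {
    x <- as.numeric(rep_i$embed1d)
    n <- sqrt(sum(x^2)); if (n > 1e-12) v1 <- x / n
  }
  v2 <- numeric(size2d)
  if (!is.null(rep_i$pharm2d) && length(rep_i$pharm2d) > 0L) {
    v2[rep_i$pharm2d + 1L] <- 1
    v2 <- v2 / sqrt(sum(v2^2))
  }
  v3 <- numeric(dim3d)
  if (!is.null(rep_i$shape3d)) v3 <- as.numeric(rep_i$shape3d)
  c(v1, v2, v3)
}

#' Screen a compound library against a reference panel
#'
#' Runs the full three-channel screen: per-reference similarity scores for
#' every library compound, the hyper-space filter at `cfg$theta`, weighted
#' aggregation across channels, robust (median/MAD) outlier flagging in the
#' concatenated representation space, centroid-based cluster labels (for
#' reporting only) and the final ranking.
#'
#' @param library_records,reference_records standardised compound sets.
#' @param model an `embedding_model`.
#' @param cfg a [screening_config()].
#' @param library_reps,reference_reps optional precomputed representations
#'   ([represent_library()]), e.g. to re-rank at a different theta without
#'   recomputing conformers.
#' @param quiet suppress progress messages.
#' @return a `candidate_ranking`; its `rows` carry the full results-table
#'   columns. Attribute `"reps"` holds the library representations,
#'   `"ref_reps"` the panel's, and `"excluded"` any compounds dropped with
#'   their reasons.
#' @export
screen_library <- function(library_records, reference_records, model,
                           cfg = screening_config(),
                           library_reps = NULL, reference_reps = NULL,
                           quiet = TRUE) {
  refs_ok <- reference_records[reference_records$status == "ok", , drop = FALSE]
  if (nrow(refs_ok) == 0L) .fatal_input("reference panel has no valid molecule")

  if (is.null(reference_reps))
    reference_reps <- represent_library(refs_ok, model, cfg, quiet = quiet)
  if (is.null(library_reps))
    library_reps <- represent_library(library_records, model, cfg, quiet = quiet)

  lib_ok <- library_records[library_records$status == "ok", , drop = FALSE]
  lib_ok <- lib_ok[lib_ok$id %in% names(library_reps), , drop = FALSE]

  has_channel <- vapply(library_reps[lib_ok$id], function(r) {
    !is.null(r$embed1d) || !is.null(r$pharm2d) || !is.null(r$shape3d)
  }, logical(1))
  excluded <- data.frame(id = lib_ok$id[!has_channel],
                         reason = rep("no representation available",
                                      sum(!has_channel)),
                         stringsAsFactors = FALSE)
  if (nrow(excluded) > 0L && !quiet)
    message("excluding ", nrow(excluded), " compound(s) with no representation")
  lib_ok <- lib_ok[has_channel, , drop = FALSE]
  if (nrow(lib_ok) == 0L) .fatal_empty("no compound has any representation")

  if (!quiet) message("scoring ", nrow(lib_ok), " compounds against ",
                      nrow(refs_ok), " references ...")
  score_tab <- data.frame(
    compound_id = lib_ok$id, canonical_smiles = lib_ok$canonical_smiles,
    s1d_raw = NA_real_, s1d_ref = NA_character_,
    s2d_raw = NA_real_, s2d_ref = NA_character_,
    s3d_raw = NA_real_, s3d_ref = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lib_ok))) {
    brs <- best_reference_score(library_reps[[lib_ok$id[i]]], reference_reps,
                                rule = cfg$reference_rule)
    score_tab$s1d_raw[i] <- brs$s_raw[brs$representation == "embed1d"]
    score_tab$s1d_ref[i] <- brs$reference_id[brs$representation == "embed1d"]
    score_tab$s2d_raw[i] <- brs$s_raw[brs$representation == "pharm2d"]
    score_tab$s2d_ref[i] <- brs$reference_id[brs$representation == "pharm2d"]
    score_tab$s3d_raw[i] <- brs$s_raw[brs$representation == "shape3d"]
    score_tab$s3d_ref[i] <- brs$reference_id[brs$representation == "shape3d"]
  }

  # distances to the reference-panel centroid in the concatenated space
  dim1d <- model$hp$dim
  size2d <- cfg$pharm2d$size
  dim3d <- cfg$shape3d$dim
  ref_mat <- t(vapply(reference_reps, .concat_representation,
                      numeric(dim1d + size2d + dim3d),
                      dim1d = dim1d, size2d = size2d, dim3d = dim3d))
  centroid <- colMeans(ref_mat)
  lib_mat <- t(vapply(library_reps[lib_ok$id], .concat_representation,
                      numeric(dim1d + size2d + dim3d),
                      dim1d = dim1d, size2d = size2d, dim3d = dim3d))
  dist_to_panel <- sqrt(rowSums(sweep(lib_mat, 2, centroid)^2))

  agg <- aggregate_and_flag(score_tab, cfg, dist_to_panel)
  score_tab <- cbind(score_tab, agg)

  # cluster labels: reporting only, never a filtering decision
  k <- min(8L, nrow(lib_mat) - 1L)
  score_tab$cluster <- if (k >= 2L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(cfg$seed)
    cl <- tryCatch(stats::kmeans(lib_mat, centers = k, nstart = 3L)$cluster,
                   error = function(e) rep(1L, nrow(lib_mat)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    as.integer(cl)
  } else 1L

  ranking <- rank_candidates(score_tab, cfg)
  attr(ranking, "reps") <- library_reps
  attr(ranking, "ref_reps") <- reference_reps
  attr(ranking, "excluded") <- excluded
  ranking
}

#' Single-representation (ablation) screen
#'
#' Ranks the library by one channel's filtered best-reference score alone and
#' returns the top k compounds. This is the comparison mode in which each
#' representation competes independently.
#'
#' @param representation `"embed1d"`/`"1d"`, `"pharm2d"`/`"2d"` or
#'   `"shape3d"`/`"3d"`.
#' @param k list length; if k exceeds the library size the full ranking is
#'   returned with a warning.
#' @param library_reps,reference_reps representations from
#'   [represent_library()].
#' @param cfg a [screening_config()].
#' @return data.frame `compound_id`, `s_raw`, `s_filtered`, `reference_id`,
#'   `rank`, ordered best-first, with at most k rows.
#' @export
single_representation_screen <- function(representation, k,
                                         library_reps, reference_reps,
                                         cfg = screening_config()) {
  representation <- switch(tolower(representation),
                           "1d" = , "embed1d" = "embed1d",
                           "2d" = , "pharm2d" = "pharm2d",
                           "3d" = , "shape3d" = "shape3d",
                           .fatal_config(paste0("unknown representation: ",
                                                representation)))
  ids <- names(library_reps)
  s_raw <- rep(NA_real_, length(ids))
  ref_id <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    cv <- library_reps[[i]][[representation]]
    if (is.null(cv)) next
    best <- -Inf; best_ref <- NA_character_
    for (rn in names(reference_reps)) {
      rv <- reference_reps[[rn]][[representation]]
      if (is.null(rv)) next
      s <- suppressWarnings(similarity(cv, rv))
      if (s > best) { best <- s; best_ref <- rn }
    }
    if (is.finite(best)) { s_raw[i] <- best; ref_id[i] <- best_ref }
  }
  s_filtered <- hyperspace_filter(s_raw, cfg$theta)
  ord <- order(-ifelse(is.na(s_filtered), -Inf, s_filtered),
               -ifelse(is.na(s_raw), -Inf, s_raw), ids)
  out <- data.frame(compound_id = ids[ord], s_raw = s_raw[ord],
                    s_filtered = s_filtered[ord], reference_id = ref_id[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  if (k > nrow(out)) {
    warning("k = ", k, " exceeds library size ", nrow(out),
            "; returning the full ranking")
    k <- nrow(out)
  }
  out[seq_len(k), , drop = FALSE]
}
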
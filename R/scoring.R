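# Similarity scoring and candidate ranking.
#
# The similarity kernel is the dot product of the representation vectors:
# for dense channels the vectors are unit-normalised first (cosine, clamped
# to [0,1]); for the sparse pharmacophore channel the bounded analogue is the
# Tanimoto coefficient. The hyper-space filter then zeroes scores below the
# cut-off theta and zeroes exact matches (s = 1), so that only novel
# analogues of the reference actives survive.

#' Screening configuration
#'
#' @param theta similarity cut-off in (0,1); default 0.75. Scores below theta
#'   are zeroed, as are exact matches (s = 1).
#' @param top_n truncate the candidate list to the best `top_n` passing
#'   compounds (NULL = no truncation).
#' @param representation_weights non-negative weights for the 1D/2D/3D
#'   channels, summing to 1; renormalised over available channels per
#'   compound.
#' @param aggregate_rule how filtered channel scores combine: weighted
#'   `mean` (default), `min`, or `rank_mean` (mean of within-library
#'   percentile ranks).
#' @param reference_rule combine scores across the reference panel by `max`
#'   (default) or `mean`.
#' @param theta_scope apply the pass threshold to the `aggregate` score
#'   (default) or require it `per_channel`.
#' @param outlier_mad_k robust-deviation multiplier for the outlier flag.
#' @param seed global seed (conformers, clustering).
#' @param n_conf conformers per molecule for the 3D channel.
#' @param radius substructure-sentence radius for the 1D channel.
#' @param pharm2d a [pharm2d_scheme()].
#' @param shape3d a [shape3d_scheme()].
#' @return a `screening_config` list.
#' @export
screening_config <- function(theta = 0.75, top_n = NULL,
                             representation_weights = c(1, 1, 1) / 3,
                             aggregate_rule = c("mean", "min", "rank_mean"),
                             reference_rule = c("max", "mean"),
                             theta_scope = c("aggregate", "per_channel"),
                             outlier_mad_k = 3.5, seed = 1L, n_conf = 5L,
                             radius = 1L,
                             pharm2d = pharm2d_scheme(),
                             shape3d = shape3d_scheme()) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    .fatal_config("theta must lie strictly between 0 and 1")
  w <- representation_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-12)
    .fatal_config("representation_weights must be 3 non-negative values summing to 1")
  if (!is.null(top_n) && (!is.numeric(top_n) || top_n < 1))
    .fatal_config("top_n must be a positive integer or NULL")
  if (outlier_mad_k <= 0) .fatal_config("outlier_mad_k must be positive")
  structure(list(theta = theta, top_n = if (is.null(top_n)) NULL else as.integer(top_n),
                 representation_weights = w,
                 aggregate_rule = match.arg(aggregate_rule),
                 reference_rule = match.arg(reference_rule),
                 theta_scope = match.arg(theta_scope),
                 outlier_mad_k = outlier_mad_k, seed = as.integer(seed),
                 n_conf = as.integer(n_conf), radius = as.integer(radius),
                 pharm2d = pharm2d, shape3d = shape3d),
            class = "screening_config")
}

#' Similarity between two representation vectors
#'
#' Dense kinds (1D embedding, 3D feature map): dot product of the
#' unit-normalised vectors (cosine), clamped to [0,1]. Sparse pharmacophore
#' fingerprints: Tanimoto coefficient of the on-bit sets. Symmetric;
#' `similarity(v, v) == 1` for any non-zero v; a zero operand gives 0 with a
#' warning.
#'
#' @param v,w representation vectors of the same kind: numeric vectors
#'   (dense) or `pharm2d` bit-position vectors.
#' @return similarity in [0,1].
#' @export
similarity <- function(v, w) {
  kv <- attr(v, "kind"); kw <- attr(w, "kind")
  sparse_v <- identical(kv, "pharm2d"); sparse_w <- identical(kw, "pharm2d")
  if (sparse_v != sparse_w)
    .fatal_config("similarity: representation kind mismatch")
  if (sparse_v) {
    if (length(v) == 0L || length(w) == 0L) {
      if (length(v) == 0L && length(w) == 0L)
        warning("similarity of empty fingerprints is defined as 0")
      return(0)
    }
    return(length(intersect(v, w)) / length(union(v, w)))
  }
  if (!is.null(kv) && !is.null(kw) && !identical(kv, kw))
    .fatal_config("similarity: representation kind mismatch")
  if (length(v) != length(w))
    .fatal_config("similarity: dense vectors differ in length")
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv < 1e-12 || nw < 1e-12) {
    warning("similarity against a zero vector is 0")
    return(0)
  }
  max(0, min(1, sum(v * w) / (nv * nw)))
}

#' The hyper-space filter
#'
#' Piecewise filter of a similarity score s at cut-off theta:
#' 0 when s = 1 (exact duplicates of a reference are rejected: the screen
#' seeks novel analogues), s when theta <= s < 1, and 0 when s < theta.
#' Equality with 1 is tested at tolerance 1e-9 because the cosine of two
#' identical vectors can deviate in the last bits.
#'
#' @param s similarity score(s) in [0,1] (vectorised); NA passes through.
#' @param theta cut-off in (0,1), default 0.75.
#' @return filtered score(s).
#' @examples
#' hyperspace_filter(c(1, 0.8, 0.5, 0.75), theta = 0.75)  # 0 0.80 0 0.75
#' @export
hyperspace_filter <- function(s, theta = 0.75) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    .fatal_config("theta must lie strictly between 0 and 1")
  bad <- !is.na(s) & (s < -1e-9 | s > 1 + 1e-9)
  if (any(bad))
    .fatal_config(paste0("similarity outside [0,1]: ", paste(
      format(s[bad][seq_len(min(3, sum(bad)))]), collapse = ", "),
      " - unnormalised similarity upstream?"))
  out <- s
  dup <- !is.na(s) & abs(s - 1) <= 1e-9
  low <- !is.na(s) & s < theta
  out[dup | low] <- 0
  out
}

#' Best-reference similarity scores for one compound
#'
#' Per representation channel, the compound is scored against every
#' reference in the panel and the scores are combined by the configured
#' reference rule (default: maximum, recording the maximising reference).
#' A channel missing for the compound (e.g. failed 3D embedding) stays
#' missing rather than 0.
#'
#' @param compound list with elements `embed1d`, `pharm2d`, `shape3d`
#'   (any may be NULL).
#' @param references list of reference representation lists (same shape),
#'   named by reference ID.
#' @param rule `"max"` or `"mean"`.
#' @return data.frame with one row per channel: `representation`, `s_raw`,
#'   `reference_id`.
#' @export
best_reference_score <- function(compound, references, rule = "max") {
  if (length(references) == 0L) .fatal_input("empty reference panel")
  ref_ids <- names(references)
  channels <- c("embed1d", "pharm2d", "shape3d")
  res <- data.frame(representation = channels, s_raw = NA_real_,
                    reference_id = NA_character_, stringsAsFactors = FALSE)
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    cv <- compound[[ch]]
    if (is.null(cv)) next
    sims <- rep(NA_real_, length(references))
    for (ri in seq_along(references)) {
      rv <- references[[ri]][[ch]]
      if (is.null(rv)) next
      sims[ri] <- suppressWarnings(similarity(cv, rv))
    }
    if (all(is.na(sims))) next
    if (rule == "mean") {
      res$s_raw[ci] <- mean(sims, na.rm = TRUE)
      res$reference_id[ci] <- ref_ids[which.max(sims)]
    } else {
      best <- which.max(sims)
      res$s_raw[ci] <- sims[best]
      res$reference_id[ci] <- ref_ids[best]
    }
  }
  res
}

# Weighted aggregate of filtered channel scores with weights renormalised
# over available (non-missing) channels.
.aggregate_scores <- function(filtered, weights, rule) {
  avail <- !is.na(filtered)
  if (!any(avail)) return(NA_real_)
  w <- weights[avail]
  if (sum(w) <= 0) w <- rep(1, sum(avail))
  w <- w / sum(w)
  x <- filtered[avail]
  switch(rule,
         mean = sum(w * x),
         min = min(x),
         rank_mean = sum(w * x))  # percentile ranks substituted upstream
}

#' Aggregate channel scores and flag outliers
#'
#' Each channel's raw best-reference score passes through the hyper-space
#' filter; the filtered scores combine into the aggregate under the
#' configured rule with weights renormalised over available channels.
#' A compound is flagged as an outlier when its concatenated, per-channel
#' unit-normalised representation lies farther from the reference-panel
#' centroid than `median + outlier_mad_k * MAD` of the cohort's distances.
#'
#' @param score_tab data.frame: rows = compounds, columns `s1d_raw`,
#'   `s2d_raw`, `s3d_raw`.
#' @param cfg a [screening_config()].
#' @param dist_to_panel numeric vector of cohort distances to the panel
#'   centroid (NA disables the outlier flag for that compound).
#' @return data.frame with `s_aggregate` (aggregate of filtered channel
#'   scores), `filtered_score` (aggregate after one more pass through the
#'   filter) and `outlier_flag`.
#' @export
aggregate_and_flag <- function(score_tab, cfg, dist_to_panel = NULL) {
  raw <- as.matrix(score_tab[, c("s1d_raw", "s2d_raw", "s3d_raw")])
  if (cfg$aggregate_rule == "rank_mean") {
    # percentile rank of the filtered score within each channel
    filt <- apply(raw, 2, hyperspace_filter, theta = cfg$theta)
    filt <- matrix(filt, nrow = nrow(raw))
    for (j in 1:3) {
      ok <- !is.na(filt[, j])
      if (any(ok)) filt[ok, j] <- rank(filt[ok, j]) / sum(ok)
    }
  } else {
    filt <- matrix(hyperspace_filter(raw, cfg$theta), nrow = nrow(raw))
  }
  agg <- vapply(seq_len(nrow(filt)), function(i) {
    .aggregate_scores(filt[i, ], cfg$representation_weights, cfg$aggregate_rule)
  }, numeric(1))

  outlier <- rep(FALSE, nrow(raw))
  if (!is.null(dist_to_panel)) {
    d <- dist_to_panel
    med <- stats::median(d, na.rm = TRUE)
    madv <- stats::mad(d, na.rm = TRUE)
    if (is.na(madv) || madv < 1e-12) {
      warning("degenerate cohort (MAD = 0): outlier detection disabled")
    } else {
      outlier <- !is.na(d) & (d - med) > cfg$outlier_mad_k * madv
    }
  }
  data.frame(s_aggregate = agg,
             filtered_score = hyperspace_filter(agg, cfg$theta),
             outlier_flag = outlier)
}

#' Rank screened compounds
#'
#' Orders compounds by aggregate score (descending, ties by compound ID
#' ascending), assigns ranks, and sets the pass flag: aggregate's filtered
#' value >= theta (or every available channel >= theta under
#' `theta_scope = "per_channel"`) and not an outlier. The candidate list is
#' the passing set, truncated at `top_n` when configured. Lowering theta
#' never removes a passing compound.
#'
#' @param score_tab data.frame with columns `compound_id`,
#'   `canonical_smiles`, `s1d_raw`, `s1d_ref`, `s2d_raw`, `s2d_ref`,
#'   `s3d_raw`, `s3d_ref`, `s_aggregate`, `filtered_score`, `outlier_flag`.
#' @param cfg a [screening_config()].
#' @return a `candidate_ranking`: list with `rows` (full ordered table with
#'   `pass` and `rank`) and `candidates` (passing IDs after `top_n`).
#' @export
rank_candidates <- function(score_tab, cfg) {
  tab <- score_tab
  if (cfg$theta_scope == "per_channel") {
    raw <- as.matrix(tab[, c("s1d_raw", "s2d_raw", "s3d_raw")])
    filt <- matrix(hyperspace_filter(raw, cfg$theta), nrow = nrow(raw))
    ch_ok <- vapply(seq_len(nrow(filt)), function(i) {
      x <- filt[i, ]; all(is.na(x) | x >= cfg$theta) && any(!is.na(x))
    }, logical(1))
    tab$pass <- ch_ok & !is.na(tab$filtered_score) &
      tab$filtered_score > 0 & !tab$outlier_flag
  } else {
    tab$pass <- !is.na(tab$filtered_score) &
      tab$filtered_score >= cfg$theta & !tab$outlier_flag
  }
  ord <- order(-ifelse(is.na(tab$s_aggregate), -Inf, tab$s_aggregate),
               tab$compound_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  cand <- tab$compound_id[tab$pass]
  if (!is.null(cfg$top_n) && length(cand) > cfg$top_n)
    cand <- cand[seq_len(cfg$top_n)]
  structure(list(rows = tab, candidates = cand, theta = cfg$theta),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("<candidate_ranking> ", nrow(x$rows), " compounds, ",
      sum(x$rows$pass), " passing theta = ", x$theta,
      " (", length(x$candidates), " candidates)\n", sep = "")
  print(utils::head(x$rows[, c("compound_id", "s_aggregate",
                               "filtered_score", "pass", "rank")], 10))
  invisible(x)
}
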
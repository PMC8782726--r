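test_that("similarity kernel handles self-match, orthogonality and mismatches", {
  v <- c(1, 0, 0); w <- c(0, 1, 0)
  expect_identical(similarity(v, w), 0)              # orthogonal
  expect_lt(abs(similarity(v, v) - 1), 1e-12)        # self-similarity
  expect_identical(similarity(c(1, 1), c(-1, -1)), 0)  # negative cosine clamps
  a <- structure(c(1L, 2L, 3L), kind = "pharm2d", size = 2048L)
  b <- structure(c(2L, 3L, 4L), kind = "pharm2d", size = 2048L)
  expect_identical(similarity(a, b), 0.5)            # |A^B| / |AuB| = 2/4
  expect_error(similarity(a, v), "kind", class = "triscreen_config_error")
  expect_warning(z <- similarity(c(0, 0, 0), v), "zero")
  expect_identical(z, 0)
})

test_that("out-of-range similarities are fatal in the filter", {
  expect_error(hyperspace_filter(1.2), "outside",
               class = "triscreen_config_error")
  expect_error(hyperspace_filter(-0.2), "outside",
               class = "triscreen_config_error")
  expect_error(hyperspace_filter(0.5, theta = 1), "theta",
               class = "triscreen_config_error")
  # within tolerance of the boundaries is accepted
  expect_identical(hyperspace_filter(1 + 1e-12), 0)
  expect_identical(hyperspace_filter(-1e-12, theta = 0.5), 0)
})

test_that("best_reference_score takes the per-channel maximum with its reference", {
  mk <- function(x) structure(x, kind = "embed1d")
  refs <- list(
    R1 = list(embed1d = mk(c(1, 0)), pharm2d = NULL, shape3d = NULL),
    R2 = list(embed1d = mk(c(1, 1)), pharm2d = NULL, shape3d = NULL),
    R3 = list(embed1d = mk(c(0, 1)), pharm2d = NULL, shape3d = NULL))
  cmp <- list(embed1d = mk(c(1, 0.2)), pharm2d = NULL, shape3d = NULL)
  got <- best_reference_score(cmp, refs)
  row <- got[got$representation == "embed1d", ]
  # brute-force oracle over the panel
  sims <- vapply(refs, function(r) similarity(cmp$embed1d, r$embed1d),
                 numeric(1))
  expect_identical(row$s_raw, unname(max(sims)))
  expect_identical(row$reference_id, names(which.max(sims)))
  # missing channels stay missing
  expect_true(is.na(got$s_raw[got$representation == "pharm2d"]))
  # singleton panel: the max is that single similarity
  got1 <- best_reference_score(cmp, refs["R2"])
  expect_identical(got1$s_raw[1], unname(sims["R2"]))
  expect_error(best_reference_score(cmp, list()), "empty",
               class = "triscreen_input_error")
})

test_that("aggregation renormalises weights over available channels", {
  cfg <- screening_config(theta = 0.75)
  tab <- data.frame(s1d_raw = c(0.8, 0.9, 1.0, 0.9),
                    s2d_raw = c(0.8, NA,  1.0, 0.5),
                    s3d_raw = c(0.8, 0.8, 1.0, 0.9))
  agg <- aggregate_and_flag(tab, cfg)
  expect_equal(agg$s_aggregate[1], 0.8)               # mean of equals
  expect_equal(agg$s_aggregate[2], (0.9 + 0.8) / 2)   # renormalised weights
  expect_equal(agg$s_aggregate[3], 0)                 # duplicate rejection
  # sub-theta channel contributes 0, not its raw value
  expect_equal(agg$s_aggregate[4], (0.9 + 0 + 0.9) / 3)
})

test_that("degenerate cohorts disable outlier detection with a warning", {
  cfg <- screening_config()
  tab <- data.frame(s1d_raw = c(0.8, 0.8), s2d_raw = c(0.8, 0.8),
                    s3d_raw = c(0.8, 0.8))
  expect_warning(agg <- aggregate_and_flag(tab, cfg, dist_to_panel = c(1, 1)),
                 "MAD")
  expect_false(any(agg$outlier_flag))
  # a clear outlier is flagged when the cohort has spread
  tabn <- tab[rep(1, 12), ]
  d <- c(seq(1, 2, length.out = 11), 100)
  agg2 <- aggregate_and_flag(tabn, cfg, dist_to_panel = d)
  expect_identical(which(agg2$outlier_flag), 12L)
})

test_that("ranking sets pass flags, ranks and top-n truncation correctly", {
  cfg <- screening_config(theta = 0.75)
  mk_tab <- function(aggs, ids = LETTERS[seq_along(aggs)]) {
    data.frame(compound_id = ids, canonical_smiles = "C",
               s1d_raw = aggs, s1d_ref = "R", s2d_raw = aggs, s2d_ref = "R",
               s3d_raw = aggs, s3d_ref = "R",
               s_aggregate = hyperspace_filter(aggs, cfg$theta),
               filtered_score = hyperspace_filter(aggs, cfg$theta),
               outlier_flag = FALSE, stringsAsFactors = FALSE)
  }
  tab <- mk_tab(c(0.9, 0.8, 0.76, 0.7, 0.2))
  rk <- rank_candidates(tab, cfg)
  expect_identical(sum(rk$rows$pass), 3L)
  expect_identical(rk$rows$rank, 1:5)
  # lowering theta keeps every previous passer (monotonicity)
  cfg06 <- screening_config(theta = 0.6)
  tab06 <- mk_tab(c(0.9, 0.8, 0.76, 0.7, 0.2))
  tab06$s_aggregate <- hyperspace_filter(c(0.9, 0.8, 0.76, 0.7, 0.2), 0.6)
  tab06$filtered_score <- tab06$s_aggregate
  rk06 <- rank_candidates(tab06, cfg06)
  expect_true(all(rk$rows$compound_id[rk$rows$pass] %in%
                    rk06$rows$compound_id[rk06$rows$pass]))
  expect_identical(sum(rk06$rows$pass), 4L)
  # top-n truncation of the candidate list
  cfg2 <- screening_config(theta = 0.75, top_n = 2L)
  rk2 <- rank_candidates(tab, cfg2)
  expect_identical(rk2$candidates, c("A", "B"))
  # outliers never pass
  tab$outlier_flag[1] <- TRUE
  rk3 <- rank_candidates(tab, cfg)
  expect_false(rk3$rows$pass[rk3$rows$compound_id == "A"])
})

test_that("config validation rejects malformed settings", {
  expect_error(screening_config(theta = 0), "theta",
               class = "triscreen_config_error")
  expect_error(screening_config(representation_weights = c(1, 1, 1)),
               "weights", class = "triscreen_config_error")
  expect_error(screening_config(top_n = 0), "top_n",
               class = "triscreen_config_error")
  expect_error(screening_config(outlier_mad_k = -1), "outlier_mad_k",
               class = "triscreen_config_error")
})

test_that("similarity is symmetric over random sparse pairs", {
  set.seed(11)
  for (i in seq_len(200)) {
    a <- structure(sample(0:255, sample(1:30, 1)), kind = "pharm2d")
    b <- structure(sample(0:255, sample(1:30, 1)), kind = "pharm2d")
    expect_identical(similarity(a, b), similarity(b, a))
  }
})
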
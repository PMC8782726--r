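# Pipeline commands: pretrain (corpus -> embedding model on disk) and screen
# (library + references + model -> results table + manifest). These are the
# programmatic counterparts of the command-line interface in inst/cli.

.manifest <- function(cfg, inputs, counts, seed) {
  list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = counts,
    engines = engine_versions()
  )
}

#' Pre-train the substructure embedding model from a corpus file
#'
#' Reads the corpus, standardises it, applies the corpus filter rules, builds
#' substructure sentences and trains the skip-gram model; writes the model
#' directory plus a run manifest. Rerunning with the same inputs and seed
#' reproduces the vector matrix bit-for-bit.
#'
#' @param corpus_path SMILES corpus (.smi/.csv/.sdf).
#' @param out_dir model output directory.
#' @param hp [embedding_hp()].
#' @param rules [corpus_filter_rules()].
#' @param policy [standardization_policy()].
#' @param quiet suppress progress messages.
#' @return the trained `embedding_model`, invisibly.
#' @export
cmd_pretrain <- function(corpus_path, out_dir, hp = embedding_hp(),
                         rules = corpus_filter_rules(),
                         policy = standardization_policy(), quiet = FALSE) {
  t0 <- Sys.time()
  raw <- read_library(corpus_path)
  std <- standardize(raw, policy)
  filt <- filter_pretraining_corpus(std, rules)
  if (!quiet) {
    rej <- attr(filt, "rejections")
    message("corpus: ", nrow(raw), " read, ", sum(std$status == "ok"),
            " standardised, ", nrow(filt), " retained",
            if (nrow(rej)) paste0(" (rejected: ",
              paste(sprintf("%s=%d", names(table(rej$reason)),
                            as.integer(table(rej$reason))), collapse = ", "),
              ")") else "")
  }
  sentences <- mol_sentences(filt, radius = hp$radius)
  model <- train_embedding(sentences, hp)
  save_embedding(model, out_dir)

  counts <- list(read = nrow(raw), standardized_ok = sum(std$status == "ok"),
                 corpus_filtered = nrow(filt),
                 vocabulary = length(model$vocab))
  jsonlite::write_json(
    .manifest(unclass(hp), list(corpus = corpus_path), counts, hp$seed),
    file.path(out_dir, "run-manifest.json"), auto_unbox = TRUE, digits = NA)
  if (!quiet)
    message("model: ", length(model$vocab), " tokens x ", hp$dim,
            " dims written to ", out_dir, " (",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
            " s)")
  invisible(model)
}

#' Screen a library file against a reference panel file
#'
#' Executes the full three-channel screen and writes `results.tsv`,
#' `run-manifest.json` and a human-readable `summary.txt` to `out_dir`.
#' With `mode = "1d"/"2d"/"3d"` the single-representation ablation ranking
#' is written instead (`ablation-<mode>.tsv`, truncated at `top_k`).
#'
#' @param library_path screening library (.smi/.csv/.sdf).
#' @param references_path reference actives file; must contain at least one
#'   valid molecule.
#' @param model_dir embedding-model directory from [cmd_pretrain()].
#' @param out_dir output directory.
#' @param cfg [screening_config()].
#' @param mode `"combined"` (default), `"1d"`, `"2d"` or `"3d"`.
#' @param top_k list length for ablation mode (default 5).
#' @param policy [standardization_policy()].
#' @param quiet suppress progress messages.
#' @return the `candidate_ranking` (combined mode) or the ablation
#'   data.frame, invisibly.
#' @export
cmd_screen <- function(library_path, references_path, model_dir, out_dir,
                       cfg = screening_config(), mode = "combined",
                       top_k = 5L, policy = standardization_policy(),
                       quiet = FALSE) {
  mode <- tolower(mode)
  if (!mode %in% c("combined", "1d", "2d", "3d"))
    .fatal_config(paste0("unknown mode: ", mode))
  model <- load_embedding(model_dir)

  refs <- standardize(read_library(references_path), policy)
  if (!any(refs$status == "ok"))
    .fatal_input("reference file contains no valid molecule")
  lib_raw <- read_library(library_path)
  lib <- standardize(lib_raw, policy)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs_ok <- refs[refs$status == "ok", , drop = FALSE]
  ref_reps <- represent_library(refs_ok, model, cfg, quiet = quiet)
  lib_reps <- represent_library(lib, model, cfg, quiet = quiet)

  if (mode != "combined") {
    abl <- single_representation_screen(mode, top_k, lib_reps, ref_reps, cfg)
    out_path <- file.path(out_dir, paste0("ablation-", mode, ".tsv"))
    tab <- abl
    tab$s_raw <- sprintf("%.6f", tab$s_raw)
    tab$s_filtered <- sprintf("%.6f", tab$s_filtered)
    utils::write.table(tab, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!quiet) message("ablation (", mode, "): top ", nrow(abl),
                        " written to ", out_path)
    return(invisible(abl))
  }

  ranking <- screen_library(lib, refs, model, cfg,
                            library_reps = lib_reps,
                            reference_reps = ref_reps, quiet = quiet)
  write_results_table(ranking, file.path(out_dir, "results.tsv"))

  counts <- list(read = nrow(lib_raw),
                 standardized_ok = sum(lib$status == "ok"),
                 represented = length(lib_reps) - nrow(attr(ranking, "excluded")),
                 scored = nrow(ranking$rows),
                 passed = sum(ranking$rows$pass),
                 candidates = length(ranking$candidates))
  jsonlite::write_json(
    .manifest(
      c(unclass(cfg)[c("theta", "top_n", "representation_weights",
                       "aggregate_rule", "reference_rule", "theta_scope",
                       "outlier_mad_k", "seed", "n_conf", "radius")],
        list(mode = mode)),
      list(library = library_path, references = references_path),
      counts, cfg$seed),
    file.path(out_dir, "run-manifest.json"), auto_unbox = TRUE, digits = NA)

  writeLines(c(
    "screening summary",
    sprintf("  library:        %s", library_path),
    sprintf("  references:     %s (%d valid)", references_path, nrow(refs_ok)),
    sprintf("  read:           %d", counts$read),
    sprintf("  standardised:   %d", counts$standardized_ok),
    sprintf("  scored:         %d", counts$scored),
    sprintf("  passing theta=%.2f: %d", cfg$theta, counts$passed),
    sprintf("  candidates:     %d", counts$candidates)
  ), file.path(out_dir, "summary.txt"))
  if (!quiet) message("screen: ", counts$scored, " scored, ", counts$passed,
                      " passing theta = ", cfg$theta, "; results in ", out_dir)
  invisible(ranking)
}
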
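# Shared fixtures, built once per test run and cached for every file that
# needs them. The "study" fixture is the default desk-scale configuration:
# 2,000-molecule corpus, 14 references, 28 planted analogues, 14 exact
# duplicates, 150 decoys.

.fx_cache <- new.env(parent = emptyenv())

# Full study-scale run: fixture files, trained model, combined screen.
study_fixture <- function() {
  if (!exists("study", .fx_cache)) {
    dir <- file.path(tempdir(), "triscreen-study")
    spec <- fixture_spec(seed = 1)
    paths <- make_fixture_set(spec, file.path(dir, "fx"))
    model_dir <- file.path(dir, "model")
    model <- cmd_pretrain(paths$corpus, model_dir, embedding_hp(seed = 1),
                          quiet = TRUE)
    cfg <- screening_config(seed = 1)
    out_dir <- file.path(dir, "out")
    ranking <- cmd_screen(paths$library, paths$panel, model_dir, out_dir,
                          cfg = cfg, quiet = TRUE)
    labels <- utils::read.delim(paths$labels, stringsAsFactors = FALSE)
    assign("study", list(
      dir = dir, spec = spec, paths = paths, model_dir = model_dir,
      model = model, cfg = cfg, out_dir = out_dir, ranking = ranking,
      labels = labels,
      panel = make_reference_panel(spec)
    ), .fx_cache)
  }
  get("study", .fx_cache)
}

# Small embedding model over a toy corpus, for unit tests that need a model
# but not the full study fixture.
toy_model <- function() {
  if (!exists("toy", .fx_cache)) {
    smis <- c("CCO", "CCN", "CCC", "CCCO", "CCCN", "c1ccccc1", "c1ccccc1O",
              "c1ccccc1N", "CC(=O)O", "CC(=O)N", "CCOC", "CCOCC", "OCCO",
              "NCCN", "CC(C)O", "CC(C)N", "c1ccncc1", "Cc1ccccc1",
              "OCc1ccccc1", "NCc1ccccc1")
    sent <- mol_sentences(stats::setNames(ob_canonical(smis),
                                          paste0("T", seq_along(smis))))
    model <- train_embedding(sent, embedding_hp(dim = 16, epochs = 2,
                                                window = 5, seed = 42))
    assign("toy", list(model = model, sentences = sent, smiles = smis),
           .fx_cache)
  }
  get("toy", .fx_cache)
}

# Build a compound set from SMILES via the file interface.
as_mol_set <- function(smiles, ids = paste0("M", seq_along(smiles))) {
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste(smiles, ids), f)
  read_library(f)
}

# Brute-force Tanimoto on two bit-position sets via dense logical vectors
# (independent of the package's set-arithmetic path).
tanimoto_oracle <- function(a, b, size = 2048L) {
  A <- logical(size); A[a + 1L] <- TRUE
  B <- logical(size); B[b + 1L] <- TRUE
  if (!any(A | B)) return(0)
  sum(A & B) / sum(A | B)
}

# Direct piecewise oracle for the hyper-space filter.
filter_oracle <- function(s, theta) {
  if (abs(s - 1) <= 1e-9) 0
  else if (s >= theta) s
  else 0
}
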
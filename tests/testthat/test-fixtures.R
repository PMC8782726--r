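test_that("reference panel has 14 valid, pairwise-distinct members", {
  panel <- make_reference_panel()
  expect_identical(nrow(panel), 14L)
  expect_true(all(panel$status == "ok"))
  expect_identical(anyDuplicated(panel$canonical_smiles), 0L)
  # round-trips through the I/O layer unchanged
  f <- withr::local_tempfile(fileext = ".smi")
  write_smi(panel, f)
  back <- read_library(f)
  expect_identical(back$canonical_smiles, panel$canonical_smiles)
  # no two members are 2D-identical: all pairwise Tanimoto < 1 (brute force)
  fps <- lapply(panel$canonical_smiles, pharm2d_fingerprint)
  for (i in 1:13) for (j in (i + 1):14) {
    expect_lt(tanimoto_oracle(fps[[i]], fps[[j]]), 1)
  }
})

test_that("screening library composition matches the spec arithmetic", {
  fx <- study_fixture()
  lib <- read_library(fx$paths$library)
  labels <- fx$labels
  expect_identical(nrow(lib), 14L * 2L + 14L + 150L)  # 192
  expect_identical(as.vector(table(labels$class)[c("analogue", "duplicate",
                                                   "decoy")]),
                   c(28L, 14L, 150L))
  panel <- fx$panel
  lib_std <- standardize(lib)
  # every duplicate's canonical SMILES equals its reference's
  dups <- labels[labels$class == "duplicate", ]
  for (i in seq_len(nrow(dups))) {
    expect_identical(
      lib_std$canonical_smiles[lib_std$id == dups$id[i]],
      panel$canonical_smiles[panel$id == dups$parent[i]])
  }
  # every analogue differs from its parent by >= 1 heavy atom
  anas <- labels[labels$class == "analogue", ]
  for (i in seq_len(nrow(anas))) {
    na_ana <- lib_std$n_heavy_atoms[lib_std$id == anas$id[i]]
    na_par <- panel$n_heavy_atoms[panel$id == anas$parent[i]]
    expect_gte(na_ana, na_par + 1L)
  }
  # decoys never collide with the panel
  dec <- lib_std$canonical_smiles[lib_std$id %in%
                                    labels$id[labels$class == "decoy"]]
  expect_length(intersect(dec, panel$canonical_smiles), 0L)
})

test_that("pre-training corpus is valid and covers the library vocabulary", {
  fx <- study_fixture()
  corpus <- read_library(fx$paths$corpus)
  expect_identical(nrow(corpus), 2000L)
  expect_true(all(corpus$status == "ok"))
  lib <- standardize(read_library(fx$paths$library))
  lib_tokens <- unique(unlist(mol_sentences(lib, radius = 1L)))
  vocab_tokens <- names(fx$model$vocab)
  coverage <- mean(lib_tokens %in% vocab_tokens)
  expect_gte(coverage, 0.9)
})

test_that("identical fixture specs generate checksum-identical files", {
  spec <- fixture_spec(seed = 5, n_corpus = 150L, n_decoys = 20L,
                       n_analogues_per_reference = 1L)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  make_fixture_set(spec, d1)
  make_fixture_set(spec, d2)
  for (f in c("corpus.smi", "panel.smi", "library.smi", "labels.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("decoy exhaustion is a fatal error with a count", {
  # a tiny substituent set bounds the edit space well below the request
  spec <- fixture_spec(seed = 2, n_decoys = 5000L,
                       substituents = c("F", "Cl"))
  expect_error(make_screening_library(spec), "exhausted",
               class = "triscreen_input_error")
})
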
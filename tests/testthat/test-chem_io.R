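test_that("smi libraries read with order, IDs and parse-failure isolation", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment line", "c1ccccc1 benzene", "CCO ethanol",
               "notasmiles xyz", "C1CC1 cycloprop"), f)
  recs <- read_library(f)
  expect_identical(nrow(recs), 4L)
  expect_identical(recs$id, c("benzene", "ethanol", "xyz", "cycloprop"))
  expect_identical(recs$status, c("ok", "ok", "parse_failed", "ok"))
  expect_true(is.na(recs$canonical_smiles[3]))
  expect_false(anyNA(recs$canonical_smiles[-3]))
  expect_identical(recs$n_heavy_atoms[c(1, 2, 4)], c(6L, 3L, 3L))
})

test_that("csv libraries read one record per row with given IDs", {
  f <- withr::local_tempfile(fileext = ".csv")
  smis <- c("CCO", "CCN", "CCC", "c1ccccc1", "CC(=O)O", "CCOC", "OCCO",
            "NCCN", "CC(C)O", "c1ccncc1", "Cc1ccccc1", "OCc1ccccc1",
            "CC(=O)N", "CCCCO")
  tab <- data.frame(id = sprintf("X%02d", 1:14), smiles = smis)
  write.csv(tab, f, row.names = FALSE)
  recs <- read_library(f)
  expect_identical(nrow(recs), length(readLines(f)) - 1L)  # rows minus header
  expect_identical(recs$id, tab$id)
  expect_true(all(recs$status == "ok"))
})

test_that("missing IDs are auto-generated and duplicates are fatal", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "CCN"), f)
  recs <- read_library(f)
  expect_identical(recs$id, c("CMP0001", "CMP0002"))

  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "CCN a"), f2)
  expect_error(read_library(f2), "duplicate", class = "triscreen_input_error")
})

test_that("missing and empty files are fatal with explicit messages", {
  expect_error(read_library(file.path(tempdir(), "nope.smi")), "not found",
               class = "triscreen_input_error")
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("# only a comment", f)
  expect_error(read_library(f), "empty", class = "triscreen_input_error")
})

test_that("sdf libraries read with molecule titles as IDs", {
  f <- withr::local_tempfile(fileext = ".sdf")
  sdf <- ChemmineR::smiles2sdf(c(mol_a = "CCO", mol_b = "c1ccccc1"))
  ChemmineR::write.SDF(sdf, f)
  recs <- read_library(f)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$id, c("mol_a", "mol_b"))
  expect_true(all(recs$status == "ok"))
  expect_identical(recs$n_heavy_atoms, c(3L, 6L))
})

test_that("standardisation strips solvates, neutralises and is idempotent", {
  recs <- read_library(local({
    f <- tempfile(fileext = ".smi")
    writeLines(c("O.O.c1cc(O)ccc1 phenol_dihydrate",
                 "c1ccccc1 benzene",
                 "[Na+].CC(=O)[O-] na_acetate"), f)
    f
  }))
  std <- standardize(recs)
  phenol <- ob_canonical("Oc1ccccc1")
  expect_identical(std$canonical_smiles[1], phenol)
  # idempotence on the already-canonical record
  expect_identical(std$canonical_smiles[2], recs$canonical_smiles[2])
  # acetate: neutralised (no formal charges survive) and desalted
  expect_false(grepl("[+-]", std$canonical_smiles[3]))
  expect_identical(std$canonical_smiles[3], ob_canonical("CC(=O)O"))
  # standardising the standardised set is a no-op
  expect_identical(standardize(std)$canonical_smiles, std$canonical_smiles)
})

test_that("corpus filter applies element, size and fragment rules with reasons", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol",          # retained (3 heavy atoms, boundary)
               "CO methanol",          # size: 2 heavy atoms
               "[Fe] iron",            # element
               "CCO.CCO dimer",        # fragment
               "CCO ethanol2"), f)     # duplicate canonical
  recs <- read_library(f)
  # keep multi-fragment entry intact: no largest-fragment stripping here
  std <- standardize(recs, standardization_policy(keep_largest_fragment = FALSE))
  filt <- filter_pretraining_corpus(std)
  expect_identical(filt$id, "ethanol")
  rej <- attr(filt, "rejections")
  expect_identical(rej$reason[match(c("methanol", "iron", "dimer", "ethanol2"),
                                    rej$id)],
                   c("size", "element", "fragment", "duplicate"))
  # subset and order preservation on a passing set
  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCCC a", "CCO b", "c1ccccc1 c"), f2)
  std2 <- standardize(read_library(f2))
  filt2 <- filter_pretraining_corpus(std2)
  expect_identical(filt2$id, std2$id)
  # empty output is fatal with per-rule counts
  f3 <- withr::local_tempfile(fileext = ".smi")
  writeLines("CO tiny", f3)
  expect_error(filter_pretraining_corpus(standardize(read_library(f3))),
               "size", class = "triscreen_empty_error")
})

test_that("results tables round-trip at 6-decimal precision with tie rule", {
  tab <- data.frame(
    compound_id = c("B", "A", "C"),
    canonical_smiles = c("CC", "CCC", "CCCC"),
    s1d_raw = c(0.8, 0.8, 0.5), s1d_ref = "REF01",
    s2d_raw = c(0.8, 0.8, 0.5), s2d_ref = "REF01",
    s3d_raw = c(0.8, 0.8, 0.5), s3d_ref = "REF01",
    stringsAsFactors = FALSE)
  cfg <- screening_config(theta = 0.75)
  agg <- aggregate_and_flag(tab, cfg)
  ranking <- rank_candidates(cbind(tab, agg), cfg)
  # identical aggregates: tie broken by compound_id ascending
  expect_identical(ranking$rows$compound_id[1:2], c("A", "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(ranking, f)
  lines <- readLines(f)
  expect_identical(length(lines), 4L)  # header + 3 rows
  back <- read_results_table(f)
  expect_identical(sprintf("%.6f", back$s_aggregate),
                   sprintf("%.6f", ranking$rows$s_aggregate))
  expect_false(any(back$pass[back$compound_id == "C"]))
})

test_that("written smi files reproduce canonical SMILES on re-read", {
  fx <- toy_model()
  recs <- standardize(as_mol_set(fx$smiles))
  f <- withr::local_tempfile(fileext = ".smi")
  write_smi(recs, f)
  back <- read_library(f)
  expect_identical(back$canonical_smiles, recs$canonical_smiles)
})
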
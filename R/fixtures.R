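# Synthetic inputs: a 14-member reference panel of documented, structurally
# diverse actives (stand-ins spanning flavonoid, stilbenoid, macrolide,
# polyamine and small-acid chemistry -- explicitly synthetic, not a claim
# about any particular assay panel), a screening library with planted
# analogues, exact duplicates and decoys, and a pre-training corpus that
# covers the substructure vocabulary of panel and library.

# Parent structures for the reference panel. Chosen to span the scaffold
# classes of typical mitophagy-inducer panels (flavonol, stilbene, coumarin-
# like biaryl, polyamine, macrolactone, phenolic acids, indoleamine,
# uncoupler-like aryl hydrazone) while staying small enough for fast 3D work.
.reference_smiles <- c(
  REF01 = "O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",          # flavonol
  REF02 = "Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1",                     # stilbenoid
  REF03 = "COc1cc(C=Cc2ccc(O)cc2)cc(OC)c1",                   # dimethoxystilbene
  REF04 = "O=c1oc2cc(O)ccc2c2cc(O)ccc12",                     # dibenzopyranone
  REF05 = "NCCCCNCCCN",                                       # polyamine
  REF06 = "NC(=O)c1cccnc1",                                   # pyridine amide
  REF07 = "O=C1CCCCCCCCCCO1",                                 # macrolactone
  REF08 = "O=C(O)c1ccccc1O",                                  # salicylate
  REF09 = "O=C(O)C=Cc1ccc(O)c(O)c1",                          # hydroxycinnamate
  REF10 = "COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O",    # diarylheptanoid
  REF11 = "Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2",          # flavanol
  REF12 = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",                    # indoleamine
  REF13 = "N#CC(C#N)=NNc1ccc(OC(F)(F)F)cc1",                  # aryl hydrazone
  REF14 = "CS(=O)CCCCN=C=S"                                   # isothiocyanate
)

.decoy_scaffolds <- c("C1CCCCC1", "C1CCNCC1", "C1COCCN1", "C1CCOCC1",
                      "C1CNCCN1", "C1CCCC1", "c1ccsc1", "c1cncnc1",
                      "C1CCNC1", "C1CCOC1")

.substituents <- c("C", "O", "OC", "N", "F", "Cl", "CC", "C#N",
                   "C(C)C", "CO", "C(=O)N", "S")

#' Fixture specification
#'
#' Defaults define the desk-scale study conditions: a 2,000-molecule
#' pre-training corpus, a 14-member reference panel, 2 planted analogues per
#' reference, one exact duplicate per reference, and 150 decoys (192-compound
#' library).
#'
#' @param seed integer seed; identical specs generate identical files.
#' @param n_corpus pre-training corpus size (>= 100).
#' @param n_decoys decoy count.
#' @param n_analogues_per_reference planted analogues per reference (1-3
#'   substituent edits each).
#' @param scaffolds decoy parent scaffolds (disjoint from the panel's).
#' @param substituents single-attachment fragments for analogue/decoy edits.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_corpus = 2000L, n_decoys = 150L,
                         n_analogues_per_reference = 2L,
                         scaffolds = .decoy_scaffolds,
                         substituents = .substituents) {
  if (n_corpus < 100L) .fatal_config("n_corpus must be >= 100")
  structure(list(seed = as.integer(seed), n_corpus = as.integer(n_corpus),
                 n_decoys = as.integer(n_decoys),
                 n_analogues_per_reference = as.integer(n_analogues_per_reference),
                 scaffolds = scaffolds, substituents = substituents),
            class = "fixture_spec")
}

# Character offsets right after each atom token (+ trailing ring-closure
# digits), i.e. syntactically plausible branch insertion points.
.insertion_points <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pts <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      while (i <= n && chars[i] != "]") i <- i + 1L
      i <- i + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "p", "s")) {
      i <- i + 1L
      if (i <= n && ch %in% c("C", "B") && chars[i] %in% c("l", "r"))
        i <- i + 1L
    } else {
      i <- i + 1L
      next
    }
    # skip ring-closure digits (and %nn) directly after the atom
    while (i <= n && (grepl("[0-9]", chars[i]) ||
                      (chars[i] == "%" && i + 2L <= n))) {
      i <- if (chars[i] == "%") i + 3L else i + 1L
    }
    pts <- c(pts, i - 1L)
  }
  pts
}

# Apply one substituent edit at the p-th insertion point; NA if invalid.
.edit_smiles <- function(smiles, substituent, p) {
  pts <- .insertion_points(smiles)
  if (length(pts) == 0L) return(NA_character_)
  pos <- pts[((p - 1L) %% length(pts)) + 1L]
  paste0(substr(smiles, 1L, pos), "(", substituent, ")",
         substring(smiles, pos + 1L))
}

# Deterministic enumeration of valid single/multi-edit variants of a parent.
# Returns canonical SMILES, deduplicated, excluding the parent itself.
# Validation is batched with an early exit so enumeration cost scales with
# the number of variants requested, not the size of the edit space.
.enumerate_variants <- function(parent, substituents, n_edits = 1L,
                                max_out = Inf) {
  parent_can <- ob_canonical(parent)
  frontier <- parent
  seen <- character(0)
  for (round in seq_len(n_edits)) {
    cand <- character(0)
    for (f in frontier) {
      npts <- length(.insertion_points(f))
      for (p in seq_len(npts)) {
        for (s in substituents) {
          e <- .edit_smiles(f, s, p)
          if (!is.na(e)) cand <- c(cand, e)
        }
      }
    }
    cand <- unique(cand)
    new_round <- character(0)
    batch <- 400L
    for (start in seq(1L, length(cand), by = batch)) {
      chunk <- cand[start:min(start + batch - 1L, length(cand))]
      can <- ob_canonical(chunk)
      ok <- !is.na(can) & can != parent_can & !can %in% seen &
        !can %in% new_round
      new_round <- c(new_round, unique(can[ok]))
      if (length(seen) + length(new_round) >= max_out) break
    }
    seen <- c(seen, new_round)
    if (length(seen) >= max_out) return(seen[seq_len(max_out)])
    frontier <- new_round
    if (length(frontier) > 30L) frontier <- frontier[seq_len(30L)]
  }
  seen
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  }, add = TRUE)
  expr
}

#' Generate the 14-member reference panel
#'
#' Documented, structurally diverse, valid molecules labelled REF01..REF14.
#' These are synthetic stand-ins for a known-actives panel, spanning
#' flavonoid, stilbenoid, macrolide, polyamine and small-acid scaffolds.
#'
#' @param spec a [fixture_spec()] (the panel itself is fixed; the spec is
#'   accepted for interface symmetry).
#' @return standardised compound set of 14 records, all `status == "ok"`.
#' @export
make_reference_panel <- function(spec = fixture_spec()) {
  standardize(.mol_set(names(.reference_smiles), unname(.reference_smiles)))
}

#' Generate the screening library with ground-truth labels
#'
#' The library contains (a) planted analogues: each reference with 1-3
#' substituent edits; (b) one exact duplicate of each reference (to exercise
#' the s = 1 rejection branch of the hyper-space filter); (c) decoys
#' enumerated from scaffolds disjoint from the panel's. Ground-truth class
#' labels are attached as attribute `"labels"` and never consulted by the
#' screen itself.
#'
#' @param spec a [fixture_spec()].
#' @param panel reference panel from [make_reference_panel()].
#' @return standardised compound set with attribute `labels` (data.frame
#'   `id`, `class` in analogue/duplicate/decoy, `parent`).
#' @export
make_screening_library <- function(spec = fixture_spec(),
                                   panel = make_reference_panel(spec)) {
  ids <- character(0); smis <- character(0)
  class_ <- character(0); parent_ <- character(0)

  # planted analogues: 1-3 edits, deterministic walk over insertion points
  for (ri in seq_len(nrow(panel))) {
    parent <- panel$canonical_smiles[ri]
    vars <- .enumerate_variants(parent, spec$substituents, n_edits = 1L,
                                max_out = 6L * spec$n_analogues_per_reference)
    vars <- .with_seed(spec$seed + ri, sample(vars))
    vars <- vars[seq_len(min(spec$n_analogues_per_reference, length(vars)))]
    for (ai in seq_along(vars)) {
      ids <- c(ids, sprintf("ANA%02d_%d", ri, ai))
      smis <- c(smis, vars[ai])
      class_ <- c(class_, "analogue"); parent_ <- c(parent_, panel$id[ri])
    }
  }

  # exact duplicates of every reference
  for (ri in seq_len(nrow(panel))) {
    ids <- c(ids, sprintf("DUP%02d", ri))
    smis <- c(smis, panel$canonical_smiles[ri])
    class_ <- c(class_, "duplicate"); parent_ <- c(parent_, panel$id[ri])
  }

  # decoys: scaffold x substituent enumeration, up to 3 edits, disjoint from
  # panel scaffolds; seeded sample of the enumerated space
  pool <- character(0)
  for (sc in spec$scaffolds) {
    need <- ceiling(3 * spec$n_decoys / length(spec$scaffolds))
    pool <- c(pool, .enumerate_variants(sc, spec$substituents, n_edits = 2L,
                                        max_out = need))
  }
  pool <- setdiff(unique(pool), c(panel$canonical_smiles, smis))
  if (length(pool) < spec$n_decoys)
    .fatal_input(paste0("decoy enumeration exhausted: ", length(pool),
                        " available, ", spec$n_decoys, " requested"))
  pool <- .with_seed(spec$seed, sample(pool, spec$n_decoys))
  ids <- c(ids, sprintf("DEC%03d", seq_len(spec$n_decoys)))
  smis <- c(smis, pool)
  class_ <- c(class_, rep("decoy", spec$n_decoys))
  parent_ <- c(parent_, rep(NA_character_, spec$n_decoys))

  lib <- standardize(.mol_set(ids, smis))
  attr(lib, "labels") <- data.frame(id = ids, class = class_,
                                    parent = parent_, stringsAsFactors = FALSE)
  lib
}

#' Generate the pre-training corpus
#'
#' Scaffold x substituent enumeration over both the panel's parents and the
#' decoy scaffolds, sized to `spec$n_corpus`, so the corpus vocabulary covers
#' the substructure tokens occurring in the panel and screening library
#' (out-of-vocabulary tokens remain an exercised edge case, not the norm).
#'
#' @param spec a [fixture_spec()].
#' @return standardised compound set of `n_corpus` valid molecules.
#' @export
make_pretraining_corpus <- function(spec = fixture_spec()) {
  parents <- c(unname(.reference_smiles), spec$scaffolds)
  per_parent <- ceiling(1.2 * spec$n_corpus / length(parents))
  pool <- unname(ob_canonical(parents))
  for (p in parents) {
    pool <- c(pool, .enumerate_variants(p, spec$substituents, n_edits = 2L,
                                        max_out = per_parent))
  }
  pool <- unique(pool[!is.na(pool)])
  if (length(pool) > spec$n_corpus) {
    keep_parents <- pool[seq_along(parents)]
    rest <- .with_seed(spec$seed,
                       sample(setdiff(pool, keep_parents),
                              spec$n_corpus - length(keep_parents)))
    pool <- c(keep_parents, rest)
  }
  ids <- sprintf("CRP%05d", seq_along(pool))
  standardize(.mol_set(ids, pool))
}

#' Write a complete fixture set to disk
#'
#' Outputs `corpus.smi`, `panel.smi`, `library.smi`, `labels.tsv` and
#' `fixture-manifest.json` under `dir`. Identical specs produce
#' checksum-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return invisibly, the list of generated file paths.
#' @export
make_fixture_set <- function(spec = fixture_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_reference_panel(spec)
  library_ <- make_screening_library(spec, panel)
  corpus <- make_pretraining_corpus(spec)

  paths <- list(
    corpus = file.path(dir, "corpus.smi"),
    panel = file.path(dir, "panel.smi"),
    library = file.path(dir, "library.smi"),
    labels = file.path(dir, "labels.tsv"),
    manifest = file.path(dir, "fixture-manifest.json")
  )
  write_smi(corpus, paths$corpus)
  write_smi(panel, paths$panel)
  write_smi(library_, paths$library)
  utils::write.table(attr(library_, "labels"), paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    spec = spec[c("seed", "n_corpus", "n_decoys", "n_analogues_per_reference")],
    counts = list(corpus = nrow(corpus), panel = nrow(panel),
                  library = nrow(library_)),
    checksums = as.list(tools::md5sum(unlist(paths[1:4]))),
    engines = engine_versions()
  ), paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
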
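test_that("sentence token counts follow heavy_atoms * (R + 1)", {
  cases <- list(
    list(smiles = "c1ccccc1", R = 1L, n_heavy = 6L),
    list(smiles = "C",        R = 1L, n_heavy = 1L),
    list(smiles = "CCO",      R = 0L, n_heavy = 3L),
    list(smiles = "CCO",      R = 2L, n_heavy = 3L),
    list(smiles = "NC(=O)c1cccnc1", R = 1L, n_heavy = 9L)
  )
  for (cs in cases) {
    s <- mol_sentence(ob_canonical(cs$smiles), radius = cs$R)
    expect_length(s, cs$n_heavy * (cs$R + 1L))
  }
})

test_that("environment identifiers respect molecular symmetry", {
  # benzene: all atoms equivalent at every radius -> one token per radius
  s <- mol_sentence("c1ccccc1", radius = 1L)
  expect_identical(length(unique(s)), 2L)
  # ethanol at radius 0: brute-force environment comparison says all three
  # heavy atoms differ (CH3 vs CH2-O vs OH)
  s0 <- mol_sentence("CCO", radius = 0L)
  expect_identical(length(unique(s0)), 3L)
  # para-xylene: 2 distinct carbons in the ring + 1 methyl at r0
  sx <- mol_sentence(ob_canonical("Cc1ccc(C)cc1"), radius = 0L)
  expect_identical(length(unique(sx)), 3L)
})

test_that("sentences are deterministic and spelling-invariant via canonical form", {
  spellings <- c("c1ccccc1O", "Oc1ccccc1", "c1(O)ccccc1")
  cans <- ob_canonical(spellings)
  expect_identical(length(unique(cans)), 1L)
  sents <- lapply(cans, mol_sentence, radius = 1L)
  expect_identical(sents[[1]], sents[[2]])
  expect_identical(sents[[2]], sents[[3]])
  # repeated calls are identical
  expect_identical(mol_sentence(cans[1], 1L), sents[[1]])
})

test_that("radii are interleaved in atom order", {
  g <- mol_graphs(ob_canonical("CCO"))[[1]]
  s01 <- mol_sentence(g, radius = 1L)
  s0 <- mol_sentence(g, radius = 0L)
  # tokens 1,3,5 are the radius-0 identifiers of atoms 1..3
  expect_identical(s01[c(1, 3, 5)], s0)
})

test_that("negative radius is a config error and batch interface tolerates failures", {
  expect_error(mol_sentence("CCO", radius = -1), "radius",
               class = "triscreen_config_error")
  recs <- as_mol_set(c("CCO", "xxxx", "CCN"))
  sents <- mol_sentences(recs)
  expect_length(sents, 3L)
  expect_null(sents[[2]])
  expect_false(is.null(sents[[1]]))
})
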
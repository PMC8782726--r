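test_that("feature-map vectors are unit-norm, fixed-length and deterministic", {
  smi <- ob_canonical("COc1cc(C=Cc2ccc(cc2)O)cc(c1)OC")
  v1 <- shape3d_fingerprint(smi, n_conf = 5L, seed = 7L)
  v2 <- shape3d_fingerprint(smi, n_conf = 5L, seed = 7L)
  expect_identical(v1, v2)
  expect_length(v1, shape3d_scheme()$dim)
  expect_lt(abs(sqrt(sum(v1^2)) - 1), 1e-12)
  # rigid benzene: any seed gives the identical vector
  b1 <- shape3d_fingerprint("c1ccccc1", seed = 1L)
  b2 <- shape3d_fingerprint("c1ccccc1", seed = 999L)
  expect_identical(b1, b2)
})

test_that("aggregating identical conformers equals the single conformer", {
  # benzene has no rotatable bonds: every sampled conformer is the base
  # geometry, so the mean over k conformers equals n_conf = 1
  v1 <- shape3d_fingerprint("c1ccccc1", n_conf = 1L, seed = 3L)
  vk <- shape3d_fingerprint("c1ccccc1", n_conf = 7L, seed = 3L)
  expect_equal(v1, vk, tolerance = 1e-12)
})

test_that("torsion sampling responds to seed and compound identity", {
  smi <- ob_canonical("OCCCCCCCCO")  # flexible chain
  va <- shape3d_fingerprint(smi, n_conf = 8L, seed = 1L, id = "A")
  vb <- shape3d_fingerprint(smi, n_conf = 8L, seed = 1L, id = "B")
  # per-molecule seeding: different compound ids sample different conformers
  expect_false(identical(va, vb))
  # same id, same seed: reproducible
  expect_identical(va, shape3d_fingerprint(smi, n_conf = 8L, seed = 1L,
                                           id = "A"))
})

test_that("featureless or invalid molecules yield a missing 3D channel", {
  # hydrogen sulfide: no pharmacophore-typed atom at all -> channel missing
  expect_null(shape3d_fingerprint("S"))
  expect_error(shape3d_fingerprint("c1ccccc1", n_conf = 0L),
               "n_conf", class = "triscreen_config_error")
})

test_that("3D geometry is reproducible and independent of batch context", {
  smi <- ob_canonical("CC(=O)NCCc1c[nH]c2ccc(OC)cc12")
  alone <- mol_graphs(smi, coords3d = TRUE)[[1]]$xyz
  batched <- mol_graphs(c(ob_canonical("CCO"), smi, ob_canonical("CCN")),
                        coords3d = TRUE)[[2]]$xyz
  expect_identical(alone, batched)
})
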
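# Reaction featurization: Morgan fingerprints, DRFP, descriptors, graphs.

test_that("concatenated Morgan reaction fingerprints have the documented layout", {
  rx <- list(
    reaction(c(aryl_halide = "Clc1ccccc1", ligand = "CP(C)C",
               base = "CCN(CC)CC", additive = "Oc1ccccc1"), 50),
    reaction(c(aryl_halide = "Brc1ccccc1", ligand = "CP(C)C",
               base = "CCN(CC)CC", additive = "COc1ccccc1"), 60)
  )
  fp <- morgan_reaction_fp(rx, radius = 2, bits_per_component = 512,
                           mode = "concat")
  expect_equal(ncol(fp), 2048)
  expect_equal(nrow(fp), 2)
  expect_true(all(fp %in% c(0, 1)))
  expect_identical(attr(fp, "featurizer_tag"), "morgan_concat")
  # determinism
  fp2 <- morgan_reaction_fp(rx, radius = 2, bits_per_component = 512,
                            mode = "concat")
  expect_identical(unclass(fp), unclass(fp2))
})

test_that("identical SMILES in two roles give identical 512-bit blocks", {
  rx <- list(reaction(c(a = "CCO", b = "CCO"), 10, validate = FALSE))
  fp <- morgan_reaction_fp(rx, mode = "concat")
  expect_identical(fp[1, 1:512], fp[1, 513:1024])
})

test_that("summed Morgan mode adds per-component bit presence", {
  rx <- list(reaction(c(a = "CC", b = "CC", c = "CC", d = "CCO"), 10,
                      validate = FALSE))
  fp <- morgan_reaction_fp(rx, mode = "sum")
  expect_equal(ncol(fp), 512)
  # every bit set by ethane appears at least 3 times (roles a, b, c)
  cc_bits <- unique(morgan_bits("CC"))
  expect_true(all(fp[1, cc_bits] >= 3))
  expect_true(all(fp >= 0))
  expect_true(all(fp == round(fp)))
})

test_that("unparseable SMILES raises a featurization error naming the role", {
  rx <- list(reaction(c(a = "CC", b = "C(("), 10, validate = FALSE))
  expect_error(morgan_reaction_fp(rx), "role 'b'")
})

test_that("fingerprint environment count grows with molecule size", {
  # radius-2 circular environment count of a lone atom cannot exceed that
  # of a chain containing it
  n_c <- sum(morgan_reaction_fp(list(reaction(c(a = "C"), 1,
                                              validate = FALSE)))[1, ])
  n_ccc <- sum(morgan_reaction_fp(list(reaction(c(a = "CCC"), 1,
                                                validate = FALSE)))[1, ])
  expect_lte(n_c, n_ccc)
})

test_that("DRFP of a null reaction is the zero vector and width is configurable", {
  v <- drfp_reaction_fp("CC>>CC")
  expect_length(v, 2048)
  expect_true(all(v == 0))
  expect_length(drfp_reaction_fp("CC>>CCO", n_bits = 1024), 1024)
  expect_true(all(drfp_reaction_fp("c1ccccc1>>c1ccccc1") == 0))
})

test_that("DRFP is invariant to reactant order and detects change", {
  a <- drfp_reaction_fp("CC.CCO>>CCN")
  b <- drfp_reaction_fp("CCO.CC>>CCN")
  expect_identical(a, b)
  expect_gt(sum(drfp_reaction_fp("CC>>CCO")), 0)
  expect_error(drfp_reaction_fp("CC>"), "reactants>>products")
})

test_that("descriptor concatenation respects role order and reports misses", {
  rx <- list(
    reaction(c(a = "CC", b = "CCO"), 10, validate = FALSE),
    reaction(c(a = "CCC", b = "CCO"), 20, validate = FALSE)
  )
  tabs <- list(
    a = matrix(1:6, 2, 3, dimnames = list(c("CC", "CCC"), NULL)),
    b = matrix(7:10, 1, 4, dimnames = list("CCO", NULL))
  )
  fm <- descriptor_concat(rx, tabs)
  expect_equal(dim(fm), c(2L, 7L))
  expect_equal(unclass(fm)[1, ], c(1, 3, 5, 7, 8, 9, 10),
               ignore_attr = TRUE)
  rx_bad <- list(reaction(c(a = "CCCC", b = "CCO"), 1, validate = FALSE))
  expect_error(descriptor_concat(rx_bad, tabs), "component 'CCCC'")
})

test_that("molecular graphs carry the expected topology and features", {
  g <- mol_to_graph("CC")
  expect_equal(g$n_atoms, 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(ncol(g$x), node_feature_width())

  gb <- mol_to_graph("c1ccccc1")
  expect_equal(gb$n_atoms, 6)
  expect_equal(nrow(gb$edges), 6)
  arom_col <- 12 + 5 + 5 + 4 + 1   # element, degree, charge, hybridization
  expect_equal(gb$x[, arom_col], rep(1, 6))
  expect_equal(gb$edge_attr[, 4], rep(1, 6))   # aromatic bond type slot

  expect_error(mol_to_graph("C(("), "parse")
})

test_that("graph featurization is invariant to the SMILES writing", {
  g1 <- mol_to_graph("c1ccccc1")
  g2 <- mol_to_graph("C1=CC=CC=C1")
  expect_identical(g1$x, g2$x)
  expect_identical(g1$edge_attr, g2$edge_attr)
})

test_that("elements outside the vocabulary map to the 'other' slot", {
  expect_message(g <- mol_to_graph("[Se]"), "other")
  expect_equal(g$x[1, 12], 1)   # slot 12 = other, after the 11 elements
})
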
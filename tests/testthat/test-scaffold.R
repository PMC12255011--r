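# Scaffold groupings below were verified against an independent
# cheminformatics toolkit's Bemis-Murcko implementation (agreement on all
# probe molecules after canonicalizing both outputs with one canonicalizer).

test_that("murcko_scaffold strips side chains and keeps ring-linker cores", {
  # same benzene core from different decorations
  benz <- murcko_scaffold(c("CC(=O)c1ccccc1", "c1ccccc1CCN",
                            "OCc1ccc(CC)cc1", "c1ccc(cc1)C(=O)NCC"))
  expect_equal(length(unique(benz)), 1)
  expect_equal(benz[1], canonicalize_smiles("c1ccccc1"))

  # acyclic molecules share the empty scaffold
  expect_identical(murcko_scaffold(c("CCCCO", "CCOCC", "CC")),
                   c("", "", ""))

  # two rings joined by an amide linker keep the linker and its carbonyl
  amide <- murcko_scaffold("c1ccc(cc1)C(=O)Nc1ccccc1")
  expect_equal(amide, canonicalize_smiles("O=C(Nc1ccccc1)c1ccccc1"))

  # distinct ring systems stay distinct
  others <- murcko_scaffold(c("C1CCNCC1CC", "c1ccc2[nH]ccc2c1CC",
                              "c1ccc2ccccc2c1CCC", "c1ccsc1CC"))
  expect_equal(length(unique(others)), 4)
  expect_false(any(others %in% benz))

  expect_true(is.na(murcko_scaffold("not_a_smiles")))
})

test_that("scaffold extraction is invariant to the input SMILES spelling", {
  pairs <- list(c("c1ccccc1CCN", "NCCc1ccccc1"),
                c("CC(=O)c1ccccc1", "c1ccccc1C(C)=O"))
  for (p in pairs) {
    expect_equal(murcko_scaffold(p[1]), murcko_scaffold(p[2]))
  }
})

test_that("scaffold profiles reproduce the entropy arithmetic", {
  # four molecules, four distinct scaffolds: uniform maximum
  prof4 <- scaffold_profile(scaffolds = c("A", "B", "C", "D"))
  expect_equal(prof4$H, 2)
  expect_equal(prof4$H_normalized, 1)
  expect_equal(prof4$unique_total_ratio, 1)

  # counts {2,1,1}: H = 1.5 bits, normalized by log2(3)
  prof <- scaffold_profile(scaffolds = c("A", "A", "B", "C"))
  expect_equal(prof$H, 1.5)
  expect_equal(prof$H_normalized, 1.5 / log2(3), tolerance = 1e-9)
  expect_equal(prof$H_normalized, 0.946394, tolerance = 1e-6)
  expect_equal(prof$unique_total_ratio, 0.75)

  # degenerate single-scaffold convention
  prof1 <- scaffold_profile(scaffolds = c("A", "A", "A"))
  expect_equal(prof1$H, 0)
  expect_equal(prof1$H_normalized, 0)

  expect_equal(sum(prof$p), 1, tolerance = 1e-9)
  expect_error(scaffold_profile(character(0)), "empty")
})

test_that("entropy matches the oracle and is permutation/merge coherent", {
  set.seed(13)
  for (i in 1:200) {
    counts <- sample(1:20, sample(1:8, 1), replace = TRUE)
    labels <- rep(sprintf("S%d", seq_along(counts)), counts)
    prof <- scaffold_profile(scaffolds = labels)
    expect_equal(prof$H, oracle_entropy(counts), tolerance = 1e-12)
    expect_lte(prof$H, log2(prof$M) + 1e-12)
    # permuting scaffold labels leaves H unchanged
    relabel <- rep(sprintf("T%d", sample(seq_along(counts))), counts)
    expect_equal(scaffold_profile(scaffolds = relabel)$H, prof$H,
                 tolerance = 1e-12)
    # merging two scaffold classes never increases H
    if (length(counts) >= 2) {
      merged <- c(counts[1] + counts[2], counts[-(1:2)])
      expect_lte(oracle_entropy(merged), prof$H + 1e-12)
    }
  }
})

test_that("scaffold novelty is the unseen-scaffold fraction", {
  a <- scaffold_profile(scaffolds = c("A", "B", "C", "D"))
  b <- scaffold_profile(scaffolds = c("A", "B"))
  e <- scaffold_profile(scaffolds = c("X", "Y"))
  expect_equal(scaffold_novelty(a, b), 0.5)
  expect_equal(scaffold_novelty(a, a), 0)
  expect_equal(scaffold_novelty(e, a), 1)
})

test_that("scaffold-overlap score is the union-frequency correlation", {
  a <- scaffold_profile(scaffolds = rep(c("A", "B"), c(9, 1)))
  b <- scaffold_profile(scaffolds = rep(c("A", "B"), c(1, 9)))
  expect_equal(scaffold_overlap_score(a, a), 1)
  expect_equal(scaffold_overlap_score(a, b), -1)
  # hand-computed case: frequencies (.75,.25,0) vs (.25,.25,.5) over the
  # union give r = -0.755929 (closed-form Pearson arithmetic)
  x <- scaffold_profile(scaffolds = rep(c("A", "B"), c(3, 1)))
  y <- scaffold_profile(scaffolds = rep(c("A", "B", "C"), c(1, 1, 2)))
  expect_equal(scaffold_overlap_score(x, y), -0.7559289, tolerance = 1e-6)
  # constant frequency vector over the union: undefined
  u <- scaffold_profile(scaffolds = c("A", "B"))
  v <- scaffold_profile(scaffolds = c("A", "B"))
  expect_warning(res <- scaffold_overlap_score(u, v), "constant")
  expect_true(is.na(res))
})

test_that("the split-level scaffold audit runs on synthetic data", {
  p <- cached_prepared()
  audit <- scaffold_audit(p$table, p$splits)
  expect_named(audit$profiles,
               c("train", "internal_val", "test", "independent"))
  for (prof in audit$profiles) {
    expect_gte(prof$H_normalized, 0)
    expect_lte(prof$H_normalized, 1)
  }
  expect_true(all(audit$novelty_vs_train >= 0 & audit$novelty_vs_train <= 1))
})
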
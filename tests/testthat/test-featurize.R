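# Fingerprints, descriptors, Tanimoto similarity, graph featurization.

test_that("MACCS keys are 166 bits and folded families honor nbits", {
  f <- fingerprint(parse_molecule("CCO"), "maccs")
  expect_length(f$bits, 166L)
  expect_true(all(f$bits %in% c(0L, 1L)))
  for (kind in c("atompairs", "morgan", "topotorsion", "rdkit_path"))
    for (nb in c(512L, 1024L, 2048L))
      expect_length(fingerprint("CC(=O)Oc1ccccc1", kind, nb)$bits, nb)
  expect_ugtsom_error(fingerprint("CCO", "morgan", 100L), "bad_fp")
})

test_that("fingerprints are pure functions of the canonical molecule", {
  aliases <- c("OCC", "CCO", "C(O)C")
  for (kind in c("maccs", "morgan", "atompairs", "topotorsion", "rdkit_path")) {
    fps <- lapply(aliases, function(s)
      fingerprint(parse_molecule(s), kind, 1024L)$bits)
    expect_identical(fps[[2]], fps[[1]], info = kind)
    expect_identical(fps[[3]], fps[[1]], info = kind)
  }
  f1 <- fingerprint("c1ccccc1CCO", "morgan", 1024L)
  f2 <- fingerprint("c1ccccc1CCO", "morgan", 1024L)
  expect_identical(f1$bits, f2$bits)
})

test_that("Tanimoto similarity matches raw set arithmetic", {
  mols <- list("CCO", "CCCO", "c1ccccc1O")
  M <- tanimoto_matrix(mols, "morgan", 1024L)
  expect_equal(diag(M), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))
  # brute-force oracle on the raw on-bit index sets
  fps <- lapply(mols, function(s) which(fingerprint(s, "morgan", 1024L)$bits == 1L))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(M[i, j],
                 length(intersect(fps[[i]], fps[[j]])) /
                   length(union(fps[[i]], fps[[j]])))
  }
  expect_equal(tanimoto(fingerprint("CCO", "morgan"),
                        fingerprint("CCO", "morgan")), 1.0)
  expect_equal(mean_max_similarity(list("CCO"), list("CCO")), 1.0)
  expect_ugtsom_error(tanimoto_matrix(list()), "bad_input")
})

test_that("bit collisions do not increase with fingerprint width", {
  mols <- lapply(fx_molecules(60L), `[[`, "smiles")
  for (kind in c("morgan", "atompairs", "rdkit_path")) {
    coll <- vapply(c(512L, 1024L, 2048L), function(nb) {
      sum(vapply(mols, function(s) {
        f <- fingerprint(s, kind, nb)
        f$n_features - sum(f$bits)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(coll) <= 0), info = kind)
  }
})

test_that("descriptors are stable, named and physically sensible", {
  d <- descriptors("C")
  expect_equal(unname(d["MW"]), 16.04, tolerance = 1e-3)
  expect_identical(names(descriptors("c1ccccc1O")), names(d))
  expect_identical(descriptors(parse_molecule("OCC")),
                   descriptors(parse_molecule("CCO")))
  da <- descriptors("CC(=O)O")
  expect_equal(unname(da["n_atoms"]), 4)
  expect_equal(unname(da["n_rings"]), 0)
  expect_equal(unname(descriptors("c1ccccc1")["n_aromatic_atoms"]), 6)
})

test_that("the descriptor scaler standardizes training data and imputes", {
  recs <- fx_molecules(60L)
  X <- build_features(recs, feature_spec("descriptors"))
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_true(max(abs(colMeans(Z))) < 1e-9)
  keep <- apply(X, 2, stats::sd) > 0
  expect_true(max(abs(apply(Z[, keep], 2, stats::sd) - 1)) < 1e-6)
  # non-finite entries impute to the training median
  X2 <- X; X2[1, 3] <- NA
  Z2 <- apply_scaler(sc, X2)
  expect_true(all(is.finite(Z2)))
})

test_that("graph featurization matches molecular structure", {
  g <- mol_to_graph("C", "classifier")
  expect_equal(nrow(g$node_feats), 1L)
  expect_equal(nrow(g$edges), 0L)

  ge <- mol_to_graph("CCO", "wln")
  expect_equal(nrow(ge$node_feats), 3L)
  expect_equal(nrow(ge$edges), 2L)
  o_row <- which(as_molgraph("CCO", canonicalize = TRUE)$atoms$Z == 8L)
  expect_equal(unname(ge$node_feats[o_row, "deg_1"]), 1)

  gb <- mol_to_graph("c1ccccc1", "wln")
  expect_equal(sum(gb$node_feats[, "aromatic"]), 6)
  expect_equal(sum(gb$edge_feats[, "bt_aromatic"]), 6)
  expect_equal(sum(gb$edge_feats[, "in_ring"]), 6)
  expect_equal(sum(gb$edge_feats[, "conjugated"]), 6)
  expect_ugtsom_error(mol_to_graph("[H][H]"), "invalid_smiles")
})

test_that("one-hot blocks decode back to the atom properties", {
  voc <- ugtsom:::FEATURE_VOCAB_V1
  recs <- fx_molecules(120L)
  for (rec in recs[seq(1, length(recs), by = 2)]) {
    mg <- rec$graph
    g <- mol_to_graph(mg, "wln")
    nf <- g$node_feats
    # every one-hot block sums to exactly 1
    blocks <- list(el = 1:10, deg = 11:16, val = 17:23, nH = 24:28)
    for (b in blocks)
      expect_true(all(rowSums(nf[, b, drop = FALSE]) == 1))
    for (i in seq_len(nrow(nf))) {
      el <- c(voc$elements, "other")[which(nf[i, blocks$el] == 1)]
      expect_equal(el, if (mg$atoms$symbol[i] %in% voc$elements)
        mg$atoms$symbol[i] else "other")
      expect_equal(unname(which(nf[i, blocks$deg] == 1)) - 1L,
                   min(mg$atoms$degree[i], voc$degree_max + 1L))
      expect_equal(unname(which(nf[i, blocks$val] == 1)) - 1L,
                   min(mg$atoms$valence[i], voc$valence_max + 1L))
      expect_equal(unname(which(nf[i, blocks$nH] == 1)) - 1L,
                   min(mg$atoms$n_h[i], voc$imp_h_max + 1L))
      expect_equal(unname(nf[i, "aromatic"]),
                   as.numeric(mg$atoms$aromatic[i]))
    }
  }
})
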
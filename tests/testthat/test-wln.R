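# Architecture and training properties of the WLN site-of-metabolism model.

test_that("single-atom graphs pass through the WL update unchanged by depth", {
  m <- fx_random_wln()
  h1 <- wl_update(m, "C", n_iter = 1)
  h3 <- wl_update(m, "C", n_iter = 3)
  # no neighbors: only the self transformation applies each round; verify
  # the embedding is finite and the depth-1 result determines depth-3
  expect_true(all(is.finite(h1)))
  expect_equal(nrow(h1), 1L)
  expect_equal(dim(h1), dim(h3))
  expect_error(wl_update(m, "C", n_iter = 0))
})

test_that("zero parameters with zero bias give all-zero embeddings", {
  m <- fx_random_wln()
  m0 <- m
  m0$theta <- lapply(m$theta, function(x) x * 0)
  h <- wl_update(m0, "CC(=O)Oc1ccccc1", n_iter = 1)
  expect_true(all(h == 0))
})

test_that("WL local features are equivariant under atom reindexing", {
  m <- fx_random_wln()
  set.seed(20)
  recs <- fx_molecules(60L)[seq(1, 50)]
  worst <- 0
  for (rec in recs) {
    mg <- rec$graph
    perm <- sample(ugtsom:::n_atoms(mg))
    h <- wl_update(m, mg)
    hp <- wl_update(m, ugtsom:::permute_molgraph(mg, perm))
    worst <- max(worst, max(abs(hp[perm, , drop = FALSE] - h)))
  }
  expect_lt(worst, 1e-5)
})

test_that("with one WL iteration, edits beyond the neighborhood radius do not
          touch local features", {
  m <- fx_random_wln()
  # atom chains written in fixed order; the edit (O -> N) sits 4 and 3 bonds
  # from atoms 1 and 2 respectively
  a <- as_molgraph("CCCCO")
  b <- as_molgraph("CCCCN")
  ha <- wl_update(m, a, n_iter = 1)
  hb <- wl_update(m, b, n_iter = 1)
  expect_equal(ha[1, ], hb[1, ], tolerance = 1e-12)
  expect_equal(ha[2, ], hb[2, ], tolerance = 1e-12)
  expect_gt(max(abs(ha[4, ] - hb[4, ])), 0)
})

test_that("global attention weights are a convex combination", {
  m <- fx_random_wln()
  h <- wl_update(m, "CC(=O)Oc1ccccc1", include_sugar = TRUE)
  at <- global_attention(m, h)
  expect_equal(rowSums(at$weights), rep(1, nrow(h)), tolerance = 1e-12)
  expect_true(all(at$weights >= 0))
  # singleton universe: weight 1 on itself, context = own value projection
  h1 <- wl_update(m, "C")
  a1 <- global_attention(m, h1)
  expect_equal(as.numeric(a1$weights), 1)
  expect_equal(a1$context, h1 %*% m$theta$Wv, ignore_attr = TRUE)
  # uniform logits (zeroed query/key): context is the mean value projection
  mu <- m
  mu$theta$Wq <- mu$theta$Wq * 0
  mu$theta$Wk <- mu$theta$Wk * 0
  au <- global_attention(mu, h)
  V <- h %*% m$theta$Wv
  expect_equal(au$context[1, ], colMeans(V), tolerance = 1e-10)
})

test_that("the co-reactant changes substrate context vectors", {
  m <- fx_random_wln()
  mg <- parse_molecule("Cc1ccc(O)cc1")$graph
  h_alone <- wl_update(m, mg, include_sugar = FALSE)
  h_with <- wl_update(m, mg, include_sugar = TRUE)
  n_sub <- ugtsom:::n_atoms(mg)
  # local features of the substrate are identical (no cross-molecule bonds)
  expect_equal(h_with[seq_len(n_sub), ], h_alone, tolerance = 1e-12)
  ctx_alone <- global_attention(m, h_alone)$context
  ctx_with <- global_attention(m, h_with)$context[seq_len(n_sub), ]
  expect_gt(max(abs(ctx_with - ctx_alone)), 0)
})

test_that("score_sites ranks deterministically and handles edge cases", {
  m <- fx_random_wln()
  # single-candidate substrate: that site is top-1 whatever the parameters
  p <- score_sites(m, parse_molecule("Cc1ccc(O)cc1"))
  expect_equal(nrow(p$ranked_sites), 1L)
  expect_equal(p$ranked_sites$site_class, "ArOH")
  expect_equal(p$ranked_sites$rank, 1L)
  # no candidate sites: explicit reason, not an error
  p0 <- score_sites(m, parse_molecule("CCCC"))
  expect_equal(p0$reason, "no potential SOM")
  expect_equal(nrow(p0$ranked_sites), 0L)
  # determinism
  rec <- parse_molecule("OCc1ccc(O)cc1C(=O)O")
  expect_identical(score_sites(m, rec)$ranked_sites,
                   score_sites(m, rec)$ranked_sites)
})

test_that("site rankings are invariant to atom reindexing of the substrate", {
  m <- fx_random_wln()
  set.seed(21)
  recs <- fx_molecules(120L)
  checked <- 0L
  worst <- 0
  for (rec in recs) {
    if (checked >= 50L) break
    sites <- enumerate_candidate_sites(rec)
    if (nrow(sites) < 2L) next
    checked <- checked + 1L
    mg <- rec$graph
    perm <- sample(ugtsom:::n_atoms(mg))
    r1 <- score_sites(m, mg)$ranked_sites
    r2 <- score_sites(m, ugtsom:::permute_molgraph(mg, perm))$ranked_sites
    # map permuted atom indices back and compare scores site by site
    r2$orig <- order(perm)[r2$atom_index]
    merged <- merge(r1, r2, by.x = "atom_index", by.y = "orig")
    expect_equal(nrow(merged), nrow(r1))
    worst <- max(worst, max(abs(merged$reactivity_score.x -
                                  merged$reactivity_score.y)))
  }
  expect_gte(checked, 30L)
  expect_lt(worst, 1e-5)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  rx <- fx_reactions(40L, seed = 13L)
  cfg <- wln_config(hidden_width = 24L, seed = 99L,
                    early_stop = early_stop_policy(max_epochs = 6L))
  m1 <- train_wln(rx[1:32], cfg, validation = rx[33:40])
  expect_lt(m1$log$loss[5], m1$log$loss[1])
  expect_lte(nrow(m1$log), 6L)
  m2 <- train_wln(rx[1:32], cfg, validation = rx[33:40])
  expect_equal(m1$best_valid_top1, m2$best_valid_top1, tolerance = 1e-6)
  expect_equal(m1$theta, m2$theta, tolerance = 1e-12)
})

test_that("single-candidate-only training warns and samples carbon negatives", {
  rx1 <- fx_reactions(12L, seed = 31L, mode = "single")
  cfg <- wln_config(hidden_width = 16L, seed = 1L,
                    early_stop = early_stop_policy(max_epochs = 2L))
  expect_warning(train_wln(rx1[1:10], cfg, validation = rx1[11:12]),
                 "single candidate site")
})

test_that("a trained model recovers the planted site preference", {
  m <- fx_trained_wln()
  expect_gt(m$best_valid_top1, 0.8)
  rx <- fx_reactions(120L, seed = 7L)
  probes <- rx[101:120]
  preds <- lapply(probes, function(r)
    score_sites(m, r$reactants[[r$substrate_index]]))
  truths <- lapply(probes, function(r)
    data.frame(atom_index = r$som_atom_index, site_class = r$som_class))
  expect_gt(topk_accuracy(preds, truths, 1), 0.8)
  tab <- per_class_topk(preds, truths)
  expect_true(all(tab$top_1[!is.na(tab$top_1)] >= 0))
})
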
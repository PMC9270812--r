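# Shared fixtures, built lazily once per test session. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# a literature-style mapped glucuronidation (3,5-dibromoanthranilic acid),
# used across the parser tests
DBA_GLUCURONIDATION_SMIRKS <- paste0(
  "[O:1]=[C:2]([OH:3])[C:4]1=[CH:5][C:6]([Br:7])=[CH:8][C:9]([Br:10])=",
  "[C:11]1[NH2:12].[O:13]=[C:14]([OH:15])[CH:16]1[O:17][CH*:18][CH:19]",
  "([OH:20])[CH:21]([OH:22])[CH:23]1[OH:24] >> [Br:7][C:6]1=[CH:8][C:9]",
  "([Br:10])=[C:11]([NH2:12])[C:4]([C:2]([O:3][CH:18]2[O:17][CH:16]",
  "([C:14]([OH:15])=[O:13])[CH:23]([CH:21]([CH:19]2[OH:20])[OH:22])",
  "[OH:24])=[O:1])=[CH:5]1")

fx_molecules <- function(n = 120L, seed = 9L, noise = 0)
  fixture(paste0("mols_", n, "_", seed, "_", noise), function()
    gen_substrate_set(generator_config(n_molecules = n, seed = seed,
                                       label_noise = noise)))

fx_reactions <- function(n = 40L, seed = 7L, mode = "multi")
  fixture(paste0("rxns_", n, "_", seed, "_", mode), function()
    gen_reaction_set(generator_config(n_molecules = n, seed = seed,
                                      site_ambiguity = mode)))

# an untrained WLN with seeded random weights (for architecture-level
# property tests that do not depend on fitting)
fx_random_wln <- function(seed = 1L, hidden = 32L) {
  fixture(paste0("wln_rand_", seed, "_", hidden), function() {
    d_in <- ncol(mol_to_graph("CCO", "wln")$node_feats)
    structure(list(
      theta = ugtsom:::nn_init_params(
        ugtsom:::wln_param_dims(d_in, 6L, hidden), seed = seed),
      config = wln_config(hidden_width = hidden, seed = seed),
      d_in = d_in, log = data.frame(), best_valid_top1 = NA_real_),
      class = "wln_model")
  })
}

# a small trained WLN shared by ranking tests
fx_trained_wln <- function() {
  fixture("wln_trained_small", function() {
    rx <- fx_reactions(120L, seed = 7L)
    train_wln(rx[1:100],
              wln_config(hidden_width = 64L, seed = 42L,
                         early_stop = early_stop_policy(max_epochs = 30L)),
              validation = rx[101:120])
  })
}

expect_ugtsom_error <- function(expr, class_suffix) {
  expect_error(expr, class = paste0("ugtsom_", class_suffix))
}
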
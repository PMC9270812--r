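# Molecule/reaction parsing, SOM identification and site enumeration.

test_that("parse_molecule canonicalizes and validates", {
  rec <- parse_molecule("OCC")
  expect_s3_class(rec, "molecule_record")
  expect_equal(rec$smiles, "CCO")
  # canonicalization is idempotent
  expect_equal(parse_molecule(rec$smiles)$smiles, rec$smiles)

  dba <- parse_molecule("O=C(C1=CC(Br)=CC(Br)=C1N)O")
  expect_equal(sum(dba$graph$atoms$Z == 35), 2L)  # two bromines
  expect_equal(ugtsom:::n_atoms(dba$graph), 12L)

  expect_ugtsom_error(parse_molecule("not_a_smiles"), "invalid_smiles")
  expect_ugtsom_error(parse_molecule(""), "invalid_smiles")
  expect_ugtsom_error(parse_molecule("CCO.OCC"), "invalid_smiles")
})

test_that("SMILES writer round-trips through canonicalization", {
  smis <- c("CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1", "C[N+](C)(C)C",
            "N#Cc1ccccc1", "c1cc[nH]c1", "OC(=O)C1OCC(O)C(O)C1O",
            "Clc1cccc(CC(N)C(=O)O)c1")
  for (s in smis) {
    mg <- as_molgraph(s, canonicalize = TRUE)
    expect_equal(ugtsom:::ob_canonical_smiles(ugtsom:::write_smiles(mg)),
                 mg$smiles, info = s)
  }
})

test_that("atom maps survive the writer and permutation preserves structure", {
  s <- "[CH3:5][C:6](=[O:7])[OH:8]"
  mg <- as_molgraph(s)
  w <- ugtsom:::write_smiles(mg)
  expect_identical(as_molgraph(w)$atoms$map, mg$atoms$map)
  set.seed(3)
  mg2 <- as_molgraph("O=C(O)c1cc(Br)cc(Br)c1N")
  perm <- sample(ugtsom:::n_atoms(mg2))
  mgp <- ugtsom:::permute_molgraph(mg2, perm)
  expect_equal(ugtsom:::ob_canonical_smiles(mgp$smiles),
               ugtsom:::ob_canonical_smiles(mg2$smiles))
})

test_that("parse_reaction handles the curated mapped SMIRKS dialect", {
  rec <- parse_reaction(DBA_GLUCURONIDATION_SMIRKS)
  expect_length(rec$reactants, 2L)
  expect_length(rec$products, 1L)
  expect_equal(rec$formed_bonds, list(c(3L, 18L)))
  expect_equal(rec$som_map, 3L)
  expect_equal(rec$som_class, "COOH")
  expect_equal(rec$substrate_index, 1L)
  # the SOM atom is the hydroxyl oxygen of the carboxyl
  sub <- rec$reactants[[rec$substrate_index]]
  expect_equal(sub$atoms$Z[rec$som_atom_index], 8L)
})

test_that("malformed reactions are rejected distinctly", {
  expect_ugtsom_error(parse_reaction("CCO.CCN"), "bad_smirks")
  # unbalanced: product carries a map absent from reactants
  expect_ugtsom_error(parse_reaction(
    "[CH3:1][OH:2].[OH:3][CH3:4]>>[CH3:1][O:2][CH3:9]"), "unbalanced")
  # missing maps
  expect_ugtsom_error(parse_reaction("CCO>>CCO"), "unmapped_atoms")
  # no glucuronic acid among reactants
  expect_ugtsom_error(parse_reaction(
    "[CH3:1][OH:2].[CH4:3]>>[CH3:1][O:2][CH3:3]"), "no_glucuronyl")
})

test_that("identity reactions and sulfur conjugation are rejected", {
  sugar <- "[OH:20][C:21](=[O:22])[CH:23]1[O:24][CH2:25][CH:26]([OH:27])[CH:28]([OH:29])[CH:30]1[OH:31]"
  # identity: sugar plus thiol, nothing formed
  expect_ugtsom_error(
    parse_reaction(paste0("[CH3:1][SH:2].", sugar,
                          ">>[CH3:1][SH:2].", sugar)),
    "no_edit")
  # S-glucuronidation: formed bond touches sulfur
  expect_ugtsom_error(
    parse_reaction(paste0("[CH3:1][SH:2].", sugar,
                          ">>[CH3:1][S:2][CH:25]1[O:24][CH:23]([C:21]([OH:20])=[O:22])[CH:30]([OH:31])[CH:28]([OH:29])[CH:26]1[OH:27]")),
    "excluded_reaction")
})

test_that("SOM classes follow the COOH > ArOH > AlOH precedence", {
  phen <- as_molgraph("Oc1ccccc1", canonicalize = TRUE)
  o_phen <- which(phen$atoms$Z == 8L)
  expect_equal(classify_som_type(phen, o_phen), "ArOH")

  ac <- as_molgraph("CC(=O)O", canonicalize = TRUE)
  o_hydroxyl <- which(ac$atoms$Z == 8L & ac$atoms$n_h == 1L)
  expect_equal(classify_som_type(ac, o_hydroxyl), "COOH")

  allyl <- as_molgraph("OCC=CC1CCCCC1", canonicalize = TRUE)
  o_al <- which(allyl$atoms$Z == 8L)
  expect_equal(classify_som_type(allyl, o_al), "AlOH")

  aniline <- as_molgraph("Nc1ccccc1", canonicalize = TRUE)
  expect_equal(classify_som_type(aniline, which(aniline$atoms$Z == 7L)),
               "Nitrogen")
  expect_ugtsom_error(classify_som_type(ac, which(ac$atoms$Z == 6L)[1]),
                      "unclassifiable_site")
})

test_that("candidate site enumeration is deterministic and chemically scoped", {
  expect_equal(nrow(enumerate_candidate_sites(as_molgraph("CCC"))), 0L)

  cresol <- enumerate_candidate_sites(parse_molecule("Cc1ccc(O)cc1"))
  expect_equal(nrow(cresol), 1L)
  expect_equal(cresol$site_class, "ArOH")

  dba <- enumerate_candidate_sites(parse_molecule("O=C(O)c1cc(Br)cc(Br)c1N"))
  expect_equal(sort(dba$site_class), c("COOH", "Nitrogen"))

  # excluded nitrogens: quaternary, nitro-like (charged), nitrile
  expect_equal(nrow(enumerate_candidate_sites(as_molgraph("C[N+](C)(C)C"))), 0L)
  expect_equal(nrow(enumerate_candidate_sites(as_molgraph("N#CC"))), 0L)
  # pyridine nitrogen (sp2 lone pair) is a candidate; methoxy O is not
  pyr <- enumerate_candidate_sites(as_molgraph("COc1ccncc1", canonicalize = TRUE))
  expect_equal(pyr$site_class, "Nitrogen")
  # ordering is by atom index
  multi <- enumerate_candidate_sites(parse_molecule("OCc1ccc(O)cc1C(=O)O"))
  expect_false(is.unsorted(multi$atom_index))
})

test_that("site enumeration is invariant to input atom ordering", {
  aliases <- c("Oc1ccc(CC(N)C(=O)O)cc1", "C(c1ccc(O)cc1)C(C(=O)O)N",
               "NC(Cc1ccc(O)cc1)C(=O)O")
  sets <- lapply(aliases, function(s) {
    rec <- parse_molecule(s)
    st <- enumerate_candidate_sites(rec)
    st$symbol <- rec$graph$atoms$symbol[st$atom_index]
    st[order(st$atom_index), c("site_class", "symbol")]
  })
  for (i in 2:3) expect_equal(sets[[i]], sets[[1]])
})

test_that("the glucuronidation atom mapper reconstructs mapped reactions", {
  # build a product with the package's own conjugation, then strip maps
  rec <- parse_molecule("Cc1ccc(O)cc1")
  site <- enumerate_candidate_sites(rec)$atom_index[1]
  smk <- ugtsom:::make_reaction_smirks(rec, site)
  prod_smiles <- gsub(":[0-9]+", "", strsplit(smk, ">>", fixed = TRUE)[[1]][2])
  mapped <- map_glucuronidation(rec$smiles, prod_smiles)
  expect_s3_class(mapped, "reaction_record")
  expect_equal(mapped$som_class, "ArOH")
  expect_equal(
    mapped$reactants[[mapped$substrate_index]]$atoms$Z[mapped$som_atom_index],
    8L)
  # substrate == product: no glucuronide present
  expect_ugtsom_error(map_glucuronidation("Oc1ccccc1", "Oc1ccccc1"),
                      "no_glucuronyl")
})

test_that("diglucuronide products are declared unsupported", {
  rec <- parse_molecule("Oc1ccc(O)cc1")
  sites <- enumerate_candidate_sites(rec)$atom_index
  once <- ugtsom:::build_glucuronide(rec$graph, sites[1])
  sites2 <- enumerate_candidate_sites(once)
  ar2 <- sites2$atom_index[sites2$site_class == "ArOH"][1]
  twice <- ugtsom:::build_glucuronide(once, ar2)
  expect_ugtsom_error(
    map_glucuronidation(rec$smiles, ugtsom:::write_smiles(twice)),
    "unsupported")
})

test_that("molecule and reaction file readers skip bad rows with warnings", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles,label\nm1,CCO,1\nm2,xxxx_bad,0\nm3,c1ccccc1O,0", tmp)
  expect_warning(recs <- read_molecules(tmp), "skipping")
  expect_length(recs, 2L)
  expect_equal(recs[[2]]$label, 0L)

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tmol_a", "CCN"), smi)
  recs2 <- read_molecules(smi)
  expect_equal(recs2[[1]]$id, "mol_a")

  rxn <- withr::local_tempfile(fileext = ".smirks")
  writeLines(c(DBA_GLUCURONIDATION_SMIRKS, "# comment", "garbage>>garbage"), rxn)
  expect_warning(rxns <- read_reactions(rxn), "skipping")
  expect_length(rxns, 1L)
})
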
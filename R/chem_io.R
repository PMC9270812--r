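# Molecule and reaction input: SMILES/CSV readers, atom-mapped glucuronidation
# SMIRKS parsing and validation, formed-bond detection, site-of-metabolism
# (SOM) identification and classification, candidate-site enumeration, and a
# glucuronidation-specific atom mapper for unmapped substrate/product pairs.
#
# Conventions: atom-map numbers are 1-based (SMIRKS convention); internal atom
# indices are 1-based as usual in R. Only O- and N-glucuronidation are
# modeled; the uridine diphosphate leaving group is never represented, so the
# glucuronosyl co-reactant carries a hydrogen placeholder on the anomeric
# carbon and reactions balance on heavy atoms.

# Free glucuronosyl co-reactant (heavy-atom skeleton of glucuronic acid with
# the anomeric substituent left implicit). Ring: C1(anomeric)-O-C(COOH)-
# C(OH)-C(OH)-C(OH).
GLUCURONYL_SMILES <- "OC(=O)C1OCC(O)C(O)C1O"

# Pyranose-uronic-acid core, stereochemistry-agnostic (input data mixes
# alpha/beta depictions). First pattern atom is the anomeric carbon.
GLUCURONYL_SMARTS <- paste0(
  "[#6;R]1[#8;R][#6;R]([#6X3](=[#8X1])[#8])",
  "[#6;R]([#8X2H1])[#6;R]([#8X2H1])[#6;R]1[#8X2H1]"
)

.chem_env <- new.env(parent = emptyenv())

glucuronyl_molgraph <- function() {
  if (is.null(.chem_env$sugar)) {
    mg <- as_molgraph(GLUCURONYL_SMILES)
    m <- ob_smarts_match(ob_mol(mg$smiles), GLUCURONYL_SMARTS)
    if (length(m) != 1L)
      stop_ugtsom("internal", "glucuronosyl template does not match its own pattern")
    .chem_env$sugar <- list(mg = mg, pattern_atoms = m[[1]],
                            anomeric = m[[1]][1])
  }
  .chem_env$sugar
}

#' Parse and canonicalize a molecule
#'
#' @param smiles a single SMILES string.
#' @param id optional identifier (defaults to the canonical SMILES).
#' @param label optional 0/1 substrate label.
#' @return a `molecule_record`: list with `id`, `smiles` (canonical), `label`
#'   and the parsed `graph` (a [as_molgraph()] object in canonical atom
#'   order).
#' @examples
#' rec <- parse_molecule("OCC")
#' rec$smiles  # "CCO"
#' @export
parse_molecule <- function(smiles, id = NULL, label = NA_integer_) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop_ugtsom("invalid_smiles", "SMILES must be a non-empty string")
  if (grepl(".", smiles, fixed = TRUE))
    stop_ugtsom("invalid_smiles",
                "multi-component SMILES not allowed for a molecule record: ",
                smiles)
  mg <- as_molgraph(smiles, canonicalize = TRUE)
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop_ugtsom("invalid_label", "label must be 0, 1 or NA")
  structure(
    list(id = if (is.null(id)) mg$smiles else as.character(id),
         smiles = mg$smiles, label = as.integer(label), graph = mg),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("molecule", x$id, ":", x$smiles,
      if (!is.na(x$label)) paste0("(label ", x$label, ")"), "\n")
  invisible(x)
}

#' Classify a nucleophilic site
#'
#' Assigns one of the four SOM classes to an O or N atom: carboxylic acid
#' (`COOH`), aromatic hydroxyl (`ArOH`), aliphatic hydroxyl (`AlOH`) or
#' nitrogen site (`Nitrogen`). For oxygens the precedence is
#' COOH > ArOH > AlOH, so a carboxyl hydroxyl is never reported as an
#' aliphatic hydroxyl; every nitrogen maps to `Nitrogen`.
#'
#' @param mg a [as_molgraph()] object (or `molecule_record`).
#' @param atom_index 1-based atom index of an O or N atom.
#' @return one of `"AlOH"`, `"ArOH"`, `"COOH"`, `"Nitrogen"`.
#' @export
classify_som_type <- function(mg, atom_index) {
  if (inherits(mg, "molecule_record")) mg <- mg$graph
  stopifnot(inherits(mg, "molgraph"))
  if (atom_index < 1L || atom_index > n_atoms(mg))
    stop_ugtsom("bad_atom", "atom index out of range: ", atom_index)
  Z <- mg$atoms$Z[atom_index]
  if (Z == 7L) return("Nitrogen")
  if (Z != 8L)
    stop_ugtsom("unclassifiable_site",
                "site atom must be O or N, got ",
                mg$atoms$symbol[atom_index])
  adj <- mg_neighbors(mg)
  nbr <- adj$nbr[[atom_index]]
  cn <- nbr[mg$atoms$Z[nbr] == 6L]
  if (length(cn) == 0L)
    stop_ugtsom("unclassifiable_site", "oxygen with no carbon neighbor")
  for (c_at in cn) {
    # carboxyl: the carbon also bears a double-bonded oxygen
    kk <- adj$bond[[c_at]]
    for (k in kk) {
      other <- setdiff(c(mg$bonds$a1[k], mg$bonds$a2[k]), c_at)
      if (length(other) == 1L && other != atom_index &&
          mg$atoms$Z[other] == 8L && mg$bonds$order[k] == 2L)
        return("COOH")
    }
  }
  if (any(mg$atoms$aromatic[cn])) return("ArOH")
  "AlOH"
}

#' Enumerate candidate glucuronidation sites
#'
#' Deterministically lists every potential O- or N-glucuronidation site of a
#' molecule, ordered by atom index. Oxygen candidates are neutral hydroxyls
#' (aliphatic, aromatic or carboxylic). Nitrogen candidates are neutral,
#' non-quaternary nitrogens that either carry a hydrogen or are
#' sp2/aromatic with a free lone pair; nitrile and nitro nitrogens are
#' excluded. The result is the denominator set for top-k ranking.
#'
#' @param mg a [as_molgraph()] object or `molecule_record`.
#' @return data.frame with columns `atom_index` and `site_class`; zero rows
#'   mean "no potential SOM".
#' @export
enumerate_candidate_sites <- function(mg) {
  if (inherits(mg, "molecule_record")) mg <- mg$graph
  stopifnot(inherits(mg, "molgraph"))
  out_idx <- integer(0); out_cls <- character(0)
  adj <- mg_neighbors(mg)
  for (i in seq_len(n_atoms(mg))) {
    a <- mg$atoms[i, ]
    if (a$Z == 8L) {
      if (a$charge != 0L || a$n_h < 1L) next
      nbr <- adj$nbr[[i]]
      if (!any(mg$atoms$Z[nbr] == 6L)) next
      out_idx <- c(out_idx, i)
      out_cls <- c(out_cls, classify_som_type(mg, i))
    } else if (a$Z == 7L) {
      if (a$charge != 0L || a$degree >= 4L) next
      orders <- mg$bonds$order[adj$bond[[i]]]
      if (any(orders == 3L)) next                       # nitrile
      sp2_lone_pair <- (a$aromatic && a$n_h == 0L && a$degree == 2L) ||
        (!a$aromatic && any(orders == 2L) && a$degree <= 2L)
      if (a$n_h >= 1L || sp2_lone_pair) {
        out_idx <- c(out_idx, i)
        out_cls <- c(out_cls, "Nitrogen")
      }
    }
  }
  data.frame(atom_index = out_idx, site_class = out_cls,
             stringsAsFactors = FALSE)
}

# --- reaction parsing ------------------------------------------------------

# bonds of a mapped molgraph as a set of "i-j" map-pair keys (i < j)
bond_map_pairs <- function(mg) {
  if (nrow(mg$bonds) == 0L) return(character(0))
  m1 <- mg$atoms$map[mg$bonds$a1]
  m2 <- mg$atoms$map[mg$bonds$a2]
  paste(pmin(m1, m2), pmax(m1, m2), sep = "-")
}

#' Parse an atom-mapped glucuronidation reaction
#'
#' Accepts a reaction SMIRKS (`reactants >> products`, reactants separated by
#' `.`), validates the atom mapping (every heavy reactant atom mapped with a
#' unique positive number, product map multiset equal to the reactant one),
#' requires a glucuronosyl moiety among the reactants, and locates the formed
#' bond and the site of metabolism.
#'
#' @param smirks an atom-mapped reaction string. The curly `[CH*:n]`
#'   reactive-site annotation accepted by some curation pipelines is
#'   tolerated and stripped.
#' @return a `reaction_record`: list with `smirks`, `reactants` / `products`
#'   (lists of molgraphs), `formed_bonds` (list of map-number pairs),
#'   `som_map`, `som_class`, `substrate_index` (which reactant hosts the
#'   SOM), `som_atom_index` (atom index inside that reactant) and
#'   `sugar_index` (which reactant is the glucuronosyl donor).
#' @export
parse_reaction <- function(smirks) {
  stopifnot(is.character(smirks), length(smirks) == 1L)
  if (length(gregexpr(">>", smirks, fixed = TRUE)[[1]]) != 1L ||
      !grepl(">>", smirks, fixed = TRUE))
    stop_ugtsom("bad_smirks", "reaction must contain exactly one '>>': ",
                smirks)
  halves <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L || !nzchar(trimws(halves[1])) ||
      !nzchar(trimws(halves[2])))
    stop_ugtsom("bad_smirks", "empty reactant or product side")
  parse_side <- function(s) {
    comps <- trimws(strsplit(trimws(s), ".", fixed = TRUE)[[1]])
    lapply(comps, as_molgraph, canonicalize = FALSE)
  }
  reactants <- parse_side(halves[1])
  products <- parse_side(halves[2])

  rmaps <- unlist(lapply(reactants, function(m) m$atoms$map))
  pmaps <- unlist(lapply(products, function(m) m$atoms$map))
  if (any(rmaps <= 0L))
    stop_ugtsom("unmapped_atoms", "every reactant heavy atom needs an atom map")
  if (anyDuplicated(rmaps))
    stop_ugtsom("duplicate_maps", "duplicated reactant atom-map numbers")
  if (!identical(sort(rmaps), sort(pmaps)))
    stop_ugtsom("unbalanced", "reactant and product atom-map multisets differ")

  sugar_hits <- vapply(reactants, function(m)
    length(ob_smarts_match(ob_mol(m$smiles), GLUCURONYL_SMARTS)) > 0L,
    logical(1))
  if (!any(sugar_hits))
    stop_ugtsom("no_glucuronyl", "no glucuronic-acid moiety among reactants")
  sugar_index <- which(sugar_hits)[1]

  rec <- structure(
    list(smirks = smirks, reactants = reactants, products = products,
         sugar_index = sugar_index, formed_bonds = NULL,
         som_map = NA_integer_, som_class = NA_character_,
         substrate_index = NA_integer_, som_atom_index = NA_integer_),
    class = "reaction_record"
  )
  rec$formed_bonds <- extract_formed_bonds(rec)
  som <- identify_som(rec)
  rec$substrate_index <- som$substrate_index
  rec$som_atom_index <- som$atom_index
  rec$som_map <- som$som_map
  rec$som_class <- som$som_class
  rec
}

#' @export
print.reaction_record <- function(x, ...) {
  cat("glucuronidation reaction:", length(x$reactants), "reactants ->",
      length(x$products), "products\n")
  cat("  SOM: map", x$som_map, "class", x$som_class, "\n")
  invisible(x)
}

#' Bonds formed by a mapped reaction
#'
#' Compares the bond sets of the reactant and product sides (as unordered
#' atom-map pairs) and returns the pairs present only among the products.
#'
#' @param rec a `reaction_record` (fields `reactants`/`products` suffice).
#' @return list of integer pairs `c(map_i, map_j)` with `map_i < map_j`.
#' @export
extract_formed_bonds <- function(rec) {
  rb <- unlist(lapply(rec$reactants, bond_map_pairs))
  pb <- unlist(lapply(rec$products, bond_map_pairs))
  formed <- setdiff(pb, rb)
  if (length(formed) == 0L)
    stop_ugtsom("no_edit", "reaction forms no new bond (identity reaction?)")
  lapply(strsplit(formed, "-", fixed = TRUE),
         function(p) as.integer(p))
}

#' Identify the site of metabolism of a parsed reaction
#'
#' The formed bond must join the glucuronosyl anomeric carbon to an O or N
#' atom of another reactant (the substrate); that atom is the SOM. Formed
#' bonds internal to the sugar, multiple formed bonds at the anomeric carbon,
#' and S-/C-glucuronidation are rejected.
#'
#' @param rec a `reaction_record` with `formed_bonds` populated.
#' @return list with `substrate_index`, `atom_index`, `som_map`, `som_class`.
#' @export
identify_som <- function(rec) {
  sugar <- rec$reactants[[rec$sugar_index]]
  hit <- ob_smarts_match(ob_mol(sugar$smiles), GLUCURONYL_SMARTS)[[1]]
  anomeric_map <- sugar$atoms$map[hit[1]]
  touches <- vapply(rec$formed_bonds, function(p) anomeric_map %in% p,
                    logical(1))
  if (sum(touches) == 0L)
    stop_ugtsom("no_anomeric_bond",
                "no formed bond involves the glucuronosyl anomeric carbon")
  if (sum(touches) > 1L)
    stop_ugtsom("ambiguous_edit",
                ">1 formed bond at the anomeric carbon; manual review needed")
  pair <- rec$formed_bonds[[which(touches)]]
  som_map <- setdiff(pair, anomeric_map)
  if (length(som_map) != 1L)
    stop_ugtsom("ambiguous_edit", "formed bond is internal to the sugar")
  sugar_maps <- sugar$atoms$map
  if (som_map %in% sugar_maps)
    stop_ugtsom("ambiguous_edit",
                "formed bond lies entirely inside the glucuronosyl reactant")
  host <- which(vapply(rec$reactants, function(m) som_map %in% m$atoms$map,
                       logical(1)))
  host <- setdiff(host, rec$sugar_index)
  if (length(host) != 1L)
    stop_ugtsom("bad_som", "SOM atom not found in a unique substrate reactant")
  mg <- rec$reactants[[host]]
  idx <- which(mg$atoms$map == som_map)
  Z <- mg$atoms$Z[idx]
  if (!Z %in% c(7L, 8L))
    stop_ugtsom("excluded_reaction",
                "formed bond touches ", mg$atoms$symbol[idx],
                ": only O- and N-glucuronidation are modeled")
  list(substrate_index = host, atom_index = idx, som_map = som_map,
       som_class = classify_som_type(mg, idx))
}

# --- building mapped reactions (shared with the synthetic generator) -------

# Attach the glucuronosyl group at `site` of a substrate molgraph. The
# nucleophile loses one hydrogen; the anomeric CH2 placeholder loses one.
build_glucuronide <- function(substrate, site) {
  if (inherits(substrate, "molecule_record")) substrate <- substrate$graph
  if (substrate$atoms$n_h[site] < 1L)
    stop_ugtsom("bad_attachment",
                "site atom has no hydrogen to displace: atom ", site)
  sugar <- glucuronyl_molgraph()$mg
  an <- glucuronyl_molgraph()$anomeric
  n0 <- n_atoms(substrate)
  atoms <- rbind(substrate$atoms, sugar$atoms)
  rownames(atoms) <- NULL
  sb <- sugar$bonds
  sb$a1 <- sb$a1 + n0; sb$a2 <- sb$a2 + n0
  bonds <- rbind(substrate$bonds, sb,
                 data.frame(a1 = site, a2 = an + n0, order = 1L,
                            aromatic = FALSE, in_ring = FALSE,
                            conjugated = FALSE))
  atoms$n_h[site] <- atoms$n_h[site] - 1L
  atoms$n_h[an + n0] <- atoms$n_h[an + n0] - 1L
  atoms$degree[site] <- atoms$degree[site] + 1L
  atoms$degree[an + n0] <- atoms$degree[an + n0] + 1L
  atoms$valence[site] <- atoms$valence[site] + 1L
  atoms$valence[an + n0] <- atoms$valence[an + n0] + 1L
  out <- substrate
  out$atoms <- atoms
  out$bonds <- bonds
  out$smiles <- write_smiles(out)
  out
}

# Fully mapped SMIRKS for glucuronidation of `substrate` at atom `site`.
# Substrate atoms take maps 1..n, sugar atoms n+1..n+12; the product is the
# conjugate with maps carried over (heavy-atom balanced by construction).
make_reaction_smirks <- function(substrate, site) {
  if (inherits(substrate, "molecule_record")) substrate <- substrate$graph
  sub <- substrate
  n0 <- n_atoms(sub)
  sub$atoms$map <- seq_len(n0)
  sugar <- glucuronyl_molgraph()$mg
  sugar$atoms$map <- n0 + seq_len(n_atoms(sugar))
  product <- build_glucuronide(sub, site)
  product$atoms$map[(n0 + 1L):n_atoms(product)] <- sugar$atoms$map
  paste0(write_smiles(sub), ".", write_smiles(sugar), ">>",
         write_smiles(product))
}

#' Atom-map an unmapped substrate/glucuronide pair
#'
#' Given an unmapped substrate SMILES and the SMILES of one of its
#' glucuronide metabolites, locates the single glucuronosyl moiety in the
#' product, excises it, matches the remaining aglycone onto the substrate by
#' graph isomorphism (element and bond-order colored VF2), and emits a fully
#' atom-mapped, balanced reaction record whose formed bond joins the
#' attachment atom to the anomeric carbon.
#'
#' @param substrate_smiles SMILES of the parent molecule.
#' @param product_smiles SMILES of the glucuronide conjugate (exactly one
#'   glucuronosyl group).
#' @return a `reaction_record` (see [parse_reaction()]).
#' @export
map_glucuronidation <- function(substrate_smiles, product_smiles) {
  sub <- as_molgraph(substrate_smiles, canonicalize = TRUE)
  prod <- as_molgraph(product_smiles, canonicalize = TRUE)
  hits <- ob_smarts_match(ob_mol(prod$smiles), GLUCURONYL_SMARTS)
  if (length(hits) == 0L)
    stop_ugtsom("no_glucuronyl", "product contains no glucuronosyl moiety")
  if (length(hits) > 1L)
    stop_ugtsom("unsupported", "multiple glucuronide moieties are unsupported")
  sugar_atoms <- hits[[1]]
  anomeric <- sugar_atoms[1]
  adj <- mg_neighbors(prod)
  attach_at <- setdiff(adj$nbr[[anomeric]], sugar_atoms)
  if (length(attach_at) != 1L)
    stop_ugtsom("no_glucuronyl",
                "anomeric carbon has no aglycone attachment (free sugar?)")
  agly_atoms <- setdiff(seq_len(n_atoms(prod)), sugar_atoms)
  if (length(agly_atoms) != n_atoms(sub))
    stop_ugtsom("aglycone_mismatch",
                "aglycone size differs from the substrate")

  g_sub <- mg_igraph(sub)
  g_prod <- mg_igraph(prod)
  g_agly <- igraph::induced_subgraph(g_prod, agly_atoms)
  ecolor <- function(mg, g, keep = NULL) {
    el <- igraph::as_edgelist(g, names = FALSE)
    if (!is.null(keep)) {
      # translate subgraph vertex ids back to parent ids
      el <- cbind(keep[el[, 1]], keep[el[, 2]])
    }
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    bkey <- paste(pmin(mg$bonds$a1, mg$bonds$a2),
                  pmax(mg$bonds$a1, mg$bonds$a2))
    ord <- mg$bonds$order[match(key, bkey)]
    arom <- mg$bonds$aromatic[match(key, bkey)]
    as.integer(ifelse(arom, 5L, ord))
  }
  iso <- igraph::graph.get.isomorphisms.vf2(
    g_agly, g_sub,
    vertex.color1 = as.integer(prod$atoms$Z[agly_atoms]),
    vertex.color2 = as.integer(sub$atoms$Z),
    edge.color1 = ecolor(prod, g_agly, keep = agly_atoms),
    edge.color2 = ecolor(sub, g_sub)
  )
  if (length(iso) == 0L)
    stop_ugtsom("aglycone_mismatch",
                "aglycone does not match the substrate after excision")
  map21 <- as.integer(iso[[1]])  # aglycone position -> substrate atom

  n0 <- n_atoms(sub)
  sub$atoms$map <- seq_len(n0)
  sugar <- glucuronyl_molgraph()$mg
  sugar$atoms$map <- n0 + seq_len(n_atoms(sugar))
  prod$atoms$map <- NA_integer_
  prod$atoms$map[agly_atoms] <- map21
  # align product sugar atoms with the free co-reactant: pattern position t
  # matches product atom sugar_atoms[t] and free-sugar atom free_pat[t]
  free_pat <- glucuronyl_molgraph()$pattern_atoms
  prod$atoms$map[sugar_atoms] <- n0 + free_pat
  smirks <- paste0(write_smiles(sub), ".", write_smiles(sugar), ">>",
                   write_smiles(prod))
  parse_reaction(smirks)
}

# --- batch readers / writers ----------------------------------------------

#' Read a molecule table
#'
#' Reads either a CSV with columns `id`, `smiles` and optional `label`, or a
#' SMILES file (one molecule per line, optional tab-separated id).
#' Unparseable rows are logged with a warning and skipped.
#'
#' @param path file path.
#' @return list of `molecule_record`s.
#' @export
read_molecules <- function(path) {
  stopifnot(file.exists(path))
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  rows <- if (is_csv) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
      stop_ugtsom("bad_input", "CSV must have columns id, smiles")
    if (is.null(df$label)) df$label <- NA_integer_
    df
  } else {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    data.frame(
      smiles = vapply(parts, `[`, character(1), 1L),
      id = vapply(parts, function(p) if (length(p) > 1L) p[2] else p[1],
                  character(1)),
      label = NA_integer_, stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (r in seq_len(nrow(rows))) {
    rec <- tryCatch(
      parse_molecule(rows$smiles[r], id = rows$id[r], label = rows$label[r]),
      ugtsom_error = function(e) {
        warning("skipping row ", r, " (", rows$smiles[r], "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

#' Write a normalized molecule table
#'
#' Writes `id`, canonical `smiles`, `label`, and the candidate-site
#' annotation as a JSON column of `(atom_index, class)` records.
#'
#' @param records list of `molecule_record`s.
#' @param path output CSV path.
#' @export
write_molecules <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    smiles = vapply(records, `[[`, character(1), "smiles"),
    label = vapply(records, `[[`, integer(1), "label"),
    sites = vapply(records, function(r) {
      s <- enumerate_candidate_sites(r)
      as.character(jsonlite::toJSON(s))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a reaction SMIRKS file (one mapped reaction per line)
#'
#' @param path file path; lines starting with `#` are ignored.
#' @param skip_invalid log-and-skip unparseable lines instead of failing.
#' @return list of `reaction_record`s.
#' @export
read_reactions <- function(path, skip_invalid = TRUE) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  out <- list()
  for (r in seq_along(ln)) {
    rec <- tryCatch(parse_reaction(ln[r]), ugtsom_error = function(e) {
      if (!skip_invalid) stop(e)
      warning("skipping reaction line ", r, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}
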
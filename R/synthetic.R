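# Synthetic benchmark generator: substrate/nonsubstrate sets with a planted
# structural rule, and balanced atom-mapped glucuronidation SMIRKS with known
# sites of metabolism. Molecules are built by rule-based scaffold decoration
# (aromatic/saturated cores x substituent menus), which guarantees chemical
# validity and exact ground truth with no external data.

# Substituent menu. `site` names the candidate-site class the fragment
# introduces ("core_OH" resolves to ArOH on aromatic cores, AlOH otherwise).
SYN_FRAGMENTS <- list(
  core_OH   = list(sm = "O",        site = "core_OH"),
  ch2oh     = list(sm = "CO",       site = "AlOH"),
  ethanol   = list(sm = "CCO",      site = "AlOH"),
  sec_oh    = list(sm = "C(C)O",    site = "AlOH"),
  cooh      = list(sm = "C(=O)O",   site = "COOH"),
  ch2cooh   = list(sm = "CC(=O)O",  site = "COOH"),
  amine     = list(sm = "N",        site = "Nitrogen"),
  ch2nh2    = list(sm = "CN",       site = "Nitrogen"),
  nhme      = list(sm = "NC",       site = "Nitrogen"),
  methyl    = list(sm = "C",        site = "none"),
  ethyl     = list(sm = "CC",       site = "none"),
  isopropyl = list(sm = "C(C)C",    site = "none"),
  fluoro    = list(sm = "F",        site = "none"),
  chloro    = list(sm = "Cl",       site = "none"),
  bromo     = list(sm = "Br",       site = "none"),
  methoxy   = list(sm = "OC",       site = "none"),
  cf3       = list(sm = "C(F)(F)F", site = "none"),
  nitrile   = list(sm = "C#N",      site = "none"),
  acetyl    = list(sm = "C(=O)C",   site = "none")
)

# Cores: 5 substitutable positions each. Pyridine's ring nitrogen is itself
# a (hydrogen-free) candidate site, providing hard negatives for ranking.
SYN_CORES <- list(
  benzene     = list(template = "c1c%sc%sc%sc%sc1%s", aromatic = TRUE,
                     ring_site = FALSE),
  pyridine    = list(template = "n1c%sc%sc%sc%sc1%s", aromatic = TRUE,
                     ring_site = TRUE),
  cyclohexane = list(template = "C1C%sC%sC%sC%sC1%s", aromatic = FALSE,
                     ring_site = FALSE)
)

SOM_CLASSES <- c("AlOH", "ArOH", "COOH", "Nitrogen")

# Planted site-preference rule used by the reaction generator: the SOM of a
# multi-site molecule is its highest-priority candidate class, lowest atom
# index within a class; only hydrogen-bearing sites can react.
SOM_PRIORITY <- c("ArOH", "COOH", "AlOH", "Nitrogen")

#' Synthetic-benchmark generator configuration
#'
#' @param n_molecules number of molecules (or reactions) to generate.
#' @param rule planted substrate rule; `"ArOH_or_COOH"` (a molecule is a
#'   substrate iff it carries an aromatic hydroxyl or a carboxylic acid) is
#'   the default and currently the only built-in rule.
#' @param site_ambiguity `"multi"` (every reaction substrate has >= 2
#'   candidate sites; the planted preference rule picks the SOM) or
#'   `"single"` (exactly one candidate site).
#' @param label_noise probability in `[0, 1)` of flipping a substrate label.
#' @param seed integer seed; fixes the entire output.
#' @param class_mix named target proportions of AlOH/ArOH/COOH/Nitrogen SOMs
#'   for the reaction generator (must sum to 1).
#' @export
generator_config <- function(n_molecules = 100L, rule = "ArOH_or_COOH",
                             site_ambiguity = c("multi", "single"),
                             label_noise = 0, seed = 1L,
                             class_mix = c(AlOH = 0.25, ArOH = 0.25,
                                           COOH = 0.25, Nitrogen = 0.25)) {
  site_ambiguity <- match.arg(site_ambiguity)
  rule <- match.arg(rule, "ArOH_or_COOH")
  stopifnot(n_molecules >= 1L, label_noise >= 0, label_noise < 1,
            abs(sum(class_mix) - 1) < 1e-8,
            setequal(names(class_mix), SOM_CLASSES))
  structure(list(n_molecules = as.integer(n_molecules), rule = rule,
                 site_ambiguity = site_ambiguity, label_noise = label_noise,
                 seed = as.integer(seed),
                 class_mix = class_mix[SOM_CLASSES]),
            class = "generator_config")
}

#' The planted substrate rule as a pattern matcher
#'
#' Returns a predicate that labels a molecule by the generator's structural
#' rule, evaluated on the parsed structure (not on generator bookkeeping).
#'
#' @param rule rule identifier (see [generator_config()]).
#' @return function(mol) -> 0/1.
#' @export
rule_matcher <- function(rule = "ArOH_or_COOH") {
  rule <- match.arg(rule, "ArOH_or_COOH")
  function(mol) {
    sites <- enumerate_candidate_sites(resolve_graph(mol))
    as.integer(any(sites$site_class %in% c("ArOH", "COOH")))
  }
}

fragment_site_class <- function(frag, core_aromatic) {
  s <- SYN_FRAGMENTS[[frag]]$site
  if (s == "core_OH") return(if (core_aromatic) "ArOH" else "AlOH")
  s
}

# Assemble one decorated scaffold. `frags` are menu names, length <= 5.
assemble_molecule <- function(core, frags) {
  co <- SYN_CORES[[core]]
  slots <- rep("", 5L)
  if (length(frags)) slots[seq_along(frags)] <- vapply(
    frags, function(f) SYN_FRAGMENTS[[f]]$sm, character(1))
  branch <- ifelse(nzchar(slots[1:4]), sprintf("(%s)", slots[1:4]), "")
  do.call(sprintf, c(list(co$template), as.list(c(branch, slots[5]))))
}

# classes the assembled molecule will expose as candidate sites
planned_site_classes <- function(core, frags) {
  co <- SYN_CORES[[core]]
  cls <- vapply(frags, fragment_site_class, character(1),
                core_aromatic = co$aromatic)
  cls <- cls[cls != "none"]
  if (co$ring_site) cls <- c(cls, "Nitrogen")
  cls
}

draw_molecule <- function(want_positive, rule) {
  core <- sample(names(SYN_CORES), 1L)
  co <- SYN_CORES[[core]]
  k <- sample(1:3, 1L)
  pos_frags <- names(SYN_FRAGMENTS)[vapply(names(SYN_FRAGMENTS), function(f)
    fragment_site_class(f, co$aromatic) %in% c("ArOH", "COOH"), logical(1))]
  neg_frags <- setdiff(names(SYN_FRAGMENTS), pos_frags)
  frags <- if (want_positive) {
    c(sample(pos_frags, 1L),
      if (k > 1L) sample(names(SYN_FRAGMENTS), k - 1L, replace = TRUE))
  } else {
    sample(neg_frags, k, replace = TRUE)
  }
  assemble_molecule(core, frags)
}

#' Generate a substrate/nonsubstrate set with a planted rule
#'
#' Molecules are unique (by canonical SMILES) decorated scaffolds; the label
#' is the planted structural rule evaluated by its own pattern matcher on
#' the parsed molecule, with labels flipped at rate `label_noise`.
#'
#' @param config a [generator_config()].
#' @return list of `molecule_record`s with 0/1 labels; attributes
#'   `clean_labels` (pre-noise) and `config`.
#' @export
gen_substrate_set <- function(config = generator_config()) {
  set.seed(config$seed)
  match_rule <- rule_matcher(config$rule)
  seen <- character(0)
  out <- list(); clean <- integer(0)
  want_pos <- TRUE
  tries <- 0L
  while (length(out) < config$n_molecules) {
    tries <- tries + 1L
    if (tries > 200L * config$n_molecules)
      stop_ugtsom("generator_exhausted",
                  "cannot generate ", config$n_molecules, " unique molecules")
    smi <- draw_molecule(want_pos, config$rule)
    rec <- tryCatch(parse_molecule(smi), ugtsom_error = function(e) NULL)
    if (is.null(rec) || rec$smiles %in% seen) next
    lab <- match_rule(rec)
    if (lab != as.integer(want_pos)) next      # decoration produced the wrong class
    seen <- c(seen, rec$smiles)
    clean <- c(clean, lab)
    flip <- config$label_noise > 0 && stats::runif(1) < config$label_noise
    rec$label <- if (flip) 1L - lab else lab
    rec$id <- sprintf("syn%04d", length(out) + 1L)
    out[[length(out) + 1L]] <- rec
    want_pos <- !want_pos                      # alternate for class balance
  }
  attr(out, "clean_labels") <- clean
  attr(out, "config") <- config
  out
}

# The planted preference rule: highest-priority hydrogen-bearing candidate
# class, lowest atom index inside the class.
planted_som <- function(mg) {
  sites <- enumerate_candidate_sites(mg)
  if (nrow(sites) == 0L) return(NULL)
  sites$has_h <- mg$atoms$n_h[sites$atom_index] >= 1L
  for (cl in SOM_PRIORITY) {
    hit <- sites[sites$site_class == cl & sites$has_h, , drop = FALSE]
    if (nrow(hit)) return(hit[which.min(hit$atom_index), ])
  }
  NULL
}

# Draw a substrate whose top-priority class equals `target` and whose
# candidate-site count matches the ambiguity mode.
draw_reaction_substrate <- function(target, mode) {
  prio_rank <- match(target, SOM_PRIORITY)
  core <- if (target == "ArOH") {
    sample(c("benzene", "pyridine"), 1L)
  } else sample(names(SYN_CORES), 1L)
  co <- SYN_CORES[[core]]
  # pyridine ring N outranks nothing (lowest priority) but adds a candidate;
  # forbid it when the target itself is the only permitted class in single mode
  ok_frag <- function(f) {
    cl <- fragment_site_class(f, co$aromatic)
    if (cl == "none") return(TRUE)
    r <- match(cl, SOM_PRIORITY)
    r >= prio_rank            # never introduce a higher-priority class
  }
  menu <- names(SYN_FRAGMENTS)[vapply(names(SYN_FRAGMENTS), ok_frag,
                                      logical(1))]
  target_frags <- names(SYN_FRAGMENTS)[vapply(names(SYN_FRAGMENTS),
    function(f) fragment_site_class(f, co$aromatic) == target, logical(1))]
  if (length(target_frags) == 0L) return(NULL)
  if (mode == "single") {
    if (co$ring_site) return(NULL)
    decoys <- menu[vapply(menu, function(f)
      fragment_site_class(f, co$aromatic) == "none", logical(1))]
    k <- sample(0:2, 1L)
    frags <- c(sample(target_frags, 1L),
               if (k) sample(decoys, k, replace = TRUE))
  } else {
    extra <- sample(menu, sample(1:2, 1L), replace = TRUE)
    frags <- c(sample(target_frags, 1L), extra)
  }
  assemble_molecule(core, frags)
}

#' Generate atom-mapped glucuronidation reactions with known SOMs
#'
#' For each reaction a substrate is decorated so that the planted preference
#' rule (ArOH > COOH > AlOH > Nitrogen, lowest atom index, hydrogen-bearing
#' sites only) selects a site of the requested class; the glucuronosyl group
#' is attached there and a balanced, fully atom-mapped SMIRKS is emitted and
#' re-parsed, so every record is validated by the reaction parser itself.
#'
#' @param config a [generator_config()]; `class_mix` sets the target SOM
#'   class proportions, `site_ambiguity` the candidate-count regime.
#' @return list of `reaction_record`s; attributes `smirks` (character
#'   vector), `truth` (data.frame id, smiles, som_atom_index, som_class) and
#'   `config`.
#' @export
gen_reaction_set <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_molecules
  targets <- sample(SOM_CLASSES, n, replace = TRUE, prob = config$class_mix)
  out <- vector("list", n)
  smirks <- character(n)
  truth <- vector("list", n)
  seen <- character(0)
  for (i in seq_len(n)) {
    for (tries in seq_len(500L)) {
      smi <- draw_reaction_substrate(targets[i], config$site_ambiguity)
      if (is.null(smi)) next
      rec <- tryCatch(parse_molecule(smi), ugtsom_error = function(e) NULL)
      if (is.null(rec) || rec$smiles %in% seen) next
      sites <- enumerate_candidate_sites(rec)
      if (config$site_ambiguity == "single" && nrow(sites) != 1L) next
      if (config$site_ambiguity == "multi" && nrow(sites) < 2L) next
      som <- planted_som(rec$graph)
      if (is.null(som) || som$site_class != targets[i]) next
      smk <- tryCatch(make_reaction_smirks(rec, som$atom_index),
                      ugtsom_error = function(e) NULL)
      if (is.null(smk)) next
      rr <- tryCatch(parse_reaction(smk), ugtsom_error = function(e) NULL)
      if (is.null(rr) || rr$som_atom_index != som$atom_index) next
      seen <- c(seen, rec$smiles)
      out[[i]] <- rr
      smirks[i] <- smk
      truth[[i]] <- data.frame(id = sprintf("rxn%04d", i),
                               smiles = rec$smiles,
                               som_atom_index = som$atom_index,
                               som_class = som$site_class,
                               stringsAsFactors = FALSE)
      break
    }
    if (is.null(out[[i]]))
      stop_ugtsom("generator_exhausted",
                  "cannot place a ", targets[i], " site (reaction ", i, ")")
  }
  attr(out, "smirks") <- smirks
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "config") <- config
  out
}

#' Write a generated benchmark to disk
#'
#' Emits the CSV/SMIRKS dialects the readers consume plus a JSON manifest
#' recording the configuration and seed.
#'
#' @param dir output directory (created if needed).
#' @param molecules optional result of [gen_substrate_set()].
#' @param reactions optional result of [gen_reaction_set()].
#' @export
write_benchmark <- function(dir, molecules = NULL, reactions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  if (!is.null(molecules)) {
    write_molecules(molecules, file.path(dir, "molecules.csv"))
    manifest$molecules <- unclass(attr(molecules, "config"))
  }
  if (!is.null(reactions)) {
    writeLines(attr(reactions, "smirks"), file.path(dir, "reactions.smirks"))
    utils::write.csv(attr(reactions, "truth"),
                     file.path(dir, "reaction_truth.csv"), row.names = FALSE)
    manifest$reactions <- unclass(attr(reactions, "config"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
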
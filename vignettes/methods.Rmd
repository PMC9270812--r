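---
title: "Predicting UGT-mediated metabolism: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting UGT-mediated metabolism: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

UDP-glucuronosyltransferases (UGTs) are the dominant phase-II
drug-metabolizing enzymes. They transfer a glucuronosyl group from an
activated donor onto a nucleophilic atom of the substrate — an aliphatic or
aromatic hydroxyl, a carboxylic acid, or a nitrogen — in an SN2-type
substitution at the sugar's anomeric carbon (C1). Two questions matter in
practice: *is this molecule a UGT substrate at all?* and, if so, *which atom
is glucuronidated?* (the site of metabolism, SOM). `ugtsom` answers both
with a gated two-stage workflow: a consensus classifier first, then a
site-ranking graph network restricted to predicted substrates, because
ranking sites of a nonsubstrate is not meaningful.

Only O- and N-glucuronidation are modeled. S- and C-glucuronidation are so
rare that no usable training signal exists for them, and the uridine
diphosphate leaving group is never represented: every reaction releases
exactly one equivalent, so it carries no discriminating information. As a
consequence the glucuronosyl co-reactant is written with a hydrogen
placeholder on the anomeric carbon and reactions balance on heavy atoms,
which is also how curated reaction tables in this area are commonly drawn.

## Reaction representation and atom mapping

Reactions enter as atom-mapped SMIRKS (`reactants >> products`, reactants
separated by `.`). The parser enforces: exactly one `>>`; every reactant
heavy atom mapped with a unique positive integer; product map multiset
equal to the reactant multiset (a balanced equation); and a glucuronosyl
moiety among the reactants, recognized by a stereochemistry-agnostic SMARTS
for the pyranose-uronic-acid core (curated data mixes alpha and beta
depictions, so anomeric stereochemistry is deliberately ignored). The
formed bond is the set difference of product and reactant bond sets
expressed as map-number pairs; for a single glucuronidation exactly one
pair survives and it must join the anomeric carbon to an O or N of another
reactant — that atom is the SOM. The `[CH*:n]` asterisk annotation used by
some curation pipelines to flag the reactive carbon is tolerated and
stripped before parsing.

For unmapped substrate/metabolite pairs, `map_glucuronidation()` excises
the single glucuronosyl group from the product, matches the remaining
aglycone onto the substrate by VF2 graph isomorphism (vertices colored by
element, edges by bond order), and emits a fully mapped SMIRKS that is then
re-parsed by the same validator. Ambiguity from molecular symmetry is
harmless: any automorphism maps the attachment atom to a chemically
equivalent one.

SOM classes follow the four-group convention — AlOH, ArOH, COOH, Nitrogen —
with oxygen precedence COOH > ArOH > AlOH, and the COOH label placed on the
hydroxyl oxygen (the atom that actually forms the glycosidic bond). The
candidate-site enumeration that defines top-k denominators takes every
neutral hydroxyl oxygen and every neutral, non-quaternary nitrogen that
either bears a hydrogen or is sp2/aromatic with a free lone pair; nitrile
and nitro nitrogens are excluded. The nitrogen rule is our own decision
(the literature does not pin one down); it matches known N-glucuronidation
chemotypes (amines, anilines, azine ring nitrogens) while keeping
chemically impossible acceptors out of the denominator.

## Molecular representations

Five fingerprint families feed the traditional classifiers: MACCS keys
(166 bits, computed by Open Babel), and four hashed families implemented in
the package — Morgan/circular with radius 2, atom pairs, topological
torsions, and linear paths up to seven bonds — each foldable to 512, 1024
or 2048 bits. The physicochemical descriptor channel concatenates the Open
Babel property block (logP, TPSA, molar refractivity, H-bond counts,
molecular weight, ...) with twenty topological descriptors computed from
the heavy-atom graph (element counts, ring and aromaticity statistics,
rotatable bonds, Wiener index, distance statistics). This deliberately
replaces the large Java-based descriptor suites used historically: the
channel's role in the ensemble is to carry bulk physicochemical signal,
not any specific descriptor, and the manifest of names is stored with
every trained model so vectors are reproducible. Descriptor
standardization (and median imputation of failures) is always fit on
training folds only.

Graph models consume one-hot node/edge encodings frozen as vocabulary
version v1: element (9 named slots + other), degree (0–4, 5+), explicit
valence (0–5, 6+), implicit hydrogen count (0–3, 4+), aromaticity flag; the
classifier scheme adds formal charge and ring membership. Bonds carry type
(single/double/triple/aromatic), conjugation and ring flags. Out-of-range
values land in an explicit "other" slot so every one-hot block sums to
exactly one. Hydrogens are implicit throughout — heavy-atom graphs match
the mapped SMIRKS, which map heavy atoms only. Conjugation is defined as:
aromatic bonds, plus bonds whose two atoms both participate in a pi system
through some other channel (another multiple bond, an aromatic ring, or an
N/O/S lone pair, as in amides and esters).

## Substrate classification

Five traditional learners (random forest, extremely randomized trees,
RBF-SVM with Platt calibration, ridge-penalized logistic regression, a
single-hidden-layer neural network) are paired with fingerprints or
descriptors, and two graph classifiers are available: a GCN (two rounds of
mean-aggregated message passing; readout concatenates a gated weighted sum
with column-wise max-pooling, then a feed-forward head) and an
AttentiveFP-style network (neighbor attention at the atom level, then
attentive readout rounds at the molecule level). GAT, Weave and MPNN are
registered names that raise "not implemented" rather than silently
aliasing another architecture. All gradient training minimizes binary
cross-entropy with logits under Adam and stops early at the first
satisfied criterion: 500-epoch cap, 10 stale epochs on the training
metric, or 15 on the validation metric.

Models are ranked by stratified ten-fold cross-validated MCC (ties by AUC,
then name). Folds are stratified — the data are near-balanced so this is
benign and it stabilizes sensitivity/specificity. Consensus committees are
all subsets of the top models, voted by the arithmetic mean of member
class-1 probabilities with an inclusive 0.5 threshold (a mean of exactly
0.5 is a substrate call). With the default committee floor of two members,
m top models yield 2^m − m − 1 committees; counting the degenerate
single-member committees too (a one-model soft vote is identical to that
model) gives 2^m − 1, the convention behind the familiar ten-model total
of 1023. Both counts are available via the `min_size` argument of
`enumerate_consensus()`.

Hyperparameters use documented defaults with small seeded grids available;
we use deterministic seeded search rather than Bayesian optimization so
that every fit is exactly reproducible single-threaded.

## The WLN site-of-metabolism model

The ranker treats glucuronidation as a graph edit: one new bond between
the substrate nucleophile and the anomeric carbon. The reaction graph
contains the substrate plus the glucuronosyl co-reactant (auto-appended at
prediction time when only a substrate is supplied). Three stages:

1. **Weisfeiler–Lehman refinement.** Atom features are embedded
   (`ReLU(W x)`), then for each of `n_wl_iterations` rounds every atom
   merges its own state with a sum of learned messages from its neighbors
   and incident bonds. One iteration is the default — deeper refinement
   measurably hurts on glucuronidation data, consistent with the local
   character of the reaction center.
2. **Global attention.** Scaled dot-product attention over *all* reactant
   atoms (both molecules) produces a context vector per atom — a convex
   combination of value projections. This is what lets the substrate "see"
   the co-reactant and distant intramolecular features.
3. **Pair scoring.** For each candidate site, the concatenation of (local,
   context) features of the site atom and of the anomeric carbon passes
   through a feed-forward head to a reactivity logit. Only
   (candidate site, anomeric carbon) pairs are scored — every reaction here
   forms exactly one bond to C1, so scoring all atom pairs would spend
   capacity on pairs that can never react.

Training uses one positive pair per reaction (the observed SOM) and the
substrate's other candidate sites as negatives; there are no
cross-substrate negatives because the evaluation is a per-molecule
ranking. If every training reaction has a single candidate site, the
trainer warns and samples carbon atoms as negatives rather than training
on positives alone. Sites are returned in descending score order with ties
broken by ascending atom index (canonical order for molecules parsed by
`parse_molecule()`), making rankings total and deterministic.

Defaults: 1 WL iteration, learning rate 0.001, batch size 20, epoch cap
500 with patience 10 (train) / 15 (validation) — the settings that a grid
over iterations, batch sizes and learning rates favors on this problem
class. The hidden width defaults to 128: the one-hot feature space is
small (28 input features), and widening to several hundred units triples
the dense-algebra cost per epoch without measurable ranking gain on the
synthetic benchmark; the width is exposed in `wln_config()` for anyone who
wants to scale it.

Evaluation is top-k accuracy: the fraction of substrates with any true SOM
within the k best-ranked candidates, with enumeration misses counted as
errors (a true site absent from the candidate set can never be ranked, and
hiding such misses would flatter the model). `per_class_topk()` breaks
this down by AlOH/ArOH/COOH/Nitrogen, reporting empty classes as absent
rather than zero.

## The synthetic benchmark

Because the curated literature datasets cannot be redistributed, every
test runs on a generator that plants known structure. Molecules are built
by rule-based scaffold decoration — benzene, pyridine and cyclohexane cores
with up to three substituents from a menu of hydroxyl, carboxyl, amine and
decoy groups — which guarantees validity, uniqueness (by canonical SMILES)
and exact ground truth without any external data. The substrate label is
the planted rule "contains an aromatic hydroxyl or a carboxylic acid",
always evaluated by its own pattern matcher on the parsed molecule (never
by generator bookkeeping), with optional label noise. Reactions pick their
SOM by a planted preference rule (ArOH > COOH > AlOH > Nitrogen, lowest
atom index, hydrogen-bearing sites only), attach the glucuronosyl group
there, and emit balanced mapped SMIRKS that are re-parsed and re-validated
before being returned. Pyridine's ring nitrogen is itself a candidate site
that can never react (no hydrogen), providing hard negatives for the
ranking task. The glucuronosyl template omits ring stereochemistry: the
recognition pattern is stereo-agnostic, and the anomeric hydrogen
placeholder has no stereocenter until conjugation.

What the generator does *not* emulate: the chemical diversity of real
drug-like space (scaffold decoration spans a few hundred thousand
structures, not medicinal chemistry), realistic class imbalance,
experimental label noise structure, or ambiguous multi-site regiochemistry
driven by electronics rather than class priority. Passing the recovery
tests therefore demonstrates that the machinery — parsing, featurization,
training, ranking, voting — is correct and that the models can extract a
planted structure from a few hundred examples; it does not certify
accuracy on real UGT data, whose published headline numbers additionally
depend on specific curated sets and tuned hyperparameters.

## Numerical choices and problem sizes

All graph-network training runs on a small tape-based reverse-mode
autodiff engine written for this package (dense matrices; gather/scatter
and per-segment softmax/max for batching variable-size graphs), verified
against finite differences to ~1e-7 relative error. Adam uses the standard
(0.9, 0.999, 1e-8) moments; parameters are Glorot-initialized from the
model seed; training is single-threaded, so a seed fixes every result
bit-for-bit. BCE-with-logits is computed in the stable `max(z,0) − zy +
log1p(exp(−|z|))` form. MCC is defined as 0 when any denominator factor
vanishes; AUC is the Mann–Whitney rank statistic with half-credit for
ties, which is equivalent to trapezoidal ROC integration.

The shipped tests exercise: metric oracles on 1,000 random confusion
tables and 200 random score sets; a 500-reaction SMIRKS round trip;
permutation invariance on 50 molecules; WLN recovery with 220 training /
40 validation / 60 probe reactions; and substrate recovery on 1,000
molecules with a ten-model roster under ten-fold cross-validation — sizes
chosen to make the full suite a routine run on a single CPU while keeping
every check statistically meaningful.

## Known limitations

- Chemistry perception (aromaticity, implicit hydrogens, canonical SMILES)
  is Open Babel's; molecules that other toolkits perceive differently may
  featurize differently.
- The candidate-site definition is a package decision; real UGT data can
  contain SOMs outside it (those appear as extra positive-labeled sites in
  training and count as enumeration misses at evaluation).
- Single-member "committees" exist only to reconcile the two counting
  conventions for consensus enumeration; they add nothing statistically.
- The pair-head architecture and hidden width are package defaults, not
  literature-derived values; absolute metrics on real data will depend on
  tuning that the package deliberately keeps seeded and deterministic.
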
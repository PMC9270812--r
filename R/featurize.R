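# Molecular representations for the classifiers and graph networks:
# five fingerprint families, a 2D physicochemical descriptor vector, and
# one-hot node/edge featurized molecular graphs.

FP_KINDS <- c("atompairs", "maccs", "morgan", "topotorsion", "rdkit_path")
FP_NBITS <- c(512L, 1024L, 2048L)

# Deterministic integer hashing on doubles (exact below 2^53); all folded
# fingerprint families share it.
.HASH_P <- 2147483647
hash_seq <- function(xs) {
  h <- 5381
  for (x in xs) h <- (h * 33 + x) %% .HASH_P
  h
}

resolve_graph <- function(mol) {
  if (inherits(mol, "molecule_record")) return(mol$graph)
  if (inherits(mol, "molgraph")) return(mol)
  if (is.character(mol)) return(as_molgraph(mol, canonicalize = TRUE))
  stop_ugtsom("bad_input", "expected molgraph, molecule_record or SMILES")
}

# pi flag: atom carries pi electrons (aromatic or incident multiple bond)
atom_pi_flags <- function(mg) {
  pi <- mg$atoms$aromatic
  for (k in seq_len(nrow(mg$bonds))) {
    if (mg$bonds$order[k] >= 2L || mg$bonds$aromatic[k]) {
      pi[mg$bonds$a1[k]] <- TRUE
      pi[mg$bonds$a2[k]] <- TRUE
    }
  }
  pi
}

morgan_invariants <- function(mg) {
  vapply(seq_len(n_atoms(mg)), function(i) {
    a <- mg$atoms[i, ]
    hash_seq(c(a$Z, a$degree, a$n_h, a$charge + 10L,
               as.integer(a$aromatic), as.integer(a$in_ring)))
  }, numeric(1))
}

fp_morgan_raw <- function(mg, radius = 2L) {
  ids <- morgan_invariants(mg)
  feats <- ids
  adj <- mg_neighbors(mg)
  for (r in seq_len(radius)) {
    new_ids <- numeric(n_atoms(mg))
    for (i in seq_len(n_atoms(mg))) {
      nb <- adj$nbr[[i]]; bk <- adj$bond[[i]]
      if (length(nb)) {
        ord <- ifelse(mg$bonds$aromatic[bk], 5, mg$bonds$order[bk])
        pairs <- vapply(seq_along(nb),
                        function(t) hash_seq(c(ord[t], ids[nb[t]])),
                        numeric(1))
        new_ids[i] <- hash_seq(c(r, ids[i], sort(pairs)))
      } else new_ids[i] <- hash_seq(c(r, ids[i]))
    }
    ids <- new_ids
    feats <- c(feats, ids)
  }
  unique(feats)
}

fp_atompairs_raw <- function(mg) {
  n <- n_atoms(mg)
  if (n < 2L) return(numeric(0))
  pi <- atom_pi_flags(mg)
  inv <- vapply(seq_len(n), function(i)
    hash_seq(c(mg$atoms$Z[i], mg$atoms$degree[i], as.integer(pi[i]))),
    numeric(1))
  D <- mg_distances(mg)
  feats <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- D[i, j]
    if (!is.finite(d) || d > 30) next
    lo <- min(inv[i], inv[j]); hi <- max(inv[i], inv[j])
    feats <- c(feats, hash_seq(c(lo, d, hi)))
  }
  unique(feats)
}

fp_topotorsion_raw <- function(mg) {
  pi <- atom_pi_flags(mg)
  inv <- vapply(seq_len(n_atoms(mg)), function(i)
    hash_seq(c(mg$atoms$Z[i], as.integer(pi[i]),
               max(mg$atoms$degree[i] - 1L, 0L))),
    numeric(1))
  adj <- mg_neighbors(mg)
  feats <- numeric(0)
  for (j in seq_len(n_atoms(mg))) for (k in adj$nbr[[j]]) {
    if (j >= k) next                       # central bond j-k once
    for (i in setdiff(adj$nbr[[j]], k)) for (l in setdiff(adj$nbr[[k]], j)) {
      if (i == l) next
      fwd <- c(inv[i], inv[j], inv[k], inv[l])
      rev <- rev(fwd)
      use <- if (paste(fwd, collapse = ",") <= paste(rev, collapse = ","))
        fwd else rev
      feats <- c(feats, hash_seq(use))
    }
  }
  unique(feats)
}

# Linear-path (Daylight/RDKit-style) fingerprint: all simple bond paths of
# length 1..7, encoded as alternating atom/bond codes, direction-canonical.
fp_path_raw <- function(mg, max_len = 7L) {
  adj <- mg_neighbors(mg)
  acode <- vapply(seq_len(n_atoms(mg)), function(i)
    hash_seq(c(mg$atoms$Z[i], as.integer(mg$atoms$aromatic[i]))), numeric(1))
  bcode <- ifelse(mg$bonds$aromatic, 5, mg$bonds$order)
  feats <- numeric(0)
  walk <- function(path_atoms, path_bonds) {
    nb <- length(path_bonds)
    if (nb >= 1L) {
      fwd <- numeric(0)
      for (t in seq_along(path_bonds))
        fwd <- c(fwd, acode[path_atoms[t]], bcode[path_bonds[t]])
      fwd <- c(fwd, acode[path_atoms[length(path_atoms)]])
      rv <- rev(fwd)
      use <- if (paste(fwd, collapse = ",") <= paste(rv, collapse = ","))
        fwd else rv
      feats <<- c(feats, hash_seq(use))
    }
    if (nb >= max_len) return()
    tip <- path_atoms[length(path_atoms)]
    nbs <- adj$nbr[[tip]]; bks <- adj$bond[[tip]]
    for (t in seq_along(nbs)) {
      if (nbs[t] %in% path_atoms) next
      walk(c(path_atoms, nbs[t]), c(path_bonds, bks[t]))
    }
  }
  for (i in seq_len(n_atoms(mg))) walk(i, integer(0))
  unique(feats)
}

#' Compute a molecular fingerprint
#'
#' Five families are available: hashed atom pairs, MACCS structural keys
#' (166 bits, computed by Open Babel), Morgan/circular (radius 2), topological
#' torsions, and linear-path fingerprints. The four hashed families fold into
#' 512, 1024 or 2048 bits.
#'
#' @param mol SMILES, `molgraph` or `molecule_record`.
#' @param kind one of `"atompairs"`, `"maccs"`, `"morgan"`, `"topotorsion"`,
#'   `"rdkit_path"`.
#' @param nbits 512, 1024 or 2048 for folded families; ignored for MACCS.
#' @return an `fp_vector`: list with `kind`, `nbits`, binary `bits`, and
#'   `n_features` (raw feature count before folding, `NA` for MACCS).
#' @export
fingerprint <- function(mol, kind = "morgan", nbits = 1024L) {
  kind <- match.arg(kind, FP_KINDS)
  if (kind == "maccs") {
    mg <- resolve_graph(mol)
    bits <- ob_maccs(mg$smiles)
    return(structure(list(kind = kind, nbits = 166L, bits = bits,
                          n_features = NA_integer_), class = "fp_vector"))
  }
  if (!nbits %in% FP_NBITS)
    stop_ugtsom("bad_fp", "nbits must be one of ",
                paste(FP_NBITS, collapse = "/"), " for kind ", kind)
  mg <- resolve_graph(mol)
  raw <- switch(kind,
    morgan = fp_morgan_raw(mg),
    atompairs = fp_atompairs_raw(mg),
    topotorsion = fp_topotorsion_raw(mg),
    rdkit_path = fp_path_raw(mg)
  )
  bits <- integer(nbits)
  if (length(raw)) bits[(raw %% nbits) + 1L] <- 1L
  structure(list(kind = kind, nbits = as.integer(nbits), bits = bits,
                 n_features = length(raw)), class = "fp_vector")
}

#' @export
print.fp_vector <- function(x, ...) {
  cat("fingerprint", x$kind, "(", x$nbits, "bits,", sum(x$bits), "set )\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#' @param a,b `fp_vector`s of the same kind and width.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fp_vector"), inherits(b, "fp_vector"),
            a$kind == b$kind, a$nbits == b$nbits)
  inter <- sum(a$bits & b$bits)
  uni <- sum(a$bits | b$bits)
  if (uni == 0L) return(0)
  inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param mols list of molecules (SMILES / molgraph / molecule_record).
#' @param kind,nbits fingerprint settings (Morgan/1024 by default, the
#'   settings used for the diversity QC of the training data).
#' @return symmetric matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(mols, kind = "morgan", nbits = 1024L) {
  if (length(mols) == 0L) stop_ugtsom("bad_input", "empty molecule set")
  fps <- lapply(mols, fingerprint, kind = kind, nbits = nbits)
  n <- length(fps)
  M <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    M[i, j] <- M[j, i] <- tanimoto(fps[[i]], fps[[j]])
  M
}

#' Mean of per-test-molecule maximum similarity to a training set
#' @param train,test lists of molecules.
#' @inheritParams tanimoto_matrix
#' @export
mean_max_similarity <- function(train, test, kind = "morgan", nbits = 1024L) {
  if (length(train) == 0L || length(test) == 0L)
    stop_ugtsom("bad_input", "empty molecule set")
  ftr <- lapply(train, fingerprint, kind = kind, nbits = nbits)
  fte <- lapply(test, fingerprint, kind = kind, nbits = nbits)
  mean(vapply(fte, function(f)
    max(vapply(ftr, tanimoto, numeric(1), b = f)), numeric(1)))
}

# --- descriptors -----------------------------------------------------------

#' 2D physicochemical descriptor vector
#'
#' Combines the Open Babel property block (logP, TPSA, molar refractivity,
#' H-bond donor/acceptor counts, molecular weight, ...) with topological
#' descriptors computed from the heavy-atom graph (element counts, ring and
#' aromaticity statistics, rotatable bonds, Wiener index, ...). Names are
#' stable across molecules.
#'
#' @param mol SMILES, `molgraph` or `molecule_record`.
#' @return named numeric vector.
#' @export
descriptors <- function(mol) {
  mg <- resolve_graph(mol)
  p <- ob_props(mg$smiles)
  n <- n_atoms(mg)
  nb <- nrow(mg$bonds)
  Z <- mg$atoms$Z
  ncomp <- length(unique(mg_components(mg)))
  D <- mg_distances(mg)
  fin <- D[is.finite(D) & upper.tri(D)]
  carbons <- which(Z == 6L)
  sp3 <- if (length(carbons)) {
    pi <- atom_pi_flags(mg)
    sum(!pi[carbons] & !mg$atoms$aromatic[carbons]) / length(carbons)
  } else 0
  rot <- 0L
  for (k in seq_len(nb)) {
    b <- mg$bonds[k, ]
    if (b$order == 1L && !b$in_ring &&
        mg$atoms$degree[b$a1] > 1L && mg$atoms$degree[b$a2] > 1L)
      rot <- rot + 1L
  }
  topo <- c(
    n_atoms = n, n_bonds = nb,
    n_rings = nb - n + ncomp,
    n_aromatic_atoms = sum(mg$atoms$aromatic),
    frac_aromatic = sum(mg$atoms$aromatic) / n,
    n_C = sum(Z == 6L), n_N = sum(Z == 7L), n_O = sum(Z == 8L),
    n_S = sum(Z == 16L), n_halogen = sum(Z %in% c(9L, 17L, 35L, 53L)),
    n_hetero = sum(Z != 6L),
    frac_csp3 = sp3,
    n_rotatable = rot,
    n_hbd_graph = sum(Z %in% c(7L, 8L) & mg$atoms$n_h > 0L),
    n_hba_graph = sum(Z %in% c(7L, 8L)),
    n_charged = sum(mg$atoms$charge != 0L),
    wiener = if (length(fin)) sum(fin) else 0,
    mean_dist = if (length(fin)) mean(fin) else 0,
    max_dist = if (length(fin)) max(fin) else 0,
    mean_degree = mean(mg$atoms$degree)
  )
  c(p, topo)
}

#' Fit a descriptor scaler on a training matrix
#'
#' Stores per-column medians (for imputing non-finite values) and the
#' post-imputation mean and standard deviation. Constant columns get unit
#' scale. Scaling parameters must be fit on training folds only and applied
#' unchanged to held-out data.
#'
#' @param X numeric matrix (rows = molecules).
#' @return a `descriptor_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  med <- apply(X, 2, function(col) stats::median(col[is.finite(col)]))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  structure(list(median = med, mean = mu, sd = sd_),
            class = "descriptor_scaler")
}

#' Apply a fitted descriptor scaler
#' @param scaler a [fit_scaler()] result.
#' @param X numeric matrix with the same columns.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- scaler$median[j]
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

# --- graph featurization ---------------------------------------------------

# Frozen one-hot vocabularies (version 1). Out-of-vocabulary values land in
# the explicit final "other" slot so every one-hot block sums to exactly 1.
FEATURE_VOCAB_V1 <- list(
  elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),  # + other
  degree_max = 4L,        # slots 0..4 + "5+"
  valence_max = 5L,       # slots 0..5 + "6+"
  imp_h_max = 3L,         # slots 0..3 + "4+"
  charges = c(-1L, 0L, 1L),                                     # + other
  bond_orders = c("single", "double", "triple", "aromatic")
)

one_hot <- function(value, n_slots) {
  v <- integer(n_slots)
  v[min(value, n_slots - 1L) + 1L] <- 1L
  v
}

atom_feature_row <- function(mg, i, scheme) {
  voc <- FEATURE_VOCAB_V1
  a <- mg$atoms[i, ]
  el <- integer(length(voc$elements) + 1L)
  pos <- match(a$symbol, voc$elements)
  el[if (is.na(pos)) length(el) else pos] <- 1L
  deg <- one_hot(a$degree, voc$degree_max + 2L)
  val <- one_hot(a$valence, voc$valence_max + 2L)
  imh <- one_hot(a$n_h, voc$imp_h_max + 2L)
  base <- c(el, deg, val, imh, as.integer(a$aromatic))
  if (scheme == "wln") return(base)
  chg <- integer(length(voc$charges) + 1L)
  cpos <- match(a$charge, voc$charges)
  chg[if (is.na(cpos)) length(chg) else cpos] <- 1L
  c(base, chg, as.integer(a$in_ring))
}

bond_feature_row <- function(mg, k) {
  b <- mg$bonds[k, ]
  bt <- integer(4L)
  bt[if (b$aromatic) 4L else min(b$order, 3L)] <- 1L
  c(bt, as.integer(b$conjugated), as.integer(b$in_ring))
}

atom_feature_names <- function(scheme) {
  voc <- FEATURE_VOCAB_V1
  nm <- c(paste0("el_", c(voc$elements, "other")),
          paste0("deg_", c(0:voc$degree_max, "more")),
          paste0("val_", c(0:voc$valence_max, "more")),
          paste0("nH_", c(0:voc$imp_h_max, "more")),
          "aromatic")
  if (scheme == "classifier")
    nm <- c(nm, paste0("chg_", c(voc$charges, "other")), "in_ring")
  nm
}

#' Node/edge one-hot featurization of a molecular graph
#'
#' Encodes atoms (element, degree, explicit valence, implicit hydrogen
#' count, aromaticity; the classifier scheme adds formal charge and ring
#' membership) and bonds (bond type, conjugation, ring membership) as
#' one-hot/flag blocks for the graph models.
#'
#' @param mol SMILES, `molgraph` or `molecule_record`.
#' @param scheme `"classifier"` (graph classifiers) or `"wln"` (SOM model).
#' @return list with `node_feats` (n_atoms x d matrix), `edge_feats`
#'   (n_bonds x 6), `edges` (n_bonds x 2), `scheme`, `vocab_version`.
#' @export
mol_to_graph <- function(mol, scheme = c("classifier", "wln")) {
  scheme <- match.arg(scheme)
  mg <- resolve_graph(mol)
  if (n_atoms(mg) == 0L) stop_ugtsom("bad_input", "zero-heavy-atom molecule")
  nf <- t(vapply(seq_len(n_atoms(mg)), atom_feature_row,
                 numeric(length(atom_feature_names(scheme))),
                 mg = mg, scheme = scheme))
  colnames(nf) <- atom_feature_names(scheme)
  nb <- nrow(mg$bonds)
  ef <- if (nb > 0L)
    t(vapply(seq_len(nb), bond_feature_row, numeric(6L), mg = mg))
  else matrix(0, 0L, 6L)
  colnames(ef) <- c("bt_single", "bt_double", "bt_triple", "bt_aromatic",
                    "conjugated", "in_ring")
  list(node_feats = nf, edge_feats = ef,
       edges = cbind(mg$bonds$a1, mg$bonds$a2),
       scheme = scheme, vocab_version = "v1")
}
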
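# Low-level bridge to Open Babel through the ChemmineOB SWIG bindings.
# Everything chemistry-perception related (parsing, canonicalization,
# aromaticity, implicit hydrogens, SMARTS matching) is delegated to Open
# Babel; this file is the only place that touches OBMol handles.

.ob_env <- new.env(parent = emptyenv())

# The exported surface of ChemmineOB wraps only a fraction of the Open Babel
# API; the full SWIG bindings live in its namespace. Resolved once per session.
ob_api <- function() {
  if (is.null(.ob_env$api)) .ob_env$api <- asNamespace("ChemmineOB")
  .ob_env$api
}

# Parse one SMILES into an OBMol handle. Open Babel prints its own complaints
# to the console; we convert failure into a classed R error.
ob_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, identity),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) == 0L)
    stop_ugtsom("invalid_smiles", "unparseable SMILES: ", smiles)
  mol <- mols[[1]]
  if (ob_api()$OBMol_NumAtoms(mol) == 0L)
    stop_ugtsom("invalid_smiles", "SMILES has no atoms: ", smiles)
  mol
}

ob_canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) ""
  )
  out <- sub("[ \t\r\n].*$", "", out)
  if (!nzchar(out))
    stop_ugtsom("invalid_smiles", "unparseable SMILES: ", smiles)
  out
}

# Per-atom and per-bond property tables for a parsed molecule, in the atom
# order Open Babel assigned (which for SMILES input is order of appearance).
ob_tables <- function(mol) {
  OB <- ob_api()
  n <- OB$OBMol_NumAtoms(mol)
  nb <- OB$OBMol_NumBonds(mol)
  Z <- integer(n); arom <- logical(n); ring <- logical(n)
  nH <- integer(n); chg <- integer(n); val <- integer(n); deg <- integer(n)
  for (i in seq_len(n)) {
    a <- OB$OBMol_GetAtom(mol, i)
    Z[i]    <- OB$OBAtom_GetAtomicNum(a)
    arom[i] <- OB$OBAtom_IsAromatic(a)
    ring[i] <- OB$OBAtom_IsInRing(a)
    nH[i]   <- OB$OBAtom_GetImplicitHCount(a)
    chg[i]  <- OB$OBAtom_GetFormalCharge(a)
    val[i]  <- OB$OBAtom_GetExplicitValence(a)
    deg[i]  <- OB$OBAtom_GetExplicitDegree(a)
  }
  if (nb > 0L) {
    a1 <- integer(nb); a2 <- integer(nb); ord <- integer(nb)
    barom <- logical(nb); bring <- logical(nb)
    for (k in seq_len(nb)) {
      b <- OB$OBMol_GetBond(mol, k - 1L)
      a1[k] <- OB$OBBond_GetBeginAtomIdx(b)
      a2[k] <- OB$OBBond_GetEndAtomIdx(b)
      ord[k] <- OB$OBBond_GetBondOrder(b)
      barom[k] <- OB$OBBond_IsAromatic(b)
      bring[k] <- OB$OBBond_IsInRing(b)
    }
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord,
                        aromatic = barom, in_ring = bring)
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0), in_ring = logical(0))
  }
  list(
    atoms = data.frame(Z = Z, aromatic = arom, in_ring = ring, n_h = nH,
                       charge = chg, valence = val, degree = deg),
    bonds = bonds
  )
}

# SMARTS matching returning 1-based atom-index vectors, one per unique match.
ob_smarts_match <- function(mol, pattern) {
  OB <- ob_api()
  sp <- OB$OBSmartsPattern()
  if (!OB$OBSmartsPattern_Init(sp, pattern))
    stop_ugtsom("bad_smarts", "failed to parse SMARTS: ", pattern)
  if (!OB$OBSmartsPattern_Match(sp, mol)) return(list())
  OB$OBSmartsPattern_GetUMapList(sp)
}

# Physicochemical property block computed by Open Babel (logP, TPSA, MR,
# H-bond donor/acceptor counts, molecular weight, ...).
ob_props <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  p <- ChemmineOB::prop_OB(mols)
  num <- vapply(p, is.numeric, logical(1))
  unlist(p[1, num, drop = TRUE])
}

# MACCS structural keys. Open Babel pads the 166-key set into a 256-long
# vector; keys are 1-based, so the fingerprint proper is the first 166 slots.
ob_maccs <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  as.integer(fp[seq_len(166L)])
}

# Classed condition helpers -------------------------------------------------

stop_ugtsom <- function(class, ...) {
  stop(structure(
    class = c(paste0("ugtsom_", class), "ugtsom_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
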
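# Internal molecular graph representation ("molgraph"): plain atom and bond
# tables derived from an Open Babel parse, plus the atom-map numbers read
# directly from the SMILES text. All atom indices are 1-based.

ELEMENT_SYMBOLS <- c(
  "1" = "H", "5" = "B", "6" = "C", "7" = "N", "8" = "O", "9" = "F",
  "15" = "P", "16" = "S", "17" = "Cl", "35" = "Br", "53" = "I"
)

element_symbol <- function(Z) {
  s <- ELEMENT_SYMBOLS[as.character(Z)]
  ifelse(is.na(s), paste0("#", Z), s)
}

# --- SMILES atom scanner ---------------------------------------------------
# Identifies atom tokens in order of appearance (the order Open Babel assigns
# atom indices for SMILES input) and extracts atom-map numbers. Also returns
# a cleaned string with the curly "reactive-site" asterisk dialect sometimes
# seen in curated SMIRKS (e.g. "[CH*:18]") stripped, which standard SMILES
# parsers reject.
smiles_atom_scan <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  out_tok <- character(0)
  maps <- integer(0)
  arom <- logical(0)
  starred <- logical(0)
  cleaned <- character(0)
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic_organic <- c("b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop_ugtsom("invalid_smiles", "unclosed bracket atom in: ", smiles)
      tok <- paste(chars[i:j], collapse = "")
      has_star <- grepl("*", tok, fixed = TRUE)
      inner <- substr(tok, 2L, nchar(tok) - 1L)
      sym <- regmatches(inner, regexpr("^[0-9]*([A-Za-z][a-z]?)", inner))
      sym_only <- sub("^[0-9]*", "", sym)
      if (has_star && nzchar(sym_only)) tok <- gsub("*", "", tok, fixed = TRUE)
      m <- regmatches(tok, regexpr(":[0-9]+\\]$", tok))
      map_no <- if (length(m)) as.integer(sub("\\]", "", sub(":", "", m))) else 0L
      out_tok <- c(out_tok, tok)
      maps <- c(maps, map_no)
      arom <- c(arom, nzchar(sym_only) &&
                  substr(sym_only, 1L, 1L) %in% letters)
      starred <- c(starred, has_star)
      cleaned <- c(cleaned, tok)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      out_tok <- c(out_tok, paste0(ch, chars[i + 1L]))
      maps <- c(maps, 0L); arom <- c(arom, FALSE); starred <- c(starred, FALSE)
      cleaned <- c(cleaned, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% organic || ch %in% aromatic_organic) {
      out_tok <- c(out_tok, ch)
      maps <- c(maps, 0L)
      arom <- c(arom, ch %in% aromatic_organic)
      starred <- c(starred, FALSE)
      cleaned <- c(cleaned, ch)
      i <- i + 1L
    } else {
      cleaned <- c(cleaned, ch)
      i <- i + 1L
    }
  }
  list(
    atoms = data.frame(token = out_tok, map = maps, aromatic = arom,
                       starred = starred, stringsAsFactors = FALSE),
    cleaned = paste(cleaned, collapse = "")
  )
}

# --- molgraph construction -------------------------------------------------

#' Build the internal molecular graph from a SMILES string
#'
#' Parses `smiles` with Open Babel and assembles per-atom and per-bond
#' property tables (element, aromaticity, ring membership, implicit hydrogen
#' count, formal charge, valence, degree; bond order, aromatic/ring/conjugated
#' flags). Atom-map numbers present in the SMILES are read from the text and
#' attached to the atoms; indices are 1-based and follow the order of
#' appearance in the input string (or canonical order when
#' `canonicalize = TRUE`).
#'
#' @param smiles a single SMILES string.
#' @param canonicalize if `TRUE`, the molecule is re-parsed from its Open
#'   Babel canonical SMILES so the atom order is canonical. Atom maps do not
#'   survive canonicalization, so mapped reaction components should use
#'   `canonicalize = FALSE`.
#' @return an object of class `molgraph`: a list with `atoms`, `bonds` and
#'   `smiles` entries.
#' @export
as_molgraph <- function(smiles, canonicalize = FALSE) {
  scan <- smiles_atom_scan(smiles)
  smi <- scan$cleaned
  if (canonicalize) {
    smi <- ob_canonical_smiles(smi)
    scan <- smiles_atom_scan(smi)
  }
  mol <- ob_mol(smi)
  tab <- ob_tables(mol)
  n <- nrow(tab$atoms)
  if (n != nrow(scan$atoms))
    stop_ugtsom("parse_mismatch",
                "atom scanner found ", nrow(scan$atoms),
                " atoms but Open Babel found ", n, " in: ", smi)
  if (any(tab$atoms$Z == 1L))
    stop_ugtsom("invalid_smiles", "explicit hydrogen atoms unsupported: ", smi)
  if (any(tab$atoms$aromatic & !tab$atoms$in_ring))
    stop_ugtsom("invalid_smiles", "aromatic atom outside a ring in: ", smi)
  atoms <- tab$atoms
  atoms$symbol <- element_symbol(atoms$Z)
  atoms$map <- scan$atoms$map
  bonds <- tab$bonds
  bonds$conjugated <- conjugated_flags(atoms, bonds)
  structure(
    list(smiles = smi, atoms = atoms, bonds = bonds),
    class = "molgraph"
  )
}

# A bond takes part in a conjugated system when it is aromatic, or when both
# of its atoms contribute to a pi system through some *other* channel: an
# aromatic ring, another multiple bond, or a heteroatom lone pair (N, O, S
# with spare valence, as in amides and esters).
conjugated_flags <- function(atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  n <- nrow(atoms)
  multi_cnt <- integer(n)
  for (k in seq_len(nb)) {
    if (bonds$order[k] >= 2L || bonds$aromatic[k]) {
      multi_cnt[bonds$a1[k]] <- multi_cnt[bonds$a1[k]] + 1L
      multi_cnt[bonds$a2[k]] <- multi_cnt[bonds$a2[k]] + 1L
    }
  }
  lone_pair <- atoms$Z %in% c(7L, 8L, 16L) & atoms$charge <= 0L
  flag <- logical(nb)
  for (k in seq_len(nb)) {
    if (bonds$aromatic[k]) { flag[k] <- TRUE; next }
    u <- bonds$a1[k]; v <- bonds$a2[k]
    own <- as.integer(bonds$order[k] >= 2L)
    pi_u <- atoms$aromatic[u] || (multi_cnt[u] - own) > 0L || lone_pair[u]
    pi_v <- atoms$aromatic[v] || (multi_cnt[v] - own) > 0L || lone_pair[v]
    flag[k] <- pi_u && pi_v && (own > 0L || multi_cnt[u] > 0L || multi_cnt[v] > 0L)
  }
  flag
}

#' @export
print.molgraph <- function(x, ...) {
  cat("molgraph:", x$smiles, "\n")
  cat(" ", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

n_atoms <- function(mg) nrow(mg$atoms)

# igraph view of the heavy-atom skeleton (used for distances, components
# and isomorphism matching).
mg_igraph <- function(mg) {
  g <- igraph::make_empty_graph(n = n_atoms(mg), directed = FALSE)
  if (nrow(mg$bonds) > 0L)
    g <- igraph::add_edges(g, rbind(mg$bonds$a1, mg$bonds$a2))
  g
}

mg_distances <- function(mg) {
  igraph::distances(mg_igraph(mg))
}

mg_components <- function(mg) {
  igraph::components(mg_igraph(mg))$membership
}

# Neighbor list: for each atom, the indices of bonded atoms and the bond rows.
mg_neighbors <- function(mg) {
  n <- n_atoms(mg)
  nbr <- vector("list", n)
  bnd <- vector("list", n)
  for (k in seq_len(nrow(mg$bonds))) {
    u <- mg$bonds$a1[k]; v <- mg$bonds$a2[k]
    nbr[[u]] <- c(nbr[[u]], v); bnd[[u]] <- c(bnd[[u]], k)
    nbr[[v]] <- c(nbr[[v]], u); bnd[[v]] <- c(bnd[[v]], k)
  }
  list(nbr = nbr, bond = bnd)
}

# Reindex atoms with a permutation: perm[i] is the new index of old atom i.
permute_molgraph <- function(mg, perm) {
  stopifnot(length(perm) == n_atoms(mg), all(sort(perm) == seq_len(n_atoms(mg))))
  inv <- order(perm)
  atoms <- mg$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mg$bonds
  bonds$a1 <- perm[bonds$a1]
  bonds$a2 <- perm[bonds$a2]
  out <- mg
  out$atoms <- atoms
  out$bonds <- bonds
  out$smiles <- write_smiles(out)
  out
}

# --- SMILES writer ---------------------------------------------------------
# Emits a fully bracketed SMILES (explicit H counts, charges and atom maps),
# which every mainstream parser accepts and which preserves mapping -- Open
# Babel's own writers drop atom maps.

write_smiles <- function(mg, with_maps = TRUE) {
  n <- n_atoms(mg)
  if (n == 0L) stop_ugtsom("invalid_molgraph", "empty molecule")
  adj <- mg_neighbors(mg)
  visited <- logical(n)
  bond_done <- logical(nrow(mg$bonds))
  ring_digit <- 0L
  closures <- vector("list", n)   # per atom: list of (digit, bond row)
  children <- vector("list", n)   # per atom: DFS tree children (j, bond row)

  bond_sym <- function(k) {
    b <- mg$bonds[k, ]
    if (b$aromatic) return("")
    if (b$order == 1L) {
      if (mg$atoms$aromatic[b$a1] && mg$atoms$aromatic[b$a2]) return("-")
      return("")
    }
    if (b$order == 2L) return("=")
    if (b$order == 3L) return("#")
    stop_ugtsom("invalid_molgraph", "unsupported bond order: ", b$order)
  }

  atom_token <- function(i) {
    a <- mg$atoms[i, ]
    sym <- a$symbol
    if (a$aromatic) sym <- tolower(sym)
    h <- if (a$n_h == 0L) "" else if (a$n_h == 1L) "H" else paste0("H", a$n_h)
    chg <- if (a$charge == 0L) ""
      else if (a$charge == 1L) "+"
      else if (a$charge == -1L) "-"
      else if (a$charge > 0L) paste0("+", a$charge)
      else paste0("-", abs(a$charge))
    mp <- if (with_maps && a$map > 0L) paste0(":", a$map) else ""
    paste0("[", sym, h, chg, mp, "]")
  }

  # Pass 1: DFS assigns spanning-tree children and ring-closure digits.
  walk <- function(i) {
    visited[i] <<- TRUE
    nb <- adj$nbr[[i]]; bk <- adj$bond[[i]]
    for (t in seq_along(nb)) {
      j <- nb[t]; k <- bk[t]
      if (bond_done[k]) next
      bond_done[k] <<- TRUE
      if (visited[j]) {
        ring_digit <<- ring_digit + 1L
        d <- ring_digit
        closures[[i]] <<- c(closures[[i]], list(list(d = d, k = k)))
        closures[[j]] <<- c(closures[[j]], list(list(d = d, k = k)))
      } else {
        children[[i]] <<- c(children[[i]], list(list(j = j, k = k)))
        walk(j)
      }
    }
  }

  # Pass 2: emit tokens along the tree; closure digits appear at both ends.
  emit <- function(i) {
    s <- atom_token(i)
    for (cl in closures[[i]]) {
      dd <- if (cl$d > 9L) paste0("%", cl$d) else as.character(cl$d)
      s <- paste0(s, bond_sym(cl$k), dd)
    }
    kids <- children[[i]]
    for (t in seq_along(kids)) {
      sub <- paste0(bond_sym(kids[[t]]$k), emit(kids[[t]]$j))
      s <- if (t < length(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }

  parts <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    walk(root)
    parts <- c(parts, emit(root))
  }
  paste(parts, collapse = ".")
}
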
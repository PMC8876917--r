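# Molecular graphs parsed from a SMILES subset: organic-subset atoms
# (B C N O P S F Cl Br I), aromatic lowercase (b c n o p s), bracket atoms
# with charge and explicit H, branches, ring closures (digits and %nn),
# bond symbols - = # :, dot-separated fragments. Stereo markers (/ \ @) are
# accepted and discarded; isotopes are rejected.

# Standard atomic weights (IUPAC conventional values). Bracket atoms may be
# any element listed here (salt counterions such as [Na+] must parse so that
# desalting can drop them); bare atoms are restricted to the organic subset.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971,
  Br = 79.904, Ag = 107.868, I = 126.904, Ba = 137.327, Pt = 195.084,
  Au = 196.967, Hg = 200.592, Li = 6.94
)

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s")

# Default valences used to assign implicit hydrogens to bare organic-subset
# atoms (smallest valence >= current bond-order sum; aromatic bonds count 1.5).
.VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Construct a molecule object
#'
#' Low-level constructor; most users should call [parse_smiles()]. A molecule
#' is a labelled graph: a data frame of heavy atoms (element, aromatic flag,
#' formal charge, implicit hydrogen count) and a data frame of bonds
#' (1-based atom indices and bond order, where aromatic bonds have order 1.5).
#'
#' @param atoms data.frame with columns `element`, `aromatic`, `charge`,
#'   `implicit_h`.
#' @param bonds data.frame with columns `a`, `b`, `order`.
#' @param source_smiles the SMILES string the molecule was parsed from.
#' @return An object of class `molecule`.
#' @export
new_molecule <- function(atoms, bonds, source_smiles = NA_character_) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  n <- nrow(atoms)
  if (n == 0L) stop("molecule must contain at least one atom", call. = FALSE)
  if (nrow(bonds) > 0L) {
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n))
      stop("bond endpoint out of range", call. = FALSE)
    if (any(bonds$a == bonds$b)) stop("self-bond not allowed", call. = FALSE)
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  }
  structure(
    list(atoms = atoms, bonds = bonds, source_smiles = source_smiles),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule> %d heavy atoms, %d bonds%s\n",
    nrow(x$atoms), nrow(x$bonds),
    if (is.na(x$source_smiles)) "" else paste0(" (", x$source_smiles, ")")
  ))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol a `molecule`.
#' @return integer heavy-atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

.parse_error <- function(smiles, pos, msg) {
  stop(sprintf("SMILES parse error at position %d in \"%s\": %s",
               pos, smiles, msg), call. = FALSE)
}

# Parse the interior of a bracket atom expression, e.g. "O-", "N+", "nH",
# "NH3+", "Na+]". Returns list(element, aromatic, charge, explicit_h).
.parse_bracket <- function(body, smiles, pos) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?|[bcnops])(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?$",
    body))[[1]]
  if (length(m) == 0L)
    .parse_error(smiles, pos, sprintf("cannot parse bracket atom [%s]", body))
  if (nzchar(m[2]))
    .parse_error(smiles, pos, sprintf("isotope specification '%s' not supported", m[2]))
  sym <- m[3]
  aromatic <- sym %in% .AROMATIC_ELEMENTS
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% names(.ATOMIC_WEIGHTS))
    .parse_error(smiles, pos, sprintf("unsupported element '%s'", sym))
  hcount <- 0L
  if (nzchar(m[5])) {
    hcount <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2L))
  }
  charge <- 0L
  cs <- m[6]
  if (nzchar(cs)) {
    if (grepl("^[+-][0-9]+$", cs)) {
      charge <- as.integer(cs)
    } else {
      charge <- nchar(cs) * if (substring(cs, 1L, 1L) == "+") 1L else -1L
    }
  }
  list(element = element, aromatic = aromatic, charge = charge,
       explicit_h = hcount)
}

#' Parse a SMILES string into a molecule
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms (b, c, n, o, p, s), bracket atoms with formal charge and
#' explicit hydrogen counts, branches, ring closures (`1`-`9` and `%nn`),
#' bond symbols `-`, `=`, `#`, `:` and dot-separated fragments. Stereo
#' markers (`/`, `\`, `@`) are accepted and discarded; isotopes and elements
#' outside the supported table are rejected with an error naming the token
#' and position.
#'
#' Multi-fragment inputs (salts) are desalted: only the largest connected
#' fragment by heavy-atom count is returned, with ties broken by higher
#' molecular weight, then by lexicographically smaller canonical key.
#' Implicit hydrogens on bare atoms follow the default-valence model
#' (B 3; C 4; N 3; O 2; P 3/5; S 2/4/6; halogens 1); bracket atoms carry
#' only their explicit hydrogen count.
#'
#' @param smiles a single non-empty SMILES string.
#' @return A [new_molecule()] object for the largest fragment.
#' @examples
#' parse_smiles("CCO")
#' parse_smiles("c1ccccc1")
#' parse_smiles("CC(=O)[O-].[Na+]")  # acetate retained, sodium dropped
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("`smiles` must be a single non-empty string", call. = FALSE)

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  nch <- length(chars)

  element <- character(); aromatic <- logical(); charge <- integer()
  explicit_h <- integer(); bracket <- logical()
  bond_a <- integer(); bond_b <- integer(); bond_o <- numeric()

  prev <- NA_integer_        # atom the next atom/ring digit bonds to
  stack <- integer()         # branch stack
  pending <- NA_real_        # explicit bond order awaiting use
  ring_open <- list()        # label -> list(atom, order)

  add_atom <- function(el, arom, chg, eh, brk) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    explicit_h[length(explicit_h) + 1L] <<- eh
    bracket[length(bracket) + 1L] <<- brk
    length(element)
  }
  add_bond <- function(a, b, order) {
    if (is.na(order)) order <- if (aromatic[a] && aromatic[b]) 1.5 else 1
    bond_a[length(bond_a) + 1L] <<- a
    bond_b[length(bond_b) + 1L] <<- b
    bond_o[length(bond_o) + 1L] <<- order
  }
  place_atom <- function(idx, pos) {
    if (!is.na(prev)) {
      add_bond(prev, idx, pending)
    } else if (!is.na(pending)) {
      .parse_error(smiles, pos, "bond symbol with no preceding atom")
    }
    pending <<- NA_real_
    prev <<- idx
  }
  close_ring <- function(label, pos) {
    if (is.na(prev)) .parse_error(smiles, pos, "ring closure before any atom")
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      order <- if (!is.na(pending)) pending else op$order
      if (is.na(order)) order <- if (aromatic[op$atom] && aromatic[prev]) 1.5 else 1
      if (op$atom == prev)
        .parse_error(smiles, pos, sprintf("ring closure %s forms a self-bond", label))
      add_bond(op$atom, prev, order)
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- list(atom = prev, order = pending)
    }
    pending <<- NA_real_
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                        "/" = 1, "\\" = 1)
      i <- i + 1L
    } else if (ch == ".") {
      if (!is.na(pending))
        .parse_error(smiles, i, "bond symbol before fragment separator")
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .parse_error(smiles, i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        .parse_error(smiles, i, "unmatched closing parenthesis")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        .parse_error(smiles, i, "'%' must be followed by two digits")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "[") {
      close_pos <- NA_integer_
      j <- i + 1L
      while (j <= nch) {
        if (chars[j] == "]") { close_pos <- j; break }
        j <- j + 1L
      }
      if (is.na(close_pos)) .parse_error(smiles, i, "unmatched '['")
      body <- paste(chars[(i + 1L):(close_pos - 1L)], collapse = "")
      at <- .parse_bracket(body, smiles, i)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$explicit_h, TRUE)
      place_atom(idx, i)
      i <- close_pos + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE, 0L, NA_integer_, FALSE)
        place_atom(idx, i)
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        idx <- add_atom(ch, FALSE, 0L, NA_integer_, FALSE)
        place_atom(idx, i)
        i <- i + 1L
      } else {
        .parse_error(smiles, i, sprintf("unsupported element '%s'", ch))
      }
    } else if (ch %in% .AROMATIC_ELEMENTS) {
      idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
      place_atom(idx, i)
      i <- i + 1L
    } else {
      .parse_error(smiles, i, sprintf("unexpected character '%s'", ch))
    }
  }

  if (length(stack) > 0L)
    .parse_error(smiles, nch, "unmatched opening parenthesis")
  if (length(ring_open) > 0L)
    .parse_error(smiles, nch,
                 sprintf("unmatched ring closure(s): %s",
                         paste(names(ring_open), collapse = ", ")))
  if (!is.na(pending))
    .parse_error(smiles, nch, "dangling bond symbol")
  if (length(element) == 0L)
    .parse_error(smiles, 1L, "no atoms")

  n <- length(element)
  # implicit hydrogens: aromatic bonds tracked separately so that aromatic
  # O/S (where each ring bond contributes 1 to the valence, matching the
  # Kekule treatment) differ from aromatic B/C/N/P (1.5 per ring bond)
  bond_sum <- numeric(n)
  arom_cnt <- integer(n)
  if (length(bond_a) > 0L) {
    for (k in seq_along(bond_a)) {
      for (e in c(bond_a[k], bond_b[k])) {
        if (bond_o[k] == 1.5) arom_cnt[e] <- arom_cnt[e] + 1L
        else bond_sum[e] <- bond_sum[e] + bond_o[k]
      }
    }
  }
  implicit_h <- integer(n)
  for (k in seq_len(n)) {
    implicit_h[k] <- if (bracket[k]) explicit_h[k] else
      .implicit_h_count(element[k], aromatic[k], bond_sum[k], arom_cnt[k])
  }

  atoms <- data.frame(element = element, aromatic = aromatic,
                      charge = charge, implicit_h = implicit_h,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a = bond_a, b = bond_b, order = bond_o)

  # connected components (largest-fragment selection)
  comp <- .components(n, bonds)
  if (max(comp) > 1L) {
    keep <- .pick_largest_fragment(atoms, bonds, comp, smiles)
    idx_map <- integer(n)
    sel <- which(comp == keep)
    idx_map[sel] <- seq_along(sel)
    atoms <- atoms[sel, , drop = FALSE]
    rownames(atoms) <- NULL
    bsel <- bonds$a %in% sel
    bonds <- bonds[bsel, , drop = FALSE]
    bonds$a <- idx_map[bonds$a]
    bonds$b <- idx_map[bonds$b]
    rownames(bonds) <- NULL
  }

  new_molecule(atoms, bonds, smiles)
}

# default-valence implicit hydrogen count for an organic-subset atom
.implicit_h_count <- function(element, aromatic, bond_sum, arom_count) {
  per_arom <- if (aromatic && element %in% c("O", "S")) 1 else 1.5
  need <- ceiling(bond_sum + per_arom * arom_count)
  vals <- .VALENCES[[element]]
  ok <- vals[vals >= need]
  if (length(ok) == 0L) 0L else as.integer(ok[1L] - need)
}

# connected components by BFS; returns component id per atom
.components <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
      adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

.fragment_molecule <- function(atoms, bonds, comp, cid, smiles) {
  sel <- which(comp == cid)
  idx_map <- integer(length(comp))
  idx_map[sel] <- seq_along(sel)
  a2 <- atoms[sel, , drop = FALSE]
  rownames(a2) <- NULL
  b2 <- bonds[bonds$a %in% sel, , drop = FALSE]
  if (nrow(b2) > 0L) { b2$a <- idx_map[b2$a]; b2$b <- idx_map[b2$b] }
  rownames(b2) <- NULL
  new_molecule(a2, b2, smiles)
}

.pick_largest_fragment <- function(atoms, bonds, comp, smiles) {
  sizes <- tabulate(comp)
  cand <- which(sizes == max(sizes))
  if (length(cand) == 1L) return(cand)
  mws <- vapply(cand, function(cid)
    molecular_weight(.fragment_molecule(atoms, bonds, comp, cid, smiles)),
    numeric(1))
  cand <- cand[mws == max(mws)]
  if (length(cand) == 1L) return(cand)
  keys <- vapply(cand, function(cid)
    canonical_key(.fragment_molecule(atoms, bonds, comp, cid, smiles)),
    character(1))
  cand[order(keys)][1L]
}

#' Molecular weight
#'
#' Sum of standard atomic weights over heavy atoms plus implicit hydrogens,
#' reported to three decimals.
#'
#' @param mol a `molecule`.
#' @return mass in Dalton.
#' @examples
#' molecular_weight(parse_smiles("CCO"))  # 46.069
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  w <- sum(.ATOMIC_WEIGHTS[mol$atoms$element]) +
    sum(mol$atoms$implicit_h) * .ATOMIC_WEIGHTS[["H"]]
  round(unname(w), 3L)
}

# atom label used for canonicalization (element|aromatic|charge|implicit H)
.atom_labels <- function(mol) {
  paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
        mol$atoms$charge, mol$atoms$implicit_h, sep = "|")
}

.adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(integer()), n)
  ord <- rep(list(numeric()), n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (k in seq_len(nrow(b))) {
      adj[[b$a[k]]] <- c(adj[[b$a[k]]], b$b[k])
      ord[[b$a[k]]] <- c(ord[[b$a[k]]], b$order[k])
      adj[[b$b[k]]] <- c(adj[[b$b[k]]], b$a[k])
      ord[[b$b[k]]] <- c(ord[[b$b[k]]], b$order[k])
    }
  }
  list(nbr = adj, order = ord)
}

# iterative neighbourhood refinement; returns integer ranks (1..k)
.refine_ranks <- function(ranks, adj) {
  repeat {
    sig <- vapply(seq_along(ranks), function(i) {
      nb <- adj$nbr[[i]]
      if (length(nb) == 0L) return(sprintf("%06d;", ranks[i]))
      ns <- sort(sprintf("%.1f:%06d", adj$order[[i]], ranks[nb]))
      paste0(sprintf("%06d;", ranks[i]), paste(ns, collapse = ","))
    }, character(1))
    new_ranks <- match(sig, sort(unique(sig)))
    if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
    ranks <- new_ranks
  }
}

.key_from_ranks <- function(mol, ranks, labels) {
  pos <- order(ranks)             # canonical position of each atom
  canon_pos <- integer(length(ranks))
  canon_pos[pos] <- seq_along(ranks)
  atom_part <- paste(labels[pos], collapse = " ")
  b <- mol$bonds
  if (nrow(b) > 0L) {
    i <- pmin(canon_pos[b$a], canon_pos[b$b])
    j <- pmax(canon_pos[b$a], canon_pos[b$b])
    bond_part <- paste(sort(sprintf("%d-%d:%.1f", i, j, b$order)),
                       collapse = " ")
  } else bond_part <- ""
  paste(atom_part, "/", bond_part)
}

.canonical_key_rec <- function(mol, ranks, adj, labels) {
  ranks <- .refine_ranks(ranks, adj)
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1L])
  if (length(tied) == 0L) return(.key_from_ranks(mol, ranks, labels))
  cls <- which(ranks == min(tied))
  keys <- vapply(cls, function(a) {
    r2 <- ranks * 2L
    r2[a] <- r2[a] - 1L
    r2 <- match(r2, sort(unique(r2)))
    .canonical_key_rec(mol, r2, adj, labels)
  }, character(1))
  min(keys)
}

#' Canonical structure key
#'
#' A string that is identical for any two parses or atom-order permutations
#' of the same molecular graph (same elements, aromatic flags, formal
#' charges, implicit hydrogens, and bonds), and different for non-isomorphic
#' graphs except in the rare event of refinement collisions (none are known
#' for this atom/bond vocabulary). Computed by iterative neighbourhood
#' refinement with exhaustive deterministic tie-breaking, so symmetric
#' molecules are handled exactly.
#'
#' Used as the deduplication key when cleaning compound sets.
#'
#' @param mol a `molecule`.
#' @return a single string.
#' @examples
#' canonical_key(parse_smiles("CCO")) == canonical_key(parse_smiles("OCC"))
#' @export
canonical_key <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  labels <- .atom_labels(mol)
  adj <- .adjacency_list(mol)
  ranks <- match(labels, sort(unique(labels)))
  .canonical_key_rec(mol, ranks, adj, labels)
}
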
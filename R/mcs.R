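# Exact maximum common substructure (connected, label-compatible) between
# two molecular graphs, and the overlap-coefficient statistic used for core
# scaffold screening. Atoms are compatible when element and aromatic flag
# agree; bonds when their orders agree (aromatic matches aromatic). The
# search is exact backtracking with branch-and-bound, so it is restricted to
# modest sizes (combined heavy-atom count <= 80 by default); pre-filter with
# fingerprints for anything larger.

.bond_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  m <- matrix(0, n, n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    m[cbind(b$a, b$b)] <- b$order
    m[cbind(b$b, b$a)] <- b$order
  }
  m
}

.mcs_atom_label <- function(mol) {
  paste(mol$atoms$element, as.integer(mol$atoms$aromatic), sep = "|")
}

#' Maximum common substructure of two molecules
#'
#' Finds a maximum connected common subgraph under atom compatibility (same
#' element and same aromatic flag) and bond compatibility (same order;
#' aromatic matches aromatic). Maximizes the mapped atom count; ties are
#' broken by shared-bond count, then by lexicographically smallest atom-pair
#' list, so the result is deterministic.
#'
#' @param a,b `molecule` objects with a combined heavy-atom count of at most
#'   `max_atoms`.
#' @param max_atoms size guard for the exact search (default 80). Larger
#'   inputs are rejected with an error advising fingerprint pre-filtering.
#' @return object of class `mcs_result`: `atom_pairs` (two-column matrix of
#'   1-based indices into `a` and `b`), `n_atoms`, `n_bonds`.
#' @examples
#' res <- maximum_common_substructure(parse_smiles("CCO"), parse_smiles("CCN"))
#' res$n_atoms  # 2 (the C-C unit)
#' @export
maximum_common_substructure <- function(a, b, max_atoms = 80L) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"))
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  if (na + nb > max_atoms)
    stop(sprintf(paste0("combined heavy-atom count %d exceeds the exact-search ",
                        "guard (%d); pre-filter candidates by fingerprint ",
                        "similarity before MCS"), na + nb, max_atoms),
         call. = FALSE)

  la <- .mcs_atom_label(a); lb <- .mcs_atom_label(b)
  ba <- .bond_matrix(a); bb <- .bond_matrix(b)
  compat <- outer(la, lb, "==")

  best <- list(size = 0L, bonds = 0L, pairs_a = integer(0),
               pairs_b = integer(0), key = "")

  pair_key <- function(pa, pb) {
    o <- order(pa)
    paste(sprintf("%03d:%03d", pa[o], pb[o]), collapse = " ")
  }
  consider <- function(pa, pb, nbonds) {
    sz <- length(pa)
    if (sz < best$size) return(invisible())
    if (sz == best$size) {
      if (nbonds < best$bonds) return(invisible())
      key <- pair_key(pa, pb)
      if (nbonds == best$bonds &&
          best$size > 0L && key >= best$key) return(invisible())
      best <<- list(size = sz, bonds = nbonds, pairs_a = pa, pairs_b = pb,
                    key = key)
    } else {
      best <<- list(size = sz, bonds = nbonds, pairs_a = pa, pairs_b = pb,
                    key = pair_key(pa, pb))
    }
  }

  # extension candidates: unmapped compatible pairs adjacent (with matching
  # bond order) to at least one mapped pair; `excluded` holds pair ids
  # already fully explored at an enclosing level
  extend <- function(pa, pb, nbonds, used_a, used_b, excluded) {
    consider(pa, pb, nbonds)
    rem <- min(na - length(pa), nb - length(pb))
    if (length(pa) + rem < best$size) return(invisible())
    cand_a <- integer(0); cand_b <- integer(0); cand_bonds <- integer(0)
    for (i in seq_len(na)) {
      if (used_a[i]) next
      for (j in seq_len(nb)) {
        if (used_b[j] || !compat[i, j]) next
        if (((i - 1L) * nb + j) %in% excluded) next
        nbonds_ij <- 0L
        connected <- FALSE
        for (k in seq_along(pa)) {
          oa <- ba[i, pa[k]]
          if (oa > 0 && oa == bb[j, pb[k]]) {
            connected <- TRUE
            nbonds_ij <- nbonds_ij + 1L
          }
        }
        if (connected) {
          cand_a <- c(cand_a, i); cand_b <- c(cand_b, j)
          cand_bonds <- c(cand_bonds, nbonds_ij)
        }
      }
    }
    if (length(cand_a) == 0L) return(invisible())
    for (k in seq_along(cand_a)) {
      i <- cand_a[k]; j <- cand_b[k]
      used_a[i] <- TRUE; used_b[j] <- TRUE
      extend(c(pa, i), c(pb, j), nbonds + cand_bonds[k], used_a, used_b,
             excluded)
      used_a[i] <- FALSE; used_b[j] <- FALSE
      excluded <- c(excluded, (i - 1L) * nb + j)
    }
  }

  # seed pairs ordered by rarest atom label first (deterministic)
  label_count <- table(c(la, lb))
  seeds <- which(compat, arr.ind = TRUE)
  if (nrow(seeds) > 0L) {
    rarity <- label_count[la[seeds[, 1L]]]
    seeds <- seeds[order(rarity, seeds[, 1L], seeds[, 2L]), , drop = FALSE]
    excluded <- integer(0)
    for (s in seq_len(nrow(seeds))) {
      i <- seeds[s, 1L]; j <- seeds[s, 2L]
      used_a <- logical(na); used_b <- logical(nb)
      used_a[i] <- TRUE; used_b[j] <- TRUE
      extend(i, j, 0L, used_a, used_b, excluded)
      excluded <- c(excluded, (i - 1L) * nb + j)
    }
  }

  pairs <- cbind(a = best$pairs_a, b = best$pairs_b)
  if (best$size > 0L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  structure(
    list(atom_pairs = pairs, n_atoms = best$size, n_bonds = best$bonds),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<mcs_result> %d atoms, %d bonds\n", x$n_atoms, x$n_bonds))
  invisible(x)
}

#' Overlap coefficient of an MCS result
#'
#' MCS heavy-atom count divided by the heavy-atom count of the smaller
#' molecule. Values above 0.9 are treated as high substructure similarity
#' (scaffold possession) by [scaffold_screen()].
#'
#' @param res an `mcs_result` produced from `(a, b)`.
#' @param a,b the two molecules.
#' @return overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(res, a, b) {
  stopifnot(inherits(res, "mcs_result"))
  res$n_atoms / min(nrow(a$atoms), nrow(b$atoms))
}

#' Screen a molecule against core scaffolds
#'
#' Runs an exact MCS against each scaffold and reports the overlap
#' coefficient. A scaffold match is flagged high-similarity when the overlap
#' coefficient is strictly greater than `overlap_cut`; a molecule contains
#' no core scaffold when no match is flagged.
#'
#' @param drug a `molecule`.
#' @param scaffolds named list of `molecule`s (names are scaffold ids), or a
#'   data.frame with columns `id` and `smiles`.
#' @param overlap_cut high-similarity threshold (default 0.9, strict).
#' @param max_atoms passed to [maximum_common_substructure()].
#' @return data.frame with columns `scaffold_id`, `mcs_atoms`,
#'   `overlap_coefficient`, `is_high_similarity`.
#' @export
scaffold_screen <- function(drug, scaffolds, overlap_cut = 0.9,
                            max_atoms = 80L) {
  stopifnot(inherits(drug, "molecule"))
  if (is.data.frame(scaffolds)) {
    mols <- lapply(scaffolds$smiles, parse_smiles)
    names(mols) <- scaffolds$id
    scaffolds <- mols
  }
  if (length(scaffolds) == 0L)
    stop("`scaffolds` must be non-empty", call. = FALSE)
  rows <- lapply(names(scaffolds), function(id) {
    sc <- scaffolds[[id]]
    res <- maximum_common_substructure(drug, sc, max_atoms = max_atoms)
    oc <- overlap_coefficient(res, drug, sc)
    data.frame(scaffold_id = id, mcs_atoms = res$n_atoms,
               overlap_coefficient = oc,
               is_high_similarity = oc > overlap_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
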
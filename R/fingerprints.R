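# Hashed substructure fingerprints: a path-based family (linear fragments of
# up to `max_path_len` atoms, the FP2 convention) and a circular family
# (Morgan-style iterated neighbourhood hashing, the ECFP convention; radius r
# corresponds to ECFP(2r)). Feature strings are hashed with FNV-1a (32 bit)
# and folded modulo `n_bits`, so fingerprints are bit-exact across platforms
# and runs.

#' FNV-1a 32-bit hash
#'
#' Hashes each string byte-wise with the Fowler-Noll-Vo 1a function
#' (offset basis 2166136261, prime 16777619), returning the unsigned 32-bit
#' value as a double. This is the hash behind every fingerprint bit, exposed
#' so that the bit assignment is externally checkable.
#'
#' @param x character vector.
#' @return double vector of values in `[0, 2^32)`.
#' @examples
#' fnv1a32("")       # 2166136261 (the offset basis)
#' fnv1a32("foobar") # 3214735720
#' @export
fnv1a32 <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    h <- 2166136261
    for (byte in utf8ToInt(s)) {
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      lo <- bitwXor(as.integer(lo), as.integer(byte))
      # 32-bit multiply by the FNV prime, split to stay within double precision
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.new_fingerprint <- function(bits, n_bits, family, params) {
  structure(
    list(bits = as.integer(sort(unique(bits))), n_bits = as.integer(n_bits),
         family = family, params = params),
    class = "fingerprint"
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s, %d/%d bits set [%s]\n", x$family,
              length(x$bits), x$n_bits,
              paste(sprintf("%s=%s", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

.check_nbits <- function(n_bits) {
  if (n_bits < 64 || bitwAnd(as.integer(n_bits), as.integer(n_bits - 1)) != 0L)
    stop("`n_bits` must be a power of two >= 64", call. = FALSE)
}

# atom token for path encoding: lowercase element if aromatic, charge
# appended when non-zero ("N", "c", "O-1", "N+1")
.atom_tokens <- function(mol) {
  el <- mol$atoms$element
  tok <- ifelse(mol$atoms$aromatic, tolower(el), el)
  chg <- mol$atoms$charge
  ifelse(chg != 0L, paste0(tok, sprintf("%+d", chg)), tok)
}

.bond_token <- function(order) {
  # order 1, 2, 3 or 1.5 (aromatic)
  c(`1` = "-", `2` = "=", `3` = "#", `1.5` = ":")[as.character(order)]
}

# enumerate canonical encodings of all simple paths of 1..max_len atoms;
# each path string is the lexicographic minimum of its forward and reverse
# token sequences
.enumerate_paths <- function(mol, max_len) {
  n <- nrow(mol$atoms)
  atok <- .atom_tokens(mol)
  adj <- .adjacency_list(mol)
  btok <- lapply(adj$order, .bond_token)
  out <- character(0)
  emit <- function(tokens) {
    fwd <- paste(tokens, collapse = "")
    rev_ <- paste(rev(tokens), collapse = "")
    out[[length(out) + 1L]] <<- if (fwd <= rev_) fwd else rev_
  }
  visited <- logical(n)
  walk <- function(v, tokens, depth) {
    emit(tokens)
    if (depth == max_len) return(invisible())
    visited[v] <<- TRUE
    nbrs <- adj$nbr[[v]]
    for (k in seq_along(nbrs)) {
      w <- nbrs[k]
      if (!visited[w])
        walk(w, c(tokens, btok[[v]][k], atok[w]), depth + 1L)
    }
    visited[v] <<- FALSE
  }
  for (s in seq_len(n)) walk(s, atok[s], 1L)
  unique(out)
}

#' Path-based (linear fragment) fingerprint
#'
#' Enumerates all simple paths of 1 to `max_path_len` atoms, encodes each as
#' an alternating string of atom tokens (element, aromaticity, charge) and
#' bond tokens, canonicalizes the string as the lexicographic minimum of its
#' forward and reverse reading, and sets bit
#' `fnv1a32(string) mod n_bits`. Rings contribute through their constituent
#' simple paths, matching linear-fragment fingerprint semantics.
#'
#' @param mol a `molecule`.
#' @param max_path_len maximum path length in atoms (default 7, the FP2
#'   convention).
#' @param n_bits fingerprint length; a power of two >= 64 (default 1024).
#' @return a `fingerprint` object (family `"path"`).
#' @examples
#' fp <- path_fingerprint(parse_smiles("CCC"))
#' length(fp$bits)  # 3 distinct paths: C, C-C, C-C-C
#' @export
path_fingerprint <- function(mol, max_path_len = 7L, n_bits = 1024L) {
  stopifnot(inherits(mol, "molecule"), max_path_len >= 1L)
  .check_nbits(n_bits)
  paths <- .enumerate_paths(mol, max_path_len)
  bits <- fnv1a32(paths) %% n_bits
  .new_fingerprint(bits, n_bits, "path",
                   list(max_path_len = as.integer(max_path_len)))
}

#' Circular (Morgan-style) fingerprint
#'
#' Iterative neighbourhood hashing: the initial atom identifier hashes the
#' invariant (element, aromaticity, charge, degree, implicit hydrogen
#' count); each iteration hashes the previous identifier together with the
#' sorted multiset of (bond order, neighbour identifier) pairs. Identifiers
#' from iterations 0..`radius` are folded into `n_bits`. Radius r
#' corresponds to an ECFP diameter of 2r.
#'
#' Identifiers whose neighbourhood has stopped growing (the atom's
#' environment already covers everything reachable) are not re-emitted, so
#' a single atom has one set bit at any radius and small molecules are not
#' over-weighted by saturated environments.
#'
#' @param mol a `molecule`.
#' @param radius neighbourhood radius (default 2, the ECFP4 convention).
#' @param n_bits fingerprint length; a power of two >= 64 (default 1024).
#' @return a `fingerprint` object (family `"circular"`).
#' @export
circular_fingerprint <- function(mol, radius = 2L, n_bits = 1024L) {
  stopifnot(inherits(mol, "molecule"), radius >= 0L)
  .check_nbits(n_bits)
  adj <- .adjacency_list(mol)
  n <- nrow(mol$atoms)
  degree <- lengths(adj$nbr)
  ids <- fnv1a32(paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
                       mol$atoms$charge, degree, mol$atoms$implicit_h,
                       sep = "|"))
  all_ids <- ids
  reach <- as.list(seq_len(n))   # atoms within distance r of each atom
  r <- 0L
  while (r < radius) {
    new_reach <- lapply(seq_len(n), function(i)
      sort(unique(c(reach[[i]], unlist(reach[adj$nbr[[i]]])))))
    grew <- lengths(new_reach) > lengths(reach)
    if (!any(grew)) break
    new_ids <- ids
    for (i in which(grew)) {
      nb <- adj$nbr[[i]]
      env <- paste(sort(sprintf("%.1f_%.0f", adj$order[[i]], ids[nb])),
                   collapse = ",")
      new_ids[i] <- fnv1a32(sprintf("%.0f;%s", ids[i], env))
    }
    all_ids <- c(all_ids, new_ids[grew])
    ids <- new_ids
    reach <- new_reach
    r <- r + 1L
  }
  .new_fingerprint(all_ids %% n_bits, n_bits, "circular",
                   list(radius = as.integer(radius)))
}

.compatible_fps <- function(a, b) {
  inherits(a, "fingerprint") && inherits(b, "fingerprint") &&
    a$n_bits == b$n_bits && a$family == b$family &&
    identical(a$params, b$params)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A AND B| / |A OR B|` over set bits. By documented convention the
#' similarity of two all-zero fingerprints is 1 (identical absence of
#' features); an all-zero versus a non-zero fingerprint scores 0.
#'
#' @param a,b `fingerprint` objects with identical length, family and
#'   generation parameters.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!.compatible_fps(a, b))
    stop("fingerprints must share length, family and parameters",
         call. = FALSE)
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(a$bits) + length(b$bits) - inter
  if (uni == 0L) return(1)
  inter / uni
}

#' Similarity profile of a query against a reference set
#'
#' Mean, minimum and maximum Tanimoto similarity of `query` over a non-empty
#' list of reference fingerprints, as used for novelty assessment against
#' approved antibacterial drugs.
#'
#' @param query a `fingerprint`.
#' @param reference non-empty list of compatible `fingerprint`s.
#' @return object of class `similarity_profile` with fields `mean_tc`,
#'   `min_tc`, `max_tc`, `n_reference`.
#' @export
similarity_profile <- function(query, reference) {
  if (!is.list(reference) || length(reference) == 0L)
    stop("`reference` must be a non-empty list of fingerprints", call. = FALSE)
  tcs <- vapply(reference, function(r) tanimoto(query, r), numeric(1))
  structure(
    list(mean_tc = mean(tcs), min_tc = min(tcs), max_tc = max(tcs),
         n_reference = length(tcs)),
    class = "similarity_profile"
  )
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("<similarity_profile> mean %.3f (%.3f-%.3f) over %d references\n",
              x$mean_tc, x$min_tc, x$max_tc, x$n_reference))
  invisible(x)
}

#' Serialize a fingerprint to a hex string
#'
#' Big-endian within each nibble group: bit 0 is the most significant bit of
#' the first hex digit. Round-trips with [hex_to_fingerprint()].
#'
#' @param fp a `fingerprint`.
#' @return a string of `n_bits / 4` hex digits.
#' @export
fingerprint_to_hex <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  v <- integer(fp$n_bits)
  v[fp$bits + 1L] <- 1L
  nib <- matrix(v, nrow = 4L)
  paste(sprintf("%x", 8L * nib[1L, ] + 4L * nib[2L, ] + 2L * nib[3L, ] +
                  nib[4L, ]), collapse = "")
}

#' @rdname fingerprint_to_hex
#' @param hex hex string produced by [fingerprint_to_hex()].
#' @param family,params fingerprint family and generation parameters to
#'   attach.
#' @export
hex_to_fingerprint <- function(hex, family = "path",
                               params = list(max_path_len = 7L)) {
  stopifnot(is.character(hex), length(hex) == 1L)
  nibbles <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- integer(0)
  for (k in seq_along(nibbles)) {
    base <- (k - 1L) * 4L
    nb <- nibbles[k]
    if (bitwAnd(nb, 8L) != 0L) bits <- c(bits, base)
    if (bitwAnd(nb, 4L) != 0L) bits <- c(bits, base + 1L)
    if (bitwAnd(nb, 2L) != 0L) bits <- c(bits, base + 2L)
    if (bitwAnd(nb, 1L) != 0L) bits <- c(bits, base + 3L)
  }
  .new_fingerprint(bits, length(nibbles) * 4L, family, params)
}

#' Fingerprint feature matrix
#'
#' Stacks a list of compatible fingerprints into a dense 0/1 matrix for
#' model fitting, one row per fingerprint.
#'
#' @param fps list of compatible `fingerprint`s.
#' @param row_names optional row names.
#' @return numeric matrix with `n_bits` columns.
#' @export
fingerprint_matrix <- function(fps, row_names = NULL) {
  stopifnot(is.list(fps), length(fps) > 0L)
  n_bits <- fps[[1L]]$n_bits
  for (fp in fps)
    if (!.compatible_fps(fps[[1L]], fp))
      stop("all fingerprints must share length, family and parameters",
           call. = FALSE)
  m <- matrix(0, nrow = length(fps), ncol = n_bits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits + 1L] <- 1
  colnames(m) <- paste0("b", seq_len(n_bits) - 1L)
  rownames(m) <- row_names
  m
}

#' Compute fingerprints for a vector of SMILES
#'
#' Convenience wrapper used throughout the pipeline: parses each SMILES and
#' computes the configured fingerprint.
#'
#' @param smiles character vector.
#' @param family `"path"` or `"circular"`.
#' @param n_bits fingerprint length.
#' @param max_path_len path length for the path family.
#' @param radius radius for the circular family.
#' @return list of `fingerprint`s (NULL for unparseable entries).
#' @export
fingerprints_for <- function(smiles, family = c("path", "circular"),
                             n_bits = 1024L, max_path_len = 7L, radius = 2L) {
  family <- match.arg(family)
  lapply(smiles, function(s) {
    mol <- tryCatch(parse_smiles(s), error = function(e) NULL)
    if (is.null(mol)) return(NULL)
    if (family == "path") path_fingerprint(mol, max_path_len, n_bits)
    else circular_fingerprint(mol, radius, n_bits)
  })
}
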
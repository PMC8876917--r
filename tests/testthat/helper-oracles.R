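# Independent oracles and random-molecule machinery shared across tests.
# The oracles deliberately take different routes from the implementation:
# igraph for path enumeration and isomorphism, subset enumeration for MCS,
# a re-derivation of FNV-1a on 16-bit halves for hashing, pROC/trapezoids
# for AUC.

# ---- independent FNV-1a 32-bit (verified against fixed vectors) ----------
# multiply by the prime via its shift-add decomposition
# 16777619 = 2^24 + 2^8 + 147, each addend exact in double precision
oracle_fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b))
    h <- ((h %% 256) * 16777216 + (h %% 16777216) * 256 + h * 147) %%
      4294967296
  }
  h
}

# ---- igraph bridge -------------------------------------------------------
mol_to_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds) > 0L)
    g <- igraph::add_edges(g, rbind(mol$bonds$a, mol$bonds$b))
  g
}

# atom/bond tokens re-derived from the documented encoding
atom_token <- function(mol, i) {
  el <- mol$atoms$element[i]
  tok <- if (mol$atoms$aromatic[i]) tolower(el) else el
  chg <- mol$atoms$charge[i]
  if (chg != 0L) paste0(tok, sprintf("%+d", chg)) else tok
}
bond_token_of <- function(order) c(`1` = "-", `2` = "=", `3` = "#",
                                   `1.5` = ":")[as.character(order)]

bond_order_lookup <- function(mol) {
  key <- paste(pmin(mol$bonds$a, mol$bonds$b),
               pmax(mol$bonds$a, mol$bonds$b))
  stats::setNames(mol$bonds$order, key)
}

# all simple paths of 1..max_len atoms via igraph, encoded and canonicalized
oracle_path_strings <- function(mol, max_len = 7L) {
  n <- nrow(mol$atoms)
  g <- mol_to_igraph(mol)
  orders <- bond_order_lookup(mol)
  out <- vapply(seq_len(n), function(i) atom_token(mol, i), character(1))
  if (n > 1L && nrow(mol$bonds) > 0L) {
    for (from in seq_len(n)) {
      paths <- igraph::all_simple_paths(g, from = from,
                                        cutoff = max_len - 1L)
      for (p in paths) {
        v <- as.integer(p)
        toks <- atom_token(mol, v[1L])
        for (k in seq_len(length(v) - 1L)) {
          o <- orders[[paste(min(v[k], v[k + 1L]), max(v[k], v[k + 1L]))]]
          toks <- c(toks, bond_token_of(o), atom_token(mol, v[k + 1L]))
        }
        fwd <- paste(toks, collapse = "")
        bwd <- paste(rev(toks), collapse = "")
        out <- c(out, if (fwd <= bwd) fwd else bwd)
      }
    }
  }
  unique(out)
}

oracle_path_bits <- function(mol, max_len = 7L, n_bits = 1024L) {
  sort(unique(vapply(oracle_path_strings(mol, max_len), oracle_fnv1a,
                     numeric(1)) %% n_bits))
}

# ---- exhaustive connected-common-subgraph oracle -------------------------
# enumerate connected subsets of A's atoms; for each, try all label-
# compatible injections into B; count the subset when the shared-bond graph
# is connected. Returns the maximum atom count.
oracle_mcs_atoms <- function(a, b) {
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  la <- paste(a$atoms$element, a$atoms$aromatic)
  lb <- paste(b$atoms$element, b$atoms$aromatic)
  ba <- matrix(0, na, na); bb <- matrix(0, nb, nb)
  if (nrow(a$bonds)) {
    ba[cbind(a$bonds$a, a$bonds$b)] <- a$bonds$order
    ba[cbind(a$bonds$b, a$bonds$a)] <- a$bonds$order
  }
  if (nrow(b$bonds)) {
    bb[cbind(b$bonds$a, b$bonds$b)] <- b$bonds$order
    bb[cbind(b$bonds$b, b$bonds$a)] <- b$bonds$order
  }

  # connected subsets of A via BFS-style growth (each subset found once)
  subsets <- list()
  grow <- function(set, frontier, banned) {
    subsets[[length(subsets) + 1L]] <<- set
    cand <- setdiff(unique(unlist(lapply(set, function(v) which(ba[v, ] > 0)))),
                    c(set, banned))
    for (w in cand) {
      grow(c(set, w), NULL, banned)
      banned <- c(banned, w)
    }
  }
  banned <- integer(0)
  for (s in seq_len(na)) {
    grow(s, NULL, banned)
    banned <- c(banned, s)
  }

  shared_connected <- function(set, img) {
    k <- length(set)
    if (k == 1L) return(TRUE)
    adj <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      o <- ba[set[i], set[j]]
      if (o > 0 && o == bb[img[i], img[j]]) adj[i, j] <- adj[j, i] <- TRUE
    }
    seen <- logical(k); queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nxt <- which(adj[v, ] & !seen)
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    all(seen)
  }

  best <- 0L
  inject <- function(set, img, used_b) {
    k <- length(img)
    if (k == length(set)) {
      if (shared_connected(set, img)) best <<- max(best, k)
      return(invisible())
    }
    tgt <- set[k + 1L]
    for (j in which(lb == la[tgt] & !used_b)) {
      used_b[j] <- TRUE
      inject(set, c(img, j), used_b)
      used_b[j] <- FALSE
    }
  }
  for (set in subsets) {
    if (length(set) <= best) next
    inject(set, integer(0), logical(nb))
  }
  best
}

# ---- random molecules (grammar-conformant, via the synthetic module) -----
random_molecules <- function(n, seed = 1L) {
  cfg <- generator_config(n_active = ceiling(n / 2), n_inactive_ic50 = 0L,
                          n_inactive_label_only = floor(n / 2),
                          n_library = 2L, n_scaffold_actives_in_library = 1L,
                          n_novel_actives_in_library = 1L, n_reference = 1L,
                          planted = list(n_duplicates = 0L, n_heavy = 0L,
                                         n_cross_similar = 0L,
                                         n_label_conflicts = 0L),
                          seed = seed)
  smiles <- generate_activity_corpus(cfg)$records$smiles[seq_len(n)]
  lapply(smiles, parse_smiles)
}

# random permutation of a molecule's atom order (same graph, new labels)
permute_molecule <- function(mol, seed) {
  n <- nrow(mol$atoms)
  perm <- abxscreen:::with_seed(seed, sample.int(n))   # perm[i] = new index
  atoms <- mol$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds) > 0L) {
    bonds$a <- perm[bonds$a]
    bonds$b <- perm[bonds$b]
  }
  new_molecule(atoms, bonds, mol$source_smiles)
}

# random fingerprints with a given bit budget (for similarity tests)
random_fingerprint <- function(n_bits = 256L, density = 0.1, seed = 1L) {
  bits <- abxscreen:::with_seed(seed,
    which(stats::runif(n_bits) < density) - 1L)
  hex <- paste(rep("0", n_bits / 4), collapse = "")
  fp <- hex_to_fingerprint(hex)
  fp$bits <- as.integer(bits)
  fp
}

# 12-molecule fixture, all <= 8 heavy atoms, spanning aromatic/aliphatic,
# heteroatoms, branching and rings
mcs_fixture <- function() {
  lapply(c("CCO", "CCN", "c1ccccc1", "C1CCCCC1", "Cc1ccco1", "CC(C)C",
           "CC(=O)N", "C1CCC1", "c1ccncc1", "OCC(N)C", "CC(=O)OC",
           "C#CCO"), parse_smiles)
}

# ---- shared heavyweight fixture (built once per test run) ----------------
.fixture_env <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  cfg <- generator_config(seed = 1L)
  corpus <- generate_activity_corpus(cfg)
  lib <- generate_drug_library(cfg)
  benchmark <- build_benchmark(corpus$records, seed = 1L, n_bits = 512L)
  specs <- list(
    svm = model_spec("svm", chosen = list(gamma = 0.01, cost = 10)),
    rf = model_spec("rf", chosen = list(n_estimators = 750L)),
    mlp = model_spec("mlp", chosen = list(hidden = 4L, alpha = 1e-4,
                                          maxit = 100L)))
  report <- benchmark_study(benchmark, specs, seed = 1L)
  bundles <- lapply(specs, function(sp) train_final(benchmark, sp, seed = 1L))
  prepped <- prepare_library(lib$library, n_bits = 512L)
  screen <- full_screen(bundles, prepped, lib$reference$smiles,
                        scaffolds = lib$scaffolds)
  .fixture_env$fx <- list(cfg = cfg, corpus = corpus, lib = lib,
                          benchmark = benchmark, specs = specs,
                          report = report, bundles = bundles,
                          prepped = prepped, screen = screen)
  .fixture_env$fx
}
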
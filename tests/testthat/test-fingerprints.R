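test_that("fnv1a32 reproduces published test vectors", {
  # reference values computed independently from the FNV-1a definition
  expect_equal(fnv1a32(""), 2166136261)
  expect_equal(fnv1a32("a"), 3826002220)
  expect_equal(fnv1a32("foobar"), 3214735720)
  # agreement with the independent shift-add re-derivation
  for (s in c("C", "c:c:c", "C-C-O", "N+1", "O=C-N-C"))
    expect_equal(fnv1a32(s), oracle_fnv1a(s))
})

test_that("path fingerprints enumerate canonical simple paths", {
  fp <- path_fingerprint(parse_smiles("CCC"))
  expect_s3_class(fp, "fingerprint")
  expect_equal(length(fp$bits), 3L)  # C, C-C, C-C-C
  expect_equal(fp$n_bits, 1024L)

  expect_equal(length(path_fingerprint(parse_smiles("C"))$bits), 1L)

  # benzene and cyclohexane use disjoint token sets
  b <- path_fingerprint(parse_smiles("c1ccccc1"))
  ch <- path_fingerprint(parse_smiles("C1CCCCC1"))
  expect_equal(tanimoto(b, ch), 0)
  expect_false(identical(b$bits, ch$bits))

  # bits equal the FNV hashes of the independent path enumeration
  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  expect_identical(path_fingerprint(mol)$bits,
                   as.integer(oracle_path_bits(mol)))

  expect_error(path_fingerprint(parse_smiles("C"), n_bits = 100L),
               "power of two")
})

test_that("simple-path counts on chains follow the closed form", {
  # an n-atom chain has (n - l + 1) paths of l atoms, l = 1..min(n, max_len).
  # On a chain whose atom tokens are pairwise distinct, every path has a
  # unique canonical string, so the distinct-string count equals the
  # closed-form path count.
  units <- c("F", "B", "C", "N", "O", "P", "S", "[C+]", "[N+]", "Cl")
  for (n in 1:10) {
    smi <- if (n == 1L) "C" else paste(units[1:n], collapse = "")
    expected <- sum(n - seq_len(min(n, 7L)) + 1L)
    paths <- abxscreen:::.enumerate_paths(parse_smiles(smi), 7L)
    expect_equal(length(paths), expected)
    expect_equal(length(oracle_path_strings(parse_smiles(smi), 7L)),
                 expected)
  }
  # homoatomic chains collapse to one string per path length
  for (n in c(3L, 8L))
    expect_equal(length(abxscreen:::.enumerate_paths(
      parse_smiles(paste(rep("C", n), collapse = "")), 7L)), min(n, 7L))
})

test_that("circular fingerprints hash iterated neighbourhoods", {
  for (r in 0:3)
    expect_equal(length(circular_fingerprint(parse_smiles("C"), radius = r)$bits),
                 1L)
  # ethanol at radius 0: three distinct atom invariants
  expect_equal(length(circular_fingerprint(parse_smiles("CCO"), radius = 0)$bits),
               3L)
  # connectivity isomers differ at radius 2
  f1 <- circular_fingerprint(parse_smiles("CCCC"))
  f2 <- circular_fingerprint(parse_smiles("CC(C)C"))
  expect_false(identical(f1$bits, f2$bits))
})

test_that("fingerprints are deterministic and permutation-invariant", {
  mols <- random_molecules(20, seed = 5L)
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    expect_identical(path_fingerprint(m)$bits, path_fingerprint(m)$bits)
    pm <- permute_molecule(m, seed = i)
    expect_identical(path_fingerprint(pm)$bits, path_fingerprint(m)$bits)
    expect_identical(circular_fingerprint(pm)$bits,
                     circular_fingerprint(m)$bits)
  }
})

test_that("tanimoto matches set arithmetic and documented conventions", {
  f12 <- random_fingerprint(256L, seed = 1L)
  f12$bits <- c(1L, 2L)
  f13 <- f12; f13$bits <- c(1L, 3L)
  expect_equal(tanimoto(f12, f13), 1 / 3)
  expect_equal(tanimoto(f12, f12), 1)
  dis <- f12; dis$bits <- c(7L, 9L)
  expect_equal(tanimoto(f12, dis), 0)
  # all-zero convention
  z1 <- f12; z1$bits <- integer(0)
  z2 <- z1
  expect_equal(tanimoto(z1, z2), 1)
  expect_equal(tanimoto(z1, f12), 0)
  # incompatible fingerprints are a usage error
  other <- random_fingerprint(512L, seed = 2L)
  expect_error(tanimoto(f12, other), "share length")
  cf <- circular_fingerprint(parse_smiles("CC"), n_bits = 256L)
  expect_error(tanimoto(f12, cf), "share length|family")
})

test_that("tanimoto is symmetric with unit self-similarity (500 random pairs)", {
  for (k in 1:500) {
    a <- random_fingerprint(256L, density = 0.15, seed = k)
    b <- random_fingerprint(256L, density = 0.15, seed = 10000L + k)
    # brute-force dense-vector oracle
    va <- vb <- logical(256)
    va[a$bits + 1L] <- TRUE; vb[b$bits + 1L] <- TRUE
    expected <- if (!any(va | vb)) 1 else sum(va & vb) / sum(va | vb)
    expect_equal(tanimoto(a, b), expected, tolerance = 1e-15)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    if (length(a$bits) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("similarity profiles match a direct loop oracle", {
  q <- random_fingerprint(256L, seed = 99L)
  refs <- lapply(1:20, function(k) random_fingerprint(256L, seed = 200L + k))
  pr <- similarity_profile(q, refs)
  tcs <- vapply(refs, function(r) tanimoto(q, r), numeric(1))
  expect_equal(pr$mean_tc, mean(tcs), tolerance = 1e-12)
  expect_equal(pr$min_tc, min(tcs), tolerance = 1e-12)
  expect_equal(pr$max_tc, max(tcs), tolerance = 1e-12)
  expect_equal(pr$n_reference, 20L)
  expect_true(pr$min_tc <= pr$mean_tc && pr$mean_tc <= pr$max_tc)

  # forced arithmetic: identical to one of three references, disjoint from
  # the other two
  a <- q; a$bits <- c(1L, 2L, 3L)
  r1 <- q; r1$bits <- c(1L, 2L, 3L)
  r2 <- q; r2$bits <- c(10L, 11L)
  r3 <- q; r3$bits <- c(20L)
  pr2 <- similarity_profile(a, list(r1, r2, r3))
  expect_equal(pr2$mean_tc, 1 / 3)
  expect_equal(pr2$min_tc, 0)
  expect_equal(pr2$max_tc, 1)
  pr3 <- similarity_profile(a, list(a))
  expect_equal(c(pr3$mean_tc, pr3$min_tc, pr3$max_tc), c(1, 1, 1))

  expect_error(similarity_profile(q, list()), "non-empty")
})

test_that("hex serialization round-trips and the matrix stacks bits", {
  fp <- path_fingerprint(parse_smiles("CC(=O)Nc1ccccc1"), n_bits = 256L)
  expect_identical(hex_to_fingerprint(fingerprint_to_hex(fp))$bits, fp$bits)
  fps <- fingerprints_for(c("CCO", "CCN"), n_bits = 128L)
  m <- fingerprint_matrix(fps, row_names = c("a", "b"))
  expect_equal(dim(m), c(2L, 128L))
  expect_equal(sum(m[1, ]), length(fps[[1]]$bits))
  expect_equal(unname(which(m[2, ] == 1)) - 1L, fps[[2]]$bits)
})
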
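test_that("the generator echoes its configuration exactly", {
  cfg <- generator_config(n_active = 200L, n_inactive_ic50 = 150L,
                          n_inactive_label_only = 400L, seed = 1L)
  corpus <- generate_activity_corpus(cfg)
  planted_extra <- cfg$planted$n_duplicates + 2L * cfg$planted$n_label_conflicts +
    cfg$planted$n_heavy + 2L * cfg$planted$n_cross_similar
  expect_equal(nrow(corpus$records), 750L + planted_extra)
  expect_equal(sum(corpus$truth$class == "active" &
                     corpus$truth$role == "normal"), 200L)
  expect_equal(sum(corpus$truth$class == "inactive_ic50" &
                     corpus$truth$role == "normal"), 150L)
  expect_equal(sum(corpus$truth$class == "inactive_label" &
                     corpus$truth$role == "normal"), 400L)

  lib <- generate_drug_library(generator_config(n_library = 100L,
                                                n_novel_actives_in_library = 10L,
                                                seed = 7L))
  expect_equal(nrow(lib$library), 100L)
  expect_equal(sum(lib$truth$role == "novel_active"), 10L)
  expect_error(generator_config(n_active = -1L), ">= 0")
  expect_error(generator_config(n_library = 5L,
                                n_scaffold_actives_in_library = 4L,
                                n_novel_actives_in_library = 4L),
               "exceeds n_library")
})

test_that("every emitted SMILES parses and truth covers each record once", {
  cfg <- generator_config(n_active = 40L, n_inactive_ic50 = 30L,
                          n_inactive_label_only = 80L, seed = 3L)
  corpus <- generate_activity_corpus(cfg)
  lib <- generate_drug_library(cfg)
  for (s in c(corpus$records$smiles, lib$library$smiles,
              lib$reference$smiles, lib$scaffolds$smiles))
    expect_s3_class(parse_smiles(s), "molecule")
  expect_identical(sort(corpus$records$compound_id),
                   sort(corpus$truth$compound_id))
  expect_equal(anyDuplicated(corpus$truth$compound_id), 0L)
  expect_identical(sort(lib$library$drug_id), sort(lib$truth$drug_id))
})

test_that("identical configurations regenerate identical corpora and files", {
  cfg <- generator_config(n_active = 30L, n_inactive_ic50 = 20L,
                          n_inactive_label_only = 50L, seed = 11L)
  expect_identical(generate_activity_corpus(cfg),
                   generate_activity_corpus(cfg))
  expect_identical(generate_drug_library(cfg), generate_drug_library(cfg))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_corpus(cfg, d1)
  write_corpus(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("IC50 distributions straddle the cutoff as configured", {
  cfg <- generator_config(seed = 2L)
  # closed-form check of the distribution itself
  expect_gte(stats::plnorm(cfg$cutoff, log(cfg$ic50_active$median),
                           cfg$ic50_active$sigma_log), 0.95)
  expect_lte(stats::plnorm(cfg$cutoff, log(cfg$ic50_inactive$median),
                           cfg$ic50_inactive$sigma_log), 0.05)
  corpus <- generate_activity_corpus(cfg)
  truth <- corpus$truth
  rec <- corpus$records
  act <- rec$ic50_umol[truth$class == "active" & truth$role == "normal"]
  ina <- rec$ic50_umol[truth$class == "inactive_ic50" &
                         truth$role == "normal"]
  expect_gte(mean(act < cfg$cutoff), 0.95)
  expect_gte(mean(ina > cfg$cutoff), 0.95)
})

test_that("scaffold families separate in fingerprint space", {
  cfg <- generator_config(n_active = 40L, n_inactive_ic50 = 40L,
                          n_inactive_label_only = 0L, seed = 17L,
                          planted = list(n_duplicates = 0L, n_heavy = 0L,
                                         n_cross_similar = 0L,
                                         n_label_conflicts = 0L))
  corpus <- generate_activity_corpus(cfg)
  fps <- fingerprints_for(corpus$records$smiles, n_bits = 512L)
  act <- corpus$truth$class == "active"
  n <- length(fps)
  within <- c(); between <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tc <- tanimoto(fps[[i]], fps[[j]])
    if (act[i] == act[j]) within <- c(within, tc)
    else between <- c(between, tc)
  }
  expect_gt(mean(within), mean(between))
})

test_that("planted violations are exactly the ones the filters remove", {
  cfg <- generator_config(n_active = 40L, n_inactive_ic50 = 30L,
                          n_inactive_label_only = 80L, seed = 23L,
                          planted = list(n_duplicates = 4L, n_heavy = 3L,
                                         n_cross_similar = 2L,
                                         n_label_conflicts = 2L))
  corpus <- generate_activity_corpus(cfg)
  out <- clean_compounds(corpus$records)
  expect_equal(out$provenance$dedup_removed, 4L)
  expect_equal(out$provenance$conflict_removed, 4L)   # both members of each pair
  expect_equal(out$provenance$mw_removed, 3L)
  expect_equal(out$provenance$cross_removed, 2L)
  expect_equal(out$provenance$parse_skipped, 0L)

  # the cross-similar twins really are fingerprint near-duplicates
  xsa <- corpus$records$smiles[grepl("^XSA", corpus$records$compound_id)]
  xsb <- corpus$records$smiles[grepl("^XSB", corpus$records$compound_id)]
  for (k in seq_along(xsa)) {
    fa <- path_fingerprint(parse_smiles(xsa[k]))
    fb <- path_fingerprint(parse_smiles(xsb[k]))
    expect_gt(tanimoto(fa, fb), 0.9)
    expect_false(canonical_key(parse_smiles(xsa[k])) ==
                   canonical_key(parse_smiles(xsb[k])))
  }
})

test_that("planted novels sit near the aliphatic actives but far from the reference", {
  cfg <- generator_config(seed = 29L)
  corpus <- generate_activity_corpus(cfg)
  lib <- generate_drug_library(cfg)
  nv_fps <- fingerprints_for(
    lib$library$smiles[lib$truth$role == "novel_active"], n_bits = 512L)
  dc_fps <- fingerprints_for(
    lib$library$smiles[lib$truth$role == "decoy"][1:20], n_bits = 512L)
  ref_fps <- fingerprints_for(lib$reference$smiles, n_bits = 512L)
  nv_mean <- vapply(nv_fps, function(f)
    similarity_profile(f, ref_fps)$mean_tc, numeric(1))
  dc_mean <- vapply(dc_fps, function(f)
    similarity_profile(f, ref_fps)$mean_tc, numeric(1))
  # novel-planted molecules are less reference-like than the decoy family
  expect_lt(mean(nv_mean), mean(dc_mean))
})
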
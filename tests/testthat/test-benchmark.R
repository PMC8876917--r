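test_that("activity labelling follows the strict IC50 cutoff", {
  expect_equal(label_activity(5), "active")
  expect_equal(label_activity(15), "inactive")
  expect_equal(label_activity(10), "inactive")        # boundary convention
  expect_equal(label_activity(NA, inactive_label = TRUE), "inactive")
  expect_equal(label_activity(c(1, 10, 9.999, NA),
                              inactive_label = c(FALSE, FALSE, FALSE, TRUE)),
               c("active", "inactive", "active", "inactive"))
  expect_equal(label_activity(5, cutoff = 4), "inactive")
  expect_error(label_activity(NA, inactive_label = FALSE), "neither")
  expect_error(label_activity(-1), "positive")
})

# a hand-built fixture exercising each cleaning step:
#  - 2 exact duplicates (same structure, new ids)
#  - 1 compound above 1000 Da
#  - 1 inactive that is a fingerprint near-duplicate (Tc > 0.9) of an active
#  - remaining records untouched
cleaning_fixture <- function() {
  heavy <- paste(rep("C", 85), collapse = "")
  base_active <- "c1cc(C(=O)NC)c2cc(CCCCCCC)ccc2c1"
  near_dup <- sub("CCCCCCC", "CCCCCCCC", base_active)  # same 7-atom paths
  data.frame(
    compound_id = sprintf("M%02d", 1:10),
    smiles = c("CCO",                 # M01 active
               "OCC",                 # M02 duplicate of M01
               "CCN",                 # M03 active
               "NCC",                 # M04 duplicate of M03
               heavy,                 # M05 too heavy
               base_active,           # M06 active
               near_dup,              # M07 inactive, Tc > 0.9 vs M06
               "c1ccccc1",            # M08 inactive
               "C1CCCCC1",            # M09 inactive (label only)
               "CC(=O)OC"),           # M10 inactive
    ic50_umol = c(1, 1, 2, 2, 50, 0.5, 80, 40, NA, 60),
    inactive = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

test_that("clean_compounds applies the three filters in order with exact counts", {
  out <- clean_compounds(cleaning_fixture())
  expect_equal(out$provenance$dedup_removed, 2L)
  expect_equal(out$provenance$conflict_removed, 0L)
  expect_equal(out$provenance$mw_removed, 1L)
  expect_equal(out$provenance$cross_removed, 1L)
  expect_equal(out$provenance$parse_skipped, 0L)
  expect_equal(nrow(out$positives) + nrow(out$negatives), 6L)
  expect_setequal(out$positives$compound_id, c("M01", "M03", "M06"))
  expect_setequal(out$negatives$compound_id, c("M08", "M09", "M10"))
  # provenance counts account for every input record
  p <- out$provenance
  expect_equal(p$n_input,
               p$n_positives + p$n_negatives + p$parse_skipped +
                 p$dedup_removed + p$conflict_removed + p$mw_removed +
                 p$cross_removed)
})

test_that("cleaning is idempotent and the no-violation case is the identity", {
  out <- clean_compounds(cleaning_fixture())
  again <- clean_compounds(rbind(out$positives, out$negatives)[,
    c("compound_id", "smiles", "ic50_umol", "inactive")])
  expect_equal(again$provenance$dedup_removed, 0L)
  expect_equal(again$provenance$mw_removed, 0L)
  expect_equal(again$provenance$cross_removed, 0L)
  expect_setequal(again$positives$compound_id, out$positives$compound_id)
  expect_setequal(again$negatives$compound_id, out$negatives$compound_id)

  clean_in <- data.frame(compound_id = c("A", "B"),
                         smiles = c("CCO", "c1ccccc1"),
                         ic50_umol = c(1, 100), inactive = 0L)
  res <- clean_compounds(clean_in)
  expect_equal(nrow(res$positives) + nrow(res$negatives), 2L)
})

test_that("conflicting duplicate labels remove the whole group", {
  recs <- data.frame(
    compound_id = c("A1", "A2", "B"),
    smiles = c("CCO", "OCC", "CCN"),
    ic50_umol = c(1, NA, 2),
    inactive = c(0L, 1L, 0L), stringsAsFactors = FALSE)
  out <- clean_compounds(recs)
  expect_equal(out$provenance$conflict_removed, 2L)
  expect_equal(out$provenance$dedup_removed, 0L)
  expect_setequal(out$positives$compound_id, "B")
})

test_that("unparseable SMILES are skipped and logged, never silently dropped", {
  recs <- data.frame(
    compound_id = c("OK", "BAD"),
    smiles = c("CCO", "C1CC"),
    ic50_umol = c(1, 1), inactive = 0L, stringsAsFactors = FALSE)
  out <- clean_compounds(recs)
  expect_equal(out$provenance$parse_skipped, 1L)
  expect_equal(out$provenance$skipped_ids, "BAD")
  expect_equal(nrow(out$positives), 1L)
})

test_that("negative resampling keeps every IC50-bearing negative in every set", {
  negatives <- data.frame(
    compound_id = c(sprintf("F%02d", 1:6), sprintf("P%02d", 1:20)),
    smiles = "c1ccccc1",
    ic50_umol = c(stats::runif(6, 20, 100), rep(NA_real_, 20)),
    inactive = c(rep(0L, 6), rep(1L, 20)), stringsAsFactors = FALSE)
  sets <- sample_negatives(negatives, n_target = 10L, n_repeats = 10L,
                           seed = 7L)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_equal(nrow(s), 10L)
    expect_true(all(sprintf("F%02d", 1:6) %in% s$compound_id))
    expect_equal(sum(is.na(s$ic50_umol)), 4L)
    expect_equal(anyDuplicated(s$compound_id), 0L)
  }
  # union of fixed members across sets is exactly the IC50-bearing negatives
  fixed_union <- Reduce(intersect, lapply(sets, `[[`, "compound_id"))
  expect_true(all(sprintf("F%02d", 1:6) %in% fixed_union))

  # seed replay reproduces the sets exactly; a different seed does not
  sets2 <- sample_negatives(negatives, n_target = 10L, n_repeats = 10L,
                            seed = 7L)
  expect_identical(sets, sets2)
  sets3 <- sample_negatives(negatives, n_target = 10L, n_repeats = 10L,
                            seed = 8L)
  expect_false(identical(sets, sets3))

  expect_error(sample_negatives(negatives, n_target = 30L), "insufficient")
  expect_error(sample_negatives(negatives, n_target = 3L), "below")
})

test_that("build_benchmark assembles positive-sized negative sets and features", {
  cfg <- generator_config(n_active = 30L, n_inactive_ic50 = 20L,
                          n_inactive_label_only = 60L, seed = 5L,
                          planted = list(n_duplicates = 1L, n_heavy = 1L,
                                         n_cross_similar = 1L,
                                         n_label_conflicts = 1L))
  corpus <- generate_activity_corpus(cfg)
  bm <- build_benchmark(corpus$records, seed = 5L, n_repeats = 4L,
                        n_bits = 256L)
  expect_s3_class(bm, "benchmark_dataset")
  expect_length(bm$negative_sets, 4L)
  npos <- nrow(bm$positives)
  for (s in bm$negative_sets) expect_equal(nrow(s), npos)
  # positives and negatives are disjoint by canonical key
  for (s in bm$negative_sets)
    expect_length(intersect(bm$positives$key, s$key), 0L)
  # features cover every compound
  expect_true(all(bm$positives$compound_id %in% rownames(bm$features)))
  expect_true(all(bm$negative_sets[[1]]$compound_id %in%
                    rownames(bm$features)))
  expect_equal(ncol(bm$features), 256L)
})
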
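# Drug-library screening: weight/status filtering, three-model consensus
# prediction (active only when every model assigns probability strictly
# greater than 0.5), fingerprint-similarity novelty assessment against the
# approved-antibacterial reference, and core-scaffold MCS screening.
#
# Boundary conventions are kept exactly as defined for each stage: benchmark
# cleaning removes compounds with molecular weight strictly greater than
# 1000 Da, while library preparation removes drugs at or above 1000 Da.

#' Prepare a drug library for screening
#'
#' Parses each drug, drops entries with molecular weight at or above
#' `max_mw` (note: `>=`, unlike the strict `>` of benchmark cleaning), and,
#' when a `status` column is present, keeps only rows whose status is
#' `"approved"` and not `"withdrawn"`. Surviving drugs are fingerprinted
#' with the supplied configuration. Unparseable SMILES are logged, never
#' silently dropped.
#'
#' @param drugs data.frame with columns `drug_id`, `smiles`, optionally
#'   `status`.
#' @param max_mw weight ceiling in Da (default 1000; removal is `>=`).
#' @param family,n_bits,max_path_len,radius fingerprint configuration.
#' @return object of class `drug_library`: data.frame `drugs` (id, smiles,
#'   mw, key), list `fingerprints`, `feature_params`, and a `log` of removal
#'   counts.
#' @export
prepare_library <- function(drugs, max_mw = 1000, family = "path",
                            n_bits = 1024L, max_path_len = 7L, radius = 2L) {
  stopifnot(is.data.frame(drugs))
  if (!all(c("drug_id", "smiles") %in% names(drugs)))
    stop("`drugs` needs columns drug_id and smiles", call. = FALSE)
  n_input <- nrow(drugs)
  status_removed <- 0L
  if (!is.null(drugs$status)) {
    ok <- tolower(drugs$status) == "approved"
    status_removed <- sum(!ok)
    drugs <- drugs[ok, , drop = FALSE]
  }
  mols <- lapply(drugs$smiles, function(s)
    tryCatch(parse_smiles(s), error = function(e) NULL))
  parsed <- !vapply(mols, is.null, logical(1))
  skipped_ids <- drugs$drug_id[!parsed]
  drugs <- drugs[parsed, , drop = FALSE]
  mols <- mols[parsed]

  mw <- vapply(mols, molecular_weight, numeric(1))
  heavy <- mw >= max_mw
  mw_removed <- sum(heavy)
  drugs <- drugs[!heavy, , drop = FALSE]
  mols <- mols[!heavy]
  mw <- mw[!heavy]
  if (nrow(drugs) == 0L)
    stop("no drugs survive library preparation", call. = FALSE)

  fps <- lapply(mols, function(m) {
    if (family == "path") path_fingerprint(m, max_path_len, n_bits)
    else circular_fingerprint(m, radius, n_bits)
  })
  out <- data.frame(drug_id = as.character(drugs$drug_id),
                    smiles = as.character(drugs$smiles),
                    mw = mw,
                    key = vapply(mols, canonical_key, character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(
    list(drugs = out, fingerprints = fps,
         feature_params = list(family = family, n_bits = as.integer(n_bits),
                               max_path_len = as.integer(max_path_len),
                               radius = as.integer(radius)),
         log = list(n_input = n_input, status_removed = status_removed,
                    parse_skipped = length(skipped_ids),
                    skipped_ids = skipped_ids, mw_removed = mw_removed,
                    n_retained = nrow(out))),
    class = "drug_library"
  )
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("<drug_library> %d drugs (%s fingerprints, %d bits)\n",
              nrow(x$drugs), x$feature_params$family,
              x$feature_params$n_bits))
  invisible(x)
}

#' Predict a drug library with the three-model bundles
#'
#' Applies each method's bundle to the library and forms the consensus: a
#' drug is consensus-active only when every model assigns probability
#' strictly greater than `threshold`.
#'
#' @param bundles named list of `model_bundle`s (names `svm`, `rf`, `mlp`).
#' @param library a `drug_library`.
#' @param threshold per-model activity threshold (default 0.5, strict).
#' @return data.frame with `drug_id`, one probability and one activity flag
#'   per model, and `consensus_active`.
#' @export
predict_library <- function(bundles, library, threshold = 0.5) {
  stopifnot(inherits(library, "drug_library"), length(bundles) >= 1L)
  for (b in bundles)
    if (!identical(b$feature_params, library$feature_params))
      stop("bundle and library fingerprint configurations differ",
           call. = FALSE)
  x <- fingerprint_matrix(library$fingerprints,
                          row_names = library$drugs$drug_id)
  out <- data.frame(drug_id = library$drugs$drug_id,
                    stringsAsFactors = FALSE)
  active <- rep(TRUE, nrow(out))
  for (m in names(bundles)) {
    p <- predict(bundles[[m]], x)
    out[[paste0("prob_", m)]] <- p
    out[[paste0("active_", m)]] <- p > threshold
    active <- active & (p > threshold)
  }
  out$consensus_active <- active
  out
}

#' Structural-novelty screen against a reference set
#'
#' Computes the Tanimoto similarity profile of each candidate against the
#' reference fingerprints (approved antibacterial drugs). A candidate is
#' `novel_structure` when mean similarity is strictly below `mean_cut` and
#' maximum similarity strictly below `max_cut`; the broader
#' `low_similarity_bucket` holds candidates with mean similarity at or below
#' `bucket_cut`.
#'
#' @param candidate_fps named list of candidate `fingerprint`s (names are
#'   drug ids).
#' @param reference_fps non-empty list of reference `fingerprint`s.
#' @param mean_cut mean-similarity threshold (default 0.1, strict).
#' @param max_cut maximum-similarity threshold (default 0.2, strict).
#' @param bucket_cut low-similarity bucket threshold (default 0.2, `<=`).
#' @return data.frame with `drug_id`, `mean_tc`, `min_tc`, `max_tc`,
#'   `low_similarity_bucket`, `novel_structure`.
#' @export
novelty_screen <- function(candidate_fps, reference_fps, mean_cut = 0.1,
                           max_cut = 0.2, bucket_cut = 0.2) {
  if (!is.list(reference_fps) || length(reference_fps) == 0L)
    stop("`reference_fps` must be a non-empty list", call. = FALSE)
  if (length(candidate_fps) == 0L)
    return(data.frame(drug_id = character(0), mean_tc = numeric(0),
                      min_tc = numeric(0), max_tc = numeric(0),
                      low_similarity_bucket = logical(0),
                      novel_structure = logical(0)))
  rows <- lapply(seq_along(candidate_fps), function(i) {
    pr <- similarity_profile(candidate_fps[[i]], reference_fps)
    data.frame(drug_id = names(candidate_fps)[i],
               mean_tc = pr$mean_tc, min_tc = pr$min_tc, max_tc = pr$max_tc,
               low_similarity_bucket = pr$mean_tc <= bucket_cut,
               novel_structure = pr$mean_tc < mean_cut & pr$max_tc < max_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the consensus and novelty rules to a prediction table
#'
#' Decision rules applied to an already-computed table of per-model
#' probabilities and similarity profiles: a drug is consensus-active when
#' every model probability is strictly greater than `threshold`, and
#' structurally novel when additionally its mean and maximum similarity to
#' the reference set are strictly below `mean_cut` and `max_cut`.
#'
#' @param table data.frame with columns `prob_svm`, `prob_rf`, `prob_mlp`
#'   and, for the novelty columns, `mean_tc` and `max_tc`.
#' @param threshold per-model activity threshold (default 0.5, strict).
#' @param mean_cut,max_cut novelty thresholds (defaults 0.1 and 0.2,
#'   strict).
#' @return the table with added `consensus_active` and (when similarity
#'   columns are present) `novel_structure` logical columns.
#' @export
apply_screen_rules <- function(table, threshold = 0.5, mean_cut = 0.1,
                               max_cut = 0.2) {
  need <- c("prob_svm", "prob_rf", "prob_mlp")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  table$consensus_active <- table$prob_svm > threshold &
    table$prob_rf > threshold & table$prob_mlp > threshold
  if (all(c("mean_tc", "max_tc") %in% names(table)))
    table$novel_structure <- table$consensus_active &
      table$mean_tc < mean_cut & table$max_tc < max_cut
  table
}

#' Full screening workflow
#'
#' Predicts the library with all three bundles, excludes consensus-active
#' drugs that are structurally identical (by canonical key) to a member of
#' the approved-antibacterial reference, runs the novelty screen on the
#' remainder, and, when scaffolds are supplied, the core-scaffold MCS
#' screen. A drug is `scaffold_free` when no scaffold match has an overlap
#' coefficient strictly greater than `overlap_cut`.
#'
#' @param bundles named list of `model_bundle`s.
#' @param library a `drug_library`.
#' @param reference data.frame with column `smiles` (approved antibacterial
#'   drugs), or character vector of SMILES.
#' @param scaffolds optional data.frame with columns `id`, `smiles`, or
#'   named list of `molecule`s; `NULL` skips the scaffold screen.
#' @param threshold consensus probability threshold (default 0.5).
#' @param mean_cut,max_cut novelty thresholds (defaults 0.1 and 0.2).
#' @param overlap_cut scaffold high-similarity threshold (default 0.9).
#' @return object of class `screen_report`: `predictions`, `novelty`,
#'   `scaffold_matches` data.frames and a `counts` list (per-model counts,
#'   consensus count, reference overlap, novelty and scaffold tallies).
#' @export
full_screen <- function(bundles, library, reference, scaffolds = NULL,
                        threshold = 0.5, mean_cut = 0.1, max_cut = 0.2,
                        overlap_cut = 0.9) {
  stopifnot(inherits(library, "drug_library"))
  if (is.data.frame(reference)) reference <- reference$smiles
  if (length(reference) == 0L)
    stop("empty approved-antibacterial reference set", call. = FALSE)
  ref_mols <- lapply(reference, parse_smiles)
  fp <- library$feature_params
  ref_fps <- lapply(ref_mols, function(m) {
    if (fp$family == "path") path_fingerprint(m, fp$max_path_len, fp$n_bits)
    else circular_fingerprint(m, fp$radius, fp$n_bits)
  })
  ref_keys <- vapply(ref_mols, canonical_key, character(1))

  predictions <- predict_library(bundles, library, threshold = threshold)
  consensus_ids <- predictions$drug_id[predictions$consensus_active]
  in_reference <- library$drugs$key[match(consensus_ids,
                                          library$drugs$drug_id)] %in% ref_keys
  candidate_ids <- consensus_ids[!in_reference]

  cand_idx <- match(candidate_ids, library$drugs$drug_id)
  cand_fps <- library$fingerprints[cand_idx]
  names(cand_fps) <- candidate_ids
  novelty <- novelty_screen(cand_fps, ref_fps, mean_cut = mean_cut,
                            max_cut = max_cut)

  scaffold_matches <- NULL
  scaffold_free_count <- NA_integer_
  high_overlap_count <- NA_integer_
  if (!is.null(scaffolds) && NROW(scaffolds) > 0L) {
    if (is.data.frame(scaffolds)) {
      sc <- lapply(scaffolds$smiles, parse_smiles)
      names(sc) <- scaffolds$id
      scaffolds <- sc
    }
    rows <- lapply(candidate_ids, function(id) {
      drug <- parse_smiles(library$drugs$smiles[library$drugs$drug_id == id])
      cbind(drug_id = id,
            scaffold_screen(drug, scaffolds, overlap_cut = overlap_cut))
    })
    scaffold_matches <- do.call(rbind, rows)
    if (!is.null(scaffold_matches) && nrow(scaffold_matches) > 0L) {
      by_drug <- tapply(scaffold_matches$is_high_similarity,
                        scaffold_matches$drug_id, any)
      scaffold_free_count <- sum(!by_drug)
      high_overlap_count <- sum(by_drug)
    }
  }

  per_model <- vapply(names(bundles), function(m)
    sum(predictions[[paste0("active_", m)]]), integer(1))
  counts <- list(
    n_library = nrow(library$drugs),
    per_model = as.list(per_model),
    consensus_active = length(consensus_ids),
    consensus_in_reference = sum(in_reference),
    novel_candidates = length(candidate_ids),
    novel_structure = sum(novelty$novel_structure),
    low_similarity_bucket = sum(novelty$low_similarity_bucket),
    scaffold_free = scaffold_free_count,
    scaffold_high_overlap = high_overlap_count
  )
  structure(
    list(predictions = predictions, novelty = novelty,
         scaffold_matches = scaffold_matches, counts = counts,
         thresholds = list(consensus = threshold, novelty_mean = mean_cut,
                           novelty_max = max_cut, overlap = overlap_cut)),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    paste0("<screen_report> %d drugs screened; per-model active: %s; ",
           "consensus %d (%d known antibacterials); novel candidates %d, ",
           "structurally novel %d\n"),
    c$n_library,
    paste(sprintf("%s %d", names(c$per_model), unlist(c$per_model)),
          collapse = ", "),
    c$consensus_active, c$consensus_in_reference, c$novel_candidates,
    c$novel_structure))
  invisible(x)
}
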
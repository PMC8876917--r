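# Benchmark construction: IC50 cutoff labelling, the three cleaning steps
# (deduplicate; molecular weight > 1000 Da; cross-class fingerprint
# similarity > 0.9), and balanced negative resampling (every IC50-bearing
# inactive in every set, topped up from label-only inactives, repeated
# n_repeats times).

#' Label an activity record
#'
#' A compound is active when its IC50 is strictly below `cutoff` (10 umol/L
#' by default); it is inactive when the IC50 is at or above the cutoff, or
#' when it carries only an inactive label. An IC50 exactly at the cutoff is
#' inactive (the active class is defined strictly below the cutoff).
#'
#' @param ic50 IC50 in umol/L, or `NA` when only a label is available.
#' @param inactive_label logical; `TRUE` when the record carries an inactive
#'   flag instead of a measurement.
#' @param cutoff activity cutoff in umol/L (default 10).
#' @return `"active"` or `"inactive"` (vectorized).
#' @export
label_activity <- function(ic50, inactive_label = FALSE, cutoff = 10) {
  n <- max(length(ic50), length(inactive_label))
  ic50 <- rep_len(ic50, n)
  inactive_label <- rep_len(inactive_label, n)
  if (any(is.na(ic50) & !inactive_label))
    stop("record with neither an IC50 value nor an inactive label",
         call. = FALSE)
  if (any(!is.na(ic50) & ic50 <= 0))
    stop("IC50 must be positive", call. = FALSE)
  ifelse(!is.na(ic50) & ic50 < cutoff, "active", "inactive")
}

.as_activity_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("compound_id", "smiles")
  if (!all(need %in% names(records)))
    stop("records need columns compound_id and smiles", call. = FALSE)
  if (is.null(records$ic50_umol)) records$ic50_umol <- NA_real_
  if (is.null(records$inactive)) records$inactive <- 0L
  records$compound_id <- as.character(records$compound_id)
  records$smiles <- as.character(records$smiles)
  records$ic50_umol <- as.numeric(records$ic50_umol)
  records$inactive <- as.integer(records$inactive)
  records
}

#' Clean raw activity records into positive and negative compound sets
#'
#' Applies, in order: (1) structural deduplication by canonical key (first
#' record kept; a duplicate group whose records disagree on the activity
#' label is removed entirely and logged as a conflict); (2) removal of
#' compounds with molecular weight strictly greater than `max_mw`;
#' (3) removal of every inactive compound whose path-fingerprint Tanimoto
#' similarity to any active compound is strictly greater than `cross_sim`
#' (actives, the scarce class, are preserved). Unparseable SMILES are
#' skipped and logged, never silently dropped. Re-running on the output is a
#' no-op.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `ic50_umol` (NA allowed), `inactive` (0/1).
#' @param cutoff IC50 activity cutoff in umol/L (default 10).
#' @param max_mw molecular-weight ceiling in Da (default 1000, strict >).
#' @param cross_sim cross-class similarity ceiling (default 0.9, strict >).
#' @param n_bits,max_path_len path-fingerprint parameters for step 3.
#' @return list with `positives` and `negatives` (data.frames with added
#'   `key`, `mw`, `label` columns) and `provenance` (named removal counts:
#'   `n_input`, `parse_skipped`, `dedup_removed`, `conflict_removed`,
#'   `mw_removed`, `cross_removed`, `n_positives`, `n_negatives`).
#' @export
clean_compounds <- function(records, cutoff = 10, max_mw = 1000,
                            cross_sim = 0.9, n_bits = 1024L,
                            max_path_len = 7L) {
  records <- .as_activity_records(records)
  n_input <- nrow(records)

  mols <- lapply(records$smiles, function(s)
    tryCatch(parse_smiles(s), error = function(e) NULL))
  parsed <- !vapply(mols, is.null, logical(1))
  skipped <- records[!parsed, , drop = FALSE]
  records <- records[parsed, , drop = FALSE]
  mols <- mols[parsed]

  records$key <- vapply(mols, canonical_key, character(1))
  records$mw <- vapply(mols, molecular_weight, numeric(1))
  records$label <- label_activity(records$ic50_umol,
                                  records$inactive == 1L, cutoff)

  # step 1: deduplicate by canonical key; conflicting labels remove the group
  dedup_removed <- 0L
  conflict_removed <- 0L
  keep <- logical(nrow(records))
  for (grp in split(seq_len(nrow(records)), records$key)) {
    labs <- unique(records$label[grp])
    if (length(labs) > 1L) {
      conflict_removed <- conflict_removed + length(grp)
    } else {
      keep[grp[1L]] <- TRUE
      dedup_removed <- dedup_removed + length(grp) - 1L
    }
  }
  mols <- mols[keep]
  records <- records[keep, , drop = FALSE]

  # step 2: molecular weight filter (strictly greater than max_mw)
  heavy <- records$mw > max_mw
  mw_removed <- sum(heavy)
  mols <- mols[!heavy]
  records <- records[!heavy, , drop = FALSE]

  # step 3: cross-class similarity; remove the inactive member of any
  # active/inactive pair with Tanimoto > cross_sim
  is_pos <- records$label == "active"
  cross_removed <- 0L
  if (any(is_pos) && any(!is_pos)) {
    fps <- lapply(mols, path_fingerprint, max_path_len = max_path_len,
                  n_bits = n_bits)
    pos_fps <- fps[is_pos]
    neg_idx <- which(!is_pos)
    drop_neg <- vapply(neg_idx, function(i) {
      for (pf in pos_fps) if (tanimoto(fps[[i]], pf) > cross_sim) return(TRUE)
      FALSE
    }, logical(1))
    cross_removed <- sum(drop_neg)
    drop <- rep(FALSE, nrow(records))
    drop[neg_idx[drop_neg]] <- TRUE
    records <- records[!drop, , drop = FALSE]
    is_pos <- records$label == "active"
  }

  rownames(records) <- NULL
  positives <- records[is_pos, , drop = FALSE]
  negatives <- records[!is_pos, , drop = FALSE]
  rownames(positives) <- NULL
  rownames(negatives) <- NULL

  list(
    positives = positives,
    negatives = negatives,
    provenance = list(
      n_input = n_input,
      parse_skipped = nrow(skipped),
      skipped_ids = skipped$compound_id,
      dedup_removed = dedup_removed,
      conflict_removed = conflict_removed,
      mw_removed = mw_removed,
      cross_removed = cross_removed,
      n_positives = nrow(positives),
      n_negatives = nrow(negatives)
    )
  )
}

#' Resample balanced negative sets
#'
#' Each of `n_repeats` sets contains every IC50-bearing negative plus a
#' without-replacement random sample of label-only negatives, topped up to
#' `n_target` compounds; sets differ only in the sampled portion and are
#' fully reproducible from `seed`.
#'
#' @param negatives data.frame of negative records (as returned by
#'   [clean_compounds()]): label-only negatives are rows with `NA` in
#'   `ic50_umol`.
#' @param n_target target set size (normally the positive-set size).
#' @param n_repeats number of sets (default 10).
#' @param seed integer seed.
#' @return list of `n_repeats` data.frames.
#' @export
sample_negatives <- function(negatives, n_target, n_repeats = 10L, seed = 1L) {
  stopifnot(is.data.frame(negatives), n_target >= 1L, n_repeats >= 1L)
  fixed <- negatives[!is.na(negatives$ic50_umol), , drop = FALSE]
  pool <- negatives[is.na(negatives$ic50_umol), , drop = FALSE]
  need <- n_target - nrow(fixed)
  if (need < 0L)
    stop(sprintf("n_target (%d) is below the number of IC50-bearing negatives (%d)",
                 n_target, nrow(fixed)), call. = FALSE)
  if (need > nrow(pool))
    stop(sprintf(paste0("insufficient label-only negatives: need %d more to ",
                        "reach %d but only %d are available"),
                 need, n_target, nrow(pool)), call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(k) {
      take <- if (need > 0L) sample.int(nrow(pool), need) else integer(0)
      out <- rbind(fixed, pool[take, , drop = FALSE])
      rownames(out) <- NULL
      out
    })
  })
}

#' Build the benchmark dataset
#'
#' Runs [clean_compounds()] and [sample_negatives()], then featurizes every
#' surviving compound with the configured fingerprint. The result holds the
#' positive set, the resampled negative sets, the feature matrix (rows keyed
#' by compound id) and the cleaning provenance.
#'
#' @inheritParams clean_compounds
#' @param n_repeats number of negative sets (default 10).
#' @param seed integer seed for negative resampling.
#' @param family fingerprint family (`"path"` or `"circular"`).
#' @param radius circular-fingerprint radius.
#' @return object of class `benchmark_dataset`.
#' @export
build_benchmark <- function(records, cutoff = 10, max_mw = 1000,
                            cross_sim = 0.9, n_repeats = 10L, seed = 1L,
                            family = "path", n_bits = 1024L,
                            max_path_len = 7L, radius = 2L) {
  cleaned <- clean_compounds(records, cutoff = cutoff, max_mw = max_mw,
                             cross_sim = cross_sim, n_bits = n_bits,
                             max_path_len = max_path_len)
  if (nrow(cleaned$positives) == 0L)
    stop("no positive compounds survive cleaning", call. = FALSE)
  negative_sets <- sample_negatives(cleaned$negatives,
                                    n_target = nrow(cleaned$positives),
                                    n_repeats = n_repeats, seed = seed)
  all_df <- rbind(cleaned$positives, cleaned$negatives)
  fps <- fingerprints_for(all_df$smiles, family = family, n_bits = n_bits,
                          max_path_len = max_path_len, radius = radius)
  features <- fingerprint_matrix(fps, row_names = all_df$compound_id)
  structure(
    list(
      positives = cleaned$positives,
      negative_sets = negative_sets,
      features = features,
      feature_params = list(family = family, n_bits = as.integer(n_bits),
                            max_path_len = as.integer(max_path_len),
                            radius = as.integer(radius)),
      provenance = cleaned$provenance,
      seed = as.integer(seed)
    ),
    class = "benchmark_dataset"
  )
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("<benchmark_dataset> %d positives, %d negative sets of %d (%s fingerprints, %d bits)\n",
              nrow(x$positives), length(x$negative_sets),
              nrow(x$negative_sets[[1L]]), x$feature_params$family,
              x$feature_params$n_bits))
  invisible(x)
}

# evaluate the rng-protected expression under a fixed seed
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
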
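# File I/O, pipeline configuration and the end-to-end workflow:
# build-benchmark -> train -> screen -> novelty, each stage writing its
# artifact and a structured log line with counts.

#' Read a .smi file
#'
#' One SMILES per line, optionally followed by a whitespace-separated id.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return data.frame with columns `smiles` and `id` (NA when absent).
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p)
      if (length(p) > 1L) paste(p[-1L], collapse = " ") else NA_character_,
      character(1)),
    stringsAsFactors = FALSE)
}

#' Read molecules from an SDF (V2000) file
#'
#' Minimal reader for the V2000 connection table: element symbols, bond
#' orders (4 = aromatic), and `M  CHG` formal charges. Coordinates and all
#' other properties are ignored; implicit hydrogens are assigned by the
#' same default-valence model as [parse_smiles()] (aromatic flags are taken
#' from aromatic bonds).
#'
#' @param path file path.
#' @return list of `molecule`s, named by the record title line when present.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0L, utils::head(lines == "$$$$", -1L))))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L) next
    counts <- rec[4L]
    na <- as.integer(substr(counts, 1L, 3L))
    nb <- as.integer(substr(counts, 4L, 6L))
    if (is.na(na) || na < 1L) next
    atom_lines <- rec[5L:(4L + na)]
    element <- trimws(substr(atom_lines, 32L, 34L))
    bonds <- if (nb > 0L) {
      bl <- rec[(5L + na):(4L + na + nb)]
      data.frame(a = as.integer(substr(bl, 1L, 3L)),
                 b = as.integer(substr(bl, 4L, 6L)),
                 code = as.integer(substr(bl, 7L, 9L)))
    } else data.frame(a = integer(0), b = integer(0), code = integer(0))
    aromatic <- logical(na)
    if (nrow(bonds) > 0L) {
      ar <- bonds$code == 4L
      aromatic[c(bonds$a[ar], bonds$b[ar])] <- TRUE
    }
    charge <- integer(na)
    for (ml in grep("^M  CHG", rec, value = TRUE)) {
      f <- as.integer(strsplit(trimws(substring(ml, 7L)), "[[:space:]]+")[[1]])
      n <- f[1L]
      for (k in seq_len(n)) charge[f[2L * k]] <- f[2L * k + 1L]
    }
    order <- ifelse(bonds$code == 4L, 1.5, bonds$code)
    bad <- !element %in% names(.ATOMIC_WEIGHTS)
    if (any(bad))
      stop("unsupported element in SDF record: ", element[bad][1L],
           call. = FALSE)
    # implicit H by the organic-subset valence model where applicable
    bond_sum <- numeric(na)
    arom_cnt <- integer(na)
    for (k in seq_len(nrow(bonds))) {
      for (e in c(bonds$a[k], bonds$b[k])) {
        if (order[k] == 1.5) arom_cnt[e] <- arom_cnt[e] + 1L
        else bond_sum[e] <- bond_sum[e] + order[k]
      }
    }
    implicit_h <- integer(na)
    for (i in seq_len(na)) {
      if (!element[i] %in% names(.VALENCES) || charge[i] != 0L) next
      implicit_h[i] <- .implicit_h_count(element[i], aromatic[i],
                                         bond_sum[i], arom_cnt[i])
    }
    atoms <- data.frame(element = element, aromatic = aromatic,
                        charge = charge, implicit_h = implicit_h,
                        stringsAsFactors = FALSE)
    mol <- new_molecule(atoms,
                        data.frame(a = bonds$a, b = bonds$b, order = order))
    out[[length(out) + 1L]] <- mol
    names(out)[length(out)] <- trimws(rec[1L])
  }
  out
}

#' Pipeline configuration
#'
#' All workflow constants in one place, with the reference analysis values
#' as defaults: IC50 cutoff 10 umol/L; benchmark weight filter > 1000 Da and
#' library weight filter >= 1000 Da; cross-class similarity ceiling 0.9;
#' 10 negative sets; 80/20 split with 5-fold CV; consensus threshold 0.5;
#' novelty thresholds mean < 0.1 and max < 0.2; scaffold overlap threshold
#' 0.9. Fingerprints are path fingerprints folded to 512 bits (the package's
#' desk-scale default; see the methods vignette).
#'
#' @param paths named list of input/output paths (`activity`, `library`,
#'   `reference`, `scaffolds`, `output`).
#' @param fingerprint named list: `family`, `n_bits`, `max_path_len`,
#'   `radius`.
#' @param cutoff IC50 cutoff in umol/L.
#' @param filters named list: `benchmark_max_mw`, `library_max_mw`,
#'   `cross_sim`.
#' @param cv named list: `k`, `n_repeats`, `test_frac`.
#' @param models named list per method: chosen hyperparameters used for
#'   training (grids come from [default_grid()] when grid search is
#'   requested).
#' @param thresholds named list: `consensus`, `novelty_mean`, `novelty_max`,
#'   `overlap`.
#' @param seed integer master seed; all pipeline randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(),
                            fingerprint = list(family = "path",
                                               n_bits = 512L,
                                               max_path_len = 7L,
                                               radius = 2L),
                            cutoff = 10,
                            filters = list(benchmark_max_mw = 1000,
                                           library_max_mw = 1000,
                                           cross_sim = 0.9),
                            cv = list(k = 5L, n_repeats = 10L,
                                      test_frac = 0.2),
                            models = list(
                              svm = list(gamma = 0.01, cost = 10),
                              rf = list(n_estimators = 750L),
                              mlp = list(hidden = 4L, alpha = 1e-4,
                                         maxit = 100L)),
                            thresholds = list(consensus = 0.5,
                                              novelty_mean = 0.1,
                                              novelty_max = 0.2,
                                              overlap = 0.9),
                            seed = 1L) {
  stopifnot(thresholds$consensus > 0, thresholds$consensus < 1,
            thresholds$novelty_mean >= 0, thresholds$novelty_max <= 1,
            thresholds$overlap > 0, thresholds$overlap <= 1,
            cv$test_frac > 0, cv$test_frac < 1)
  structure(list(paths = paths, fingerprint = fingerprint, cutoff = cutoff,
                 filters = filters, cv = cv, models = models,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration
#'
#' JSON round-trip: `config_to_json(parse_config(x))` is byte-identical to
#' `config_to_json(cfg)`.
#'
#' @param cfg a [pipeline_config()].
#' @return JSON string.
#' @export
config_to_json <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, pretty = TRUE,
                   digits = NA)
}

#' @rdname config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
parse_config <- function(json) {
  if (length(json) == 1L && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

.log_stage <- function(stage, ...) {
  kv <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(sprintf("%s=%s", names(kv), unlist(kv)),
                        collapse = " ")))
}

#' Run the full screening pipeline
#'
#' Executes build-benchmark -> train -> screen -> novelty in order on the
#' input files named in `cfg$paths` (activity CSV, library CSV or .smi,
#' reference .smi, optional scaffolds .smi), writing `predictions.csv`,
#' `novelty.csv`, `scaffolds.csv`, `metrics.csv`, `provenance.json` and
#' `report.json` into `cfg$paths$output`. Reruns with an identical
#' configuration reproduce all outputs byte-identically.
#'
#' @param cfg a [pipeline_config()] with `paths` set.
#' @param study logical; also run [benchmark_study()] and write the metric
#'   panel (default TRUE).
#' @return the `screen_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, study = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c("activity", "library", "reference")) {
    if (is.null(cfg$paths[[p]]))
      stop("cfg$paths$", p, " is not set", call. = FALSE)
    if (!file.exists(cfg$paths[[p]]))
      stop("input file not found: ", cfg$paths[[p]], call. = FALSE)
  }
  out_dir <- cfg$paths$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- cfg$fingerprint

  # stage 1: benchmark
  records <- utils::read.csv(cfg$paths$activity, stringsAsFactors = FALSE)
  benchmark <- build_benchmark(
    records, cutoff = cfg$cutoff, max_mw = cfg$filters$benchmark_max_mw,
    cross_sim = cfg$filters$cross_sim, n_repeats = cfg$cv$n_repeats,
    seed = cfg$seed, family = fp$family, n_bits = fp$n_bits,
    max_path_len = fp$max_path_len, radius = fp$radius)
  .log_stage("benchmark",
             input = benchmark$provenance$n_input,
             positives = benchmark$provenance$n_positives,
             negatives = benchmark$provenance$n_negatives,
             sets = length(benchmark$negative_sets))
  jsonlite::write_json(benchmark$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 2: train (and optionally evaluate)
  specs <- lapply(names(cfg$models), function(m)
    model_spec(m, chosen = cfg$models[[m]]))
  names(specs) <- names(cfg$models)
  metrics_summary <- NULL
  if (study) {
    report <- benchmark_study(benchmark, specs,
                              test_frac = cfg$cv$test_frac, k = cfg$cv$k,
                              seed = cfg$seed)
    metrics_summary <- report$summary
    utils::write.csv(report$summary, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    for (m in names(specs))
      .log_stage("study", method = m,
                 mean_accuracy = sprintf("%.3f", mean(
                   report$per_run$accuracy[report$per_run$method == m])))
  }
  bundles <- lapply(specs, function(sp)
    train_final(benchmark, sp, seed = cfg$seed))
  .log_stage("train", methods = paste(names(bundles), collapse = ","),
             fits_per_method = length(benchmark$negative_sets))

  # stage 3: screen
  lib_raw <- if (grepl("\\.smi$", cfg$paths$library)) {
    smi <- read_smi(cfg$paths$library)
    data.frame(drug_id = ifelse(is.na(smi$id),
                                sprintf("DRUG%04d", seq_len(nrow(smi))),
                                smi$id),
               smiles = smi$smiles, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(cfg$paths$library, stringsAsFactors = FALSE)
  }
  library <- prepare_library(lib_raw, max_mw = cfg$filters$library_max_mw,
                             family = fp$family, n_bits = fp$n_bits,
                             max_path_len = fp$max_path_len,
                             radius = fp$radius)
  .log_stage("library", input = library$log$n_input,
             retained = library$log$n_retained,
             mw_removed = library$log$mw_removed)
  reference <- read_smi(cfg$paths$reference)
  scaffolds <- NULL
  if (!is.null(cfg$paths$scaffolds) && file.exists(cfg$paths$scaffolds)) {
    sc <- read_smi(cfg$paths$scaffolds)
    scaffolds <- data.frame(id = ifelse(is.na(sc$id),
                                        sprintf("S%02d", seq_len(nrow(sc))),
                                        sc$id),
                            smiles = sc$smiles, stringsAsFactors = FALSE)
  }

  # stage 4: consensus + novelty + scaffold screen
  screen <- full_screen(bundles, library, reference$smiles,
                        scaffolds = scaffolds,
                        threshold = cfg$thresholds$consensus,
                        mean_cut = cfg$thresholds$novelty_mean,
                        max_cut = cfg$thresholds$novelty_max,
                        overlap_cut = cfg$thresholds$overlap)
  .log_stage("screen", consensus = screen$counts$consensus_active,
             novel_candidates = screen$counts$novel_candidates,
             novel_structure = screen$counts$novel_structure)

  utils::write.csv(screen$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$novelty, file.path(out_dir, "novelty.csv"),
                   row.names = FALSE)
  if (!is.null(screen$scaffold_matches))
    utils::write.csv(screen$scaffold_matches,
                     file.path(out_dir, "scaffolds.csv"), row.names = FALSE)
  report_json <- list(counts = screen$counts,
                      thresholds = screen$thresholds,
                      provenance = benchmark$provenance,
                      seed = cfg$seed)
  if (!is.null(metrics_summary)) report_json$metrics <- metrics_summary
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(screen)
}
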
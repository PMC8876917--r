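# Synthetic molecule corpora with planted ground truth. Molecules are built
# by decorating scaffold templates with randomly grown substituent chains,
# which guarantees parseability, a controllable scaffold signal, and
# MCS-verifiable scaffold containment. Accidental structural duplicates are
# rejected at generation time (canonical-key uniqueness), so the planted
# violations are exactly the ones counted in the truth table.
#
# Statistical structure the corpus emulates:
#   * two aromatic bicyclic active families (naphthalene / quinoline) that
#     always carry an amide pharmacophore motif, plus one aliphatic
#     sulfur-decorated active family with no motif -- the latter stands for
#     actives outside the approved-drug chemical space, exactly as a
#     diverse bioactivity extract backs the prediction of drugs unlike any
#     approved antibacterial;
#   * IC50-bearing and label-only inactives are mono-aromatic (benzene /
#     pyridine) and never carry nitrogen substituents, but do carry a
#     carbonyl decoy (ester or ketone) so carbonyl fragments alone do not
#     separate the classes;
#   * label-only inactives vastly outnumber IC50-bearing ones (the class
#     imbalance motif);
#   * active and inactive IC50s are log-normal and straddle the 10 umol/L
#     cutoff from opposite sides;
#   * planted violations (exact duplicates, conflicting label pairs,
#     >1000 Da compounds, cross-class near-duplicates) exercise each
#     cleaning step;
#   * the drug library mixes scaffold-bearing actives (reference family),
#     actives on an unseen aliphatic ring (the planted structurally-novel
#     candidates) and inactive-family decoys.

.ACTIVE_MOTIF <- "C(=O)NC"                   # amide pharmacophore of the
                                             # aromatic active families
.INACTIVE_DECOYS <- c("C(=O)OC", "C(=O)C")   # carbonyl decoys, no N
# reference drugs are fully decorated and avoid plain alkyl chains, so
# their bit overlap with aliphatic-ring molecules is negligible
.REFERENCE_POOL <- c("C", "O", "OC", "F", "Cl", "OCO", "C(F)(F)F", "OC(F)F")

# random substituent: a 0-4 atom C/hetero chain, never two heteroatoms in a
# row, optionally halogen-terminated when it ends in carbon
.random_sub <- function(hetero = "O", halos = c("F", "Cl"), p_hetero = 0.3,
                        p_halo = 0.3) {
  k <- sample(0:4, 1L)
  if (k == 0L) return("")
  units <- character(k)
  prev_het <- TRUE                      # attachment-adjacent heteroatom ok,
  for (i in seq_len(k)) {               # but never two in a row
    het <- !prev_het && stats::runif(1) < p_hetero
    units[i] <- if (het) hetero else "C"
    prev_het <- het
  }
  out <- paste(units, collapse = "")
  if (length(halos) > 0L && units[k] == "C" && stats::runif(1) < p_halo)
    out <- paste0(out, sample(halos, 1L))
  out
}

.sub_shared <- function() .random_sub("O", c("F", "Cl"))
.sub_sulfur <- function() .random_sub("S", character(0))
.sub_reference <- function() sample(.REFERENCE_POOL, 1L)

# Scaffold families. Each entry: SMILES template with {s} substituent
# slots, undecorated core, substituent generator, and whether molecules of
# the family carry the class motif.
.SCAFFOLDS <- list(
  active = list(
    naphthalene = list(template = "c1cc{s}c2cc{s}cc{s}c2c1",
                       core = "c1ccc2ccccc2c1",
                       sub_fun = .sub_shared, use_motif = TRUE),
    quinoline = list(template = "c1cc{s}c2nc{s}cc{s}c2c1",
                     core = "c1ccc2ncccc2c1",
                     sub_fun = .sub_shared, use_motif = TRUE),
    cyclohexane = list(template = "C1C{s}CC{s}CC1{s}", core = "C1CCCCC1",
                       sub_fun = .sub_sulfur, use_motif = FALSE)
  ),
  inactive = list(
    benzene = list(template = "c1c{s}cc{s}cc1{s}", core = "c1ccccc1",
                   sub_fun = .sub_shared, use_motif = TRUE),
    pyridine = list(template = "c1c{s}cc{s}nc1{s}", core = "c1ccncc1",
                    sub_fun = .sub_shared, use_motif = TRUE)
  ),
  novel = list(
    cycloheptane = list(template = "C1C{s}CC{s}CC{s}C1", core = "C1CCCCCC1",
                        sub_fun = .sub_sulfur, use_motif = FALSE)
  )
)

# the approved-antibacterial reference family and its core scaffolds: the
# two aromatic bicyclic active families only
.REFERENCE_SCAFFOLDS <- c("naphthalene", "quinoline")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic corpus configuration
#'
#' Defaults define the package's desk-scale study conditions: about 1200
#' activity records with the label-only inactives outnumbering IC50-bearing
#' ones, log-normal IC50s straddling the 10 umol/L cutoff (actives: median
#' 1 umol/L; inactives: median 100 umol/L; both sigma_log 0.5 on the
#' natural log scale), a handful of planted cleaning violations, and a
#' 120-drug library with 10 planted novel actives.
#'
#' @param n_active number of active records.
#' @param n_inactive_ic50 number of IC50-bearing inactive records.
#' @param n_inactive_label_only number of label-only inactive records.
#' @param n_library drug-library size.
#' @param n_scaffold_actives_in_library library drugs decorated from the
#'   reference scaffold families (consensus-active and scaffold-matched by
#'   construction).
#' @param n_novel_actives_in_library library drugs on the unseen aliphatic
#'   family (planted structurally-novel candidates).
#' @param n_reference size of the approved-antibacterial reference set
#'   (reference-family molecules).
#' @param planted list of planted violation counts: `n_duplicates`,
#'   `n_heavy`, `n_cross_similar`, `n_label_conflicts`.
#' @param ic50_active,ic50_inactive lists with `median` (umol/L) and
#'   `sigma_log` (natural-log scale).
#' @param cutoff activity cutoff in umol/L.
#' @param seed integer seed; identical configurations generate identical
#'   corpora.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_active = 260L, n_inactive_ic50 = 200L,
                             n_inactive_label_only = 700L,
                             n_library = 120L,
                             n_scaffold_actives_in_library = 20L,
                             n_novel_actives_in_library = 10L,
                             n_reference = 25L,
                             planted = list(n_duplicates = 3L, n_heavy = 2L,
                                            n_cross_similar = 3L,
                                            n_label_conflicts = 2L),
                             ic50_active = list(median = 1, sigma_log = 0.5),
                             ic50_inactive = list(median = 100,
                                                  sigma_log = 0.5),
                             cutoff = 10,
                             seed = 1L) {
  cfg <- list(n_active = as.integer(n_active),
              n_inactive_ic50 = as.integer(n_inactive_ic50),
              n_inactive_label_only = as.integer(n_inactive_label_only),
              n_library = as.integer(n_library),
              n_scaffold_actives_in_library =
                as.integer(n_scaffold_actives_in_library),
              n_novel_actives_in_library =
                as.integer(n_novel_actives_in_library),
              n_reference = as.integer(n_reference),
              planted = lapply(planted, as.integer),
              ic50_active = ic50_active, ic50_inactive = ic50_inactive,
              cutoff = cutoff, seed = as.integer(seed))
  counts <- c(unlist(cfg[c("n_active", "n_inactive_ic50",
                           "n_inactive_label_only", "n_library",
                           "n_scaffold_actives_in_library",
                           "n_novel_actives_in_library", "n_reference")]),
              unlist(cfg$planted))
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$n_scaffold_actives_in_library + cfg$n_novel_actives_in_library >
      cfg$n_library)
    stop("library composition exceeds n_library", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# instantiate a scaffold template: the motif (if any) goes into one random
# slot, remaining slots are grown by the substituent generator
.decorate <- function(template, motif, sub_fun) {
  n_slots <- lengths(regmatches(template, gregexpr("\\{s\\}", template)))
  subs <- vapply(seq_len(n_slots), function(i) sub_fun(), character(1))
  if (!is.null(motif)) subs[sample.int(n_slots, 1L)] <- motif
  for (s in subs) {
    rep <- if (nzchar(s)) paste0("(", s, ")") else ""
    template <- sub("\\{s\\}", rep, template)
  }
  template
}

# draw n structurally distinct molecules from a scaffold family; `seen` is
# an environment of canonical keys already used (updated in place)
.sample_family <- function(n, family, motif_fun, seen,
                           subset = NULL, sub_fun = NULL,
                           max_tries = 200L) {
  if (n == 0L) {
    out <- character(0)
    attr(out, "scaffold_id") <- character(0)
    return(out)
  }
  scs <- .SCAFFOLDS[[family]]
  if (!is.null(subset)) scs <- scs[subset]
  picks <- sample(names(scs), n, replace = TRUE)
  smiles <- character(n)
  for (i in seq_len(n)) {
    sc <- scs[[picks[i]]]
    for (try in seq_len(max_tries)) {
      cand <- .decorate(sc$template,
                        motif = if (sc$use_motif) motif_fun() else NULL,
                        sub_fun = sub_fun %||% sc$sub_fun)
      key <- canonical_key(parse_smiles(cand))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        smiles[i] <- cand
        break
      }
      if (try == max_tries)
        stop("could not grow enough distinct molecules; ",
             "requested counts exceed what the decoration grammar supports",
             call. = FALSE)
    }
  }
  attr(smiles, "scaffold_id") <- picks
  smiles
}

.rlnorm_ic50 <- function(n, spec) {
  stats::rlnorm(n, meanlog = log(spec$median), sdlog = spec$sigma_log)
}

#' Generate a synthetic activity corpus
#'
#' Builds activity records (actives and inactives with the structure
#' described in [generator_config()]) plus the configured planted
#' violations, and a ground-truth table recording every record's class,
#' scaffold and planted role. All regular records are structurally distinct
#' by canonical key, so the cleaning filters remove exactly the planted
#' violations. Output is identical for identical configurations.
#'
#' @param cfg a [generator_config()].
#' @return list with `records` (data.frame: `compound_id`, `smiles`,
#'   `ic50_umol`, `inactive`) and `truth` (data.frame: `compound_id`,
#'   `class`, `scaffold_id`, `role`).
#' @export
generate_activity_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    seen <- new.env(parent = emptyenv())
    act <- .sample_family(cfg$n_active, "active",
                          function() .ACTIVE_MOTIF, seen)
    ina <- .sample_family(cfg$n_inactive_ic50, "inactive",
                          function() sample(.INACTIVE_DECOYS, 1L), seen)
    lab <- .sample_family(cfg$n_inactive_label_only, "inactive",
                          function() sample(.INACTIVE_DECOYS, 1L), seen)

    records <- data.frame(
      compound_id = c(sprintf("ACT%04d", seq_len(cfg$n_active)),
                      sprintf("INA%04d", seq_len(cfg$n_inactive_ic50)),
                      sprintf("LAB%04d", seq_len(cfg$n_inactive_label_only))),
      smiles = c(act, ina, lab),
      ic50_umol = c(.rlnorm_ic50(cfg$n_active, cfg$ic50_active),
                    .rlnorm_ic50(cfg$n_inactive_ic50, cfg$ic50_inactive),
                    rep(NA_real_, cfg$n_inactive_label_only)),
      inactive = c(rep(0L, cfg$n_active + cfg$n_inactive_ic50),
                   rep(1L, cfg$n_inactive_label_only)),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      compound_id = records$compound_id,
      class = c(rep("active", cfg$n_active),
                rep("inactive_ic50", cfg$n_inactive_ic50),
                rep("inactive_label", cfg$n_inactive_label_only)),
      scaffold_id = c(attr(act, "scaffold_id"), attr(ina, "scaffold_id"),
                      attr(lab, "scaffold_id")),
      role = "normal", stringsAsFactors = FALSE)

    add <- function(rec_rows, truth_rows) {
      records <<- rbind(records, rec_rows)
      truth <<- rbind(truth, truth_rows)
    }

    # exact duplicates: a copy of an existing regular record under a new id
    if (cfg$planted$n_duplicates > 0L) {
      src <- sample.int(nrow(records), cfg$planted$n_duplicates)
      dup <- records[src, , drop = FALSE]
      dup$compound_id <- sprintf("DUP%04d", seq_len(nrow(dup)))
      add(dup, data.frame(compound_id = dup$compound_id,
                          class = truth$class[src],
                          scaffold_id = truth$scaffold_id[src],
                          role = "duplicate", stringsAsFactors = FALSE))
    }

    # conflicting labels: the same structure once active, once label-only
    if (cfg$planted$n_label_conflicts > 0L) {
      n <- cfg$planted$n_label_conflicts
      smi <- .sample_family(n, "active", function() .ACTIVE_MOTIF, seen)
      rec <- data.frame(
        compound_id = c(sprintf("CFA%04d", seq_len(n)),
                        sprintf("CFB%04d", seq_len(n))),
        smiles = c(smi, smi),
        ic50_umol = c(.rlnorm_ic50(n, cfg$ic50_active), rep(NA_real_, n)),
        inactive = c(rep(0L, n), rep(1L, n)), stringsAsFactors = FALSE)
      add(rec, data.frame(compound_id = rec$compound_id,
                          class = rep(c("active", "inactive_label"), each = n),
                          scaffold_id = rep(attr(smi, "scaffold_id"), 2L),
                          role = "conflict", stringsAsFactors = FALSE))
    }

    # heavy compounds: alkyl chains beyond 1000 Da
    if (cfg$planted$n_heavy > 0L) {
      n <- cfg$planted$n_heavy
      rec <- data.frame(
        compound_id = sprintf("HVY%04d", seq_len(n)),
        smiles = vapply(seq_len(n), function(i)
          paste(rep("C", 80L + i), collapse = ""), character(1)),
        ic50_umol = .rlnorm_ic50(n, cfg$ic50_inactive),
        inactive = 0L, stringsAsFactors = FALSE)
      add(rec, data.frame(compound_id = rec$compound_id,
                          class = "inactive_ic50", scaffold_id = "chain",
                          role = "heavy", stringsAsFactors = FALSE))
    }

    # cross-class near-duplicates: an active with a long alkyl tail paired
    # with an IC50-bearing inactive extended by one chain carbon; all paths
    # of up to 7 atoms coincide, so the path fingerprints are identical
    # (Tc = 1) while the canonical keys differ. Tail lengths 7, 9, 11, ...
    # keep the planted pairs structurally distinct from one another.
    if (cfg$planted$n_cross_similar > 0L) {
      n <- cfg$planted$n_cross_similar
      tails <- vapply(seq_len(n), function(i)
        paste(rep("C", 5L + 2L * i), collapse = ""), character(1))
      base <- vapply(seq_len(n), function(i) {
        sc <- .SCAFFOLDS$active[[sample(.REFERENCE_SCAFFOLDS, 1L)]]
        t <- sub("\\{s\\}", paste0("(", .ACTIVE_MOTIF, ")"), sc$template)
        t <- sub("\\{s\\}", paste0("(", tails[i], ")"), t)
        gsub("\\{s\\}", "", t)
      }, character(1))
      twin <- vapply(seq_len(n), function(i)
        sub(paste0("(", tails[i], ")"), paste0("(", tails[i], "C)"),
            base[i], fixed = TRUE), character(1))
      rec <- data.frame(
        compound_id = c(sprintf("XSA%04d", seq_len(n)),
                        sprintf("XSB%04d", seq_len(n))),
        smiles = c(base, twin),
        ic50_umol = c(.rlnorm_ic50(n, cfg$ic50_active),
                      .rlnorm_ic50(n, cfg$ic50_inactive)),
        inactive = 0L, stringsAsFactors = FALSE)
      add(rec, data.frame(compound_id = rec$compound_id,
                          class = rep(c("active", "inactive_ic50"), each = n),
                          scaffold_id = "active_pair",
                          role = rep(c("cross_similar_active",
                                       "cross_similar_inactive"), each = n),
                          stringsAsFactors = FALSE))
    }

    rownames(records) <- NULL
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic drug library, reference set and scaffold list
#'
#' The library mixes (a) actives decorated from the reference scaffold
#' families (consensus-active and scaffold-matched by construction),
#' (b) actives on the unseen aliphatic family (planted structurally-novel
#' candidates) and (c) inactive-family decoys. The reference set emulates
#' approved antibacterial drugs (reference-family molecules); the scaffold
#' list holds the undecorated reference cores.
#'
#' @param cfg a [generator_config()].
#' @return list with `library` (data.frame: `drug_id`, `smiles`), `truth`
#'   (data.frame: `drug_id`, `role`, `scaffold_id`), `reference`
#'   (data.frame: `ref_id`, `smiles`) and `scaffolds` (data.frame: `id`,
#'   `smiles`).
#' @export
generate_drug_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 1L, {
    seen <- new.env(parent = emptyenv())
    n_sc <- cfg$n_scaffold_actives_in_library
    n_nv <- cfg$n_novel_actives_in_library
    n_dc <- cfg$n_library - n_sc - n_nv
    sc <- .sample_family(n_sc, "active", function() .ACTIVE_MOTIF, seen,
                         subset = .REFERENCE_SCAFFOLDS)
    # planted novels: sulfur-decorated aliphatic rings, chemically close to
    # the aliphatic active family the models trained on, but sharing
    # essentially no fragments with the aromatic reference drugs
    nv <- .sample_family(n_nv, "novel", function() NULL, seen)
    dc <- .sample_family(n_dc, "inactive",
                         function() sample(.INACTIVE_DECOYS, 1L), seen)
    library <- data.frame(
      drug_id = sprintf("DRG%04d", seq_len(cfg$n_library)),
      smiles = c(sc, nv, dc), stringsAsFactors = FALSE)
    truth <- data.frame(
      drug_id = library$drug_id,
      role = c(rep("scaffold_active", n_sc), rep("novel_active", n_nv),
               rep("decoy", n_dc)),
      scaffold_id = c(attr(sc, "scaffold_id"), attr(nv, "scaffold_id"),
                      attr(dc, "scaffold_id")),
      stringsAsFactors = FALSE)
    reference <- data.frame(
      ref_id = sprintf("ABX%04d", seq_len(cfg$n_reference)),
      smiles = as.character(
        .sample_family(cfg$n_reference, "active", function() .ACTIVE_MOTIF,
                       seen, subset = .REFERENCE_SCAFFOLDS,
                       sub_fun = .sub_reference)),
      stringsAsFactors = FALSE)
    ref_sc <- .SCAFFOLDS$active[.REFERENCE_SCAFFOLDS]
    scaffolds <- data.frame(
      id = names(ref_sc),
      smiles = vapply(ref_sc, function(s) s$core, character(1)),
      stringsAsFactors = FALSE)
    rownames(scaffolds) <- NULL
    list(library = library, truth = truth, reference = reference,
         scaffolds = scaffolds)
  })
}

#' Write a generated corpus to a directory
#'
#' Writes `activity.csv`, `library.csv`, `reference_abx.smi`,
#' `scaffolds.smi`, `truth.csv` and `library_truth.csv`.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(cfg, dir) {
  corpus <- generate_activity_corpus(cfg)
  lib <- generate_drug_library(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(corpus$records, file.path(dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(lib$library, file.path(dir, "library.csv"),
                   row.names = FALSE)
  utils::write.csv(lib$truth, file.path(dir, "library_truth.csv"),
                   row.names = FALSE)
  writeLines(paste(lib$reference$smiles, lib$reference$ref_id),
             file.path(dir, "reference_abx.smi"))
  writeLines(paste(lib$scaffolds$smiles, lib$scaffolds$id),
             file.path(dir, "scaffolds.smi"))
  invisible(dir)
}
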
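#' Screen peptides by bioactivity score annotations
#'
#' Applies the two screening thresholds of the discovery workflow to
#' externally predicted score columns: peptides are retained when their
#' general bioactivity score meets `general_threshold` (0.7 by default;
#' skipped when no general column is present), and a per-activity flag is
#' set when the specific score meets `specific_threshold` (0.5 by
#' default). Missing scores (NA, or `"-"` in text input) are treated as
#' below threshold. Score columns are inputs from external predictors;
#' this package never computes them.
#'
#' @param peptides Data frame with a `peptide` column, optionally a
#'   general score column, and one numeric column per specific activity.
#' @param general_threshold Minimum general score for retention.
#' @param specific_threshold Minimum specific score for a flag.
#' @param general_col Name of the general score column (ignored when
#'   absent).
#' @param specific_cols Names of the specific score columns (default: all
#'   numeric columns other than the general column).
#' @param merge_groups Optional named list of character vectors; for each
#'   entry a logical column `group_<name>` is added that is TRUE when any
#'   member activity is flagged.
#' @param exclusive_groups Logical; when TRUE the merge groups are target
#'   classes in priority order: each peptide is assigned only to the
#'   first listed group with a firing flag, so the `group_<name>` columns
#'   are disjoint. Use this to reproduce target-class counts in which a
#'   peptide flagged for two receptor classes is assigned to the more
#'   specific one (listed first).
#' @return The retained rows with added logical `flag_<col>` columns (and
#'   `group_<name>` columns when requested).
#' @examples
#' screen_by_scores(candidate_peptides(),
#'   merge_groups = list(ace = c("ace_inhibitory", "antihypertensive")))
#' @export
screen_by_scores <- function(peptides, general_threshold = 0.7,
                             specific_threshold = 0.5,
                             general_col = "general_score",
                             specific_cols = NULL,
                             merge_groups = NULL,
                             exclusive_groups = FALSE) {
  stopifnot(is.data.frame(peptides), "peptide" %in% names(peptides))
  if (general_threshold < 0 || general_threshold > 1 ||
      specific_threshold < 0 || specific_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  as_score <- function(v) {
    if (is.character(v)) v[v %in% c("-", "−", "")] <- NA
    v <- suppressWarnings(as.numeric(v))
    v
  }
  out <- peptides
  if (general_col %in% names(out)) {
    g <- as_score(out[[general_col]])
    if (any(is.na(g) & !is.na(out[[general_col]])))
      stop("malformed general score values")
    g[is.na(g)] <- -Inf
    out <- out[g >= general_threshold, , drop = FALSE]
  }
  if (is.null(specific_cols)) {
    cand <- setdiff(names(out), c("peptide", general_col))
    specific_cols <- cand[vapply(out[cand], function(v)
      is.numeric(v) || is.character(v), logical(1))]
  }
  for (col in specific_cols) {
    if (!col %in% names(out))
      stop(sprintf("score column '%s' not present", col))
    s <- as_score(out[[col]])
    out[[paste0("flag_", col)]] <- !is.na(s) & s >= specific_threshold
  }
  if (!is.null(merge_groups)) {
    assigned <- rep(FALSE, nrow(out))
    for (nm in names(merge_groups)) {
      members <- paste0("flag_", merge_groups[[nm]])
      miss <- setdiff(members, names(out))
      if (length(miss))
        stop(sprintf("merge group '%s' references missing column(s): %s",
                     nm, paste(miss, collapse = ", ")))
      g <- Reduce(`|`, out[members])
      if (exclusive_groups) {
        g <- g & !assigned
        assigned <- assigned | g
      }
      out[[paste0("group_", nm)]] <- g
    }
  }
  rownames(out) <- NULL
  out
}

#' Build a pipeline configuration
#'
#' Validates and normalizes the configuration consumed by
#' [run_pipeline()]. All paths are checked at validation time.
#'
#' @param fasta Path to the input FASTA file.
#' @param rules Path to a protease rule TSV, or a list of
#'   [protease_rule()] objects (default: the shipped rule table).
#' @param enzymes Optional character vector restricting which rules run.
#' @param min_length Minimum retained fragment length.
#' @param motif_db Optional path to a motif TSV for activity profiling.
#' @param activities Activity labels to profile (default: all labels in
#'   the motif database).
#' @param score_table Optional path to a TSV of peptide score
#'   annotations (`peptide` column plus score columns).
#' @param general_threshold,specific_threshold Screening thresholds.
#' @param mass_mode `"monoisotopic"` or `"average"` for peptide
#'   descriptors.
#' @param ro5_mode Rule-of-five counting mode.
#' @param pdb Optional named list of affinity inputs: each element a list
#'   with `path`, `group_a`, `group_b`.
#' @param cutoff,rsa_threshold,temperature Affinity parameters.
#' @param seed Integer seed recorded in the manifest (the core stages are
#'   deterministic; the seed is echoed for provenance).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, rules = NULL, enzymes = NULL,
                            min_length = 3L, motif_db = NULL,
                            activities = NULL, score_table = NULL,
                            general_threshold = 0.7,
                            specific_threshold = 0.5,
                            mass_mode = "monoisotopic",
                            ro5_mode = "lipinski4", pdb = NULL,
                            cutoff = 5.5, rsa_threshold = 0.05,
                            temperature = 298.15, seed = 1L) {
  if (!file.exists(fasta)) stop(sprintf("FASTA not found: %s", fasta))
  if (is.null(rules)) rules <- default_protease_rules()
  if (is.character(rules)) rules <- read_protease_rules(rules)
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  if (!is.null(enzymes)) {
    nm <- vapply(rules, `[[`, "", "name")
    miss <- setdiff(enzymes, nm)
    if (length(miss))
      stop(sprintf("unknown enzyme(s): %s", paste(miss, collapse = ", ")))
    rules <- rules[match(enzymes, nm)]
  }
  if (!is.null(motif_db) && !file.exists(motif_db))
    stop(sprintf("motif database not found: %s", motif_db))
  if (!is.null(score_table) && !file.exists(score_table))
    stop(sprintf("score table not found: %s", score_table))
  if (general_threshold < 0 || general_threshold > 1 ||
      specific_threshold < 0 || specific_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  for (p in pdb) {
    if (!file.exists(p$path)) stop(sprintf("PDB not found: %s", p$path))
    if (is.null(p$group_a) || is.null(p$group_b))
      stop("each pdb entry needs group_a and group_b")
  }
  structure(list(
    fasta = fasta, rules = rules, min_length = as.integer(min_length),
    motif_db = motif_db, activities = activities,
    score_table = score_table,
    general_threshold = general_threshold,
    specific_threshold = specific_threshold,
    mass_mode = match.arg(mass_mode, c("monoisotopic", "average")),
    ro5_mode = match.arg(ro5_mode, c("lipinski4", "extended5")),
    pdb = pdb, cutoff = cutoff, rsa_threshold = rsa_threshold,
    temperature = temperature, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a YAML mapping whose keys mirror the arguments of
#' [pipeline_config()]; relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  cfg$fasta <- rel(cfg$fasta)
  cfg$motif_db <- rel(cfg$motif_db)
  cfg$score_table <- rel(cfg$score_table)
  if (is.character(cfg$rules)) cfg$rules <- rel(cfg$rules)
  if (!is.null(cfg$pdb))
    cfg$pdb <- lapply(cfg$pdb, function(p) { p$path <- rel(p$path); p })
  do.call(pipeline_config, cfg)
}

#' Run the peptide discovery pipeline
#'
#' Executes digestion, activity profiling (when a motif database is
#' configured), physicochemical profiling, score screening (when a score
#' table is configured), drug-likeness evaluation of the retained
#' peptides, and contact-based affinity scoring (when complexes are
#' configured). Writes one TSV per stage plus a JSON run manifest
#' recording the package version, every parameter and the MD5 digest of
#' each input and output. Identical configurations produce byte-identical
#' outputs; timestamps go only to the log file.
#'
#' @param config A `pipeline_config` (or a YAML path).
#' @param out_dir Output directory (created if needed).
#' @param log Logical: write `pipeline.log` with per-stage wall times.
#' @return Invisibly, a list with the per-stage data frames and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, log = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    if (log) cat(sprintf("[%s] %s\n", format(Sys.time()), msg),
                 file = logfile, append = TRUE)
  }
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    note("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    r
  }
  outputs <- character(0)
  results <- list()

  proteins <- t_stage("read_fasta", read_fasta(config$fasta))
  dig <- t_stage("digest", digest_all(proteins, config$rules,
                                      config$min_length))
  f <- file.path(out_dir, "digest.tsv")
  write_tsv_report(dig, f); outputs <- c(outputs, f)
  results$digest <- dig

  if (!is.null(config$motif_db)) {
    db <- read_bioactivity_table(config$motif_db)
    acts <- if (is.null(config$activities)) unique(db$activity)
            else config$activities
    prof <- t_stage("profile",
                    activity_summary(proteins, config$rules, db, acts,
                                     config$min_length))
    f <- file.path(out_dir, "profile.tsv")
    write_tsv_report(prof, f); outputs <- c(outputs, f)
    results$profile <- prof
  }

  phys <- t_stage("physchem", physchem_report(proteins))
  f <- file.path(out_dir, "physchem.tsv")
  write_tsv_report(phys, f); outputs <- c(outputs, f)
  results$physchem <- phys

  # peptide set: unique retained fragments across all digests
  digests <- attr(dig, "digests")
  peptides <- sort(unique(unlist(lapply(digests, function(d)
    d$retained$sequence))))
  if (!is.null(config$score_table)) {
    scores <- utils::read.delim(config$score_table,
                                stringsAsFactors = FALSE)
    if (!"peptide" %in% names(scores))
      stop("score table must have a 'peptide' column")
    screened <- t_stage("screen",
                        screen_by_scores(scores,
                                         config$general_threshold,
                                         config$specific_threshold))
    f <- file.path(out_dir, "screen.tsv")
    write_tsv_report(screened, f); outputs <- c(outputs, f)
    results$screen <- screened
    peptides <- union(peptides, screened$peptide)
  }

  if (length(peptides)) {
    druglike <- t_stage("druglike",
                        peptide_descriptors(peptides, config$ro5_mode))
    f <- file.path(out_dir, "druglike.tsv")
    write_tsv_report(druglike, f); outputs <- c(outputs, f)
    results$druglike <- druglike
  }

  if (!is.null(config$pdb)) {
    aff <- t_stage("affinity", {
      rows <- lapply(names(config$pdb), function(nm) {
        p <- config$pdb[[nm]]
        cx <- read_pdb_complex(p$path, p$group_a, p$group_b)
        a <- binding_affinity(cx, config$cutoff, config$rsa_threshold,
                              config$temperature)
        data.frame(complex = nm, dg = a$dg, kd = a$kd,
                   n_contacts = sum(a$stats$ic),
                   nis_apolar = a$stats$nis[["apolar"]],
                   nis_charged = a$stats$nis[["charged"]],
                   nis_polar = a$stats$nis[["polar"]],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    f <- file.path(out_dir, "affinity.tsv")
    write_tsv_report(aff, f); outputs <- c(outputs, f)
    results$affinity <- aff
  }

  manifest <- list(
    tool = "pepsilico",
    version = as.character(utils::packageVersion("pepsilico")),
    parameters = list(
      min_length = config$min_length,
      enzymes = vapply(config$rules, `[[`, "", "name"),
      activities = config$activities,
      general_threshold = config$general_threshold,
      specific_threshold = config$specific_threshold,
      mass_mode = config$mass_mode, ro5_mode = config$ro5_mode,
      cutoff = config$cutoff, rsa_threshold = config$rsa_threshold,
      temperature = config$temperature, seed = config$seed),
    inputs = as.list(tools::md5sum(stats::na.omit(c(
      config$fasta, config$motif_db, config$score_table,
      vapply(config$pdb, `[[`, "", "path"))))),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  note("pipeline complete: %d output file(s) in %s", length(outputs),
       out_dir)
  invisible(results)
}
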
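#' Define a protease cleavage rule
#'
#' A rule is a named set of cleavage-site patterns. Each pattern is a pair
#' (P1, P1'): the bond C-terminal to a residue in the P1 set is cleaved
#' when the following residue is in the P1' set, or unconditionally when
#' P1' is empty.
#'
#' @param name Protease name.
#' @param sites A list of patterns, each a list with elements `p1`
#'   (character vector of residues) and optional `p1prime`. A single
#'   pattern may be given directly as `list(p1 = ..., p1prime = ...)`.
#' @param ec_number EC number string (informational).
#' @return An object of class `protease_rule`.
#' @examples
#' tryptic <- protease_rule("trypsin-like", list(p1 = c("K", "R")))
#' cleavage_sites("AAKAARAA", tryptic)
#' @export
protease_rule <- function(name, sites, ec_number = "") {
  if (!is.character(name) || !nzchar(name)) stop("rule name must be non-empty")
  if (!is.list(sites)) stop("sites must be a list")
  if (!is.null(sites$p1)) sites <- list(sites)  # single pattern shorthand
  if (!length(sites)) stop("rule must have at least one site pattern")
  sites <- lapply(sites, function(s) {
    p1 <- toupper(s$p1)
    p1p <- if (is.null(s$p1prime)) character(0) else toupper(s$p1prime)
    if (!length(p1)) stop("site pattern with empty P1 set")
    bad <- setdiff(c(p1, p1p), AA_ALPHABET)
    if (length(bad))
      stop(sprintf("site pattern residues outside the 20-letter alphabet: %s",
                   paste(bad, collapse = ", ")))
    list(p1 = p1, p1prime = p1p)
  })
  structure(list(name = name, ec_number = ec_number, sites = sites),
            class = "protease_rule")
}

#' @export
print.protease_rule <- function(x, ...) {
  pat <- vapply(x$sites, function(s) {
    sprintf("[%s]|%s", paste(s$p1, collapse = ""),
            if (length(s$p1prime)) sprintf("[%s]", paste(s$p1prime, collapse = ""))
            else "*")
  }, character(1))
  cat(sprintf("protease_rule '%s'%s: %s\n", x$name,
              if (nzchar(x$ec_number)) sprintf(" (EC %s)", x$ec_number) else "",
              paste(pat, collapse = ", ")))
  invisible(x)
}

#' Read protease rules from a TSV table
#'
#' Columns: `name`, `ec_number`, `p1_residues`, `p1prime_residues`
#' (residues concatenated without separators; empty P1' means the site is
#' unconditional). Rows sharing a name are merged into one multi-pattern
#' rule.
#'
#' @param path TSV file path.
#' @return Named list of [protease_rule()] objects.
#' @export
read_protease_rules <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "ec_number", "p1_residues", "p1prime_residues")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("rule table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  rules <- lapply(split(tab, tab$name), function(rows) {
    sites <- lapply(seq_len(nrow(rows)), function(i) {
      list(p1 = seq_chars(rows$p1_residues[i]),
           p1prime = if (nzchar(rows$p1prime_residues[i]))
             seq_chars(rows$p1prime_residues[i]) else character(0))
    })
    protease_rule(rows$name[1], sites, rows$ec_number[1])
  })
  rules[unique(tab$name)]
}

#' Built-in protease rule table
#'
#' Simplified cleavage specificities for the plant cysteine proteases
#' ficin, papain and stem bromelain, expressed in the (P1, P1') rule
#' grammar. These defaults are an editable convenience for exploratory
#' digestion, not a reference specificity standard; supply your own rule
#' table for production use.
#'
#' @return Named list of [protease_rule()] objects.
#' @export
default_protease_rules <- function() {
  read_protease_rules(system.file("extdata", "protease_rules.tsv",
                                  package = "pepsilico", mustWork = TRUE))
}

#' Enumerate cleavage sites of a rule on a sequence
#'
#' Bond `i` joins residues `i` and `i + 1` (1-based). A bond is cleaved if
#' any site pattern of the rule matches.
#'
#' @param sequence Protein sequence string.
#' @param rule A [protease_rule()].
#' @return Strictly increasing integer vector of cleaved bond indices
#'   (possibly empty).
#' @export
cleavage_sites <- function(sequence, rule) {
  sequence <- validate_sequence(sequence)
  stopifnot(inherits(rule, "protease_rule"))
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) return(integer(0))
  hit <- rep(FALSE, n - 1L)
  for (s in rule$sites) {
    m <- chars[seq_len(n - 1L)] %in% s$p1
    if (length(s$p1prime))
      m <- m & chars[2:n] %in% s$p1prime
    hit <- hit | m
  }
  which(hit)
}

#' Virtually digest one protein
#'
#' Cleaves the sequence exhaustively at every bond matching the rule (no
#' missed cleavages) and computes the theoretical degree of hydrolysis
#' DH = d / D x 100, where d is the number of hydrolyzed peptide bonds and
#' D the total number of peptide bonds in the chain. Fragments shorter
#' than `min_length` are excluded from the retained set (the default 3
#' drops single residues and dipeptides) but still count towards d and the
#' partition of the sequence.
#'
#' @param protein Either a sequence string or a one-row data frame / list
#'   with elements `id` and `sequence`.
#' @param rule A [protease_rule()].
#' @param min_length Minimum retained fragment length (default 3).
#' @return An object of class `digest_result`: list with `protein_id`,
#'   `fragments` (data frame sequence/start/end, 1-based inclusive), `d`,
#'   `D`, `dh_percent`, `retained`, `min_length`, `enzyme`.
#' @examples
#' rule <- protease_rule("trypsin-like", list(p1 = c("K", "R")))
#' digest("AAKAARAA", rule)
#' @export
digest <- function(protein, rule, min_length = 3L) {
  if (is.character(protein) && length(protein) == 1L) {
    id <- "query"; sequence <- protein
  } else {
    protein <- as.list(protein)
    id <- as.character(protein$id[1]); sequence <- as.character(protein$sequence[1])
  }
  sequence <- validate_sequence(sequence, id)
  if (min_length < 1L) stop("min_length must be >= 1")
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, rule)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  frags <- data.frame(
    sequence = substring(sequence, starts, ends),
    start = starts, end = ends, stringsAsFactors = FALSE)
  d <- length(sites)
  D <- n - 1L
  if (D == 0L) {
    message(sprintf("protein '%s' has a single residue; DH defined as 0", id))
    dh <- 0
  } else {
    dh <- d / D * 100
  }
  retained <- frags[nchar(frags$sequence) >= min_length, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(protein_id = id, fragments = frags, d = d, D = D,
                 dh_percent = dh, retained = retained,
                 min_length = as.integer(min_length), enzyme = rule$name),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest of '%s' with %s: %d fragment(s), %d retained (length >= %d)\n",
              x$protein_id, x$enzyme, nrow(x$fragments), nrow(x$retained),
              x$min_length))
  cat(sprintf("  d = %d cleaved bonds of D = %d; DH = %.4f%%\n",
              x$d, x$D, x$dh_percent))
  invisible(x)
}

#' Digest a set of proteins with a set of proteases
#'
#' Runs [digest()] independently for every (protein, rule) pair.
#'
#' @param proteins Data frame of protein records (`id`, `sequence`).
#' @param rules A list of [protease_rule()] objects (or a single rule).
#' @param min_length Minimum retained fragment length.
#' @return A data frame with one row per pair: `protein_id`, `enzyme`,
#'   `n_fragments`, `n_retained`, `d`, `D`, `dh_percent`. The full
#'   [digest()] results are attached as the `"digests"` attribute (a list
#'   named `<protein_id>|<enzyme>`).
#' @export
digest_all <- function(proteins, rules, min_length = 3L) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L)
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  if (!length(rules)) stop("rules must be a non-empty list")
  res <- list(); rows <- list(); k <- 0L
  for (i in seq_len(nrow(proteins))) {
    for (rule in rules) {
      k <- k + 1L
      dg <- digest(proteins[i, ], rule, min_length)
      res[[paste(dg$protein_id, dg$enzyme, sep = "|")]] <- dg
      rows[[k]] <- data.frame(
        protein_id = dg$protein_id, enzyme = dg$enzyme,
        n_fragments = nrow(dg$fragments), n_retained = nrow(dg$retained),
        d = dg$d, D = dg$D, dh_percent = dg$dh_percent,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "digests") <- res
  out
}
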
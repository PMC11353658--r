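#' Match released fragments against a motif database
#'
#' A released fragment matches when its full sequence equals a database
#' fragment annotated with the requested activity (exact equality, not
#' containment). Multiplicities are preserved: the same released sequence
#' at two loci counts twice.
#'
#' @param fragments Character vector of released (retained) fragment
#'   sequences, or a `digest_result` whose retained set is used.
#' @param db Motif data frame with columns `fragment`, `activity`.
#' @param activity Activity label to match.
#' @return Character vector of the matching fragments (possibly empty).
#' @export
match_released <- function(fragments, db, activity) {
  if (inherits(fragments, "digest_result")) fragments <- fragments$retained$sequence
  stopifnot(is.data.frame(db), all(c("fragment", "activity") %in% names(db)))
  pool <- unique(db$fragment[db$activity == activity])
  fragments[fragments %in% pool]
}

#' Frequency of release of active fragments (AE)
#'
#' AE = d / N, where d is the number of fragments with a given activity
#' released by a protease from a protein and N the protein's residue count.
#'
#' @param d_released Count of released matching fragments.
#' @param n_residues Residue count of the parent protein.
#' @return AE (dimensionless, in \[0, 1\] for exhaustive digests).
#' @export
release_frequency_AE <- function(d_released, n_residues) {
  if (n_residues < 1L) stop("n_residues must be >= 1")
  if (d_released < 0L) stop("d_released must be >= 0")
  d_released / n_residues
}

.count_occurrences <- function(sequence, fragment) {
  n <- nchar(sequence); m <- nchar(fragment)
  if (m > n) return(0L)
  starts <- seq_len(n - m + 1L)
  sum(substring(sequence, starts, starts + m - 1L) == fragment)
}

#' Density of active fragments in the intact protein (A)
#'
#' A = a / N: the number of occurrences of any database fragment with the
#' requested activity as a substring of the intact sequence (counted at
#' every start position, overlaps allowed, each distinct database fragment
#' counted separately), divided by the residue count N.
#'
#' @inheritParams match_released
#' @param sequence Intact protein sequence.
#' @return A (dimensionless, >= 0).
#' @export
profile_density_A <- function(sequence, db, activity) {
  sequence <- validate_sequence(sequence)
  pool <- unique(db$fragment[db$activity == activity])
  if (!length(pool)) return(0)
  occ <- sum(vapply(pool, .count_occurrences, integer(1), sequence = sequence))
  occ / nchar(sequence)
}

#' Relative frequency of release (W)
#'
#' W = AE / A. Undefined (NA) when the protein contains no database
#' fragment with the activity (A = 0); never infinite.
#'
#' @param AE Release frequency from [release_frequency_AE()].
#' @param A Occurrence density from [profile_density_A()].
#' @return W, or `NA_real_` when `A` is 0.
#' @export
relative_frequency_W <- function(AE, A) {
  if (A < 0) stop("A must be >= 0")
  if (A == 0) return(NA_real_)
  AE / A
}

#' Per-protein activity profile for one digest
#'
#' Combines the release and density statistics for each requested activity:
#' d (released matching fragments), N, AE = d/N, A and W = AE/A.
#'
#' @param protein One-row data frame / list with `id` and `sequence`.
#' @param rule A [protease_rule()].
#' @param db Motif data frame.
#' @param activities Character vector of activity labels.
#' @param min_length Minimum retained fragment length for the digest.
#' @return Data frame with one row per activity: `protein_id`, `enzyme`,
#'   `activity`, `d_released`, `n_residues`, `AE`, `A`, `W`.
#' @export
activity_profile <- function(protein, rule, db, activities, min_length = 3L) {
  dg <- digest(protein, rule, min_length)
  sequence <- if (is.character(protein)) protein else as.character(as.list(protein)$sequence[1])
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- lapply(activities, function(act) {
    d_rel <- length(match_released(dg$retained$sequence, db, act))
    ae <- release_frequency_AE(d_rel, n)
    a <- profile_density_A(sequence, db, act)
    data.frame(protein_id = dg$protein_id, enzyme = rule$name, activity = act,
               d_released = d_rel, n_residues = n, AE = ae, A = a,
               W = relative_frequency_W(ae, a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summed release frequencies per protease and activity
#'
#' For every (rule, activity) pair, sums AE over all proteins, the layout
#' used to compare proteases by the total release of active fragments.
#'
#' @param proteins Data frame of protein records.
#' @param rules List of [protease_rule()] objects.
#' @param db Motif data frame.
#' @param activities Character vector of activity labels.
#' @param min_length Minimum retained fragment length.
#' @return Data frame with columns `enzyme`, `activity`, `sum_AE`.
#' @export
activity_summary <- function(proteins, rules, db, activities, min_length = 3L) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L)
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  per <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    do.call(rbind, lapply(rules, function(rule)
      activity_profile(proteins[i, ], rule, db, activities, min_length)))
  }))
  agg <- stats::aggregate(AE ~ enzyme + activity, data = per, FUN = sum)
  names(agg)[names(agg) == "AE"] <- "sum_AE"
  ord <- order(match(agg$enzyme, vapply(rules, `[[`, "", "name")),
               match(agg$activity, activities))
  out <- agg[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_protein") <- per
  out
}
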
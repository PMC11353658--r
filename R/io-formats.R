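#' Read protein records from a FASTA file
#'
#' Parses a FASTA file into a data frame of protein records with strict
#' validation: sequences are uppercased and must consist only of the 20
#' canonical one-letter amino-acid codes; record identifiers (the first
#' whitespace-delimited token of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKV", ">p2", "AAKAARAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no records in FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate record id '%s' in %s", dup, path))
  }
  seqs <- as.character(set)
  seqs <- mapply(validate_sequence, seqs, ids, USE.NAMES = FALSE)
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then reading reproduces ids,
#' descriptions and sequences exactly.
#'
#' @param records Data frame with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc),
                       paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a bioactive-peptide motif table
#'
#' Reads a tab-separated motif database in the style of bioactive-peptide
#' repositories: one row per known active fragment with a controlled
#' activity label and a free-text source identifier. Duplicated
#' (fragment, activity) pairs are collapsed with a warning.
#'
#' @param path Path to a TSV file with columns `fragment`, `activity`,
#'   `source_id`.
#' @return A data frame with columns `fragment`, `activity`, `source_id`.
#' @export
read_bioactivity_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("fragment", "activity", "source_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("motif table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(tab) == 0L) stop("motif table has no rows")
  tab$fragment <- toupper(tab$fragment)
  if (any(!nzchar(tab$fragment)))
    stop(sprintf("empty fragment in motif table row %d",
                 which(!nzchar(tab$fragment))[1]))
  if (any(!nzchar(tab$activity)))
    stop(sprintf("empty activity label in motif table row %d",
                 which(!nzchar(tab$activity))[1]))
  for (i in seq_len(nrow(tab))) validate_sequence(tab$fragment[i])
  key <- paste(tab$fragment, tab$activity, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicated (fragment, activity) pair(s) collapsed",
                    sum(duplicated(key))))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[need]
}

.element_from_atom <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  fallback <- toupper(substr(gsub("[0-9']", "", trimws(elety)), 1, 1))
  ifelse(is.na(el) | !nzchar(el), fallback, el)
}

#' Read a two-group protein--peptide complex from a PDB file
#'
#' Parses coordinate ATOM records of the first model, keeping heavy atoms
#' only (hydrogens dropped), the first alternate location, and 1-based
#' residue numbering as given (insertion codes are appended to the residue
#' number to form a string key). HETATM records and waters are discarded.
#' Residue names that cannot be mapped to the 20 canonical residues are
#' retained but flagged in the `unmapped` attribute.
#'
#' @param path Path to a PDB coordinate file.
#' @param group_a,group_b Character vectors of chain identifiers defining
#'   the two sides of the interface; they must be disjoint and present.
#' @return An object of class `complex_structure`: a list with `atoms`
#'   (data frame: chain, resno, resid, aa, elety, element, x, y, z),
#'   `group_a`, `group_b`.
#' @export
read_pdb_complex <- function(path, group_a, group_b) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b))
    stop("both chain groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("group_a and group_b must be disjoint")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # first alternate location only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at$element <- .element_from_atom(at$elesy, at$elety)
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  have <- unique(at$chain)
  absent <- setdiff(c(group_a, group_b), have)
  if (length(absent))
    stop(sprintf("requested chain(s) absent from %s: %s", path,
                 paste(absent, collapse = ", ")))
  at <- at[at$chain %in% c(group_a, group_b), , drop = FALSE]
  if (!nrow(at)) stop("zero atoms in the requested chain groups")
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  atoms <- data.frame(
    chain = at$chain,
    resno = paste0(at$resno, ins),
    resid = at$resid,
    aa = unname(AA_THREE_TO_ONE[at$resid]),
    elety = trimws(at$elety),
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in PDB file")
  for (g in list(a = group_a, b = group_b)) {
    if (!sum(atoms$chain %in% g))
      stop(sprintf("zero atoms in group {%s}", paste(g, collapse = ",")))
  }
  unmapped <- unique(atoms$resid[is.na(atoms$aa)])
  structure(list(atoms = atoms, group_a = group_a, group_b = group_b),
            unmapped = unmapped, class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("complex_structure: %d heavy atoms, group A = {%s}, group B = {%s}\n",
              nrow(x$atoms), paste(x$group_a, collapse = ","),
              paste(x$group_b, collapse = ",")))
  un <- attr(x, "unmapped")
  if (length(un))
    cat(sprintf("  unmapped residue name(s): %s\n", paste(un, collapse = ", ")))
  invisible(x)
}

# Shared TSV writer: header row, tabs, floating point at 4 decimals.
write_tsv_report <- function(df, path, digits = 4L) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", formatC(v, format = "f", digits = digits)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
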
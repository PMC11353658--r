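# Seeded generators for every input the pipeline consumes: random protein
# records with controlled residue composition, small motif databases, and
# toy two-chain complexes whose interfacial contacts are known by
# construction (the oracle for the affinity module).

#' Generate random protein records with controlled composition
#'
#' Residues are drawn independently with the given composition; the
#' empirical composition converges to the target as length grows. Fully
#' deterministic given the seed.
#'
#' @param n Number of proteins.
#' @param length Sequence length (scalar or vector of length `n`).
#' @param composition Named numeric vector of residue frequencies over
#'   the 20-letter alphabet, summing to 1 (default: uniform).
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return Data frame of protein records (`id`, `description`,
#'   `sequence`).
#' @export
generate_proteins <- function(n = 9L, length = 200L,
                              composition = NULL, seed = 1L,
                              prefix = "SYN") {
  if (is.null(composition))
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  if (is.null(names(composition)) ||
      !setequal(names(composition), AA_ALPHABET))
    stop("composition must be named over the 20-letter alphabet")
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition must be non-negative and sum to 1")
  composition <- composition[AA_ALPHABET]
  length <- rep_len(as.integer(length), n)
  if (any(length < 1L)) stop("length must be >= 1")
  withr::local_seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length[i], replace = TRUE,
                 prob = composition), collapse = ""),
    character(1))
  data.frame(id = sprintf("%s_%03d", prefix, seq_len(n)),
             description = sprintf("synthetic protein %d", seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Generate a small synthetic motif database
#'
#' Draws short random fragments and assigns activity labels round-robin;
#' fragments can optionally be forced to occur in given parent sequences.
#'
#' @param n_motifs Number of motifs.
#' @param lengths Candidate motif lengths (sampled uniformly).
#' @param activities Activity labels to cycle through.
#' @param from Optional character vector of parent sequences; when given,
#'   motifs are substrings sampled from them (guaranteeing occurrences).
#' @param seed Integer seed.
#' @return Motif data frame (`fragment`, `activity`, `source_id`).
#' @export
generate_motif_db <- function(n_motifs = 10L, lengths = 3:5,
                              activities = c("ACE inhibitor",
                                             "DPP IV inhibitor",
                                             "antioxidative"),
                              from = NULL, seed = 1L) {
  withr::local_seed(seed)
  frags <- character(n_motifs)
  for (i in seq_len(n_motifs)) {
    len <- sample(lengths, 1L)
    if (is.null(from)) {
      frags[i] <- paste(sample(AA_ALPHABET, len, replace = TRUE),
                        collapse = "")
    } else {
      parent <- from[sample(length(from), 1L)]
      if (nchar(parent) < len) len <- nchar(parent)
      start <- sample(nchar(parent) - len + 1L, 1L)
      frags[i] <- substr(parent, start, start + len - 1L)
    }
  }
  db <- data.frame(fragment = frags,
                   activity = rep_len(activities, n_motifs),
                   source_id = sprintf("SYNDB%04d", seq_len(n_motifs)),
                   stringsAsFactors = FALSE)
  db[!duplicated(paste(db$fragment, db$activity)), , drop = FALSE]
}

.ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Compact 5-atom residue template: backbone N, CA, C, O plus one
# representative side-chain atom (CB; OG for Ser-like polar probing is
# unnecessary for contact logic). Offsets are within 1.5 A of the
# residue center so engineered center distances translate into
# guaranteed contact / non-contact margins.
.residue_atoms <- function(aa, center) {
  off <- rbind(N = c(-1.2, 0.6, 0), CA = c(0, 0, 0), C = c(1.2, 0.6, 0),
               O = c(1.2, 1.5, 0.5), CB = c(0, -1.5, 0.5))
  el <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  names <- rownames(off)
  if (aa == "G") { off <- off[1:4, , drop = FALSE]; el <- el[1:4]; names <- names[1:4] }
  data.frame(elety = names, element = unname(el),
             x = center[1] + off[, 1], y = center[2] + off[, 2],
             z = center[3] + off[, 3], stringsAsFactors = FALSE)
}

.format_pdb_atoms <- function(df) {
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(df)),
          sprintf("%-4s", substr(df$elety, 1, 4)),
          df$resid3, df$chain, df$resno, df$x, df$y, df$z, 1.0, 0.0,
          df$element)
}

#' Generate a toy two-chain complex with known interfacial contacts
#'
#' Lays two chains of compact residue clusters on a grid: residue i of
#' each chain sits at x = 10 i; chain B residues sit at a large
#' inter-chain separation except for the first `n_contacts` residues,
#' which are brought within guaranteed contact distance of their chain-A
#' counterparts. The generator therefore knows the interfacial contact
#' list by construction, independent of any distance computation.
#'
#' @param sequence_a,sequence_b Residue sequences of the two chains (the
#'   classes of engineered contacts follow from these).
#' @param n_contacts Number of engineered contact pairs (residue i of A
#'   with residue i of B for i = 1..n_contacts).
#' @param separation Inter-chain center distance for non-contact residues
#'   in angstroms (must exceed cutoff + 2 * atom extent; default 20).
#' @param contact_distance Center distance of engineered contact pairs in
#'   angstroms. The allowed range \[6, 6.8\] guarantees both a heavy-atom
#'   pair within a 5.5 A cutoff (even for glycine, whose cluster lacks
#'   the side-chain atom and so spans only 1.5 A towards the interface on
#'   one side) and no atom overlap (closest approach >= 3.2 A).
#' @param seed Integer seed (perturbs z-offsets slightly; geometry class
#'   membership is unaffected).
#' @param class_map Residue polarity class map used to compute the
#'   ground-truth class-pair counts.
#' @return A list: `pdb_text` (character vector of PDB lines),
#'   `truth` (list with `contacts` data frame, `ic` named counts, and
#'   `n_atoms`), `sequence_a`, `sequence_b`.
#' @export
generate_toy_complex <- function(sequence_a = "KDLSAVGE",
                                 sequence_b = "RETSVGLA",
                                 n_contacts = 3L, separation = 20,
                                 contact_distance = 6, seed = 1L,
                                 class_map = AA_POLARITY_CLASS) {
  sequence_a <- validate_sequence(sequence_a)
  sequence_b <- validate_sequence(sequence_b)
  na <- nchar(sequence_a); nb <- nchar(sequence_b)
  if (n_contacts > min(na, nb))
    stop("n_contacts cannot exceed the shorter chain length")
  if (separation <= 10)
    stop("separation must exceed 10 A to keep non-contact pairs apart")
  if (contact_distance < 6)
    stop("contact_distance below 6 A would overlap atoms of the residue clusters")
  if (contact_distance > 6.8)
    stop("contact_distance above 6.8 A cannot guarantee a heavy-atom contact at a 5.5 A cutoff")
  withr::local_seed(seed)
  jitter_z <- function(n) stats::runif(n, -0.3, 0.3)
  rows <- list()
  ca <- seq_chars(sequence_a); cb <- seq_chars(sequence_b)
  za <- jitter_z(na); zb <- jitter_z(nb)
  for (i in seq_len(na)) {
    at <- .residue_atoms(ca[i], c(10 * i, 0, za[i]))
    at$chain <- "A"; at$resno <- i; at$resid3 <- .ONE_TO_THREE[ca[i]]
    rows[[length(rows) + 1L]] <- at
  }
  for (j in seq_len(nb)) {
    y <- if (j <= n_contacts) contact_distance else separation
    at <- .residue_atoms(cb[j], c(10 * j, y, zb[j]))
    at$chain <- "B"; at$resno <- j; at$resid3 <- .ONE_TO_THREE[cb[j]]
    rows[[length(rows) + 1L]] <- at
  }
  atoms <- do.call(rbind, rows)
  contacts <- if (n_contacts > 0L) {
    idx <- seq_len(n_contacts)
    data.frame(resno_a = idx, aa_a = ca[idx],
               resno_b = idx, aa_b = cb[idx],
               class_pair = .pair_label(.residue_class(ca[idx], ca[idx], class_map),
                                        .residue_class(cb[idx], cb[idx], class_map)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(resno_a = integer(0), aa_a = character(0),
               resno_b = integer(0), aa_b = character(0),
               class_pair = character(0), stringsAsFactors = FALSE)
  }
  ic <- stats::setNames(integer(length(IC_PAIR_LEVELS)), IC_PAIR_LEVELS)
  if (nrow(contacts)) {
    tab <- table(factor(contacts$class_pair, levels = IC_PAIR_LEVELS))
    ic[] <- as.integer(tab)
  }
  pdb_text <- c("HEADER    SYNTHETIC TOY COMPLEX",
                .format_pdb_atoms(atoms), "END")
  list(pdb_text = pdb_text,
       truth = list(contacts = contacts, ic = ic, n_atoms = nrow(atoms)),
       sequence_a = sequence_a, sequence_b = sequence_b)
}

#' Write a generated toy complex to a PDB file
#'
#' @param toy Result of [generate_toy_complex()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_complex <- function(toy, path) {
  writeLines(toy$pdb_text, path)
  invisible(path)
}

#' Bundled candidate peptides with published screening scores
#'
#' The twelve milkfish muscle-derived candidate peptides carried through
#' the docking and drug-likeness stages, with their machine-learning
#' bioactivity score annotations (ACE-inhibitory, antihypertensive,
#' antidiabetic and DPPIV-inhibitory). Scores below the screening
#' threshold of 0.5 are recorded as NA. The scores are annotations from
#' external predictors; this package never computes them.
#'
#' @return Data frame with columns `peptide`, `ace_inhibitory`,
#'   `antihypertensive`, `antidiabetic`, `dppiv_inhibitory`.
#' @export
candidate_peptides <- function() {
  data.frame(
    peptide = c("PMNPPK", "VNPYKWL", "AAPNF", "PPPPV", "PMIPG", "YPPPT",
                "AMYF", "PPPS", "MVWH", "AAWMIY", "AWMIYT", "MQML"),
    ace_inhibitory = c(0.977, 0.663, 0.510, 0.582, NA, NA,
                       0.528, 0.591, 0.612, NA, NA, NA),
    antihypertensive = c(NA, NA, NA, NA, 0.818, 0.837,
                         0.903, 0.957, 0.936, 0.778, 0.517, NA),
    antidiabetic = c(NA, NA, NA, NA, NA, NA,
                     NA, NA, NA, 0.574, 0.519, 0.813),
    dppiv_inhibitory = c(NA, NA, NA, NA, NA, NA,
                         NA, NA, NA, NA, NA, 0.594),
    stringsAsFactors = FALSE)
}
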
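#' Molecular formula of a linear peptide
#'
#' Element counts (C, H, N, O, S) from residue templates plus one water
#' for the free termini.
#'
#' @param sequence Sequence string.
#' @return Named integer vector over C, H, N, O, S; the formatted formula
#'   string is attached as attribute `"formula"`.
#' @examples
#' molecular_formula("PPPS")  # C18 H28 N4 O6
#' @export
molecular_formula <- function(sequence) {
  sequence <- validate_sequence(sequence)
  counts <- colSums(AA_RESIDUE_FORMULA[seq_chars(sequence), , drop = FALSE])
  counts["H"] <- counts["H"] + 2L  # water
  counts["O"] <- counts["O"] + 1L
  counts <- as.integer(counts)
  names(counts) <- colnames(AA_RESIDUE_FORMULA)
  nz <- counts > 0L
  structure(counts,
            formula = paste0(names(counts)[nz],
                             ifelse(counts[nz] > 1L, counts[nz], ""),
                             collapse = ""))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param counts Named integer vector of element counts (C, H, N, O, S).
#' @return Mass in Da.
#' @export
formula_mass_monoisotopic <- function(counts) {
  el <- names(counts)
  bad <- setdiff(el, names(ELEMENT_MASS_MONO))
  if (length(bad)) stop(sprintf("unknown element(s): %s", paste(bad, collapse = ", ")))
  sum(ELEMENT_MASS_MONO[el] * as.numeric(counts))
}

#' Lipinski hydrogen-bond acceptor count
#'
#' Lipinski convention: HBA = total number of nitrogen and oxygen atoms.
#'
#' @param sequence Sequence string.
#' @return Integer count.
#' @examples
#' hba_count("PPPS")  # 10
#' @export
hba_count <- function(sequence) {
  f <- molecular_formula(sequence)
  unname(f["N"] + f["O"])
}

#' Lipinski hydrogen-bond donor count
#'
#' Lipinski convention: HBD = hydrogens bonded to nitrogen or oxygen.
#' For a linear peptide: N-terminal amine hydrogens (2, or 1 for an
#' N-terminal proline), one backbone amide hydrogen per non-proline
#' residue after the first, side-chain N-H / O-H hydrogens, and the
#' C-terminal carboxyl O-H.
#'
#' @param sequence Sequence string.
#' @return Integer count.
#' @examples
#' hbd_count("PPPS")  # 4
#' @export
hbd_count <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  nterm_h <- if (chars[1] == "P") 1L else 2L
  amide_h <- if (length(chars) > 1L) sum(chars[-1] != "P") else 0L
  as.integer(nterm_h + amide_h + sum(AA_SIDECHAIN_DONOR_H[chars]) + 1L)
}

#' Additive logP estimate for a peptide
#'
#' Transparent additive estimator: the sum of Fauchere--Pliska side-chain
#' octanol/water contributions plus a fixed polar-backbone term per
#' residue and a terminal-ionization penalty. Intended for rule-of-five
#' screening of short peptides; it does not reproduce machine-learned
#' logP predictions.
#'
#' @param sequence Sequence string.
#' @return Dimensionless logP estimate.
#' @export
logp_estimate <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  sum(AA_SIDECHAIN_PI[chars]) + length(chars) * LOGP_BACKBONE + LOGP_TERMINI
}

#' Additive topological polar surface area estimate
#'
#' Ertl fragment-additive TPSA from residue templates: N-terminal amine
#' (26.02, or 12.03 for proline), backbone amide nitrogens (12.03; 3.24
#' for proline, which carries no amide hydrogen), one backbone carbonyl
#' oxygen (17.07) per residue before the last, the C-terminal carboxyl
#' group (37.30) and side-chain polar fragments.
#'
#' @param sequence Sequence string.
#' @return TPSA estimate in squared angstroms.
#' @examples
#' tpsa_estimate("PPPS")  # 139.28
#' @export
tpsa_estimate <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  n <- length(chars)
  nterm <- if (chars[1] == "P") TPSA_FRAG$nterm_amine_pro else TPSA_FRAG$nterm_amine
  amide <- if (n > 1L)
    sum(ifelse(chars[-1] == "P", TPSA_FRAG$amide_n_pro, TPSA_FRAG$amide_nh))
  else 0
  nterm + amide + (n - 1L) * TPSA_FRAG$carbonyl_o + TPSA_FRAG$carboxyl +
    sum(AA_SIDECHAIN_TPSA[chars])
}

#' Lipinski rule-of-five evaluation
#'
#' Counts violations of the inclusive limits MW <= 500 Da, HBA <= 10,
#' HBD <= 5 and logP <= 5 (`lipinski4` mode); `extended5` adds
#' TPSA <= 140 A^2.
#'
#' @param mw Molecular weight in Da.
#' @param hba,hbd Acceptor / donor counts.
#' @param logp logP value.
#' @param tpsa TPSA in A^2 (required for `extended5`).
#' @param mode `"lipinski4"` or `"extended5"`.
#' @return A list with `flags` (named logical vector, TRUE = rule
#'   violated) and `n_violations`.
#' @export
ro5_violations <- function(mw, hba, hbd, logp, tpsa = NULL,
                           mode = c("lipinski4", "extended5")) {
  mode <- match.arg(mode)
  flags <- c(mw_gt_500 = mw > 500, hba_gt_10 = hba > 10,
             hbd_gt_5 = hbd > 5, logp_gt_5 = logp > 5)
  if (mode == "extended5") {
    if (is.null(tpsa)) stop("extended5 mode requires tpsa")
    flags <- c(flags, tpsa_gt_140 = tpsa > 140)
  }
  list(flags = flags, n_violations = sum(flags))
}

#' Sequence-derived drug-likeness descriptors for peptides
#'
#' One row per peptide: molecular formula, monoisotopic mass, Lipinski
#' hydrogen-bond acceptor and donor counts, additive logP and TPSA
#' estimates, and the rule-of-five violation count with per-rule flags.
#'
#' @param sequences Character vector of peptide sequences.
#' @param mode Rule-counting mode, see [ro5_violations()].
#' @return Data frame with columns `sequence`, `formula`, `mw_mono`,
#'   `hba`, `hbd`, `logp_est`, `tpsa_est`, `ro5_violations` and one
#'   logical column per rule flag.
#' @examples
#' peptide_descriptors(c("PPPS", "PPPPV"))
#' @export
peptide_descriptors <- function(sequences, mode = c("lipinski4", "extended5")) {
  mode <- match.arg(mode)
  rows <- lapply(sequences, function(s) {
    s <- validate_sequence(s)
    f <- molecular_formula(s)
    mw <- molecular_weight(s, "monoisotopic")
    hba <- hba_count(s); hbd <- hbd_count(s)
    lp <- logp_estimate(s); tp <- tpsa_estimate(s)
    v <- ro5_violations(mw, hba, hbd, lp, tp, mode)
    out <- data.frame(sequence = s, formula = attr(f, "formula"),
                      mw_mono = mw, hba = hba, hbd = hbd,
                      logp_est = lp, tpsa_est = tp,
                      ro5_violations = v$n_violations,
                      stringsAsFactors = FALSE)
    for (nm in names(v$flags)) out[[nm]] <- unname(v$flags[nm])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
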
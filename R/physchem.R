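#' Peptide / protein molecular weight
#'
#' Sum of residue masses plus one water, using the standard average or
#' monoisotopic residue-mass table. Average masses match the convention of
#' protein-level property calculators; monoisotopic masses are the
#' convention for small-peptide descriptors.
#'
#' @param sequence Sequence string.
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' molecular_weight("PPPS", "monoisotopic")  # 396.2009
#' @export
molecular_weight <- function(sequence, mode = c("average", "monoisotopic")) {
  sequence <- validate_sequence(sequence)
  mode <- match.arg(mode)
  chars <- seq_chars(sequence)
  if (mode == "monoisotopic")
    sum(AA_MASS_MONO[chars]) + WATER_MONO
  else
    sum(AA_MASS_AVG[chars]) + WATER_AVG
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over all residues; bounded by the scale
#' extremes -4.5 (Arg) and 4.5 (Ile).
#'
#' @param sequence Sequence string.
#' @return Dimensionless GRAVY value.
#' @export
gravy <- function(sequence) {
  sequence <- validate_sequence(sequence)
  mean(AA_KD_HYDROPATHY[seq_chars(sequence)])
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains (Ikai's formula):
#' AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu)), with X in
#' mole-percent.
#'
#' @param sequence Sequence string.
#' @return Dimensionless aliphatic index (>= 0).
#' @export
aliphatic_index <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  x <- function(aa) 100 * mean(chars == aa)
  x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L"))
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic: II = (10 / L) * sum of DIWV
#' values over consecutive residue pairs. Values above 40 predict an
#' unstable protein in vivo (strictly: unstable iff II > 40).
#'
#' @param sequence Sequence string of length >= 2.
#' @return Instability index with attribute `stability_class`
#'   (`"stable"` or `"unstable"`).
#' @export
instability_index <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) stop("instability index requires at least 2 residues")
  ii <- 10 / n * sum(AA_DIWV[cbind(chars[-n], chars[-1])])
  structure(ii, stability_class = if (ii > 40) "unstable" else "stable")
}

#' Net charge of a sequence at a given pH
#'
#' Henderson--Hasselbalch charge over the free termini and the ionizable
#' side chains (D, E, C, Y negative; K, R, H positive).
#'
#' @param sequence Sequence string.
#' @param pH pH value.
#' @param pka_set Name of a shipped pKa set (currently `"bjellqvist"`) or
#'   a list with elements `nterm`, `cterm`, `positive`, `negative`.
#' @return Net charge (elementary charges); strictly decreasing in pH.
#' @export
net_charge <- function(sequence, pH, pka_set = "bjellqvist") {
  sequence <- validate_sequence(sequence)
  pka <- if (is.character(pka_set)) {
    if (!pka_set %in% names(PKA_SETS))
      stop(sprintf("unknown pKa set '%s'", pka_set))
    PKA_SETS[[pka_set]]
  } else pka_set
  chars <- seq_chars(sequence)
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  q <- pos_frac(pka$nterm) + neg_frac(pka$cterm)
  for (aa in names(pka$positive))
    q <- q + sum(chars == aa) * pos_frac(pka$positive[[aa]])
  for (aa in names(pka$negative))
    q <- q + sum(chars == aa) * neg_frac(pka$negative[[aa]])
  unname(q)
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson--Hasselbalch net charge crosses zero, found
#' by bisection on \[0, 14\] to |charge| < 1e-4. The titration function is
#' strictly monotone, so the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on the absolute net charge.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka_set = "bjellqvist", tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka_set)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Charged residue counts
#'
#' @param sequence Sequence string.
#' @return Named integer vector: `neg` (Asp + Glu), `pos` (Arg + Lys).
#' @export
charged_residue_counts <- function(sequence) {
  sequence <- validate_sequence(sequence)
  chars <- seq_chars(sequence)
  c(neg = sum(chars %in% c("D", "E")), pos = sum(chars %in% c("K", "R")))
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill--von Hippel estimate: 5500 per Trp, 1490 per Tyr and, with
#' cystines oxidized, 125 per disulfide pair (floor(nCys / 2)).
#'
#' @param sequence Sequence string.
#' @param cystines `"oxidized"` or `"reduced"`.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(sequence,
                                   cystines = c("oxidized", "reduced")) {
  sequence <- validate_sequence(sequence)
  cystines <- match.arg(cystines)
  chars <- seq_chars(sequence)
  e <- EXTINCTION_TRP * sum(chars == "W") + EXTINCTION_TYR * sum(chars == "Y")
  if (cystines == "oxidized")
    e <- e + EXTINCTION_CYSTINE * (sum(chars == "C") %/% 2L)
  e
}

#' Amino-acid class distribution
#'
#' Residue fractions over five classes: negatively charged (Glu, Asp),
#' positively charged (Lys, Arg), non-polar (Val, Pro, Met, Leu, Ile, Gly,
#' Ala), polar (Thr, Ser, Gln, Asn, His, Cys) and aromatic (Tyr, Trp,
#' Phe). The grouping covers all 20 residues, so the fractions sum to 1.
#'
#' @param sequence Sequence string.
#' @return Named numeric vector of fractions
#'   (negative, positive, nonpolar, polar, aromatic).
#' @export
aa_class_distribution <- function(sequence) {
  sequence <- validate_sequence(sequence)
  cls <- AA_FIVE_CLASSES[seq_chars(sequence)]
  lv <- c("negative", "positive", "nonpolar", "polar", "aromatic")
  tab <- table(factor(cls, levels = lv))
  fr <- as.numeric(tab) / length(cls)
  names(fr) <- lv
  fr
}

#' Estimated N-end-rule half-life
#'
#' Static lookup of the published half-life associated with the
#' N-terminal residue.
#'
#' @param sequence Sequence string.
#' @param organism `"mammalian"`, `"yeast"` or `"ecoli"`.
#' @return Half-life as a character string (e.g. `"30 hour"`).
#' @export
half_life <- function(sequence, organism = c("mammalian", "yeast", "ecoli")) {
  sequence <- validate_sequence(sequence)
  organism <- match.arg(organism)
  nt <- substr(sequence, 1, 1)
  AA_HALF_LIFE[[organism]][match(nt, AA_HALF_LIFE$residue)]
}

#' Physicochemical report for a set of protein records
#'
#' One row per record with the full descriptor panel: length, average and
#' monoisotopic mass, charged residue counts, theoretical pI, GRAVY,
#' aliphatic and instability indices (with stability class), extinction
#' coefficients and the five-class residue fractions.
#'
#' @param records Data frame with columns `id` and `sequence` (a single
#'   sequence string is also accepted).
#' @param pka_set pKa set for the pI calculation.
#' @return Data frame, one row per record.
#' @export
physchem_report <- function(records, pka_set = "bjellqvist") {
  if (is.character(records))
    records <- data.frame(id = if (is.null(names(records)))
      paste0("seq", seq_along(records)) else names(records),
      sequence = records, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    s <- validate_sequence(records$sequence[i], records$id[i])
    cr <- charged_residue_counts(s)
    ii <- instability_index(s)
    cls <- aa_class_distribution(s)
    data.frame(
      id = records$id[i], length = nchar(s),
      mw_average = molecular_weight(s, "average"),
      mw_monoisotopic = molecular_weight(s, "monoisotopic"),
      neg_residues = unname(cr["neg"]), pos_residues = unname(cr["pos"]),
      pI = isoelectric_point(s, pka_set),
      gravy = gravy(s), aliphatic_index = aliphatic_index(s),
      instability_index = as.numeric(ii),
      stability_class = attr(ii, "stability_class"),
      ext_coef_oxidized = extinction_coefficient(s, "oxidized"),
      ext_coef_reduced = extinction_coefficient(s, "reduced"),
      frac_negative = cls[["negative"]], frac_positive = cls[["positive"]],
      frac_nonpolar = cls[["nonpolar"]], frac_polar = cls[["polar"]],
      frac_aromatic = cls[["aromatic"]],
      half_life_mammalian = half_life(s, "mammalian"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
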
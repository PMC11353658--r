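# Reference tables for the 20 canonical amino acids.
#
# Sources (published constants, transcribed here so the package has no
# runtime data dependencies):
#   - residue masses: IUPAC standard atomic weights (average) and standard
#     monoisotopic isotope masses, as used by common proteomics calculators
#   - hydropathy: Kyte & Doolittle (1982)
#   - instability weights: Guruprasad, Reddy & Pandit (1990) DIWV matrix
#   - pKa: Bjellqvist-style set used by common pI web calculators
#   - maximal ASA: Tien et al. (2013), theoretical values
#   - side-chain octanol/water contributions: Fauchere & Pliska (1983)
#   - polar-surface fragment contributions: Ertl, Rohde & Selzer (2000)

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

# Residue (peptide-bonded, i.e. amino acid minus water) masses in Da.
AA_MASS_MONO <- c(
  A = 71.03711, C = 103.00918, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04048, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)

AA_MASS_AVG <- c(
  A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1140, F = 147.1738,
  G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576,
  M = 131.1960, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857,
  S = 87.0773, T = 101.1039, V = 99.1310, W = 186.2099, Y = 163.1732)

WATER_MONO <- 18.010565
WATER_AVG <- 18.0153

ELEMENT_MASS_MONO <- c(C = 12.0, H = 1.00782503, N = 14.0030740,
                       O = 15.9949146, S = 31.9720707)

# Kyte-Doolittle hydropathy.
AA_KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Guruprasad dipeptide instability weight values, DIWV[x, y] for pair x->y.
AA_DIWV <- local({
  m <- matrix(1, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  set <- function(a, b, v) m[a, b] <<- v
  set("A", "C", 44.94); set("A", "D", -7.49); set("A", "H", -7.49)
  set("A", "P", 20.26)
  set("C", "D", 20.26); set("C", "H", 33.60); set("C", "L", 20.26)
  set("C", "M", 33.60); set("C", "P", 20.26); set("C", "Q", -6.54)
  set("C", "T", 33.60); set("C", "V", -6.54); set("C", "W", 24.68)
  set("D", "F", -6.54); set("D", "K", -7.49); set("D", "R", -6.54)
  set("D", "S", 20.26); set("D", "T", -14.03)
  set("E", "C", 44.94); set("E", "D", 20.26); set("E", "E", 33.60)
  set("E", "H", -6.54); set("E", "I", 20.26); set("E", "P", 20.26)
  set("E", "Q", 20.26); set("E", "S", 20.26); set("E", "W", -14.03)
  set("F", "D", 13.34); set("F", "K", -14.03); set("F", "P", 20.26)
  set("F", "Y", 33.601)
  set("G", "A", -7.49); set("G", "E", -6.54); set("G", "G", 13.34)
  set("G", "I", -7.49); set("G", "K", -7.49); set("G", "N", -7.49)
  set("G", "T", -7.49); set("G", "W", 13.34); set("G", "Y", -7.49)
  set("H", "F", -9.37); set("H", "G", -9.37); set("H", "I", 44.94)
  set("H", "K", 24.68); set("H", "N", 24.68); set("H", "P", -1.88)
  set("H", "T", -6.54); set("H", "W", -1.88); set("H", "Y", 44.94)
  set("I", "E", 44.94); set("I", "H", 13.34); set("I", "K", -7.49)
  set("I", "L", 20.26); set("I", "P", -1.88); set("I", "V", -7.49)
  set("K", "G", -7.49); set("K", "I", -7.49); set("K", "L", -7.49)
  set("K", "M", 33.60); set("K", "P", -6.54); set("K", "Q", 24.64)
  set("K", "R", 33.60); set("K", "V", -7.49)
  set("L", "K", -7.49); set("L", "P", 20.26); set("L", "Q", 33.60)
  set("L", "R", 20.26); set("L", "W", 24.68)
  set("M", "A", 13.34); set("M", "H", 58.28); set("M", "M", -1.88)
  set("M", "P", 44.94); set("M", "Q", -6.54); set("M", "R", -6.54)
  set("M", "S", 44.94); set("M", "T", -1.88); set("M", "Y", 24.68)
  set("N", "C", -1.88); set("N", "F", -14.03); set("N", "G", -14.03)
  set("N", "I", 44.94); set("N", "K", 24.68); set("N", "P", -1.88)
  set("N", "Q", -6.54); set("N", "T", -7.49); set("N", "W", -9.37)
  set("P", "A", 20.26); set("P", "C", -6.54); set("P", "D", -6.54)
  set("P", "E", 18.38); set("P", "F", 20.26); set("P", "M", -6.54)
  set("P", "P", 20.26); set("P", "Q", 20.26); set("P", "R", -6.54)
  set("P", "S", 20.26); set("P", "V", 20.26); set("P", "W", -1.88)
  set("Q", "C", -6.54); set("Q", "D", 20.26); set("Q", "E", 20.26)
  set("Q", "F", -6.54); set("Q", "P", 20.26); set("Q", "Q", 20.26)
  set("Q", "S", 44.94); set("Q", "V", -6.54); set("Q", "Y", -6.54)
  set("R", "G", -7.49); set("R", "H", 20.26); set("R", "N", 13.34)
  set("R", "P", 20.26); set("R", "Q", 20.26); set("R", "R", 58.28)
  set("R", "S", 44.94); set("R", "W", 58.28); set("R", "Y", -6.54)
  set("S", "C", 33.60); set("S", "E", 20.26); set("S", "P", 44.94)
  set("S", "Q", 20.26); set("S", "R", 20.26); set("S", "S", 20.26)
  set("T", "E", 20.26); set("T", "F", 13.34); set("T", "G", -7.49)
  set("T", "N", -14.03); set("T", "Q", -6.54); set("T", "W", -14.03)
  set("V", "D", -14.03); set("V", "G", -7.49); set("V", "K", -1.88)
  set("V", "P", 20.26); set("V", "T", -7.49); set("V", "Y", -6.54)
  set("W", "A", -14.03); set("W", "G", -9.37); set("W", "H", 24.68)
  set("W", "L", 13.34); set("W", "M", 24.68); set("W", "N", 13.34)
  set("W", "T", -14.03); set("W", "V", -7.49)
  set("Y", "A", 24.68); set("Y", "D", 24.68); set("Y", "E", -6.54)
  set("Y", "G", -7.49); set("Y", "H", 13.34); set("Y", "M", 44.94)
  set("Y", "P", 13.34); set("Y", "R", -15.91); set("Y", "T", -7.49)
  set("Y", "W", -9.37); set("Y", "Y", 13.34)
  m
})

# Bjellqvist-style ionizable-group pKa values (selectable by name).
PKA_SETS <- list(
  bjellqvist = list(
    nterm = 7.50, cterm = 3.55,
    positive = c(K = 10.00, R = 12.00, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)))

# Gill & von Hippel molar extinction coefficients at 280 nm (M^-1 cm^-1).
EXTINCTION_TRP <- 5500
EXTINCTION_TYR <- 1490
EXTINCTION_CYSTINE <- 125

# ProtParam-style N-end-rule half-life lookup (N-terminal residue ->
# half-life in mammalian reticulocytes in vitro, yeast in vivo,
# E. coli in vivo).
AA_HALF_LIFE <- data.frame(
  residue = AA_ALPHABET,
  mammalian = c("4.4 hour", "1.2 hour", "1.1 hour", "1 hour", "1.1 hour",
                "30 hour", "3.5 hour", "20 hour", "1.3 hour", "5.5 hour",
                "30 hour", "1.4 hour", ">20 hour", "0.8 hour", "1 hour",
                "1.9 hour", "7.2 hour", "100 hour", "2.8 hour", "2.8 hour"),
  yeast = c(">20 hour", ">20 hour", "3 min", "30 min", "3 min",
            ">20 hour", "10 min", "30 min", "3 min", "3 min",
            ">20 hour", "3 min", ">20 hour", "10 min", "2 min",
            ">20 hour", ">20 hour", ">20 hour", "3 min", "10 min"),
  ecoli = c(">10 hour", ">10 hour", ">10 hour", ">10 hour", "2 min",
            ">10 hour", ">10 hour", ">10 hour", "2 min", "2 min",
            ">10 hour", ">10 hour", "?", ">10 hour", "2 min",
            ">10 hour", ">10 hour", ">10 hour", "2 min", "2 min"),
  stringsAsFactors = FALSE)

# Amino-acid class grouping used for composition summaries: negatively
# charged (Glu, Asp), positively charged (Lys, Arg), non-polar
# (Val, Pro, Met, Leu, Ile, Gly, Ala), polar (Thr, Ser, Gln, Asn, His, Cys)
# and aromatic (Tyr, Trp, Phe).  All 20 residues are covered.
AA_FIVE_CLASSES <- c(
  D = "negative", E = "negative",
  K = "positive", R = "positive",
  V = "nonpolar", P = "nonpolar", M = "nonpolar", L = "nonpolar",
  I = "nonpolar", G = "nonpolar", A = "nonpolar",
  T = "polar", S = "polar", Q = "polar", N = "polar", H = "polar",
  C = "polar",
  Y = "aromatic", W = "aromatic", F = "aromatic")

# Element inventory (C, H, N, O, S) of each peptide-bonded residue.
AA_RESIDUE_FORMULA <- local({
  m <- rbind(
    A = c(3, 5, 1, 1, 0),  C = c(3, 5, 1, 1, 1),  D = c(4, 5, 1, 3, 0),
    E = c(5, 7, 1, 3, 0),  F = c(9, 9, 1, 1, 0),  G = c(2, 3, 1, 1, 0),
    H = c(6, 7, 3, 1, 0),  I = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    L = c(6, 11, 1, 1, 0), M = c(5, 9, 1, 1, 1),  N = c(4, 6, 2, 2, 0),
    P = c(5, 7, 1, 1, 0),  Q = c(5, 8, 2, 2, 0),  R = c(6, 12, 4, 1, 0),
    S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  V = c(5, 9, 1, 1, 0),
    W = c(11, 10, 2, 1, 0), Y = c(9, 9, 1, 2, 0))
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Side-chain hydrogens bonded to N or O (Lipinski donor convention;
# thiol S-H is not a donor).
AA_SIDECHAIN_DONOR_H <- c(
  A = 0, C = 0, D = 1, E = 1, F = 0, G = 0, H = 1, I = 0, K = 2, L = 0,
  M = 0, N = 2, P = 0, Q = 2, R = 4, S = 1, T = 1, V = 0, W = 1, Y = 1)

# Ertl fragment-additive topological polar surface area (A^2).
# Backbone fragments by context plus side-chain contributions.
TPSA_FRAG <- list(
  nterm_amine = 26.02,      # primary amine N with two H
  nterm_amine_pro = 12.03,  # proline N-terminus: secondary amine N-H
  amide_nh = 12.03,         # backbone amide N-H (non-proline, position > 1)
  amide_n_pro = 3.24,       # proline backbone amide N (no H)
  carbonyl_o = 17.07,       # backbone amide C=O (all residues but the last)
  carboxyl = 37.30)         # C-terminal COOH (O-H + C=O)

AA_SIDECHAIN_TPSA <- c(
  A = 0, C = 0, D = 37.30, E = 37.30, F = 0, G = 0, H = 28.68, I = 0,
  K = 26.02, L = 0, M = 0, N = 43.09, P = 0, Q = 43.09, R = 50.41,
  S = 20.23, T = 20.23, V = 0, W = 15.79, Y = 20.23)

# Fauchere-Pliska side-chain octanol/water partition contributions (pi).
AA_SIDECHAIN_PI <- c(
  A = 0.31, C = 1.54, D = -0.77, E = -0.64, F = 1.79, G = 0.00, H = 0.13,
  I = 1.80, K = -0.99, L = 1.70, M = 1.23, N = -0.60, P = 0.72, Q = -0.22,
  R = -1.01, S = -0.04, T = 0.26, V = 1.22, W = 2.25, Y = 0.96)

# Backbone / terminal corrections for the additive logP estimate: each
# residue carries a polar backbone unit, and the zwitterionic termini
# carry a fixed penalty.
LOGP_BACKBONE <- -0.53
LOGP_TERMINI <- -0.70

# Residue polarity classes for contact-based affinity scoring
# (editable via the class_map argument of the affinity functions).
AA_POLARITY_CLASS <- c(
  D = "charged", E = "charged", H = "charged", K = "charged", R = "charged",
  C = "polar", M = "polar", N = "polar", Q = "polar", S = "polar",
  T = "polar", W = "polar", Y = "polar",
  A = "apolar", F = "apolar", G = "apolar", I = "apolar", L = "apolar",
  P = "apolar", V = "apolar")

# Maximal accessible surface area per residue (A^2), theoretical values
# of Tien et al. (2013); reference for relative solvent accessibility.
AA_MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0, E = 223.0,
  Q = 225.0, G = 104.0, H = 224.0, I = 197.0, L = 201.0, K = 236.0,
  M = 224.0, F = 240.0, P = 159.0, S = 155.0, T = 172.0, V = 174.0,
  W = 285.0, Y = 263.0)

# Van der Waals radii by element (A) for surface calculations.
ELEMENT_VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_RADIUS_DEFAULT <- 1.70

# Ideal gas constant in kcal K^-1 mol^-1.
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Validate a peptide or protein sequence
#'
#' Checks that a sequence is a non-empty string over the 20 canonical
#' one-letter amino-acid codes. Lower-case input is uppercased. Ambiguity
#' and non-standard codes (B, J, O, U, X, Z) are rejected, since masses and
#' descriptors are undefined for them.
#'
#' @param sequence Character scalar.
#' @param id Optional record label used in error messages.
#' @return The validated, uppercased sequence (invisibly usable).
#' @export
validate_sequence <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop(sprintf("empty sequence%s",
                 if (is.null(id)) "" else sprintf(" in record '%s'", id)))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf(
      "illegal residue '%s' at position %d%s (only the 20 canonical codes are accepted)",
      chars[bad[1]], bad[1],
      if (is.null(id)) "" else sprintf(" in record '%s'", id)))
  }
  sequence
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
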
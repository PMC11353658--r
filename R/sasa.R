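# Shrake-Rupley solvent-accessible surface area with a fixed,
# deterministic point set, so results are bit-reproducible across runs.

# Deterministic quasi-uniform unit-sphere points (golden-section spiral).
sphere_points <- function(n = 960L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi),
        y = sin(theta) * sin(phi),
        z = cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake--Rupley)
#'
#' Rolls a spherical probe over heavy atoms using a fixed deterministic
#' quasi-uniform point set on each atom's solvent-expanded sphere. A test
#' point is accessible if it lies outside the expanded sphere of every
#' other atom.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` and `element`.
#' @param probe Probe radius in angstroms (water: 1.4).
#' @param n_points Number of sphere test points per atom (fixed for
#'   determinism).
#' @return Numeric vector of per-atom ASA values in squared angstroms.
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  radii <- ELEMENT_VDW_RADIUS[atoms$element]
  radii[is.na(radii)] <- VDW_RADIUS_DEFAULT
  r_ext <- radii + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    # candidate occluders: atoms whose expanded spheres can intersect i's
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    test <- pts * r_ext[i]
    test <- sweep(test, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r_ext[j]^2
      if (!any(acc)) break
    }
    out[i] <- sum(acc) / n_points * 4 * pi * r_ext[i]^2
  }
  out
}

#' Per-residue relative solvent accessibility of a complex
#'
#' Sums atomic ASA per residue over the whole complex and divides by the
#' residue's maximal-ASA reference value to obtain relative solvent
#' accessibility (RSA).
#'
#' @param complex A `complex_structure` from [read_pdb_complex()].
#' @inheritParams atom_sasa
#' @return Data frame with one row per residue: `chain`, `resno`, `aa`,
#'   `asa`, `rsa` (NA when the residue is not one of the 20 canonical).
#' @export
residue_rsa <- function(complex, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(complex, "complex_structure"))
  at <- complex$atoms
  asa <- atom_sasa(at, probe, n_points)
  key <- paste(at$chain, at$resno, sep = "|")
  agg <- tapply(asa, key, sum)
  first <- !duplicated(key)
  res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    aa = at$aa[first], stringsAsFactors = FALSE)
  res$asa <- as.numeric(agg[paste(res$chain, res$resno, sep = "|")])
  res$rsa <- res$asa / AA_MAX_ASA[res$aa]
  res
}
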
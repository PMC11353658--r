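# Contact-based binding-affinity scoring of two-group complexes:
# interfacial-contact classification, non-interacting-surface composition,
# the printed linear free-energy model, Kd conversion and stage-weighted
# docking score combination.

IC_PAIR_LEVELS <- c("charged_charged", "charged_polar", "charged_apolar",
                    "polar_polar", "polar_apolar", "apolar_apolar")

.pair_label <- function(ca, cb) {
  ord <- c(charged = 1L, polar = 2L, apolar = 3L)
  a <- ifelse(ord[ca] <= ord[cb], ca, cb)
  b <- ifelse(ord[ca] <= ord[cb], cb, ca)
  paste(a, b, sep = "_")
}

.residue_class <- function(aa, resid, class_map) {
  cls <- class_map[aa]
  if (any(is.na(cls))) {
    bad <- unique(resid[is.na(cls)])
    stop(sprintf("residue(s) without a polarity class: %s",
                 paste(bad, collapse = ", ")))
  }
  cls
}

#' Classified interfacial contacts of a two-group complex
#'
#' An interfacial contact (IC) is an unordered residue pair, one residue
#' from each chain group, with any heavy-atom--heavy-atom distance within
#' the cutoff. Contacts are binned by the unordered pair of residue
#' polarity classes (charged / polar / apolar).
#'
#' @param complex A `complex_structure`.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 5.5).
#' @param class_map Named character vector mapping one-letter residue
#'   codes to `"charged"`, `"polar"` or `"apolar"`; editable, defaults to
#'   the map shipped with the package.
#' @return A list of class `interface_stats` with `ic` (named counts over
#'   the six unordered class pairs), `contacts` (data frame of the residue
#'   pairs) and the parameters used.
#' @export
interfacial_contacts <- function(complex, cutoff = 5.5,
                                 class_map = AA_POLARITY_CLASS) {
  stopifnot(inherits(complex, "complex_structure"))
  at <- complex$atoms
  ia <- at$chain %in% complex$group_a
  ib <- at$chain %in% complex$group_b
  if (!any(ia) || !any(ib)) stop("both chain groups must have atoms")
  A <- at[ia, , drop = FALSE]; B <- at[ib, , drop = FALSE]
  counts <- stats::setNames(integer(length(IC_PAIR_LEVELS)), IC_PAIR_LEVELS)
  pairs <- list()
  if (cutoff >= 0 && nrow(A) && nrow(B)) {
    ax <- as.matrix(A[, c("x", "y", "z")])
    bx <- as.matrix(B[, c("x", "y", "z")])
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), `+`) - 2 * ax %*% t(bx)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      res_a <- paste(A$chain[hit[, 1]], A$resno[hit[, 1]], sep = "|")
      res_b <- paste(B$chain[hit[, 2]], B$resno[hit[, 2]], sep = "|")
      keep <- !duplicated(paste(res_a, res_b, sep = "~"))
      ra <- hit[keep, 1]; rb <- hit[keep, 2]
      ca <- .residue_class(A$aa[ra], A$resid[ra], class_map)
      cb <- .residue_class(B$aa[rb], B$resid[rb], class_map)
      lab <- .pair_label(ca, cb)
      tab <- table(factor(lab, levels = IC_PAIR_LEVELS))
      counts[] <- as.integer(tab)
      pairs <- data.frame(
        chain_a = A$chain[ra], resno_a = A$resno[ra], aa_a = A$aa[ra],
        chain_b = B$chain[rb], resno_b = B$resno[rb], aa_b = B$aa[rb],
        class_pair = lab, stringsAsFactors = FALSE)
    }
  }
  if (!is.data.frame(pairs))
    pairs <- data.frame(chain_a = character(0), resno_a = character(0),
                        aa_a = character(0), chain_b = character(0),
                        resno_b = character(0), aa_b = character(0),
                        class_pair = character(0), stringsAsFactors = FALSE)
  structure(list(ic = counts, contacts = pairs, cutoff = cutoff),
            class = "interface_stats")
}

#' @export
print.interface_stats <- function(x, ...) {
  cat(sprintf("interface_stats (cutoff %.2f A): %d contact(s)\n",
              x$cutoff, sum(x$ic)))
  print(x$ic)
  if (!is.null(x$nis)) {
    cat(sprintf("NIS%%: apolar %.3f, charged %.3f, polar %.3f (rsa >= %.2f)\n",
                x$nis[["apolar"]], x$nis[["charged"]], x$nis[["polar"]],
                x$rsa_threshold))
  }
  invisible(x)
}

#' Non-interacting surface composition
#'
#' Surface residues are those with relative solvent accessibility (on the
#' complex) at or above the threshold; non-interacting surface (NIS)
#' residues are surface residues that take part in no interfacial
#' contact. Returns the percentage of NIS residues in each polarity
#' class (the three percentages sum to 100).
#'
#' @inheritParams interfacial_contacts
#' @param rsa_threshold Relative accessibility defining the surface
#'   (default 0.05).
#' @param probe Probe radius in angstroms.
#' @param n_points Sphere points per atom for the surface calculation.
#' @param contacts Optional precomputed [interfacial_contacts()] result.
#' @return Named numeric vector: `apolar`, `charged`, `polar` percentages.
#' @export
nis_percentages <- function(complex, rsa_threshold = 0.05, probe = 1.4,
                            n_points = 960L, cutoff = 5.5,
                            class_map = AA_POLARITY_CLASS, contacts = NULL) {
  stopifnot(inherits(complex, "complex_structure"))
  if (is.null(contacts))
    contacts <- interfacial_contacts(complex, cutoff, class_map)
  rsa <- residue_rsa(complex, probe, n_points)
  if (any(is.na(rsa$aa)))
    stop(sprintf("residue(s) without a polarity class: %s",
                 paste(unique(complex$atoms$resid[is.na(complex$atoms$aa)]),
                       collapse = ", ")))
  surf <- rsa[rsa$rsa >= rsa_threshold, , drop = FALSE]
  if (!nrow(surf)) stop("no surface residues at this RSA threshold")
  ic_res <- unique(c(paste(contacts$contacts$chain_a,
                           contacts$contacts$resno_a, sep = "|"),
                     paste(contacts$contacts$chain_b,
                           contacts$contacts$resno_b, sep = "|")))
  key <- paste(surf$chain, surf$resno, sep = "|")
  nis <- surf[!key %in% ic_res, , drop = FALSE]
  if (!nrow(nis))
    return(c(apolar = 0, charged = 0, polar = 0))
  cls <- .residue_class(nis$aa, nis$aa, class_map)
  tab <- table(factor(cls, levels = c("apolar", "charged", "polar")))
  out <- 100 * as.numeric(tab) / nrow(nis)
  names(out) <- c("apolar", "charged", "polar")
  out
}

#' Full interface statistics of a complex
#'
#' Convenience wrapper combining [interfacial_contacts()] and
#' [nis_percentages()] into the input of
#' [predict_binding_affinity()].
#'
#' @inheritParams nis_percentages
#' @return An `interface_stats` object with both `ic` counts and `nis`
#'   percentages.
#' @export
interface_stats <- function(complex, cutoff = 5.5, rsa_threshold = 0.05,
                            probe = 1.4, n_points = 960L,
                            class_map = AA_POLARITY_CLASS) {
  ics <- interfacial_contacts(complex, cutoff, class_map)
  ics$nis <- nis_percentages(complex, rsa_threshold, probe, n_points,
                             cutoff, class_map, contacts = ics)
  ics$rsa_threshold <- rsa_threshold
  ics
}

#' Contact-based binding-affinity prediction
#'
#' Linear free-energy model over classified interfacial contacts and the
#' non-interacting-surface composition:
#' dG = -0.09459 IC(charged,charged) - 0.10007 IC(charged,apolar)
#'      + 0.19577 IC(polar,polar) - 0.22671 IC(polar,apolar)
#'      + 0.18681 NIS%(apolar) + 0.3810 NIS%(charged) - 15.9433.
#' Charged--polar and apolar--apolar contacts carry zero weight, as
#' printed in the source model.
#'
#' @param stats An `interface_stats` object (with `nis` set), or a named
#'   list/vector with elements `charged_charged`, `charged_apolar`,
#'   `polar_polar`, `polar_apolar`, `nis_apolar`, `nis_charged`.
#' @return Predicted binding free energy in kcal/mol.
#' @examples
#' predict_binding_affinity(c(charged_charged = 0, charged_apolar = 0,
#'   polar_polar = 0, polar_apolar = 0, nis_apolar = 0, nis_charged = 0))
#' @export
predict_binding_affinity <- function(stats) {
  if (inherits(stats, "interface_stats")) {
    if (is.null(stats$nis))
      stop("interface_stats lacks NIS percentages; use interface_stats()")
    v <- c(stats$ic[c("charged_charged", "charged_apolar",
                      "polar_polar", "polar_apolar")],
           nis_apolar = unname(stats$nis[["apolar"]]),
           nis_charged = unname(stats$nis[["charged"]]))
  } else {
    v <- unlist(stats)
  }
  need <- c("charged_charged", "charged_apolar", "polar_polar",
            "polar_apolar", "nis_apolar", "nis_charged")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop(sprintf("missing component(s): %s", paste(miss, collapse = ", ")))
  unname(-0.09459 * v["charged_charged"] - 0.10007 * v["charged_apolar"] +
           0.19577 * v["polar_polar"] - 0.22671 * v["polar_apolar"] +
           0.18681 * v["nis_apolar"] + 0.3810 * v["nis_charged"] - 15.9433)
}

#' Dissociation constant from binding free energy
#'
#' Kd = exp(dG / (R T)) with R = 1.9872e-3 kcal K^-1 mol^-1, from
#' dG = R T ln Kd.
#'
#' @param dg Binding free energy in kcal/mol.
#' @param temperature Temperature in K (default 298.15, i.e. 25 C).
#' @return Kd in mol/L.
#' @examples
#' kd_from_dg(-12.3)  # ~9.6e-10 M
#' @export
kd_from_dg <- function(dg, temperature = 298.15) {
  exp(dg / (GAS_CONSTANT_KCAL * temperature))
}

#' Binding free energy from a dissociation constant
#'
#' Inverse of [kd_from_dg()]; exact round trip.
#'
#' @param kd Dissociation constant in mol/L (> 0).
#' @param temperature Temperature in K.
#' @return dG in kcal/mol.
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be positive")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Stage-weighted docking score combination
#'
#' Weighted sum of docking energy components, with weights depending on
#' the protocol stage:
#' it0 = 0.01 EvdW + 0.1 Eelec + 1.0 Edesolv - 0.01 BSA + 0.01 EAIR;
#' it1 = 1.0 EvdW + 1.0 Eelec + 1.0 Edesolv - 0.01 BSA + 0.1 EAIR;
#' itw = 1.0 EvdW + 1.0 Eelec + 1.0 Edesolv + 0.01 EAIR (no BSA term).
#' The energy components are inputs; no docking is performed.
#'
#' @param e_vdw,e_elec,e_desolv,e_air Energy components in kcal/mol.
#' @param bsa Buried surface area in squared angstroms.
#' @param stage `"it0"`, `"it1"` or `"itw"`.
#' @return The combined score.
#' @export
haddock_stage_score <- function(e_vdw, e_elec, e_desolv, bsa, e_air,
                                stage = c("it0", "it1", "itw")) {
  stage <- match.arg(stage)
  stopifnot(all(is.finite(c(e_vdw, e_elec, e_desolv, bsa, e_air))))
  switch(stage,
    it0 = 0.01 * e_vdw + 0.1 * e_elec + 1.0 * e_desolv - 0.01 * bsa + 0.01 * e_air,
    it1 = 1.0 * e_vdw + 1.0 * e_elec + 1.0 * e_desolv - 0.01 * bsa + 0.1 * e_air,
    itw = 1.0 * e_vdw + 1.0 * e_elec + 1.0 * e_desolv + 0.01 * e_air)
}

#' Binding affinity of a parsed complex
#'
#' End-to-end convenience: interface statistics, free-energy prediction
#' and Kd conversion for one complex.
#'
#' @inheritParams interface_stats
#' @param temperature Temperature in K for the Kd conversion.
#' @return A list of class `affinity_result`: `dg` (kcal/mol), `kd`
#'   (mol/L), `temperature`, `gas_constant` and the `interface_stats`.
#' @export
binding_affinity <- function(complex, cutoff = 5.5, rsa_threshold = 0.05,
                             temperature = 298.15, probe = 1.4,
                             n_points = 960L,
                             class_map = AA_POLARITY_CLASS) {
  st <- interface_stats(complex, cutoff, rsa_threshold, probe, n_points,
                        class_map)
  dg <- predict_binding_affinity(st)
  structure(list(dg = dg, kd = kd_from_dg(dg, temperature),
                 temperature = temperature,
                 gas_constant = GAS_CONSTANT_KCAL, stats = st),
            class = "affinity_result")
}

#' @export
print.affinity_result <- function(x, ...) {
  cat(sprintf("predicted dG = %.4f kcal/mol; Kd = %.3e M at %.2f K\n",
              x$dg, x$kd, x$temperature))
  invisible(x)
}
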
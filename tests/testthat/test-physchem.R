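# Frozen expected values for the two reference sequences were computed
# with an independent protein-analysis implementation before these tests
# were written.
REF1 <- "MKWVTFISLLLLFSSAYSRGV"
REF2 <- "ACDEFGHIKLMNPQRSTVWY"

test_that("molecular weight matches the independent oracle and additivity", {
  expect_equal(molecular_weight("PPPS", "monoisotopic"), 396.20088,
               tolerance = 1e-6)
  expect_equal(molecular_weight("G", "monoisotopic"), 75.03202,
               tolerance = 1e-5)
  expect_equal(molecular_weight(REF1, "average"), 2418.8923,
               tolerance = 1e-3)
  expect_equal(molecular_weight(REF2, "average"), 2395.7134,
               tolerance = 1e-3)

  set.seed(13)
  for (i in 1:20) {
    a <- random_sequence(sample(1:30, 1))
    b <- random_sequence(sample(1:30, 1))
    for (mode in c("average", "monoisotopic")) {
      water <- if (mode == "average") 18.0153 else 18.010565
      expect_equal(molecular_weight(paste0(a, b), mode),
                   molecular_weight(a, mode) + molecular_weight(b, mode) -
                     water, tolerance = 1e-9)
    }
  }
})

test_that("GRAVY is the hydropathy mean and stays within scale bounds", {
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy(REF1), 1.071429, tolerance = 1e-6)
  expect_equal(gravy(REF2), -0.49, tolerance = 1e-9)
  set.seed(37)
  for (i in 1:100) {
    s <- random_sequence(sample(1:200, 1))
    g <- gravy(s)
    chars <- strsplit(s, "")[[1]]
    expect_equal(g, sum(pepsilico:::AA_KD_HYDROPATHY[chars]) / nchar(s))
    expect_gte(g, -4.5); expect_lte(g, 4.5)
  }
})

test_that("aliphatic index follows Ikai's mole-percent formula", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("IILL"), 390)
  expect_equal(aliphatic_index("DDDD"), 0)
  expect_equal(aliphatic_index("AVIL"), 25 + 2.9 * 25 + 3.9 * 50)
})

test_that("instability index matches the dipeptide-weight oracle", {
  # poly-A tetrapeptide: (10/4) * 3 * DIWV(A,A) = 7.5 with DIWV(A,A) = 1
  expect_equal(as.numeric(instability_index("AAAA")), 7.5)
  expect_equal(as.numeric(instability_index(REF1)), 21.6143,
               tolerance = 1e-4)
  expect_equal(as.numeric(instability_index(REF2)), 84.74,
               tolerance = 1e-4)
  expect_error(instability_index("A"), "at least 2")

  set.seed(43)
  for (i in 1:20) {
    s <- random_sequence(100)
    chars <- strsplit(s, "")[[1]]
    acc <- 0
    for (j in 1:99) acc <- acc + pepsilico:::AA_DIWV[chars[j], chars[j + 1]]
    expect_equal(as.numeric(instability_index(s)), 10 / 100 * acc)
  }
})

test_that("stability class is unstable strictly above 40", {
  expect_equal(attr(instability_index(REF2), "stability_class"), "unstable")
  expect_equal(attr(instability_index("AAAA"), "stability_class"), "stable")
})

test_that("pI is the unique zero of the monotone titration curve", {
  set.seed(47)
  for (i in 1:20) {
    s <- random_sequence(sample(2:60, 1))
    pi_val <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pi_val)), 1e-3)
    # strictly decreasing in pH
    ph <- seq(0.5, 13.5, length.out = 20)
    q <- vapply(ph, function(p) net_charge(s, p), numeric(1))
    expect_true(all(diff(q) < 0))
  }
  expect_gt(isoelectric_point("K"), isoelectric_point("D"))
})

test_that("charged residue counts are simple D+E / K+R tallies", {
  expect_equal(charged_residue_counts("DEKR"), c(neg = 2L, pos = 2L))
  expect_equal(charged_residue_counts("AAAA"), c(neg = 0L, pos = 0L))
  expect_equal(charged_residue_counts("DDEEEKKRRR"), c(neg = 5L, pos = 5L))
})

test_that("extinction coefficients follow the chromophore sums", {
  expect_equal(extinction_coefficient("AAAA"), 0)
  expect_equal(extinction_coefficient("WY"), 6990)
  expect_equal(extinction_coefficient(REF1, "reduced"), 6990)
  expect_equal(extinction_coefficient("CC", "oxidized"), 125)
  expect_equal(extinction_coefficient("CC", "reduced"), 0)
  expect_equal(extinction_coefficient("CCC", "oxidized"), 125)  # one pair
})

test_that("five-class residue fractions cover all residues and sum to 1", {
  d <- aa_class_distribution("DEKR")
  expect_equal(unname(d["negative"]), 0.5)
  expect_equal(unname(d["positive"]), 0.5)
  expect_equal(unname(d["nonpolar"] + d["polar"] + d["aromatic"]), 0)
  expect_equal(unname(aa_class_distribution("YWF")["aromatic"]), 1)

  set.seed(53)
  for (i in 1:50) {
    s <- random_sequence(sample(1:100, 1))
    fr <- aa_class_distribution(s)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    chars <- strsplit(s, "")[[1]]
    expect_equal(unname(fr["nonpolar"]),
                 mean(chars %in% c("V", "P", "M", "L", "I", "G", "A")))
  }
})

test_that("half-life lookup keys on the N-terminal residue", {
  expect_equal(half_life("MKWV", "mammalian"), "30 hour")
  expect_equal(half_life("VAAA", "mammalian"), "100 hour")
  expect_equal(half_life("RAAA", "yeast"), "2 min")
})

test_that("physchem_report assembles one consistent row per record", {
  rec <- data.frame(id = c("a", "b"), sequence = c(REF1, REF2))
  rep <- physchem_report(rec)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$length, c(21L, 20L))
  expect_equal(rep$gravy, c(1.071429, -0.49), tolerance = 1e-6)
  expect_equal(rep$stability_class, c("stable", "unstable"))
  expect_equal(rep$frac_negative + rep$frac_positive + rep$frac_nonpolar +
                 rep$frac_polar + rep$frac_aromatic, c(1, 1),
               tolerance = 1e-9)
})
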
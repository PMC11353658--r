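test_that("far-apart chains have zero interfacial contacts", {
  toy <- generate_toy_complex(n_contacts = 0, seed = 2)
  cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
  ic <- interfacial_contacts(cx)
  expect_equal(sum(ic$ic), 0L)
  # cutoff 0 also yields none for non-overlapping structures
  expect_equal(sum(interfacial_contacts(cx, cutoff = 0)$ic), 0L)
})

test_that("contact counts match the generator's declared ground truth", {
  toy <- generate_toy_complex(sequence_a = "KDLSAVGE",
                              sequence_b = "RETSVGLA",
                              n_contacts = 3, seed = 2)
  cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
  ic <- interfacial_contacts(cx)
  expect_equal(ic$ic, toy$truth$ic)
  expect_equal(nrow(ic$contacts), 3L)
})

test_that("contact counting agrees with an all-pairs oracle on random toys", {
  set.seed(83)
  for (i in 1:20) {
    sa <- random_sequence(sample(4:8, 1))
    sb <- random_sequence(sample(4:8, 1))
    toy <- generate_toy_complex(sa, sb,
                                n_contacts = sample(0:min(nchar(sa), nchar(sb)), 1),
                                seed = i)
    cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
    cutoff <- runif(1, 4, 8)
    ic <- interfacial_contacts(cx, cutoff = cutoff)
    A <- cx$atoms[cx$atoms$chain == "A", ]
    B <- cx$atoms[cx$atoms$chain == "B", ]
    expect_equal(sum(ic$ic), length(oracle_contacts(A, B, cutoff)))
  }
})

test_that("contact classification is symmetric under group swap", {
  toy <- generate_toy_complex("KDLSAVGE", "RETSVGLA", n_contacts = 4,
                              seed = 9)
  path <- toy_complex_file(toy)
  ab <- interfacial_contacts(read_pdb_complex(path, "A", "B"))
  ba <- interfacial_contacts(read_pdb_complex(path, "B", "A"))
  expect_equal(ab$ic, ba$ic)
})

test_that("NIS percentages are normalized over NIS residues", {
  toy <- generate_toy_complex("KDLSAVGE", "RETSVGLA", n_contacts = 2,
                              seed = 4)
  cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
  nis <- nis_percentages(cx)
  expect_equal(sum(nis), 100, tolerance = 1e-6)
  expect_true(all(nis >= 0))
  # the grid toys are fully exposed: every non-contact residue is NIS,
  # so class percentages reflect the class map of those residues
  st <- interface_stats(cx)
  ic_res <- unique(c(paste(st$contacts$chain_a, st$contacts$resno_a),
                     paste(st$contacts$chain_b, st$contacts$resno_b)))
  all_res <- c(strsplit("KDLSAVGE", "")[[1]], strsplit("RETSVGLA", "")[[1]])
  keys <- c(paste("A", 1:8), paste("B", 1:8))
  nis_aa <- all_res[!keys %in% ic_res]
  cls <- pepsilico:::AA_POLARITY_CLASS[nis_aa]
  expect_equal(unname(nis[["charged"]]),
               100 * mean(cls == "charged"), tolerance = 1e-6)
})

test_that("an unreachable RSA threshold is reported as an empty surface", {
  toy <- generate_toy_complex(n_contacts = 0, seed = 5)
  cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
  expect_error(nis_percentages(cx, rsa_threshold = 10), "no surface")
})

test_that("the affinity model evaluates the printed linear form", {
  zero <- c(charged_charged = 0, charged_apolar = 0, polar_polar = 0,
            polar_apolar = 0, nis_apolar = 0, nis_charged = 0)
  expect_equal(predict_binding_affinity(zero), -15.9433)
  pp10 <- zero; pp10["polar_polar"] <- 10
  expect_equal(predict_binding_affinity(pp10), -15.9433 + 1.9577,
               tolerance = 1e-10)

  set.seed(89)
  for (i in 1:50) {
    v <- c(charged_charged = sample(0:30, 1), charged_apolar = sample(0:30, 1),
           polar_polar = sample(0:30, 1), polar_apolar = sample(0:30, 1),
           nis_apolar = runif(1, 0, 100), nis_charged = runif(1, 0, 100))
    by_hand <- sum(c(-0.09459, -0.10007, 0.19577, -0.22671,
                     0.18681, 0.3810) * v) - 15.9433
    expect_equal(predict_binding_affinity(v), by_hand, tolerance = 1e-10)
  }
})

test_that("the affinity model is linear in its components", {
  set.seed(97)
  dg0 <- predict_binding_affinity(
    c(charged_charged = 0, charged_apolar = 0, polar_polar = 0,
      polar_apolar = 0, nis_apolar = 0, nis_charged = 0))
  for (i in 1:10) {
    s1 <- c(charged_charged = sample(0:9, 1), charged_apolar = sample(0:9, 1),
            polar_polar = sample(0:9, 1), polar_apolar = sample(0:9, 1),
            nis_apolar = runif(1, 0, 50), nis_charged = runif(1, 0, 50))
    s2 <- c(charged_charged = sample(0:9, 1), charged_apolar = sample(0:9, 1),
            polar_polar = sample(0:9, 1), polar_apolar = sample(0:9, 1),
            nis_apolar = runif(1, 0, 50), nis_charged = runif(1, 0, 50))
    lhs <- predict_binding_affinity(s1 + s2) - dg0
    rhs <- (predict_binding_affinity(s1) - dg0) +
      (predict_binding_affinity(s2) - dg0)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("Kd conversion and its inverse are exact round trips", {
  expect_equal(kd_from_dg(0), 1)
  expect_error(dg_from_kd(0), "positive")
  set.seed(101)
  x <- runif(1000, -20, 5)
  expect_equal(dg_from_kd(kd_from_dg(x)), x, tolerance = 1e-12)
  kd <- 10^runif(100, -12, 0)
  expect_equal(kd_from_dg(dg_from_kd(kd)), kd, tolerance = 1e-12)
})

test_that("stage scores apply the printed stage weights", {
  expect_equal(haddock_stage_score(0, 0, 0, 0, 0, "it0"), 0)
  expect_equal(haddock_stage_score(0, 0, 0, 0, 0, "it1"), 0)
  expect_equal(haddock_stage_score(0, 0, 0, 0, 0, "itw"), 0)
  expect_equal(haddock_stage_score(10, 10, 10, 100, 10, "it0"),
               0.1 + 1 + 10 - 1 + 0.1)
  expect_equal(haddock_stage_score(10, 10, 10, 100, 10, "it1"),
               10 + 10 + 10 - 1 + 1)
  # itw has no buried-surface term
  expect_equal(haddock_stage_score(10, 10, 10, 100, 10, "itw"),
               haddock_stage_score(10, 10, 10, 99999, 10, "itw"))
  expect_error(haddock_stage_score(0, 0, 0, 0, 0, "it9"))
})

test_that("single-residue SASA approaches the isolated-sphere analytic value", {
  # one fully exposed atom: ASA must equal 4*pi*(r + probe)^2
  atoms <- data.frame(x = 0, y = 0, z = 0, element = "C")
  expect_equal(atom_sasa(atoms), 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  # two distant atoms are both fully exposed
  atoms2 <- data.frame(x = c(0, 50), y = 0, z = 0, element = c("N", "O"))
  expect_equal(atom_sasa(atoms2),
               4 * pi * (c(1.55, 1.52) + 1.4)^2, tolerance = 1e-9)
  # a buried atom loses surface
  cluster <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  cluster$element <- "C"
  sas <- atom_sasa(cluster)
  center <- which(cluster$x == 0 & cluster$y == 0 & cluster$z == 0)
  expect_lt(sas[center], min(sas[-center]))
})

test_that("end-to-end binding affinity is reproducible on a toy complex", {
  toy <- generate_toy_complex("KDLSAVGE", "RETSVGLA", n_contacts = 3,
                              seed = 6)
  cx <- read_pdb_complex(toy_complex_file(toy), "A", "B")
  a1 <- binding_affinity(cx)
  a2 <- binding_affinity(cx)
  expect_identical(a1$dg, a2$dg)   # fixed sphere points: bit-reproducible
  expect_equal(a1$kd, kd_from_dg(a1$dg), tolerance = 1e-15)
  expect_equal(a1$dg, a1$gas_constant * a1$temperature * log(a1$kd),
               tolerance = 1e-9)
})
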
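ace_db <- data.frame(fragment = c("AAK", "AA"),
                     activity = c("ACE inhibitor", "ACE inhibitor"),
                     source_id = c("d1", "d2"),
                     stringsAsFactors = FALSE)

test_that("released-fragment matching is exact and multiplicity-preserving", {
  expect_equal(match_released(c("AAK", "AAR"), ace_db, "ACE inhibitor"),
               "AAK")
  expect_equal(match_released(character(0), ace_db, "ACE inhibitor"),
               character(0))
  # same sequence released at two loci counts twice
  expect_equal(match_released(c("AAK", "AAK"), ace_db, "ACE inhibitor"),
               c("AAK", "AAK"))
  # containment does not match
  expect_equal(match_released("AAKA", ace_db, "ACE inhibitor"),
               character(0))
  # unknown activity yields an empty result, not an error
  expect_equal(match_released("AAK", ace_db, "renin inhibitor"),
               character(0))
})

test_that("matching agrees with a brute-force double loop", {
  set.seed(17)
  frags <- replicate(100, random_sequence(sample(2:5, 1)))
  db <- generate_motif_db(10, lengths = 2:4, seed = 17)
  for (act in unique(db$activity)) {
    brute <- character(0)
    for (f in frags)
      for (k in which(db$activity == act))
        if (identical(f, db$fragment[k])) { brute <- c(brute, f); break }
    expect_equal(match_released(frags, db, act), brute)
  }
})

test_that("AE follows d/N including the worked tryptic digest", {
  expect_equal(release_frequency_AE(1, 8), 0.125)
  expect_equal(release_frequency_AE(0, 50), 0)
  expect_equal(release_frequency_AE(3, 100), 0.03)
  expect_error(release_frequency_AE(1, 0), ">= 1")

  # full path: AAKAARAA digested at K/R releases AAK once; AE = 1/8
  dg <- digest("AAKAARAA", kr_rule())
  d_rel <- length(match_released(dg$retained$sequence, ace_db,
                                 "ACE inhibitor"))
  expect_equal(release_frequency_AE(d_rel, 8), 0.125)
})

test_that("occurrence density A counts overlapping substring starts", {
  # "AA" occurs in AAKAARAA at starts 1, 4, 7 only
  db <- data.frame(fragment = "AA", activity = "x", source_id = "s")
  expect_equal(profile_density_A("AAKAARAA", db, "x"), 3 / 8)
  expect_equal(profile_density_A("AAKAARAA", db, "absent"), 0)

  set.seed(19)
  for (i in 1:50) {
    s <- random_sequence(60)
    db2 <- generate_motif_db(6, lengths = 2:3, seed = i)
    act <- db2$activity[1]
    brute <- sum(vapply(unique(db2$fragment[db2$activity == act]),
                        function(f) oracle_substring_count(s, f),
                        integer(1)))
    expect_equal(profile_density_A(s, db2, act), brute / 60)
  }
})

test_that("W = AE/A with NA (never infinity) at A = 0", {
  expect_equal(relative_frequency_W(0.1, 0.2), 0.5)
  expect_equal(relative_frequency_W(0, 0.7), 0)
  expect_true(is.na(relative_frequency_W(0.2, 0)))

  # worked case: AAKAARAA, db {AAK}, K/R rule -> AE = 1/8, A = 1/8, W = 1
  db <- data.frame(fragment = "AAK", activity = "ACE inhibitor",
                   source_id = "d1")
  prof <- activity_profile(list(id = "p", sequence = "AAKAARAA"),
                           kr_rule(), db, "ACE inhibitor")
  expect_equal(prof$AE, 0.125)
  expect_equal(prof$A, 0.125)
  expect_equal(prof$W, 1)
})

test_that("released matches never exceed substring occurrences (AE <= A)", {
  set.seed(29)
  for (i in 1:200) {
    s <- random_sequence(sample(10:80, 1))
    rule <- protease_rule("r", list(p1 = sample(pepsilico:::AA_ALPHABET, 3)))
    db <- generate_motif_db(5, lengths = 3:4, from = s, seed = i)
    act <- db$activity[1]
    dg <- digest(s, rule)
    d_rel <- length(match_released(dg$retained$sequence, db, act))
    ae <- release_frequency_AE(d_rel, nchar(s))
    a <- profile_density_A(s, db, act)
    expect_lte(ae, a + 1e-12)
  }
})

test_that("activity_summary sums per-protein AE and doubles for twins", {
  db <- data.frame(fragment = c("AAK", "VPP"),
                   activity = c("ACE inhibitor", "ACE inhibitor"),
                   source_id = c("1", "2"))
  one <- data.frame(id = "p1", sequence = "AAKAARAA")
  s1 <- activity_summary(one, list(kr_rule()), db, "ACE inhibitor")
  expect_equal(s1$sum_AE, 0.125)

  twin <- data.frame(id = c("p1", "p2"), sequence = rep("AAKAARAA", 2))
  s2 <- activity_summary(twin, list(kr_rule()), db, "ACE inhibitor")
  expect_equal(s2$sum_AE, 0.25)

  # synthetic 3-protein set equals per-protein recomputation summed
  prot <- generate_proteins(n = 3, length = 90, seed = 41)
  db3 <- generate_motif_db(8, lengths = 3:4, from = prot$sequence, seed = 41)
  acts <- unique(db3$activity)
  summ <- activity_summary(prot, list(kr_rule()), db3, acts)
  for (act in acts) {
    by_hand <- sum(vapply(seq_len(3), function(i)
      activity_profile(prot[i, ], kr_rule(), db3, act)$AE, numeric(1)))
    expect_equal(summ$sum_AE[summ$activity == act], by_hand)
  }
})

test_that("activities absent from the db give all-zero profiles", {
  prof <- activity_profile(list(id = "p", sequence = "AAKAARAA"),
                           kr_rule(), ace_db, c("ACE inhibitor", "unknown"))
  row <- prof[prof$activity == "unknown", ]
  expect_equal(row$d_released, 0L)
  expect_equal(row$AE, 0)
  expect_equal(row$A, 0)
  expect_true(is.na(row$W))
})
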
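toy_groups <- function(n_a = 2L, n_b = 2L, n_q = 0L) {
  c(rep("GROUP_A", n_a), rep("GROUP_B", n_b), rep("QUERY", n_q))
}

make_grouped <- function(seqs, groups, ref = names(seqs)[1L]) {
  ref_alignment(seqs, meta = data.frame(id = names(seqs),
                                        species = names(seqs),
                                        group = groups),
                reference_id = ref)
}

test_that("discovery on the worked-example alignment finds the 12 fingerprint positions", {
  aln <- hcar_fixture_alignment()
  prof <- discover_diagnostic_positions(aln)
  expect_equal(prof$position,
               c(27L, 83L, 86L, 91L, 103L, 107L, 142L, 167L, 168L, 173L,
                 176L, 178L))
  # states stated in the source text: 27 V/A, 173 G/T, 167 HCAR3 = L
  expect_equal(prof$state_a[prof$position == 27], "V")
  expect_equal(prof$state_b[prof$position == 27], "A")
  expect_equal(prof$state_a[prof$position == 173], "G")
  expect_equal(prof$state_b[prof$position == 173], "T")
  expect_equal(prof$state_b[prof$position == 167], "L")
  # the non-diagnostic remainder of the 18 differing positions
  expect_equal(length(nondiagnostic_difference_positions(aln)), 6L)
})

test_that("identical groups yield an empty profile; missing group errors", {
  seqs <- c(a1 = "MKLV", a2 = "MKLV", b1 = "MKLV", b2 = "MKLV")
  aln <- make_grouped(seqs, toy_groups())
  expect_silent_profile <- suppressWarnings(discover_diagnostic_positions(aln))
  expect_equal(nrow(expect_silent_profile), 0L)

  aln2 <- make_grouped(seqs, c(rep("GROUP_A", 4L)))
  expect_error(suppressWarnings(discover_diagnostic_positions(aln2)),
               "GROUP_B")
})

test_that("strict discovery excludes gap/X columns and insertion columns", {
  seqs <- c(a1 = "MKLVW", a2 = "MKLVW",
            b1 = "MQLXW", b2 = "MQL-W")
  aln <- make_grouped(seqs, toy_groups())
  prof <- suppressWarnings(discover_diagnostic_positions(aln))
  expect_equal(prof$position, 2L)   # pos 4 has X and gap in group B
  # insertion column (reference gap) never becomes diagnostic
  seqs2 <- c(a1 = "MK-LV", a2 = "MK-LV", b1 = "MKWLV", b2 = "MKWLV")
  prof2 <- suppressWarnings(discover_diagnostic_positions(
    make_grouped(seqs2, toy_groups())))
  expect_equal(nrow(prof2), 0L)
})

test_that("relaxed discovery requires disjoint state sets", {
  seqs <- c(a1 = "MKL", a2 = "MRL", b1 = "MQL", b2 = "MEL")
  prof <- suppressWarnings(discover_diagnostic_positions(
    make_grouped(seqs, toy_groups()), strict = FALSE))
  expect_equal(prof$position, 2L)
  expect_equal(prof$state_a, "KR")
  expect_equal(prof$state_b, "EQ")
  # same column fails strict mode
  strictp <- suppressWarnings(discover_diagnostic_positions(
    make_grouped(seqs, toy_groups()), strict = TRUE))
  expect_equal(nrow(strictp), 0L)
})

test_that("discovery matches the exhaustive per-column oracle on random alignments", {
  set.seed(101)
  for (i in 1:50) {
    seqs <- random_alignment(nseq = 8L, ncols = 50L)
    groups <- toy_groups(4L, 4L)
    aln <- make_grouped(seqs, groups)
    for (strict in c(TRUE, FALSE)) {
      got <- suppressWarnings(discover_diagnostic_positions(aln, strict))
      want <- oracle_discover(seqs, stats::setNames(
        ifelse(groups == "GROUP_A", "A", "B"), names(seqs)),
        ref = names(seqs)[1L], strict = strict)
      expect_equal(got$position, want$positions)
      expect_equal(got$state_a, want$state_a)
      expect_equal(got$state_b, want$state_b)
    }
  }
})

test_that("discovery is invariant to record order and duplicated group members", {
  aln <- hcar_fixture_alignment()
  prof <- discover_diagnostic_positions(aln)

  perm <- sample(names(aln$seqs))
  aln_perm <- ref_alignment(aln$seqs[perm],
                            meta = aln$meta[match(perm, aln$meta$id), ],
                            reference_id = "human_HCAR2")
  prof_perm <- discover_diagnostic_positions(aln_perm)
  expect_equal(prof_perm$position, prof$position)
  expect_equal(prof_perm$state_a, prof$state_a)

  dup <- c(aln$seqs, human_HCAR2_copy = unname(aln$seqs[["human_HCAR2"]]))
  meta <- rbind(aln$meta, data.frame(id = "human_HCAR2_copy",
                                     species = "Homo_sapiens",
                                     group = "GROUP_A"))
  prof_dup <- discover_diagnostic_positions(
    ref_alignment(dup, meta = meta, reference_id = "human_HCAR2"))
  expect_equal(prof_dup$position, prof$position)
})

test_that("pairwise substitution differences count only double-residue columns", {
  aln <- make_grouped(c(a = "MKLV", b = "MKIV", c = "MK-V"), toy_groups(1, 1, 1))
  expect_equal(count_pairwise_differences(aln, "a", "a"), 0L)
  expect_equal(count_pairwise_differences(aln, "a", "b"), 1L)
  expect_equal(count_pairwise_differences(aln, "a", "c"), 0L)  # gap excluded
  expect_error(count_pairwise_differences(aln, "a", "zz"), "unknown id")
  # the worked example's headline count
  hc <- hcar_fixture_alignment()
  expect_equal(count_pairwise_differences(hc, "human_HCAR2", "human_HCAR3"),
               18L)
})

test_that("pocket partition splits the profile as published", {
  prof <- discover_diagnostic_positions(hcar_fixture_alignment())
  part <- partition_by_pocket(prof, hcar_distal_positions())
  expect_equal(part$distal, c(27L, 142L, 167L, 168L, 173L))
  expect_equal(part$proximal, c(83L, 86L, 91L, 103L, 107L, 176L, 178L))
  expect_length(part$proximal, 7L)
  expect_error(partition_by_pocket(prof, c(27L, 999L)), "not in profile")
  # degenerate splits
  expect_equal(partition_by_pocket(prof, integer(0))$proximal, prof$position)
  expect_equal(partition_by_pocket(prof, prof$position)$proximal, integer(0))
})

test_that("per-lineage classification reproduces the published match counts", {
  aln <- hcar_fixture_alignment()
  prof <- partition_by_pocket(discover_diagnostic_positions(aln),
                              hcar_distal_positions())$profile

  counts <- function(id) {
    r <- classify_sequence(aln, id, prof)
    c(a = r$n_a, b = r$n_b, n = r$n_neither, amb = r$n_ambiguous)
  }
  # tarsier: 9 HCAR2, 2 HCAR3, serine at 173 matching neither
  expect_equal(counts("tarsier_HCAR23"), c(a = 9, b = 2, n = 1, amb = 0))
  tars <- classify_sequence(aln, "tarsier_HCAR23", prof)$calls
  expect_equal(tars$call[tars$position == 173], "NEITHER")
  expect_equal(tars$residue[tars$position == 173], "S")
  # New World monkey: S at 27 and N at 173 match neither profile
  marm <- classify_sequence(aln, "marmoset_HCAR23", prof)$calls
  expect_equal(marm$call[marm$position %in% c(27, 173)],
               c("NEITHER", "NEITHER"))
  expect_equal(marm$residue[marm$position %in% c(27, 173)], c("S", "N"))
  # Old World monkey: 11 HCAR2 + HCAR3-like threonine at 173
  expect_equal(counts("macaque_HCAR23"), c(a = 11, b = 1, n = 0, amb = 0))
  # strepsirrhine: 9 HCAR2, HCAR3-like at 27 and 168, neither at 173
  expect_equal(counts("sifaka_HCAR23"), c(a = 9, b = 2, n = 1, amb = 0))
  # siamang pair: 11/12 vs 8 HCAR3 + 3 HCAR2 + neither at 91
  expect_equal(counts("siamang_HCAR2like"), c(a = 11, b = 1, n = 0, amb = 0))
  expect_equal(counts("siamang_HCAR3like"), c(a = 3, b = 8, n = 1, amb = 0))
  sia <- classify_sequence(aln, "siamang_HCAR3like", prof)$calls
  expect_equal(sia$call[sia$position == 91], "NEITHER")
  # hoolock: one copy mirrors the siamang pattern with an ambiguous site,
  # the other shows 9 HCAR2 / 3 HCAR3
  expect_equal(counts("hoolock_copy1"), c(a = 3, b = 8, n = 0, amb = 1))
  expect_equal(counts("hoolock_copy2"), c(a = 9, b = 3, n = 0, amb = 0))
  # orangutan paralogs: 10 of 12 positions distinguish; 86 and 142 side with
  # the HCAR2 state in the HCAR3-like copy
  pon <- classify_sequence(aln, "pongo_abelii_HCAR3like", prof)$calls
  expect_equal(pon$position[pon$call == "MATCH_A"], c(86L, 142L))
  expect_equal(sum(pon$call == "MATCH_B"), 10L)
})

test_that("verdict rules behave as documented", {
  aln <- hcar_fixture_alignment()
  prof <- partition_by_pocket(discover_diagnostic_positions(aln),
                              hcar_distal_positions())$profile
  # pure consensus query
  r <- classify_sequence(aln, "human_HCAR2", prof)
  expect_equal(r$n_a, nrow(prof)); expect_equal(r$n_b, 0L)
  expect_equal(r$verdict, "A_LIKE")
  # distal-only mismatches keep the pocket verdict
  expect_equal(classify_sequence(aln, "tarsier_HCAR23", prof)$verdict,
               "A_LIKE")
  # a proximal A-state residue in a B-majority copy blocks B_LIKE under the
  # pocket rule but not under majority
  expect_equal(classify_sequence(aln, "siamang_HCAR3like", prof)$verdict,
               "MIXED")
  expect_equal(classify_sequence(aln, "siamang_HCAR3like", prof,
                                 rule = "majority")$verdict, "B_LIKE")
})

test_that("classification counts are complete and monotone under profile pruning", {
  aln <- hcar_fixture_alignment()
  prof <- discover_diagnostic_positions(aln)
  for (id in c("tarsier_HCAR23", "hoolock_copy1", "human_HCAR3")) {
    r <- classify_sequence(aln, id, prof)
    expect_equal(r$n_a + r$n_b + r$n_neither + r$n_ambiguous, nrow(prof))
    expect_lte(r$pocket_n_a, r$n_a)
    expect_lte(r$pocket_n_b, r$n_b)
    # dropping any one position never increases a count
    for (drop in sample(seq_len(nrow(prof)), 4L)) {
      sub <- prof[-drop, ]
      attr(sub, "reference_id") <- attr(prof, "reference_id")
      r2 <- classify_sequence(aln, id, sub)
      expect_lte(r2$n_a, r$n_a); expect_lte(r2$n_b, r$n_b)
      expect_lte(r2$n_neither, r$n_neither)
      expect_lte(r2$n_ambiguous, r$n_ambiguous)
    }
  }
})

test_that("group members classify with zero opposite-group matches", {
  aln <- hcar_fixture_alignment()
  prof <- discover_diagnostic_positions(aln)
  for (id in aln$meta$id[aln$meta$group == "GROUP_A"]) {
    expect_equal(classify_sequence(aln, id, prof)$n_b, 0L)
  }
  for (id in aln$meta$id[aln$meta$group == "GROUP_B"]) {
    expect_equal(classify_sequence(aln, id, prof)$n_a, 0L)
  }
})

test_that("classify_cohort vectorises classify_sequence and keeps input order", {
  aln <- hcar_fixture_alignment()
  prof <- discover_diagnostic_positions(aln)
  one <- classify_cohort(aln, prof, query_ids = "tarsier_HCAR23")
  expect_length(one$results, 1L)
  single <- classify_sequence(aln, "tarsier_HCAR23", prof)
  expect_identical(one$results[[1L]]$calls, single$calls)
  expect_equal(one$summary$n_a, single$n_a)

  all_q <- classify_cohort(aln, prof)
  expect_equal(all_q$summary$query_id,
               aln$meta$id[aln$meta$group == "QUERY"])
  expect_equal(all_q$summary$species[all_q$summary$query_id ==
                                       "tarsier_HCAR23"], "Carlito_syrichta")
})
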
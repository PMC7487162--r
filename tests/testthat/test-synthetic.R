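test_that("fixture generation is deterministic and truth-complete", {
  fr1 <- fixture_reference(n_families = 3, members_per_family = 4, seed = 5)
  fr2 <- fixture_reference(n_families = 3, members_per_family = 4, seed = 5)
  expect_identical(fr1$ref$sequences, fr2$ref$sequences)
  expect_identical(fr1$truth, fr2$truth)
  fr3 <- fixture_reference(n_families = 3, members_per_family = 4, seed = 6)
  expect_false(identical(fr1$ref$sequences, fr3$ref$sequences))

  # Same-seed byte identity extends to the written artifact directory.
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(fixture_write_all(d1, seed = 9, n_families = 3,
                                     members_per_family = 4, n_decoys = 3))
  suppressMessages(fixture_write_all(d2, seed = 9, n_families = 3,
                                     members_per_family = 4, n_decoys = 3))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  empty <- fixture_reference(n_families = 0, seed = 1)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("planted TM architecture is recovered by the hydropathy fallback", {
  fr <- fixture_reference(n_families = 2, members_per_family = 3,
                          tm_count = 6L, seed = 3)
  expect_equal(nrow(fr$truth), 6L)
  counted <- vapply(fr$ref$sequences, fallback_tm_count, integer(1))
  expect_equal(unname(counted), fr$truth$tm_count)

  tgt <- fixture_target_proteome(fr, members_per_family = 4,
                                 n_fragments = 3, n_soluble = 3,
                                 n_non_slc = 3, seed = 3)
  mem <- tgt$truth[tgt$truth$class == "member", ]
  expect_equal(unname(vapply(tgt$proteome[mem$gene_id], fallback_tm_count,
                             integer(1))),
               mem$tm_count)
  sol <- tgt$truth[tgt$truth$class == "soluble", ]
  expect_true(all(vapply(tgt$proteome[sol$gene_id], fallback_tm_count,
                         integer(1)) == 0L))
})

test_that("decoy classes violate exactly their designated constraint", {
  fr <- fixture_reference(n_families = 4, seed = 13)
  tgt <- fixture_target_proteome(fr, members_per_family = 6,
                                 n_fragments = 8, n_soluble = 8,
                                 n_non_slc = 8, seed = 13)
  st <- family_profile_stats(fr$ref, fr$tm_counts)
  tr <- tgt$truth
  lo <- setNames(st$accept_lo, st$family)
  hi <- setNames(st$accept_hi, st$family)
  thr <- setNames(st$tm_threshold, st$family)

  frag <- tr[tr$class == "fragment", ]
  expect_true(all(frag$length < lo[frag$family]))
  expect_true(all(frag$tm_count >= thr[frag$family]))  # TM filter passes

  sol <- tr[tr$class == "soluble", ]
  expect_true(all(sol$length >= lo[sol$family] & sol$length <= hi[sol$family]))
  expect_true(all(thr[sol$family] >= 1L))  # TM filter armed

  mem <- tr[tr$class == "member", ]
  expect_true(all(mem$length >= lo[mem$family] & mem$length <= hi[mem$family]))
})

test_that("noise degrades classification monotonically", {
  fr <- fixture_reference(n_families = 4, members_per_family = 6, seed = 17)
  tgt <- fixture_target_proteome(fr, members_per_family = 8,
                                 n_fragments = 0, n_soluble = 0,
                                 n_non_slc = 0, seed = 17)
  subj <- setNames(fr$truth$family, fr$truth$gene_id)
  sizes <- table(subj)
  sizes <- setNames(as.integer(sizes), names(sizes))
  unsorted_frac <- vapply(c(0, 0.25, 0.5), function(p) {
    hits <- fixture_hit_tables(tgt, fr, rank_swap_prob = p, seed = 17)
    asg <- classify_candidates(hits$blast_hits, subj, sizes)
    mean(asg$label == "Unsorted")
  }, numeric(1))
  expect_equal(unsorted_frac[1], 0)  # noise 0: everything sorted
  expect_true(all(diff(unsorted_frac) > 0))  # rises with noise

  # Full corruption: accuracy collapses to chance, most genes Unsorted
  # or mislabelled.
  hits1 <- fixture_hit_tables(tgt, fr, rank_swap_prob = 1, seed = 17)
  asg1 <- classify_candidates(hits1$blast_hits, subj, sizes)
  truth_fam1 <- setNames(tgt$truth$family, tgt$truth$gene_id)
  expect_lt(mean(asg1$label == truth_fam1[asg1$gene_id]), 0.2)

  # Noise 0 recovers every planted family label.
  hits0 <- fixture_hit_tables(tgt, fr, seed = 17)
  asg0 <- classify_candidates(hits0$blast_hits, subj, sizes)
  truth_fam <- setNames(tgt$truth$family, tgt$truth$gene_id)
  expect_equal(asg0$label, unname(truth_fam[asg0$gene_id]))

  # Empty truth gives empty tables.
  tgt0 <- list(truth = tgt$truth[0, ], proteome = character(0))
  h0 <- fixture_hit_tables(tgt0, fr, seed = 1)
  expect_equal(nrow(h0$hmm_hits), 0L)
  expect_equal(nrow(h0$blast_hits), 0L)
})

test_that("cohorts plant group templates, traits, tree and gate fodder", {
  groups <- list(
    insecta = list(n = 10L, template = c(SLC2 = 12, SLC6 = 8, SLC60 = 0)),
    arachnida = list(n = 10L, template = c(SLC2 = 3, SLC6 = 8, SLC60 = 9)))
  ch <- fixture_cohort(groups, noise_sd = 1, busco_low_frac = 0.2, seed = 23)
  expect_equal(dim(ch$matrix), c(20L, 3L))
  expect_true(all(ch$matrix >= 0))
  expect_equal(sort(unique(ch$traits$taxonomic_group)),
               c("arachnida", "insecta"))
  # Planted means are near the template (sd 1, n = 10).
  ins <- ch$matrix[ch$traits$species[ch$traits$taxonomic_group == "insecta"], ]
  expect_lt(abs(mean(ins[, "SLC2"]) - 12), 2)
  # Ultrametric tree over exactly the cohort species.
  expect_setequal(ch$tree$tip.label, rownames(ch$matrix))
  d <- ape::node.depth.edgelength(ch$tree)[1:20]
  expect_lt(max(d) - min(d), 1e-6)
  # About 20% of species fall below the completeness cutoff.
  expect_equal(sum(ch$busco < 75), 4L)
})
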
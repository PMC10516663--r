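test_that("global alignment handles the textbook cases", {
  a <- align_pair(strrep("ACGUU", 4), strrep("ACGUU", 4))
  expect_equal(a$score, 20)
  expect_false(grepl("-", a$seq_a, fixed = TRUE))

  # a deletion costs one gap column
  a2 <- align_pair("ACGU", "AGU")
  expect_equal(sum(strsplit(a2$seq_b, "")[[1]] == "-"), 1)
  expect_equal(a2$score, 3 * 1 + (-5 - 1))
  # verified against the exhaustive DP oracle
  expect_equal(a2$score, oracle_nw_score("ACGU", "AGU"))
})

test_that("alignment score equals the DP optimum and its own column scoring", {
  set.seed(17)
  for (rep in 1:15) {
    a <- random_rna(sample(10:40, 1)); b <- random_rna(sample(10:40, 1))
    al <- align_pair(a, b)
    expect_equal(al$score, oracle_nw_score(a, b), info = sprintf("rep %d", rep))
    expect_equal(al$score, oracle_score_alignment(al$seq_a, al$seq_b),
                 info = sprintf("rep %d (column rescore)", rep))
    # ungapping reproduces the inputs; no gap/gap columns
    expect_equal(gsub("-", "", al$seq_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", al$seq_b, fixed = TRUE), b)
    cols <- cbind(strsplit(al$seq_a, "")[[1]], strsplit(al$seq_b, "")[[1]])
    expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
  }
})

test_that("percent identity counts doubly ungapped columns only", {
  expect_equal(percent_identity(list(seq_a = "ACGU", seq_b = "ACGU")), 100)
  expect_equal(percent_identity(list(seq_a = "ACGU", seq_b = "ACGA")), 75)
  expect_equal(percent_identity(list(seq_a = "AC-U", seq_b = "ACGU")), 100)
  expect_error(percent_identity(list(seq_a = "--", seq_b = "AA")), "undefined")
  # symmetric under the deterministic aligner, and equal to a brute count
  set.seed(29)
  for (rep in 1:10) {
    a <- random_rna(40); b <- random_rna(40)
    p1 <- percent_identity(align_pair(a, b))
    p2 <- percent_identity(align_pair(b, a))
    expect_equal(p1, p2, info = sprintf("rep %d", rep))
  }
})

test_that("covariation classes follow the support and identity rules", {
  # three members maintaining one pair through different identities
  aln <- c(m1 = "GAAAC", m2 = "AAAAU", m3 = "UAAAA")
  rep1 <- covariation_report(aln, data.frame(i = 1, j = 5), ref_row = 1,
                             thresholds = list(strong_frac = 0.85))
  expect_equal(rep1$per_pair$class, "covariant")
  expect_equal(rep1$per_pair$support, 3)

  aln2 <- c(m1 = "GAAAC", m2 = "GAAAC", m3 = "GAAAC")
  rep2 <- covariation_report(aln2, data.frame(i = 1, j = 5))
  expect_equal(rep2$per_pair$class, "invariant")
  expect_equal(rep2$invariant_pair_count, 1)

  # one broken member out of three (below the strong threshold) -> inconsistent
  aln3 <- c(m1 = "GAAAC", m2 = "AAAAU", m3 = "AAAAA")
  rep3 <- covariation_report(aln3, data.frame(i = 1, j = 5))
  expect_equal(rep3$per_pair$class, "inconsistent")

  # a reference pair mapping onto a gapped member column is a coordinate error
  aln4 <- c(m1 = "GAAAC", m2 = "G-AAC")
  expect_error(covariation_report(aln4, data.frame(i = 2, j = 4)), "gapped")
})

test_that("covariation support equals a brute-force recount", {
  d <- default_descriptor_6e()
  r <- rng_new(41)
  s <- sample_ires(d, r)
  cl <- evolve_clade(s, generator_params(substitution_rate = 0.08,
                                         compensation_prob = 0.5), r)
  rep <- covariation_report(cl$members, s$annotation)
  for (k in seq_len(nrow(rep$per_pair))) {
    expect_equal(rep$per_pair$support[k],
                 oracle_pair_support(cl$members, rep$per_pair$col_i[k],
                                     rep$per_pair$col_j[k]))
  }
})

test_that("conservation statistics match a brute-force column scan", {
  aln <- c(a = "ACGU", b = "ACGU")
  cs <- conservation_stats(aln)
  expect_equal(cs$fraction_invariant_columns, 1.0)
  expect_equal(unname(cs$pairwise_identity_matrix["a", "b"]), 100)

  aln2 <- c(a = "ACGU", b = "ACGA")  # differ at 1 of 4
  expect_equal(conservation_stats(aln2)$fraction_invariant_columns, 0.75)
  aln3 <- c(a = "AAAACCCC", b = "AAAAGGGG")
  expect_equal(conservation_stats(aln3)$fraction_invariant_columns, 0.5)

  set.seed(53)
  for (rep in 1:8) {
    rows <- vapply(1:4, function(k) random_rna(30), "")
    names(rows) <- paste0("r", 1:4)
    cs <- conservation_stats(rows)
    mat <- do.call(rbind, strsplit(rows, ""))
    expect_equal(cs$fraction_invariant_columns,
                 mean(apply(mat, 2, function(cc) length(unique(cc)) == 1)))
    expect_true(isSymmetric(cs$pairwise_identity_matrix))
    expect_true(all(diag(cs$pairwise_identity_matrix) == 100))
  }
  expect_error(conservation_stats(c(a = "ACGU")), "two rows")
})

test_that("probe concordance counts unpaired reactive positions", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(47))
  loops <- setdiff(seq_len(nchar(s$seq)),
                   c(s$annotation$pairs$i, s$annotation$pairs$j))
  helices <- c(s$annotation$pairs$i, s$annotation$pairs$j)
  expect_equal(probe_concordance(s$annotation, loops), 1.0)
  expect_equal(probe_concordance(s$annotation, helices), 0.0)
  expect_error(probe_concordance(s$annotation, integer()), "undefined")
  expect_error(probe_concordance(s$annotation, 10000), "outside")

  # simulated probing with 10% misassigned positions: concordance near 0.9
  r <- rng_new(48)
  noisy <- vapply(loops, function(p) {
    if (rng_unif(r) < 0.10) helices[rng_int(r, length(helices))] else p
  }, numeric(1))
  conc <- probe_concordance(s$annotation, noisy)
  expect_gt(conc, 0.80)
  expect_lt(conc, 0.97)
})

test_that("fully compensated clades have no inconsistent pairs", {
  d <- default_descriptor_6e()
  r <- rng_new(51)
  s <- sample_ires(d, r)
  cl <- evolve_clade(s, generator_params(substitution_rate = 0.05,
                                         compensation_prob = 1.0, n_taxa = 26), r)
  rep <- covariation_report(cl$members, s$annotation)
  expect_equal(rep$n_members, 26)
  expect_true(all(rep$per_pair$support == 26))
  expect_equal(sum(rep$per_pair$class == "inconsistent"), 0)
  # every true pair is invariant or covariant
  expect_equal(rep$invariant_pair_count + sum(rep$per_pair$class == "covariant"),
               nrow(s$annotation$pairs))
})
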
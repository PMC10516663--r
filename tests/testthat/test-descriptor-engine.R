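test_that("the default type 6e descriptor carries the class constraints", {
  d <- default_descriptor_6e()
  expect_equal(d$total_len_range, c(142L, 154L))
  expect_setequal(d$allowed_start_codons,
                  c("GCU", "ACU", "ACC", "UCU", "UCA", "UCG"))
  expect_false("CAA" %in% d$allowed_start_codons)
  expect_true(validate_descriptor(d))
  # helix bounds anchored on the reference model: P2.1/P2.2 around 5 bp,
  # P1.2 reaching 11 bp
  expect_equal(d$helices$P1.2$max_bp, 11)
  expect_true(d$helices$P2.1$min_bp <= 5 && 5 <= d$helices$P2.1$max_bp)
  expect_true(d$helices$P2.2$min_bp <= 5 && 5 <= d$helices$P2.2$max_bp)
  # invariant wobble at the P1/L1 junction
  req <- d$helices$P1.1$required_pairs
  expect_true(any(vapply(req, function(r) r$kind == "GU", logical(1))))
  expect_true(d$pk3_is_h_type)
})

test_that("descriptor validation refuses malformed grammars", {
  d <- toy_descriptor()
  bad <- d; bad$helices$H1$min_bp <- 20
  expect_error(validate_descriptor(bad), "min_bp")
  bad <- d; bad$loops$La$motif <- "ACGUACGU"
  expect_error(validate_descriptor(bad), "motif longer")
  bad <- d; bad$order <- c(d$order, "H3_5p")
  expect_error(validate_descriptor(bad), "unknown helix")
})

test_that("matching is exhaustive: engine equals the brute-force oracle", {
  d <- toy_descriptor()
  set.seed(61)
  n_with_matches <- 0
  for (rep in 1:50) {
    seq <- if (rep <= 15) plant_toy(rep) else random_rna(60)
    rec <- genome_record("t", seq)
    got <- sort(match_keys(match_descriptor(rec, d)))
    want <- sort(oracle_toy_placements(seq, d))
    expect_equal(got, want, info = sprintf("rep %d", rep))
    if (length(want)) n_with_matches <- n_with_matches + 1
  }
  expect_gt(n_with_matches, 10)  # the comparison exercised real matches
})

test_that("a generated IRES is recovered as the best match (round trip)", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(11))
  m <- match_descriptor(genome_record("ires11", s$seq), d)
  expect_gt(length(m), 0)
  truth <- paste(s$annotation$pairs$i, s$annotation$pairs$j)
  got <- paste(m[[1]]$annotation$pairs$i, m[[1]]$annotation$pairs$j)
  expect_setequal(got, truth)
  expect_equal(m[[1]]$annotation$start_codon$triplet,
               s$annotation$start_codon$triplet)
})

test_that("unmatchable sequences yield an empty result, not an error", {
  d <- default_descriptor_6e()
  polyA <- genome_record("a", strrep("A", 150))
  expect_length(match_descriptor(polyA, d), 0)
  short <- genome_record("s", "ACGU")
  expect_length(match_descriptor(short, d), 0)
})

test_that("every reported match satisfies the independent validator", {
  d <- default_descriptor_6e()
  for (seed in c(1, 4, 9)) {
    s <- sample_ires(d, rng_new(seed))
    rec <- genome_record("v", s$seq)
    for (m in match_descriptor(rec, d))
      expect_true(isTRUE(validate_annotation(rec$seq, m$annotation, d)),
                  info = sprintf("seed %d", seed))
  }
})

test_that("the search is deterministic", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(13))
  rec <- genome_record("det", s$seq)
  a <- match_descriptor(rec, d)
  b <- match_descriptor(rec, d)
  expect_identical(match_keys(a), match_keys(b))
  expect_identical(vapply(a, `[[`, numeric(1), "score"),
                   vapply(b, `[[`, numeric(1), "score"))
})

test_that("borders are reported inclusive of the initiation codon", {
  d <- default_descriptor_6e()
  for (seed in 1:10) {
    s <- sample_ires(d, rng_new(seed))
    m <- match_descriptor(genome_record("b", s$seq), d,
                          params = list(best_only = TRUE))
    expect_length(m, 1)
    b <- report_borders(m[[1]])
    expect_equal(b$length_incl_codon, nchar(s$seq))
    expect_equal(b$three_prime_border, s$annotation$start_codon$interval$end)
    expect_gte(b$length_incl_codon, d$total_len_range[1])
    expect_lte(b$length_incl_codon, d$total_len_range[2])
  }
  # the worked coordinate example: a match spanning 1044-1191 is 148 nt
  expect_equal(1191 - 1044 + 1, 148)
})

test_that("toeprint windows follow the +16-18 / +19-21 counting", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(2))
  m <- match_descriptor(genome_record("tp", s$seq), d,
                        params = list(best_only = TRUE))[[1]]
  # fabricate +1 positions by shifting the annotation
  shift_to <- function(m, plus1) {
    delta <- plus1 - m$annotation$start_codon$interval$start
    m$annotation <- shift_annotation <- m$annotation
    m$annotation$start_codon$interval$start <-
      m$annotation$start_codon$interval$start + delta
    m$annotation$start_codon$interval$end <-
      m$annotation$start_codon$interval$end + delta
    m
  }
  tp <- predict_toeprints(shift_to(m, 6906))
  expect_equal(c(tp$p_site$start, tp$p_site$end), c(6921L, 6923L))
  tp1 <- predict_toeprints(shift_to(m, 1))
  expect_equal(c(tp1$p_site$start, tp1$p_site$end), c(16L, 18L))
  tp2 <- predict_toeprints(shift_to(m, 1189))
  expect_equal(c(tp2$alternate$start, tp2$alternate$end), c(1207L, 1209L))
})

test_that("disruptive mutations abolish the match; compensation restores it", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(19))
  rec <- genome_record("mut", s$seq)
  truth_pairs <- paste(s$annotation$pairs$i, s$annotation$pairs$j)
  same_topology <- function(matches) {
    length(matches) > 0 &&
      setequal(paste(matches[[1]]$annotation$pairs$i,
                     matches[[1]]$annotation$pairs$j), truth_pairs)
  }
  expect_true(same_topology(match_descriptor(rec, d)))
  flip <- c(A = "C", C = "A", G = "A", U = "C")  # break WC and wobble
  for (helix in c("P2.2", "P3.1")) {
    a <- s$annotation$element_coords[[paste0(helix, "_5p")]]
    b <- s$annotation$element_coords[[paste0(helix, "_3p")]]
    # clobber two pairs in the middle of the helix on one strand
    pos5 <- a$start + 1:2
    pos3 <- b$end - 1:2
    x <- strsplit(s$seq, "")[[1]]
    disrupted <- apply_mutation(rec, data.frame(position = pos5,
                                                new_base = flip[x[pos3]]))
    expect_false(same_topology(match_descriptor(disrupted, d)),
                 label = sprintf("%s disruption still matches", helix))
    # compensatory substitution on the partner strand restores pairing
    x2 <- strsplit(disrupted$seq, "")[[1]]
    restored <- apply_mutation(disrupted,
                               data.frame(position = pos3,
                                          new_base = chartr("ACGU", "UGCA", x2[pos5])))
    expect_true(same_topology(match_descriptor(restored, d)),
                label = sprintf("%s compensation does not restore", helix))
  }
  # empty edit list is the identity
  expect_identical(apply_mutation(rec, data.frame(position = integer(),
                                                  new_base = character())), rec)
  expect_error(apply_mutation(rec, data.frame(position = 10000, new_base = "A")),
               "out of range")
})

test_that("decoy IGRs rarely match: scanner specificity regression", {
  d <- default_descriptor_6e()
  r <- rng_new(77)
  hits <- 0
  n_decoys <- 100
  src <- sample_ires(d, rng_new(500))
  for (k in seq_len(n_decoys)) {
    dec <- make_decoy(src$seq, r)
    if (length(match_descriptor(genome_record("d", dec), d)) > 0) hits <- hits + 1
  }
  # regression bound: dinucleotide-shuffled true IRESs, which preserve
  # composition, stay below a 5% match rate at the default score threshold
  expect_lte(hits / n_decoys, 0.05)
})
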
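stem_pairs <- function(n_bp, total) data.frame(i = 1:n_bp, j = total:(total - n_bp + 1))

test_that("the printed T7-leader hairpin evaluates to -25.80 kcal/mol", {
  seq <- chartr("T", "U", "GGCCGACCCGGTGACGGGTCGGCC")
  eb <- evaluate_structure(seq, stem_pairs(10, 24))
  expect_equal(eb$total, -25.80, tolerance = 1e-9)
  # itemization is auditable: total is the sum of its terms
  expect_equal(eb$total, sum(eb$terms$value), tolerance = 1e-9)
  expect_equal(sum(grepl("^stack", eb$terms$feature)), 9)
})

test_that("an empty pair list has zero energy", {
  expect_equal(evaluate_structure("ACGUACGU", data.frame(i = integer(), j = integer()))$total, 0)
})

test_that("a two-stack toy hairpin equals hand-summed table entries", {
  # GGC AAAA GCC: stem G-C, G-C, C-G with a 4-nt AAAA loop
  seq <- "GGCAAAAGCC"
  eb <- evaluate_structure(seq, stem_pairs(3, 10))
  p <- read_energy_params()
  # stack keys: closing pair (i,j), then the inner pair read (j-1, i+1)
  hand <- p$stack["GC", "CG"] +         # (1,10) on (2,9)
    p$stack["GC", "GC"] +               # (2,9) on (3,8)
    p$hairpin[4] + p$mismatch_hairpin[["CG"]]["A", "A"]
  expect_equal(eb$total, hand, tolerance = 1e-9)
})

test_that("hairpin evaluation matches an independent reference on fixed cases", {
  # expected totals computed with an independent nearest-neighbor
  # implementation configured with the same 37 C parameter vintage
  cases <- list(
    list(seq = "GCGCCAAAAGGCGC", bp = 5, want = -8.40),
    list(seq = "GGCGCAAUAAGCGCC", bp = 5, want = -8.40),
    list(seq = "GGACGUUUCGCGUCC", bp = 6, want = -6.60),   # wobble-closed triloop
    list(seq = "GCUAGCGAAAGCUAGC", bp = 6, want = -11.90)) # bonus tetraloop
  for (cs in cases) {
    eb <- evaluate_structure(cs$seq, stem_pairs(cs$bp, nchar(cs$seq)))
    expect_equal(eb$total, cs$want, tolerance = 1e-9, info = cs$seq)
  }
})

test_that("energy is additive over disconnected components", {
  set.seed(71)
  for (rep in 1:10) {
    n1 <- sample(4:7, 1); n2 <- sample(4:7, 1)
    make_hairpin <- function(n_bp) {
      stem <- paste(sample(c("G", "C", "A", "U"), n_bp, replace = TRUE,
                           prob = c(.35, .35, .15, .15)), collapse = "")
      paste0(stem, random_rna(4), chartr("ACGU", "UGCA",
                                         paste(rev(strsplit(stem, "")[[1]]), collapse = "")))
    }
    h1 <- make_hairpin(n1); h2 <- make_hairpin(n2)
    linker <- random_rna(6)
    e1 <- evaluate_structure(h1, stem_pairs(n1, nchar(h1)))$total
    e2 <- evaluate_structure(h2, stem_pairs(n2, nchar(h2)))$total
    joint_pairs <- rbind(stem_pairs(n1, nchar(h1)),
                         data.frame(i = nchar(h1) + 6 + 1:n2,
                                    j = nchar(h1) + 6 + nchar(h2):(nchar(h2) - n2 + 1)))
    e12 <- evaluate_structure(paste0(h1, linker, h2), joint_pairs)$total
    expect_equal(e12, e1 + e2, tolerance = 1e-9)
  }
})

test_that("pseudoknots score as the sum of their layers", {
  # H-type pseudoknot: two crossing stems evaluated as independent helices
  s <- "GGGGAAAACCCCAAAAGGGGAAAAUUUU"
  hmm <- data.frame(i = c(1:4, 13:16), j = c(12:9, 28:25))
  expect_error(evaluate_structure(s, hmm), NA)
})

test_that("structural errors are refused", {
  expect_error(evaluate_structure("GACAAA", data.frame(i = 1, j = 3)),
               "hairpin loop")
  expect_error(evaluate_structure("AAAAAAAA", data.frame(i = 1, j = 8)),
               "non-complementary")
})

test_that("match ranking is a stable permutation with the documented tie-break", {
  fake <- function(score, dg, start, len) {
    structure(list(annotation = NULL, score = score, delta_g = dg,
                   record_id = "x",
                   genome_interval = interval(start, start + len - 1)),
              class = "ires_match")
  }
  # equal scores: more stable (more negative dG) first
  m <- list(fake(10, -10, 5, 100), fake(10, -20, 9, 100))
  r <- rank_matches(m)
  expect_equal(r[[1]]$delta_g, -20)
  # single match unchanged
  expect_length(rank_matches(m[1]), 1)
  # random lists: output is a permutation, scores non-increasing
  set.seed(81)
  for (rep in 1:10) {
    ms <- lapply(1:8, function(k) fake(sample(1:5, 1), -sample(1:30, 1),
                                       sample(1:50, 1), sample(100:150, 1)))
    rs <- rank_matches(ms)
    expect_setequal(vapply(rs, `[[`, numeric(1), "delta_g"),
                    vapply(ms, `[[`, numeric(1), "delta_g"))
    sc <- vapply(rs, `[[`, numeric(1), "score")
    expect_true(all(diff(sc) <= 0))
  }
})

test_that("evaluation is deterministic given the same parameter file", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(33))
  e1 <- evaluate_structure(s$seq, s$annotation$pairs[, c("i", "j")])
  e2 <- evaluate_structure(s$seq, s$annotation$pairs[, c("i", "j")])
  expect_identical(e1$total, e2$total)
  expect_identical(e1$terms, e2$terms)
})
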
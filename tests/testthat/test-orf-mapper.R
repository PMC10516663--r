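test_that("frame translation follows the standard code with tails dropped", {
  r <- genome_record("t", "AUGAAAUAA")
  expect_equal(translate_frame(r, 0), "MK*")
  # frame 1 of NAUGAA is AUG AA -> "M" with the 2-nt tail dropped
  r2 <- genome_record("t2", "NAUGAA")
  expect_equal(translate_frame(r2, 1), "M")
  # ambiguity codes that do not resolve translate as X
  r3 <- genome_record("t3", "AUGNNNUAA")
  expect_equal(translate_frame(r3, 0), "MX*")
})

test_that("translation agrees with a codon-table oracle on random sequences", {
  set.seed(11)
  for (rep in 1:12) {
    s <- random_rna(300)
    r <- genome_record("r", s)
    for (frame in 0:2)
      expect_equal(translate_frame(r, frame), oracle_translate(s, frame),
                   info = sprintf("rep %d frame %d", rep, frame))
  }
})

test_that("ORF finding reports AUG ORFs and open frames", {
  r <- genome_record("o", "AUGAAAUAA")
  orfs <- find_orfs(r, min_aa = 2)
  aug <- Filter(function(o) o$start_kind == "AUG", orfs)
  expect_length(aug, 1)
  expect_equal(aug[[1]]$protein, "MK")
  expect_equal(c(aug[[1]]$interval$start, aug[[1]]$interval$end), c(1L, 9L))

  # poly-A: one stop-free open frame per frame, no AUG ORFs
  polyA <- genome_record("a", strrep("A", 100))
  orfs <- find_orfs(polyA, min_aa = 5)
  expect_equal(sort(vapply(orfs, `[[`, "", "start_kind")), rep("frame_open", 3))
})

test_that("ORF finding agrees with an exhaustive oracle on random sequences", {
  set.seed(23)
  for (rep in 1:50) {
    s <- random_rna(500)
    r <- genome_record("r", s)
    got <- find_orfs(r, min_aa = 5)
    want <- oracle_orfs(s, min_aa = 5)
    key <- function(st, en, kind) sprintf("%d:%d:%s", st, en, kind)
    got_keys <- sort(vapply(got, function(o)
      key(o$interval$start, o$interval$end, o$start_kind), ""))
    want_keys <- sort(vapply(want, function(o) key(o$start, o$end, o$kind), ""))
    expect_equal(got_keys, want_keys, info = sprintf("rep %d", rep))
  }
})

test_that("reported ORFs are stable under 3' extension beyond their stops", {
  set.seed(31)
  s <- random_rna(600)
  r <- genome_record("r", s)
  orfs <- find_orfs(r, min_aa = 5)
  ext <- genome_record("r", paste0(s, random_rna(90)))
  orfs_ext <- find_orfs(ext, min_aa = 5)
  key <- function(o) sprintf("%d:%d:%s", o$interval$start, o$interval$end, o$start_kind)
  closed <- Filter(function(o) endsWith(translate_frame(
    genome_record("z", substr(s, o$interval$start, o$interval$end)), 0), "*"), orfs)
  expect_true(all(vapply(closed, key, "") %in% vapply(orfs_ext, key, "")))
})

test_that("dicistronic mapping recovers embedded layouts and rejects others", {
  d <- default_descriptor_6e()
  r <- rng_new(7)
  s <- sample_ires(d, r)
  g <- embed_genome(s, generator_params(), r, id = "g7")
  lay <- map_dicistronic(g$record)
  expect_equal(c(lay$orf1$interval$start, lay$orf1$interval$end),
               c(g$layout$orf1$interval$start, g$layout$orf1$interval$end))
  expect_equal(c(lay$orf2$interval$start, lay$orf2$interval$end),
               c(g$layout$orf2$interval$start, g$layout$orf2$interval$end))
  expect_equal(lay$orf2$start_kind, "frame_open")
  expect_equal(lay$orf1$start_kind, "AUG")

  # single ORF: no layout
  single <- genome_record("s", paste0("AUG", paste(rep("GCA", 300), collapse = ""), "UAA"))
  expect_error(map_dicistronic(single, list(min_genome_len = 100)), "no dicistronic layout")

  # two ORFs separated by less than the IGR minimum: no layout
  orf <- paste0("AUG", paste(rep("GCA", 200), collapse = ""), "UAA")
  close2 <- genome_record("c", paste0("UAA", orf, strrep("A", 10), "UAA", orf))
  expect_error(map_dicistronic(close2, list(min_genome_len = 100)),
               "no dicistronic layout")

  # YGDD requirement is honored
  g2 <- embed_genome(sample_ires(d, rng_new(8)),
                     generator_params(include_ygdd = FALSE), rng_new(8), id = "g8")
  expect_error(map_dicistronic(g2$record, list(require_ygdd = TRUE)),
               "no dicistronic layout")
})

test_that("IGR extraction arithmetic and coordinate mapping are exact", {
  set.seed(55)
  s <- random_rna(6000)
  rec <- genome_record("g", s)
  lay <- structure(list(
    orf1 = orf_annotation(1, 4999, 0, "+", "", "frame_open"),
    orf2 = orf_annotation(5151, 5900, 2, "+", "", "frame_open"),
    igr = interval(5000, 5150)), class = "dicistronic_layout")
  ex <- extract_igr(rec, lay, flank_into_orf2 = 75)
  expect_equal(ex$offset, 4999L)
  expect_equal(nchar(ex$record$seq), 5225 - 5000 + 1)
  expect_equal(ex$record$seq, substr(s, 5000, 5225))
  ex0 <- extract_igr(rec, lay, flank_into_orf2 = 0)
  expect_equal(nchar(ex0$record$seq), 151)
  # flank beyond the record end truncates with a warning
  lay2 <- lay; lay2$igr <- interval(5000, 5990)
  expect_warning(ex2 <- extract_igr(rec, lay2, flank_into_orf2 = 75), "truncated")
  expect_true(ex2$truncated)
})

test_that("matching an extract maps back to the same genome coordinates", {
  d <- default_descriptor_6e()
  r <- rng_new(42)
  s <- sample_ires(d, r)
  g <- embed_genome(s, generator_params(), r, id = "eq")
  lay <- map_dicistronic(g$record)
  ex <- extract_igr(g$record, lay,
                    flank_into_orf2 = 75 + d$total_len_range[2])
  m_local <- match_descriptor(ex$record, d,
                              params = list(window = nchar(ex$record$seq)))
  expect_gt(length(m_local), 0)
  best <- m_local[[1]]
  # full-genome search over the same region gives identical coordinates
  m_global <- match_descriptor(g$record, d,
                               params = list(window = nchar(g$record$seq) -
                                               lay$igr$start + 1))
  expect_gt(length(m_global), 0)
  expect_equal(best$genome_interval$start + ex$offset,
               m_global[[1]]$genome_interval$start)
  expect_equal(best$genome_interval$end + ex$offset,
               m_global[[1]]$genome_interval$end)
})
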
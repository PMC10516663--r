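test_that("FASTA reading normalizes alphabets and preserves entries", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs$x$seq, "ACGU")
  expect_equal(recs$x$source_alphabet, "DNA")

  writeLines(c(">a", "AC", "GU", ">b desc here", "GGG"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(nchar(recs$a$seq), 4)
  expect_equal(nchar(recs$b$seq), 3)
  expect_equal(recs$b$description, "desc here")

  writeLines(c(">dup", "ACGU", ">dup", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("alphabet normalization is idempotent and rejects junk", {
  r <- genome_record("r", "acgtACGT")
  r2 <- genome_record("r", r$seq)
  expect_equal(r2$seq, r$seq)
  expect_error(genome_record("bad", "ACGZ"), "non-IUPAC")
  expect_error(genome_record("empty", ""), "empty")
})

test_that("FASTA round trip reproduces random records", {
  set.seed(402)
  recs <- lapply(1:20, function(k) {
    alphabet <- sample(c("DNA", "RNA"), 1)
    s <- random_rna(sample(30:200, 1))
    if (alphabet == "DNA") s <- chartr("U", "T", s)
    genome_record(sprintf("rec%02d", k), s, sprintf("random record %d", k))
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(length(back), 20)
  for (k in seq_along(recs)) {
    expect_equal(back[[k]]$id, recs[[k]]$id)
    expect_equal(back[[k]]$seq, recs[[k]]$seq)
    expect_equal(back[[k]]$source_alphabet, recs[[k]]$source_alphabet)
    expect_equal(back[[k]]$description, recs[[k]]$description)
  }
})

test_that("GFF3 writer emits valid 1-based features with parent/child links", {
  rec <- genome_record("g1", random_rna(400, seed = 7))
  f <- withr::local_tempfile(fileext = ".gff3")
  orf <- data.frame(seqid = "g1", start = 1, end = 300, strand = "+",
                    type = "CDS", score = NA_real_, ID = "orf1",
                    Name = "ORF1", Parent = NA_character_)
  write_gff3(list(rec), orf, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  cds <- strsplit(grep("\tCDS\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(cds[4:5]), c(1L, 300L))
  expect_true(validate_gff3(f))

  # IRES parent with one child row per non-empty element
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(3))
  g <- embed_genome(s, generator_params(), rng_new(4), id = "g2")
  feats <- annotation_to_features(g$annotation, "g2")
  n_helix_strands <- 14  # 7 helices x 2 strands
  expect_gte(nrow(feats), 1 + n_helix_strands)
  expect_equal(sum(feats$type == "IRES"), 1)
  expect_true(all(feats$Parent[-1] == feats$ID[1]))
  write_gff3(list(g$record), feats, f)
  expect_true(validate_gff3(f))

  # out-of-bounds interval is refused
  bad <- orf; bad$end <- 1000
  expect_error(write_gff3(list(rec), bad, f), "out of bounds")
})

test_that("GFF3 output agrees with an independent parser", {
  d <- default_descriptor_6e()
  s <- sample_ires(d, rng_new(21))
  g <- embed_genome(s, generator_params(), rng_new(22), id = "gx")
  feats <- annotation_to_features(g$annotation, "gx")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(g$record), feats, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), nrow(feats))
  ires_row <- gr[gr$type == "IRES"]
  expect_equal(BiocGenerics::start(ires_row), g$ires_interval$start)
  expect_equal(BiocGenerics::end(ires_row), g$ires_interval$end)
})

test_that("dot-bracket layering is minimal and round-trips", {
  # plain nested helix: a single layer
  db <- write_dotbracket("GGGGAAAACCCC", data.frame(i = 1:4, j = 12:9))
  expect_length(db$layers, 1)
  expect_equal(db$layers[1], "((((....))))")

  # H-type pseudoknot: exactly two layers (brute-force minimality check)
  pk <- data.frame(i = c(1, 2, 3, 7, 8, 9), j = c(14, 13, 12, 20, 19, 18))
  db2 <- write_dotbracket(random_rna(20, seed = 5), pk)
  expect_length(db2$layers, 2)
  expect_equal(oracle_min_layers(pk), 2L)

  # greedy layering matches brute-force minimum on random valid pair sets
  set.seed(99)
  for (rep in 1:25) {
    n <- 30
    pos <- sample(n, 8)
    pairs <- data.frame(i = pmin(pos[1:4], pos[5:8]), j = pmax(pos[1:4], pos[5:8]))
    got <- max(assign_layers(pairs))
    expect_equal(got, oracle_min_layers(pairs))
    back <- parse_dotbracket(write_dotbracket(random_rna(n), pairs))
    expect_equal(back[order(back$i), ], pairs[order(pairs$i), ],
                 ignore_attr = TRUE)
  }

  # conflicting pairs are refused
  expect_error(write_dotbracket("ACGUACGU", data.frame(i = c(1, 1), j = c(8, 7))),
               "two pairs")
})

test_that("descriptor matches never need more than three layers", {
  d <- default_descriptor_6e()
  for (seed in c(2, 12)) {
    s <- sample_ires(d, rng_new(seed))
    expect_lte(max(assign_layers(s$annotation$pairs)), 3)
  }
})

test_that("reactive-position lists read as sorted 1-based integers", {
  f <- withr::local_tempfile()
  writeLines(c("# probing run 1", "12", "5", "", "40"), f)
  expect_equal(read_positions(f), c(5L, 12L, 40L))
  writeLines(c("12", "x"), f)
  expect_error(read_positions(f), "non-integer")
})
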
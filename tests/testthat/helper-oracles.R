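# Independent oracles and fixture builders. Everything here is deliberately
# written without reusing package internals beyond trivial constructors, so
# the tests cross-check the implementation rather than restate it.

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# --- codon-table translation oracle (hash lookup, no Biostrings) ----------
CODON_TABLE <- local({
  bases <- c("U", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  # standard table order: first base slowest, third fastest
  codons <- unlist(lapply(bases, function(b1) lapply(bases, function(b2)
    lapply(bases, function(b3) paste0(b1, b2, b3)))))
  stats::setNames(aa, codons)
})

oracle_translate <- function(seq, frame = 0) {
  s <- substr(seq, frame + 1, nchar(seq))
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (k in seq_len(n)) {
    cd <- substr(s, 3 * k - 2, 3 * k)
    out[k] <- if (cd %in% names(CODON_TABLE)) CODON_TABLE[[cd]] else "X"
  }
  paste(out, collapse = "")
}

# --- exhaustive ORF scan oracle -------------------------------------------
oracle_orfs <- function(seq, min_aa) {
  res <- list()
  for (frame in 0:2) {
    prot <- oracle_translate(seq, frame)
    if (!nzchar(prot)) next
    aa <- strsplit(prot, "")[[1]]
    bounds <- c(0, which(aa == "*"), length(aa) + 1)
    for (k in seq_len(length(bounds) - 1)) {
      a <- bounds[k] + 1; b <- bounds[k + 1] - 1
      if (b < a) next
      stop_follows <- bounds[k + 1] <= length(aa)
      end_aa <- if (stop_follows) b + 1 else b
      if (b - a + 1 >= min_aa)
        res[[length(res) + 1]] <- list(start = frame + 3 * (a - 1) + 1,
                                       end = frame + 3 * end_aa,
                                       kind = "frame_open")
      ms <- which(aa[a:b] == "M")
      if (length(ms)) {
        maa <- a + ms[1] - 1
        if (b - maa + 1 >= min_aa)
          res[[length(res) + 1]] <- list(start = frame + 3 * (maa - 1) + 1,
                                         end = frame + 3 * end_aa,
                                         kind = "AUG")
      }
    }
  }
  res
}

# --- brute-force global alignment (plain quadratic NW, affine gaps) -------
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                           X[i, j + 1] + gap_extend,
                           Y[i, j + 1] + gap_open + gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                           X[i + 1, j] + gap_open + gap_extend,
                           Y[i + 1, j] + gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score a gapped alignment directly (self-consistency oracle)
oracle_score_alignment <- function(ga, gb, match = 1, mismatch = -1,
                                   gap_open = -5, gap_extend = -1) {
  a <- strsplit(ga, "")[[1]]; b <- strsplit(gb, "")[[1]]
  sc <- 0; in_gap <- ""
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      which_gap <- if (a[k] == "-") "a" else "b"
      sc <- sc + gap_extend + if (in_gap != which_gap) gap_open else 0
      in_gap <- which_gap
    } else {
      sc <- sc + if (a[k] == b[k]) match else mismatch
      in_gap <- ""
    }
  }
  sc
}

# --- brute-force minimal layering of a pair set ---------------------------
oracle_min_layers <- function(pairs) {
  n <- nrow(pairs)
  if (!n) return(0L)
  crossing <- function(k, l) {
    (pairs$i[k] < pairs$i[l] && pairs$i[l] < pairs$j[k] && pairs$j[k] < pairs$j[l]) ||
      (pairs$i[l] < pairs$i[k] && pairs$i[k] < pairs$j[l] && pairs$j[l] < pairs$j[k])
  }
  for (L in 1:4) {
    combos <- expand.grid(rep(list(1:L), n))
    for (r in seq_len(nrow(combos))) {
      asg <- as.integer(combos[r, ])
      ok <- TRUE
      for (k in seq_len(n - 1)) for (l in (k + 1):n)
        if (asg[k] == asg[l] && crossing(k, l)) ok <- FALSE
      if (ok) return(L)
    }
  }
  stop("no layering with <= 4 layers")
}

# --- covariation support recount ------------------------------------------
oracle_pair_support <- function(alignment, col_i, col_j) {
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  sum(vapply(alignment, function(s)
    paste0(substr(s, col_i, col_i), substr(s, col_j, col_j)) %in% ok, logical(1)))
}

# --- toy 2-helix descriptor and exhaustive placement oracle ---------------
toy_descriptor <- function() {
  ires_descriptor(
    name = "toy",
    helices = list(H1 = list(min_bp = 3, max_bp = 5, allow_wobble = TRUE),
                   H2 = list(min_bp = 3, max_bp = 5, allow_wobble = TRUE)),
    loops = list(La = list(min_len = 1, max_len = 5),
                 Lb = list(min_len = 1, max_len = 5),
                 Lc = list(min_len = 0, max_len = 4)),
    order = c("H1_5p", "La", "H2_5p", "Lb", "H1_3p", "Lc", "H2_3p"),
    total_len_range = c(20, 40),
    allowed_start_codons = "GCU",
    pk_groups = list(PKI = c("H1", "H2")),
    pk3_is_h_type = FALSE,
    score_min = -Inf)
}

# canonical fingerprint of a placement: all element coords + codon start
placement_key <- function(coords, codon_start) {
  paste(c(vapply(coords, function(iv) sprintf("%d-%d", iv[1], iv[2]), ""),
          codon_start), collapse = "|")
}

# exhaustively enumerate all toy-descriptor placements in a sequence
oracle_toy_placements <- function(seq, d = toy_descriptor()) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  ok_pair <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  out <- character()
  widths <- expand.grid(h1 = 3:5, la = 1:5, h2 = 3:5, lb = 1:5, lc = 0:4)
  for (cs in seq_len(n - 2)) {
    if (paste(x[cs:(cs + 2)], collapse = "") != "GCU") next
    for (r in seq_len(nrow(widths))) {
      w <- as.integer(widths[r, ])  # h1, la, h2, lb, lc in grid order
      names(w) <- names(widths)
      ord_w <- c(w["h1"], w["la"], w["h2"], w["lb"], w["h1"], w["lc"], w["h2"])
      total <- sum(ord_w) + 3
      if (total < d$total_len_range[1] || total > d$total_len_range[2]) next
      s0 <- cs - sum(ord_w)
      if (s0 < 1) next
      ends <- s0 - 1 + cumsum(ord_w)
      starts <- ends - ord_w + 1
      # order: H1_5p La H2_5p Lb H1_3p Lc H2_3p
      h1a <- c(starts[1], ends[1]); h2a <- c(starts[3], ends[3])
      h1b <- c(starts[5], ends[5]); h2b <- c(starts[7], ends[7])
      good <- TRUE
      for (t in seq_len(w[["h1"]]))
        if (!ok_pair(x[h1a[1] + t - 1], x[h1b[2] - t + 1])) { good <- FALSE; break }
      if (good) for (t in seq_len(w[["h2"]]))
        if (!ok_pair(x[h2a[1] + t - 1], x[h2b[2] - t + 1])) { good <- FALSE; break }
      if (!good) next
      coords <- list(c(starts[1], ends[1]), c(starts[2], ends[2]),
                     c(starts[3], ends[3]), c(starts[4], ends[4]),
                     c(starts[5], ends[5]), c(starts[6], ends[6]),
                     c(starts[7], ends[7]))
      out <- c(out, placement_key(coords, cs))
    }
  }
  unique(out)
}

match_keys <- function(matches) {
  vapply(matches, function(m) {
    coords <- lapply(m$annotation$element_coords, function(iv) c(iv$start, iv$end))
    placement_key(coords, m$annotation$start_codon$interval$start)
  }, character(1))
}

# plant a toy IRES inside random flanks (for oracle-vs-engine comparisons)
plant_toy <- function(seed) {
  d <- toy_descriptor()
  r <- rng_new(seed)
  s <- sample_ires(d, r)
  left <- random_rna(max(0, 30 - nchar(s$seq)), seed = seed + 1000)
  paste0(left, s$seq)
}
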
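# Ground-truthed synthetic data: descriptor-satisfying IRESs, dicistronic
# genomes that embed them, compensatorily evolved clades, and
# composition-matched decoys. Every draw goes through an explicit RNG
# instance (rng_new), so fixtures are byte-identical under a fixed seed.

NT <- c("A", "C", "G", "U")
STOPS <- c("UAA", "UAG", "UGA")

#' Generator parameters
#'
#' Defaults emulate the study conditions the pipeline targets: clades of 26
#' related viral sequences, an ORF1 of a few hundred codons carrying the
#' RdRp-proxy YGDD motif, an IGR comfortably inside the 100-400 nt scan
#' window, and moderate divergence (5% per-site substitution) with mostly
#' structure-preserving (compensated) changes in helices.
#'
#' @param seed Optional convenience seed (generators also accept an RNG).
#' @param orf1_len_codons,orf2_len_codons Length ranges in codons.
#' @param igr_padding Range of unstructured IGR nucleotides 5' of the IRES.
#' @param substitution_rate Per-site substitution probability per clade
#'   member.
#' @param compensation_prob Probability that a substitution hitting a paired
#'   position is accompanied by the partner change restoring WC/G-U pairing.
#' @param n_taxa Clade size (>= 2).
#' @param include_ygdd Embed the YGDD motif in ORF1?
#' @param wobble_prob Probability an unconstrained sampled helix pair is G-U.
#' @return A list of validated generator parameters.
#' @export
generator_params <- function(seed = NULL,
                             orf1_len_codons = c(250L, 350L),
                             orf2_len_codons = c(180L, 260L),
                             igr_padding = c(110L, 180L),
                             substitution_rate = 0.05,
                             compensation_prob = 0.9,
                             n_taxa = 26L,
                             include_ygdd = TRUE,
                             wobble_prob = 0.1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            compensation_prob >= 0, compensation_prob <= 1,
            wobble_prob >= 0, wobble_prob <= 1, n_taxa >= 2,
            igr_padding[1] >= 10)
  list(seed = seed, orf1_len_codons = as.integer(orf1_len_codons),
       orf2_len_codons = as.integer(orf2_len_codons),
       igr_padding = as.integer(igr_padding),
       substitution_rate = substitution_rate,
       compensation_prob = compensation_prob, n_taxa = as.integer(n_taxa),
       include_ygdd = isTRUE(include_ygdd), wobble_prob = wobble_prob)
}

rng_range <- function(rng, lo, hi) lo + rng_int(rng, hi - lo + 1L) - 1L

#' Sample an IRES sequence from a descriptor
#'
#' Draws element lengths within bounds (rejection-sampled until the total
#' falls in the descriptor's length window), fills loop motifs from their
#' IUPAC consensus (sampling degenerate positions), fills helices with
#' complementary strands (G-U wobble with probability `wobble_prob`,
#' required pairs honored), free loop positions uniformly, and the
#' initiation codon uniformly from the allowed set. The returned annotation
#' is re-checked with the independent validator.
#'
#' @param descriptor An `ires_descriptor`.
#' @param rng An [rng_new()] instance.
#' @param wobble_prob Override for the descriptor's wobble probability.
#' @return List with `seq` (RNA string including the codon), `annotation`
#'   (local 1-based coordinates) and `frozen` (positions that class-defining
#'   evolution should not touch: motif windows, required pairs, the codon).
#' @export
sample_ires <- function(descriptor, rng, wobble_prob = descriptor$wobble_prob) {
  rngv <- descriptor$total_len_range
  hmins <- vapply(descriptor$helices, `[[`, numeric(1), "min_bp")
  hmaxs <- vapply(descriptor$helices, `[[`, numeric(1), "max_bp")
  lmins <- vapply(descriptor$loops, `[[`, numeric(1), "min_len")
  lmaxs <- vapply(descriptor$loops, `[[`, numeric(1), "max_len")
  tok <- parse_order(descriptor)
  ok <- FALSE
  for (try in 1:1000) {
    hb <- stats::setNames(mapply(function(a, b) rng_range(rng, a, b), hmins, hmaxs),
                          names(descriptor$helices))
    ll <- stats::setNames(mapply(function(a, b) rng_range(rng, a, b), lmins, lmaxs),
                          names(descriptor$loops))
    width <- sum(ifelse(tok$type == "helix", hb[tok$helix], ll[tok$name]))
    total <- width + 3L
    if (total >= rngv[1] && total <= rngv[2]) { ok <- TRUE; break }
  }
  if (!ok) stop("unsatisfiable descriptor: element bounds conflict with the total length window")
  lay <- layout_elements(descriptor, hb, ll)
  total <- lay$end[nrow(lay)] + 3L
  in_loop <- logical(total)
  for (k in which(lay$type == "loop"))
    if (lay$end[k] >= lay$start[k]) in_loop[lay$start[k]:lay$end[k]] <- TRUE
  non_pairing <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                      G = c("A", "G"), U = c("C", "U"))
  # helix uniqueness guards: a ground-truthed instance must not leave room
  # for an alternative placement of any single helix formed by
  # chance-complementary neighboring bases. Each guard is the complete pair
  # matrix of one alternative (outward/inward extension by one, a single
  # strand sliding into its flanking loops, or a full register shift); an
  # alternative is "live" if every row pairs, and is broken by making one
  # row with a repairable position non-complementary.
  guard_list <- local({
    gs <- list()
    for (h in names(descriptor$helices)) {
      a <- lay[lay$helix %in% h & lay$side == "5p", ]
      b <- lay[lay$helix %in% h & lay$side == "3p", ]
      i0 <- a$start:a$end
      j0 <- b$end:b$start
      add <- function(m) gs[[length(gs) + 1L]] <<- m
      add(rbind(c(a$start - 1L, b$end + 1L)))   # outward extension
      add(rbind(c(a$end + 1L, b$start - 1L)))   # inward extension
      for (s in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
        add(cbind(i0 + s, j0))                  # 5' strand slide
        add(cbind(i0, j0 + s))                  # 3' strand slide
        if (abs(s) <= 2L) add(cbind(i0 + s, j0 + s))  # register shift
      }
    }
    gs
  })
  guard_live <- function(x, m) {
    p <- m[, 1]; q <- m[, 2]
    if (min(p, q) < 1L || max(p, q) > total || any(p >= q)) return(FALSE)
    all(can_pair(x[p], x[q]))
  }
  fill_ok <- FALSE
  for (attempt in 1:25) {
    x <- character(total)
    frozen <- integer()
    # loops: motif (anywhere within the loop) then free positions
    for (k in which(lay$type == "loop")) {
      s <- lay$start[k]; e <- lay$end[k]
      if (e < s) next
      x[s:e] <- NT[rng_int(rng, 4L, e - s + 1L)]
      spec <- descriptor$loops[[lay$name[k]]]
      if (!is.null(spec$motif)) {
        mchars <- strsplit(toupper(spec$motif), "")[[1]]
        off <- rng_range(rng, 0L, (e - s + 1L) - length(mchars))
        for (t in seq_along(mchars)) {
          set <- IUPAC_SETS[[mchars[t]]]
          x[s + off + t - 1L] <- set[rng_int(rng, length(set))]
        }
        frozen <- c(frozen, (s + off):(s + off + length(mchars) - 1L))
      }
    }
    # helices: pick each pair, honoring required pairs and the wobble rate
    for (h in names(descriptor$helices)) {
      a <- lay[lay$helix %in% h & lay$side == "5p", ]
      b <- lay[lay$helix %in% h & lay$side == "3p", ]
      spec <- descriptor$helices[[h]]
      L <- hb[[h]]
      req <- stats::setNames(rep(NA_character_, L), seq_len(L))
      for (rp in spec$required_pairs) req[resolve_offset(rp$offset, L)] <- rp$kind
      for (t in seq_len(L)) {
        p5 <- a$start + t - 1L; p3 <- b$end - t + 1L
        if (!is.na(req[t]) && req[t] == "GU") {
          duo <- if (rng_int(rng, 2L) == 1L) c("G", "U") else c("U", "G")
          frozen <- c(frozen, p5, p3)
        } else if (!is.na(req[t]) && req[t] == "WC") {
          b5 <- NT[rng_int(rng, 4L)]
          duo <- c(b5, chartr("ACGU", "UGCA", b5))
          frozen <- c(frozen, p5, p3)
        } else if (isTRUE(spec$allow_wobble) && rng_unif(rng) < wobble_prob) {
          duo <- if (rng_int(rng, 2L) == 1L) c("G", "U") else c("U", "G")
        } else {
          b5 <- NT[rng_int(rng, 4L)]
          duo <- c(b5, chartr("ACGU", "UGCA", b5))
        }
        x[p5] <- duo[1]; x[p3] <- duo[2]
      }
    }
    codon <- descriptor$allowed_start_codons[rng_int(rng, length(descriptor$allowed_start_codons))]
    cs <- total - 2L
    x[cs:total] <- strsplit(codon, "")[[1]]
    frozen <- sort(unique(c(frozen, cs:total)))
    free_pos <- function(p) p >= 1 && p <= total && in_loop[p] && !p %in% frozen
    # every guard partner position of a given position (across all guards)
    guard_partners <- function(t) {
      out <- integer()
      for (g in guard_list) {
        hit <- g[, 1] == t | g[, 2] == t
        if (any(hit)) out <- c(out, ifelse(g[hit, 1] == t, g[hit, 2], g[hit, 1]))
      }
      out[out >= 1L & out <= total]
    }
    fix_one <- function(x, p, q) {
      tgt <- if (free_pos(p)) p else if (free_pos(q)) q else NA
      if (is.na(tgt)) return(NULL)
      other <- if (tgt == p) x[q] else x[p]
      # prefer a base that also avoids pairing with every other guard
      # partner of this position, so repairs cannot oscillate
      partners <- unique(x[guard_partners(tgt)])
      strict <- NT[vapply(NT, function(b)
        !any(can_pair(b, partners)), logical(1))]
      opts <- if (length(strict)) strict else non_pairing[[other]]
      x[tgt] <- opts[rng_int(rng, length(opts))]
      x
    }
    clean <- FALSE
    for (sweep in 1:50) {
      changed <- FALSE; blocked <- FALSE
      for (g in guard_list) {
        if (!guard_live(x, g)) next
        done <- FALSE
        for (ci in seq_len(nrow(g))) {
          x2 <- fix_one(x, g[ci, 1], g[ci, 2])
          if (!is.null(x2)) { x <- x2; changed <- TRUE; done <- TRUE; break }
        }
        if (!done) blocked <- TRUE
      }
      if (!changed) { clean <- !blocked; break }
    }
    if (clean) { fill_ok <- TRUE; break }
  }
  # in rare geometries a constrained (frozen) neighborhood leaves one
  # alternative register unbreakable; downstream recovery checks tolerate
  # the +-2 nt wobble this can cause
  if (!fill_ok)
    message("note: sampled IRES retains a marginal alternative helix register")
  seq <- paste(x, collapse = "")
  pr <- pairs_from_layout(lay)
  pr$kind <- pair_kind(x[pr$i], x[pr$j])
  ann <- structure_annotation(
    element_coords = stats::setNames(lapply(seq_len(nrow(lay)), function(i)
      interval(lay$start[i], lay$end[i])), lay$name),
    pairs = pr[, c("i", "j", "kind")],
    pk_groups = descriptor$pk_groups, domains = descriptor$domains,
    start_codon = list(interval = interval(cs, total), triplet = codon))
  chk <- validate_annotation(seq, ann, descriptor)
  if (!isTRUE(chk))
    stop(paste("internal error: sampled IRES fails its own descriptor:",
               paste(chk, collapse = "; ")))
  list(seq = seq, annotation = ann, frozen = frozen)
}

# n random codons avoiding stops
random_codons <- function(rng, n) {
  out <- character(n)
  for (k in seq_len(n)) {
    repeat {
      cd <- paste(NT[rng_int(rng, 4L, 3L)], collapse = "")
      if (!cd %in% STOPS) break
    }
    out[k] <- cd
  }
  out
}

#' Embed an IRES into a synthetic dicistronic genome
#'
#' Layout: short 5' UTR (with an in-frame stop planted just before the ORF1
#' AUG so the open frame starts cleanly), ORF1 (AUG ... stop, optionally
#' carrying the YGDD RdRp proxy near its 3' end), unstructured IGR padding
#' with a stop planted in the ORF2 reading frame just before the IRES, the
#' IRES itself (PKI abutting the first ORF2 codon), and ORF2 continuing in
#' the frame set by the initiation codon to a stop plus a short 3' tail.
#'
#' @param ires Output of [sample_ires()].
#' @param params [generator_params()].
#' @param rng An [rng_new()] instance.
#' @param id Record identifier.
#' @return List with `record`, `layout` (the truth `dicistronic_layout` as
#'   [map_dicistronic()] should recover it), `ires_interval` (genome
#'   coordinates of the IRES span including the codon), `annotation`
#'   (genome coordinates), `frozen` (genome coordinates) and `orf1_aug`.
#' @export
embed_genome <- function(ires, params = generator_params(), rng, id = "synthetic_genome") {
  utr5_len <- rng_range(rng, 24L, 48L)
  utr5 <- paste(NT[rng_int(rng, 4L, utr5_len)], collapse = "")
  n1 <- rng_range(rng, params$orf1_len_codons[1], params$orf1_len_codons[2])
  codons1 <- c("AUG", random_codons(rng, n1 - 1L))
  if (params$include_ygdd) {
    # Tyr-Gly-Asp-Asp, the conserved RdRp catalytic motif
    ins <- length(codons1) - 10L
    codons1[ins:(ins + 3L)] <- c("UAU", "GGU", "GAU", "GAU")
  }
  orf1 <- paste(c(codons1, STOPS[rng_int(rng, 3L)]), collapse = "")
  # plant a stop immediately before the AUG, in its frame
  substr(utr5, utr5_len - 2L, utr5_len) <- "UAA"
  pad_len <- rng_range(rng, params$igr_padding[1], params$igr_padding[2])
  pad <- paste(NT[rng_int(rng, 4L, pad_len)], collapse = "")
  pre_len <- utr5_len + nchar(orf1)
  ires_start <- pre_len + pad_len + 1L
  ires_len <- nchar(ires$seq)
  codon_start <- ires_start + ires_len - 3L
  # plant a stop in the ORF2 frame at the 3' end of the padding
  fr <- (codon_start - 1L) %% 3L
  q <- pre_len + pad_len - 2L
  while ((q - 1L) %% 3L != fr) q <- q - 1L
  substr(pad, q - pre_len, q - pre_len + 2L) <- "UAA"
  # the genome base abutting the IRES 5' border must not extend the 5'-most
  # helix (same uniqueness guard the IRES sampler applies internally)
  first_el <- names(ires$annotation$element_coords)[1]
  if (grepl("_5p$", first_el)) {
    b3 <- ires$annotation$element_coords[[sub("_5p$", "_3p", first_el)]]
    qpos <- b3$end + 1L
    if (qpos <= ires_len) {
      partner <- substr(ires$seq, qpos, qpos)
      stop_local <- (q - pre_len):(q - pre_len + 2L)
      if (isTRUE(can_pair(substr(pad, pad_len, pad_len), partner)) &&
          !pad_len %in% stop_local) {
        repl <- switch(partner, A = "C", C = "A", G = "A", U = "C", "A")
        substr(pad, pad_len, pad_len) <- repl
      }
    }
  }
  n2 <- rng_range(rng, params$orf2_len_codons[1], params$orf2_len_codons[2])
  orf2_rest <- paste(c(random_codons(rng, n2 - 1L), STOPS[rng_int(rng, 3L)]), collapse = "")
  tail3 <- paste(NT[rng_int(rng, 4L, rng_range(rng, 15L, 30L))], collapse = "")
  genome <- paste0(utr5, orf1, pad, ires$seq, orf2_rest, tail3)
  rec <- genome_record(id, genome, "synthetic dicistronic genome")

  # truth layout, computed exactly as the scanner sees it
  orf1_start <- utr5_len + 1L
  orf1_end <- utr5_len + nchar(orf1)
  orf2_stop_end <- ires_start + ires_len - 1L + nchar(orf2_rest)
  x <- strsplit(genome, "")[[1]]
  p <- codon_start - 3L
  while (p >= 1L) {
    if (paste(x[p:(p + 2L)], collapse = "") %in% STOPS) break
    p <- p - 3L
  }
  orf2_start <- p + 3L
  prot1 <- as.character(Biostrings::translate(
    Biostrings::RNAString(substr(genome, orf1_start, orf1_end - 3L)),
    no.init.codon = TRUE))
  prot2 <- as.character(Biostrings::translate(
    Biostrings::RNAString(substr(genome, orf2_start, orf2_stop_end - 3L)),
    no.init.codon = TRUE))
  layout <- structure(list(
    orf1 = orf_annotation(orf1_start, orf1_end, (orf1_start - 1L) %% 3L, "+",
                          prot1, "AUG"),
    orf2 = orf_annotation(orf2_start, orf2_stop_end, (orf2_start - 1L) %% 3L, "+",
                          prot2, "frame_open"),
    igr = interval(orf1_end + 1L, orf2_start - 1L)), class = "dicistronic_layout")
  offset <- ires_start - 1L
  list(record = rec, layout = layout,
       ires_interval = interval(ires_start, ires_start + ires_len - 1L),
       annotation = shift_annotation(ires$annotation, offset),
       frozen = ires$frozen + offset,
       orf1_aug = orf1_start)
}

#' Evolve a clade of IRES sequences with compensatory substitutions
#'
#' Each member is mutated independently from the ancestor at
#' `substitution_rate` per site. A substitution hitting a paired position is
#' compensated with probability `compensation_prob`: the partner base is set
#' to restore Watson-Crick or G-U complementarity, chosen uniformly among
#' the restoring bases (not necessarily the ancestral identity — which is
#' what makes maintained pairs covariant rather than invariant). Positions
#' listed in `frozen` (motifs, required pairs, the codon) are never touched.
#'
#' @param ancestor_ires Output of [sample_ires()].
#' @param params [generator_params()].
#' @param rng An [rng_new()] instance.
#' @param freeze_motifs Keep class-defining positions fixed (default TRUE).
#' @return A `clade_truth`: list with `ancestor`, `members` (named character
#'   vector), `true_structure` (per-member annotations), `ires_interval`,
#'   and `substitution_log` (data.frame `member`, `position`, `from`, `to`,
#'   `compensated`).
#' @export
evolve_clade <- function(ancestor_ires, params = generator_params(), rng,
                         freeze_motifs = TRUE) {
  anc <- strsplit(ancestor_ires$seq, "")[[1]]
  L <- length(anc)
  frozen <- if (freeze_motifs) ancestor_ires$frozen else integer()
  prs <- ancestor_ires$annotation$pairs
  partner <- integer(L)
  partner[prs$i] <- prs$j; partner[prs$j] <- prs$i
  restoring <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  members <- stats::setNames(vector("list", params$n_taxa),
                             sprintf("member_%02d", seq_len(params$n_taxa)))
  logs <- list()
  for (m in seq_len(params$n_taxa)) {
    x <- anc
    hit <- rng_unif(rng, L) < params$substitution_rate
    hit[frozen] <- FALSE
    for (pos in which(hit)) {
      from <- x[pos]
      to <- setdiff(NT, from)[rng_int(rng, 3L)]
      x[pos] <- to
      logs[[length(logs) + 1L]] <- data.frame(
        member = names(members)[m], position = pos, from = from, to = to,
        compensated = FALSE, stringsAsFactors = FALSE)
      q <- partner[pos]
      if (q > 0L && !q %in% frozen && rng_unif(rng) < params$compensation_prob) {
        opts <- restoring[[to]]
        newq <- opts[rng_int(rng, length(opts))]
        if (newq != x[q]) {
          logs[[length(logs) + 1L]] <- data.frame(
            member = names(members)[m], position = q, from = x[q], to = newq,
            compensated = TRUE, stringsAsFactors = FALSE)
          x[q] <- newq
        }
      }
    }
    members[[m]] <- paste(x, collapse = "")
  }
  members <- unlist(members)
  true_structure <- lapply(members, function(s) {
    ann <- ancestor_ires$annotation
    xc <- strsplit(s, "")[[1]]
    if (nrow(ann$pairs)) ann$pairs$kind <- pair_kind(xc[ann$pairs$i], xc[ann$pairs$j])
    ann
  })
  structure(list(ancestor = ancestor_ires$seq, members = members,
                 true_structure = true_structure,
                 ires_interval = interval(1L, L),
                 substitution_log = if (length(logs)) do.call(rbind, logs)
                                    else data.frame(member = character(),
                                                    position = integer(),
                                                    from = character(),
                                                    to = character(),
                                                    compensated = logical())),
            class = "clade_truth")
}

#' Replay a substitution log
#'
#' Applies the logged substitutions of one member, in order, to the
#' ancestor. `evolve_clade()` guarantees this reproduces the member exactly.
#'
#' @param ancestor_seq Ancestor sequence string.
#' @param log The `substitution_log` of a `clade_truth`.
#' @param member Member name.
#' @return The reconstructed sequence string.
#' @export
replay_substitutions <- function(ancestor_seq, log, member) {
  x <- strsplit(ancestor_seq, "")[[1]]
  rows <- log[log$member == member, , drop = FALSE]
  for (k in seq_len(nrow(rows))) {
    if (x[rows$position[k]] != rows$from[k])
      stop(sprintf("log mismatch at position %d", rows$position[k]))
    x[rows$position[k]] <- rows$to[k]
  }
  paste(x, collapse = "")
}

#' Dinucleotide-preserving shuffle (decoy generator)
#'
#' Euler-path shuffle (random arborescence method): the returned sequence
#' has exactly the same dinucleotide counts — and therefore mononucleotide
#' composition, length, first and last base — as the input, but a randomized
#' order. Used to build composition-matched decoy IGRs for specificity
#' controls. Retries if the shuffle reproduces the input.
#'
#' @param seq Sequence string (>= 20 nt).
#' @param rng An [rng_new()] instance.
#' @param max_tries Retry budget for degenerate cases.
#' @return Shuffled sequence string.
#' @export
make_decoy <- function(seq, rng, max_tries = 50L) {
  if (nchar(seq) < 20) stop("decoy shuffling needs >= 20 nt")
  x <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(x)
  verts <- unique(x)
  last <- x[n]
  edges <- split(x[-1], factor(x[-n], levels = verts))
  for (try in seq_len(max_tries)) {
    # pick a random final edge for every vertex except the terminal one,
    # keep only choices whose final-edge graph is an arborescence into `last`
    fin <- stats::setNames(vapply(verts, function(v) {
      if (v == last) NA_character_
      else { e <- edges[[v]]; e[rng_int(rng, length(e))] }
    }, character(1)), verts)
    reaches <- function(v) {
      seen <- character()
      while (!is.na(fin[[v]]) && !v %in% seen) { seen <- c(seen, v); v <- fin[[v]] }
      v == last
    }
    if (!all(vapply(setdiff(verts, last), reaches, logical(1)))) next
    # shuffle the remaining edges, appending the final edge last
    pools <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!is.na(fin[[v]])) {
        drop <- match(fin[[v]], e)
        e <- e[-drop]
      }
      if (length(e) > 1) e <- e[with_rng(rng, sample.int(length(e)))]
      c(e, if (!is.na(fin[[v]])) fin[[v]])
    })
    names(pools) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- x[1]
    v <- x[1]
    ok <- TRUE
    for (k in 2:n) {
      e <- pools[[v]]
      if (ptr[[v]] > length(e)) { ok <- FALSE; break }
      w <- e[ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
      out[k] <- w
      v <- w
    }
    if (!ok) next
    res <- paste(out, collapse = "")
    if (res != seq || try == max_tries) return(res)
  }
  stop("decoy shuffle failed (degenerate sequence?)")
}
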
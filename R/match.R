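# Descriptor-constrained backtracking search for IGR IRES placements.
#
# The search is anchored at the 3' end: IGR IRESs end in PKI whose 3' helix
# strand abuts the initiation codon, so candidate codons are enumerated from
# the 3' end of the window and the element chain is placed right-to-left,
# checking helix complementarity, required pairs, loop motifs and length
# bounds as soon as both strands of a helix are fixed. Every satisfying
# placement is emitted; the enumeration order is fixed, so output is
# deterministic.

# best motif placement within a loop: slides the IUPAC consensus, counting
# mismatches at non-N positions only. Returns c(matched, mismatches) for the
# minimal-mismatch window (ties -> 5'-most), or NULL if loop shorter than the
# motif.
motif_best <- function(xchars, s, e, motif_chars) {
  L <- e - s + 1L
  m <- length(motif_chars)
  if (L < m) return(NULL)
  non_n <- motif_chars != "N"
  best <- NULL
  for (off in 0:(L - m)) {
    obs <- xchars[(s + off):(s + off + m - 1L)]
    mism <- sum(non_n & !iupac_match(obs, motif_chars))
    if (is.null(best) || mism < best[2]) best <- c(sum(non_n) - mism, mism)
    if (best[2] == 0L) break
  }
  best
}

# check an antiparallel helix: 5' strand [s5, s5+L-1] against 3' strand
# [s3, s3+L-1]; returns pair kinds (outermost first) or NULL on failure
helix_kinds <- function(xchars, s5, s3, L, allow_wobble, required_pairs) {
  b5 <- xchars[s5:(s5 + L - 1L)]
  b3 <- xchars[(s3 + L - 1L):s3]
  kinds <- pair_kind(b5, b3)
  if (anyNA(kinds)) return(NULL)
  if (!allow_wobble && any(kinds == "GU")) return(NULL)
  for (rp in required_pairs) {
    idx <- resolve_offset(rp$offset, L)
    if (kinds[idx] != rp$kind) return(NULL)
  }
  kinds
}

#' Find descriptor matches in a sequence
#'
#' Backtracking constraint search for placements of an IRES descriptor:
#' candidate initiation codons are enumerated from the 3' end of the search
#' window, PKI is anchored immediately 5' of the codon, and the remaining
#' helix strands and loops are placed leftwards under complementarity
#' (Watson-Crick, plus G-U where the helix allows wobble), element length
#' bounds, motif consensus and the total length window. Each satisfying
#' placement is scored as
#' `w_bp * total_bp + w_motif * motif_matches - w_energy * deltaG`
#' and results are sorted by score (ties: lower deltaG, then 5'-most, then
#' shortest). IUPAC ambiguity codes in the input never satisfy a pair or a
#' motif position.
#'
#' @param record A [genome_record()] (typically an IGR extract).
#' @param descriptor An `ires_descriptor`.
#' @param params Optional list: `score_min` (default from the descriptor),
#'   `best_only` (FALSE), `window` (search only the last 260 nt),
#'   `energy_params` (defaults to the packaged Turner 1999 tables).
#' @return List of `ires_match` objects (possibly empty), each with fields
#'   `annotation` ([structure_annotation()] in record coordinates), `score`,
#'   `delta_g`, `record_id` and `genome_interval`.
#' @export
match_descriptor <- function(record, descriptor, params = list()) {
  p <- utils::modifyList(list(score_min = descriptor$score_min,
                              best_only = FALSE, window = 260L,
                              energy_params = NULL), params)
  n <- nchar(record$seq)
  if (n < descriptor$total_len_range[1]) return(list())
  win_start <- max(1L, n - as.integer(p$window) + 1L)
  x <- strsplit(record$seq, "")[[1]]

  tok <- parse_order(descriptor)
  K <- nrow(tok)
  rev_idx <- K:1
  elems <- lapply(rev_idx, function(i) {
    t <- tok[i, ]
    if (t$type == "helix") {
      h <- descriptor$helices[[t$helix]]
      list(type = "helix", name = t$name, helix = t$helix, side = t$side,
           min = h$min_bp, max = h$max_bp, allow_wobble = isTRUE(h$allow_wobble),
           required = h$required_pairs)
    } else {
      l <- descriptor$loops[[t$name]]
      list(type = "loop", name = t$name,
           min = l$min_len, max = l$max_len,
           motif = if (is.null(l$motif)) NULL else strsplit(toupper(l$motif), "")[[1]],
           max_mismatch = l$max_mismatch)
    }
  })
  # helix length is fixed when its (3'-most) strand is met first in the
  # right-to-left walk; sanity-check the order supports that
  seen <- character()
  for (e in elems) {
    if (e$type == "helix") {
      if (e$side == "5p" && !e$helix %in% seen)
        stop(sprintf("helix %s: _5p strand met before _3p in 3'->5' walk", e$helix))
      seen <- c(seen, e$helix)
    }
  }
  minw <- rev(cumsum(vapply(rev(elems), function(e)
    if (e$type == "helix") e$min else e$min, numeric(1))))
  maxw <- rev(cumsum(vapply(rev(elems), function(e)
    if (e$type == "helix") e$max else e$max, numeric(1))))
  rng <- descriptor$total_len_range

  st <- new.env(parent = emptyenv())
  st$helix_len <- integer(); st$helix3_start <- integer()
  st$starts <- integer(K); st$ends <- integer(K)
  st$matches <- list()

  finalize <- function(codon_start, codon_end, motif_total) {
    lay <- data.frame(name = rev(vapply(elems, `[[`, "", "name")),
                      type = rev(vapply(elems, `[[`, "", "type")),
                      helix = rev(vapply(elems, function(e)
                        if (e$type == "helix") e$helix else NA_character_, "")),
                      side = rev(vapply(elems, function(e)
                        if (e$type == "helix") e$side else NA_character_, "")),
                      start = st$starts, end = st$ends,
                      stringsAsFactors = FALSE)
    lay$width <- lay$end - lay$start + 1L
    pr <- pairs_from_layout(lay)
    pr$kind <- pair_kind(x[pr$i], x[pr$j])
    coords <- stats::setNames(lapply(seq_len(nrow(lay)), function(i)
      interval(lay$start[i], lay$end[i])), lay$name)
    five <- lay$start[1]
    ann <- structure_annotation(
      element_coords = coords,
      pairs = pr[, c("i", "j", "kind")],
      pk_groups = descriptor$pk_groups, domains = descriptor$domains,
      start_codon = list(interval = interval(codon_start, codon_end),
                         triplet = paste(x[codon_start:codon_end], collapse = "")))
    local_pairs <- data.frame(i = pr$i - five + 1L, j = pr$j - five + 1L)
    dg <- evaluate_structure(substr(record$seq, five, codon_end), local_pairs,
                             params = p$energy_params)$total
    w <- descriptor$score_weights
    bp_total <- sum(lay$width[lay$type == "helix" & lay$side == "5p"])
    score <- unname(w["bp"] * bp_total + w["motif"] * motif_total - w["energy"] * dg)
    m <- structure(list(annotation = ann, score = score, delta_g = dg,
                        record_id = record$id,
                        genome_interval = interval(five, codon_end)),
                   class = "ires_match")
    st$matches[[length(st$matches) + 1L]] <- m
  }

  descend <- function(k, right, codon_start, codon_end, motif_total) {
    if (k > K) {
      total <- codon_end - right
      if (total >= rng[1] && total <= rng[2]) finalize(codon_start, codon_end, motif_total)
      return(invisible())
    }
    D <- codon_end - right
    lo <- max(minw[k], rng[1] - D); hi <- min(maxw[k], rng[2] - D)
    if (lo > hi || right - minw[k] + 1L < win_start) return(invisible())
    e <- elems[[k]]
    ri <- K - k + 1L  # index into st$starts (5'->3' orientation)
    for (len in e$min:e$max) {
      s <- right - len + 1L
      if (s < win_start) break
      if (e$type == "loop") {
        mt <- motif_total
        if (!is.null(e$motif)) {
          if (len < length(e$motif)) next
          mb <- motif_best(x, s, right, e$motif)
          if (is.null(mb) || mb[2] > e$max_mismatch) next
          mt <- mt + mb[1]
        }
        st$starts[ri] <- s; st$ends[ri] <- right
        descend(k + 1L, s - 1L, codon_start, codon_end, mt)
      } else if (e$side == "3p") {
        st$helix_len[e$helix] <- len
        st$helix3_start[e$helix] <- s
        st$starts[ri] <- s; st$ends[ri] <- right
        descend(k + 1L, s - 1L, codon_start, codon_end, motif_total)
      } else {
        L <- st$helix_len[e$helix]
        if (len != L) next  # length fixed by the 3' strand
        if (is.null(helix_kinds(x, s, st$helix3_start[e$helix], L,
                                e$allow_wobble, e$required))) next
        st$starts[ri] <- s; st$ends[ri] <- right
        descend(k + 1L, s - 1L, codon_start, codon_end, motif_total)
      }
    }
    invisible()
  }

  first_codon <- win_start + rng[1] - 3L
  cs <- n - 2L
  while (cs >= first_codon) {
    triplet <- paste(x[cs:(cs + 2L)], collapse = "")
    if (triplet %in% descriptor$allowed_start_codons)
      descend(1L, cs - 1L, cs, cs + 2L, 0)
    cs <- cs - 1L
  }

  matches <- st$matches
  if (!is.null(p$score_min))
    matches <- Filter(function(m) m$score >= p$score_min, matches)
  matches <- matches[match_order(matches)]
  if (isTRUE(p$best_only) && length(matches)) matches <- matches[1]
  matches
}

# deterministic ordering: score desc, deltaG asc, 5'-most, shortest
match_order <- function(matches) {
  if (!length(matches)) return(integer())
  order(-vapply(matches, `[[`, numeric(1), "score"),
        vapply(matches, `[[`, numeric(1), "delta_g"),
        vapply(matches, function(m) m$genome_interval$start, integer(1)),
        vapply(matches, function(m) interval_len(m$genome_interval), integer(1)))
}

#' @export
print.ires_match <- function(x, ...) {
  cat(sprintf("<ires_match> %s [%d, %d] score %.2f dG %.2f codon %s\n",
              x$record_id, x$genome_interval$start, x$genome_interval$end,
              x$score, x$delta_g, x$annotation$start_codon$triplet))
  invisible(x)
}

#' Report IRES borders
#'
#' The 5' border is the 5'-most structural element's first nucleotide, the
#' 3' border the last nucleotide of the initiation codon, and the length is
#' inclusive of the codon (the convention in which a 1044-1191 element is
#' reported as 148 nt long).
#'
#' @param match An `ires_match`.
#' @return List with `five_prime_border`, `three_prime_border`,
#'   `length_incl_codon`.
#' @export
report_borders <- function(match) {
  list(five_prime_border = match$genome_interval$start,
       three_prime_border = match$genome_interval$end,
       length_incl_codon = interval_len(match$genome_interval))
}

#' Toeprint offset rule
#'
#' Ribosomes bound with the codon-anticodon mimic in the P site protect the
#' mRNA up to +16 to +18 nt from the first (+1) nucleotide of the initiation
#' codon (counting the +1 nucleotide as position 1); a weaker alternate
#' state yields +19 to +21.
#'
#' @param p_site_offsets,alternate_offsets Integer offset windows.
#' @return A `toeprint_rule` object.
#' @export
toeprint_rule <- function(p_site_offsets = 16:18, alternate_offsets = 19:21) {
  stopifnot(all(p_site_offsets > 0), all(alternate_offsets > 0))
  structure(list(p_site_offsets = p_site_offsets,
                 alternate_offsets = alternate_offsets),
            class = "toeprint_rule")
}

#' Predict toeprint windows for a match
#'
#' @param match An `ires_match` with an assigned start codon.
#' @param rule A [toeprint_rule()].
#' @return Named list of [interval()]s (`p_site`, `alternate`) in the same
#'   coordinates as the match.
#' @export
predict_toeprints <- function(match, rule = toeprint_rule()) {
  p <- match$annotation$start_codon$interval$start
  list(p_site = interval(p + min(rule$p_site_offsets) - 1L,
                         p + max(rule$p_site_offsets) - 1L),
       alternate = interval(p + min(rule$alternate_offsets) - 1L,
                            p + max(rule$alternate_offsets) - 1L))
}

#' Apply point substitutions to a record
#'
#' Fixture support for mutational analysis: returns an edited copy, so
#' disruptive substitutions in one helix strand and compensatory double
#' mutants restoring complementarity can be tested against the descriptor.
#'
#' @param record A [genome_record()].
#' @param edits data.frame with columns `position`, `new_base`, or a list of
#'   `c(position, base)` pairs.
#' @return The edited `genome_record`.
#' @export
apply_mutation <- function(record, edits) {
  if (is.list(edits) && !is.data.frame(edits))
    edits <- data.frame(position = vapply(edits, function(e) as.integer(e[[1]]), integer(1)),
                        new_base = vapply(edits, function(e) as.character(e[[2]]), character(1)))
  if (!nrow(edits)) return(record)
  x <- strsplit(record$seq, "")[[1]]
  pos <- as.integer(edits$position)
  if (any(pos < 1 | pos > length(x)))
    stop(sprintf("edit position %d out of range 1-%d",
                 pos[pos < 1 | pos > length(x)][1], length(x)))
  x[pos] <- toupper(chartr("T", "U", edits$new_base))
  out <- record
  out$seq <- paste(x, collapse = "")
  out
}
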
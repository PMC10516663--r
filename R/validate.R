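#' Independently validate a structure annotation against a descriptor
#'
#' A from-scratch checker, kept free of any code shared with the search in
#' [match_descriptor()], used to re-validate every reported match and the
#' generator's ground truth: element tiling and 5'->3' order, per-element
#' length bounds, antiparallel complementarity of every helix pair
#' (Watson-Crick or, where allowed, G-U), required pairs, loop motif
#' consensus within the mismatch budget, the initiation codon (allowed set,
#' immediately 3' of the final element), the total length window, and the
#' three-layer bound on crossing pairs.
#'
#' @param seq Nucleotide string the annotation refers to.
#' @param ann A [structure_annotation()].
#' @param descriptor An `ires_descriptor`.
#' @return `TRUE` if valid, otherwise a character vector of violations.
#' @export
validate_annotation <- function(seq, ann, descriptor) {
  bad <- character()
  base_at <- function(p) substr(seq, p, p)
  tok_names <- descriptor$order
  cov <- ann$element_coords[tok_names]
  if (any(vapply(cov, is.null, logical(1)))) {
    return(sprintf("missing element(s): %s",
                   paste(tok_names[vapply(cov, is.null, logical(1))], collapse = " ")))
  }
  # contiguous tiling in descriptor order
  for (k in seq_along(tok_names)[-1]) {
    prev <- cov[[k - 1]]; cur <- cov[[k]]
    if (cur$start != prev$end + 1)
      bad <- c(bad, sprintf("%s does not abut %s", tok_names[k], tok_names[k - 1]))
  }
  # element sizes
  for (k in seq_along(tok_names)) {
    nm <- tok_names[k]
    w <- cov[[k]]$end - cov[[k]]$start + 1
    if (grepl("_(5p|3p)$", nm)) {
      h <- descriptor$helices[[sub("_(5p|3p)$", "", nm)]]
      if (w < h$min_bp || w > h$max_bp)
        bad <- c(bad, sprintf("%s width %d outside %d-%d bp", nm, w, h$min_bp, h$max_bp))
    } else {
      l <- descriptor$loops[[nm]]
      if (w < l$min_len || w > l$max_len)
        bad <- c(bad, sprintf("%s width %d outside %d-%d nt", nm, w, l$min_len, l$max_len))
    }
  }
  # helices: strand widths equal, antiparallel pairing, wobble policy,
  # required pairs
  for (h in names(descriptor$helices)) {
    a <- cov[[paste0(h, "_5p")]]; b <- cov[[paste0(h, "_3p")]]
    if (is.null(a) || is.null(b)) next
    L5 <- a$end - a$start + 1; L3 <- b$end - b$start + 1
    if (L5 != L3) { bad <- c(bad, sprintf("%s strand widths differ", h)); next }
    spec <- descriptor$helices[[h]]
    for (t in seq_len(L5)) {
      p5 <- a$start + t - 1; p3 <- b$end - t + 1
      kd <- pair_kind(base_at(p5), base_at(p3))
      if (is.na(kd))
        bad <- c(bad, sprintf("%s pair %d (%d:%d) not complementary", h, t, p5, p3))
      else if (kd == "GU" && !isTRUE(spec$allow_wobble))
        bad <- c(bad, sprintf("%s pair %d is a disallowed wobble", h, t))
    }
    for (rp in spec$required_pairs) {
      t <- if (rp$offset > 0) rp$offset else L5 + 1 + rp$offset
      p5 <- a$start + t - 1; p3 <- b$end - t + 1
      kd <- pair_kind(base_at(p5), base_at(p3))
      if (is.na(kd) || kd != rp$kind)
        bad <- c(bad, sprintf("%s required %s pair at index %d not satisfied", h, rp$kind, t))
    }
  }
  # the annotation's own pair list must agree with the element geometry
  expect_pairs <- character()
  for (h in names(descriptor$helices)) {
    a <- cov[[paste0(h, "_5p")]]; b <- cov[[paste0(h, "_3p")]]
    L <- a$end - a$start + 1
    expect_pairs <- c(expect_pairs,
                      paste(a$start + seq_len(L) - 1, b$end - seq_len(L) + 1))
  }
  got_pairs <- if (nrow(ann$pairs)) paste(ann$pairs$i, ann$pairs$j) else character()
  if (!setequal(expect_pairs, got_pairs))
    bad <- c(bad, "pair list disagrees with element coordinates")
  # loop motifs
  for (l in names(descriptor$loops)) {
    spec <- descriptor$loops[[l]]
    if (is.null(spec$motif)) next
    iv <- cov[[l]]
    loop_seq <- substr(seq, iv$start, iv$end)
    mchars <- strsplit(toupper(spec$motif), "")[[1]]
    m <- length(mchars)
    ok <- FALSE
    if (nchar(loop_seq) >= m) {
      for (off in 0:(nchar(loop_seq) - m)) {
        obs <- strsplit(substr(loop_seq, off + 1, off + m), "")[[1]]
        mism <- sum(mchars != "N" & !iupac_match(obs, mchars))
        if (mism <= spec$max_mismatch) { ok <- TRUE; break }
      }
    }
    if (!ok) bad <- c(bad, sprintf("loop %s fails motif %s", l, spec$motif))
  }
  # initiation codon: abuts the last element, allowed set
  last_end <- cov[[length(cov)]]$end
  if (is.null(ann$start_codon)) {
    bad <- c(bad, "no start codon assigned")
  } else {
    ci <- ann$start_codon$interval
    if (ci$start != last_end + 1)
      bad <- c(bad, "start codon does not abut the 3' element")
    trip <- toupper(substr(seq, ci$start, ci$end))
    if (trip != ann$start_codon$triplet)
      bad <- c(bad, "recorded triplet disagrees with sequence")
    if (!trip %in% descriptor$allowed_start_codons)
      bad <- c(bad, sprintf("start codon %s not in allowed set", trip))
    total <- ci$end - cov[[1]]$start + 1
    if (total < descriptor$total_len_range[1] || total > descriptor$total_len_range[2])
      bad <- c(bad, sprintf("total length %d outside %d-%d", total,
                            descriptor$total_len_range[1], descriptor$total_len_range[2]))
  }
  # crossing-layer bound
  if (nrow(ann$pairs)) {
    nl <- max(assign_layers(ann$pairs))
    if (nl > 3) bad <- c(bad, sprintf("%d crossing layers (max 3)", nl))
  }
  # H-type PKIII: no paired positions strictly inside the PKIII loops
  if (isTRUE(descriptor$pk3_is_h_type) && length(descriptor$pk_groups$PKIII)) {
    pk3 <- descriptor$pk_groups$PKIII
    loop_names <- intersect(names(descriptor$loops),
                            unlist(descriptor$domains[["2"]], use.names = FALSE))
    paired_pos <- c(ann$pairs$i, ann$pairs$j)
    for (l in loop_names) {
      iv <- cov[[l]]
      if (!is.null(iv) && any(paired_pos >= iv$start & paired_pos <= iv$end))
        bad <- c(bad, sprintf("PKIII loop %s contains paired positions", l))
    }
    if (any(ann$optional_stemloops))
      bad <- c(bad, "optional stem-loops flagged on an H-type PKIII descriptor")
  }
  if (length(bad)) bad else TRUE
}
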
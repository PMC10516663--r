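#' Translate one reading frame of a genome record
#'
#' Standard genetic code; stop codons are rendered `*`, codons containing
#' ambiguity codes that do not resolve to a unique amino acid are rendered
#' `X`, and an incomplete 3' tail (< 3 nt) is dropped.
#'
#' @param record A [genome_record()].
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` (default) or `"-"` (translate the reverse complement).
#' @return Amino-acid string.
#' @export
translate_frame <- function(record, frame, strand = "+") {
  stopifnot(inherits(record, "genome_record"), frame %in% 0:2)
  s <- record$seq
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  s <- substr(s, frame + 1, nchar(s))
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  s <- substr(s, 1, n)
  as.character(Biostrings::translate(Biostrings::RNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

orf_annotation <- function(start, end, frame, strand, protein, start_kind) {
  structure(list(interval = interval(start, end, strand), frame = frame,
                 strand = strand, protein = protein, start_kind = start_kind),
            class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("<orf> [%d, %d] frame %d%s %s, %d aa\n", x$interval$start,
              x$interval$end, x$frame, x$strand, x$start_kind, nchar(x$protein)))
  invisible(x)
}

# aa index -> nt coordinates of that codon on the + strand of the translated
# sequence; for "-" strand results are mapped back to original coordinates.
codon_to_nt <- function(aa_from, aa_to, frame, strand, seq_len) {
  s <- frame + 3L * (aa_from - 1L) + 1L
  e <- frame + 3L * aa_to
  if (strand == "-") c(seq_len - e + 1L, seq_len - s + 1L) else c(s, e)
}

#' Find open reading frames
#'
#' Reports, per frame and strand, both AUG-initiated ORFs and stop-to-stop
#' open stretches (`start_kind = "frame_open"`) of at least `min_aa` codons.
#' IGR IRESs direct initiation at non-AUG codons, so the downstream cistron
#' of a dicistronic genome is only visible as an open frame; its true start
#' is assigned later by an IRES match. Intervals are codon-aligned and
#' include the terminating stop codon when one is present; proteins exclude
#' the stop.
#'
#' @param record A [genome_record()].
#' @param min_aa Minimum protein length in codons (>= 1).
#' @param strands Strands to scan (default `"+"` only).
#' @return List of `orf_annotation` objects sorted by start coordinate.
#' @export
find_orfs <- function(record, min_aa, strands = "+") {
  stopifnot(min_aa >= 1)
  n <- nchar(record$seq)
  out <- list()
  for (strand in strands) {
    for (frame in 0:2) {
      prot <- translate_frame(record, frame, strand)
      if (!nzchar(prot)) next
      aa <- strsplit(prot, "")[[1]]
      stops <- which(aa == "*")
      seg_starts <- c(1L, stops + 1L)
      seg_ends <- c(stops - 1L, length(aa))
      keep <- seg_ends >= seg_starts
      seg_starts <- seg_starts[keep]; seg_ends <- seg_ends[keep]
      has_stop <- seg_ends + 1L <= length(aa)  # stop codon follows the run
      for (k in seq_along(seg_starts)) {
        a <- seg_starts[k]; b <- seg_ends[k]
        prot_run <- paste(aa[a:b], collapse = "")
        end_aa <- if (has_stop[k]) b + 1L else b
        if (b - a + 1L >= min_aa) {
          nt <- codon_to_nt(a, end_aa, frame, strand, n)
          out[[length(out) + 1L]] <-
            orf_annotation(nt[1], nt[2], frame, strand, prot_run, "frame_open")
        }
        m <- regexpr("M", prot_run, fixed = TRUE)
        if (m > 0) {
          maa <- a + as.integer(m) - 1L
          if (b - maa + 1L >= min_aa) {
            nt <- codon_to_nt(maa, end_aa, frame, strand, n)
            out[[length(out) + 1L]] <-
              orf_annotation(nt[1], nt[2], frame, strand,
                             substr(prot_run, m, nchar(prot_run)), "AUG")
          }
        }
      }
    }
  }
  out[order(vapply(out, function(o) o$interval$start, integer(1)),
            vapply(out, function(o) o$interval$end, integer(1)))]
}

#' Recognize the dicistronic genome layout
#'
#' Selects the two longest non-overlapping open frames in genome order whose
#' gap (the candidate IGR) lies within the configured bounds. Both cistrons
#' are taken from the stop-to-stop open frames reported by [find_orfs()]:
#' ORF2 of a dicistrovirus initiates at a non-AUG codon set by the IGR IRES,
#' so its reported start is provisional until an IRES match fixes it
#' ([assign_ires_start()]). Ties are broken by maximal combined length, then
#' smallest IGR, then 5'-most ORF1.
#'
#' @param record A [genome_record()].
#' @param params List of options: `min_genome_len` (default 600),
#'   `min_orf_aa` (150), `igr_min` (100), `igr_max` (400), `require_ygdd`
#'   (FALSE; when TRUE, ORF1 must contain the RdRp proxy motif `YGDD`).
#' @return A `dicistronic_layout`: list with `orf1`, `orf2`
#'   (`orf_annotation`) and `igr` ([interval()]).
#' @export
map_dicistronic <- function(record, params = list()) {
  p <- utils::modifyList(list(min_genome_len = 600L, min_orf_aa = 150L,
                              igr_min = 100L, igr_max = 400L,
                              require_ygdd = FALSE), params)
  if (nchar(record$seq) < p$min_genome_len)
    stop(sprintf("record '%s' is shorter (%d nt) than min_genome_len (%d)",
                 record$id, nchar(record$seq), p$min_genome_len))
  orfs <- find_orfs(record, min_aa = p$min_orf_aa)
  orfs <- Filter(function(o) o$start_kind == "frame_open", orfs)
  best <- NULL
  if (length(orfs) >= 2) {
    for (i in seq_along(orfs)) {
      for (j in seq_along(orfs)) {
        o1 <- orfs[[i]]; o2 <- orfs[[j]]
        if (o1$interval$end >= o2$interval$start) next
        gap <- o2$interval$start - o1$interval$end - 1L
        if (gap < p$igr_min || gap > p$igr_max) next
        if (p$require_ygdd && !grepl("YGDD", o1$protein, fixed = TRUE)) next
        key <- c(interval_len(o1$interval) + interval_len(o2$interval),
                 -gap, -o1$interval$start)
        if (is.null(best) ||
            key[1] > best$key[1] ||
            (key[1] == best$key[1] && key[2] > best$key[2]) ||
            (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3]))
          best <- list(o1 = o1, o2 = o2, gap = gap, key = key)
      }
    }
  }
  if (is.null(best))
    stop(structure(class = c("iresscope_no_layout", "error", "condition"),
                   list(message = sprintf(
                     "no dicistronic layout found in record '%s' (need two open frames >= %d aa separated by %d-%d nt)",
                     record$id, p$min_orf_aa, p$igr_min, p$igr_max),
                     call = NULL)))
  o1 <- best$o1
  if (startsWith(o1$protein, "M")) o1$start_kind <- "AUG"
  structure(list(orf1 = o1, orf2 = best$o2,
                 igr = interval(o1$interval$end + 1L, best$o2$interval$start - 1L)),
            class = "dicistronic_layout")
}

#' @export
print.dicistronic_layout <- function(x, ...) {
  cat(sprintf("<dicistronic_layout> ORF1 [%d, %d] | IGR %d nt | ORF2 [%d, %d]\n",
              x$orf1$interval$start, x$orf1$interval$end, interval_len(x$igr),
              x$orf2$interval$start, x$orf2$interval$end))
  invisible(x)
}

#' Extract the IGR plus a flank into ORF2
#'
#' Returns the candidate IGR plus `flank_into_orf2` nucleotides of the
#' downstream cistron (default 75 nt, enough to cover a primer-binding site
#' placed 61-75 nt downstream of the putative initiation codon) as a new
#' record, together with the offset mapping local to genome coordinates
#' (`genome = local + offset`).
#'
#' @param record A [genome_record()].
#' @param layout A `dicistronic_layout` for `record`.
#' @param flank_into_orf2 Nucleotides of ORF2 to append (default 75).
#' @return List with `record` (the extract), `offset`, and `truncated`
#'   (TRUE if the flank ran past the end of the genome).
#' @export
extract_igr <- function(record, layout, flank_into_orf2 = 75L) {
  start <- layout$igr$start
  end <- layout$igr$end + as.integer(flank_into_orf2)
  truncated <- end > nchar(record$seq)
  if (truncated) {
    warning(sprintf("flank truncated at record end (%d > %d)", end, nchar(record$seq)))
    end <- nchar(record$seq)
  }
  sub <- genome_record(paste0(record$id, "_igr"),
                       substr(record$seq, start, end),
                       sprintf("IGR extract %d-%d of %s", start, end, record$id))
  sub$source_alphabet <- record$source_alphabet
  list(record = sub, offset = start - 1L, truncated = truncated)
}

#' Fix the ORF2 start from an IRES match
#'
#' @param layout A `dicistronic_layout`.
#' @param codon_start Genome coordinate of the first nucleotide of the
#'   IRES-assigned initiation codon.
#' @return The layout with `orf2` re-anchored (`start_kind = "IRES_assigned"`)
#'   and the IGR adjusted accordingly.
#' @export
assign_ires_start <- function(layout, codon_start) {
  o2 <- layout$orf2
  if (codon_start < layout$igr$start || codon_start > o2$interval$end)
    stop(sprintf("IRES codon start %d incompatible with layout", codon_start))
  drop_aa <- (codon_start - o2$interval$start) %/% 3L
  o2$interval <- interval(codon_start, o2$interval$end, o2$strand)
  o2$protein <- substr(o2$protein, drop_aa + 1L, nchar(o2$protein))
  o2$start_kind <- "IRES_assigned"
  layout$orf2 <- o2
  layout$igr <- interval(layout$igr$start, codon_start - 1L)
  layout
}
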
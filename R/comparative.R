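# Alignment-based validation of structure models: a structural model is
# credible when the helices it proposes are maintained across homologous
# sequences either by strict conservation or by compensatory (covariant)
# substitutions that preserve complementarity.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh algorithm,
#' compiled). A gap of length k costs `gap_open + k * gap_extend`.
#' Traceback is deterministic: at ties the diagonal move is preferred, then
#' a gap in `b`, then a gap in `a`.
#'
#' @param a,b [genome_record()]s or plain sequence strings.
#' @param params Optional scores: `match` (+1), `mismatch` (-1), `gap_open`
#'   (-5), `gap_extend` (-1).
#' @return A `pairwise_alignment`: list with gapped `seq_a`, `seq_b` and
#'   `score`.
#' @export
align_pair <- function(a, b, params = list()) {
  p <- utils::modifyList(list(match = 1, mismatch = -1, gap_open = -5,
                              gap_extend = -1), params)
  sa <- if (inherits(a, "genome_record")) a$seq else toupper(a)
  sb <- if (inherits(b, "genome_record")) b$seq else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align empty sequences")
  out <- .gotoh_align(sa, sb, p$match, p$mismatch, p$gap_open, p$gap_extend)
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$seq_a, "\n", x$seq_b, "\n", sprintf("score %.1f\n", x$score), sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x matches / columns in which neither sequence is gapped. Columns with
#' a gap in either row are excluded from the denominator (identity
#' definitions differ between programs; this one is fixed and documented).
#'
#' @param aln A `pairwise_alignment`, or any list with gapped `seq_a`,
#'   `seq_b`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  a <- strsplit(aln$seq_a, "")[[1]]
  b <- strsplit(aln$seq_b, "")[[1]]
  if (length(a) != length(b)) stop("gapped sequences differ in length")
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("undefined identity: no ungapped columns")
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

#' Read a pre-aligned FASTA file
#'
#' Rows are normalized to upper-case RNA (`T -> U`) but gaps (`-` or `.`,
#' unified to `-`) are preserved. All rows must have equal length.
#'
#' @param path Aligned FASTA.
#' @return Named character vector of gapped sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  v <- toupper(chartr("T.", "U-", as.character(set)))
  names(v) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(v))) > 1)
    stop("alignment rows differ in length")
  v
}

# map 1-based ungapped positions of a reference row to alignment columns
ungapped_to_columns <- function(ref_row, positions) {
  cols <- which(strsplit(ref_row, "")[[1]] != "-")
  if (any(positions < 1 | positions > length(cols)))
    stop(sprintf("position %d outside the ungapped reference (1-%d)",
                 positions[positions < 1 | positions > length(cols)][1], length(cols)))
  cols[positions]
}

#' Covariation support for the base pairs of a reference structure
#'
#' For each base pair of the reference structure (given in ungapped
#' coordinates of the reference row), counts the alignment members whose
#' bases at the two columns form a Watson-Crick or G-U pair (`support`), and
#' classifies the pair: `invariant` if every member carries one identical
#' pair; `covariant` if complementarity is maintained in all members through
#' at least two distinct pair identities, or in at least the strong-support
#' threshold of members with at least two identities; `inconsistent`
#' otherwise. The strong threshold is a fraction of the membership
#' (default 0.85, i.e. at least 22 of 26 members), so it scales with
#' alignment size.
#'
#' @param alignment Named character vector of gapped rows (equal length),
#'   e.g. from [read_alignment()]; the clade generator's members can be
#'   passed directly (substitution-only evolution needs no gaps).
#' @param reference_structure A [structure_annotation()] or a data.frame of
#'   pairs `i`, `j` in ungapped coordinates of the reference row.
#' @param ref_row Index or name of the reference row (default 1).
#' @param thresholds List: `strong_frac` (default 0.85).
#' @return A `covariation_report`: list with `n_members`, `per_pair`
#'   (data.frame: `pair_id`, `col_i`, `col_j`, `class`, `support`,
#'   `n_identities`, `identities`), `invariant_pair_count`,
#'   `supported_pair_count` and `thresholds`.
#' @export
covariation_report <- function(alignment, reference_structure, ref_row = 1,
                               thresholds = list(strong_frac = 0.85)) {
  if (length(unique(nchar(alignment))) > 1) stop("alignment rows differ in length")
  n <- length(alignment)
  pairs <- if (inherits(reference_structure, "structure_annotation"))
    reference_structure$pairs else as.data.frame(reference_structure)
  if (!nrow(pairs)) stop("reference structure has no pairs")
  strong <- as.integer(ceiling(thresholds$strong_frac * n))
  rows <- do.call(rbind, strsplit(alignment, ""))
  ci <- ungapped_to_columns(alignment[[ref_row]], pairs$i)
  cj <- ungapped_to_columns(alignment[[ref_row]], pairs$j)
  per <- lapply(seq_len(nrow(pairs)), function(k) {
    bi <- rows[, ci[k]]; bj <- rows[, cj[k]]
    if (any(bi == "-" | bj == "-"))
      stop(sprintf("pair %d maps to a gapped column", k))
    ok <- !is.na(pair_kind(bi, bj))
    idents <- sort(unique(paste0(bi, bj)[ok]))
    support <- sum(ok)
    cls <- if (support == n && length(unique(paste0(bi, bj))) == 1) "invariant"
           else if (support >= strong && length(idents) >= 2) "covariant"
           else "inconsistent"
    data.frame(pair_id = k, col_i = ci[k], col_j = cj[k], class = cls,
               support = support, n_identities = length(idents),
               identities = paste(idents, collapse = ","),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(n_members = n, per_pair = per,
                 invariant_pair_count = sum(per$class == "invariant"),
                 supported_pair_count = sum(per$support >= strong),
                 thresholds = list(all = n, strong = strong,
                                   strong_frac = thresholds$strong_frac)),
            class = "covariation_report")
}

#' @export
print.covariation_report <- function(x, ...) {
  cat(sprintf("<covariation_report> %d members, %d pairs: %d invariant, %d covariant, %d inconsistent (strong >= %d)\n",
              x$n_members, nrow(x$per_pair), x$invariant_pair_count,
              sum(x$per_pair$class == "covariant"),
              sum(x$per_pair$class == "inconsistent"), x$thresholds$strong))
  invisible(x)
}

#' Column conservation and pairwise identity of an alignment
#'
#' @param alignment Named character vector of gapped rows (>= 2).
#' @return List with `fraction_invariant_columns` (fraction of columns,
#'   ungapped in every row, carrying a single base identity) and
#'   `pairwise_identity_matrix` (percent, diagonal 100).
#' @export
conservation_stats <- function(alignment) {
  if (length(alignment) < 2) stop("need at least two rows")
  rows <- do.call(rbind, strsplit(alignment, ""))
  ungapped <- colSums(rows == "-") == 0
  frac <- if (!any(ungapped)) NA_real_ else {
    mean(apply(rows[, ungapped, drop = FALSE], 2,
               function(col) length(unique(col)) == 1))
  }
  n <- length(alignment)
  m <- matrix(100, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      keep <- rows[i, ] != "-" & rows[j, ] != "-"
      pid <- if (!any(keep)) NA_real_ else 100 * sum(rows[i, keep] == rows[j, keep]) / sum(keep)
      m[i, j] <- m[j, i] <- pid
    }
  }
  list(fraction_invariant_columns = frac, pairwise_identity_matrix = m)
}

#' Concordance between chemical probing and a structure model
#'
#' Fraction of reactive (single-strand-selective) positions that the model
#' leaves unpaired. Helix positions — including helix-terminal ones — count
#' as paired; wobble pairs count as paired.
#'
#' @param annotation A [structure_annotation()].
#' @param reactive_positions Integer positions (same coordinates as the
#'   annotation), e.g. from [read_positions()].
#' @return Fraction in `[0, 1]`.
#' @export
probe_concordance <- function(annotation, reactive_positions) {
  if (!length(reactive_positions)) stop("undefined concordance: no reactive positions")
  span <- annotation_span(annotation)
  if (any(reactive_positions < span[1] | reactive_positions > span[2]))
    stop("reactive position outside the annotation span")
  paired <- c(annotation$pairs$i, annotation$pairs$j)
  mean(!reactive_positions %in% paired)
}
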
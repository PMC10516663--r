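WC_PAIRS <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
GU_PAIRS <- c(GU = TRUE, UG = TRUE)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"), B = c("C", "G", "U"),
  D = c("A", "G", "U"), H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

#' Classify a base pair
#'
#' @param a,b Single RNA bases (upper case). IUPAC ambiguity codes never
#'   pair (conservative treatment of uncertain sequence).
#' @return `"WC"` for Watson-Crick, `"GU"` for a G-U wobble, `NA` otherwise.
#' @export
pair_kind <- function(a, b) {
  key <- paste0(a, b)
  ifelse(!is.na(WC_PAIRS[key]), "WC", ifelse(!is.na(GU_PAIRS[key]), "GU", NA_character_))
}

can_pair <- function(a, b, wobble = TRUE) {
  k <- pair_kind(a, b)
  !is.na(k) & (wobble | k == "WC")
}

# does observed base match an IUPAC consensus code? N in the *sequence* never
# matches a non-N consensus position (ambiguity is not evidence).
iupac_match <- function(base, code) {
  mapply(function(b, cd) {
    if (cd == "N") return(TRUE)
    b %in% IUPAC_SETS[[cd]]
  }, base, code, USE.NAMES = FALSE)
}

#' Construct a structure annotation
#'
#' A concrete fold of an IGR IRES: named element coordinates (helix strands,
#' loops), the base-pair list, the grouping of helices into pseudoknots
#' PKI/PKII/PKIII and domains 1-3, the initiation codon, and flags for the
#' optional stem-loops (SLIII/SLIV/SLV) that distinguish the larger IRES
#' types. All coordinates are 1-based inclusive on the annotated sequence.
#'
#' @param element_coords Named list of [interval()]s (or `c(start, end)`).
#' @param pairs data.frame with columns `i`, `j`, `kind` (`"WC"`/`"GU"`).
#' @param pk_groups Named list mapping `PKI`/`PKII`/`PKIII` to helix names.
#' @param domains Named list mapping `"1"`/`"2"`/`"3"` to element names.
#' @param start_codon List with `interval` and `triplet`.
#' @param optional_stemloops Named logical vector `SLIII`, `SLIV`, `SLV`.
#' @return Object of class `structure_annotation`.
#' @export
structure_annotation <- function(element_coords, pairs, pk_groups = list(),
                                 domains = list(),
                                 start_codon = NULL,
                                 optional_stemloops = c(SLIII = FALSE, SLIV = FALSE,
                                                        SLV = FALSE)) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    if (any(pairs$i >= pairs$j)) stop("pairs must satisfy i < j")
    pos <- c(pairs$i, pairs$j)
    if (anyDuplicated(pos))
      stop(sprintf("position %d occurs in two base pairs", pos[duplicated(pos)][1]))
    pairs <- pairs[order(pairs$i), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(element_coords = element_coords, pairs = pairs,
                 pk_groups = pk_groups, domains = domains,
                 start_codon = start_codon,
                 optional_stemloops = optional_stemloops),
            class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("<structure_annotation> %d elements, %d base pairs\n",
              length(x$element_coords), nrow(x$pairs)))
  if (!is.null(x$start_codon))
    cat(sprintf("  start codon %s at %d-%d\n", x$start_codon$triplet,
                x$start_codon$interval$start, x$start_codon$interval$end))
  invisible(x)
}

# shift all coordinates of an annotation by a fixed offset (local -> genome)
shift_annotation <- function(ann, offset) {
  offset <- as.integer(offset)
  ann$element_coords <- lapply(ann$element_coords, function(iv)
    interval(iv$start + offset, iv$end + offset, iv$strand))
  if (nrow(ann$pairs)) {
    ann$pairs$i <- ann$pairs$i + offset
    ann$pairs$j <- ann$pairs$j + offset
  }
  if (!is.null(ann$start_codon))
    ann$start_codon$interval <- interval(ann$start_codon$interval$start + offset,
                                         ann$start_codon$interval$end + offset)
  ann
}

annotation_span <- function(ann) {
  starts <- vapply(ann$element_coords, `[[`, integer(1), "start")
  ends <- vapply(ann$element_coords, `[[`, integer(1), "end")
  if (!is.null(ann$start_codon)) {
    starts <- c(starts, ann$start_codon$interval$start)
    ends <- c(ends, ann$start_codon$interval$end)
  }
  c(min(starts), max(ends))
}

# positions (within the annotation span) that are in no base pair
unpaired_positions <- function(ann) {
  span <- annotation_span(ann)
  setdiff(seq(span[1], span[2]), c(ann$pairs$i, ann$pairs$j))
}

#' Flatten a structure annotation into GFF3 feature rows
#'
#' Emits one parent row of type `IRES` spanning the annotation plus one child
#' row per named element, linked by `Parent`.
#'
#' @param ann A [structure_annotation()].
#' @param seqid Record identifier the coordinates refer to.
#' @param ires_id Feature ID for the parent row.
#' @param score Optional score for the parent row.
#' @return data.frame suitable for [write_gff3()].
#' @export
annotation_to_features <- function(ann, seqid, ires_id = "ires1", score = NA_real_) {
  span <- annotation_span(ann)
  parent <- data.frame(seqid = seqid, start = span[1], end = span[2],
                       strand = "+", type = "IRES", score = score,
                       ID = ires_id, Name = ires_id, Parent = NA_character_,
                       stringsAsFactors = FALSE)
  kids <- do.call(rbind, lapply(names(ann$element_coords), function(nm) {
    iv <- ann$element_coords[[nm]]
    if (iv$end < iv$start) return(NULL)  # zero-width loop: nothing to emit
    data.frame(seqid = seqid, start = iv$start, end = iv$end, strand = "+",
               type = if (grepl("^P", nm)) "helix_strand" else "loop",
               score = NA_real_, ID = paste0(ires_id, ":", nm), Name = nm,
               Parent = ires_id, stringsAsFactors = FALSE)
  }))
  codon <- NULL
  if (!is.null(ann$start_codon)) {
    codon <- data.frame(seqid = seqid, start = ann$start_codon$interval$start,
                        end = ann$start_codon$interval$end, strand = "+",
                        type = "start_codon", score = NA_real_,
                        ID = paste0(ires_id, ":start_codon"),
                        Name = ann$start_codon$triplet, Parent = ires_id,
                        stringsAsFactors = FALSE)
  }
  rbind(parent, kids, codon)
}
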
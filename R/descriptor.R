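#' Construct an IRES structural descriptor
#'
#' A descriptor is the grammar of an IRES class: an ordered list of helix
#' strands and loops (5' to 3'), per-helix base-pair bounds and wobble
#' policy, optional loop consensus motifs with a mismatch budget, the
#' grouping of helices into pseudoknots and domains, the allowed (non-AUG)
#' initiation codons, and the total length window including the first ORF2
#' codon. [match_descriptor()] searches sequences for placements satisfying
#' the grammar; [sample_ires()] draws sequences from it.
#'
#' @param name Descriptor name (e.g. `"6e"`).
#' @param helices Named list; each entry has `min_bp`, `max_bp`,
#'   `allow_wobble`, and optionally `required_pairs` (list of
#'   `list(offset, kind)`, where offset 1 is the outermost pair — the 5'-most
#'   base of the 5' strand — and negative offsets count from the innermost).
#' @param loops Named list; each entry has `min_len`, `max_len`, and
#'   optionally `motif` (IUPAC consensus matched anywhere within the loop)
#'   and `max_mismatch`.
#' @param order Character vector of strand tokens in 5'->3' order: `<helix>_5p`,
#'   `<helix>_3p` and loop names. Each helix must contribute exactly one
#'   `_5p` and one `_3p` token with `_5p` first.
#' @param total_len_range Length 2 vector, min/max total span in nt
#'   including the initiation codon.
#' @param allowed_start_codons Character vector of RNA triplets.
#' @param pk_groups,domains Named lists of element names.
#' @param pk3_is_h_type Must PKIII be a plain H-type pseudoknot (its loops
#'   free of stem-loops)?
#' @param score_weights Named numeric: `bp`, `motif`, `energy` — weights of
#'   the match score `bp*total_bp + motif*motif_matches - energy*deltaG`.
#' @param wobble_prob Probability the generator makes an (unconstrained)
#'   helix pair a G-U wobble.
#' @param score_min Default score threshold for reporting matches.
#' @return Object of class `ires_descriptor`, validated.
#' @export
ires_descriptor <- function(name, helices, loops, order, total_len_range,
                            allowed_start_codons,
                            pk_groups = list(), domains = list(),
                            pk3_is_h_type = TRUE,
                            score_weights = c(bp = 1, motif = 2, energy = 0.1),
                            wobble_prob = 0.1, score_min = 0) {
  for (h in names(helices)) {
    if (is.null(helices[[h]]$allow_wobble)) helices[[h]]$allow_wobble <- TRUE
    if (is.null(helices[[h]]$required_pairs)) helices[[h]]$required_pairs <- list()
  }
  for (l in names(loops)) {
    if (is.null(loops[[l]]$max_mismatch)) loops[[l]]$max_mismatch <- 0L
  }
  d <- structure(list(name = name, helices = helices, loops = loops,
                      order = order, total_len_range = as.integer(total_len_range),
                      allowed_start_codons = toupper(allowed_start_codons),
                      pk_groups = pk_groups, domains = domains,
                      pk3_is_h_type = isTRUE(pk3_is_h_type),
                      score_weights = score_weights,
                      wobble_prob = wobble_prob, score_min = score_min),
                 class = "ires_descriptor")
  validate_descriptor(d)
  d
}

#' Validate an IRES descriptor
#'
#' Checks name uniqueness, helix/loop bounds, motif lengths, the strand
#' order (each helix once as `_5p` and once as `_3p`, in that order), the
#' total length window, and that the pairing plan never needs more than
#' three mutually crossing layers.
#'
#' @param d An `ires_descriptor`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_descriptor <- function(d) {
  if (anyDuplicated(c(names(d$helices), names(d$loops))))
    stop("descriptor element names must be unique")
  for (h in names(d$helices)) {
    e <- d$helices[[h]]
    if (!(e$min_bp >= 1 && e$min_bp <= e$max_bp && e$max_bp <= 15))
      stop(sprintf("helix %s: need 1 <= min_bp <= max_bp <= 15", h))
  }
  for (l in names(d$loops)) {
    e <- d$loops[[l]]
    if (!(e$min_len >= 0 && e$min_len <= e$max_len))
      stop(sprintf("loop %s: need 0 <= min_len <= max_len", l))
    if (!is.null(e$motif) && nchar(e$motif) > e$max_len)
      stop(sprintf("loop %s: motif longer than max_len", l))
    if (!is.null(e$motif)) {
      bad <- setdiff(strsplit(toupper(e$motif), "")[[1]], names(IUPAC_SETS))
      if (length(bad)) stop(sprintf("loop %s: non-IUPAC motif characters", l))
    }
  }
  tok <- parse_order(d)
  for (h in names(d$helices)) {
    w5 <- which(tok$helix == h & tok$side == "5p")
    w3 <- which(tok$helix == h & tok$side == "3p")
    if (length(w5) != 1 || length(w3) != 1 || w5 >= w3)
      stop(sprintf("helix %s must appear once as _5p then once as _3p", h))
  }
  miss <- setdiff(names(d$loops), tok$name[tok$type == "loop"])
  if (length(miss)) stop(sprintf("loops not in order: %s", paste(miss, collapse = " ")))
  # full-size IGR IRES descriptors live in 100-260 nt; the lower bound is
  # relaxed so that cut-down test descriptors (2-helix toys) validate too
  if (length(d$total_len_range) != 2 || d$total_len_range[1] > d$total_len_range[2] ||
      d$total_len_range[1] < 15 || d$total_len_range[2] > 260)
    stop("total_len_range must be within 15-260 nt")
  if (!all(nchar(d$allowed_start_codons) == 3))
    stop("start codons must be triplets")
  # representative placement at minimal widths -> layer count of the plan
  rep_pairs <- representative_pairs(d)
  nl <- if (nrow(rep_pairs)) max(assign_layers(rep_pairs)) else 0L
  if (nl > 3) stop(sprintf("pairing plan requires %d crossing layers (max 3)", nl))
  invisible(TRUE)
}

# tokenize the order vector into a data.frame
parse_order <- function(d) {
  toks <- d$order
  type <- ifelse(grepl("_5p$|_3p$", toks), "helix", "loop")
  helix <- ifelse(type == "helix", sub("_(5p|3p)$", "", toks), NA)
  side <- ifelse(type == "helix", sub("^.*_(5p|3p)$", "\\1", toks), NA)
  if (any(type == "helix" & !helix %in% names(d$helices)))
    stop("order references unknown helix")
  if (any(type == "loop" & !toks %in% names(d$loops)))
    stop(sprintf("order references unknown loop '%s'",
                 toks[type == "loop" & !toks %in% names(d$loops)][1]))
  data.frame(name = toks, type = type, helix = helix, side = side,
             stringsAsFactors = FALSE)
}

# element widths at given per-element sizes -> coordinates; used for the
# layer-count check and by the generator
layout_elements <- function(d, helix_bp, loop_len, start = 1L) {
  tok <- parse_order(d)
  width <- ifelse(tok$type == "helix", helix_bp[tok$helix], loop_len[tok$name])
  ends <- start - 1L + cumsum(width)
  starts <- ends - width + 1L
  data.frame(tok, start = starts, end = ends, width = width,
             stringsAsFactors = FALSE)
}

representative_pairs <- function(d) {
  hb <- vapply(d$helices, `[[`, numeric(1), "min_bp")
  ll <- vapply(d$loops, `[[`, numeric(1), "min_len")
  lay <- layout_elements(d, hb, ll)
  pairs_from_layout(lay)
}

# derive the base-pair position list from an element layout
pairs_from_layout <- function(lay) {
  hx <- unique(lay$helix[lay$type == "helix"])
  out <- lapply(hx, function(h) {
    a <- lay[lay$type == "helix" & lay$helix == h & lay$side == "5p", ]
    b <- lay[lay$type == "helix" & lay$helix == h & lay$side == "3p", ]
    L <- a$width
    data.frame(i = a$start + seq_len(L) - 1L, j = b$end - seq_len(L) + 1L,
               helix = h, pair_index = seq_len(L))
  })
  df <- do.call(rbind, out)
  if (is.null(df)) data.frame(i = integer(), j = integer(), helix = character(),
                              pair_index = integer()) else df[order(df$i), ]
}

# resolve a required_pairs offset to a pair index for helix length L
resolve_offset <- function(offset, L) {
  idx <- if (offset > 0) offset else L + 1L + offset
  if (idx < 1 || idx > L) stop(sprintf("required pair offset %d invalid for %d bp", offset, L))
  idx
}

#' Load an IRES descriptor from a YAML file
#'
#' @param path Path to a descriptor config (see the packaged
#'   `descriptor_6e.yaml` for the format).
#' @return An `ires_descriptor`.
#' @export
read_descriptor <- function(path) {
  if (!file.exists(path)) stop(sprintf("descriptor config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  need <- c("name", "helices", "loops", "order", "total_len_range",
            "allowed_start_codons")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("descriptor config missing fields: %s", paste(miss, collapse = " ")))
  sw <- if (!is.null(cfg$score_weights))
    c(bp = cfg$score_weights$bp, motif = cfg$score_weights$motif,
      energy = cfg$score_weights$energy) else c(bp = 1, motif = 2, energy = 0.1)
  ires_descriptor(name = cfg$name, helices = cfg$helices, loops = cfg$loops,
                  order = unlist(cfg$order),
                  total_len_range = unlist(cfg$total_len_range),
                  allowed_start_codons = unlist(cfg$allowed_start_codons),
                  pk_groups = lapply(cfg$pk_groups, unlist),
                  domains = lapply(cfg$domains, unlist),
                  pk3_is_h_type = isTRUE(cfg$pk3_is_h_type),
                  score_weights = sw,
                  wobble_prob = if (is.null(cfg$wobble_prob)) 0.1 else cfg$wobble_prob,
                  score_min = if (is.null(cfg$score_min)) 0 else cfg$score_min)
}

#' The default type 6e (Wenling-class) descriptor
#'
#' Loads the packaged descriptor for the compact ~150 nt IGR IRES class:
#' total length 142-154 nt including the first ORF2 codon, helices
#' P1.1-P1.3 (PKII), the H-type PKIII (P2.1/P2.2, five pairs each by
#' default), the 3'-terminal PKI (P3.1/P3.2), conserved L1.1a/L1.1b loop
#' motifs, an invariant G-U wobble at the P1.1/L1.1a junction, and the
#' non-AUG initiation codon set GCU (Ala), ACU/ACC (Thr), UCU/UCA/UCG (Ser).
#'
#' @return An `ires_descriptor`.
#' @export
default_descriptor_6e <- function() {
  read_descriptor(system.file("extdata", "descriptor_6e.yaml",
                              package = "iresscope", mustWork = TRUE))
}

#' @export
print.ires_descriptor <- function(x, ...) {
  cat(sprintf("<ires_descriptor> %s: %d helices, %d loops, %d-%d nt, codons {%s}\n",
              x$name, length(x$helices), length(x$loops),
              x$total_len_range[1], x$total_len_range[2],
              paste(x$allowed_start_codons, collapse = ",")))
  invisible(x)
}
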
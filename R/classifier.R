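# Typing of IGR IRESs (6a-6e) from architecture and length.
#
# The five types differ in which pseudoknots and optional stem-loops they
# carry and in total length: 6c (126-132 nt) has PKI and PKII but no PKIII;
# 6e (142-154 nt) adds a compact H-type PKIII without SLIV/SLV; 6d
# (161-168 nt) has a PKIII with SLIV but no SLV; 6a (176-193 nt) has SLIV
# and SLV; 6b (195-205 nt) additionally carries SLIII on PKI.

#' Default IGR IRES type length ranges (nt, including the first ORF2 codon)
#' @return Named list of `c(min, max)` per type.
#' @export
default_type_ranges <- function() {
  list(`6c` = c(126L, 132L), `6e` = c(142L, 154L), `6d` = c(161L, 168L),
       `6a` = c(176L, 193L), `6b` = c(195L, 205L))
}

#' Load and check type length ranges
#'
#' The five ranges must be pairwise disjoint; ambiguous custom
#' configurations are refused at load time.
#'
#' @param ranges Named list of `c(min, max)`, or a YAML file path.
#' @return The validated ranges.
#' @export
load_type_ranges <- function(ranges = default_type_ranges()) {
  if (is.character(ranges)) ranges <- lapply(yaml::read_yaml(ranges), as.integer)
  types <- names(ranges)
  for (t in types) {
    r <- ranges[[t]]
    if (length(r) != 2 || r[1] > r[2]) stop(sprintf("invalid range for %s", t))
  }
  if (length(types) > 1) {
    for (i in 1:(length(types) - 1)) for (j in (i + 1):length(types)) {
      a <- ranges[[i]]; b <- ranges[[j]]
      if (a[1] <= b[2] && b[1] <= a[2])
        stop(sprintf("length ranges for %s and %s overlap: classification would be ambiguous",
                     types[i], types[j]))
    }
  }
  ranges
}

START_CODON_SETS <- list(
  `6a` = c("GCU", "GCA", "CAA"),
  `6b` = c("GCU", "GCA", "CAA"),
  `6c` = c("GCU", "GCA", "CAA"),  # provisional: reported for 6a/6b, adopted for 6c/6d
  `6d` = c("GCU", "GCA", "CAA"),
  `6e` = c("GCU", "ACU", "ACC", "UCU", "UCA", "UCG"))

#' Check an initiation codon against a type's codon set
#'
#' @param triplet Three RNA bases.
#' @param type One of `6a`-`6e`.
#' @return List with `ok`, `codon`, `amino_acid` (single-letter), `type`.
#' @export
codon_check <- function(triplet, type) {
  triplet <- toupper(chartr("T", "U", triplet))
  if (!is.character(triplet) || nchar(triplet) != 3 ||
      !all(strsplit(triplet, "")[[1]] %in% c("A", "C", "G", "U")))
    stop(sprintf("'%s' is not an RNA triplet", triplet))
  if (!type %in% names(START_CODON_SETS)) stop(sprintf("unknown type '%s'", type))
  aa <- unname(Biostrings::GENETIC_CODE[chartr("U", "T", triplet)])
  list(ok = triplet %in% START_CODON_SETS[[type]], codon = triplet,
       amino_acid = aa, type = type)
}

# architecture flags of an annotation
annotation_architecture <- function(ann) {
  helices <- unique(sub("_(5p|3p)$", "",
                        grep("_(5p|3p)$", names(ann$element_coords), value = TRUE)))
  pk <- ann$pk_groups
  has <- function(group, prefix) {
    if (length(pk[[group]])) all(pk[[group]] %in% helices)
    else any(startsWith(helices, prefix))
  }
  sl <- ann$optional_stemloops
  get_sl <- function(nm) isTRUE(unname(sl[nm]))
  pk3_hx <- if (length(pk$PKIII)) intersect(pk$PKIII, helices)
            else helices[startsWith(helices, "P2")]
  h_type <- length(pk3_hx) == 2 && nrow(ann$pairs) > 0 && {
    hp <- function(h) {
      a <- ann$element_coords[[paste0(h, "_5p")]]; b <- ann$element_coords[[paste0(h, "_3p")]]
      c(a$start, b$end)
    }
    s1 <- hp(pk3_hx[1]); s2 <- hp(pk3_hx[2])
    (s1[1] < s2[1] && s2[1] < s1[2] && s1[2] < s2[2]) ||
      (s2[1] < s1[1] && s1[1] < s2[2] && s2[2] < s1[2])
  }
  list(has_pki = has("PKI", "P3"), has_pkii = has("PKII", "P1"),
       has_pkiii = has("PKIII", "P2"),
       pkiii_h_type = h_type,
       sliii = get_sl("SLIII"), sliv = get_sl("SLIV"), slv = get_sl("SLV"))
}

#' Classify an IGR IRES annotation into types 6a-6e
#'
#' Architecture rules: 6e requires PKI, PKII and an H-type PKIII with
#' neither SLIV nor SLV; 6c has PKI and PKII but no PKIII; 6d a PKIII with
#' SLIV but not SLV; 6a SLIV and SLV without SLIII; 6b additionally SLIII.
#' The call also requires the length to fall in the type's range; an
#' architecture that fits a type whose length range is missed yields
#' `unclassified` with a near-type hint (the printed ranges are empirical,
#' not definitional). Start-codon compatibility is reported as evidence but
#' is never decisive.
#'
#' @param annotation A [structure_annotation()].
#' @param length_nt Total IRES length in nt including the initiation codon.
#' @param ranges Validated type length ranges ([load_type_ranges()]).
#' @return An `ires_type_call`: list with `type`, `evidence`, `length_nt`.
#' @export
classify_type <- function(annotation, length_nt, ranges = load_type_ranges()) {
  arch <- annotation_architecture(annotation)
  rules <- list(
    `6e` = c(pki = arch$has_pki, pkii = arch$has_pkii,
             `H-type PKIII` = arch$has_pkiii && arch$pkiii_h_type,
             `no SLIV` = !arch$sliv, `no SLV` = !arch$slv),
    `6c` = c(pki = arch$has_pki, pkii = arch$has_pkii,
             `no PKIII` = !arch$has_pkiii),
    `6d` = c(pki = arch$has_pki, pkii = arch$has_pkii, pkiii = arch$has_pkiii,
             SLIV = arch$sliv, `no SLV` = !arch$slv),
    `6a` = c(pki = arch$has_pki, pkii = arch$has_pkii, pkiii = arch$has_pkiii,
             SLIV = arch$sliv, SLV = arch$slv, `no SLIII` = !arch$sliii),
    `6b` = c(pki = arch$has_pki, pkii = arch$has_pkii, pkiii = arch$has_pkiii,
             SLIV = arch$sliv, SLV = arch$slv, SLIII = arch$sliii))
  arch_ok <- vapply(rules, all, logical(1))
  evidence <- character()
  call_type <- "unclassified"
  for (t in names(ranges)) {
    if (!isTRUE(arch_ok[t])) next
    r <- ranges[[t]]
    if (length_nt >= r[1] && length_nt <= r[2]) {
      call_type <- t
      evidence <- c(evidence,
                    sprintf("architecture satisfies %s: %s", t,
                            paste(names(rules[[t]]), collapse = ", ")),
                    sprintf("length %d nt within %d-%d", length_nt, r[1], r[2]))
      break
    }
  }
  if (call_type == "unclassified") {
    near <- names(arch_ok)[arch_ok]
    if (length(near)) {
      t <- near[1]; r <- ranges[[t]]
      evidence <- c(evidence,
                    sprintf("near-%s: architecture fits but length %d nt outside %d-%d",
                            t, length_nt, r[1], r[2]))
    }
    for (t in names(rules)) {
      viol <- names(rules[[t]])[!rules[[t]]]
      if (length(viol))
        evidence <- c(evidence, sprintf("%s violated: %s", t, paste(viol, collapse = ", ")))
    }
  }
  if (!is.null(annotation$start_codon)) {
    ct <- if (call_type == "unclassified") "6e" else call_type
    cc <- codon_check(annotation$start_codon$triplet, ct)
    evidence <- c(evidence, sprintf("start codon %s (%s) %s the %s codon set",
                                    cc$codon, cc$amino_acid,
                                    if (cc$ok) "in" else "not in", ct))
  }
  structure(list(type = call_type, evidence = evidence,
                 length_nt = as.integer(length_nt)),
            class = "ires_type_call")
}

#' @export
print.ires_type_call <- function(x, ...) {
  cat(sprintf("<ires_type_call> %s (%d nt)\n", x$type, x$length_nt))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}
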
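IUPAC_RNA <- c("A", "C", "G", "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Construct a genome record
#'
#' A genome record holds one nucleotide sequence in a normalized RNA alphabet
#' (A/C/G/U plus IUPAC ambiguity codes) together with its identifier and the
#' alphabet of the original input. DNA input is transparently transcribed
#' (T -> U) and the original alphabet remembered so output can be written back
#' as DNA.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Nucleotide sequence (DNA or RNA, any case).
#' @param description Free-text description (may be empty).
#' @return An object of class `genome_record` with fields `id`, `description`,
#'   `seq` (RNA, upper case) and `source_alphabet` (`"DNA"` or `"RNA"`).
#' @export
genome_record <- function(id, seq, description = "") {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("record id must be a non-empty string")
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop(sprintf("record '%s' has an empty sequence", id))
  raw <- toupper(seq)
  alphabet <- if (grepl("T", raw, fixed = TRUE) && !grepl("U", raw, fixed = TRUE)) "DNA"
              else if (grepl("U", raw, fixed = TRUE)) "RNA"
              else "DNA"
  norm <- chartr("T", "U", raw)
  bad <- setdiff(unique(strsplit(norm, "")[[1]]), IUPAC_RNA)
  if (length(bad))
    stop(sprintf("record '%s' contains non-IUPAC characters: %s", id,
                 paste(bad, collapse = " ")))
  structure(list(id = id, description = description, seq = norm,
                 source_alphabet = alphabet),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d nt, source %s)\n", x$id, nchar(x$seq),
              x$source_alphabet))
  invisible(x)
}

#' Read a FASTA file into a list of genome records
#'
#' Sequences are normalized to the RNA alphabet (T -> U, upper case); the
#' source alphabet of each entry is recorded. Duplicate identifiers within one
#' file are an error.
#'
#' @param path Path to a FASTA file (DNA or RNA).
#' @return A named list of [genome_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0) return(list())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record id in '%s': %s", path,
                 ids[duplicated(ids)][1]))
  recs <- lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (!nzchar(s)) stop(sprintf("empty sequence for record '%s'", ids[i]))
    genome_record(ids[i], s, desc[i])
  })
  names(recs) <- ids
  recs
}

#' Write genome records to a FASTA file
#'
#' Records whose `source_alphabet` is DNA are written back in the DNA
#' alphabet (U -> T); RNA records are written as RNA.
#'
#' @param records List of [genome_record()] objects.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "genome_record"))
    s <- if (r$source_alphabet == "DNA") chartr("U", "T", r$seq) else r$seq
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a 1-based inclusive interval
#'
#' All user-facing coordinates in the package are 1-based and inclusive,
#' matching the conventional notation for positions in viral genomes
#' (e.g. a codon written as positions 6906-6908).
#'
#' @param start,end Integer positions, `1 <= start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `ires_interval` (named integer-ish list).
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  # end == start - 1 encodes a zero-width interval (e.g. a degenerate loop)
  if (is.na(start) || is.na(end) || start < 1 || end < start - 1)
    stop(sprintf("invalid interval [%s, %s]: need 1 <= start <= end", start, end))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "ires_interval")
}

#' @export
print.ires_interval <- function(x, ...) {
  cat(sprintf("[%d, %d] (%s)\n", x$start, x$end, x$strand)); invisible(x)
}

interval_len <- function(iv) iv$end - iv$start + 1L

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write sequence features as GFF3
#'
#' Features are written with 1-based inclusive coordinates, nine columns and
#' the `##gff-version 3` pragma. An IRES annotation should be emitted as one
#' parent feature plus one child row per structural element, linked through
#' the `Parent` attribute (see [annotation_to_features()]).
#'
#' @param records List of [genome_record()] (supplies `##sequence-region`
#'   pragmas and bounds checking).
#' @param features A data.frame with columns `seqid`, `start`, `end`,
#'   `strand`, `type`, and optionally `score`, `ID`, `Parent`, `Name`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, features, path, source = "iresscope") {
  lens <- vapply(records, function(r) nchar(r$seq), integer(1))
  names(lens) <- vapply(records, `[[`, "", "id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (id in names(lens))
    writeLines(sprintf("##sequence-region %s 1 %d", id, lens[[id]]), con)
  if (is.null(features) || nrow(features) == 0) return(invisible(path))
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    if (!f$seqid %in% names(lens))
      stop(sprintf("feature %d references unknown record '%s'", k, f$seqid))
    if (f$start < 1 || f$end > lens[[f$seqid]] || f$start > f$end)
      stop(sprintf("feature %d [%d, %d] out of bounds for record '%s' (1..%d)",
                   k, f$start, f$end, f$seqid, lens[[f$seqid]]))
    attrs <- character()
    for (a in c("ID", "Name", "Parent")) {
      if (a %in% names(features) && !is.na(f[[a]]) && nzchar(f[[a]]))
        attrs <- c(attrs, paste0(a, "=", gff3_escape(f[[a]])))
    }
    if (!length(attrs)) attrs <- "."
    score <- if ("score" %in% names(features) && !is.na(f$score))
      sprintf("%.3f", f$score) else "."
    writeLines(paste(f$seqid, source, f$type, f$start, f$end, score,
                     f$strand, ".", paste(attrs, collapse = ";"), sep = "\t"), con)
  }
  invisible(path)
}

#' Validate a GFF3 file
#'
#' A structural checker for the GFF3 subset the package writes: version
#' pragma first, nine tab-separated columns, integer 1-based inclusive
#' coordinates with start <= end, coordinates within any declared
#' `##sequence-region`, strand in `+ - . ?`, and every `Parent` attribute
#' resolving to a previously declared `ID`.
#'
#' @param path Path to a GFF3 file.
#' @return `TRUE` if valid; otherwise an error describing the first violation.
#' @export
validate_gff3 <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##gff-version 3", lines[1]))
    stop("GFF3 must start with the '##gff-version 3' pragma")
  regions <- list()
  ids <- character()
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l)) next
    if (startsWith(l, "##sequence-region")) {
      p <- strsplit(trimws(l), "[ \t]+")[[1]]
      if (length(p) != 4) stop(sprintf("line %d: malformed sequence-region", ln))
      regions[[p[2]]] <- c(as.integer(p[3]), as.integer(p[4]))
      next
    }
    if (startsWith(l, "#")) next
    cols <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9) stop(sprintf("line %d: expected 9 columns, got %d", ln, length(cols)))
    start <- suppressWarnings(as.integer(cols[4])); end <- suppressWarnings(as.integer(cols[5]))
    if (is.na(start) || is.na(end) || start < 1 || start > end)
      stop(sprintf("line %d: invalid coordinates '%s'..'%s'", ln, cols[4], cols[5]))
    if (cols[1] %in% names(regions) && end > regions[[cols[1]]][2])
      stop(sprintf("line %d: end %d beyond sequence-region bound %d", ln, end,
                   regions[[cols[1]]][2]))
    if (!cols[7] %in% c("+", "-", ".", "?"))
      stop(sprintf("line %d: invalid strand '%s'", ln, cols[7]))
    if (cols[9] != ".") {
      kv <- strsplit(strsplit(cols[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      for (p in kv) {
        if (length(p) != 2) stop(sprintf("line %d: malformed attribute", ln))
        if (p[1] == "ID") ids <- c(ids, p[2])
        if (p[1] == "Parent" && !p[2] %in% ids)
          stop(sprintf("line %d: Parent '%s' does not resolve to a prior ID", ln, p[2]))
      }
    }
  }
  TRUE
}

#' Read a plain-text list of reactive positions
#'
#' One 1-based integer coordinate per line; blank lines and `#` comments are
#' ignored. Used to feed chemical/enzymatic probing results (positions found
#' reactive, i.e. single-stranded) into [probe_concordance()].
#'
#' @param path Path to the text file.
#' @return Sorted integer vector of positions.
#' @export
read_positions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.integer(lines))
  if (anyNA(v)) stop(sprintf("non-integer coordinate in '%s'", path))
  if (any(v < 1)) stop("coordinates must be 1-based positive integers")
  sort(v)
}
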
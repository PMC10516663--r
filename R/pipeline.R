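# End-to-end orchestration: scan genomes -> dicistronic layout -> descriptor
# match -> borders, type call, toeprint prediction -> TSV/GFF3/dot-bracket
# reports. Every stage is an exported function usable on its own; outputs
# carry no timestamps, so identical inputs give byte-identical files.

#' Default scan configuration
#'
#' @param descriptor An `ires_descriptor` (default: the packaged type 6e).
#' @param min_orf_aa Minimum ORF length in codons for layout detection.
#' @param igr_min,igr_max Candidate IGR length bounds (nt).
#' @param flank Nucleotides of ORF2 retained past the provisional start for
#'   reporting (the scan itself always keeps enough sequence to cover a full
#'   descriptor placement downstream of the provisional start, which can
#'   precede the true initiation codon by almost the IRES length).
#' @param require_ygdd Require the YGDD RdRp proxy in ORF1?
#' @param score_min Match score threshold (default: descriptor's).
#' @param scan_reverse Also scan the reverse complement if the forward
#'   strand yields no layout (several TSA entries are deposited antisense).
#' @return A named list of settings.
#' @export
scan_config <- function(descriptor = default_descriptor_6e(),
                        min_orf_aa = 150L, igr_min = 100L, igr_max = 400L,
                        flank = 75L, require_ygdd = FALSE, score_min = NULL,
                        scan_reverse = FALSE) {
  list(descriptor = descriptor, min_orf_aa = as.integer(min_orf_aa),
       igr_min = as.integer(igr_min), igr_max = as.integer(igr_max),
       flank = as.integer(flank), require_ygdd = isTRUE(require_ygdd),
       score_min = score_min, scan_reverse = isTRUE(scan_reverse))
}

scan_one <- function(record, config) {
  res <- list(record_id = record$id, status = "no_layout", reason = NA_character_,
              layout = NULL, match = NULL, type_call = NULL, toeprints = NULL)
  lay <- tryCatch(map_dicistronic(record, list(min_orf_aa = config$min_orf_aa,
                                               igr_min = config$igr_min,
                                               igr_max = config$igr_max,
                                               require_ygdd = config$require_ygdd,
                                               min_genome_len = 1L)),
                  iresscope_no_layout = function(e) e, error = function(e) e)
  if (inherits(lay, "condition")) {
    res$reason <- conditionMessage(lay)
    return(res)
  }
  res$layout <- lay
  res$status <- "no_match"
  # keep enough of ORF2 to cover a full IRES downstream of the provisional
  # start plus the reporting flank
  deep_flank <- config$flank + config$descriptor$total_len_range[2]
  ext <- extract_igr(record, lay, flank_into_orf2 = deep_flank)
  matches <- match_descriptor(ext$record, config$descriptor,
                              params = list(score_min = config$score_min,
                                            window = nchar(ext$record$seq)))
  if (!length(matches)) return(res)
  best <- matches[[1]]
  best$annotation <- shift_annotation(best$annotation, ext$offset)
  best$genome_interval <- interval(best$genome_interval$start + ext$offset,
                                   best$genome_interval$end + ext$offset)
  best$record_id <- record$id
  res$match <- best
  res$layout <- assign_ires_start(lay, best$annotation$start_codon$interval$start)
  borders <- report_borders(best)
  res$type_call <- classify_type(best$annotation, borders$length_incl_codon)
  res$toeprints <- predict_toeprints(best)
  res$status <- "match"
  res
}

#' Scan genomes for IGR IRESs
#'
#' For each input genome: recognize the dicistronic layout (or record the
#' skip reason), extract the IGR, search it with the descriptor, fix the
#' ORF2 start from the best match, classify the IRES type and predict
#' toeprint windows. A genome without a layout or match is reported, not an
#' error.
#'
#' @param inputs FASTA file path(s), or a list of [genome_record()]s.
#' @param config A [scan_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `summary.tsv`, `matches.gff3` and one layered dot-bracket file per
#'   matched genome.
#' @return List with `summary` (one row per genome) and `results`
#'   (per-genome detail), invisibly when `out_dir` is set.
#' @export
run_scan <- function(inputs, config = scan_config(), out_dir = NULL) {
  records <- if (is.character(inputs)) {
    recs <- list()
    for (path in inputs) recs <- c(recs, read_fasta(path))
    recs
  } else inputs
  if (!length(records)) message("run_scan: no input records")
  results <- lapply(records, function(rec) {
    r <- scan_one(rec, config)
    if (r$status == "no_layout" && config$scan_reverse) {
      rc <- rec
      rc$seq <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(rec$seq)))
      r2 <- scan_one(rc, config)
      if (r2$status != "no_layout") {
        r2$record_id <- rec$id
        r2$strand <- "-"
        return(r2)
      }
    }
    r$strand <- "+"
    r
  })
  summary <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(record = r$record_id, status = r$status,
                      strand = r$strand,
                      orf1_start = NA_integer_, orf1_end = NA_integer_,
                      orf2_start = NA_integer_, orf2_end = NA_integer_,
                      ires_start = NA_integer_, ires_end = NA_integer_,
                      ires_len = NA_integer_, score = NA_real_,
                      delta_g = NA_real_, codon = NA_character_,
                      type = NA_character_, p_site = NA_character_,
                      reason = r$reason, stringsAsFactors = FALSE)
    if (!is.null(r$layout)) {
      row$orf1_start <- r$layout$orf1$interval$start
      row$orf1_end <- r$layout$orf1$interval$end
      row$orf2_start <- r$layout$orf2$interval$start
      row$orf2_end <- r$layout$orf2$interval$end
    }
    if (!is.null(r$match)) {
      b <- report_borders(r$match)
      row$ires_start <- b$five_prime_border
      row$ires_end <- b$three_prime_border
      row$ires_len <- b$length_incl_codon
      row$score <- round(r$match$score, 3)
      row$delta_g <- round(r$match$delta_g, 2)
      row$codon <- r$match$annotation$start_codon$triplet
      row$type <- r$type_call$type
      row$p_site <- sprintf("%d-%d", r$toeprints$p_site$start, r$toeprints$p_site$end)
    }
    row
  }))
  out <- list(summary = summary, results = results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    feats <- list()
    for (r in results) {
      if (is.null(r$match)) next
      feats[[length(feats) + 1L]] <-
        annotation_to_features(r$match$annotation, r$record_id,
                               ires_id = paste0(r$record_id, "_ires"),
                               score = r$match$score)
      rec <- records[[which(vapply(records, `[[`, "", "id") == r$record_id)[1]]]
      span <- r$match$genome_interval
      local_pairs <- data.frame(i = r$match$annotation$pairs$i - span$start + 1L,
                                j = r$match$annotation$pairs$j - span$start + 1L)
      db <- write_dotbracket(substr(rec$seq, span$start, span$end), local_pairs)
      write_dotbracket_file(db, file.path(out_dir, paste0(r$record_id, "_ires.db")),
                            id = sprintf("%s %d-%d", r$record_id, span$start, span$end))
    }
    write_gff3(records, if (length(feats)) do.call(rbind, feats) else NULL,
               file.path(out_dir, "matches.gff3"))
    message(sprintf("run_scan: %d/%d genomes matched; outputs in %s",
                    sum(summary$status == "match"), nrow(summary), out_dir))
    return(invisible(out))
  }
  out
}

#' Covariation analysis of an alignment against a reference structure
#'
#' @param alignment Aligned FASTA path or named character vector of gapped
#'   rows.
#' @param structure Dot-bracket file path (layered format), a
#'   [structure_annotation()], or a pairs data.frame in ungapped reference
#'   coordinates.
#' @param config List: `strong_frac` (default 0.85), `ref_row` (default 1).
#' @param out_dir Optional; writes `covariation.tsv` and `covariation.txt`.
#' @return List with `report` ([covariation_report()]) and `stats`
#'   ([conservation_stats()]).
#' @export
run_covary <- function(alignment, structure, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(strong_frac = 0.85, ref_row = 1), config)
  aln <- if (is.character(alignment) && length(alignment) == 1 &&
             file.exists(alignment)) read_alignment(alignment) else alignment
  pairs <- if (is.character(structure) && length(structure) == 1 &&
               file.exists(structure)) parse_dotbracket(read_dotbracket_file(structure))
           else structure
  report <- covariation_report(aln, pairs, ref_row = cfg$ref_row,
                               thresholds = list(strong_frac = cfg$strong_frac))
  stats <- conservation_stats(aln)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$per_pair, file.path(out_dir, "covariation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lines <- c(sprintf("members: %d", report$n_members),
               sprintf("thresholds: all=%d strong=%d (frac %.2f)",
                       report$thresholds$all, report$thresholds$strong,
                       report$thresholds$strong_frac),
               sprintf("invariant pairs: %d", report$invariant_pair_count),
               sprintf("strongly supported pairs (support >= %d): %d",
                       report$thresholds$strong, report$supported_pair_count),
               sprintf("fraction invariant columns: %.4f",
                       stats$fraction_invariant_columns),
               "",
               sprintf("pair %d (%d:%d): %s, support %d, identities %s",
                       report$per_pair$pair_id, report$per_pair$col_i,
                       report$per_pair$col_j, report$per_pair$class,
                       report$per_pair$support, report$per_pair$identities))
    writeLines(lines, file.path(out_dir, "covariation.txt"))
    return(invisible(list(report = report, stats = stats)))
  }
  list(report = report, stats = stats)
}
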
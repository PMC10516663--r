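# Nearest-neighbor free-energy evaluation at 37 C.
#
# The packaged parameter file carries the Turner/Mathews 1999 tables (the
# vintage behind classic mfold 3.x): helix stacks, hairpin/bulge/internal
# initiation, hairpin and internal terminal mismatches, tetraloop bonuses,
# the terminal AU penalty, the Ninio asymmetry term and the long-loop
# logarithmic extrapolation constant. The evaluator decomposes a nested
# structure into stacks, hairpins, bulges and internal loops; multibranch
# junctions and the exterior loop carry no terms, and pseudoknotted
# structures are scored as the sum of their non-crossing layers with zero
# junction penalty — the model ranks candidate placements, it does not fold.

PAIRS6 <- c("CG", "GC", "GU", "UG", "AU", "UA")

.energy_cache <- new.env(parent = emptyenv())

#' Read a nearest-neighbor parameter file
#'
#' Parses the package's whitespace-delimited parameter format with named
#' sections (`STACK`, `HAIRPIN`, `BULGE`, `INTERNAL`, `MISMATCH_HAIRPIN`,
#' `MISMATCH_INTERNAL`, `TETRALOOP`, `MISC`). Energies are kcal/mol at 37 C.
#'
#' @param path Parameter file; default is the packaged Turner 1999 set.
#' @return A list of parameter tables of class `energy_model`.
#' @export
read_energy_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "turner1999_params.txt",
                        package = "iresscope", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec_at <- grep("^SECTION ", lines)
  sec_names <- sub("^SECTION ", "", lines[sec_at])
  sections <- stats::setNames(lapply(seq_along(sec_at), function(k) {
    from <- sec_at[k] + 1
    to <- if (k < length(sec_at)) sec_at[k + 1] - 1 else length(lines)
    if (from > to) character() else lines[from:to]
  }), sec_names)
  num <- function(v) ifelse(v == "INF", Inf, suppressWarnings(as.numeric(v)))
  parse_mat6 <- function(block) {
    m <- do.call(rbind, lapply(block, function(l) num(strsplit(l, "[ \t]+")[[1]])))
    dimnames(m) <- list(PAIRS6, PAIRS6)
    m
  }
  parse_loop <- function(block) {
    v <- rep(Inf, 30)
    for (l in block) {
      p <- strsplit(l, "[ \t]+")[[1]]
      v[as.integer(p[1])] <- num(p[2])
    }
    v
  }
  parse_mismatch <- function(block) {
    out <- list()
    cur <- NULL; rows <- list()
    flush <- function() {
      if (!is.null(cur)) {
        m <- do.call(rbind, rows)
        dimnames(m) <- list(c("A", "C", "G", "U"), c("A", "C", "G", "U"))
        out[[cur]] <<- m
      }
    }
    for (l in block) {
      if (startsWith(l, "PAIR ")) {
        flush(); cur <- sub("^PAIR ", "", l); rows <- list()
      } else rows[[length(rows) + 1]] <- num(strsplit(l, "[ \t]+")[[1]])
    }
    flush()
    out
  }
  tet <- do.call(rbind, strsplit(sections$TETRALOOP, "[ \t]+"))
  misc <- do.call(rbind, strsplit(sections$MISC, "[ \t]+"))
  miscv <- stats::setNames(as.numeric(misc[, 2]), misc[, 1])
  model <- list(stack = parse_mat6(sections$STACK),
                hairpin = parse_loop(sections$HAIRPIN),
                bulge = parse_loop(sections$BULGE),
                internal = parse_loop(sections$INTERNAL),
                mismatch_hairpin = parse_mismatch(sections$MISMATCH_HAIRPIN),
                mismatch_internal = parse_mismatch(sections$MISMATCH_INTERNAL),
                tetraloop = stats::setNames(as.numeric(tet[, 2]), tet[, 1]),
                terminal_au = miscv[["TERMINAL_AU"]],
                ninio_m = miscv[["NINIO_M"]],
                ninio_max = miscv[["NINIO_MAX"]],
                lxc = miscv[["LXC"]],
                temperature = 37)
  class(model) <- "energy_model"
  model
}

default_energy_params <- function() {
  if (is.null(.energy_cache$default))
    .energy_cache$default <- read_energy_params()
  .energy_cache$default
}

loop_init <- function(tab, size, lxc) {
  if (size <= 30) tab[size] else tab[30] + lxc * log(size / 30)
}

mismatch_term <- function(tab, pair, b1, b2) {
  if (!pair %in% PAIRS6) stop(sprintf("unknown pair %s", pair))
  if (!b1 %in% c("A", "C", "G", "U") || !b2 %in% c("A", "C", "G", "U")) return(0)
  tab[[pair]][b1, b2]
}

is_au_gu <- function(pair) pair %in% c("AU", "UA", "GU", "UG")

#' Evaluate the free energy of a sequence with a given structure
#'
#' Decomposes the pair set into non-crossing layers, then each layer into
#' stacks, hairpin loops, bulges and internal loops, summing nearest-neighbor
#' terms at 37 C. Crossing layers (pseudoknots) are summed with zero
#' junction penalty; multibranch junctions and the exterior loop contribute
#' nothing. Itemized terms are returned so the total can be audited against
#' the parameter tables.
#'
#' @param seq RNA sequence (a string; T is accepted and read as U).
#' @param pairs data.frame with columns `i`, `j` (1-based, `i < j`).
#' @param params An `energy_model` (default: packaged Turner 1999 tables).
#' @return An `energy_breakdown`: list with `total` (kcal/mol) and `terms`
#'   (data.frame of `feature`, `value`).
#' @export
evaluate_structure <- function(seq, pairs, params = NULL) {
  if (is.null(params)) params <- default_energy_params()
  seq <- chartr("Tt", "Uu", toupper(seq))
  x <- strsplit(seq, "")[[1]]
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) {
    return(structure(list(total = 0,
                          terms = data.frame(feature = character(), value = numeric())),
                     class = "energy_breakdown"))
  }
  if (any(pairs$i >= pairs$j)) stop("pairs must satisfy i < j")
  if (max(pairs$j) > length(x)) stop("pair position beyond sequence end")
  pk <- pair_kind(x[pairs$i], x[pairs$j])
  if (anyNA(pk))
    stop(sprintf("non-complementary pair %d:%d (%s-%s)",
                 pairs$i[which(is.na(pk))[1]], pairs$j[which(is.na(pk))[1]],
                 x[pairs$i[which(is.na(pk))[1]]], x[pairs$j[which(is.na(pk))[1]]]))
  layer <- assign_layers(pairs)
  paired_any <- logical(length(x))
  paired_any[c(pairs$i, pairs$j)] <- TRUE
  feats <- character(); vals <- numeric()
  add <- function(f, v) { feats[length(feats) + 1L] <<- f; vals[length(vals) + 1L] <<- v }
  pr <- function(i, j) paste0(x[i], x[j])
  occupied <- function(from, to) from <= to && any(paired_any[from:to])

  eval_nested <- function(sub) {
    sub <- sub[order(sub$i), , drop = FALSE]
    # children of each pair within this non-crossing layer
    enclosing <- function(k) {
      cand <- which(sub$i < sub$i[k] & sub$j > sub$j[k])
      if (!length(cand)) return(NA_integer_)
      cand[which.max(sub$i[cand])]
    }
    parent <- vapply(seq_len(nrow(sub)), enclosing, integer(1))
    for (k in seq_len(nrow(sub))) {
      kids <- which(parent == k)
      i <- sub$i[k]; j <- sub$j[k]
      if (!length(kids)) {
        # bases enclosed here but paired in a crossing layer make this a
        # pseudoknot junction, not a hairpin: zero term by convention
        if (occupied(i + 1L, j - 1L)) next
        size <- j - i - 1L
        if (size < 3) stop(sprintf("hairpin loop of %d nt (< 3) closed by %d:%d", size, i, j))
        hex <- paste(x[i:j], collapse = "")
        if (size == 4 && hex %in% names(params$tetraloop)) {
          add(sprintf("tetraloop(%d,%d)", i, j), params$tetraloop[[hex]])
        } else {
          e <- loop_init(params$hairpin, size, params$lxc)
          if (size > 3) e <- e + mismatch_term(params$mismatch_hairpin, pr(i, j),
                                              x[i + 1], x[j - 1])
          else if (is_au_gu(pr(i, j))) e <- e + params$terminal_au
          add(sprintf("hairpin(%d,%d)", i, j), e)
        }
      } else if (length(kids) == 1L) {
        k2 <- kids
        ii <- sub$i[k2]; jj <- sub$j[k2]
        n1 <- ii - i - 1L; n2 <- j - jj - 1L
        inner_rev <- pr(jj, ii)
        if ((n1 > 0L && occupied(i + 1L, ii - 1L)) ||
            (n2 > 0L && occupied(jj + 1L, j - 1L))) next  # crossing-layer junction
        if (n1 == 0L && n2 == 0L) {
          add(sprintf("stack(%d,%d)", i, j), params$stack[pr(i, j), inner_rev])
        } else if (n1 == 0L || n2 == 0L) {
          b <- n1 + n2
          e <- loop_init(params$bulge, b, params$lxc)
          if (b == 1L) {
            e <- e + params$stack[pr(i, j), inner_rev]
          } else {
            if (is_au_gu(pr(i, j))) e <- e + params$terminal_au
            if (is_au_gu(pr(ii, jj))) e <- e + params$terminal_au
          }
          add(sprintf("bulge(%d,%d)", i, j), e)
        } else {
          size <- n1 + n2
          e <- loop_init(params$internal, size, params$lxc) +
            min(params$ninio_max, params$ninio_m * abs(n1 - n2)) +
            mismatch_term(params$mismatch_internal, pr(i, j), x[i + 1], x[j - 1]) +
            mismatch_term(params$mismatch_internal, inner_rev, x[jj + 1], x[ii - 1])
          add(sprintf("internal(%d,%d)", i, j), e)
        }
      }
      # >= 2 children: multibranch junction, no term in this model
    }
  }
  for (l in unique(layer)) eval_nested(pairs[layer == l, , drop = FALSE])
  structure(list(total = sum(vals), terms = data.frame(feature = feats, value = vals)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  if (nrow(x$terms))
    cat(paste(sprintf("  %-18s %8.2f", x$terms$feature, x$terms$value), collapse = "\n"), "\n")
  cat(sprintf("total %8.2f kcal/mol\n", x$total))
  invisible(x)
}

#' Rank matches by score and free energy
#'
#' Stable sort with the descriptor engine's tie-break: score descending,
#' then lower (more stable) deltaG, then 5'-most, then shortest.
#'
#' @param matches List of `ires_match` objects.
#' @return The reordered list.
#' @export
rank_matches <- function(matches) {
  matches[match_order(matches)]
}
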
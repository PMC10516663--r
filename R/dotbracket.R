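BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

#' Assign base pairs to non-crossing layers
#'
#' Pairs are processed in ascending order of opening position; each pair goes
#' to the lowest-index layer in which it crosses no pair already assigned
#' there. For the pseudoknot topologies handled by the descriptor engine this
#' greedy rule attains the minimal number of layers (never more than three).
#'
#' @param pairs data.frame with integer columns `i`, `j` (`i < j`).
#' @return Integer vector of layer indices (1-based), one per pair row.
#' @export
assign_layers <- function(pairs) {
  if (!nrow(pairs)) return(integer())
  if (any(pairs$i >= pairs$j)) stop("pairs must satisfy i < j")
  pos <- c(pairs$i, pairs$j)
  if (anyDuplicated(pos))
    stop(sprintf("position %d participates in two pairs", pos[duplicated(pos)][1]))
  ord <- order(pairs$i)
  layer <- integer(nrow(pairs))
  for (k in ord) {
    l <- 1L
    repeat {
      members <- which(layer == l)
      if (!length(members) ||
          !any(pairs_cross(pairs$i[k], pairs$j[k], pairs$i[members], pairs$j[members]))) {
        layer[k] <- l
        break
      }
      l <- l + 1L
    }
  }
  layer
}

#' Serialize a structure as layered dot-bracket text
#'
#' Crossing pair sets (pseudoknots) cannot be drawn with one balanced bracket
#' string, so the structure is split into non-crossing layers
#' ([assign_layers()]) and one bracket line is emitted per layer, using the
#' bracket alphabets `()`, `[]`, `{}`, `<>` in layer order.
#'
#' @param seq Nucleotide sequence the structure annotates.
#' @param pairs data.frame with columns `i`, `j` (1-based positions, `i < j`).
#' @return Object of class `layered_dotbracket`: list with `sequence` and
#'   `layers` (character vector of bracket strings of equal length).
#' @export
write_dotbracket <- function(seq, pairs) {
  n <- nchar(seq)
  if (nrow(pairs) && (min(pairs$i) < 1 || max(pairs$j) > n))
    stop("pair positions outside sequence")
  layer <- assign_layers(pairs)
  n_layers <- if (length(layer)) max(layer) else 1L
  if (n_layers > length(BRACKET_OPEN))
    stop(sprintf("structure needs %d layers; only %d bracket alphabets available",
                 n_layers, length(BRACKET_OPEN)))
  layers <- vapply(seq_len(n_layers), function(l) {
    chars <- rep(".", n)
    sel <- which(layer == l)
    chars[pairs$i[sel]] <- BRACKET_OPEN[l]
    chars[pairs$j[sel]] <- BRACKET_CLOSE[l]
    paste(chars, collapse = "")
  }, character(1))
  structure(list(sequence = seq, layers = layers), class = "layered_dotbracket")
}

#' @export
print.layered_dotbracket <- function(x, ...) {
  cat(x$sequence, "\n")
  for (l in x$layers) cat(l, "\n")
  invisible(x)
}

#' Parse layered dot-bracket text back into a pair set
#'
#' Inverse of [write_dotbracket()]: each layer must be an individually
#' balanced bracket string; layers may cross each other.
#'
#' @param db A `layered_dotbracket` object, or a character vector of bracket
#'   strings.
#' @return data.frame with columns `i`, `j` sorted by `i`.
#' @export
parse_dotbracket <- function(db) {
  layers <- if (inherits(db, "layered_dotbracket")) db$layers else db
  out_i <- integer(); out_j <- integer()
  for (l in seq_along(layers)) {
    chars <- strsplit(layers[l], "")[[1]]
    stack <- integer()
    for (p in seq_along(chars)) {
      ch <- chars[p]
      if (ch %in% BRACKET_OPEN) {
        stack <- c(stack, p)
      } else if (ch %in% BRACKET_CLOSE) {
        if (!length(stack)) stop(sprintf("layer %d: unbalanced close at %d", l, p))
        out_i <- c(out_i, stack[length(stack)]); out_j <- c(out_j, p)
        stack <- stack[-length(stack)]
      } else if (ch != ".") {
        stop(sprintf("layer %d: unexpected character '%s'", l, ch))
      }
    }
    if (length(stack)) stop(sprintf("layer %d: unbalanced open at %d", l, stack[1]))
  }
  df <- data.frame(i = out_i, j = out_j)
  df[order(df$i), , drop = FALSE]
}

#' Write a layered dot-bracket object to a file
#' @param db A `layered_dotbracket` object.
#' @param path Output path.
#' @param id Optional FASTA-style header line.
#' @return `path`, invisibly.
#' @export
write_dotbracket_file <- function(db, path, id = NULL) {
  lines <- c(if (!is.null(id)) paste0(">", id), db$sequence, db$layers)
  writeLines(lines, path)
  invisible(path)
}

#' Read a layered dot-bracket file
#' @param path Path written by [write_dotbracket_file()].
#' @return A `layered_dotbracket` object.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2) stop("dot-bracket file needs a sequence line and at least one layer")
  if (any(nchar(lines) != nchar(lines[1])))
    stop("sequence and layer lines must have equal length")
  structure(list(sequence = lines[1], layers = lines[-1]),
            class = "layered_dotbracket")
}
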
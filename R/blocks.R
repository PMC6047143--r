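# data.frame construction without deparse/checks; hot-path helper
fast_df <- function(cols) {
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

#' Alignment block
#'
#' An `alignment_block` is one gapped multiple sequence alignment over a
#' subset of taxa: the unit read from MAF or aligned FASTA and the unit of
#' filtering and concatenation. Rows are equal-length character strings over
#' the alphabet `A,C,G,T,N,-,?` (lower case is upper-cased on read).
#'
#' @param rows named character vector, one aligned sequence per taxon; names
#'   are the taxon identifiers.
#' @param block_id text label for the block.
#' @param source provenance string (file and block index), free text.
#' @param check_gap_rows reject rows consisting purely of `-`? Readers always
#'   check; the simulator's block splitter may legitimately produce such rows
#'   and disables the check.
#' @return An object of class `alignment_block` with fields `block_id`,
#'   `taxa`, `rows`, `source`.
#' @export
alignment_block <- function(rows, block_id = "block", source = "",
                            check_gap_rows = TRUE) {
  if (length(rows) == 0L) stop("alignment block must contain at least one row")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("all rows must be named by taxon")
  if (anyDuplicated(names(rows)))
    stop("duplicate taxon identifier in block '", block_id, "': ",
         names(rows)[duplicated(names(rows))][1L])
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("rows of unequal length in block '", block_id, "' (taxon '",
         names(rows)[which(widths != widths[1L])[1L]], "')")
  if (widths[1L] < 1L) stop("zero-length alignment block '", block_id, "'")
  bad <- grepl("[^ACGTN?-]", rows)
  if (any(bad))
    stop("invalid character in block '", block_id, "', taxon '",
         names(rows)[bad][1L], "'")
  if (check_gap_rows) {
    pure <- !grepl("[^-]", rows)
    if (any(pure))
      stop("row of pure gap characters in block '", block_id, "', taxon '",
           names(rows)[pure][1L], "'")
  }
  structure(
    list(block_id = block_id, taxa = names(rows), rows = rows,
         source = source),
    class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block> ", x$block_id, ": ", length(x$taxa), " taxa x ",
      block_width(x), " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns in a block
#' @param block an `alignment_block`.
#' @export
block_width <- function(block) unname(nchar(block$rows[[1L]]))

#' Concatenated alignment
#'
#' Joins alignment blocks column-wise over a common taxon universe. Taxa
#' absent from a member block are padded with `?` (missing data) across that
#' block's columns. Block boundaries are recorded as 0-based half-open column
#' intervals and act as hard breaks for indel detection: a gap run never
#' spans two source blocks.
#'
#' @param blocks list of `alignment_block`.
#' @param taxon_universe optional character vector fixing taxon order;
#'   defaults to the union of block taxa in first-seen order. Every taxon
#'   occurring in a block must be in the universe.
#' @return An object of class `concat_alignment` with fields `taxa`, `rows`,
#'   `block_starts` (0-based column offset of each block), `block_ids`.
#' @export
concatenate_blocks <- function(blocks, taxon_universe = NULL) {
  if (length(blocks) == 0L) stop("no blocks to concatenate")
  seen <- unlist(lapply(blocks, function(b) b$taxa), use.names = FALSE)
  if (is.null(taxon_universe)) {
    taxon_universe <- unique(seen)
  } else {
    extra <- setdiff(unique(seen), taxon_universe)
    if (length(extra))
      stop("taxon not in supplied universe: ", paste(extra, collapse = ", "))
  }
  widths <- vapply(blocks, block_width, integer(1L))
  pieces <- lapply(blocks, function(b) {
    out <- vapply(taxon_universe, function(tx) {
      if (tx %in% b$taxa) unname(b$rows[[tx]])
      else strrep("?", block_width(b))
    }, character(1L))
    out
  })
  rows <- do.call(paste0, c(pieces, list(collapse = NULL)))
  names(rows) <- taxon_universe
  structure(
    list(taxa = taxon_universe, rows = rows,
         block_starts = cumsum(c(0L, widths[-length(widths)])),
         block_widths = widths,
         block_ids = vapply(blocks, function(b) b$block_id, character(1L))),
    class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat("<concat_alignment> ", length(x$taxa), " taxa x ",
      nchar(x$rows[[1L]]), " columns in ", length(x$block_ids),
      " blocks\n", sep = "")
  invisible(x)
}

#' Extract one member block of a concatenated alignment
#'
#' Returns block `i` as an `alignment_block` over the full taxon universe
#' (rows of absent taxa are all `?`). Used internally so that splid
#' extraction treats block boundaries as hard breaks.
#'
#' @param concat a `concat_alignment`.
#' @param i block index (1-based).
#' @keywords internal
concat_block_slice <- function(concat, i) {
  from <- concat$block_starts[i] + 1L
  to <- concat$block_starts[i] + concat$block_widths[i]
  rows <- substr(concat$rows, from, to)
  names(rows) <- concat$taxa
  alignment_block(rows, block_id = concat$block_ids[i],
                  source = sprintf("concat[%d]", i), check_gap_rows = FALSE)
}
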
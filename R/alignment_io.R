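#' Read an aligned FASTA file as one alignment block
#'
#' All records must have identical length (it is an alignment, not a
#' sequence set). Identifiers are taken from the header line up to the first
#' whitespace; sequence characters are upper-cased.
#'
#' @param path path to an aligned FASTA file.
#' @param block_id label for the resulting block; defaults to the file name.
#' @return an [alignment_block()].
#' @export
read_fasta_alignment <- function(path, block_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate identifier in ", path, ": ", ids[duplicated(ids)][1L])
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("unequal sequence lengths in ", path, " (record '",
         ids[which(w != w[1L])[1L]], "'): not an alignment")
  rows <- as.character(seqs)
  names(rows) <- ids
  alignment_block(rows, block_id = block_id, source = path)
}

#' Write an alignment (block or concatenation) as aligned FASTA
#'
#' @param x an `alignment_block` or `concat_alignment`.
#' @param path output file path.
#' @export
write_fasta_alignment <- function(x, path) {
  seqs <- Biostrings::BStringSet(x$rows)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a MAF (Multiple Alignment Format) file
#'
#' Parses the UCSC MAF dialect: paragraphs opened by an `a` line, sequence
#' rows on `s` lines; `i`, `e`, `q` and comment lines are ignored. The taxon
#' identifier is the `s`-line source name truncated at the first `.` (the
#' species part of `species.chromosome`) unless `split_names = FALSE`.
#' Alignment text is stored as-is: MAF alignment text is already in
#' alignment orientation regardless of the strand field, which is recorded
#' only in the block's provenance.
#'
#' Duplicate species within one paragraph: the first row is kept and a
#' warning is issued.
#'
#' @param path path to a MAF file.
#' @param split_names truncate source names at the first `.`?
#' @return list of [alignment_block()], in file order.
#' @export
read_maf <- function(path, split_names = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur_names <- character()
  cur_rows <- character()
  nblock <- 0L
  flush <- function() {
    if (length(cur_rows) == 0L) return()
    nblock <<- nblock + 1L
    keep <- !duplicated(cur_names)
    if (any(!keep))
      warning("duplicate species '", cur_names[!keep][1L],
              "' in MAF block ", nblock, "; keeping first row")
    rows <- cur_rows[keep]
    names(rows) <- cur_names[keep]
    blocks[[nblock]] <<- alignment_block(
      rows, block_id = sprintf("maf_block_%d", nblock),
      source = sprintf("%s#%d", path, nblock))
  }
  for (ln in lines) {
    if (grepl("^a($|\\s)", ln)) {
      flush()
      cur_names <- character(); cur_rows <- character()
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 7L) stop("malformed 's' line in ", path, ": ", ln)
      nm <- if (split_names) sub("\\..*$", "", f[2L]) else f[2L]
      cur_names <- c(cur_names, nm)
      cur_rows <- c(cur_rows, f[7L])
    }
    # 'i', 'e', 'q', '#' and blank lines: ignored
  }
  flush()
  if (nblock == 0L) stop("no alignment blocks found in ", path)
  blocks
}

#' Mask terminal gaps as missing data
#'
#' Gaps at the 5' and 3' ends of a row are alignment artifacts rather than
#' evidence of deletion: every `-` in the maximal leading and trailing gap
#' run of each row is replaced by `?`. Interior gaps are untouched. The
#' operation is idempotent.
#'
#' @param block an `alignment_block`.
#' @return the masked `alignment_block`.
#' @export
mask_terminal_gaps <- function(block) {
  rows <- block$rows
  lead <- regmatches(rows, regexpr("^-+", rows))
  rows <- sub("^-+", "", rows)
  pads_l <- strrep("?", nchar(block$rows) - nchar(rows))
  trail_n <- nchar(rows) - nchar(sub("-+$", "", rows))
  rows <- sub("-+$", "", rows)
  rows <- paste0(pads_l, rows, strrep("?", trail_n))
  names(rows) <- block$taxa
  alignment_block(rows, block_id = block$block_id, source = block$source,
                  check_gap_rows = FALSE)
}

#' Filter alignment blocks before concatenation
#'
#' Keeps blocks with sequence information for at least `min_taxa` taxa and
#' (if `require_gap`) at least one interior gap character. When
#' `mask_first = TRUE` terminal-gap masking is applied before the gap count,
#' so blocks whose only gaps are terminal are dropped.
#'
#' @param blocks list of `alignment_block`.
#' @param min_taxa minimum number of rows (default 2).
#' @param require_gap require at least one `-` after masking (default TRUE).
#' @param mask_first apply [mask_terminal_gaps()] before counting (default
#'   TRUE); the masked blocks are returned.
#' @return filtered (and possibly masked) list of blocks, order preserved.
#' @export
filter_blocks <- function(blocks, min_taxa = 2L, require_gap = TRUE,
                          mask_first = TRUE) {
  if (length(blocks) == 0L) return(list())
  if (mask_first) blocks <- lapply(blocks, mask_terminal_gaps)
  keep <- vapply(blocks, function(b) {
    length(b$taxa) >= min_taxa &&
      (!require_gap || any(grepl("-", b$rows, fixed = TRUE)))
  }, logical(1L))
  blocks[keep]
}
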
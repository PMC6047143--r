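#' Build a binary character matrix from splids
#'
#' One column per splid, symbols `0` (absence), `1` (presence), `?`
#' (missing). Column order follows splid order (block index, then start
#' column).
#'
#' @param splids list of `splid` objects sharing one taxon universe.
#' @param taxa ordered taxon universe.
#' @return a `binary_matrix`: character matrix (taxa x characters) with a
#'   `characters` attribute (data.frame of per-splid provenance: block,
#'   1-based start/end, size).
#' @export
build_matrix <- function(splids, taxa) {
  cells <- matrix(character(), nrow = length(taxa), ncol = length(splids),
                  dimnames = list(taxa, NULL))
  for (j in seq_along(splids)) {
    sym <- splids[[j]]$symbols
    if (!setequal(names(sym), taxa))
      stop("splid ", j, " codes a different taxon universe")
    cells[, j] <- sym[taxa]
  }
  chars <- data.frame(
    block = vapply(splids, `[[`, character(1L), "block_id"),
    start = vapply(splids, function(s) s$start + 1L, integer(1L)),
    end = vapply(splids, `[[`, integer(1L), "end"),
    size = vapply(splids, `[[`, integer(1L), "size"),
    stringsAsFactors = FALSE)
  structure(cells, characters = chars, class = c("binary_matrix", "matrix"))
}

new_binary_matrix <- function(cells, chars = NULL) {
  if (is.null(chars)) {
    k <- ncol(cells)
    chars <- data.frame(block = rep(NA_character_, k),
                        start = rep(NA_integer_, k),
                        end = rep(NA_integer_, k),
                        size = rep(NA_integer_, k))
  }
  structure(cells, characters = chars, class = c("binary_matrix", "matrix"))
}

#' Remove invariant splid characters
#'
#' Ascertainment-bias correction presupposes that every character is
#' variable, so columns whose non-`?` cells are all identical (or all
#' missing) must be dropped before likelihood analysis.
#'
#' @param m a `binary_matrix`.
#' @return the filtered `binary_matrix`; the number of removed columns is
#'   available as `attr(, "n_removed")`.
#' @export
drop_invariant <- function(m) {
  keep <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    length(unique(v[v != "?"])) >= 2L
  }, logical(1L))
  out <- new_binary_matrix(m[, keep, drop = FALSE],
                           attr(m, "characters")[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

phylip_name <- function(x, truncate = FALSE) {
  x <- gsub("[[:space:]]+", "_", x)
  if (truncate) x <- substr(x, 1L, 10L)
  x
}

#' Write a binary matrix in FASTA, PHYLIP or NEXUS format
#'
#' FASTA: one record of `0/1/?` symbols per taxon. PHYLIP: relaxed format
#' (full names, single space separator) with an `ntaxa nchar` header;
#' strict 10-character name truncation is available via `truncate_names`.
#' NEXUS: a DATA block with `FORMAT DATATYPE=STANDARD SYMBOLS="01"
#' MISSING=? GAP=-;` plus a comment listing each character's source block
#' and 1-based coordinates.
#'
#' @param m a `binary_matrix`.
#' @param path output file.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @param truncate_names truncate PHYLIP names to 10 characters?
#' @export
write_matrix <- function(m, path, format = c("fasta", "phylip", "nexus"),
                         truncate_names = FALSE) {
  format <- match.arg(format)
  taxa <- rownames(m)
  seqs <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) seqs <- setNames(rep("", length(taxa)), taxa)
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", taxa), seqs)),
    phylip = {
      nm <- phylip_name(taxa, truncate_names)
      if (anyDuplicated(nm))
        stop("PHYLIP name collision after sanitization: ",
             nm[duplicated(nm)][1L])
      c(paste(length(taxa), ncol(m)), paste(nm, seqs))
    },
    nexus = {
      chars <- attr(m, "characters")
      prov <- if (!is.null(chars) && nrow(chars) && !all(is.na(chars$block)))
        c("[Character provenance (1-based columns):",
          sprintf("  char %d = %s:%d-%d (size %d)", seq_len(nrow(chars)),
                  chars$block, chars$start, chars$end, chars$size),
          "]")
      else character()
      c("#NEXUS",
        "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), ncol(m)),
        "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
        "  MATRIX",
        paste0("    ", phylip_name(taxa), " ", seqs),
        "  ;",
        "END;",
        prov)
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read back a binary matrix written by [write_matrix()]
#'
#' Round-trip reader for the three output formats; used for verification
#' and for feeding matrices into downstream tools.
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return a `binary_matrix` (without provenance for PHYLIP/FASTA).
#' @export
read_matrix <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  to_cells <- function(taxa, seqs) {
    nch <- unique(nchar(seqs))
    if (length(nch) > 1L) stop("ragged matrix in ", path)
    cells <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                    nrow = length(taxa), byrow = TRUE,
                    dimnames = list(taxa, NULL))
    new_binary_matrix(cells)
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    return(to_cells(sub("\\s.*$", "", names(seqs)), as.character(seqs)))
  }
  if (format == "phylip") {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    body <- strsplit(trimws(lines[-1L][nzchar(trimws(lines[-1L]))]), "\\s+")
    taxa <- vapply(body, `[`, character(1L), 1L)
    seqs <- vapply(body, function(f)
      if (length(f) > 1L) paste(f[-1L], collapse = "") else "", character(1L))
    m <- to_cells(taxa, seqs)
    if (nrow(m) != hdr[1L] || ncol(m) != hdr[2L])
      stop("PHYLIP header disagrees with matrix in ", path)
    return(m)
  }
  # NEXUS via ape, falling back symbols as-is
  dat <- ape::read.nexus.data(path)
  to_cells(names(dat), vapply(dat, paste, character(1L), collapse = ""))
}

#' Write the splid summary report
#'
#' Tab-separated report with totals, the splid-size histogram, per-block
#' counts, and one row per splid (block, 1-based start/end, size, and the
#' presence/absence/missing taxon lists).
#'
#' @param stats a `splid_stats` object from [extract_splids()].
#' @param path output file.
#' @export
write_summary <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w("# splid summary")
  w("total_splids", stats$n_splids)
  w("total_loci", stats$n_loci)
  w("mode", stats$config$mode)
  w("min_size", stats$config$min_size)
  w("max_size", ifelse(is.finite(stats$config$max_size),
                       stats$config$max_size, "unbounded"))
  w("")
  w("# size histogram")
  w("size", "count")
  for (s in names(stats$per_size)) w(s, stats$per_size[[s]])
  w("")
  w("# per-block counts")
  w("block", "count")
  for (b in names(stats$per_block)) w(b, stats$per_block[[b]])
  w("")
  w("# splids")
  w("block", "start", "end", "size", "presence", "absence", "missing")
  tab <- stats$splid_table
  for (i in seq_len(nrow(tab)))
    w(tab$block[i], tab$start[i], tab$end[i], tab$size[i],
      tab$presence[i], tab$absence[i], tab$missing[i])
  invisible(path)
}
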
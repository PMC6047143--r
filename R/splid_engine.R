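#' Splid extraction configuration
#'
#' @param min_size minimum indel size (columns) for a splid; default 2,
#'   following the convention that single-residue indels are too noisy.
#' @param max_size maximum indel size; default unbounded (`Inf`).
#' @param mode `"strict"` additionally discards splids that overlap a
#'   single-residue indel shared by two or more taxa; `"fuzzy"` retains
#'   them. Strict is the default and the mode used for all headline
#'   analyses.
#' @return a `splid_config` object.
#' @export
splid_config <- function(min_size = 2L, max_size = Inf,
                         mode = c("strict", "fuzzy")) {
  mode <- match.arg(mode)
  if (min_size < 1L) stop("min_size must be >= 1")
  if (min_size > max_size) stop("min_size must be <= max_size")
  structure(list(min_size = as.integer(min_size), max_size = max_size,
                 mode = mode), class = "splid_config")
}

#' Find maximal gap runs in an alignment block
#'
#' A gap run is a maximal stretch of `-` in one row, delimited by residues,
#' row boundaries, or `?` (missing data cannot extend a gap run).
#'
#' @param block an `alignment_block`.
#' @return data.frame with columns `taxon`, `start`, `end` (0-based,
#'   half-open column interval), sorted by (start, taxon).
#' @export
find_gap_runs <- function(block) {
  m <- gregexpr("-+", block$rows)
  hit <- vapply(m, function(x) x[1L] != -1L, logical(1L))
  starts <- lapply(m[hit], as.integer)
  lens <- lapply(m[hit], attr, "match.length")
  n <- lengths(starts)
  st <- unlist(starts, use.names = FALSE)
  df <- fast_df(list(
    taxon = rep(block$taxa[hit], n),
    start = st - 1L,
    end = st - 1L + unlist(lens, use.names = FALSE)))
  if (nrow(df) == 0L)
    return(fast_df(list(taxon = character(), start = integer(),
                        end = integer())))
  df <- df[order(df$start, df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Group gap runs with identical boundaries into indels
#'
#' Runs sharing the exact (start, end) column pair in two or more rows are
#' taken as one homologous indel; runs overlapping only partially are
#' distinct indels.
#'
#' @param runs data.frame from [find_gap_runs()].
#' @return data.frame with columns `start`, `end`, `size` and a list column
#'   `taxa`, sorted by (start, end).
#' @export
group_indels <- function(runs) {
  if (nrow(runs) == 0L)
    return(fast_df(list(start = integer(), end = integer(),
                        size = integer(), taxa = list())))
  key <- paste(runs$start, runs$end)
  idx <- split(seq_len(nrow(runs)), key)
  first <- vapply(idx, `[`, integer(1L), 1L)
  out <- fast_df(list(
    start = runs$start[first], end = runs$end[first],
    size = runs$end[first] - runs$start[first],
    taxa = lapply(idx, function(i) runs$taxon[i])))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain overlapping indels into indel loci
#'
#' Two indels overlap when they share at least one alignment column
#' (half-open intervals: abutting indels do not overlap). Loci are the
#' connected components of the overlap graph; indels in different loci are
#' independent and processed separately.
#'
#' @param indels data.frame from [group_indels()].
#' @return the same data.frame with an integer `locus` column; loci numbered
#'   by span start.
#' @export
find_loci <- function(indels) {
  if (nrow(indels) == 0L) {
    indels$locus <- integer()
    return(indels)
  }
  # sorted by start: a new locus begins when start >= furthest end so far
  s <- indels$start
  cme <- cummax(indels$end)
  indels$locus <- cumsum(c(TRUE, s[-1L] >= cme[-length(cme)]))
  indels
}

#' Select candidate splids (rule 1)
#'
#' Keeps indels present in at least two taxa with size within the
#' configured bounds.
#'
#' @param indels data.frame of indels (one locus or a whole block).
#' @param config a [splid_config()].
#' @return the qualifying subset.
#' @export
candidate_splids <- function(indels, config = splid_config()) {
  keep <- lengths(indels$taxa) >= 2L &
    indels$size >= config$min_size & indels$size <= config$max_size
  out <- indels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop mutually overlapping candidates (rule 2)
#'
#' A splid may not overlap another indel that itself satisfies rule 1:
#' every candidate sharing at least one column with another candidate is
#' removed (neither is preferred). Candidates overlapping only
#' non-candidate indels survive.
#'
#' @param candidates data.frame of rule-1 candidates.
#' @return the surviving subset.
#' @export
exclude_mutual_overlaps <- function(candidates) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  drop <- logical(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (candidates$start[i] < candidates$end[j] &&
        candidates$start[j] < candidates$end[i]) {
      drop[i] <- TRUE; drop[j] <- TRUE
    }
  }
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strict-mode single-residue filter (rule 3, strict)
#'
#' In strict mode a candidate overlapping a single-residue indel that is
#' shared by two or more taxa is discarded: independent single-position
#' gaps arise too randomly to trust the boundary evidence. In fuzzy mode
#' this is the identity.
#'
#' @param candidates data.frame of candidates that passed rules 1-2.
#' @param indels all indels of the same block/locus (the size-1 triggers are
#'   looked up here).
#' @param mode `"strict"` or `"fuzzy"`.
#' @return the surviving subset.
#' @export
strict_filter <- function(candidates, indels, mode = "strict") {
  if (mode != "strict" || nrow(candidates) == 0L) return(candidates)
  trig <- indels[indels$size == 1L & lengths(indels$taxa) >= 2L, ,
                 drop = FALSE]
  if (nrow(trig) == 0L) return(candidates)
  drop <- vapply(seq_len(nrow(candidates)), function(i) {
    any(candidates$start[i] < trig$end & trig$start < candidates$end[i])
  }, logical(1L))
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Code an accepted splid as a binary character
#'
#' Per taxon of the universe: `1` if the taxon has a gap run with exactly
#' the splid's boundaries; `0` if all its characters across the splid's
#' columns are residues (`A/C/G/T/N`; an unresolved residue still shows the
#' sequence is present); `?` if the taxon is absent from the block, carries
#' `?` in those columns, or has gap characters there whose run boundaries
#' differ from the splid's (the inapplicable state of simple indel coding).
#'
#' @param start,end 0-based half-open column interval of the splid.
#' @param block the `alignment_block` the splid was found in.
#' @param taxon_universe ordered character vector of all taxa to code.
#' @return named character vector over `{"0","1","?"}`.
#' @export
code_splid <- function(start, end, block, taxon_universe) {
  w <- block_width(block)
  sym <- vapply(taxon_universe, function(tx) {
    if (!tx %in% block$taxa) return("?")
    row <- block$rows[[tx]]
    seg <- substr(row, start + 1L, end)
    if (grepl("?", seg, fixed = TRUE)) return("?")
    if (!grepl("-", seg, fixed = TRUE)) return("0")
    if (grepl("[^-]", seg)) return("?")          # partial gap overlap
    left_ok <- start == 0L || substr(row, start, start) != "-"
    right_ok <- end == w || substr(row, end + 1L, end + 1L) != "-"
    if (left_ok && right_ok) "1" else "?"        # run extends past boundary
  }, character(1L))
  names(sym) <- taxon_universe
  sym
}

extract_block_splids <- function(block, config, taxon_universe,
                                 block_index = 1L) {
  runs <- find_gap_runs(block)
  indels <- find_loci(group_indels(runs))
  n_loci <- if (nrow(indels)) max(indels$locus) else 0L
  cand <- candidate_splids(indels, config)
  cand <- exclude_mutual_overlaps(cand)
  cand <- strict_filter(cand, indels, config$mode)
  splids <- lapply(seq_len(nrow(cand)), function(i) {
    sym <- code_splid(cand$start[i], cand$end[i], block, taxon_universe)
    structure(
      list(block_id = block$block_id, block_index = block_index,
           start = cand$start[i], end = cand$end[i], size = cand$size[i],
           presence = names(sym)[sym == "1"],
           absence = names(sym)[sym == "0"],
           missing = names(sym)[sym == "?"],
           symbols = sym),
      class = "splid")
  })
  list(splids = splids, n_loci = n_loci)
}

#' @export
print.splid <- function(x, ...) {
  cat(sprintf("<splid> %s cols %d-%d (size %d): present {%s} absent {%s} missing {%s}\n",
              x$block_id, x$start + 1L, x$end, x$size,
              paste(x$presence, collapse = ","),
              paste(x$absence, collapse = ","),
              paste(x$missing, collapse = ",")))
  invisible(x)
}

#' Extract split-inducing indels from an alignment
#'
#' Runs the full pipeline per block: gap-run detection, endpoint grouping
#' into indels, locus chaining, the size/taxon-count rule, mutual-overlap
#' exclusion, the optional strict single-residue filter, and binary coding
#' with missing data. For a concatenated alignment each member block is
#' processed separately, so gap runs never cross a block boundary.
#'
#' @param x an `alignment_block` or `concat_alignment`.
#' @param config a [splid_config()].
#' @param taxon_universe taxa to code; defaults to the taxa of `x`.
#' @return list with `splids` (list of `splid` objects ordered by block
#'   index then start column) and `stats` (a `splid_stats` object, see
#'   [write_summary()]).
#' @export
extract_splids <- function(x, config = splid_config(),
                           taxon_universe = NULL) {
  if (is.null(taxon_universe)) taxon_universe <- x$taxa
  if (inherits(x, "alignment_block")) {
    blocks <- list(x)
  } else if (inherits(x, "concat_alignment")) {
    blocks <- lapply(seq_along(x$block_ids),
                     function(i) concat_block_slice(x, i))
  } else stop("x must be an alignment_block or concat_alignment")
  res <- lapply(seq_along(blocks), function(i)
    extract_block_splids(blocks[[i]], config, taxon_universe, i))
  splids <- do.call(c, lapply(res, `[[`, "splids"))
  if (is.null(splids)) splids <- list()
  stats <- splid_stats(splids, n_loci = sum(vapply(res, `[[`, integer(1L),
                                                   "n_loci")),
                       block_ids = vapply(blocks, function(b) b$block_id,
                                          character(1L)),
                       config = config)
  list(splids = splids, stats = stats)
}

splid_stats <- function(splids, n_loci, block_ids, config) {
  tab <- fast_df(list(
    block = vapply(splids, `[[`, character(1L), "block_id"),
    start = vapply(splids, function(s) s$start + 1L, integer(1L)),
    end = vapply(splids, `[[`, integer(1L), "end"),  # 1-based inclusive end
    size = vapply(splids, `[[`, integer(1L), "size"),
    presence = vapply(splids, function(s) paste(s$presence, collapse = ","),
                      character(1L)),
    absence = vapply(splids, function(s) paste(s$absence, collapse = ","),
                     character(1L)),
    missing = vapply(splids, function(s) paste(s$missing, collapse = ","),
                     character(1L))))
  us <- sort(unique(tab$size))
  per_size <- stats::setNames(tabulate(match(tab$size, us), length(us)), us)
  per_block <- stats::setNames(
    tabulate(match(tab$block, block_ids), length(block_ids)), block_ids)
  structure(list(n_splids = length(splids), n_loci = n_loci,
                 per_size = per_size, per_block = per_block,
                 splid_table = tab, config = config),
            class = "splid_stats")
}

#' @export
print.splid_stats <- function(x, ...) {
  cat("<splid_stats>", x$n_splids, "splids from", x$n_loci, "indel loci (mode",
      paste0(x$config$mode, ", min size ", x$config$min_size, ")\n"))
  invisible(x)
}
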
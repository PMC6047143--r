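# Independent oracles. These deliberately share no code with the package:
# the splid oracle scans columns with a per-row state machine (the engine
# uses regex run detection and interval tables), and the quartet oracle
# compares pruned 4-leaf topologies via ape (the engine classifies
# quadruples against split membership matrices).

# literal rules 1-3 by exhaustive column scanning; returns (start, end,
# coded pattern) rows sorted by start
oracle_extract <- function(block, min_size, max_size, mode) {
  mat <- do.call(rbind, strsplit(unname(block$rows), "", fixed = TRUE))
  w <- ncol(mat)
  taxa <- block$taxa
  keys <- character()
  ktaxa <- list()
  for (ti in seq_along(taxa)) {
    s <- NA_integer_
    for (j in seq_len(w + 1L)) {
      ch <- if (j <= w) mat[ti, j] else "X"
      if (ch == "-") {
        if (is.na(s)) s <- j
      } else if (!is.na(s)) {
        key <- paste(s - 1L, j - 1L)
        i <- match(key, keys)
        if (is.na(i)) {
          keys <- c(keys, key)
          ktaxa <- c(ktaxa, list(taxa[ti]))
        } else ktaxa[[i]] <- c(ktaxa[[i]], taxa[ti])
        s <- NA_integer_
      }
    }
  }
  empty <- data.frame(start = integer(), end = integer(),
                      pattern = character(), stringsAsFactors = FALSE)
  if (!length(keys)) return(empty)
  se <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  start <- se[, 1L]; end <- se[, 2L]
  size <- end - start
  ntx <- lengths(ktaxa)
  cand <- which(ntx >= 2L & size >= min_size & size <= max_size)
  overlaps <- function(i, j) start[i] < end[j] && start[j] < end[i]
  keep <- cand[vapply(cand, function(i)
    !any(vapply(setdiff(cand, i), overlaps, logical(1L), i)),
    logical(1L))]
  if (mode == "strict") {
    trig <- which(size == 1L & ntx >= 2L)
    keep <- keep[vapply(keep, function(i)
      !any(vapply(trig, overlaps, logical(1L), i)), logical(1L))]
  }
  if (!length(keep)) return(empty)
  pat <- vapply(keep, function(i) {
    paste(vapply(seq_along(taxa), function(ti) {
      seg <- mat[ti, (start[i] + 1L):end[i]]
      if (any(seg == "?")) return("?")
      if (all(seg != "-")) return("0")
      if (any(seg != "-")) return("?")
      lok <- start[i] == 0L || mat[ti, start[i]] != "-"
      rok <- end[i] == w || mat[ti, end[i] + 1L] != "-"
      if (lok && rok) "1" else "?"
    }, character(1L)), collapse = "")
  }, character(1L))
  o <- order(start[keep], end[keep])
  data.frame(start = start[keep][o], end = end[keep][o], pattern = pat[o],
             stringsAsFactors = FALSE)
}

# engine output in the oracle's shape, for comparison
engine_extract_df <- function(block, min_size, max_size, mode) {
  res <- extract_splids(block, splid_config(min_size, max_size, mode))
  if (!length(res$splids))
    return(data.frame(start = integer(), end = integer(),
                      pattern = character(), stringsAsFactors = FALSE))
  data.frame(
    start = vapply(res$splids, `[[`, integer(1L), "start"),
    end = vapply(res$splids, `[[`, integer(1L), "end"),
    pattern = vapply(res$splids, function(s)
      paste(s$symbols[block$taxa], collapse = ""), character(1L)),
    stringsAsFactors = FALSE)
}

# quartet topology disagreement count by pruning each quadruple
oracle_quartet_distance <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  quads <- utils::combn(tips, 4L)
  d <- 0L
  for (k in seq_len(ncol(quads))) {
    q <- quads[, k]
    a <- ape::unroot(ape::keep.tip(t1, q))
    b <- ape::unroot(ape::keep.tip(t2, q))
    if (ape::dist.topo(a, b) != 0) d <- d + 1L
  }
  d
}
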
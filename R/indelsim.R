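BASES <- c("A", "C", "G", "T")

#' Indel length models
#'
#' `geometric_length(q)`: `P(k) = (1 - q) q^(k-1)`, `k >= 1`, mean
#' `1/(1-q)`. `lavalette_length(a, M)`: `P(k) proportional to
#' (k M / (M - k + 1))^(-a)` on `k = 1..M`, normalized by direct summation;
#' a heavy-tailed distribution that approximates empirical indel length
#' spectra better than the geometric for large indels.
#'
#' @param q geometric parameter, `0 < q < 1`.
#' @param a Lavalette exponent, `a > 0`.
#' @param M Lavalette maximum length, `M >= 1`.
#' @return a `length_model` object.
#' @export
geometric_length <- function(q) {
  if (q <= 0 || q >= 1) stop("geometric q must be in (0, 1)")
  structure(list(kind = "geometric", q = q), class = "length_model")
}

#' @rdname geometric_length
#' @export
lavalette_length <- function(a, M) {
  if (a <= 0) stop("lavalette a must be > 0")
  if (M < 1) stop("lavalette M must be >= 1")
  k <- seq_len(M)
  w <- (k * M / (M - k + 1))^(-a)
  structure(list(kind = "lavalette", a = a, M = as.integer(M),
                 prob = w / sum(w)), class = "length_model")
}

#' Sample indel lengths from a length model
#'
#' @param model a `length_model`.
#' @param n number of draws.
#' @return integer vector of lengths (>= 1).
#' @export
sample_indel_length <- function(model, n = 1L) {
  switch(model$kind,
    geometric = 1L + stats::rgeom(n, prob = 1 - model$q),
    lavalette = sample.int(model$M, n, replace = TRUE, prob = model$prob),
    stop("unknown length model"))
}

#' F81 transition probability matrix
#'
#' `P(i -> j, t) = pi_j (1 - exp(-beta t)) + delta_ij exp(-beta t)` with
#' `beta = 1 / (1 - sum_k pi_k^2)`, so that one unit of branch length is one
#' expected substitution per site. Uniform frequencies reduce to
#' Jukes-Cantor (`beta = 4/3`).
#'
#' @param pi equilibrium base frequencies (length 4, positive, sum 1).
#' @param t branch length (>= 0).
#' @return 4x4 row-stochastic matrix, rows = from-state A,C,G,T.
#' @export
f81_transition <- function(pi, t) {
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 4 positive frequencies summing to 1")
  if (t < 0) stop("branch length must be >= 0")
  beta <- 1 / (1 - sum(pi^2))
  e <- exp(-beta * t)
  P <- matrix(rep(pi, each = 4L), 4L, 4L) * (1 - e) + diag(4L) * e
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Simulation configuration
#'
#' Defaults follow the geometric/q = 0.7 simulation condition: insertion
#' rate 0.03106 and deletion rate 0.04037 per site relative to a
#' substitution rate of 1, a root sequence of 5,000 sites (a desk-scale
#' stand-in for the 100,000-site condition), uniform base frequencies, and
#' a mean re-alignment block size of 140 sites.
#'
#' @param tree guide tree ([ape::phylo], branch lengths required).
#' @param root_length root sequence length in sites.
#' @param pi equilibrium base frequencies.
#' @param lambda_i insertion rate per site (relative to substitution rate 1).
#' @param lambda_d deletion rate per site.
#' @param length_model a [geometric_length()] or [lavalette_length()] model.
#' @param block_mean mean block length for [split_into_blocks()].
#' @param seed RNG seed (integer) or NULL.
#' @export
sim_config <- function(tree, root_length = 5000L, pi = rep(0.25, 4),
                       lambda_i = 0.03106, lambda_d = 0.04037,
                       length_model = geometric_length(0.7),
                       block_mean = 140L, seed = NULL) {
  if (lambda_i < 0 || lambda_d < 0) stop("rates must be >= 0")
  if (root_length < 1L) stop("root_length must be >= 1")
  f81_transition(pi, 0)  # validates pi
  structure(list(tree = tree, root_length = as.integer(root_length),
                 pi = pi, lambda_i = lambda_i, lambda_d = lambda_d,
                 length_model = length_model,
                 block_mean = block_mean, seed = seed),
            class = "sim_config")
}

# tip labels below each node of `tree`
node_descendants <- function(tree) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  # postorder: every child's leaf set is complete before its parent uses it
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Simulate sequence evolution with indels along a tree
#'
#' The root sequence is drawn i.i.d. from `pi`. Along each branch of length
#' `t`, substitutions are applied to every inherited site by a single draw
#' from the F81 transition matrix `P(t)` (exact for F81: no intra-branch
#' substitution events are needed), and indel events are placed by a
#' Poisson process: event counts `~ Poisson(lambda * L * t)` with `L` the
#' ungapped sequence length at the branch start, event times uniform on the
#' branch, events applied in time order. An insertion (uniform over the
#' `L + 1` inter-site slots, bases drawn from `pi`) creates new alignment
#' columns, gapped in all other lineages; a deletion (start uniform over
#' sites, truncated at the sequence end) turns residues of all descendant
#' leaves into `-`. The output is the true multiple alignment over the
#' leaves plus a complete insertion/deletion event log and per-branch
#' substitution counts. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (an [alignment_block()] over the leaves,
#'   in tip order), `events` (data.frame: one row per indel event with
#'   `node` (branch child end), `type`, `time`, `length`, `n_cols`,
#'   `cols` (list of final 0-based column indices), `leaves` (list of
#'   descendant tip labels)), `sub_counts` (per-branch substitution
#'   counts), and `tree`.
#' @export
simulate_alignment <- function(config) {
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  if (is.null(tree$edge.length)) stop("guide tree must have branch lengths")
  if (!is.null(config$seed)) set.seed(config$seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  L0 <- config$root_length
  P_cache <- new.env(parent = emptyenv())

  rows <- vector("list", max(tree$edge))
  rows[[root]] <- sample(BASES, L0, replace = TRUE, prob = config$pi)
  col_ids <- seq_len(L0)
  next_id <- L0 + 1L

  ev_node <- integer(); ev_type <- character(); ev_time <- numeric()
  ev_len <- integer(); ev_ids <- list()
  sub_counts <- data.frame(node = integer(), t = numeric(),
                           n_sites = integer(), n_subs = integer())
  below <- node_descendants(tree)

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    row <- rows[[parent]]
    # substitutions on inherited sites, exact under F81
    sites <- which(row != "-")
    key <- format(t, digits = 15L)
    P <- P_cache[[key]]
    if (is.null(P)) {
      P <- f81_transition(config$pi, t)
      P_cache[[key]] <- P
    }
    if (length(sites)) {
      old <- row[sites]
      u <- stats::runif(length(sites))
      cum <- t(apply(P, 1L, cumsum))
      new <- BASES[max.col(cum[match(old, BASES), , drop = FALSE] >= u,
                           ties.method = "first")]
      sub_counts <- rbind(sub_counts,
                          data.frame(node = child, t = t,
                                     n_sites = length(sites),
                                     n_subs = sum(new != old)))
      row[sites] <- new
    }
    # indel events
    Lb <- length(sites)
    n_ins <- stats::rpois(1L, config$lambda_i * Lb * t)
    n_del <- stats::rpois(1L, config$lambda_d * Lb * t)
    if (n_ins + n_del > 0L) {
      types <- c(rep("ins", n_ins), rep("del", n_del))
      times <- stats::runif(n_ins + n_del, 0, t)
      ord <- order(times)
      for (k in ord) {
        len <- sample_indel_length(config$length_model, 1L)
        pos <- which(row != "-")
        Lc <- length(pos)
        if (types[k] == "del") {
          if (Lc == 0L) next
          s <- sample.int(Lc, 1L)
          hit <- pos[s:min(s + len - 1L, Lc)]
          row[hit] <- "-"
          ev_node <- c(ev_node, child); ev_type <- c(ev_type, "del")
          ev_time <- c(ev_time, times[k]); ev_len <- c(ev_len, length(hit))
          ev_ids <- c(ev_ids, list(col_ids[hit]))
        } else {
          slot <- sample.int(Lc + 1L, 1L) - 1L   # 0 = before first site
          at <- if (slot == 0L) 0L else pos[slot]  # insert after column `at`
          ids <- seq.int(next_id, length.out = len)
          next_id <- next_id + len
          newbases <- sample(BASES, len, replace = TRUE, prob = config$pi)
          col_ids <- append(col_ids, ids, after = at)
          gapfill <- rep("-", len)
          for (v in seq_along(rows)) {
            if (!is.null(rows[[v]]))
              rows[[v]] <- append(rows[[v]], gapfill, after = at)
          }
          row <- append(row, newbases, after = at)
          ev_node <- c(ev_node, child); ev_type <- c(ev_type, "ins")
          ev_time <- c(ev_time, times[k]); ev_len <- c(ev_len, len)
          ev_ids <- c(ev_ids, list(ids))
        }
      }
    }
    rows[[child]] <- row
  }

  aln <- vapply(seq_len(ntip), function(i) paste(rows[[i]], collapse = ""),
                character(1L))
  names(aln) <- tree$tip.label
  block <- alignment_block(aln, block_id = "sim", source = "simulate",
                          check_gap_rows = FALSE)
  events <- data.frame(node = ev_node, type = ev_type, time = ev_time,
                       length = ev_len, stringsAsFactors = FALSE)
  events$n_cols <- lengths(ev_ids)
  events$cols <- I(lapply(ev_ids, function(ids) match(ids, col_ids) - 1L))
  events$leaves <- I(lapply(ev_node, function(nd) below[[nd]]))
  list(alignment = block, events = events, sub_counts = sub_counts,
       tree = tree)
}

#' Write a simulation event log as TSV
#'
#' @param events the `events` data.frame from [simulate_alignment()].
#' @param path output file.
#' @export
write_event_log <- function(events, path) {
  flat <- data.frame(
    node = events$node, type = events$type,
    time = events$time, length = events$length, n_cols = events$n_cols,
    cols = vapply(events$cols, paste, character(1L), collapse = ","),
    leaves = vapply(events$leaves, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split an alignment into blocks of geometric length
#'
#' Emulates the decomposition of genome alignments into small blocks: cut
#' points are drawn so that block lengths are `1 + Geometric` with mean
#' `block_mean` (the last block is truncated at the alignment end).
#' Concatenating the output reproduces the input columns exactly; rows that
#' are pure gap within a block are retained so the inverse property holds.
#'
#' @param block an `alignment_block` (e.g. a simulated true alignment).
#' @param block_mean target mean block length in columns.
#' @return list of `alignment_block`.
#' @export
split_into_blocks <- function(block, block_mean = 140L) {
  w <- block_width(block)
  if (block_mean < 1L) stop("block_mean must be >= 1")
  if (block_mean >= w) {
    return(list(block))
  }
  lens <- integer()
  total <- 0L
  while (total < w) {
    l <- 1L + stats::rgeom(1L, prob = 1 / block_mean)
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - w)
  ends <- cumsum(lens)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(lens), function(i) {
    rows <- substr(block$rows, starts[i], ends[i])
    names(rows) <- block$taxa
    alignment_block(rows, block_id = sprintf("%s_part%d", block$block_id, i),
                    source = block$source, check_gap_rows = FALSE)
  })
}

#' A synthetic 17-taxon guide tree
#'
#' The real genome-alignment guide tree is not redistributable here, so
#' simulations use a synthetic stand-in: a random 17-leaf tree (fixed seed)
#' rescaled to a maximum root-to-tip height of 2, matching the stated
#' simulation condition.
#'
#' @param seed seed for the tree shape (default 170).
#' @param height target root-to-tip height (default 2).
#' @return an [ape::phylo] tree.
#' @export
synthetic_guide_tree <- function(seed = 170L, height = 2) {
  tr <- withr_seed(seed, ape::rtree(17L, tip.label = sprintf("t%02d", 1:17)))
  rescale_tree(tr, height)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
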
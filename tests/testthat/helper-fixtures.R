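# Shared fixture builders. All fixtures are generated in code.

# Build one aligned row: n residue columns with 0-based half-open gap
# intervals punched in.
mkrow <- function(n, gaps = list(), base = "A") {
  r <- rep(base, n)
  for (g in gaps) r[(g[1] + 1):g[2]] <- "-"
  paste(r, collapse = "")
}

# Two concatenated blocks realizing thirteen indels in four loci, built so
# that every clause of the worked splid example holds:
#   block A (taxa a-g, 24 cols), loci I-III:
#     locus I: (1) c[1,4) (2) e[1,3) (3) d[2,5) (4) {a,b}[3,7)
#              (5) f[6,9) (6) {d,e}[8,10) (7) g[9,11) (8) {c,f}[10,11)
#       -> candidates {(4),(6)}: (1)-(3),(5),(7) single-taxon, (8) size 1
#     locus II: g[13,15) single-taxon -> nothing
#     locus III: (9) {a,b}[17,20) and (10) {c,d}[19,22) overlap -> both out
#   block B (taxa a-f only, 9 cols), locus IV:
#     (11) {a,b}[2,6) candidate; (12) e[5,7) single-taxon;
#     (13) {c,d}[4,5) single-residue in two taxa
#       -> strict drops (11); fuzzy keeps it, taxon g (absent from B) = '?'
fig_blocks <- function() {
  A <- alignment_block(c(
    a = mkrow(24, list(c(3, 7), c(17, 20))),
    b = mkrow(24, list(c(3, 7), c(17, 20))),
    c = mkrow(24, list(c(1, 4), c(10, 11), c(19, 22))),
    d = mkrow(24, list(c(2, 5), c(8, 10), c(19, 22))),
    e = mkrow(24, list(c(1, 3), c(8, 10))),
    f = mkrow(24, list(c(6, 9), c(10, 11))),
    g = mkrow(24, list(c(9, 11), c(13, 15)))), block_id = "A")
  B <- alignment_block(c(
    a = mkrow(9, list(c(2, 6))),
    b = mkrow(9, list(c(2, 6))),
    c = mkrow(9, list(c(4, 5))),
    d = mkrow(9, list(c(4, 5))),
    e = mkrow(9, list(c(5, 7))),
    f = mkrow(9)), block_id = "B")
  list(A = A, B = B)
}

fig_concat <- function() concatenate_blocks(unname(fig_blocks()))

# hand-derived expected codings over universe a-g (see fig_blocks layout)
fig_expected_strict <- function() list(
  list(block = "A", start = 3L, end = 7L,
       pattern = c(a = "1", b = "1", c = "?", d = "?", e = "0", f = "?",
                   g = "0")),
  list(block = "A", start = 8L, end = 10L,
       pattern = c(a = "0", b = "0", c = "0", d = "1", e = "1", f = "?",
                   g = "?")))

fig_expected_fuzzy_extra <- function() list(
  list(block = "B", start = 2L, end = 6L,
       pattern = c(a = "1", b = "1", c = "?", d = "?", e = "?", f = "0",
                   g = "?")))

# random gapped alignment block (caller controls the RNG seed)
rand_block <- function(max_taxa = 6L, max_cols = 30L,
                       alphabet = c("A", "C", "G", "T", "-", "?"),
                       prob = c(.2, .2, .1, .1, .3, .1)) {
  nt <- sample(2:max_taxa, 1L)
  w <- sample(5:max_cols, 1L)
  rows <- vapply(seq_len(nt), function(i)
    paste(sample(alphabet, w, TRUE, prob = prob), collapse = ""),
    character(1L))
  names(rows) <- paste0("t", seq_len(nt))
  alignment_block(rows, check_gap_rows = FALSE)
}

# splids as a comparable data.frame (block, cols, coded pattern over taxa)
splid_df <- function(splids, taxa) {
  df <- data.frame(
    block = vapply(splids, `[[`, character(1L), "block_id"),
    start = vapply(splids, `[[`, integer(1L), "start"),
    end = vapply(splids, `[[`, integer(1L), "end"),
    pattern = vapply(splids, function(s)
      paste(s$symbols[taxa], collapse = ""), character(1L)),
    stringsAsFactors = FALSE)
  df[order(df$block, df$start), , drop = FALSE]
}

# splids as an order-free multiset key (for permutation-invariance tests)
splid_multiset <- function(splids) {
  sort(vapply(splids, function(s)
    paste(s$size,
          paste(sort(s$presence), collapse = ","),
          paste(sort(s$absence), collapse = ","),
          paste(sort(s$missing), collapse = ","), sep = "|"),
    character(1L)))
}

random_binary_tree <- function(n, labels = paste0("t", seq_len(n))) {
  ape::rtree(n, tip.label = sample(labels))
}
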
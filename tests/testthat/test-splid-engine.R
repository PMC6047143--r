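test_that("gap runs are maximal and delimited by residues, edges and ?", {
  b <- alignment_block(c(a = "AC--GT", b = "AC--GT", c = "ACTTGT"))
  runs <- find_gap_runs(b)
  expect_equal(runs$taxon, c("a", "b"))
  expect_equal(runs$start, c(2L, 2L))
  expect_equal(runs$end, c(4L, 4L))
  # '?' delimits a run
  b2 <- alignment_block(c(a = "??-AC", b = "AAAAC"), check_gap_rows = FALSE)
  r2 <- find_gap_runs(b2)
  expect_equal(r2$start, 2L)
  expect_equal(r2$end, 3L)
  expect_equal(nrow(find_gap_runs(alignment_block(c(a = "ACGT")))), 0L)
})

test_that("indel grouping is by exact shared endpoints", {
  runs <- data.frame(taxon = c("a", "b", "c"), start = c(2L, 2L, 2L),
                     end = c(4L, 4L, 5L), stringsAsFactors = FALSE)
  ind <- group_indels(runs)
  expect_equal(nrow(ind), 2L)
  expect_equal(ind$size, c(2L, 3L))
  expect_equal(sort(ind$taxa[[1]]), c("a", "b"))
  expect_equal(ind$taxa[[2]], "c")
  # partial overlap without shared 5' end stays two indels
  runs2 <- data.frame(taxon = c("a", "b"), start = c(1L, 2L),
                      end = c(3L, 4L), stringsAsFactors = FALSE)
  expect_equal(nrow(group_indels(runs2)), 2L)
  # single run, single one-taxon indel
  expect_equal(nrow(group_indels(runs2[1, ])), 1L)
})

test_that("loci are connected components of column overlap", {
  ind <- group_indels(data.frame(
    taxon = c("a", "b", "c"), start = c(2L, 3L, 9L), end = c(4L, 6L, 11L),
    stringsAsFactors = FALSE))
  loc <- find_loci(ind)
  expect_equal(loc$locus, c(1L, 1L, 2L))
  # abutting half-open intervals share no column: two loci
  ind2 <- group_indels(data.frame(
    taxon = c("a", "b"), start = c(2L, 4L), end = c(4L, 6L),
    stringsAsFactors = FALSE))
  expect_equal(find_loci(ind2)$locus, c(1L, 2L))
  expect_equal(nrow(find_loci(group_indels(find_gap_runs(
    alignment_block(c(a = "AAAA", b = "AAAA")))))), 0L)
})

test_that("rule 1 selects by taxon count and size bounds", {
  ind <- group_indels(data.frame(
    taxon = c("a", "b", "c", "a", "b"),
    start = c(2L, 2L, 2L, 6L, 6L), end = c(4L, 4L, 5L, 7L, 7L),
    stringsAsFactors = FALSE))
  cand <- candidate_splids(ind, splid_config())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 2L)
  expect_equal(cand$end, 4L)
  # min_size 1 admits the size-1 two-taxon indel
  expect_equal(nrow(candidate_splids(ind, splid_config(min_size = 1))), 2L)
  # max_size excludes
  expect_equal(nrow(candidate_splids(
    ind, splid_config(min_size = 1, max_size = 1))), 1L)
})

test_that("rule 2 removes both members of an overlapping candidate pair", {
  cand <- group_indels(data.frame(
    taxon = c("a", "b", "c", "d"), start = c(2L, 2L, 3L, 3L),
    end = c(5L, 5L, 6L, 6L), stringsAsFactors = FALSE))
  expect_equal(nrow(exclude_mutual_overlaps(cand)), 0L)
  disjoint <- group_indels(data.frame(
    taxon = c("a", "b", "c", "d"), start = c(2L, 2L, 6L, 6L),
    end = c(5L, 5L, 8L, 8L), stringsAsFactors = FALSE))
  expect_equal(nrow(exclude_mutual_overlaps(disjoint)), 2L)
})

test_that("strict filter needs a single-residue indel in >= 2 taxa", {
  ind <- group_indels(data.frame(
    taxon = c("a", "b", "c", "d"), start = c(2L, 2L, 3L, 3L),
    end = c(6L, 6L, 4L, 4L), stringsAsFactors = FALSE))
  cand <- candidate_splids(ind, splid_config())
  expect_equal(nrow(strict_filter(cand, ind, "strict")), 0L)
  expect_equal(nrow(strict_filter(cand, ind, "fuzzy")), 1L)
  # one-taxon single-residue indel does not trigger
  ind2 <- group_indels(data.frame(
    taxon = c("a", "b", "c"), start = c(2L, 2L, 3L),
    end = c(6L, 6L, 4L), stringsAsFactors = FALSE))
  cand2 <- candidate_splids(ind2, splid_config())
  expect_equal(nrow(strict_filter(cand2, ind2, "strict")), 1L)
  # no single-residue indels: identity
  expect_equal(strict_filter(cand2, cand2, "strict"), cand2)
})

test_that("coding distinguishes presence, absence, missing", {
  b <- alignment_block(c(a = "AC--GT", b = "AC--GT", c = "ACTTGT"))
  sym <- code_splid(2L, 4L, b, c("a", "b", "c", "g"))
  expect_equal(sym, c(a = "1", b = "1", c = "0", g = "?"))
  # superset run codes '?'
  b2 <- alignment_block(c(a = "A----T", b = "AC--GT", d = "AC--GT"))
  expect_equal(code_splid(2L, 4L, b2, b2$taxa)[["a"]], "?")
  # '?' in the splid columns codes '?'
  b3 <- alignment_block(c(a = "AC?-GT", b = "AC--GT", d = "AC--GT"),
                        check_gap_rows = FALSE)
  expect_equal(code_splid(2L, 4L, b3, b3$taxa)[["a"]], "?")
  # universe == presence + absence: no '?' anywhere
  expect_false("?" %in% code_splid(2L, 4L, b, b$taxa))
})

test_that("worked two-block example yields the documented splid sets", {
  cc <- fig_concat()
  strict <- extract_splids(cc, splid_config(mode = "strict"))
  fuzzy <- extract_splids(cc, splid_config(mode = "fuzzy"))
  expect_equal(strict$stats$n_loci, 4L)
  got <- splid_df(strict$splids, cc$taxa)
  want <- fig_expected_strict()
  expect_equal(nrow(got), 2L)
  for (i in 1:2) {
    expect_equal(got$start[i], want[[i]]$start)
    expect_equal(got$end[i], want[[i]]$end)
    expect_equal(got$pattern[i], paste(want[[i]]$pattern, collapse = ""))
  }
  gotf <- splid_df(fuzzy$splids, cc$taxa)
  expect_equal(nrow(gotf), 3L)
  extra <- fig_expected_fuzzy_extra()[[1]]
  expect_equal(gotf$block[3], "B")
  expect_equal(gotf$pattern[3], paste(extra$pattern, collapse = ""))
})

test_that("an all-residue alignment yields no splids", {
  b <- alignment_block(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_length(extract_splids(b)$splids, 0L)
  # fewer than two taxa can never satisfy rule 1
  expect_length(extract_splids(alignment_block(c(a = "AC--GT")))$splids, 0L)
})

test_that("engine matches the column-scanning oracle on random alignments", {
  set.seed(1234)
  for (r in 1:300) {
    b <- rand_block()
    ms <- sample(1:3, 1L)
    md <- sample(c("strict", "fuzzy"), 1L)
    expect_identical(engine_extract_df(b, ms, Inf, md),
                     oracle_extract(b, ms, Inf, md),
                     label = sprintf("rep %d min_size=%d mode=%s", r, ms, md))
  }
})

test_that("strict output is always a subset of fuzzy output", {
  set.seed(77)
  for (r in 1:60) {
    b <- rand_block()
    strict <- splid_multiset(extract_splids(b, splid_config())$splids)
    fuzzy <- splid_multiset(
      extract_splids(b, splid_config(mode = "fuzzy"))$splids)
    expect_true(all(strict %in% fuzzy))
  }
})

test_that("strict mode: min_size 1 and 2 yield identical splid sets", {
  # every size-1 multi-taxon candidate is itself a strict-filter trigger
  # (it overlaps itself), so admitting size-1 candidates changes nothing
  set.seed(78)
  for (r in 1:40) {
    b <- rand_block()
    expect_equal(
      splid_multiset(extract_splids(b, splid_config(min_size = 1))$splids),
      splid_multiset(extract_splids(b, splid_config(min_size = 2))$splids))
  }
})

test_that("size-bound monotonicity can break through mutual exclusion", {
  # widening the candidate window admits an indel that overlaps an accepted
  # splid; the mutual-overlap rule then removes both, so the count drops.
  # (The naive 'count is monotone in the size bounds' intuition is false.)
  b <- alignment_block(c(a = "AAA---GA", b = "AAA---GA",
                         c = "AAAA--GA", d = "AAAA--GA",
                         e = "AAAAAAGA"))
  n_narrow <- length(extract_splids(
    b, splid_config(min_size = 3, mode = "fuzzy"))$splids)
  n_wide <- length(extract_splids(
    b, splid_config(min_size = 2, mode = "fuzzy"))$splids)
  expect_equal(n_narrow, 1L)   # only {a,b}[3,6) qualifies: accepted
  expect_equal(n_wide, 0L)     # {c,d}[4,6) joins and both are excluded
  n_cap <- length(extract_splids(
    b, splid_config(min_size = 2, max_size = 2, mode = "fuzzy"))$splids)
  expect_equal(n_cap, 1L)      # capping the size re-admits {c,d}[4,6)
})

test_that("taxon order never changes the splid multiset", {
  set.seed(88)
  for (r in 1:30) {
    b <- rand_block()
    perm <- sample(b$taxa)
    b2 <- alignment_block(b$rows[perm], block_id = b$block_id,
                          check_gap_rows = FALSE)
    expect_equal(
      splid_multiset(extract_splids(b, splid_config(min_size = 1))$splids),
      splid_multiset(extract_splids(b2, splid_config(min_size = 1))$splids))
  }
})

test_that("accepted splids never share a column and have >= 2 presence taxa", {
  set.seed(99)
  for (r in 1:50) {
    b <- rand_block()
    sp <- extract_splids(b, splid_config(min_size = 1, mode = "fuzzy"))$splids
    if (length(sp) > 1L) {
      iv <- cbind(vapply(sp, `[[`, integer(1L), "start"),
                  vapply(sp, `[[`, integer(1L), "end"))
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      expect_true(all(iv[-1L, 1L] >= iv[-nrow(iv), 2L]))
    }
    for (s in sp) expect_gte(length(s$presence), 2L)
  }
})

test_that("extraction on a concatenation equals extraction per block", {
  blocks <- fig_blocks()
  cc <- concatenate_blocks(unname(blocks))
  joint <- splid_multiset(extract_splids(cc, splid_config(mode = "fuzzy"),
                                         taxon_universe = cc$taxa)$splids)
  solo <- c(
    splid_multiset(extract_splids(blocks$A, splid_config(mode = "fuzzy"),
                                  taxon_universe = cc$taxa)$splids),
    splid_multiset(extract_splids(blocks$B, splid_config(mode = "fuzzy"),
                                  taxon_universe = cc$taxa)$splids))
  expect_equal(joint, sort(solo))
})
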
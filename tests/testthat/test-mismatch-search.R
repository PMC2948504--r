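# Query splitting, Hamming-variant expansion, and the seeded search engine
# against independent brute-force scans.

test_that("queries split into word-size children plus remainder", {
  plan <- split_query("TTTTAATTTGGGCCCGGG", 9L)
  expect_equal(plan$parts$word, c("TTTTAATTT", "GGGCCCGGG"))
  expect_equal(plan$parts$offset, c(0L, 9L))
  expect_equal(plan$remainder$seq, "")

  q21 <- strrep("A", 21)
  plan21 <- split_query(q21, 9L)
  expect_equal(plan21$parts$offset, c(0L, 9L))
  expect_equal(plan21$remainder, list(offset = 18L, seq = "AAA"))

  plan9 <- split_query("ACGTACGTA", 9L)
  expect_equal(nrow(plan9$parts), 1L)
  expect_equal(plan9$remainder$seq, "")

  expect_error(split_query("ACGT", 9L), "word_size")
})

test_that("variant expansion enumerates exact Hamming shells", {
  w <- "TTTTAATTT"
  expect_equal(enumerate_variants(w, 0L)$variant, w)
  v1 <- enumerate_variants(w, 1L)
  expect_equal(nrow(v1), 28L)              # 1 + 9*3
  expect_equal(sum(v1$mismatches == 1), 27L)
  v3 <- enumerate_variants(w, 3L)
  expect_equal(nrow(v3), sum(choose(9, 0:3) * 3^(0:3)))
  expect_false(anyDuplicated(v3$variant) > 0)
  # annotated distances are true Hamming distances
  d <- vapply(v3$variant, hamming, numeric(1), b = w)
  expect_equal(unname(d), as.numeric(v3$mismatches))
})

test_that("variant expansion equals the exhaustive Hamming filter at word size 9", {
  # distance of all 4^9 words to a fixed word, computed digit-by-digit
  word <- "GATTACAGA"
  target <- cotscan:::word_digits(encode_word(word), 9L)
  keys <- 0:(4^9 - 1)
  dist <- integer(length(keys))
  rem <- keys
  for (p in 9:1) {
    dist <- dist + (rem %% 4 != target[p])
    rem <- rem %/% 4
  }
  v <- enumerate_variants(word, 3L)
  expect_equal(nrow(v), sum(dist <= 3))
  expect_setequal(v$variant[v$mismatches == 3],
                  vapply(keys[dist == 3], decode_word, "", word_size = 9L))
})

test_that("planted exact matches are found at their locus", {
  set.seed(5)
  q <- rand_dna(21)
  rec <- paste0(rand_dna(300), q, rand_dna(300))
  ts <- make_ts(c(r1 = rec, r2 = rand_dna(400)))
  idx <- build_seed_index(ts)
  h <- seed_search(q, idx, ts, k = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$seq_id, "r1")
  expect_equal(h$offset, 300L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$orientation, "sense")
  # and via the reverse complement when only that orientation matches
  h2 <- seed_search(reverse_complement(q), idx, ts, k = 0L)
  expect_equal(h2$orientation, "revcomp")
  expect_equal(h2$offset, 300L)
})

test_that("the printed 18-nt example joins child seeds separated by exactly 9", {
  ex <- "TTTTAATTTGGGCCCGGG"
  set.seed(8)
  ts <- make_ts(c(r1 = paste0(rand_dna(123), ex, rand_dna(80))))
  idx <- build_seed_index(ts)
  plan <- split_query(ex, 9L)
  left <- seed_lookup(idx, plan$parts$word[1])
  right <- seed_lookup(idx, plan$parts$word[2])
  expect_equal(right$offset - left$offset, 9L)
  h <- seed_search(ex, idx, ts, k = 0L, both_query_orientations = FALSE)
  expect_equal(h$offset, 123L)
})

test_that("queries containing N are skipped with a warning", {
  ts <- make_ts(c(r1 = rand_dna(100)))
  idx <- build_seed_index(ts)
  expect_warning(h <- seed_search(paste0(strrep("A", 20), "N"), idx, ts),
                 "skipped")
  expect_equal(nrow(h), 0L)
  expect_warning(hn <- naive_search(paste0(strrep("A", 20), "N"), ts),
                 "skipped")
  expect_equal(nrow(hn), 0L)
})

test_that("seeded and brute-force engines return identical hit sets", {
  set.seed(101)
  for (space in 1:5) {
    seqs <- setNames(vapply(1:4, function(i) rand_dna(sample(800:1600, 1)), ""),
                     paste0("g", 1:4))
    ts <- make_ts(seqs)
    idx <- build_seed_index(ts)
    for (qi in 1:30) {
      q <- if (qi %% 2 == 0) rand_dna(21) else {
        # mutated copy of a real window, to generate hits at various distances
        r <- sample(names(seqs), 1)
        s <- sample(nchar(seqs[[r]]) - 20L, 1)
        mutate_with_hamming(substring(seqs[[r]], s, s + 20L), sample(0:3, 1))
      }
      for (k in 0:3) {
        a <- seed_search(q, idx, ts, k = k)
        b <- naive_search(q, ts, k = k)
        expect_identical(a, b)
      }
    }
  }
})

test_that("seeded search agrees with Biostrings pattern matching", {
  set.seed(33)
  seqs <- setNames(vapply(1:3, function(i) rand_dna(900), ""), paste0("g", 1:3))
  ts <- make_ts(seqs)
  idx <- build_seed_index(ts)
  subj <- Biostrings::DNAStringSet(unname(seqs))
  for (qi in 1:12) {
    r <- sample(3, 1)
    s <- sample(880, 1)
    q <- mutate_with_hamming(substring(seqs[[r]], s, s + 20L), sample(0:3, 1))
    got <- seed_search(q, idx, ts, k = 3L, both_query_orientations = FALSE)
    ext <- do.call(rbind, lapply(1:3, function(ri) {
      st <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(q), subj[[ri]], max.mismatch = 3,
        with.indels = FALSE, fixed = TRUE))
      if (length(st) == 0) return(NULL)
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subj[[ri]],
                                        starting.at = st, fixed = TRUE)
      data.frame(seq_id = paste0("g", ri), offset = st - 1L,
                 mismatches = as.integer(mm))[mm <= 3, ]
    }))
    expect_equal(got[, c("seq_id", "offset", "mismatches")], ext,
                 ignore_attr = TRUE)
  }
})

test_that("hit sets are sound, deduplicated, and monotone in k", {
  set.seed(55)
  seqs <- setNames(vapply(1:3, function(i) rand_dna(1200), ""), paste0("g", 1:3))
  ts <- make_ts(seqs)
  idx <- build_seed_index(ts)
  for (qi in 1:15) {
    r <- sample(names(seqs), 1)
    s <- sample(nchar(seqs[[r]]) - 20L, 1)
    q <- mutate_with_hamming(substring(seqs[[r]], s, s + 20L), sample(0:3, 1))
    prev <- character(0)
    for (k in 0:3) {
      h <- seed_search(q, idx, ts, k = k)
      keys <- hit_key(h)
      expect_false(anyDuplicated(paste(h$seq_id, h$offset, h$orientation)) > 0)
      expect_true(all(prev %in% keys))     # monotone growth
      prev <- keys
      # soundness: every reported hit re-verifies by direct comparison
      for (i in seq_len(nrow(h))) {
        win <- substring(seqs[[h$seq_id[i]]], h$offset[i] + 1L,
                         h$offset[i] + 21L)
        qq <- if (h$orientation[i] == "sense") q else reverse_complement(q)
        expect_equal(hamming(qq, win), h$mismatches[i])
      }
    }
  }
})

test_that("hits at record boundaries are neither missed nor invented", {
  set.seed(77)
  rec <- rand_dna(60)
  ts <- make_ts(c(r1 = rec))
  idx <- build_seed_index(ts)
  first <- substring(rec, 1, 21)
  last <- substring(rec, 40, 60)
  expect_true(0L %in% seed_search(first, idx, ts, k = 0L)$offset)
  expect_true(39L %in% seed_search(last, idx, ts, k = 0L)$offset)
  expect_identical(seed_search(first, idx, ts, k = 3L),
                   naive_search(first, ts, k = 3L))
  expect_identical(seed_search(last, idx, ts, k = 3L),
                   naive_search(last, ts, k = 3L))
})
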
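# cot-group formation, statistics, clean regions, dsRNA pair design, and the
# random-match expectation.

fake_hits <- function(starts, targets, source = "G1") {
  n <- length(starts)
  data.frame(source_gene = rep(source, n), sirna_start = starts,
             sequence = rep(strrep("A", 21), n), score = rep(0, n),
             target_gene = targets, seq_id = targets,
             offset = rep(0L, n), mismatches = rep(0L, n),
             orientation = rep("sense", n),
             region = rep("exon", n), stringsAsFactors = FALSE)
}

test_that("cot-groups are (source, off-target) classes with >= 2 members", {
  g <- form_cot_groups(fake_hits(c(10L, 500L), c("geneX", "geneX")))
  expect_equal(nrow(g), 1L)
  expect_equal(g$size, 2L)
  expect_equal(g$members[[1]], c(10L, 500L))

  expect_equal(nrow(form_cot_groups(fake_hits(10L, "geneX"))), 0L)

  # duplicate loci for one (siRNA, target) pair collapse
  g2 <- form_cot_groups(fake_hits(c(10L, 10L, 500L),
                                  c("geneX", "geneX", "geneX")))
  expect_equal(g2$size, 2L)
})

test_that("random hit tables group identically to an independent aggregation", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(30:120, 1)
    hits <- fake_hits(sample(0:400, n, replace = TRUE),
                      paste0("T", sample(1:6, n, replace = TRUE)))
    got <- form_cot_groups(hits)
    # oracle: tapply over unique pairs
    u <- unique(hits[, c("sirna_start", "target_gene")])
    cnt <- table(u$target_gene)
    want_targets <- sort(names(cnt[cnt >= 2]))
    expect_equal(got$offtarget_gene, want_targets)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$members[[i]],
                   sort(unique(u$sirna_start[u$target_gene ==
                                               got$offtarget_gene[i]])))
      expect_equal(got$size[i], length(got$members[[i]]))
    }
  }
})

test_that("cot statistics follow the members x L / length formula", {
  g1 <- form_cot_groups(fake_hits(c(0L, 600L), c("X", "X")))
  s1 <- cot_stats(g1, gene_length = 2100L)
  expect_equal(s1$coverage_percent, 2.0)          # 2 * 21 / 2100
  expect_equal(s1$n_cot_groups, 1L)
  expect_equal(s1$max_group_size, 2L)

  s0 <- cot_stats(form_cot_groups(fake_hits(integer(0), character(0))),
                  gene_length = 500L)
  expect_equal(s0$n_cot_groups, 0L)
  expect_equal(s0$coverage_percent, 0)
  expect_equal(s0$max_group_size, 0L)

  g23 <- form_cot_groups(fake_hits(c(0L, 50L, 1L, 60L, 100L),
                                   c("X", "X", "Y", "Y", "Y")))
  s23 <- cot_stats(g23, gene_length = 210L)
  expect_equal(s23$coverage_percent, 50.0)        # 5 * 21 / 210

  expect_error(cot_stats(g1, gene_length = 20L), "gene_length")
})

test_that("clean regions are maximal and exclude both members of any pair", {
  G <- 1000L
  none <- clean_regions(form_cot_groups(fake_hits(integer(0), character(0))), G)
  expect_equal(unname(none), cbind(0L, G), ignore_attr = TRUE)

  one <- form_cot_groups(fake_hits(c(100L, 400L), c("X", "X")))
  regs <- clean_regions(one, G)
  expect_equal(unname(regs[, 1]), c(0L, 101L))
  expect_equal(unname(regs[, 2]), c(420L, G))
  # neither region contains both [100,121) and [400,421)
  for (i in seq_len(nrow(regs))) {
    both <- regs[i, 1] <= 100L && regs[i, 2] >= 421L
    expect_false(both)
  }
})

test_that("clean regions verify and are inextensible on random group sets", {
  violates <- function(a, b, groups, L = 21L) {
    for (m in groups$members) {
      inside <- sum(m >= a & m + L <= b)
      if (inside >= 2) return(TRUE)
    }
    FALSE
  }
  set.seed(13)
  for (rep in 1:15) {
    G <- sample(500:1500, 1)
    n <- sample(1:5, 1)
    hits <- fake_hits(sample(0:(G - 21L), 4 * n, replace = FALSE),
                      paste0("T", rep(seq_len(n), each = 4)))
    groups <- form_cot_groups(hits)
    regs <- clean_regions(groups, G)
    for (i in seq_len(nrow(regs))) {
      a <- regs[i, 1]; b <- regs[i, 2]
      expect_false(violates(a, b, groups))
      if (a > 0L) expect_true(violates(a - 1L, b, groups))
      if (b < G) expect_true(violates(a, b + 1L, groups))
    }
  }
})

test_that("UTR masks subtract from clean regions", {
  G <- 600L
  regs <- clean_regions(form_cot_groups(fake_hits(integer(0), character(0))),
                        G, utr_mask = cbind(start = c(0L, 550L),
                                            end = c(50L, 600L)))
  expect_equal(unname(regs), cbind(50L, 550L), ignore_attr = TRUE)
})

test_that("unconstrained genes always admit a clean dsRNA pair", {
  set.seed(14)
  gs <- make_gs(rand_dna(1000))
  d <- design_dsrna_pairs(gs, fake_hits(integer(0), character(0)),
                          min_len = 300L, max_len = 800L)
  expect_true(d$feasible)
  p <- d$pairs[1, ]
  expect_gte(p$region1_end - p$region1_start, 300L)
  expect_gte(p$region2_end - p$region2_start, 300L)
  expect_lte(p$region1_end, p$region2_start)
})

test_that("a gene blocked everywhere reports the blocking off-target", {
  set.seed(15)
  gs <- make_gs(rand_dna(900))
  blocked <- fake_hits(0:(900L - 21L), rep("BLOCKER", 880L))
  d <- design_dsrna_pairs(gs, blocked, min_len = 300L, max_len = 800L)
  expect_false(d$feasible)
  expect_equal(nrow(d$pairs), 0L)
  expect_true("BLOCKER" %in% d$blocking_genes)
  expect_error(design_dsrna_pairs(make_gs(rand_dna(400)), blocked,
                                  min_len = 300L), "min_len")
})

test_that("emitted pairs pass an independent disjointness check", {
  region_set <- function(hits, a, b, L = 21L) {
    u <- unique(hits[, c("sirna_start", "target_gene")])
    unique(u$target_gene[u$sirna_start >= a & u$sirna_start + L <= b])
  }
  set.seed(16)
  for (rep in 1:8) {
    G <- sample(800:1400, 1)
    gs <- make_gs(rand_dna(G))
    n <- sample(2:6, 1)
    hits <- fake_hits(sample(0:(G - 21L), 3 * n, replace = FALSE),
                      paste0("T", rep(seq_len(n), each = 3)))
    d <- design_dsrna_pairs(gs, hits, min_len = 250L, max_len = 700L,
                            n_choices = 4L)
    for (i in seq_len(nrow(d$pairs))) {
      p <- d$pairs[i, ]
      s1 <- region_set(hits, p$region1_start, p$region1_end)
      s2 <- region_set(hits, p$region2_start, p$region2_end)
      expect_length(intersect(s1, s2), 0L)
      expect_lte(p$region1_end, p$region2_start)   # non-overlapping
    }
  }
})

test_that("UTR avoidance keeps designed regions outside UTRs", {
  set.seed(17)
  gs <- make_gs(rand_dna(1200))
  gs$utr_mature <- cbind(start = c(0L, 1100L), end = c(80L, 1200L))
  d <- design_dsrna_pairs(gs, fake_hits(integer(0), character(0)),
                          min_len = 300L, max_len = 500L, avoid_utr = TRUE)
  expect_true(d$feasible)
  for (i in seq_len(nrow(d$pairs))) {
    p <- d$pairs[i, ]
    expect_gte(p$region1_start, 80L)
    expect_lte(p$region2_end, 1100L)
  }
})

test_that("the random-match expectation has its closed form and exact terms", {
  expect_equal(expected_random_matches(21L, 0L, 4^21, both_strands = FALSE), 1.0)
  expect_equal(expected_random_matches(21L, 0L, 4^21, both_strands = TRUE), 2.0)

  # term-by-term check of the Hamming-ball size at L = 8 by full enumeration
  word <- "GATTACAG"
  target <- cotscan:::word_digits(encode_word(word), 8L)
  keys <- 0:(4^8 - 1)
  dist <- integer(length(keys)); rem <- keys
  for (p in 8:1) {
    dist <- dist + (rem %% 4 != target[p])
    rem <- rem %/% 4
  }
  for (i in 0:3) {
    expect_equal(sum(dist == i), choose(8, i) * 3^i)
    expect_equal(sum(dist <= i), hamming_ball_size(8L, i))
  }
  expect_equal(hamming_ball_size(21L, 3L), sum(choose(21, 0:3) * 3^(0:3)))
})
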
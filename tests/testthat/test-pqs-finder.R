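test_that("parameter objects enforce the grammar's bounds", {
  p <- pqs_params()
  expect_equal(c(p$min_tract, p$max_tract, p$min_loop, p$max_loop), c(2, 7, 1, 7))
  expect_equal(p$n_tracts, 4L)
  expect_error(pqs_params(min_tract = 0), "min_tract")
  expect_error(pqs_params(min_tract = 5, max_tract = 3), "min_tract")
  expect_error(pqs_params(min_loop = 0), "min_loop")
  expect_equal(max_motif_span(pqs_params()), 49)
  expect_equal(max_motif_span(pqs_params(2, 2, 1, 1)), 11)
})

test_that("single-strand scan matches frozen oracle-derived examples", {
  h <- find_pqs_strand("GGGAGGGAGGGAGGG")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1, 15))
  expect_equal(h$tract_lengths[[1]], c(3L, 3L, 3L, 3L))
  expect_equal(h$loop_lengths[[1]], c(1L, 1L, 1L))

  expect_equal(nrow(find_pqs_strand("ATATATATAT")), 0)

  h2 <- find_pqs_strand("GGAGGAGGAGG")  # minimal-span motif at defaults
  expect_equal(h2$length, 11)
  expect_equal(h2$tract_lengths[[1]], c(2L, 2L, 2L, 2L))

  tandem <- paste0("GGGAGGGAGGGAGGG", "TTTT", "GGGAGGGAGGGAGGG")
  h3 <- find_pqs_strand(tandem)
  expect_equal(h3$start, c(1, 20))
  expect_equal(h3$end, c(15, 34))

  expect_error(find_pqs_strand("GGGAXGGG"), "unnormalized")
})

test_that("every reported hit satisfies the decomposition invariants", {
  set.seed(21)
  for (i in 1:50) {
    s <- random_seq(sample(30:200, 1), gc = runif(1, 0.3, 0.7))
    h <- find_pqs_strand(s)
    if (!nrow(h)) next
    for (k in seq_len(nrow(h))) {
      tr <- h$tract_lengths[[k]]; lp <- h$loop_lengths[[k]]
      expect_length(tr, 4); expect_length(lp, 3)
      expect_true(all(tr >= 2 & tr <= 7))
      expect_true(all(lp >= 1 & lp <= 7))
      expect_equal(h$end[k] - h$start[k] + 1, sum(tr) + sum(lp))
      expect_equal(h$length[k], sum(tr) + sum(lp))
      expect_lte(h$length[k], max_motif_span(pqs_params()))
      # hit_seq decomposes exactly as G^t1 loop1 G^t2 loop2 G^t3 loop3 G^t4
      pos <- 1L
      for (j in 1:4) {
        expect_equal(substr(h$hit_seq[k], pos, pos + tr[j] - 1),
                     strrep("G", tr[j]))
        pos <- pos + tr[j]
        if (j < 4) pos <- pos + lp[j]
      }
    }
    # non-overlap and sortedness on the strand
    if (nrow(h) > 1) {
      expect_true(all(diff(h$start) > 0))
      expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    }
  }
})

test_that("scanner equals the exhaustive enumerator on random sequences", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_seq(sample(10:200, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(scanner_hits_df(find_pqs_strand(s)),
                 oracle_hits_df(brute_force_pqs(s)), info = s)
  }
})

test_that("antisense coordinates mirror correctly", {
  expect_equal(map_antisense_coords(1, 15, 15), list(start = 1L, end = 15L))
  expect_equal(map_antisense_coords(1, 11, 20), list(start = 10L, end = 20L))
  m <- map_antisense_coords(4, 9, 30)
  expect_equal(map_antisense_coords(m$start, m$end, 30), list(start = 4L, end = 9L))
  expect_error(map_antisense_coords(0, 5, 10), "require")
  expect_error(map_antisense_coords(3, 12, 10), "require")
})

test_that("both-strand scan reports antisense hits in input coordinates", {
  sc <- scan_pqs("CCCTCCCTCCCTCCC")
  expect_equal(sc$n_sense, 0)
  expect_equal(sc$n_antisense, 1)
  expect_equal(sc$n_total, 1)
  expect_equal(c(sc$hits$start, sc$hits$end), c(1, 15))
  expect_equal(sc$hits$strand, "-")
  expect_equal(sc$hits$hit_seq, "GGGAGGGAGGGAGGG")  # as read on the hit strand

  off <- scan_pqs("GGGAGGGAGGGAGGG", pqs_params(scan_antisense = FALSE))
  expect_equal(off$n_antisense, 0)
  expect_equal(off$n_sense, 1)

  empty <- scan_pqs("")
  expect_equal(empty$n_total, 0)
})

test_that("scanning is strand-symmetric", {
  set.seed(41)
  for (i in 1:40) {
    s <- nucleotide_sequence(random_seq(sample(20:200, 1), gc = runif(1, 0.3, 0.7)),
                             id = "p")
    a <- scan_pqs(s)$hits
    b <- scan_pqs(reverse_complement(s))$hits
    expect_equal(a$n_total, b$n_total)
    L <- nchar(s$seq)
    flip <- function(h) {
      m <- map_antisense_coords(h$start, h$end, L)
      d <- data.frame(strand = as.character(ifelse(h$strand == "+", "-", "+")),
                      start = m$start, end = m$end, hit_seq = h$hit_seq,
                      stringsAsFactors = FALSE)
      d[order(d$strand, d$start), ]
    }
    a2 <- flip(a); rownames(a2) <- NULL
    b2 <- b[order(b$strand, b$start), c("strand", "start", "end", "hit_seq")]
    rownames(b2) <- NULL
    expect_equal(a2[order(a2$strand, a2$start), ], b2)
  }
})
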
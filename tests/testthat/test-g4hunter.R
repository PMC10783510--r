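test_that("classic scoring reproduces the published CEB family scores", {
  for (r in seq_len(nrow(CEB_TABLE))) {
    expect_equal(round_half_away(g4hunter_score(CEB_TABLE$seq[r])),
                 CEB_TABLE$g4h[r],
                 info = CEB_TABLE$id[r])
  }
  # exact rationals behind two of the printed values
  expect_equal(g4hunter_score(ceb_seq("CEBwt")), 39 / 26)
  expect_equal(g4hunter_score(ceb_seq("CEBm1")), 29 / 26)
})

test_that("run scoring handles trivial and capped cases", {
  expect_equal(g4hunter_score("AAAA"), 0)
  expect_equal(g4hunter_score("GGGG"), 4)
  expect_equal(g4hunter_score("CCC"), -3)
  expect_equal(g4hunter_score("GCGCGC"), 0)
  # run cap: every base of a 6-G run scores exactly 4
  expect_equal(score_bases("GGGGGG")$scores, rep(4, 6))
  # N scores zero and breaks runs
  expect_equal(score_bases("GGNGG")$scores, c(2, 2, 0, 2, 2))
})

test_that("soft penalties rescale C-runs of length >= 3 only", {
  m4 <- ceb_seq("CEBm4")
  expect_equal(round_half_away(
    g4hunter_score(m4, scoring_scheme("soft", 2))), 0.92)
  expect_equal(round_half_away(
    g4hunter_score(m4, scoring_scheme("soft", 1.5))), 1.04)
  expect_equal(g4hunter_score(m4, scoring_scheme("soft", 2)), 24 / 26)
  expect_equal(g4hunter_score(m4, scoring_scheme("soft", 1.5)), 27 / 26)
  # penalty 3 reduces to classic when all C-runs have length exactly 3
  expect_equal(g4hunter_score(m4, scoring_scheme("soft", 3)),
               g4hunter_score(m4))
  # runs of 1 and 2 cytosines are untouched by the soft scheme
  expect_equal(score_bases("ACCA", scoring_scheme("soft", 1.5))$scores,
               score_bases("ACCA")$scores)
  expect_error(scoring_scheme("soft", 0), "soft_penalty")
  expect_error(scoring_scheme("soft", 5), "soft_penalty")
})

test_that("sequence validation names the offending position", {
  expect_error(seq_record("x", "ACGU"), "position 4")
  expect_error(seq_record("x", ""), "empty")
  expect_equal(seq_record("x", "acgtn")$seq, "ACGTN")
})

test_that("classic scores are antisymmetric under reverse complement and bounded", {
  set.seed(42)
  for (i in 1:200) {
    s <- rand_dna(sample(5:60, 1))
    bs <- score_bases(s)
    expect_equal(g4hunter_score(revcomp(s)), -bs$mean_score)
    expect_true(all(abs(bs$scores) <= 4))
    expect_true(abs(bs$mean_score) <= 4)
  }
})

test_that("window scan agrees with direct scoring of each window", {
  wt <- ceb_seq("CEBwt")
  ws <- window_scan(wt, window = nchar(wt))
  expect_equal(nrow(ws$windows), 1L)
  expect_equal(round_half_away(ws$windows$score), 1.50)

  set.seed(7)
  s <- rand_dna(200)
  ws <- window_scan(s, window = 20, step = 3, threshold = 0.5)
  direct <- vapply(seq_len(nrow(ws$windows)), function(i)
    g4hunter_score(substr(s, ws$windows$start[i] + 1, ws$windows$end[i])),
    numeric(1))
  expect_equal(ws$windows$score, direct)

  expect_equal(nrow(window_scan(strrep("A", 1000), window = 25)$hits), 0L)
  expect_error(window_scan("ACGT", window = 10), "window")
})

test_that("a planted oligo is the only region flagged by the scan", {
  genome <- paste0(strrep("A", 50), ceb_seq("CEBwt"), strrep("A", 50))
  ws <- window_scan(genome, window = 26, threshold = 1.4)
  expect_gt(nrow(ws$hits), 0)
  # planted interval is [50, 76) 0-based; every flagged window overlaps it
  expect_true(all(ws$hits$start < 76 & ws$hits$end > 50))
  expect_true(all(ws$hits$strand == "+"))
  # reverse-complement plant is flagged as a reverse-strand candidate
  wsrc <- window_scan(revcomp(genome), window = 26, threshold = 1.4)
  expect_true(all(wsrc$hits$strand == "-"))
})

test_that("score_table combines scoring and C-run columns", {
  tab <- score_table(ceb_family())
  expect_equal(tab$score, CEB_TABLE$g4h)
  expect_equal(tab$n_stat, CEB_TABLE$n)
  expect_equal(tab$length, CEB_TABLE$length)
})
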
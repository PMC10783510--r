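# Independent brute-force oracle for the maximal nested pairing: plain
# exhaustive recursion over every choice (leave the leftmost base unpaired,
# or pair it with each admissible partner), no memoization, no traceback.
# Exponential, so only used at oligo scale.
brute_max_pairs <- function(seq, min_loop = 1L, count_at = FALSE) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ok <- function(a, b) {
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (count_at && ((a == "A" && b == "T") || (a == "T" && b == "A")))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(s[i], s[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, length(s))
}

# Structural validity of a fold object: complementary pairs, non-crossing,
# loop constraint, dot-bracket consistency.
expect_valid_fold <- function(fold) {
  s <- strsplit(fold$record$seq, "", fixed = TRUE)[[1]]
  p <- fold$pairs
  expect_equal(fold$max_pairs, nrow(p))
  if (nrow(p)) {
    comp <- c(G = "C", C = "G", A = "T", T = "A")
    expect_true(all(s[p[, 2]] == comp[s[p[, 1]]]))
    if (!fold$count_at) expect_true(all(s[p[, 1]] %in% c("G", "C")))
    expect_true(all(p[, 2] - p[, 1] - 1L >= fold$min_loop))
    expect_true(!anyDuplicated(c(p[, 1], p[, 2])))
    if (nrow(p) > 1) {
      for (a in seq_len(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
        expect_false(crossing)
      }
    }
  }
  db <- strsplit(fold$dot_bracket, "", fixed = TRUE)[[1]]
  expect_equal(sum(db == "("), nrow(p))
  expect_equal(sum(db == ")"), nrow(p))
}
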
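test_that("CEBwt is a long-loop PQS with four G-tracts and a 9-nt central loop", {
  h <- find_pqs(ceb_seq("CEBwt"), both_strands = FALSE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "long_loop")
  tr <- h$tracts[[1]]
  expect_equal(nrow(tr), 4L)
  expect_true(all(tr$end - tr$start == 3L))
  expect_equal(h$loops[[1]]$length, c(1L, 9L, 1L))
})

test_that("minimal motifs of each class are detected and classified", {
  h <- find_pqs("GGGTGGGTGGGTGGG", both_strands = FALSE)
  expect_equal(h$class, "classical")
  expect_equal(c(h$start, h$end), c(0L, 15L))

  expect_equal(nrow(find_pqs("ACGTACGTACGT")), 0L)

  hb <- find_pqs("GGGTGGGTGGGTGGAG", both_strands = FALSE)
  expect_equal(hb$class, "bulged")

  hv <- find_pqs("GGGTGGGTGGGTGG", both_strands = FALSE)
  expect_equal(hv$class, "vacancy")

  # class precedence: a classical locus is never reported as a relaxed class
  hc <- find_pqs("GGGTGGGTGGGTGGG", both_strands = FALSE)
  expect_equal(hc$class, "classical")
})

test_that("the full CEB family yields one long-loop forward hit each", {
  for (r in seq_len(nrow(CEB_TABLE))) {
    h <- find_pqs(CEB_TABLE$seq[r], both_strands = FALSE)
    expect_equal(nrow(h), 1L, info = CEB_TABLE$id[r])
    expect_equal(h$class, "long_loop", info = CEB_TABLE$id[r])
  }
  # CEBm7 additionally carries a C-motif: a minus-strand hit appears only
  # when both strands are scanned
  h7 <- find_pqs(ceb_seq("CEBm7"), both_strands = TRUE)
  expect_setequal(h7$strand, c("+", "-"))
})

test_that("every reported hit slice re-matches its class grammar", {
  g <- synth_genome(20000, c(classical = 4, long_loop = 4, bulged = 4,
                             vacancy = 4), seed = 5, minus_fraction = 0.5)
  h <- find_pqs(g$record)
  expect_gt(nrow(h), 0)
  for (i in seq_len(nrow(h)))
    expect_true(pqs_class_matches(h$sequence[i], h$class[i]))
  # minus-strand hits: forward slice's reverse complement is the motif
  minus <- which(h$strand == "-")
  for (i in minus) {
    fwd <- substr(g$record$seq, h$start[i] + 1, h$end[i])
    expect_equal(revcomp(fwd), h$sequence[i])
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  g <- synth_genome(5000, c(classical = 3), seed = 9, minus_fraction = 0.5)
  L <- g$record$length
  fwd <- find_pqs(g$record, both_strands = TRUE)
  rc <- find_pqs(seq_record("synth", revcomp(g$record$seq)),
                 both_strands = TRUE)
  mirror <- data.frame(start = L - rc$end, end = L - rc$start,
                       strand = ifelse(rc$strand == "+", "-", "+"))
  expect_equal(fwd[order(fwd$start), c("start", "end", "strand")],
               mirror[order(mirror$start), ],
               ignore_attr = TRUE)
})

test_that("relaxing the loop bound never removes a classical hit", {
  set.seed(21)
  for (i in 1:10) {
    g <- synth_genome(4000, c(classical = 3), seed = i)
    strict <- find_pqs(g$record, classes = "classical", both_strands = FALSE)
    relaxed <- find_pqs(g$record, classes = c("classical", "long_loop"),
                        both_strands = FALSE)
    expect_true(all(strict$start %in% relaxed$start[
      relaxed$class == "classical"]))
  }
})

test_that("planted-motif genomes give exact recall and no off-truth hits", {
  g <- synth_genome(30000, c(classical = 8, long_loop = 5, bulged = 5,
                             vacancy = 5), seed = 13, minus_fraction = 0.25)
  h <- find_pqs(g$record)
  expect_equal(nrow(h), nrow(g$truth))
  expect_equal(h$start, g$truth$start)
  expect_equal(h$end, g$truth$end)
  expect_equal(h$class, g$truth$class)
  expect_equal(h$strand, g$truth$strand)
})

test_that("census counts PQS, CCC-run stringency tiers and frequency", {
  fam <- ceb_family()
  hits <- do.call(rbind, lapply(fam, find_pqs, both_strands = FALSE))
  cs <- pqs_census(hits, fam, n_threshold = 2)
  expect_equal(cs$n_hits, 10L)
  # CCC runs are counted on the hit slice (tract-to-tract): the seven
  # cytosine mutants carry >= 1; only m4/m5/m7 carry two CCC runs between
  # their outermost tracts
  expect_equal(cs$ccc_ge_1, 7L)
  expect_equal(cs$ccc_ge_n, 3L)
  expect_equal(cs$freq_per_kb, 10 / sum(CEB_TABLE$length) * 1000)

  empty <- pqs_census(find_pqs("ACGTACGT"), seq_record("x", "ACGTACGT"))
  expect_equal(empty$n_hits, 0L)
  expect_equal(empty$ccc_ge_1, 0L)
  expect_equal(empty$freq_per_kb, 0)
})

test_that("census feature breakdown uses annotation overlap", {
  g <- synth_genome(10000, c(classical = 6), seed = 3)
  h <- find_pqs(g$record, both_strands = FALSE)
  ann <- GenomicRanges::GRanges("synth",
           IRanges::IRanges(c(1, 5001), c(5000, 10000)))
  ann$name <- c("left_arm", "right_arm")
  cs <- pqs_census(h, g$record, annotation = ann)
  expect_equal(sum(cs$by_feature), 6L)

  bad <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100))
  bad$name <- "x"
  expect_warning(cs2 <- pqs_census(h, g$record, annotation = bad),
                 "chromosome names")
  expect_null(cs2$by_feature)
})

test_that("BED output has six columns with scaled scores", {
  h <- find_pqs(ceb_seq("CEBwt"), both_strands = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(h, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(ncol(bed), 6L)
  expect_equal(bed$V2, h$start)
  expect_equal(bed$V4, "long_loop")
  expect_equal(bed$V5, round(g4hunter_score(h$sequence) * 100))
  expect_equal(bed$V6, "+")
})

test_that("report_all keeps overlapping same-class matches", {
  # two overlapping classical interpretations share the central tracts
  s <- "GGGTGGGTGGGTGGGTGGG"
  merged <- find_pqs(s, classes = "classical", both_strands = FALSE)
  all_hits <- find_pqs(s, classes = "classical", both_strands = FALSE,
                       report_all = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_gt(nrow(all_hits), 1L)
  expect_equal(merged$start[1], min(all_hits$start))
})
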
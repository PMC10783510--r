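test_that("the CEB family maps to its three phase regimes", {
  for (r in seq_len(nrow(CEB_TABLE))) {
    call <- classify_switch(seq_record(CEB_TABLE$id[r], CEB_TABLE$seq[r]))
    expect_equal(call$regime, CEB_TABLE$regime[r], info = CEB_TABLE$id[r])
  }
})

test_that("potassium thresholds follow the calibrated ladder", {
  expect_equal(classify_switch(ceb_seq("CEBm2"))$k_threshold_mM, 15)
  expect_equal(classify_switch(ceb_seq("CEBm3"))$k_threshold_mM, 25)
  expect_equal(classify_switch(ceb_seq("CEBm4"))$k_threshold_mM, 40)
  expect_equal(classify_switch(ceb_seq("CEBwt"))$k_threshold_mM, 0)
  expect_equal(classify_switch(ceb_seq("CEBm7"))$k_threshold_mM, Inf)
})

test_that("fold predictions per buffer: CEBm4 switches at B5", {
  m4 <- classify_switch(ceb_seq("CEBm4"))
  b <- ceb_buffers()
  expect_equal(predict_fold(m4, b$B1), "Hairpin")
  expect_equal(predict_fold(m4, b$B4), "Hairpin")   # 25 mM < 40 mM
  for (nm in paste0("B", 5:9))
    expect_equal(predict_fold(m4, b[[nm]]), "G4", info = nm)
  # any G4-locked call folds G4 in every buffer, incl. potassium-free B1
  wt <- classify_switch(ceb_seq("CEBwt"))
  for (nm in names(b)) expect_equal(predict_fold(wt, nm), "G4")
  # an all-G tract sequence with no cytosines is G4-locked
  expect_equal(classify_switch("GGGTGGGTGGGTGGG")$regime, "g4_locked")
})

test_that("fold prediction is monotone in potassium", {
  set.seed(77)
  ks <- seq(0, 140, by = 5)
  for (i in 1:25) {
    call <- classify_switch(rand_dna(sample(15:40, 1)))
    folds <- vapply(ks, function(k)
      predict_fold(call, buffer_condition(140 - k, k)), character(1))
    g4 <- folds == "G4"
    expect_true(all(diff(g4) >= 0))   # Hairpin -> G4 only, never back
  }
})

test_that("adding cytosine runs never moves a call toward G4-locked", {
  rank <- c(g4_locked = 1L, switchable = 2L, hairpin_locked = 3L)
  for (r in seq_len(nrow(CEB_TABLE))) {
    base <- CEB_TABLE$seq[r]
    before <- rank[classify_switch(base)$regime]
    after <- rank[classify_switch(paste0(base, "ACCCA"))$regime]
    expect_gte(after, before)
  }
})

test_that("the named buffers match their definitions", {
  b <- ceb_buffers()
  expect_equal(length(b), 9L)
  expect_equal(c(b$B1$na_mM, b$B1$k_mM), c(140, 0))
  expect_equal(c(b$B5$na_mM, b$B5$k_mM), c(100, 40))
  expect_equal(c(b$B9$na_mM, b$B9$k_mM), c(0, 140))
  expect_error(buffer_condition(-1, 0))
})

test_that("rule tables round-trip through the plain-text config and are tunable", {
  rules <- default_rule_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_table(rules, path)
  back <- read_rule_table(path)
  expect_equal(back$ladder$k_mM, rules$ladder$k_mM)
  expect_equal(back$hairpin_min_n, rules$hairpin_min_n)

  strict <- rules
  strict$hairpin_min_n <- 2   # tighten: N = 2 already hairpin-locked
  expect_equal(classify_switch(ceb_seq("CEBm4"), strict)$regime,
               "hairpin_locked")
})

test_that("switchable calls carry the slow-kinetics caveat", {
  expect_match(classify_switch(ceb_seq("CEBm4"))$caveat, "kinetic")
  expect_true(is.na(classify_switch(ceb_seq("CEBwt"))$caveat))
})
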
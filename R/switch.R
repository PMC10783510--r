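# Three-regime phase classification of G/C-rich PQS:
#   g4_locked      G4 predominates at every Na+/K+ balance
#   switchable     hairpin at low [K+], G4 above a sequence-dependent
#                  potassium threshold
#   hairpin_locked hairpin predominates at every balance
#
# The driver is the cytosine load of the motif: the N statistic (total C/3)
# together with the maximal G-C hairpin capacity. The classifier is an
# equilibrium call; hairpin-to-G4 conversion can be kinetically very slow,
# which is attached as a caveat to switchable calls.

#' A sodium/potassium buffer condition
#'
#' @param na_mM Sodium concentration (mM), >= 0.
#' @param k_mM Potassium concentration (mM), >= 0.
#' @param label Optional name.
#' @return Object of class `buffer_condition`.
#' @export
buffer_condition <- function(na_mM, k_mM, label = NA_character_) {
  stopifnot(is.numeric(na_mM), na_mM >= 0, is.numeric(k_mM), k_mM >= 0)
  structure(list(na_mM = na_mM, k_mM = k_mM, label = label),
            class = "buffer_condition")
}

#' The nine named Na+/K+ buffers B1-B9
#'
#' B1: 140/0, B2: 135/5, B3: 125/15, B4: 115/25, B5: 100/40, B6: 80/60,
#' B7: 70/70, B8: 20/120, B9: 0/140 (mM Na+ / mM K+), all in 10 mM lithium
#' cacodylate background (not modelled).
#'
#' @return Named list of [buffer_condition()]s.
#' @export
ceb_buffers <- function() {
  na <- c(140, 135, 125, 115, 100, 80, 70, 20, 0)
  k  <- c(0, 5, 15, 25, 40, 60, 70, 120, 140)
  labs <- paste0("B", 1:9)
  stats::setNames(
    mapply(buffer_condition, na, k, labs, SIMPLIFY = FALSE), labs)
}

#' Default classification rule table
#'
#' Tunable thresholds of the phase classifier:
#' \describe{
#'   \item{g4_max_n}{largest N statistic still called G4-locked (default 1:
#'     up to one CCC's worth of cytosines barely influences G4 formation).}
#'   \item{g4_max_pairs}{hairpin capacity (G-C bp, min_loop 1) that must not
#'     be reached for a G4-locked call (default 6).}
#'   \item{hairpin_min_n}{N statistic from which the hairpin wins at every
#'     ionic balance (default 3).}
#'   \item{ladder}{calibration points mapping N to the minimum potassium
#'     (mM) at which the G4 predominates: N 4/3 -> 15 mM, 5/3 -> 25 mM,
#'     2 -> 40 mM; linear interpolation between points, linear continuation
#'     below the first point down to (g4_max_n, 0 mM) and above the last
#'     point with the final segment's slope, capped at `k_cap`.}
#'   \item{k_cap}{largest finite threshold reported (default 140 mM).}
#' }
#' The 15 mM point is low-confidence: the underlying melting profile at
#' that balance is ambiguous and is supported by thermal-difference spectra
#' only.
#'
#' @return List of class `rule_table`.
#' @export
default_rule_table <- function() {
  structure(list(
    g4_max_n = 1,
    g4_max_pairs = 6,
    hairpin_min_n = 3,
    ladder = data.frame(n = c(4 / 3, 5 / 3, 2), k_mM = c(15, 25, 40)),
    k_cap = 140), class = "rule_table")
}

#' Read / write a rule table as plain-text YAML config
#'
#' @param path Config file path.
#' @return [read_rule_table()] returns a `rule_table`;
#'   [write_rule_table()] returns `path` invisibly.
#' @export
read_rule_table <- function(path) {
  y <- yaml::read_yaml(path)
  rt <- default_rule_table()
  for (k in c("g4_max_n", "g4_max_pairs", "hairpin_min_n", "k_cap"))
    if (!is.null(y[[k]])) rt[[k]] <- as.numeric(y[[k]])
  if (!is.null(y$ladder))
    rt$ladder <- data.frame(n = as.numeric(vapply(y$ladder, `[[`, 0, "n")),
                            k_mM = as.numeric(vapply(y$ladder, `[[`, 0, "k_mM")))
  stopifnot(nrow(rt$ladder) >= 1, !is.unsorted(rt$ladder$n))
  rt
}

#' @rdname read_rule_table
#' @param rules A `rule_table`.
#' @export
write_rule_table <- function(rules, path) {
  y <- list(g4_max_n = rules$g4_max_n, g4_max_pairs = rules$g4_max_pairs,
            hairpin_min_n = rules$hairpin_min_n, k_cap = rules$k_cap,
            ladder = lapply(seq_len(nrow(rules$ladder)), function(i)
              list(n = rules$ladder$n[i], k_mM = rules$ladder$k_mM[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Potassium threshold for a switchable N, by piecewise-linear interpolation
# of the ladder; continued linearly below the first calibration point down
# to (g4_max_n, 0) and above the last with the final slope, capped.
ladder_threshold <- function(n, rules) {
  lad <- rbind(data.frame(n = rules$g4_max_n, k_mM = 0), rules$ladder)
  lad <- lad[order(lad$n), , drop = FALSE]
  if (n >= lad$n[nrow(lad)]) {
    m <- nrow(lad)
    slope <- (lad$k_mM[m] - lad$k_mM[m - 1]) / (lad$n[m] - lad$n[m - 1])
    k <- lad$k_mM[m] + slope * (n - lad$n[m])
  } else {
    k <- stats::approx(lad$n, lad$k_mM, xout = n, ties = "ordered")$y
  }
  min(k, rules$k_cap)
}

#' Classify a sequence into a phase regime
#'
#' Computes the features (cytosine-run profile, maximal G-C hairpin
#' capacity at min_loop 1, classic G4Hunter score) and assigns one of the
#' three regimes, with the minimum potassium concentration at which the G4
#' is predicted to predominate (0 for G4-locked, Inf for hairpin-locked).
#'
#' Either pass a sequence/`seq_record` (features computed internally) or
#' supply precomputed features via `profile`, `fold` and `score`.
#'
#' @param record A `seq_record`, DNA string, or a single PQS hit row from
#'   [find_pqs()] (its motif-strand `sequence` is used).
#' @param rules A rule table (see [default_rule_table()]).
#' @param profile,fold,score Optional precomputed [c_profile()],
#'   [max_hairpin_pairs()] and [score_bases()] on the same sequence.
#' @return Object of class `switch_call`: `regime`, `k_threshold_mM`,
#'   `drivers` (n_stat, ccc_runs, max_gc_pairs, g4hunter), `caveat`
#'   (non-NA for switchable calls: conversion kinetics can be very slow).
#' @examples
#' classify_switch("AAGGGTGGGTGTAAGTGTGGGTGGGT")$regime  # "g4_locked"
#' @export
classify_switch <- function(record, rules = default_rule_table(),
                            profile = NULL, fold = NULL, score = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L, !is.null(record$sequence))
    record <- seq_record(paste0(record$seqid, ":", record$start, "-",
                                record$end, "(", record$strand, ")"),
                         record$sequence)
  }
  record <- as_seq_record(record)
  if (is.null(profile)) profile <- c_profile(record)
  if (is.null(fold)) fold <- max_hairpin_pairs(record, min_loop = 1L)
  if (is.null(score)) score <- score_bases(record)
  n <- profile$n_stat_exact
  drivers <- list(n_stat = profile$n_stat, ccc_runs = profile$ccc_runs,
                  max_gc_pairs = fold$max_pairs,
                  g4hunter = score$mean_score)
  if (n >= rules$hairpin_min_n) {
    regime <- "hairpin_locked"; k <- Inf
  } else if (n <= rules$g4_max_n && fold$max_pairs < rules$g4_max_pairs) {
    regime <- "g4_locked"; k <- 0
  } else {
    regime <- "switchable"
    k <- ladder_threshold(n, rules)
  }
  structure(list(id = record$id, regime = regime, k_threshold_mM = k,
                 drivers = drivers,
                 caveat = if (regime == "switchable")
                   paste("equilibrium call: hairpin-to-G4 conversion can be",
                         "kinetically slow (hours to days), the pre-formed",
                         "hairpin acting as a kinetic trap")
                 else NA_character_),
            class = "switch_call")
}

#' @export
print.switch_call <- function(x, ...) {
  cat("<switch_call> ", x$id, ": ", x$regime,
      if (is.finite(x$k_threshold_mM) && x$k_threshold_mM > 0)
        paste0(" (G4 from [K+] >= ", format(round(x$k_threshold_mM, 1)),
               " mM)"),
      "\n  drivers: N ", format_score(x$drivers$n_stat),
      ", CCC runs ", x$drivers$ccc_runs,
      ", hairpin capacity ", x$drivers$max_gc_pairs,
      " bp, G4Hunter ", format_score(x$drivers$g4hunter), "\n", sep = "")
  if (!is.na(x$caveat)) cat("  caveat: ", x$caveat, "\n", sep = "")
  invisible(x)
}

#' Predict the predominant fold in a buffer
#'
#' G4 if and only if the buffer's potassium concentration reaches the
#' call's threshold; hairpin otherwise. Monotone in K+: increasing
#' potassium can switch Hairpin -> G4 but never the reverse.
#'
#' @param call A `switch_call` from [classify_switch()].
#' @param buffer A [buffer_condition()] or a name from [ceb_buffers()].
#' @return `"G4"` or `"Hairpin"`.
#' @examples
#' call <- classify_switch("AAGGGTGGGTCCCACCCTGGGTGGGT")
#' predict_fold(call, "B1")  # "Hairpin"
#' predict_fold(call, "B9")  # "G4"
#' @export
predict_fold <- function(call, buffer) {
  stopifnot(inherits(call, "switch_call"))
  if (is.character(buffer)) buffer <- ceb_buffers()[[buffer]]
  stopifnot(inherits(buffer, "buffer_condition"))
  if (buffer$k_mM >= call$k_threshold_mM) "G4" else "Hairpin"
}

#' Classification table for a set of records
#'
#' @param records List of `seq_record`s.
#' @param rules A rule table.
#' @param buffers Optional named list of buffers; adds one prediction
#'   column per buffer.
#' @return data.frame: id, regime, k_threshold_mM, driver columns, and
#'   per-buffer fold predictions when requested.
#' @export
classify_table <- function(records, rules = default_rule_table(),
                           buffers = NULL) {
  if (inherits(records, "seq_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    cl <- classify_switch(rec, rules)
    row <- data.frame(id = cl$id, regime = cl$regime,
                      k_threshold_mM = cl$k_threshold_mM,
                      n_stat = cl$drivers$n_stat,
                      ccc_runs = cl$drivers$ccc_runs,
                      max_gc_pairs = cl$drivers$max_gc_pairs,
                      g4hunter = round_half_away(cl$drivers$g4hunter))
    for (b in names(buffers)) row[[b]] <- predict_fold(cl, buffers[[b]])
    row
  })
  do.call(rbind, rows)
}
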
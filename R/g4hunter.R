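#' Define a G4Hunter scoring scheme
#'
#' The classic rule scores each G in a maximal G-run of length L as
#' +min(L, cap) and each C in a maximal C-run of length L as -min(L, cap),
#' with cap = 4; A, T and N score 0. The soft variant keeps every rule but
#' replaces the per-cytosine penalty inside C-runs of length >= 3 by a fixed
#' magnitude `soft_penalty` (runs of one or two cytosines keep -1/-2),
#' reflecting the view that the classic -3 overweights hairpin competition.
#'
#' @param mode `"classic"` or `"soft"`.
#' @param soft_penalty Positive magnitude applied per C in any C-run of
#'   length >= 3 when `mode = "soft"`; must lie in (0, 4]. Ignored by the
#'   classic mode. Values of 2 and 1.5 are the recalibrations of interest.
#' @param g_run_cap Maximum per-base score magnitude (default 4).
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("soft", soft_penalty = 1.5)
#' @export
scoring_scheme <- function(mode = c("classic", "soft"), soft_penalty = 2,
                           g_run_cap = 4L) {
  mode <- match.arg(mode)
  if (mode == "soft") {
    stopifnot(is.numeric(soft_penalty), length(soft_penalty) == 1L)
    if (soft_penalty <= 0 || soft_penalty > 4)
      stop("soft_penalty must lie in (0, 4]")
  }
  structure(list(mode = mode,
                 soft_penalty = if (mode == "soft") soft_penalty else NA_real_,
                 g_run_cap = as.integer(g_run_cap)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$mode,
      if (x$mode == "soft") paste0(" (C-run penalty ", x$soft_penalty, ")"),
      ", run cap ", x$g_run_cap, "\n", sep = "")
  invisible(x)
}

# Shorthand parser used by the CLI: "classic", "soft:2", "soft:1.5".
parse_scheme <- function(spec) {
  if (identical(spec, "classic")) return(scoring_scheme("classic"))
  m <- regmatches(spec, regexec("^soft:([0-9.]+)$", spec))[[1]]
  if (length(m) == 2L)
    return(scoring_scheme("soft", soft_penalty = as.numeric(m[2])))
  stop("unknown scheme '", spec, "' (use classic, soft:2, soft:1.5, ...)")
}

#' Per-base G4Hunter scores
#'
#' Computes the signed per-base score vector and its arithmetic mean (the
#' G4Hunter score) for one sequence. A pure, deterministic function of the
#' sequence and the scheme.
#'
#' @param record A `seq_record` or DNA string.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `base_scores`: list with `scores` (numeric,
#'   one per base), `mean_score` (full precision), `scheme` and `record`.
#' @examples
#' bs <- score_bases("GGGTGGG", scoring_scheme("classic"))
#' bs$mean_score
#' @export
score_bases <- function(record, scheme = scoring_scheme("classic")) {
  record <- as_seq_record(record)
  stopifnot(inherits(scheme, "scoring_scheme"))
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  cap <- scheme$g_run_cap
  per_run <- numeric(length(r$lengths))
  gsel <- r$values == "G"
  csel <- r$values == "C"
  per_run[gsel] <- pmin(r$lengths[gsel], cap)
  per_run[csel] <- -pmin(r$lengths[csel], cap)
  if (scheme$mode == "soft") {
    soften <- csel & r$lengths >= 3L
    per_run[soften] <- -scheme$soft_penalty
  }
  scores <- rep(per_run, r$lengths)
  structure(list(scores = scores,
                 mean_score = sum(scores) / record$length,
                 scheme = scheme,
                 record = record),
            class = "base_scores")
}

#' @export
print.base_scores <- function(x, ...) {
  cat("<base_scores> ", x$record$id, ": mean ",
      format_score(x$mean_score), " (", x$scheme$mode, ", ",
      x$record$length, " nt)\n", sep = "")
  invisible(x)
}

#' G4Hunter score of a sequence
#'
#' Convenience accessor returning the mean per-base score only. The mean is
#' returned at full precision; presentation rounding (2 decimals, half away
#' from zero) is done by [format_score()].
#'
#' @inheritParams score_bases
#' @return Numeric scalar, the signed mean score.
#' @examples
#' g4hunter_score("AAGGGTGGGTGTAAGTGTGGGTGGGT")  # 39/26 = 1.5
#' @export
g4hunter_score <- function(record, scheme = scoring_scheme("classic")) {
  score_bases(record, scheme)$mean_score
}

#' Round a score half away from zero
#'
#' Presentation rounding used throughout: 2 decimals, ties rounded away from
#' zero (so 1.125 prints as 1.13 and -1.125 as -1.13), matching how the
#' oligo-family reference scores are printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Formatted presentation of a score (trailing zeros kept: 1.50 not 1.5).
format_score <- function(x, digits = 2L) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

#' Sliding-window G4Hunter scan
#'
#' Scores every window of a sequence and flags windows whose absolute mean
#' meets a threshold. Positive-mean windows are forward-strand candidates;
#' negative-mean windows carry the motif on the reverse strand (C-runs on
#' the forward strand). Coordinates are 0-based half-open on the forward
#' strand.
#'
#' @inheritParams score_bases
#' @param window Window size in nt; must satisfy 1 <= window <= length.
#' @param step Step between window starts in nt (default 1).
#' @param threshold Absolute mean score at or above which a window is
#'   flagged (default 1.2, conventional genome-scan practice).
#' @return An object of class `window_scan`: list with `windows` (data.frame
#'   of start, end, score), `hits` (flagged subset with strand), plus the
#'   scan parameters.
#' @export
window_scan <- function(record, scheme = scoring_scheme("classic"),
                        window = 25L, step = 1L, threshold = 1.2) {
  record <- as_seq_record(record)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || window > record$length)
    stop("window must lie in [1, ", record$length, "], got ", window)
  if (step < 1L) stop("step must be >= 1")
  bs <- score_bases(record, scheme)
  cs <- cumsum(c(0, bs$scores))
  starts <- seq.int(1L, record$length - window + 1L, by = step)
  ends <- starts + window - 1L
  sums <- cs[ends + 1L] - cs[starts]
  # each window is scored as a standalone subsequence: a G/C run truncated
  # by the window boundary scores by its length inside the window, so the
  # whole-sequence run sums need a boundary correction
  r <- rle(strsplit(record$seq, "", fixed = TRUE)[[1]])
  rs <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  re <- rs + r$lengths - 1L
  val <- function(v, L) {
    out <- numeric(length(L))
    g <- v == "G"; c_ <- v == "C"
    out[g] <- pmin(L[g], scheme$g_run_cap)
    out[c_] <- -pmin(L[c_], scheme$g_run_cap)
    if (scheme$mode == "soft") {
      soft <- c_ & L >= 3L
      out[soft] <- -scheme$soft_penalty
    }
    out
  }
  li <- findInterval(starts, rs)
  ri <- findInterval(ends, rs)
  gc_run <- r$values %in% c("G", "C")
  one <- li == ri                       # a single run spans the window
  fix1 <- one & gc_run[li]
  sums[fix1] <- window * val(r$values[li[fix1]], rep(window, sum(fix1)))
  lt <- !one & gc_run[li] & rs[li] < starts
  if (any(lt)) {
    inside <- re[li[lt]] - starts[lt] + 1L
    v <- r$values[li[lt]]; L <- r$lengths[li[lt]]
    sums[lt] <- sums[lt] + inside * (val(v, inside) - val(v, L))
  }
  rt <- !one & gc_run[ri] & re[ri] > ends
  if (any(rt)) {
    inside <- ends[rt] - rs[ri[rt]] + 1L
    v <- r$values[ri[rt]]; L <- r$lengths[ri[rt]]
    sums[rt] <- sums[rt] + inside * (val(v, inside) - val(v, L))
  }
  means <- sums / window
  windows <- data.frame(start = starts - 1L, end = starts - 1L + window,
                        score = means)
  flagged <- abs(means) >= threshold
  hits <- windows[flagged, , drop = FALSE]
  hits$strand <- ifelse(hits$score >= 0, "+", "-")
  rownames(hits) <- NULL
  structure(list(id = record$id, windows = windows, hits = hits,
                 window = window, step = step, threshold = threshold,
                 scheme = scheme),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat("<window_scan> ", x$id, ": ", nrow(x$windows), " windows of ",
      x$window, " nt (step ", x$step, "), ", nrow(x$hits),
      " flagged at |mean| >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Score a set of records into a TSV-ready table
#'
#' @param records List of `seq_record`s (e.g. from [read_fasta()]).
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns id, length, scheme, score (rounded to 2
#'   decimals for presentation), plus the C-run columns total_c, n_stat,
#'   ccc_runs.
#' @export
score_table <- function(records, scheme = scoring_scheme("classic")) {
  if (inherits(records, "seq_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    rec <- as_seq_record(rec)
    pr <- c_profile(rec)
    data.frame(id = rec$id, length = rec$length,
               scheme = if (scheme$mode == "soft")
                 paste0("soft:", scheme$soft_penalty) else "classic",
               score = round_half_away(g4hunter_score(rec, scheme)),
               total_c = pr$total_c, n_stat = pr$n_stat,
               ccc_runs = pr$ccc_runs)
  })
  do.call(rbind, rows)
}
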
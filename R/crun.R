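#' Cytosine-run profile of a sequence
#'
#' Decomposes a sequence into maximal runs of consecutive cytosines and
#' derives two distinct statistics that are easy to conflate:
#' \describe{
#'   \item{n_stat}{total cytosines divided by 3 — the per-oligo N statistic
#'     (a fractional "number of CCC motifs"), reported to 2 decimals.}
#'   \item{ccc_runs}{the count of discrete maximal C-runs of length >= 3 —
#'     the census criterion ("at least one run of three consecutive
#'     cytosines").}
#' }
#' `n_stat` is invariant under any composition-preserving shuffle of the
#' sequence; `ccc_runs` is not.
#'
#' @param record A `seq_record` or DNA string.
#' @return An object of class `crun_profile`: list with `runs` (data.frame
#'   of 0-based `start` and `length` for every maximal C-run), `total_c`,
#'   `n_stat` (2 decimals, half away from zero), `n_stat_exact`, `ccc_runs`.
#' @examples
#' c_profile("AAGGGTGGGTCCCACTGTGGGTGGGT")$n_stat  # 4/3 -> 1.33
#' @export
c_profile <- function(record) {
  record <- as_seq_record(record)
  m <- gregexpr("C+", record$seq)[[1]]
  if (m[1] == -1L) {
    runs <- data.frame(start = integer(0), length = integer(0))
  } else {
    runs <- data.frame(start = as.integer(m) - 1L,
                       length = attr(m, "match.length"))
  }
  total_c <- sum(runs$length)
  structure(list(runs = runs,
                 total_c = total_c,
                 n_stat = round_half_away(total_c / 3),
                 n_stat_exact = total_c / 3,
                 ccc_runs = sum(runs$length >= 3L)),
            class = "crun_profile")
}

#' @export
print.crun_profile <- function(x, ...) {
  cat("<crun_profile> ", nrow(x$runs), " C-run(s), total C ", x$total_c,
      ", N ", format_score(x$n_stat), ", CCC runs ", x$ccc_runs, "\n",
      sep = "")
  invisible(x)
}

#' Flag C-runs that can pair with a G-tract
#'
#' Each maximal C-run of length >= 3 is flagged TRUE when some G-run of
#' length >= 3 exists elsewhere in the sequence, i.e. the run could form
#' three consecutive G-C base pairs with a neighboring G-tract. Inside a
#' valid PQS this is always TRUE (four G-tracts are present by definition);
#' the flag exists for arbitrary-sequence mode.
#'
#' @param record A `seq_record` or DNA string (typically a PQS hit slice).
#' @param profile Optional precomputed [c_profile()] of the same sequence.
#' @return data.frame with the C-runs of length >= 3 (0-based start,
#'   length) and a logical `can_pair` column.
#' @examples
#' pairing_capacity_flags("CCCAAAGGG")$can_pair  # TRUE
#' @export
pairing_capacity_flags <- function(record, profile = c_profile(record)) {
  record <- as_seq_record(record)
  has_g_tract <- grepl("GGG", record$seq, fixed = TRUE)
  runs <- profile$runs[profile$runs$length >= 3L, , drop = FALSE]
  runs$can_pair <- rep(has_g_tract, nrow(runs))
  rownames(runs) <- NULL
  runs
}
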
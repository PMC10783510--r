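# Maximal intramolecular base pairing (hairpin capacity).
#
# Nussinov-style maximum-cardinality dynamic program over nested
# (non-crossing) pairings, restricted to Watson-Crick G-C pairs (optionally
# also A-T), with a minimum hairpin loop length. Pair counting only: no
# nearest-neighbor thermodynamics, no pseudoknots, no G-T wobble.

pair_ok <- function(a, b, count_at) {
  (a == "G" & b == "C") | (a == "C" & b == "G") |
    (count_at & ((a == "A" & b == "T") | (a == "T" & b == "A")))
}

#' Maximal nested G-C pairing of a sequence
#'
#' Computes the maximum number of intramolecular base pairs formable under
#' nested (non-crossing) pairing with a minimum loop length, with a
#' deterministic traceback to an explicit pair list and dot-bracket string.
#' With `min_loop = 1` the result is a base-pairing *capacity* (how many G-C
#' pairs the sequence could ever contribute to a stem); `min_loop = 3` is
#' the sterically realistic default for fold reports.
#'
#' Among co-optimal solutions the traceback pairs the outermost compatible
#' positions first: the leftmost unpaired base is paired with the farthest
#' partner that still achieves the optimum.
#'
#' @param record A `seq_record` or DNA string.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (j - i - 1 >= min_loop); must be >= 1.
#' @param count_at Also allow A-T pairs (default FALSE: G-C only).
#' @return Object of class `hairpin_fold`: list with `max_pairs`, `pairs`
#'   (two-column matrix of 1-based i < j), `dot_bracket`, `min_loop`,
#'   `count_at`, `record`.
#' @examples
#' max_hairpin_pairs("GGGAAACCC", min_loop = 3)$dot_bracket  # "(((...)))"
#' @export
max_hairpin_pairs <- function(record, min_loop = 3L, count_at = FALSE) {
  record <- as_seq_record(record)
  min_loop <- as.integer(min_loop)
  if (min_loop < 1L) stop("min_loop must be >= 1")
  s <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (n >= min_loop + 2L) {
    N <- matrix(0L, n, n)
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i + 1L, j]
        ks <- (i + min_loop + 1L):j
        ks <- ks[pair_ok(s[i], s[ks], count_at)]
        for (k in ks) {
          v <- 1L + (if (k - i >= 2L) N[i + 1L, k - 1L] else 0L) +
            (if (k < j) N[k + 1L, j] else 0L)
          if (v > best) best <- v
        }
        N[i, j] <- best
      }
    }
    # iterative traceback, outermost-first tie-break
    stack <- list(c(1L, n))
    acc <- list()
    while (length(stack)) {
      iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      while (i < j && j - i >= min_loop + 1L) {
        target <- N[i, j]
        if (target == 0L) break
        paired <- FALSE
        for (k in j:(i + min_loop + 1L)) {     # farthest partner first
          if (!pair_ok(s[i], s[k], count_at)) next
          inner <- if (k - i >= 2L) N[i + 1L, k - 1L] else 0L
          outer <- if (k < j) N[k + 1L, j] else 0L
          if (1L + inner + outer == target) {
            acc[[length(acc) + 1L]] <- c(i, k)
            if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
            j <- k - 1L; i <- i + 1L
            paired <- TRUE
            break
          }
        }
        if (!paired) i <- i + 1L
      }
    }
    if (length(acc)) {
      pairs <- do.call(rbind, acc)
      colnames(pairs) <- c("i", "j")
      pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    }
  }
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  structure(list(max_pairs = nrow(pairs),
                 pairs = pairs,
                 dot_bracket = paste(db, collapse = ""),
                 min_loop = min_loop, count_at = count_at,
                 record = record),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("<hairpin_fold> ", x$record$id, ": ", x$max_pairs,
      if (x$count_at) " WC pairs" else " G-C pairs",
      " (min_loop ", x$min_loop, ")\n  ", x$record$seq, "\n  ",
      x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Decompose a fold into stems, loops and dangling ends
#'
#' Purely descriptive decomposition of a pairing: stems are maximal runs of
#' stacked pairs ((i,j), (i+1,j-1), ...); a stem whose interior contains no
#' further pair closes a hairpin loop whose size is reported; dangling ends
#' are the unpaired 5' prefix and 3' suffix.
#'
#' @param fold A `hairpin_fold` from [max_hairpin_pairs()].
#' @return List of class `stem_report`: `stems` (data.frame with outer/inner
#'   coordinates and `length` in bp), `hairpin_loops` (data.frame of loop
#'   start/end/size for terminal stems), `dangle5`, `dangle3` (nt).
#' @export
stem_report <- function(fold) {
  stopifnot(inherits(fold, "hairpin_fold"))
  p <- fold$pairs
  n <- fold$record$length
  if (nrow(p) == 0L)
    return(structure(list(stems = data.frame(), hairpin_loops = data.frame(),
                          dangle5 = n, dangle3 = 0L),
                     class = "stem_report"))
  p <- p[order(p[, 1]), , drop = FALSE]
  key <- paste(p[, 1], p[, 2])
  stems <- list(); used <- rep(FALSE, nrow(p))
  for (r in seq_len(nrow(p))) {
    if (used[r]) next
    i <- p[r, 1]; j <- p[r, 2]; len <- 1L
    used[r] <- TRUE
    repeat {
      nxt <- match(paste(i + len, j - len), key)
      if (is.na(nxt) || used[nxt]) break
      used[nxt] <- TRUE; len <- len + 1L
    }
    stems[[length(stems) + 1L]] <-
      data.frame(outer_i = i, outer_j = j,
                 inner_i = i + len - 1L, inner_j = j - len + 1L,
                 length = len)
  }
  stems <- do.call(rbind, stems)
  # hairpin loop: innermost pair of a stem with no pair strictly inside
  loops <- list()
  for (r in seq_len(nrow(stems))) {
    ii <- stems$inner_i[r]; jj <- stems$inner_j[r]
    inside <- p[, 1] > ii & p[, 2] < jj
    if (!any(inside))
      loops[[length(loops) + 1L]] <-
        data.frame(start = ii + 1L, end = jj - 1L, size = jj - ii - 1L)
  }
  structure(list(stems = stems,
                 hairpin_loops = if (length(loops)) do.call(rbind, loops)
                                 else data.frame(),
                 dangle5 = min(p[, 1]) - 1L,
                 dangle3 = n - max(p[, 2])),
            class = "stem_report")
}

#' @export
print.stem_report <- function(x, ...) {
  cat("<stem_report> ", nrow(x$stems), " stem(s); 5' dangle ", x$dangle5,
      " nt, 3' dangle ", x$dangle3, " nt\n", sep = "")
  if (nrow(x$stems))
    for (r in seq_len(nrow(x$stems)))
      cat("  stem ", r, ": ", x$stems$length[r], " bp [",
          x$stems$outer_i[r], "-", x$stems$inner_i[r], " : ",
          x$stems$inner_j[r], "-", x$stems$outer_j[r], "]\n", sep = "")
  if (nrow(x$hairpin_loops))
    for (r in seq_len(nrow(x$hairpin_loops)))
      cat("  hairpin loop: ", x$hairpin_loops$size[r], " nt\n", sep = "")
  invisible(x)
}
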
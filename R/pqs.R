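# Putative quadruplex sequence (PQS) detection.
#
# Motif grammar, four classes:
#   classical : four G-tracts of >= 3 G, all three loops 1-7 nt
#   long_loop : exactly one loop 8-15 nt, the other two 1-7 nt
#   bulged    : exactly one tract is a G-triplet split by a single 1-7 nt
#               non-G bulge (G.GG or GG.G), other three tracts intact
#   vacancy   : exactly one tract has only GG, other three >= 3 G, loops 1-7
#
# Matching is greedy shortest (lazy quantifiers): minimal tracts, minimal
# loops, leftmost anchor. Class precedence classical > long_loop > bulged >
# vacancy resolves loci that satisfy several classes.

PQS_CLASSES <- c("classical", "long_loop", "bulged", "vacancy")

# Build the per-class list of PCRE variants, each with exactly 7 capture
# groups: tract1, loop1, tract2, loop2, tract3, loop3, tract4.
pqs_patterns <- function() {
  tr <- "(G{3,}?)"                    # intact tract, lazy
  ls <- "([ACGTN]{1,7}?)"             # short loop, lazy
  ll <- "([ACGTN]{8,15}?)"            # long loop, lazy
  bu <- c("(G[ACTN]{1,7}?GG)", "(GG[ACTN]{1,7}?G)")  # split G-triplet
  va <- "((?<!G)GG(?!G))"             # two-G tract, not part of a longer run
  glue <- function(t1, l1, t2, l2, t3, l3, t4)
    paste0(t1, l1, t2, l2, t3, l3, t4)
  long_loop <- lapply(1:3, function(i) {
    loops <- rep(ls, 3); loops[i] <- ll
    glue(tr, loops[1], tr, loops[2], tr, loops[3], tr)
  })
  bulged <- unlist(lapply(1:4, function(i) {
    lapply(bu, function(b) {
      tracts <- rep(tr, 4); tracts[i] <- b
      glue(tracts[1], ls, tracts[2], ls, tracts[3], ls, tracts[4])
    })
  }))
  vacancy <- lapply(1:4, function(i) {
    tracts <- rep(tr, 4); tracts[i] <- va
    glue(tracts[1], ls, tracts[2], ls, tracts[3], ls, tracts[4])
  })
  list(classical = list(glue(tr, ls, tr, ls, tr, ls, tr)),
       long_loop = long_loop,
       bulged = as.list(bulged),
       vacancy = vacancy)
}

# Does `seq` as a whole exactly satisfy a motif class?
#' Test whether a sequence exactly matches a PQS motif class
#'
#' Anchored re-match of the full string against the class grammar; used as
#' the self-check that every reported hit's slice satisfies its class.
#'
#' @param seq DNA string (motif-strand orientation).
#' @param class One of `"classical"`, `"long_loop"`, `"bulged"`, `"vacancy"`.
#' @return Logical scalar.
#' @export
pqs_class_matches <- function(seq, class) {
  class <- match.arg(class, PQS_CLASSES)
  pats <- pqs_patterns()[[class]]
  any(vapply(pats, function(p)
    grepl(paste0("^", p, "$"), seq, perl = TRUE), logical(1)))
}

# All matches of one variant in seq. Non-overlapping leftmost via gregexpr;
# all anchors when report_all.
match_variant <- function(seq, pattern, report_all = FALSE) {
  out <- list()
  if (!report_all) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(out)
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (k in seq_along(m)) {
      out[[length(out) + 1L]] <- list(
        start = as.integer(m[k]),
        len = attr(m, "match.length")[k],
        grp_start = cs[k, ], grp_len = cl[k, ])
    }
  } else {
    anch <- paste0("^", pattern)
    n <- nchar(seq)
    for (off in seq_len(n)) {
      sub <- substr(seq, off, n)
      m <- regexpr(anch, sub, perl = TRUE)
      if (m == 1L) {
        cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
        out[[length(out) + 1L]] <- list(
          start = off, len = attr(m, "match.length"),
          grp_start = as.integer(cs) + off - 1L, grp_len = as.integer(cl))
      }
    }
  }
  out
}

# One strand, one class -> data.frame of raw candidate hits (1-based coords
# on the scanned string, local tract/loop decomposition attached).
scan_class <- function(seq, class, report_all = FALSE) {
  cands <- list()
  for (pat in pqs_patterns()[[class]]) {
    for (m in match_variant(seq, pat, report_all)) {
      local0 <- m$grp_start - m$start            # 0-based within hit
      tracts <- data.frame(start = local0[c(1, 3, 5, 7)],
                           end = local0[c(1, 3, 5, 7)] + m$grp_len[c(1, 3, 5, 7)])
      loops <- data.frame(start = local0[c(2, 4, 6)],
                          end = local0[c(2, 4, 6)] + m$grp_len[c(2, 4, 6)])
      loops$length <- loops$end - loops$start
      cands[[length(cands) + 1L]] <- list(start = m$start, len = m$len,
                                          tracts = tracts, loops = loops)
    }
  }
  if (!length(cands)) return(cands)
  ord <- order(vapply(cands, `[[`, 0L, "start"),
               vapply(cands, `[[`, 0L, "len"))
  cands <- cands[ord]
  if (report_all) return(cands)
  # leftmost-shortest greedy, merge overlapping same-class candidates
  kept <- list(); last_end <- 0L
  for (cn in cands) {
    if (cn$start > last_end) {
      kept[[length(kept) + 1L]] <- cn
      last_end <- cn$start + cn$len - 1L
    }
  }
  kept
}

hits_df <- function(seqid, cands, class, strand, seqlen, scanned) {
  if (!length(cands)) return(empty_hits())
  start1 <- vapply(cands, `[[`, 0L, "start")
  len <- vapply(cands, `[[`, 0L, "len")
  s0 <- start1 - 1L; e0 <- s0 + len            # on scanned strand
  if (strand == "-") {                         # map to forward coords
    fs <- seqlen - e0; fe <- seqlen - s0
  } else {
    fs <- s0; fe <- e0
  }
  df <- data.frame(seqid = seqid, start = fs, end = fe, width = len,
                   strand = strand, class = class,
                   sequence = substring(scanned, start1, start1 + len - 1L),
                   stringsAsFactors = FALSE)
  df$tracts <- I(lapply(cands, `[[`, "tracts"))
  df$loops <- I(lapply(cands, `[[`, "loops"))
  df
}

empty_hits <- function() {
  df <- data.frame(seqid = character(0), start = integer(0),
                   end = integer(0), width = integer(0),
                   strand = character(0), class = character(0),
                   sequence = character(0), stringsAsFactors = FALSE)
  df$tracts <- I(list()); df$loops <- I(list())
  df
}

#' Find putative quadruplex sequences
#'
#' Scans a sequence for PQS of the requested motif classes on one or both
#' strands. Hits are reported leftmost-first; within one anchor the greedy
#' rule takes the shortest hit satisfying the class (minimal loops, minimal
#' tracts); overlapping same-class hits are merged into the leftmost
#' representative unless `report_all`; a locus satisfying several classes is
#' assigned by precedence classical > long_loop > bulged > vacancy. A
#' minus-strand hit is a C-motif on the forward strand whose reverse
#' complement satisfies the class; its `sequence` and tract/loop
#' decomposition are given on the motif (G-rich) strand, tract/loop
#' coordinates 0-based within the hit.
#'
#' @param record A `seq_record` or DNA string.
#' @param classes Character vector of classes to search (default all four).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param report_all Report every overlapping match instead of merging
#'   same-class overlaps (class precedence still applies).
#' @return data.frame with columns seqid, start, end (0-based half-open,
#'   forward strand), width, strand, class, sequence, and list-columns
#'   `tracts` and `loops`.
#' @examples
#' find_pqs("GGGTGGGTGGGTGGG", both_strands = FALSE)$class  # "classical"
#' @export
find_pqs <- function(record, classes = PQS_CLASSES, both_strands = TRUE,
                     report_all = FALSE) {
  record <- as_seq_record(record)
  classes <- match.arg(classes, PQS_CLASSES, several.ok = TRUE)
  classes <- PQS_CLASSES[PQS_CLASSES %in% classes]   # precedence order
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    scanned <- if (st == "+") record$seq else revcomp(record$seq)
    accepted <- empty_hits()
    for (cl in classes) {
      cands <- scan_class(scanned, cl, report_all)
      df <- hits_df(record$id, cands, cl, st, record$length, scanned)
      if (nrow(df) && nrow(accepted)) {
        # precedence: drop hits overlapping an accepted higher class
        keep <- vapply(seq_len(nrow(df)), function(i)
          !any(df$start[i] < accepted$end & accepted$start < df$end[i]),
          logical(1))
        df <- df[keep, , drop = FALSE]
      }
      accepted <- rbind(accepted, df)
    }
    out[[st]] <- accepted
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Census of PQS hits and their cytosine runs
#'
#' Summarizes a hit table: totals per motif class, how many hits carry at
#' least one (and at least `n_threshold`) runs of three consecutive
#' cytosines in their motif-strand slice, and the hit frequency per 1000 bp
#' of scanned sequence. When an annotation is supplied (BED/GFF path or a
#' `GRanges`), a per-feature-type overlap breakdown is appended.
#'
#' @param hits Hit table from [find_pqs()].
#' @param records The records the hits were computed on (for total bases).
#' @param n_threshold Stringency for the `ccc_ge_n` count (default 2).
#' @param use_n_stat Filter on the fractional N statistic (total C / 3)
#'   instead of the discrete CCC-run count.
#' @param annotation Optional BED/GFF3 file path or `GRanges` of features;
#'   feature labels are taken from the annotation's feature/name column.
#' @return List of class `pqs_census`: `n_hits`, `by_class`, `ccc_ge_1`,
#'   `ccc_ge_n`, `n_threshold`, `total_bases`, `freq_per_kb`, and
#'   `by_feature` (NULL without annotation).
#' @export
pqs_census <- function(hits, records, n_threshold = 2, use_n_stat = FALSE,
                       annotation = NULL) {
  if (inherits(records, "seq_record")) records <- list(records)
  total_bases <- sum(vapply(records, `[[`, 0L, "length"))
  stat <- if (nrow(hits) == 0) numeric(0) else
    vapply(hits$sequence, function(s) {
      pr <- c_profile(s)
      if (use_n_stat) pr$n_stat_exact else pr$ccc_runs
    }, numeric(1), USE.NAMES = FALSE)
  by_feature <- NULL
  if (!is.null(annotation) && nrow(hits) > 0) {
    feat <- if (inherits(annotation, "GRanges")) annotation
            else rtracklayer::import(annotation)
    if (!any(as.character(GenomicRanges::seqnames(feat)) %in% hits$seqid)) {
      warning("annotation chromosome names do not match hits; ",
              "feature breakdown skipped")
    } else {
      hr <- GenomicRanges::GRanges(hits$seqid,
              IRanges::IRanges(hits$start + 1L, hits$end))
      labels <- if (!is.null(feat$type)) as.character(feat$type)
                else if (!is.null(feat$name)) as.character(feat$name)
                else rep("feature", length(feat))
      ov <- GenomicRanges::findOverlaps(hr, feat)
      by_feature <- table(labels[S4Vectors::subjectHits(ov)])
    }
  }
  structure(list(
    n_hits = nrow(hits),
    by_class = if (nrow(hits)) table(hits$class) else table(character(0)),
    ccc_ge_1 = sum(stat >= 1),
    ccc_ge_n = sum(stat >= n_threshold),
    n_threshold = n_threshold,
    use_n_stat = use_n_stat,
    total_bases = total_bases,
    freq_per_kb = nrow(hits) / total_bases * 1000,
    by_feature = by_feature), class = "pqs_census")
}

#' @export
print.pqs_census <- function(x, ...) {
  cat("<pqs_census> ", x$n_hits, " PQS over ", x$total_bases, " bp (",
      format(round(x$freq_per_kb, 3)), " per 1000 bp)\n", sep = "")
  if (length(x$by_class))
    cat("  by class: ",
        paste(names(x$by_class), as.integer(x$by_class),
              sep = "=", collapse = ", "), "\n", sep = "")
  lab <- if (x$use_n_stat) "N" else "CCC runs"
  cat("  with ", lab, " >= 1: ", x$ccc_ge_1, "; with ", lab, " >= ",
      x$n_threshold, ": ", x$ccc_ge_n, "\n", sep = "")
  if (!is.null(x$by_feature))
    cat("  by feature: ",
        paste(names(x$by_feature), as.integer(x$by_feature),
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write PQS hits (or truth intervals) as BED6
#'
#' Columns: chrom, start, end, name (motif class), score (classic G4Hunter
#' score of the motif-strand slice x 100, rounded), strand.
#'
#' @param hits Hit table from [find_pqs()] (or any data.frame with seqid,
#'   start, end, class, strand; score recomputed from `sequence` if present).
#' @param path Output path; `""` writes to stdout.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  score <- if (!is.null(hits$sequence) && nrow(hits))
    round(vapply(hits$sequence, g4hunter_score, 0, USE.NAMES = FALSE) * 100)
  else rep(0L, nrow(hits))
  bed <- data.frame(hits$seqid, hits$start, hits$end, hits$class,
                    as.integer(score), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
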
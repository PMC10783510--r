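# Deterministic fixtures: the CEB25 oligonucleotide mutant family and
# planted-motif synthetic genomes.

#' The CEB25 oligonucleotide family
#'
#' Programmatically constructs CEBwt (the human minisatellite CEB25
#' G-quadruplex with a 9-nt central loop) and its nine mutants by
#' substituting the variable part of the central loop (positions 11-18)
#' and, for the longer members, appending 3' cytosine-run extensions:
#' \tabular{ll}{
#'   CEBwt \tab parent, loop GTAAGTGT \cr
#'   CEBm0A/CEBm0T \tab loop replaced by A-rich / T-rich controls \cr
#'   CEBm1-CEBm4 \tab loop cytosine substitutions, N rising 1 to 2 \cr
#'   CEBm5 \tab CEBm4 + CCCA tail (N = 3) \cr
#'   CEBm6 \tab CEBm1 + CCCACCCA tail (N = 3) \cr
#'   CEBm7 \tab CEBm4 + CCCACCCA tail (N = 4) \cr
#' }
#'
#' @return List of ten `seq_record`s in the canonical order CEBwt, CEBm0A,
#'   CEBm0T, CEBm1-CEBm7.
#' @examples
#' vapply(ceb_family(), `[[`, 0L, "length")
#' @export
ceb_family <- function() {
  wt <- "AAGGGTGGGTGTAAGTGTGGGTGGGT"
  loop_sub <- function(repl) {
    stopifnot(nchar(repl) == 8L)
    paste0(substr(wt, 1, 10), repl, substr(wt, 19, 26))
  }
  m1 <- loop_sub("CCCAGTGT")
  m4 <- loop_sub("CCCACCCT")
  seqs <- c(CEBwt = wt,
            CEBm0A = loop_sub("AAAAAAAT"),
            CEBm0T = loop_sub("TTTATTTT"),
            CEBm1 = m1,
            CEBm2 = loop_sub("CCCACTGT"),
            CEBm3 = loop_sub("CCCACCGT"),
            CEBm4 = m4,
            CEBm5 = paste0(m4, "CCCA"),
            CEBm6 = paste0(m1, "CCCACCCA"),
            CEBm7 = paste0(m4, "CCCACCCA"))
  stopifnot(identical(unname(nchar(seqs)),
                      c(rep(26L, 7), 30L, 34L, 34L)),
            all(vapply(seqs, function(s)
              length(gregexpr("G{3}", s)[[1]]) == 4L, logical(1))))
  mapply(seq_record, names(seqs), seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# --- planted-motif synthetic genomes ---------------------------------------

# One random motif instance of a class; loops/bulges drawn from {A, T} so a
# planted motif can satisfy its own class only.
random_motif <- function(class) {
  at <- function(len) paste(sample(c("A", "T"), len, replace = TRUE),
                            collapse = "")
  short <- function() at(sample(1:7, 1))
  tracts <- rep("GGG", 4)
  loops <- c(short(), short(), short())
  if (class == "long_loop") {
    loops[sample(1:3, 1)] <- at(sample(8:15, 1))
  } else if (class == "bulged") {
    i <- sample(1:4, 1)
    tracts[i] <- if (sample(2, 1) == 1)
      paste0("G", short(), "GG") else paste0("GG", short(), "G")
  } else if (class == "vacancy") {
    tracts[sample(1:4, 1)] <- "GG"
  }
  paste0(tracts[1], loops[1], tracts[2], loops[2],
         tracts[3], loops[3], tracts[4])
}

#' Generate a synthetic genome with planted PQS motifs
#'
#' Builds a random background at a given GC fraction with G/C-run
#' suppression (no background G- or C-run of length >= 3), then plants
#' non-overlapping motif instances of the requested classes, each flanked
#' by 8 nt of forced A/T so no background G or C lies within bulge/loop
#' reach of a planted tract, with a minimum gap between plants so no motif
#' can span two of them. By
#' construction the planted motifs are the only PQS in the genome, so a
#' scan gives 100% recall with zero off-truth hits. The seed fully
#' determines the output; the caller's RNG state is left untouched.
#'
#' @param genome_length Genome size in bp.
#' @param planted Named integer vector, counts per motif class, e.g.
#'   `c(classical = 48)`.
#' @param background_gc Background GC fraction (default 0.4).
#' @param seed Integer seed.
#' @param minus_fraction Fraction of plants inserted as reverse-complement
#'   (C-motif on the forward strand), default 0.
#' @param min_gap Minimum bp between planted motifs (default 20; must be
#'   > 15 so no loop can bridge two plants).
#' @return List with `record` (a `seq_record` named "synth") and `truth`
#'   (data.frame seqid, start, end [0-based half-open], class, strand).
#' @examples
#' g <- synth_genome(10000, c(classical = 5), seed = 7)
#' nrow(g$truth)
#' @export
synth_genome <- function(genome_length, planted, background_gc = 0.4,
                         seed = 1L, minus_fraction = 0, min_gap = 20L) {
  stopifnot(min_gap > 15L, all(names(planted) %in% PQS_CLASSES),
            background_gc >= 0, background_gc < 1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  # background: i.i.d. then resample any base completing a G/C triplet run
  p <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
         G = background_gc / 2, T = (1 - background_gc) / 2)
  s <- sample(names(p), genome_length, replace = TRUE, prob = p)
  if (genome_length >= 3L) {
    idx <- 3:genome_length
    repeat {
      bad <- idx[s[idx] == s[idx - 1L] & s[idx] == s[idx - 2L] &
                   s[idx] %in% c("G", "C")]
      if (!length(bad)) break
      for (i in bad)
        s[i] <- sample(setdiff(names(p), s[i]), 1)
    }
  }

  # motif instances and non-overlapping placement
  classes <- rep(names(planted), planted)
  motifs <- vapply(classes, random_motif, "")
  strands <- ifelse(stats::runif(length(motifs)) < minus_fraction, "-", "+")
  if (sum(nchar(motifs) + min_gap + 2L) > genome_length)
    stop("infeasible packing: ", length(motifs), " motifs do not fit in ",
         genome_length, " bp")
  # each plant carries an 8 nt A/T flank on both sides: no background G (or
  # C) can then sit within bulge/loop reach (<= 7 nt) of a planted tract,
  # so a plant can only be detected as itself
  flank <- 8L
  occ_start <- integer(0); occ_end <- integer(0)
  starts <- integer(length(motifs))
  for (i in seq_along(motifs)) {
    len <- nchar(motifs[i])
    room <- genome_length - len - 2L * flank + 1L
    if (room < 1L)
      stop("infeasible packing: motif ", i, " does not fit in ",
           genome_length, " bp")
    placed <- FALSE
    for (try in 1:5000) {
      st <- sample.int(room, 1) + flank
      lo <- st - min_gap; hi <- st + len - 1L + min_gap
      if (!any(lo <= occ_end & occ_start <= hi)) {
        occ_start <- c(occ_start, lo); occ_end <- c(occ_end, hi)
        starts[i] <- st
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place motif ", i, " of ",
           length(motifs))
  }
  for (i in seq_along(motifs)) {
    m <- if (strands[i] == "-") revcomp(motifs[i]) else motifs[i]
    len <- nchar(m); st <- starts[i]
    s[st:(st + len - 1L)] <- strsplit(m, "")[[1]]
    s[(st - flank):(st - 1L)] <-
      sample(c("A", "T"), flank, replace = TRUE)
    s[(st + len):(st + len + flank - 1L)] <-
      sample(c("A", "T"), flank, replace = TRUE)
  }
  truth <- data.frame(seqid = rep("synth", length(starts)),
                      start = starts - 1L,
                      end = starts - 1L + nchar(motifs),
                      class = classes, strand = strands,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(record = seq_record("synth", paste(s, collapse = "")), truth = truth)
}
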
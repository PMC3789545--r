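#' Per-sample observations on a splicing graph
#'
#' Bundles, for each RNA-Seq sample, the average per-base read coverage
#' of each segment, the number of spliced reads exactly confirming each
#' intron edge, and the number of read pairs linking pairs of segments.
#'
#' @param seg_counts numeric matrix, samples x segments: average
#'   per-base coverage (aligned bases in the segment / segment length).
#' @param intron_counts numeric matrix, samples x edges (aligned with
#'   the graph's edge table; adjacency edges carry zeros).
#' @param pair_counts list (one element per sample) of data.frames with
#'   columns `s1`, `s2`, `count` (`s1 <= s2`): fragments with one mate
#'   overlapping `s1` and the other `s2`.
#' @param seg_lengths integer vector of segment lengths (bases).
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(seg_counts, intron_counts = NULL,
                            pair_counts = NULL, seg_lengths = NULL) {
  seg_counts <- as.matrix(seg_counts)
  R <- nrow(seg_counts)
  if (is.null(intron_counts)) intron_counts <- matrix(0, R, 0)
  intron_counts <- as.matrix(intron_counts)
  if (is.null(pair_counts)) {
    pair_counts <- rep(list(data.frame(s1 = integer(), s2 = integer(),
                                       count = numeric())), R)
  }
  if (is.null(seg_lengths)) seg_lengths <- rep(1L, ncol(seg_counts))
  stopifnot(nrow(intron_counts) == R, length(pair_counts) == R,
            length(seg_lengths) == ncol(seg_counts),
            all(seg_counts >= 0), all(intron_counts >= 0))
  structure(list(n_samples = R,
                 seg_counts = seg_counts,
                 intron_counts = intron_counts,
                 pair_counts = pair_counts,
                 seg_lengths = as.integer(seg_lengths)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation_set: %d samples, %d segments, %d edges, max count %.3g\n",
              x$n_samples, ncol(x$seg_counts), ncol(x$intron_counts),
              if (length(x$seg_counts)) max(x$seg_counts) else 0))
  invisible(x)
}

#' Count read support on a splicing graph
#'
#' Computes, per sample, average per-base segment coverage, exact-match
#' spliced-read support per intron edge, and mate-pair segment links.
#' A sample with no alignments yields an all-zero row.
#'
#' @param graph a `segment_graph`.
#' @param alignments list of `GAlignments`, one per sample (see
#'   [read_alignments()]).
#' @return an [observation_set()].
#' @export
count_observations <- function(graph, alignments) {
  gals <- .gal_list(alignments)
  R <- length(gals)
  region <- list(chrom = graph$chrom, start = graph$region_start,
                 end = graph$region_end, strand = graph$strand)
  S <- nrow(graph$segments)
  E <- nrow(graph$edges)
  lens <- segment_lengths(graph)
  seg_counts <- matrix(0, R, S)
  intron_counts <- matrix(0, R, E)
  pair_counts <- vector("list", R)
  for (r in seq_len(R)) {
    cov <- .region_coverage(gals[r], region)
    for (s in seq_len(S)) {
      a <- graph$segments$start[s] - region$start + 1
      b <- graph$segments$end[s] - region$start
      if (b >= a) seg_counts[r, s] <- sum(cov[a:b]) / lens[s]
    }
    jn <- .read_junctions(gals[r], region)
    if (nrow(jn)) {
      for (e in which(graph$edges$type == "intron")) {
        i <- graph$edges$from[e]; j <- graph$edges$to[e]
        hit <- jn$start == graph$segments$end[i] &
               jn$end == graph$segments$start[j]
        if (any(hit)) intron_counts[r, e] <- sum(jn$count[hit])
      }
    }
    pair_counts[[r]] <- .pair_links(gals[r], graph$segments)
  }
  observation_set(seg_counts, intron_counts, pair_counts, lens)
}
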
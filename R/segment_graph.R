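#' @importFrom methods is
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Internal conventions: all coordinates 0-based half-open.  A genomic region
## is a plain list(chrom =, start =, end =, strand =).  Alignments are
## GAlignments objects (see read_alignments()), one per sample.
## ---------------------------------------------------------------------------

.as_region <- function(region) {
  stopifnot(is.list(region), !is.null(region$chrom),
            !is.null(region$start), !is.null(region$end))
  if (is.null(region$strand)) region$strand <- "*"
  region
}

.gal_list <- function(alignments) {
  if (is.null(alignments)) return(list())
  if (is(alignments, "GAlignments")) return(list(alignments))
  stopifnot(is.list(alignments))
  alignments
}

## per-base coverage over the region, index 1 == region$start (0-based)
.region_coverage <- function(gals, region) {
  len <- region$end - region$start
  cov <- numeric(len)
  for (gal in gals) {
    if (length(gal) == 0) next
    cl <- GenomicAlignments::coverage(gal)
    if (!region$chrom %in% names(cl)) next
    rle <- cl[[region$chrom]]
    lo <- region$start + 1          # 1-based
    hi <- min(region$end, length(rle))
    if (hi < lo) next
    v <- as.numeric(rle[IRanges::IRanges(lo, hi)])
    cov[seq_along(v)] <- cov[seq_along(v)] + v
  }
  cov
}

## distinct introns (0-based half-open) with support, from spliced alignments
.read_junctions <- function(gals, region) {
  out <- list()
  for (gal in gals) {
    if (length(gal) == 0) next
    j <- unlist(GenomicAlignments::junctions(gal))
    if (length(j) == 0) next
    j <- j[as.character(GenomicRanges::seqnames(j)) == region$chrom]
    if (length(j) == 0) next
    out[[length(out) + 1]] <- data.frame(
      start = GenomicRanges::start(j) - 1L,   # first intronic base, 0-based
      end = GenomicRanges::end(j))            # half-open
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      count = integer()))
  jj <- do.call(rbind, out)
  agg <- stats::aggregate(list(count = rep(1L, nrow(jj))),
                          by = list(start = jj$start, end = jj$end), FUN = sum)
  agg[order(agg$start, agg$end), , drop = FALSE]
}

## introns implied by an annotation's exon chains (0-based half-open)
.annotation_introns <- function(annotation, region) {
  if (is.null(annotation)) return(data.frame(start = integer(), end = integer()))
  ex <- annotation$exons
  ex <- ex[ex$chrom == region$chrom, , drop = FALSE]
  out <- list()
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    out[[length(out) + 1]] <- data.frame(start = e$end[-nrow(e)],
                                         end = e$start[-1])
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

#' Detect segment boundaries in a genomic region
#'
#' Scans spliced alignments and/or annotated transcript models for the
#' positions at which exonic segments must be cut: splice sites (`SS`)
#' from alignment gap endpoints and internal annotated exon ends, and
#' candidate transcription start/termination sites (`TSS`/`TTS`) from
#' annotated transcript ends and from the edges of read-coverage islands
#' (a drop to zero coverage for at least `min_gap` bases opens a new
#' island).
#'
#' @param alignments a `GAlignments` object or a list of them (one per
#'   sample), or `NULL`.
#' @param annotation an annotation as returned by [read_gtf()], or
#'   `NULL`.  At least one of `alignments` / `annotation` is required.
#' @param region `list(chrom =, start =, end =)`, 0-based half-open.
#' @param min_gap minimum zero-coverage run (bases) that terminates a
#'   coverage island.
#' @return a data.frame with columns `pos` (0-based boundary position,
#'   sorted) and `label` (`"SS"`, `"TSS"` or `"TTS"`), deduplicated.
#' @export
find_boundaries <- function(alignments = NULL, annotation = NULL, region,
                            min_gap = 20L) {
  region <- .as_region(region)
  if (region$end <= region$start) {
    return(data.frame(pos = integer(), label = character()))
  }
  gals <- .gal_list(alignments)
  if (!length(gals) && is.null(annotation)) {
    stop("find_boundaries: need alignments and/or annotation")
  }
  if (length(gals)) {
    seqs <- unique(unlist(lapply(gals, GenomeInfoDb::seqlevels)))
    if (length(seqs) && !region$chrom %in% seqs) {
      stop("find_boundaries: chromosome '", region$chrom,
           "' not present in the alignment source")
    }
  }
  pos <- integer(); lab <- character()
  add <- function(p, l) {
    keep <- p >= region$start & p <= region$end
    pos <<- c(pos, p[keep]); lab <<- c(lab, rep(l, sum(keep)))
  }
  jn <- .read_junctions(gals, region)
  if (nrow(jn)) { add(jn$start, "SS"); add(jn$end, "SS") }
  if (!is.null(annotation)) {
    ex <- annotation$exons
    ex <- ex[ex$chrom == region$chrom, , drop = FALSE]
    for (tid in unique(ex$transcript_id)) {
      e <- ex[ex$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      add(min(e$start), "TSS"); add(max(e$end), "TTS")
      if (nrow(e) > 1) {
        add(e$end[-nrow(e)], "SS")   # donor side of each internal intron
        add(e$start[-1], "SS")       # acceptor side
      }
    }
  }
  if (length(gals)) {
    cov <- .region_coverage(gals, region)
    r <- rle(cov > 0)
    ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
    # suppress zero-runs shorter than min_gap (read-length-scale gaps)
    covered <- r$values
    covered[!r$values & r$lengths < min_gap & seq_along(r$values) != 1 &
              seq_along(r$values) != length(r$values)] <- TRUE
    r2 <- rle(rep(covered, r$lengths))
    ends2 <- cumsum(r2$lengths); starts2 <- c(1, head(ends2, -1) + 1)
    isl <- which(r2$values)
    if (length(isl)) {
      add(region$start + starts2[isl] - 1L, "TSS")
      add(region$start + ends2[isl], "TTS")
    }
  }
  out <- unique(data.frame(pos = pos, label = lab))
  out <- out[order(out$pos, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate segments between consecutive boundaries
#'
#' @param boundaries data.frame from [find_boundaries()].
#' @return data.frame with `start`, `end` (0-based half-open), one row
#'   per interval between consecutive distinct boundary positions.
#' @export
candidate_segments <- function(boundaries) {
  p <- sort(unique(boundaries$pos))
  if (length(p) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = p[-length(p)], end = p[-1])
}

#' Filter candidate segments to the exonic ones
#'
#' A candidate segment is kept if (i) more than `min_frac` of its bases
#' are covered by at least one read, or (ii) it overlaps an annotated
#' exon, or (iii) it is a cut vertex whose removal disconnects two
#' segments linked by paired-end fragments.
#'
#' @param segments data.frame from [candidate_segments()].
#' @param alignments alignments (all samples pooled) used for coverage;
#'   may be `NULL`.
#' @param region the enclosing region.
#' @param annotation optional annotation ([read_gtf()]).
#' @param pair_links optional data.frame with columns `s1`, `s2`:
#'   indices (into `segments`) of segment pairs linked by read pairs.
#' @param junctions optional data.frame (`start`, `end`, 0-based
#'   half-open introns) used, with genomic adjacency, to assess
#'   connectivity for rule (iii).
#' @param min_frac covered-fraction threshold (strict `>`).
#' @return the kept subset of `segments`, with a logical `annotated`
#'   column attached.
#' @export
filter_exonic_segments <- function(segments, alignments = NULL, region,
                                   annotation = NULL, pair_links = NULL,
                                   junctions = NULL, min_frac = 0.05) {
  region <- .as_region(region)
  n <- nrow(segments)
  if (n == 0) return(cbind(segments, annotated = logical(0)))
  cov <- .region_coverage(.gal_list(alignments), region)
  frac <- vapply(seq_len(n), function(i) {
    a <- segments$start[i] - region$start + 1
    b <- segments$end[i] - region$start
    if (b < a) return(0)
    mean(cov[a:b] > 0)
  }, 0)
  keep <- frac > min_frac
  annotated <- rep(FALSE, n)
  if (!is.null(annotation)) {
    ex <- annotation$exons
    ex <- ex[ex$chrom == region$chrom, , drop = FALSE]
    if (nrow(ex)) {
      for (i in seq_len(n)) {
        annotated[i] <- any(ex$start < segments$end[i] &
                            ex$end > segments$start[i])
      }
    }
  }
  keep <- keep | annotated
  if (!is.null(pair_links) && nrow(pair_links) && any(!keep)) {
    g <- .candidate_graph(segments, junctions)
    for (s in which(!keep)) {
      for (k in seq_len(nrow(pair_links))) {
        a <- pair_links$s1[k]; b <- pair_links$s2[k]
        if (a == s || b == s) next
        with_s <- .connected_without(g, n, integer(0), a, b)
        without_s <- .connected_without(g, n, s, a, b)
        if (with_s && !without_s) { keep[s] <- TRUE; break }
      }
    }
  }
  out <- cbind(segments[keep, , drop = FALSE], annotated = annotated[keep])
  rownames(out) <- NULL
  out
}

## undirected candidate connectivity graph: genomic adjacency + junctions
.candidate_graph <- function(segments, junctions) {
  n <- nrow(segments)
  e <- list()
  if (n > 1) {
    adj <- which(segments$end[-n] == segments$start[-1])
    if (length(adj)) e[[1]] <- cbind(adj, adj + 1)
  }
  if (!is.null(junctions) && nrow(junctions)) {
    for (k in seq_len(nrow(junctions))) {
      i <- which(segments$end == junctions$start[k])
      j <- which(segments$start == junctions$end[k])
      if (length(i) == 1 && length(j) == 1) e[[length(e) + 1]] <- cbind(i, j)
    }
  }
  if (!length(e)) return(matrix(integer(0), 0, 2))
  do.call(rbind, e)
}

.connected_without <- function(edges, n, drop, a, b) {
  keep_v <- setdiff(seq_len(n), drop)
  if (!a %in% keep_v || !b %in% keep_v) return(FALSE)
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(keep_v),
                                    igraph::V(g)$name))
  g <- igraph::delete_vertices(
    g, intersect(as.character(drop), igraph::V(g)$name))
  if (!as.character(a) %in% igraph::V(g)$name ||
      !as.character(b) %in% igraph::V(g)$name) return(FALSE)
  !is.infinite(igraph::distances(g, as.character(a), as.character(b))[1, 1])
}

#' Connect exonic segments into a splicing graph
#'
#' Adds one directed edge per distinct intron whose endpoints coincide
#' exactly with segment boundaries (no fuzzy matching), plus implicit
#' adjacency edges between genomically contiguous segments.  Introns
#' that do not match any boundary pair are dropped with a warning.
#'
#' @param segments kept segments ([filter_exonic_segments()]); must have
#'   `start`/`end` columns, sorted, non-overlapping.
#' @param junctions data.frame of introns (`start`, `end`, 0-based
#'   half-open, optional `source` column `"read"`/`"annotation"`).
#' @param region the enclosing region.
#' @param boundaries optional boundary table ([find_boundaries()]) used
#'   to flag initial/terminal segments at annotated/observed transcript
#'   ends; segments bordering a genomic gap are flagged regardless.
#' @return an object of class `segment_graph`.
#' @export
add_intron_edges <- function(segments, junctions, region, boundaries = NULL) {
  region <- .as_region(region)
  n <- nrow(segments)
  if (n && any(diff(segments$start) <= 0)) {
    stop("add_intron_edges: segments must be sorted and non-overlapping")
  }
  ed <- data.frame(from = integer(), to = integer(),
                   type = character(), source = character())
  if (n > 1) {
    adj <- which(segments$end[-n] == segments$start[-1])
    if (length(adj)) {
      ed <- rbind(ed, data.frame(from = adj, to = adj + 1,
                                 type = "adjacent", source = "read"))
    }
  }
  if (!is.null(junctions) && nrow(junctions)) {
    src <- if ("source" %in% names(junctions)) junctions$source else "read"
    src <- rep_len(src, nrow(junctions))
    for (k in seq_len(nrow(junctions))) {
      if (junctions$start[k] < region$start || junctions$end[k] > region$end) {
        warning(sprintf("intron [%d,%d) crosses the region boundary; skipped",
                        junctions$start[k], junctions$end[k]))
        next
      }
      i <- which(segments$end == junctions$start[k])
      j <- which(segments$start == junctions$end[k])
      if (length(i) == 1 && length(j) == 1 && i < j) {
        hit <- ed$from == i & ed$to == j & ed$type == "intron"
        if (any(hit)) {
          if (ed$source[hit] != src[k]) ed$source[hit] <- "both"
        } else {
          ed <- rbind(ed, data.frame(from = i, to = j, type = "intron",
                                     source = src[k]))
        }
      } else {
        warning(sprintf(
          "intron [%d,%d) does not match segment boundaries; skipped",
          junctions$start[k], junctions$end[k]))
      }
    }
  }
  ed <- ed[order(ed$from, ed$to, ed$type), , drop = FALSE]
  rownames(ed) <- NULL
  ## initial/terminal flags.  With a boundary table, only annotated or
  ## observed transcript ends (TSS/TTS labels, which include coverage
  ## island edges) open/close paths — a bare genomic gap between kept
  ## segments is an intron, not transcript-end evidence.  Without one,
  ## fall back to flagging every segment bordering a gap.
  is_initial <- rep(FALSE, n); is_terminal <- rep(FALSE, n)
  if (n) {
    if (!is.null(boundaries)) {
      tss <- boundaries$pos[boundaries$label == "TSS"]
      tts <- boundaries$pos[boundaries$label == "TTS"]
      is_initial <- segments$start %in% tss
      is_terminal <- segments$end %in% tts
    } else {
      gap <- segments$end[-n] != segments$start[-1]
      is_initial <- c(TRUE, gap)
      is_terminal <- c(gap, TRUE)
    }
  }
  segs <- data.frame(start = segments$start, end = segments$end,
                     is_initial = is_initial, is_terminal = is_terminal)
  if ("annotated" %in% names(segments)) segs$annotated <- segments$annotated
  structure(list(chrom = region$chrom, strand = region$strand,
                 region_start = region$start, region_end = region$end,
                 segments = segs, edges = ed),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("segment_graph %s:%d-%d (%s): %d segments, %d edges (%d introns)\n",
              x$chrom, x$region_start, x$region_end, x$strand,
              nrow(x$segments), nrow(x$edges),
              sum(x$edges$type == "intron")))
  invisible(x)
}

#' Segment lengths of a splicing graph
#' @param graph a `segment_graph`.
#' @return integer vector of segment lengths in bases.
#' @export
segment_lengths <- function(graph) {
  graph$segments$end - graph$segments$start
}

#' Build a splicing graph from alignments and/or annotation
#'
#' Convenience driver running boundary detection, exon filtering and
#' intron-edge construction for one region.
#'
#' @inheritParams find_boundaries
#' @inheritParams filter_exonic_segments
#' @return a `segment_graph`.
#' @export
build_segment_graph <- function(alignments = NULL, annotation = NULL, region,
                                min_gap = 20L, min_frac = 0.05) {
  region <- .as_region(region)
  gals <- .gal_list(alignments)
  bounds <- find_boundaries(alignments = gals, annotation = annotation,
                            region = region, min_gap = min_gap)
  cand <- candidate_segments(bounds)
  jn <- .read_junctions(gals, region)
  jn$source <- rep("read", nrow(jn))
  ja <- .annotation_introns(annotation, region)
  if (nrow(ja)) {
    ja$count <- 0L; ja$source <- "annotation"
    jn <- rbind(jn, ja[, names(jn)])
  }
  pl <- .pair_links(gals, cand)
  kept <- filter_exonic_segments(cand, alignments = gals, region = region,
                                 annotation = annotation, pair_links = pl,
                                 junctions = jn, min_frac = min_frac)
  add_intron_edges(kept, jn, region, boundaries = bounds)
}

## mate-pair links between candidate segments: one row per (fragment,
## segment pair), s1 <= s2; aggregate over `count` for per-pair totals
.pair_links <- function(gals, segments) {
  empty <- data.frame(s1 = integer(), s2 = integer(), count = numeric())
  if (!nrow(segments)) return(empty)
  out <- list()
  for (gal in gals) {
    if (length(gal) == 0) next
    md <- S4Vectors::mcols(gal)
    if (is.null(md$qname)) next
    qn <- md$qname
    dup <- qn %in% qn[duplicated(qn)]
    if (!any(dup)) next
    blocks <- GenomicAlignments::grglist(gal[dup])
    qd <- qn[dup]
    segs_hit <- lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      hit <- integer(0)
      for (k in seq_along(b)) {
        s0 <- GenomicRanges::start(b)[k] - 1L; e0 <- GenomicRanges::end(b)[k]
        hit <- c(hit, which(segments$start < e0 & segments$end > s0))
      }
      unique(hit)
    })
    for (q in unique(qd)) {
      idx <- which(qd == q)
      if (length(idx) != 2) next
      a <- segs_hit[[idx[1]]]; b <- segs_hit[[idx[2]]]
      if (length(a) && length(b)) {
        grid <- expand.grid(s1 = a, s2 = b)
        sw <- grid$s1 > grid$s2
        tmp <- grid$s1[sw]; grid$s1[sw] <- grid$s2[sw]; grid$s2[sw] <- tmp
        out[[length(out) + 1]] <- unique(grid)   # one count per fragment/pair
      }
    }
  }
  if (!length(out)) return(empty)
  pl <- do.call(rbind, out)
  agg <- stats::aggregate(list(count = rep(1, nrow(pl))),
                          by = list(s1 = pl$s1, s2 = pl$s2), FUN = sum)
  agg[order(agg$s1, agg$s2), , drop = FALSE]
}

#' Successor list of a segment graph
#' @keywords internal
.successors <- function(graph) {
  n <- nrow(graph$segments)
  succ <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[k]
    succ[[f]] <- c(succ[[f]], graph$edges$to[k])
  }
  lapply(succ, function(s) sort(unique(s)))
}

#' Enumerate all source-to-sink paths of a splicing graph
#'
#' Depth-first enumeration of every path that starts at an initial
#' segment, ends at a terminal segment and follows graph edges.  Meant
#' for small loci and as a test oracle; raises a classed error
#' (`isomip_path_overflow`) as soon as the count exceeds `limit` rather
#' than silently truncating.
#'
#' @param graph a `segment_graph`.
#' @param limit maximum number of paths.
#' @return a binary matrix, one row per path, one column per segment.
#' @export
enumerate_paths <- function(graph, limit = 1024L) {
  n <- nrow(graph$segments)
  if (n == 0) return(matrix(0, 0, 0))
  succ <- .successors(graph)
  init <- which(graph$segments$is_initial)
  term <- graph$segments$is_terminal
  paths <- list()
  push <- function(p) {
    if (length(paths) + 1 > limit) {
      stop(structure(class = c("isomip_path_overflow", "error", "condition"),
                     list(message = sprintf(
                       "path enumeration exceeded limit %d", limit),
                       call = sys.call(-1))))
    }
    paths[[length(paths) + 1]] <<- p
  }
  walk <- function(p) {
    last <- p[length(p)]
    if (term[last]) push(p)
    for (s in succ[[last]]) walk(c(p, s))
  }
  for (s in init) walk(s)
  U <- matrix(0L, length(paths), n)
  for (i in seq_along(paths)) U[i, paths[[i]]] <- 1L
  ## deterministic order: lexicographic on the binary rows
  if (nrow(U) > 1) {
    key <- apply(U, 1, paste, collapse = "")
    U <- U[order(key), , drop = FALSE]
  }
  U
}

#' Validate a binary segment vector as a path
#'
#' @param graph a `segment_graph`.
#' @param x binary vector over segments (a row of a transcript matrix).
#' @return `TRUE` iff the selected segments form a valid path: the first
#'   is initial, the last terminal, and every consecutive selected pair
#'   is joined by a graph edge.  The all-zero vector is not a path.
#' @export
is_valid_path <- function(graph, x) {
  sel <- which(x != 0)
  if (!length(sel)) return(FALSE)
  if (!graph$segments$is_initial[sel[1]]) return(FALSE)
  if (!graph$segments$is_terminal[sel[length(sel)]]) return(FALSE)
  if (length(sel) > 1) {
    for (k in seq_len(length(sel) - 1)) {
      hit <- graph$edges$from == sel[k] & graph$edges$to == sel[k + 1]
      if (!any(hit)) return(FALSE)
    }
  }
  TRUE
}
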
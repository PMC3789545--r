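#' Read transcript annotation from a GTF file
#'
#' Exon features are grouped into transcripts and genes; the 1-based
#' closed GTF coordinates are converted to the internal 0-based
#' half-open convention.  Exon records lacking a `transcript_id` are
#' skipped with a warning.
#'
#' @param path GTF file.
#' @return an object of class `annotation`: a list with element `exons`,
#'   a data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `transcript_id`, `gene_id`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tid <- gr$transcript_id
  if (is.null(tid)) tid <- rep(NA_character_, length(gr))
  bad <- is.na(tid) | tid == ""
  if (any(bad)) {
    warning(sum(bad), " exon record(s) without transcript_id skipped")
    gr <- gr[!bad]; tid <- tid[!bad]
  }
  gid <- gr$gene_id
  if (is.null(gid)) gid <- tid
  ex <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   transcript_id = tid,
                   gene_id = gid)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  structure(list(exons = ex), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation: %d exons, %d transcripts, %d genes\n",
              nrow(x$exons), length(unique(x$exons$transcript_id)),
              length(unique(x$exons$gene_id))))
  invisible(x)
}

#' Construct an annotation from exon chains
#'
#' @param chains named list of data.frames with `start`, `end` (0-based
#'   half-open exons), one per transcript.
#' @param chrom,strand,gene_id shared coordinates/identifiers.
#' @return an `annotation`.
#' @export
annotation_from_chains <- function(chains, chrom = "chr1", strand = "+",
                                   gene_id = "G1") {
  if (is.null(names(chains))) names(chains) <- paste0("T", seq_along(chains))
  rows <- lapply(names(chains), function(tid) {
    e <- chains[[tid]]
    data.frame(chrom = chrom, start = e$start, end = e$end, strand = strand,
               transcript_id = tid, gene_id = gene_id)
  })
  structure(list(exons = do.call(rbind, rows)), class = "annotation")
}

#' Exon chains of a transcript set
#'
#' Converts the selected binary rows back to genomic exon chains,
#' merging genomically contiguous selected segments into single exons.
#'
#' @param tset a [transcript_set()].
#' @param gene_id gene identifier for the output.
#' @param tx_prefix prefix for generated transcript identifiers.
#' @return an `annotation`.
#' @export
transcript_annotation <- function(tset, gene_id = "G1", tx_prefix = "TX") {
  g <- tset$graph
  chains <- list()
  for (t in seq_len(nrow(tset$U))) {
    sel <- which(tset$U[t, ] != 0)
    if (!length(sel)) next
    st <- g$segments$start[sel]; en <- g$segments$end[sel]
    keep <- c(TRUE, st[-1] != en[-length(en)])
    grp <- cumsum(keep)
    chains[[sprintf("%s%03d", tx_prefix, t)]] <-
      data.frame(start = tapply(st, grp, min),
                 end = tapply(en, grp, max))
  }
  annotation_from_chains(chains, chrom = g$chrom, strand = g$strand,
                         gene_id = gene_id)
}

#' Write an annotation (with optional quantification results) as GTF
#'
#' @param annotation an `annotation`.
#' @param path output GTF path.
#' @param abundance optional matrix (transcripts x samples, rows in the
#'   order of `unique(annotation$exons$transcript_id)`) written as
#'   per-sample `abund_<r>` attributes.
#' @param conf_pvalue optional per-transcript confidence p-values,
#'   written as a `conf_pvalue` attribute.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, abundance = NULL,
                      conf_pvalue = NULL) {
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "isomip"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  tids <- unique(ex$transcript_id)
  tx_row <- match(ex$transcript_id, tids)
  if (!is.null(abundance)) {
    abundance <- as.matrix(abundance)
    for (r in seq_len(ncol(abundance))) {
      S4Vectors::mcols(gr)[[paste0("abund_", r)]] <-
        sprintf("%.6g", abundance[tx_row, r])
    }
  }
  if (!is.null(conf_pvalue)) {
    S4Vectors::mcols(gr)$conf_pvalue <- sprintf("%.6g", conf_pvalue[tx_row])
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read spliced alignments from SAM/BAM
#'
#' SAM files are converted on the fly; records keep their query name and
#' flag so mate pairs can be recovered.
#'
#' @param path SAM or BAM file (one sample).
#' @return a `GAlignments` object with `qname` and `flag` metadata
#'   columns.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag")))
}

## --------------------------------------------------------------------------
## Graph + counts dump: versioned TSV so the solver can be driven without
## alignment files (and external assemblers can inject graphs).
## --------------------------------------------------------------------------

#' Write a segment graph (and optional counts) as versioned TSV
#'
#' @param graph a `segment_graph`.
#' @param path output file.
#' @param obs optional [observation_set()] to embed.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path, obs = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = "\t")
  w("#isomip_graph\tv1")
  w(sprintf("#region\t%s\t%s\t%d\t%d", graph$chrom, graph$strand,
            graph$region_start, graph$region_end))
  w(sprintf("#segments\t%d", nrow(graph$segments)))
  w("start\tend\tis_initial\tis_terminal")
  for (i in seq_len(nrow(graph$segments))) {
    w(sprintf("%d\t%d\t%d\t%d", graph$segments$start[i],
              graph$segments$end[i],
              as.integer(graph$segments$is_initial[i]),
              as.integer(graph$segments$is_terminal[i])))
  }
  w(sprintf("#edges\t%d", nrow(graph$edges)))
  w("from\tto\ttype\tsource")
  for (i in seq_len(nrow(graph$edges))) {
    w(sprintf("%d\t%d\t%s\t%s", graph$edges$from[i], graph$edges$to[i],
              graph$edges$type[i], graph$edges$source[i]))
  }
  if (!is.null(obs)) {
    w(sprintf("#samples\t%d", obs$n_samples))
    w("#seg_counts")
    for (r in seq_len(obs$n_samples)) w(num(obs$seg_counts[r, ]))
    w("#intron_counts")
    for (r in seq_len(obs$n_samples)) w(num(obs$intron_counts[r, ]))
    np <- sum(vapply(obs$pair_counts, nrow, 0L))
    w(sprintf("#pair_counts\t%d", np))
    for (r in seq_len(obs$n_samples)) {
      pc <- obs$pair_counts[[r]]
      for (i in seq_len(nrow(pc))) {
        w(sprintf("%d\t%d\t%d\t%s", r, pc$s1[i], pc$s2[i],
                  format(pc$count[i], digits = 17)))
      }
    }
  }
  invisible(path)
}

#' Read a graph TSV written by [write_graph_tsv()]
#'
#' @param path input file.
#' @return list with `graph` (a `segment_graph`) and `obs` (an
#'   [observation_set()] or `NULL`).
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#isomip_graph")) {
    stop("read_graph_tsv: not a graph file (missing version header): ", path)
  }
  fields <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  reg <- fields(2)
  i <- 3
  ns <- as.integer(fields(i)[2]); i <- i + 2   # skip column header
  segs <- data.frame(start = integer(ns), end = integer(ns),
                     is_initial = logical(ns), is_terminal = logical(ns))
  for (k in seq_len(ns)) {
    f <- fields(i); i <- i + 1
    segs[k, ] <- list(as.integer(f[1]), as.integer(f[2]),
                      as.integer(f[3]) == 1L, as.integer(f[4]) == 1L)
  }
  ne <- as.integer(fields(i)[2]); i <- i + 2
  ed <- data.frame(from = integer(ne), to = integer(ne),
                   type = character(ne), source = character(ne))
  for (k in seq_len(ne)) {
    f <- fields(i); i <- i + 1
    ed[k, ] <- list(as.integer(f[1]), as.integer(f[2]), f[3], f[4])
  }
  graph <- structure(list(chrom = reg[2], strand = reg[3],
                          region_start = as.integer(reg[4]),
                          region_end = as.integer(reg[5]),
                          segments = segs, edges = ed),
                     class = "segment_graph")
  obs <- NULL
  if (i <= length(lines) && startsWith(lines[i], "#samples")) {
    R <- as.integer(fields(i)[2]); i <- i + 2   # skip "#seg_counts"
    seg_counts <- matrix(0, R, ns)
    for (r in seq_len(R)) {
      seg_counts[r, ] <- as.numeric(fields(i)); i <- i + 1
    }
    i <- i + 1                                  # skip "#intron_counts"
    intron_counts <- matrix(0, R, ne)
    for (r in seq_len(R)) {
      if (ne > 0) intron_counts[r, ] <- as.numeric(fields(i))
      i <- i + 1
    }
    np <- as.integer(fields(i)[2]); i <- i + 1
    pc <- rep(list(data.frame(s1 = integer(), s2 = integer(),
                              count = numeric())), R)
    for (k in seq_len(np)) {
      f <- fields(i); i <- i + 1
      r <- as.integer(f[1])
      pc[[r]] <- rbind(pc[[r]],
                       data.frame(s1 = as.integer(f[2]),
                                  s2 = as.integer(f[3]),
                                  count = as.numeric(f[4])))
    }
    obs <- observation_set(seg_counts, intron_counts, pc,
                           segs$end - segs$start)
  }
  list(graph = graph, obs = obs)
}

## --------------------------------------------------------------------------
## Synthetic fixture generation: planted transcripts -> SAM + GTF
## --------------------------------------------------------------------------

## transcript-coordinate interval -> genomic blocks over an exon chain
.tx_to_blocks <- function(chain, from, to) {
  # chain: data.frame(start, end) 0-based half-open exons; from/to 0-based
  lens <- chain$end - chain$start
  offs <- cumsum(c(0, lens))
  blocks <- list()
  for (e in seq_len(nrow(chain))) {
    a <- max(from, offs[e]); b <- min(to, offs[e + 1])
    if (b > a) {
      blocks[[length(blocks) + 1]] <-
        c(chain$start[e] + (a - offs[e]), chain$start[e] + (b - offs[e]))
    }
  }
  blocks
}

.blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_along(blocks)) {
    if (i > 1) {
      gap <- blocks[[i]][1] - blocks[[i - 1]][2]
      parts <- c(parts, sprintf("%dN", gap))
    }
    parts <- c(parts, sprintf("%dM", blocks[[i]][2] - blocks[[i]][1]))
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic SAM + GTF fixture from planted transcripts
#'
#' Emits, per sample, a coordinate-sorted SAM file of (optionally
#' paired) reads drawn uniformly along each planted transcript, with
#' read counts per transcript drawn around `depth * abundance` (NB
#' noise when the loss model is over-dispersed, exact expectation when
#' `model = NULL`), plus a GTF of the planted transcripts.  Regeneration
#' with the same seed is byte-identical.
#'
#' @param chains named list of exon-chain data.frames (`start`, `end`,
#'   0-based half-open) — the planted transcripts.
#' @param abundances matrix transcripts x samples of relative
#'   abundances.
#' @param dir output directory (created if needed).
#' @param chrom,chrom_len contig name and length for the SAM header.
#' @param read_length read length in bases.
#' @param depth expected number of reads per unit abundance.
#' @param paired emit read pairs (mates at the fragment ends).
#' @param frag_len fragment length for paired output.
#' @param model optional [loss_model()] supplying NB dispersion for the
#'   per-transcript read-count noise.
#' @param seed RNG seed (fixture regeneration is deterministic).
#' @return list with `sam` (vector of per-sample paths), `gtf`, and
#'   `annotation`.
#' @export
make_fixture <- function(chains, abundances, dir, chrom = "chr1",
                         chrom_len = NULL, read_length = 50L, depth = 200,
                         paired = FALSE, frag_len = 150L, model = NULL,
                         seed = 1L) {
  abundances <- as.matrix(abundances)
  stopifnot(length(chains) == nrow(abundances))
  if (is.null(names(chains))) names(chains) <- paste0("T", seq_along(chains))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (is.null(chrom_len)) {
    chrom_len <- max(vapply(chains, function(ch) max(ch$end), 0)) + 100L
  }
  R <- ncol(abundances)
  tx_len <- vapply(chains, function(ch) sum(ch$end - ch$start), 0)
  sam_paths <- character(R)
  for (r in seq_len(R)) {
    recs <- list()
    for (t in seq_along(chains)) {
      span <- if (paired) frag_len else read_length
      if (tx_len[t] < span) {
        warning(sprintf("transcript %s shorter than %d bases; skipped",
                        names(chains)[t], span))
        next
      }
      mu <- depth * abundances[t, r]
      n_frag <- if (!is.null(model) && model$kind == "nb" &&
                    model$dispersion > 0) {
        stats::rnbinom(1, mu = mu, size = 1 / model$dispersion)
      } else round(mu)
      if (n_frag < 1) next
      starts <- floor(stats::runif(n_frag, 0, tx_len[t] - span + 1))
      for (fgi in seq_len(n_frag)) {
        qn <- sprintf("%s_s%d_f%06d", names(chains)[t], r, fgi)
        if (!paired) {
          bl <- .tx_to_blocks(chains[[t]], starts[fgi],
                              starts[fgi] + read_length)
          recs[[length(recs) + 1]] <- list(
            qname = qn, flag = 0L, pos = bl[[1]][1] + 1L,
            cigar = .blocks_to_cigar(bl), rnext = "*", pnext = 0L,
            tlen = 0L, len = read_length)
        } else {
          b1 <- .tx_to_blocks(chains[[t]], starts[fgi],
                              starts[fgi] + read_length)
          b2 <- .tx_to_blocks(chains[[t]], starts[fgi] + frag_len - read_length,
                              starts[fgi] + frag_len)
          p1 <- b1[[1]][1] + 1L; p2 <- b2[[1]][1] + 1L
          tl <- b2[[length(b2)]][2] - b1[[1]][1]
          recs[[length(recs) + 1]] <- list(
            qname = qn, flag = 99L, pos = p1, cigar = .blocks_to_cigar(b1),
            rnext = "=", pnext = p2, tlen = tl, len = read_length)
          recs[[length(recs) + 1]] <- list(
            qname = qn, flag = 147L, pos = p2, cigar = .blocks_to_cigar(b2),
            rnext = "=", pnext = p1, tlen = -tl, len = read_length)
        }
      }
    }
    ord <- order(vapply(recs, function(x) x$pos, 0),
                 vapply(recs, function(x) x$qname, ""))
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
    for (x in recs[ord]) {
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t*",
                                x$qname, x$flag, chrom, x$pos, x$cigar,
                                x$rnext, x$pnext, x$tlen,
                                strrep("A", x$len)))
    }
    sam_paths[r] <- file.path(dir, sprintf("sample%d.sam", r))
    writeLines(lines, sam_paths[r])
  }
  ann <- annotation_from_chains(chains, chrom = chrom)
  gtf <- file.path(dir, "planted.gtf")
  write_gtf(ann, gtf)
  list(sam = sam_paths, gtf = gtf, annotation = ann)
}
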
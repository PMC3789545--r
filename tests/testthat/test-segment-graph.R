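region_1k <- list(chrom = "chr1", start = 0L, end = 1000L)

two_exon_ann <- annotation_from_chains(
  list(T1 = data.frame(start = c(100, 300), end = c(200, 400))))

test_that("annotation boundaries echo exon ends with the right labels", {
  b <- find_boundaries(annotation = two_exon_ann, region = region_1k)
  expect_equal(b$pos, c(100, 200, 300, 400))
  expect_equal(b$label, c("TSS", "SS", "SS", "TTS"))
})

test_that("a single spliced read yields splice-site boundaries at its gap", {
  gal <- make_gal(101, "50M150N50M")  # blocks [100,150) + [300,350)
  b <- find_boundaries(alignments = gal, region = region_1k)
  ss <- b$pos[b$label == "SS"]
  expect_equal(ss, c(150, 300))
})

test_that("boundary detection agrees with a brute-force pileup walk", {
  # 3 reads sharing one junction + a separate coverage island ending at 500
  pos <- c(101, 101, 101, 421)
  cig <- c(rep("50M100N50M", 3), "80M")
  gal <- make_gal(pos, cig)
  b <- find_boundaries(alignments = gal, region = region_1k, min_gap = 20)
  # oracle: per-base coverage walk
  cov <- oracle_coverage(pos, cig, region_1k)
  runs <- rle(cov > 0)
  ends <- cumsum(runs$lengths); starts <- c(1, head(ends, -1) + 1)
  isl <- which(runs$values)
  exp_tss <- region_1k$start + starts[isl] - 1
  exp_tts <- region_1k$start + ends[isl]
  expect_setequal(b$pos[b$label == "TSS"], exp_tss)
  expect_setequal(b$pos[b$label == "TTS"], exp_tts)
  expect_true(500 %in% b$pos[b$label == "TTS"])
  expect_setequal(b$pos[b$label == "SS"], c(150, 250))
})

test_that("degenerate boundary inputs behave as documented", {
  expect_equal(nrow(find_boundaries(annotation = two_exon_ann,
                                    region = list(chrom = "chr1", start = 5,
                                                  end = 5))), 0)
  gal <- make_gal(101, "50M")
  expect_error(find_boundaries(alignments = gal,
                               region = list(chrom = "chrX", start = 0,
                                             end = 100)),
               "chrX")
  expect_error(find_boundaries(region = region_1k), "alignments and/or")
})

test_that("exon filter applies the strict >5% coverage rule", {
  segs <- data.frame(start = 0L, end = 100L)
  reg <- list(chrom = "chr1", start = 0L, end = 100L)
  kept5 <- filter_exonic_segments(segs, make_gal(1, "5M"), reg)
  expect_equal(nrow(kept5), 0)         # 5% is not > 5%
  kept6 <- filter_exonic_segments(segs, make_gal(1, "6M"), reg)
  expect_equal(nrow(kept6), 1)
  # annotated segments survive without coverage
  kept_ann <- filter_exonic_segments(segs, NULL, reg,
                                     annotation = annotation_from_chains(
                                       list(T1 = data.frame(start = 0,
                                                            end = 100))))
  expect_equal(nrow(kept_ann), 1)
  expect_true(kept_ann$annotated)
})

test_that("an uncovered cut segment on a pair-linked route is rescued", {
  # A [0,100) covered, B [100,200) uncovered, C [200,300) covered;
  # a read pair links A and C, and B is the only route between them
  segs <- data.frame(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  reg <- list(chrom = "chr1", start = 0L, end = 300L)
  gal <- make_gal(c(1, 201), c("50M", "50M"))
  links <- data.frame(s1 = 1L, s2 = 3L)
  kept <- filter_exonic_segments(segs, gal, reg, pair_links = links)
  expect_equal(kept$start, c(0, 100, 200))
  # independent reachability oracle confirms B is a cut vertex
  adj <- rbind(c(1, 2), c(2, 3))
  expect_true(oracle_reachable(adj, 3, 1, 3))
  expect_false(oracle_reachable(adj, 3, 1, 3, dropped = 2))
  # without the pair link, B is dropped
  kept2 <- filter_exonic_segments(segs, gal, reg)
  expect_equal(kept2$start, c(0, 200))
})

test_that("intron edges require exact boundary matches and warn otherwise", {
  segs <- data.frame(start = c(0L, 200L), end = c(100L, 300L))
  reg <- list(chrom = "chr1", start = 0L, end = 300L)
  g <- add_intron_edges(segs, data.frame(start = 100, end = 200), reg)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$type, "intron")
  expect_warning(add_intron_edges(segs, data.frame(start = 90, end = 200),
                                  reg),
                 "does not match")
  expect_warning(add_intron_edges(segs, data.frame(start = 100, end = 350),
                                  reg),
                 "region boundary")
})

test_that("annotation-only graphs carry exactly the annotated introns", {
  # two transcripts: exon skip of the middle exon
  chains <- list(inc = data.frame(start = c(0, 200, 400),
                                  end = c(100, 300, 500)),
                 skp = data.frame(start = c(0, 400), end = c(100, 500)))
  ann <- annotation_from_chains(chains)
  reg <- list(chrom = "chr1", start = 0L, end = 600L)
  g <- build_segment_graph(annotation = ann, region = reg)
  # independent tally of annotated introns
  tally <- unique(do.call(rbind, lapply(chains, function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(start = e$end[-nrow(e)], end = e$start[-1])
  })))
  got <- data.frame(
    start = g$segments$end[g$edges$from[g$edges$type == "intron"]],
    end = g$segments$start[g$edges$to[g$edges$type == "intron"]])
  expect_setequal(paste(got$start, got$end),
                  paste(tally$start, tally$end))
})

test_that("mixed read + annotation edges equal an independent junction tally", {
  chains <- list(T1 = data.frame(start = c(100, 300), end = c(200, 400)))
  ann <- annotation_from_chains(chains)
  # reads add a second junction 150..300 within the annotated exons
  gal <- make_gal(c(101, 101), c("50M150N50M", "50M150N50M"))
  g <- build_segment_graph(gal, ann, region_1k)
  got <- sort(paste(
    g$segments$end[g$edges$from[g$edges$type == "intron"]],
    g$segments$start[g$edges$to[g$edges$type == "intron"]]))
  expect_equal(got, sort(c("200 300", "150 300")))
})

test_that("segment counts are average per-base coverage and introns need exact gaps", {
  segs <- data.frame(start = 0L, end = 100L)
  reg <- list(chrom = "chr1", start = 0L, end = 100L)
  g <- add_intron_edges(segs, NULL, reg)
  gal <- make_gal(rep(1, 10), rep("50M", 10))
  obs <- count_observations(g, list(gal))
  expect_equal(obs$seg_counts[1, 1], 5.0)      # 10 * 50 / 100
  expect_equal(sum(obs$intron_counts), 0)
  # empty sample: all-zero row, not an error
  obs2 <- count_observations(g, list(gal, make_gal(integer(0), character(0))))
  expect_equal(obs2$seg_counts[2, ], 0)
})

test_that("counts match brute-force per-base accumulation on a random pileup", {
  set.seed(33)
  reg <- list(chrom = "chr1", start = 0L, end = 500L)
  segs <- data.frame(start = c(0L, 100L, 300L), end = c(100L, 250L, 500L))
  g <- add_intron_edges(segs, NULL, reg)
  pos <- sample(1:450, 40, replace = TRUE)
  cig <- rep("40M", 40)
  gal <- make_gal(pos, cig)
  obs <- count_observations(g, list(gal))
  cov <- oracle_coverage(pos, cig, reg)
  for (s in 1:3) {
    expect_equal(obs$seg_counts[1, s],
                 sum(cov[(segs$start[s] + 1):segs$end[s]]) /
                   (segs$end[s] - segs$start[s]))
  }
})

test_that("mate pairs are tallied into segment pair counts", {
  segs <- data.frame(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L))
  reg <- list(chrom = "chr1", start = 0L, end = 300L)
  g <- add_intron_edges(segs, NULL, reg)
  gal <- make_gal(c(1, 231, 11, 241), c("50M", "50M", "50M", "50M"),
                  qname = c("p1", "p1", "p2", "p2"),
                  flag = c(99L, 147L, 99L, 147L))
  obs <- count_observations(g, list(gal))
  pc <- obs$pair_counts[[1]]
  expect_equal(pc$count[pc$s1 == 1 & pc$s2 == 3], 2)
})

test_that("path enumeration matches an independent DP count and the validator", {
  for (n in 0:4) {
    g <- make_cassette_graph(n)
    P <- enumerate_paths(g)
    expect_equal(nrow(P), 2^n)
    expect_equal(nrow(P), oracle_path_count(g))
    for (i in seq_len(nrow(P))) expect_true(is_valid_path(g, P[i, ]))
  }
  # linear chain: one path
  lin <- linear_graph()
  expect_equal(nrow(enumerate_paths(lin)), 1)
  # overflow raises a classed signal, never silent truncation
  expect_error(enumerate_paths(make_cassette_graph(8), limit = 10),
               class = "isomip_path_overflow")
})

test_that("annotation-only graphs reproduce the annotated transcripts exactly", {
  chains <- list(inc = data.frame(start = c(0, 200, 400),
                                  end = c(100, 300, 500)),
                 skp = data.frame(start = c(0, 400), end = c(100, 500)))
  ann <- annotation_from_chains(chains)
  reg <- list(chrom = "chr1", start = 0L, end = 600L)
  g <- build_segment_graph(annotation = ann, region = reg)
  P <- enumerate_paths(g)
  # intron chains of enumerated paths == annotated intron chains
  chain_of <- function(sel) {
    sel <- which(sel != 0)
    if (length(sel) < 2) return("")
    paste(g$segments$end[sel[-length(sel)]], g$segments$start[sel[-1]],
          sep = "-", collapse = ",")
  }
  got <- sort(apply(P, 1, chain_of))
  want <- sort(vapply(chains, function(e) {
    e <- e[order(e$start), ]
    paste(e$end[-nrow(e)], e$start[-1], sep = "-", collapse = ",")
  }, ""))
  expect_equal(got, unname(want))
})

test_that("adding reads never removes segments or edges (completeness bias)", {
  chains <- list(T1 = data.frame(start = c(100, 300), end = c(200, 400)))
  ann <- annotation_from_chains(chains)
  g0 <- build_segment_graph(annotation = ann, region = region_1k)
  gal <- make_gal(c(101, 501), c("50M150N50M", "60M"))
  g1 <- build_segment_graph(gal, ann, region_1k)
  # new boundaries may split segments, but no exonic base and no intron
  # may disappear
  covered <- function(g) {
    unlist(mapply(function(s, e) seq(s, e - 1), g$segments$start,
                  g$segments$end, SIMPLIFY = FALSE))
  }
  intron_key <- function(g) {
    ie <- g$edges$type == "intron"
    paste(g$segments$end[g$edges$from[ie]], g$segments$start[g$edges$to[ie]])
  }
  expect_true(all(covered(g0) %in% covered(g1)))
  expect_true(all(intron_key(g0) %in% intron_key(g1)))
})
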
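nb <- loss_model()

# region helper over the 1-cassette graph
cassette_region <- function(seg, intr) {
  g <- make_cassette_graph(1)
  list(graph = g,
       obs = observation_set(matrix(seg, 1), matrix(intr, 1, nrow(g$edges)),
                             seg_lengths = segment_lengths(g)))
}

# planted fixture: region A expresses the inclusion isoform with a
# 4-read deficit on its cassette segment, region B expresses skip only;
# four multireads hit the cassette segment and start at the wrong
# (B-first) placement
planted_paralogs <- function() {
  regions <- list(A = cassette_region(c(10, 6, 10), c(10, 0, 10)),
                  B = cassette_region(c(8, 0, 8), c(0, 8, 0)))
  E <- nrow(regions$A$graph$edges)
  mr <- lapply(1:4, function(i) {
    multiread(sprintf("m%02d", i), 1, list(
      list(region = 2L, seg_delta = c(0, 1, 0), intron_delta = numeric(E)),
      list(region = 1L, seg_delta = c(0, 1, 0), intron_delta = numeric(E))))
  })
  list(regions = unname(regions), multireads = mr)
}

test_that("without multireads the loop is the identity pipeline", {
  fx <- planted_paralogs()
  out <- mmo_loop(fx$regions, list(), nb,
                  hyper_params(w_sparsity = 15, w_pair = 0))
  expect_true(out$converged)
  expect_identical(out$counts[[1]]$seg, fx$regions[[1]]$obs$seg_counts)
  expect_identical(out$counts[[2]]$seg, fx$regions[[2]]$obs$seg_counts)
  # same transcripts as running the solver directly
  direct <- solve_joint(fx$regions[[1]]$graph, fx$regions[[1]]$obs, nb,
                        hyper_params(w_sparsity = 15, w_pair = 0))
  expect_equal(out$fits[[1]]$tset$U, direct$tset$U)
})

test_that("a read moves to the region with the matching coverage deficit", {
  fx <- planted_paralogs()
  counts <- lapply(fx$regions, function(rg)
    list(seg = rg$obs$seg_counts, intron = rg$obs$intron_counts))
  # read currently in region B (candidate 1)
  counts[[2]]$seg[1, 2] <- counts[[2]]$seg[1, 2] + 1
  expected <- list(list(V_exp = matrix(c(10, 10, 10), 1),
                        I_exp = matrix(c(10, 0, 10), 1)),
                   list(V_exp = matrix(c(8, 0, 8), 1),
                        I_exp = matrix(c(0, 8, 0), 1)))
  rd <- mmo_round(fx$multireads[1], counts, expected, assignments = 1L,
                  model = nb)
  expect_equal(rd$assignments, 2L)
  expect_equal(rd$n_changed, 1L)
  expect_equal(rd$counts[[1]]$seg[1, 2], 7)   # landed in region A
  expect_equal(rd$counts[[2]]$seg[1, 2], 0)
})

test_that("exact ties resolve to the earliest candidate, deterministically", {
  g <- linear_graph()
  mk <- function(seg) list(seg = matrix(seg, 1),
                           intron = matrix(0, 1, nrow(g$edges)))
  counts <- list(mk(c(5, 5)), mk(c(5, 6)))  # read currently in region 2
  expected <- list(list(V_exp = matrix(c(5, 5), 1), I_exp = matrix(0, 1, 1)),
                   list(V_exp = matrix(c(5, 5), 1), I_exp = matrix(0, 1, 1)))
  mr <- list(multiread("t1", 1, list(
    list(region = 1L, seg_delta = c(0, 1), intron_delta = 0),
    list(region = 2L, seg_delta = c(0, 1), intron_delta = 0))))
  rd <- mmo_round(mr, counts, expected, assignments = 2L, model = nb)
  expect_equal(rd$assignments, 1L)
  # re-running from the result changes nothing
  rd2 <- mmo_round(mr, rd$counts, expected, rd$assignments, model = nb)
  expect_equal(rd2$n_changed, 0L)
})

test_that("the EM-like loop recovers the planted assignment and splits coverage exactly", {
  fx <- planted_paralogs()
  out <- mmo_loop(fx$regions, fx$multireads, nb,
                  hyper_params(w_sparsity = 15, w_pair = 0))
  expect_true(out$converged)
  expect_equal(out$assignments, rep(2L, 4))          # all reads to region A
  expect_equal(out$counts[[1]]$seg[1, ], c(10, 10, 10))
  expect_equal(out$counts[[2]]$seg[1, ], c(8, 0, 8))
  expect_true(all(diff(out$objective_trace) <= 1e-9))
})

test_that("converged assignments are a coordinate-descent fixpoint", {
  # oracle: with expectations frozen, no single-read move lowers the
  # total exact NLL
  set.seed(63)
  fx <- planted_paralogs()
  extra <- lapply(1:20, function(i) {
    deltas <- diag(3)[sample.int(3, 1), ]
    multiread(sprintf("x%02d", i), 1, list(
      list(region = sample.int(2, 1), seg_delta = deltas,
           intron_delta = numeric(3)),
      list(region = sample.int(2, 1), seg_delta = deltas,
           intron_delta = numeric(3))))
  })
  mrs <- c(fx$multireads, extra)
  out <- mmo_loop(fx$regions, mrs, nb,
                  hyper_params(w_sparsity = 15, w_pair = 0), max_iters = 20)
  expected <- lapply(out$fits, `[[`, "expected")
  total_loss <- function(counts) {
    tot <- 0
    for (gix in 1:2) {
      tot <- tot + sum(nll_count(counts[[gix]]$seg[1, ],
                                 expected[[gix]]$V_exp[1, ], nb)) +
        sum(nll_count(counts[[gix]]$intron[1, ],
                      expected[[gix]]$I_exp[1, ], nb))
    }
    tot
  }
  base <- total_loss(out$counts)
  for (k in seq_along(mrs)) {
    cur <- out$assignments[k]
    for (j in seq_along(mrs[[k]]$candidates)) {
      if (j == cur) next
      cts <- out$counts
      cd_c <- mrs[[k]]$candidates[[cur]]; cd_j <- mrs[[k]]$candidates[[j]]
      cts[[cd_c$region]]$seg[1, ] <- cts[[cd_c$region]]$seg[1, ] - cd_c$seg_delta
      cts[[cd_j$region]]$seg[1, ] <- cts[[cd_j$region]]$seg[1, ] + cd_j$seg_delta
      expect_gte(total_loss(cts), base - 1e-9)
    }
  }
})

test_that("the loop objective is non-increasing on random fixtures", {
  set.seed(71)
  for (rep in 1:3) {
    regions <- list(cassette_region(round(runif(3, 2, 12)), runif(3, 0, 8)),
                    cassette_region(round(runif(3, 2, 12)), runif(3, 0, 8)))
    mrs <- lapply(1:6, function(i) {
      d <- diag(3)[sample.int(3, 1), ]
      multiread(sprintf("r%02d", i), 1, list(
        list(region = 1L, seg_delta = d, intron_delta = numeric(3)),
        list(region = 2L, seg_delta = d, intron_delta = numeric(3))))
    })
    out <- mmo_loop(regions, mrs, nb,
                    hyper_params(w_sparsity = 5, w_pair = 0), max_iters = 8)
    expect_true(all(diff(out$objective_trace) <= 1e-9))
  }
})
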
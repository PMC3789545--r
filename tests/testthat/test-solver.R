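nb <- loss_model()

test_that("validity constraints admit exactly the valid paths plus the zero row", {
  g <- make_cassette_graph(3)
  cs <- build_validity_constraints(g)
  n_feas <- 0
  for (msk in 0:(2^7 - 1)) {
    u <- as.integer(bitwAnd(msk, 2^(0:6)) > 0)
    feas <- all(cs$A %*% u <= cs$b + 1e-9)
    valid <- is_valid_path(g, u) || all(u == 0)
    expect_equal(feas, valid)
    if (feas) n_feas <- n_feas + 1
  }
  expect_equal(n_feas, 8 + 1)
  # linear chain: unique nonzero feasible row
  lin <- make_cassette_graph(0)
  cs2 <- build_validity_constraints(lin)
  expect_true(all(cs2$A %*% 1 <= cs2$b))
  # a lone middle (non-initial / non-terminal) segment is infeasible
  g1 <- make_cassette_graph(1)
  cs3 <- build_validity_constraints(g1)
  expect_false(all(cs3$A %*% c(0, 1, 0) <= cs3$b + 1e-9))
})

test_that("transcript sets validate their rows and derive intron usage", {
  g <- make_cassette_graph(1)
  ts <- transcript_set(g, rbind(c(1, 1, 1), c(1, 0, 1)))
  # inclusion path uses the two flanking introns, skip path the skip intron
  ie <- g$edges
  skip_edge <- which(ie$from == 1 & ie$to == 3)
  expect_equal(ts$intron_use[1, skip_edge], 0)
  expect_equal(ts$intron_use[2, skip_edge], 1)
  expect_equal(sum(ts$intron_use[1, ]), 2)
  expect_error(transcript_set(g, rbind(c(0, 1, 0))), "not a valid path")
})

test_that("quantification of a fixed transcript set recovers planted abundances", {
  g <- make_cassette_graph(0)
  ts <- transcript_set(g, matrix(1, 1, 1))
  obs <- observation_set(matrix(7, 1, 1), matrix(0, 1, 0),
                         seg_lengths = 100)
  q <- quantify_fixed(ts, obs, nb)
  expect_equal(q$c, 7)
  expect_equal(q$W[1, 1], 1, tolerance = 1e-4)   # W = v / c
  # two transcripts sharing no segments decouple into independent fits
  set.seed(8)
  inst <- simulate_samples(rbind(c(1, 1, 1), c(0, 0, 0)), 2, n_cassettes = 3)
  ts2 <- transcript_set(inst$graph,
                        isomip:::.patterns_to_u(inst$graph, inst$true_set))
  q2 <- quantify_fixed(ts2, inst$obs, nb)
  expect_equal(q2$c * q2$W, inst$abundances, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("quantification matches a projected-gradient oracle", {
  set.seed(21)
  for (rep in 1:3) {
    idx <- sample.int(8, 2)
    inst <- simulate_samples(idx, 1, n_cassettes = 3)
    U <- enumerate_paths(inst$graph)[sample.int(8, 4), , drop = FALSE]
    ts <- transcript_set(inst$graph, U)
    q <- quantify_fixed(ts, inst$obs, nb)
    pg <- oracle_projected_gradient(ts, inst$obs, nb, r = 1)
    expect_lt(abs(q$loss[1] - pg$loss), 1e-4 * max(1, abs(pg$loss)))
  }
})

test_that("pair penalty counts uncovered pair support", {
  g <- make_cassette_graph(1)
  ts_inc <- transcript_set(g, rbind(c(1, 1, 1)))
  pc <- data.frame(s1 = 1, s2 = 3, count = 7)
  expect_equal(pair_penalty(ts_inc, pc), 0)          # covered
  ts_none <- transcript_set(g, matrix(0, 0, 3))
  expect_equal(pair_penalty(ts_none, pc), 7)         # uncovered
  # brute-force scan oracle on random instances
  set.seed(4)
  g3 <- make_cassette_graph(3)
  P <- enumerate_paths(g3)
  for (rep in 1:5) {
    ts <- transcript_set(g3, P[sample.int(8, 3), , drop = FALSE])
    pairs <- data.frame(s1 = sample.int(7, 4, replace = TRUE),
                        s2 = sample.int(7, 4, replace = TRUE),
                        count = sample.int(5, 4, replace = TRUE))
    scan <- 0
    for (i in 1:4) {
      hit <- FALSE
      for (t in 1:3) {
        if (ts$U[t, pairs$s1[i]] == 1 && ts$U[t, pairs$s2[i]] == 1) hit <- TRUE
      }
      if (!hit) scan <- scan + pairs$count[i]
    }
    expect_equal(pair_penalty(ts, pairs), scan)
  }
})

test_that("exact solver recovers a single noiseless transcript", {
  set.seed(3)
  inst <- simulate_samples(matrix(c(1, 0, 1), 1), 1, n_cassettes = 3)
  res <- solve_joint(inst$graph, inst$obs, nb,
                     hyper_params(w_sparsity = 0.05, w_pair = 0))
  expect_equal(res$status, "optimal")
  expect_equal(nrow(res$tset$U), 1)
  expect_equal(res$tset$U[1, ],
               isomip:::.patterns_to_u(inst$graph, inst$true_set)[1, ])
  expect_equal(res$W[1, 1] * res$c, 1, tolerance = 0.01)
})

test_that("two expressed transcripts are recovered exactly from one sample", {
  # the 2-of-8 regime is always identifiable, so the solver must find
  # exactly the two true paths
  set.seed(14)
  for (rep in 1:5) {
    idx <- sample.int(8, 2)
    inst <- simulate_samples(idx, 1, n_cassettes = 3)
    res <- solve_joint(inst$graph, inst$obs, nb,
                       hyper_params(w_sparsity = 0.05, w_pair = 0))
    trueU <- isomip:::.patterns_to_u(inst$graph, inst$true_set)
    key <- function(U) sort(apply(U, 1, paste, collapse = ""))
    expect_equal(key(res$tset$U), key(trueU))
  }
})

test_that("exact mode attains the exhaustive-enumeration optimum", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(2:3, 1)
    R <- sample(1:3, 1)
    idx <- sample.int(2^n, sample(1:3, 1))
    inst <- simulate_samples(idx, R, n_cassettes = n)
    # perturb counts so the fit is not exact (random instance)
    obs <- inst$obs
    obs$seg_counts <- obs$seg_counts * matrix(runif(length(obs$seg_counts),
                                                    0.8, 1.2),
                                              nrow(obs$seg_counts))
    hp <- hyper_params(w_sparsity = runif(1, 0.01, 0.3), w_pair = 0,
                       k_max = 8L)
    res <- solve_joint(inst$graph, obs, nb, hp, mode = "exact")
    bf <- oracle_best_subset(inst$graph, obs, nb, hp)
    expect_rel_equal(res$objective, bf$objective, 1e-6)
  }
})

test_that("increasing the sparsity weight never adds transcripts", {
  set.seed(77)
  inst <- simulate_samples(sample.int(8, 3), 2, n_cassettes = 3)
  ks <- vapply(c(0.01, 0.1, 0.5, 2, 10), function(ws) {
    nrow(solve_joint(inst$graph, inst$obs, nb,
                     hyper_params(w_sparsity = ws, w_pair = 0))$tset$U)
  }, 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("joint multi-sample solving beats solving merged counts", {
  # an instance where four samples pin down the true triple but the
  # merged (summed) counts admit a cheaper two-transcript explanation
  set.seed(1)
  idx <- sample.int(8, 3)
  inst <- simulate_samples(idx, 4, n_cassettes = 3)
  merged_obs <- observation_set(matrix(colMeans(inst$obs$seg_counts), 1),
                                matrix(colMeans(inst$obs$intron_counts), 1),
                                seg_lengths = inst$obs$seg_lengths)
  hp <- hyper_params(w_sparsity = 0.02, w_pair = 0)
  res4 <- solve_joint(inst$graph, inst$obs, nb, hp)
  resm <- solve_joint(inst$graph, merged_obs, nb, hp)
  trueU <- isomip:::.patterns_to_u(inst$graph, inst$true_set)
  key <- function(U) paste(sort(apply(U, 1, paste, collapse = "")),
                           collapse = "|")
  expect_equal(key(res4$tset$U), key(trueU))
  expect_false(key(resm$tset$U) == key(trueU))
})

test_that("known transcripts suppress novel rows on noiseless data", {
  set.seed(9)
  idx <- sample.int(8, 2)
  inst <- simulate_samples(idx, 2, n_cassettes = 3)
  known <- isomip:::.patterns_to_u(inst$graph, inst$true_set)
  res <- solve_joint(inst$graph, inst$obs, nb,
                     hyper_params(w_sparsity = 5, w_pair = 0,
                                  w_known_discount = 0.1),
                     known = known)
  expect_true(all(res$tset$provenance == "known"))
  key <- function(U) sort(apply(U, 1, paste, collapse = ""))
  expect_equal(key(res$tset$U), key(known))
})

test_that("iterative mode descends greedily and stays feasible", {
  set.seed(31)
  inst <- simulate_samples(sample.int(8, 3), 2, n_cassettes = 3)
  hp <- hyper_params(w_sparsity = 0.05, w_pair = 0)
  it <- solve_joint(inst$graph, inst$obs, nb, hp, mode = "iterative")
  ex <- solve_joint(inst$graph, inst$obs, nb, hp, mode = "exact")
  expect_equal(it$status, "approximate")
  expect_gte(it$objective + 1e-9, ex$objective)
  for (t in seq_len(nrow(it$tset$U))) {
    expect_true(is_valid_path(inst$graph, it$tset$U[t, ]))
  }
  # objective decomposition is consistent
  expect_rel_equal(ex$objective,
                   ex$breakdown$fit + ex$breakdown$pair +
                     ex$breakdown$sparsity, 1e-6)
})

test_that("solver errors are informative", {
  g <- make_cassette_graph(1)
  obs <- observation_set(matrix(1, 1, 3), matrix(1, 1, 3),
                         seg_lengths = segment_lengths(g))
  expect_error(solve_joint(g, obs, nb, hyper_params(k_max = 0L),
                           known = rbind(c(1, 1, 1))),
               "k_max")
  # graph without terminal flags is rejected by the constraint builder
  g_bad <- g
  g_bad$segments$is_terminal <- FALSE
  expect_error(build_validity_constraints(g_bad), "initial or terminal")
})
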
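#' Cassette-exon toy splicing graph
#'
#' Builds the canonical identifiability test case: `n` independent
#' cassette exons between `n + 1` constitutive exons, giving `2n + 1`
#' segments, `3n` junction edges (two inclusion introns and one skip
#' intron per cassette) and `2^n` source-to-sink paths.  Exons and
#' introns are laid out as 100-base blocks on a synthetic chromosome.
#'
#' @param n_cassettes number of cassette exons (`n = 0` gives a single
#'   constitutive segment with one path).
#' @return a `segment_graph`.
#' @export
make_cassette_graph <- function(n_cassettes) {
  n <- as.integer(n_cassettes)
  stopifnot(n >= 0)
  S <- 2L * n + 1L
  block <- 100L
  start <- (seq_len(S) - 1L) * 2L * block      # 100 bp exon + 100 bp gap
  segs <- data.frame(start = start, end = start + block,
                     is_initial = c(TRUE, rep(FALSE, S - 1L)),
                     is_terminal = c(rep(FALSE, S - 1L), TRUE))
  ed <- data.frame(from = integer(), to = integer(),
                   type = character(), source = character())
  for (i in seq_len(n)) {
    cas <- 2L * i
    ed <- rbind(ed,
                data.frame(from = c(cas - 1L, cas, cas - 1L),
                           to = c(cas, cas + 1L, cas + 1L),
                           type = "intron", source = "read"))
  }
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(chrom = "toy", strand = "+",
                 region_start = 0L, region_end = max(segs$end),
                 segments = segs, edges = ed),
            class = "segment_graph")
}

## inclusion patterns (rows over cassettes) -> binary rows over segments
.patterns_to_u <- function(graph, patterns) {
  n <- (nrow(graph$segments) - 1L) %/% 2L
  if (n == 0L) return(matrix(1L, nrow(patterns), 1L))
  patterns <- matrix(as.integer(patterns), ncol = n)
  k <- nrow(patterns)
  U <- matrix(0L, k, nrow(graph$segments))
  U[, seq(1L, 2L * n + 1L, by = 2L)] <- 1L   # constitutive exons
  for (i in seq_len(n)) U[, 2L * i] <- patterns[, i]
  U
}

## all 2^n inclusion patterns in a fixed lexicographic order
.all_patterns <- function(n) {
  if (n == 0) return(matrix(integer(0), 1, 0))
  as.matrix(rev(expand.grid(rep(list(0:1), n))))[, seq_len(n), drop = FALSE]
}

#' Simulate exact expected observations for a toy instance
#'
#' For each sample, positive abundances are drawn independently and
#' uniformly for the expressed transcripts and renormalized to sum to
#' one ("uniformly redistributed"); the segment coverages and junction
#' counts are then the exact expectations implied by those abundances —
#' statistical fluctuations are deliberately ignored, which isolates the
#' combinatorial identifiability question from estimation noise.
#'
#' @param true_set matrix of inclusion patterns (rows = expressed
#'   transcripts, columns = cassettes), or a vector of pattern indices
#'   into the lexicographic enumeration of all `2^n` patterns.
#' @param n_samples number of samples.
#' @param n_cassettes number of cassettes (inferred from `true_set` when
#'   it is a matrix).
#' @return an object of class `toy_instance` with fields `graph`,
#'   `n_cassettes`, `true_set` (pattern matrix), `abundances`
#'   (transcripts x samples) and `obs` (an [observation_set()] of exact
#'   expectations).
#' @export
simulate_samples <- function(true_set, n_samples, n_cassettes = NULL) {
  if (is.matrix(true_set)) {
    n <- ncol(true_set)
    patterns <- true_set
  } else {
    stopifnot(!is.null(n_cassettes))
    n <- n_cassettes
    patterns <- .all_patterns(n)[true_set, , drop = FALSE]
  }
  if (anyDuplicated(apply(patterns, 1, paste, collapse = ""))) {
    stop("simulate_samples: true_set patterns must be distinct")
  }
  graph <- make_cassette_graph(n)
  U <- .patterns_to_u(graph, patterns)
  iu <- .intron_usage(graph, U)
  k <- nrow(U)
  A <- matrix(0, k, n_samples)
  for (r in seq_len(n_samples)) {
    u <- stats::runif(k)
    A[, r] <- u / sum(u)
  }
  seg <- t(crossprod(U, A))        # samples x segments
  intr <- t(crossprod(iu, A))      # samples x edges
  obs <- observation_set(seg, intr,
                         seg_lengths = segment_lengths(graph))
  structure(list(graph = graph, n_cassettes = n, true_set = patterns,
                 abundances = A, obs = obs),
            class = "toy_instance")
}

#' @export
print.toy_instance <- function(x, ...) {
  cat(sprintf("toy_instance: %d cassettes, %d expressed transcripts, %d samples\n",
              x$n_cassettes, nrow(x$true_set), x$obs$n_samples))
  invisible(x)
}

## can subset `idx` (columns of M) reproduce b exactly with strictly
## positive weights?  M is the (segments+edges) x transcripts matrix.
.positive_exact_fit <- function(M, idx, b, tol = 1e-8, pos_tol = 1e-8) {
  A <- M[, idx, drop = FALSE]
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  rank <- sum(sv$d > max(dim(A)) * max(sv$d, 0) * 1e-12)
  # min-norm least-squares solution
  dinv <- ifelse(sv$d > max(sv$d[1], 1e-300) * 1e-12, 1 / sv$d, 0)
  w0 <- sv$v %*% (dinv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], b))
  w0 <- as.vector(w0)
  if (max(abs(A %*% w0 - b)) > tol) return(FALSE)
  d <- ncol(A) - rank
  if (d == 0) return(min(w0) > pos_tol)
  N <- sv$v[, (rank + 1):ncol(A), drop = FALSE]
  if (d == 1) {
    n1 <- N[, 1]
    lo <- -Inf; hi <- Inf
    for (i in seq_along(w0)) {
      if (n1[i] > 1e-12) lo <- max(lo, (pos_tol - w0[i]) / n1[i])
      else if (n1[i] < -1e-12) hi <- min(hi, (pos_tol - w0[i]) / n1[i])
      else if (w0[i] <= pos_tol) return(FALSE)
    }
    return(lo <= hi)
  }
  # d >= 2: maximize the minimum coordinate by linear programming
  m <- length(w0)
  Ain <- cbind(-N, rep(1, m))          # t - (N z)_i <= w0_i
  res <- tryCatch(
    pracma::linprog(cc = c(rep(0, d), 1), A = Ain, b = w0,
                    maximize = TRUE,
                    lb = rep(-Inf, d + 1), ub = rep(Inf, d + 1)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$fval)) return(FALSE)
  res$fval >= pos_tol
}

#' Transcript sets consistent with exact observations
#'
#' Enumerates candidate transcript subsets in increasing cardinality;
#' a subset is consistent with one sample iff strictly positive
#' abundances exist whose exact expected segment coverages and junction
#' counts equal that sample's observations (linear feasibility with
#' positivity).  Returns every subset of the minimal cardinality at
#' which the per-sample consistent sets have a nonempty intersection
#' across all samples.  The true set is always among the results.
#'
#' @param instance a `toy_instance` from [simulate_samples()].
#' @param tol exact-match tolerance on observations.
#' @param pos_tol strict-positivity threshold on abundances.
#' @return list of integer vectors: indices into the lexicographic
#'   enumeration of all `2^n` inclusion patterns.
#' @export
consistent_sets <- function(instance, tol = 1e-8, pos_tol = 1e-8) {
  n <- instance$n_cassettes
  graph <- instance$graph
  pats <- .all_patterns(n)
  Uall <- .patterns_to_u(graph, pats)
  iu <- .intron_usage(graph, Uall)
  M <- rbind(t(Uall), t(iu))       # (segments + edges) x transcripts
  R <- instance$obs$n_samples
  bs <- lapply(seq_len(R), function(r)
    c(instance$obs$seg_counts[r, ], instance$obs$intron_counts[r, ]))
  n_tx <- nrow(pats)
  for (m in seq_len(n_tx)) {
    subsets <- utils::combn(n_tx, m, simplify = FALSE)
    surviving <- subsets
    for (r in seq_len(R)) {
      surviving <- Filter(function(idx)
        .positive_exact_fit(M, idx, bs[[r]], tol, pos_tol), surviving)
      if (!length(surviving)) break
    }
    if (length(surviving)) return(surviving)
  }
  list()  # unreachable: the true set is always consistent
}

#' Identifiability success rates of the cassette toy model
#'
#' Repeats the simulation of [simulate_samples()] + [consistent_sets()]
#' and reports (a) the fraction of trials in which exactly one
#' transcript set is consistent with every sample ("identifiable"), and
#' (b) the expected success rate of picking uniformly at random among
#' the consistent sets (the best possible strategy when several remain;
#' equals the mean reciprocal of the number of consistent sets, since
#' the true set is always one of them).
#'
#' @param n_cassettes number of cassette exons.
#' @param set_size number of expressed transcripts per trial.
#' @param n_samples samples per trial (shared transcript set,
#'   independently redrawn abundances).
#' @param n_trials number of trials.
#' @return named numeric vector: `unique_fraction`,
#'   `optimal_strategy_fraction` (both in `[0, 1]`), with `n_trials` as
#'   an attribute.
#' @export
success_rates <- function(n_cassettes, set_size, n_samples, n_trials) {
  stopifnot(n_trials >= 1)
  n_tx <- 2^n_cassettes
  stopifnot(set_size >= 1, set_size <= n_tx)
  uniq <- 0; recip <- 0
  for (tr in seq_len(n_trials)) {
    idx <- sample.int(n_tx, set_size)
    inst <- simulate_samples(idx, n_samples, n_cassettes = n_cassettes)
    sets <- consistent_sets(inst)
    k <- length(sets)
    if (k == 1) uniq <- uniq + 1
    recip <- recip + 1 / k
  }
  structure(c(unique_fraction = uniq / n_trials,
              optimal_strategy_fraction = recip / n_trials),
            n_trials = n_trials)
}

#' Probability of guessing the expressed transcript set at random
#'
#' @param n_transcripts number of candidate transcripts.
#' @param set_size number of expressed transcripts.
#' @return the probability `1 / choose(n_transcripts, set_size)`,
#'   expressed as a percentage.
#' @export
random_guess_probability <- function(n_transcripts, set_size) {
  if (set_size <= 0 || set_size > n_transcripts) {
    stop("random_guess_probability: need 0 < set_size <= n_transcripts")
  }
  100 / choose(n_transcripts, set_size)
}
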
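#' A multi-mapping read and its candidate placements
#'
#' @param id read identifier (used for the deterministic processing
#'   order).
#' @param sample sample index the read belongs to.
#' @param candidates list of candidate placements, each a
#'   `list(region =, seg_delta =, intron_delta =)`: the region index and
#'   the segment-coverage / intron-count increments the read contributes
#'   there.  Candidates are expected in genomic (lowest-coordinate
#'   first) order; ties in score resolve to the earliest candidate.
#' @return an object of class `multiread`.
#' @export
multiread <- function(id, sample, candidates) {
  stopifnot(length(candidates) >= 2)
  structure(list(id = id, sample = sample, candidates = candidates),
            class = "multiread")
}

## loss of one region/sample slice at given counts vs expectations
.slice_loss <- function(seg_v, seg_mu, int_v, int_mu, model, w_intron) {
  loss <- sum(nll_count(seg_v, seg_mu, model))
  if (length(int_v)) loss <- loss + w_intron * sum(nll_count(int_v, int_mu, model))
  loss
}

#' One round of loss-guided multi-mapper reassignment
#'
#' Processes the reads in id order; each read is moved to the candidate
#' placement that minimizes the summed count loss of the affected
#' regions, holding the expected coverages fixed.  Only strictly
#' improving moves are taken; equal-loss alternatives keep the
#' earliest (lowest-coordinate) candidate.
#'
#' @param multireads list of [multiread()] objects.
#' @param counts list per region of `list(seg = samples x segments
#'   matrix, intron = samples x edges matrix)` — current observed counts
#'   including each multiread at its assigned placement.
#' @param expected list per region of `list(V_exp =, I_exp =)` expected
#'   count matrices (same shapes), or `NULL` for regions without a
#'   fitted model (scored against background only, i.e. expectation 0).
#' @param assignments integer vector: current candidate index per read.
#' @param model a [loss_model()].
#' @param w_intron intron-loss weight.
#' @return list with updated `assignments`, `counts`, and `n_changed`.
#' @export
mmo_round <- function(multireads, counts, expected, assignments, model,
                      w_intron = 1) {
  ord <- order(vapply(multireads, function(m) as.character(m$id), ""))
  n_changed <- 0L
  exp_of <- function(reg, r, what) {
    e <- expected[[reg]]
    if (is.null(e)) {
      dims <- counts[[reg]][[if (what == "V_exp") "seg" else "intron"]]
      return(numeric(ncol(dims)))
    }
    e[[what]][r, ]
  }
  # score of placing the read at candidate j = the increase in that
  # region's loss over its read-free state; regions untouched by a
  # candidate contribute equally to every option and cancel
  cand_loss <- function(m, j) {
    reg <- m$candidates[[j]]$region; r <- m$sample
    sd <- m$candidates[[j]]$seg_delta
    id <- m$candidates[[j]]$intron_delta
    segv <- counts[[reg]]$seg[r, ]
    intv <- counts[[reg]]$intron[r, ]
    mu_s <- exp_of(reg, r, "V_exp"); mu_e <- exp_of(reg, r, "I_exp")
    .slice_loss(segv + sd, mu_s, intv + id, mu_e, model, w_intron) -
      .slice_loss(segv, mu_s, intv, mu_e, model, w_intron)
  }
  apply_delta <- function(m, j, sign) {
    reg <- m$candidates[[j]]$region; r <- m$sample
    counts[[reg]]$seg[r, ] <<- counts[[reg]]$seg[r, ] +
      sign * m$candidates[[j]]$seg_delta
    counts[[reg]]$intron[r, ] <<- counts[[reg]]$intron[r, ] +
      sign * m$candidates[[j]]$intron_delta
  }
  for (k in ord) {
    m <- multireads[[k]]
    cur <- assignments[k]
    apply_delta(m, cur, -1)   # lift the read out
    scores <- vapply(seq_along(m$candidates), function(j) cand_loss(m, j), 0)
    best <- which.min(scores)  # which.min takes the earliest on exact ties
    move <- best != cur &&
      (scores[best] < scores[cur] - 1e-12 ||
         (best < cur && scores[best] <= scores[cur] + 1e-12))
    if (move) {
      assignments[k] <- best
      n_changed <- n_changed + 1L
      apply_delta(m, best, +1)
    } else {
      apply_delta(m, cur, +1)
    }
  }
  list(assignments = assignments, counts = counts, n_changed = n_changed)
}

#' Alternate transcript fitting and multi-mapper reassignment
#'
#' Expectation-maximization-like loop: given current read placements,
#' transcripts are (re)quantified per region to obtain expected
#' coverages; each multi-mapping read is then reassigned to the
#' placement minimizing the count loss.  Iterations that fail to lower
#' the total exact NLL are rejected, so the reported objective sequence
#' is non-increasing; the loop stops on convergence (no reassignment),
#' an oscillation (a previously seen assignment recurs), a rejected
#' iteration, or `max_iters`.
#'
#' @param regions list per region of `list(graph =, obs =)`, where `obs`
#'   is an [observation_set()] holding counts of uniquely mapping reads
#'   only.
#' @param multireads list of [multiread()] objects; initial assignment
#'   is the first (primary) candidate.
#' @param model a [loss_model()].
#' @param hyper a [hyper_params()] for the per-region solve.
#' @param max_iters maximum loop iterations.
#' @param refit `"quantify"` re-fits abundances with the transcript sets
#'   from the first iteration's solve; `"solve"` re-runs transcript
#'   selection every iteration.
#' @return list with `assignments`, final per-region `counts`, `fits`
#'   (per-region solve results), `objective_trace`, `iterations`,
#'   `converged`, `oscillation`.
#' @export
mmo_loop <- function(regions, multireads, model, hyper = hyper_params(),
                     max_iters = 10L, refit = c("quantify", "solve")) {
  refit <- match.arg(refit)
  n_reg <- length(regions)
  assignments <- rep(1L, length(multireads))
  base_counts <- lapply(regions, function(rg)
    list(seg = rg$obs$seg_counts, intron = rg$obs$intron_counts))
  add_assigned <- function(counts, assignments) {
    for (k in seq_along(multireads)) {
      m <- multireads[[k]]; cd <- m$candidates[[assignments[k]]]
      counts[[cd$region]]$seg[m$sample, ] <-
        counts[[cd$region]]$seg[m$sample, ] + cd$seg_delta
      counts[[cd$region]]$intron[m$sample, ] <-
        counts[[cd$region]]$intron[m$sample, ] + cd$intron_delta
    }
    counts
  }
  obs_from_counts <- function(rg, cts) {
    observation_set(cts$seg, cts$intron, rg$obs$pair_counts,
                    rg$obs$seg_lengths)
  }
  fits <- vector("list", n_reg)
  tsets <- vector("list", n_reg)
  total_nll <- function(counts, expected) {
    tot <- 0
    for (g in seq_len(n_reg)) {
      R <- nrow(counts[[g]]$seg)
      for (r in seq_len(R)) {
        mu_s <- if (is.null(expected[[g]])) numeric(ncol(counts[[g]]$seg))
                else expected[[g]]$V_exp[r, ]
        mu_e <- if (is.null(expected[[g]])) numeric(ncol(counts[[g]]$intron))
                else expected[[g]]$I_exp[r, ]
        tot <- tot + .slice_loss(counts[[g]]$seg[r, ], mu_s,
                                 counts[[g]]$intron[r, ], mu_e, model,
                                 hyper$w_intron)
      }
    }
    tot
  }
  counts <- add_assigned(base_counts, assignments)
  trace <- numeric(0)
  seen <- character(0)
  oscillation <- FALSE; converged <- FALSE
  best_obj <- Inf
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    # (re)fit transcripts/abundances on the current counts
    for (g in seq_len(n_reg)) {
      obs_g <- obs_from_counts(regions[[g]], counts[[g]])
      if (is.null(tsets[[g]]) || refit == "solve") {
        fits[[g]] <- solve_joint(regions[[g]]$graph, obs_g, model, hyper)
        tsets[[g]] <- fits[[g]]$tset
      }
      q <- quantify_fixed(tsets[[g]], obs_g, model, hyper$w_intron)
      k_g <- nrow(tsets[[g]]$U)
      V_exp <- matrix(0, obs_g$n_samples, ncol(obs_g$seg_counts))
      I_exp <- matrix(0, obs_g$n_samples, ncol(obs_g$intron_counts))
      if (k_g) {
        for (r in seq_len(obs_g$n_samples)) {
          V_exp[r, ] <- q$c * as.vector(crossprod(tsets[[g]]$U, q$W[, r]))
          I_exp[r, ] <- q$c *
            as.vector(crossprod(tsets[[g]]$intron_use, q$W[, r]))
        }
      }
      fits[[g]]$W <- q$W; fits[[g]]$c <- q$c
      fits[[g]]$expected <- list(V_exp = V_exp, I_exp = I_exp)
    }
    expected <- lapply(fits, `[[`, "expected")
    obj_before_round <- total_nll(counts, expected)
    if (obj_before_round > best_obj + 1e-9) break  # reject non-improving refit
    best_obj <- min(best_obj, obj_before_round)
    rd <- mmo_round(multireads, counts, expected, assignments, model,
                    hyper$w_intron)
    obj_after <- total_nll(rd$counts, expected)
    trace <- c(trace, obj_after)
    best_obj <- min(best_obj, obj_after)
    assignments <- rd$assignments
    counts <- rd$counts
    if (rd$n_changed == 0L) { converged <- TRUE; break }
    key <- paste(assignments, collapse = ",")
    if (key %in% seen) { oscillation <- TRUE; break }
    seen <- c(seen, key)
  }
  if (!length(multireads)) converged <- TRUE
  list(assignments = assignments, counts = counts, fits = fits,
       objective_trace = trace, iterations = iter,
       converged = converged, oscillation = oscillation)
}
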
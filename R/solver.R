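#' Transcript set over a splicing graph
#'
#' A binary transcript-by-segment matrix whose nonzero rows are valid
#' paths of the graph, together with the derived per-transcript intron
#' usage indicators (a transcript uses intron edge `(i, j)` iff it
#' selects both endpoints and nothing in between).
#'
#' @param graph a `segment_graph`.
#' @param U binary matrix, transcripts x segments.
#' @param provenance character vector (`"known"`/`"novel"`), recycled.
#' @return an object of class `transcript_set` with fields `graph`,
#'   `U`, `provenance`, `intron_use` (transcripts x edges).
#' @export
transcript_set <- function(graph, U, provenance = "novel") {
  U <- as.matrix(U)
  if (ncol(U) != nrow(graph$segments)) {
    stop("transcript_set: U must have one column per segment")
  }
  for (t in seq_len(nrow(U))) {
    if (any(U[t, ] != 0) && !is_valid_path(graph, U[t, ])) {
      stop("transcript_set: row ", t, " is not a valid path")
    }
  }
  structure(list(graph = graph, U = U,
                 provenance = rep_len(provenance, nrow(U)),
                 intron_use = .intron_usage(graph, U)),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts over %d segments (%d known)\n",
              nrow(x$U), ncol(x$U), sum(x$provenance == "known")))
  invisible(x)
}

.intron_usage <- function(graph, U) {
  k <- nrow(U); E <- nrow(graph$edges)
  use <- matrix(0L, k, E)
  for (t in seq_len(k)) {
    sel <- which(U[t, ] != 0)
    if (length(sel) < 2) next
    pairs <- cbind(sel[-length(sel)], sel[-1])
    for (e in seq_len(E)) {
      f <- graph$edges$from[e]; to <- graph$edges$to[e]
      if (any(pairs[, 1] == f & pairs[, 2] == to)) use[t, e] <- 1L
    }
  }
  use
}

#' Hyper-parameters of the joint objective
#'
#' @param w_sparsity weight on the number of selected transcripts (the
#'   row-sparsity / Occam's razor term).
#' @param w_intron weight on the intron-count loss relative to the
#'   segment-coverage loss.
#' @param w_pair weight on the paired-end penalty.
#' @param w_known_discount multiplicative discount (`0..1`) on the
#'   sparsity charge of annotated transcripts, so novel transcripts are
#'   penalized harder than known ones.
#' @param k_max maximum number of transcripts.
#' @return an object of class `hyper_params`.
#' @export
hyper_params <- function(w_sparsity = 1, w_intron = 1, w_pair = 0.1,
                         w_known_discount = 0.25, k_max = 16L) {
  stopifnot(w_sparsity >= 0, w_intron >= 0, w_pair >= 0,
            w_known_discount >= 0, w_known_discount <= 1, k_max >= 0)
  structure(list(w_sparsity = w_sparsity, w_intron = w_intron,
                 w_pair = w_pair, w_known_discount = w_known_discount,
                 k_max = as.integer(k_max)),
            class = "hyper_params")
}

## normalization constant: maximal observed segment count (1 if all zero)
.norm_const <- function(obs) {
  cmax <- if (length(obs$seg_counts)) max(obs$seg_counts) else 0
  if (cmax <= 0) 1 else cmax
}

## fit one proxy per (sample, segment) and (sample, intron edge), and
## stack each sample's curves into padded matrices for vectorized
## evaluation inside the optimizer
.make_proxies <- function(obs, model, n_pieces = 6) {
  R <- obs$n_samples
  seg <- vector("list", R); intr <- vector("list", R)
  stack <- vector("list", R)
  cmax <- .norm_const(obs)
  for (r in seq_len(R)) {
    seg[[r]] <- lapply(obs$seg_counts[r, ], fit_proxy, model = model,
                       n_pieces = n_pieces,
                       mu_max = max(4 * max(obs$seg_counts[r, ], 1), 2 * cmax))
    if (ncol(obs$intron_counts)) {
      intr[[r]] <- lapply(obs$intron_counts[r, ], fit_proxy, model = model,
                          n_pieces = n_pieces,
                          mu_max = max(4 * max(obs$intron_counts[r, ], 1),
                                       2 * cmax))
    } else intr[[r]] <- list()
    stack[[r]] <- list(seg = .stack_proxies(seg[[r]]),
                       intron = .stack_proxies(intr[[r]]))
  }
  list(seg = seg, intron = intr, stack = stack)
}

## pad per-curve knot/value/slope/curvature tables into matrices so a
## whole vector of expected counts evaluates in a few vector ops
.stack_proxies <- function(plist) {
  if (!length(plist)) return(NULL)
  K <- max(vapply(plist, function(p) length(p$knots), 0L))
  S <- length(plist)
  kn <- matrix(Inf, S, K); kf <- matrix(0, S, K)
  kg <- matrix(0, S, K); cv <- matrix(0, S, K)
  for (s in seq_len(S)) {
    p <- plist[[s]]; n <- length(p$knots)
    kn[s, seq_len(n)] <- p$knots
    kf[s, ] <- p$kf[pmin(seq_len(K), n)]
    kg[s, ] <- p$kg[pmin(seq_len(K), n)]
    cv[s, ] <- p$curv[pmin(seq_len(K), max(n - 1L, 1L))]
  }
  list(kn = kn, kf = kf, kg = kg, cv = cv, S = S)
}

## evaluate all stacked curves at mu (length S); deriv gives slopes
.stack_eval <- function(st, mu, deriv = FALSE) {
  idx <- 1L + rowSums(st$kn[, -1, drop = FALSE] <= mu)
  ij <- cbind(seq_len(st$S), idx)
  d <- mu - st$kn[ij]
  a <- st$cv[ij]
  if (deriv) return(st$kg[ij] + a * d)
  st$kf[ij] + st$kg[ij] * d + 0.5 * a * d^2
}

## convex per-sample fit of W >= 0 under the proxy loss; returns W and loss
.fit_sample <- function(U, intron_use, obs, proxies, r, cmax, w_intron,
                        intron_idx) {
  k <- nrow(U)
  st_seg <- proxies$stack[[r]]$seg
  st_int <- proxies$stack[[r]]$intron
  has_int <- length(intron_idx) > 0 && !is.null(st_int)
  zero_s <- numeric(ncol(obs$seg_counts))
  if (k == 0) {
    loss <- sum(.stack_eval(st_seg, zero_s))
    if (has_int) {
      loss <- loss + w_intron *
        sum(.stack_eval(st_int, numeric(st_int$S))[intron_idx])
    }
    return(list(w = numeric(0), loss = loss))
  }
  Ue <- if (has_int) intron_use else NULL
  zero_e <- if (has_int) numeric(st_int$S) else NULL
  int_w <- if (has_int) {
    iw <- numeric(st_int$S); iw[intron_idx] <- w_intron; iw
  } else NULL
  fn <- function(w) {
    mu_s <- cmax * as.vector(crossprod(U, w))
    val <- sum(.stack_eval(st_seg, mu_s))
    if (has_int) {
      mu_e <- cmax * as.vector(crossprod(Ue, w))
      val <- val + sum(int_w * .stack_eval(st_int, mu_e))
    }
    val
  }
  gr <- function(w) {
    mu_s <- cmax * as.vector(crossprod(U, w))
    g <- cmax * as.vector(U %*% .stack_eval(st_seg, mu_s, deriv = TRUE))
    if (has_int) {
      mu_e <- cmax * as.vector(crossprod(Ue, w))
      g <- g + cmax *
        as.vector(Ue %*% (int_w * .stack_eval(st_int, mu_e, deriv = TRUE)))
    }
    g
  }
  w0 <- rep(mean(obs$seg_counts[r, ]) / (cmax * max(1, k)), k) + 1e-4
  opt <- stats::optim(w0, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(factr = 1e4, maxit = 500))
  list(w = opt$par, loss = opt$value)
}

#' Quantify a fixed transcript set
#'
#' With the transcript matrix fixed, abundance estimation decouples into
#' one convex program per sample: minimize the piecewise-quadratic proxy
#' loss of the expected segment (and intron) counts over nonnegative
#' abundances.
#'
#' @param tset a [transcript_set()].
#' @param obs an [observation_set()].
#' @param model a [loss_model()].
#' @param w_intron weight of the intron-count loss term.
#' @param proxies optional precomputed proxies (internal reuse).
#' @return list with `W` (transcripts x samples, normalized so expected
#'   counts are `c * t(U) %*% W`), `c` (normalization constant = maximal
#'   observed segment count), `loss` (per-sample proxy losses) and
#'   `total` (their sum).
#' @export
quantify_fixed <- function(tset, obs, model, w_intron = 1, proxies = NULL) {
  if (is.null(proxies)) proxies <- .make_proxies(obs, model)
  cmax <- .norm_const(obs)
  intron_idx <- which(tset$graph$edges$type == "intron")
  R <- obs$n_samples
  k <- nrow(tset$U)
  W <- matrix(0, k, R)
  loss <- numeric(R)
  for (r in seq_len(R)) {
    fit <- .fit_sample(tset$U, tset$intron_use, obs, proxies, r, cmax,
                       w_intron, intron_idx)
    if (k) W[, r] <- fit$w
    loss[r] <- fit$loss
  }
  list(W = W, c = cmax, loss = loss, total = sum(loss))
}

#' Paired-end penalty of a transcript set
#'
#' Each read-pair count between two segments is charged in full when no
#' selected transcript contains both segments, rewarding solutions whose
#' transcripts respect the long-range linkage evidence.
#'
#' @param tset a [transcript_set()].
#' @param pair_counts data.frame (`s1`, `s2`, `count`) for one sample.
#' @return the penalty (sum of uncovered pair counts).
#' @export
pair_penalty <- function(tset, pair_counts) {
  if (is.null(pair_counts) || !nrow(pair_counts)) return(0)
  pen <- 0
  for (i in seq_len(nrow(pair_counts))) {
    s1 <- pair_counts$s1[i]; s2 <- pair_counts$s2[i]
    covered <- nrow(tset$U) > 0 &&
      any(tset$U[, s1] != 0 & tset$U[, s2] != 0)
    if (!covered) pen <- pen + pair_counts$count[i]
  }
  pen
}

## pair penalty for a candidate subset, from the candidate matrix
.pair_pen_subset <- function(Ucand, sel, obs) {
  pen <- 0
  for (r in seq_len(obs$n_samples)) {
    pc <- obs$pair_counts[[r]]
    if (is.null(pc) || !nrow(pc)) next
    for (i in seq_len(nrow(pc))) {
      covered <- length(sel) > 0 &&
        any(Ucand[sel, pc$s1[i], drop = FALSE] != 0 &
            Ucand[sel, pc$s2[i], drop = FALSE] != 0)
      if (!covered) pen <- pen + pc$count[i]
    }
  }
  pen
}

#' Linear path-validity constraints over a row of the transcript matrix
#'
#' Materializes the constraint system whose binary solutions are exactly
#' the valid paths of the graph plus the all-zero row.  Returned as a
#' list of linear inequalities `a %*% u <= b` over one row `u` of the
#' transcript matrix; used by the tests to cross-check the solver's
#' notion of feasibility, and available for external MILP backends.
#'
#' The encoding: (1) a segment may only be followed within the
#' transcript by one of its edge successors: for each selected segment
#' `i` that is not terminal-only-used, if any segment after `i` is
#' selected then the first selected one must be an edge successor of
#' `i`.  This is expressed pairwise: for every non-edge pair `i < j`,
#' `u_i + u_j - sum(u_m for m in between reachable successors...)`; to
#' keep the system compact we instead forbid each invalid consecutive
#' pair: `u_i + u_j + sum_{i<m<j} (1 - u_m) <= 1 + (j - i - 1)` for all
#' `i < j` with no edge `(i, j)`; plus boundary constraints tying the
#' first/last selected segment to initial/terminal flags.
#'
#' @param graph a `segment_graph`.
#' @return list with elements `A`, `b` (dense matrix / vector), and
#'   `n` (number of segments).
#' @export
build_validity_constraints <- function(graph) {
  n <- nrow(graph$segments)
  if (!any(graph$segments$is_initial) || !any(graph$segments$is_terminal)) {
    if (n > 0) stop("build_validity_constraints: graph has no initial or terminal segment")
  }
  has_edge <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    has_edge[graph$edges$from[k], graph$edges$to[k]] <- TRUE
  }
  A <- list(); b <- numeric(0)
  add <- function(a, rhs) { A[[length(A) + 1]] <<- a; b[length(b) + 1] <<- rhs }
  # consecutive selected pairs must be edges:
  # u_i + u_j - sum_{i<m<j} u_m <= 1 for every non-edge pair i < j
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || has_edge[i, j]) next
    a <- numeric(n); a[i] <- 1; a[j] <- 1
    if (j > i + 1) a[(i + 1):(j - 1)] <- -1
    add(a, 1)
  }
  # first selected segment must be initial:
  # u_i - sum_{m<i} u_m <= 0 for every non-initial i
  for (i in which(!graph$segments$is_initial)) {
    a <- numeric(n); a[i] <- 1
    if (i > 1) a[seq_len(i - 1)] <- -1
    add(a, 0)
  }
  # last selected segment must be terminal
  for (i in which(!graph$segments$is_terminal)) {
    a <- numeric(n); a[i] <- 1
    if (i < n) a[(i + 1):n] <- -1
    add(a, 0)
  }
  list(A = if (length(A)) do.call(rbind, A) else matrix(0, 0, n),
       b = b, n = n)
}

## ---------------------------------------------------------------------------
## Joint solver: best-first branch-and-bound over path-selection binaries.
## Candidate paths are enumerated from the graph (capped); each node's lower
## bound is the convex proxy-loss quantification allowing every undecided
## path, plus the sparsity charges already committed and an optimistic
## paired-end penalty.
## ---------------------------------------------------------------------------

#' Jointly select and quantify transcripts across samples
#'
#' Minimizes, over a binary choice of graph paths and nonnegative
#' per-sample abundances, the summed proxy loss of expected vs observed
#' segment and intron counts, plus `w_pair` times the paired-end penalty
#' and `w_sparsity` times the number of selected transcripts (annotated
#' ones discounted by `w_known_discount`).  `mode = "exact"` runs a
#' best-first branch-and-bound whose node relaxation (all undecided
#' paths admitted at no sparsity charge) certifies global optimality;
#' `mode = "iterative"` adds the best single new transcript at a time
#' and freezes it, trading the certificate for speed.
#'
#' @param graph a `segment_graph`.
#' @param obs an [observation_set()].
#' @param model a [loss_model()].
#' @param hyper a [hyper_params()].
#' @param known optional binary matrix of annotated transcript rows
#'   (added to the candidate set and charged the discounted sparsity).
#' @param mode `"exact"` or `"iterative"`.
#' @param path_limit cap on enumerated candidate paths.
#' @param node_limit branch-and-bound node budget; when exhausted the
#'   best incumbent is returned with status `"time-capped"`.
#' @param proxies precomputed proxy curves (internal reuse).
#' @return an object of class `solve_result`: fields `tset`
#'   ([transcript_set()] of the selected rows), `W`, `c`, `objective`,
#'   `breakdown` (fit / pair / sparsity terms), `status`
#'   (`"optimal"`/`"approximate"`/`"time-capped"`), `nodes`.
#' @export
solve_joint <- function(graph, obs, model, hyper = hyper_params(),
                        known = NULL, mode = c("exact", "iterative"),
                        path_limit = 256L, node_limit = 1e5,
                        proxies = NULL) {
  mode <- match.arg(mode)
  Ucand <- enumerate_paths(graph, limit = path_limit)
  prov <- rep("novel", nrow(Ucand))
  if (!is.null(known)) {
    known <- as.matrix(known)
    for (t in seq_len(nrow(known))) {
      if (!is_valid_path(graph, known[t, ])) {
        stop("solve_joint: known row ", t, " is not a valid path")
      }
      hit <- which(apply(Ucand, 1, function(u) all(u == known[t, ])))
      if (length(hit)) prov[hit] <- "known"
      else { Ucand <- rbind(Ucand, known[t, ]); prov <- c(prov, "known") }
    }
  }
  if (hyper$k_max < sum(prov == "known")) {
    stop("solve_joint: k_max smaller than the number of known transcripts")
  }
  if (is.null(proxies)) proxies <- .make_proxies(obs, model)
  cmax <- .norm_const(obs)
  intron_idx <- which(graph$edges$type == "intron")
  iu_cand <- .intron_usage(graph, Ucand)
  spars_wt <- ifelse(prov == "known",
                     hyper$w_sparsity * hyper$w_known_discount,
                     hyper$w_sparsity)

  fit_subset <- function(sel) {
    U <- Ucand[sel, , drop = FALSE]
    iu <- iu_cand[sel, , drop = FALSE]
    total <- 0; W <- matrix(0, length(sel), obs$n_samples)
    for (r in seq_len(obs$n_samples)) {
      f <- .fit_sample(U, iu, obs, proxies, r, cmax, hyper$w_intron,
                       intron_idx)
      total <- total + f$loss
      if (length(sel)) W[, r] <- f$w
    }
    list(loss = total, W = W)
  }
  obj_subset <- function(sel) {
    f <- fit_subset(sel)
    pen <- .pair_pen_subset(Ucand, sel, obs)
    list(objective = f$loss + hyper$w_pair * pen + sum(spars_wt[sel]),
         fit = f$loss, pair = hyper$w_pair * pen,
         sparsity = sum(spars_wt[sel]), W = f$W)
  }

  n_cand <- nrow(Ucand)
  if (n_cand == 0) {
    empty <- obj_subset(integer(0))
    return(.solve_result(graph, Ucand, integer(0), prov, empty, cmax,
                         "optimal", 0L))
  }

  if (mode == "iterative") {
    sel <- which(prov == "known")
    cur <- obj_subset(sel)
    nodes <- 1L
    repeat {
      if (length(sel) >= hyper$k_max) break
      cand <- setdiff(seq_len(n_cand), sel)
      if (!length(cand)) break
      best_p <- NA_integer_; best <- NULL
      for (p in cand) {
        trial <- obj_subset(c(sel, p)); nodes <- nodes + 1L
        if (is.null(best) || trial$objective < best$objective - 1e-12) {
          best <- trial; best_p <- p
        }
      }
      if (best$objective < cur$objective - 1e-9) {
        sel <- sort(c(sel, best_p)); cur <- best
      } else break
    }
    # drop rows quantified at zero everywhere (they carry no signal)
    cur <- obj_subset(sel)
    return(.solve_result(graph, Ucand, sel, prov, cur, cmax,
                         "approximate", nodes))
  }

  ## exact: best-first branch and bound over path inclusion
  lower_bound <- function(included, excluded) {
    allowed <- setdiff(seq_len(n_cand), excluded)
    f <- fit_subset(allowed)
    pen <- .pair_pen_subset(Ucand, allowed, obs)
    list(bound = f$loss + hyper$w_pair * pen + sum(spars_wt[included]),
         W = f$W, allowed = allowed)
  }
  incumbent <- obj_subset(integer(0)); inc_sel <- integer(0)
  consider <- function(sel) {
    cand <- obj_subset(sel)
    if (.better_solution(cand$objective, sel, incumbent$objective, inc_sel,
                         Ucand)) {
      incumbent <<- cand; inc_sel <<- sel
    }
  }
  # greedy warm start keeps the tree small
  ws <- solve_joint(graph, obs, model, hyper, known, mode = "iterative",
                    path_limit = path_limit, proxies = proxies)
  if (nrow(ws$tset$U)) {
    sel0 <- integer(0)
    for (t in seq_len(nrow(ws$tset$U))) {
      hit <- which(apply(Ucand, 1, function(u) all(u == ws$tset$U[t, ])))
      sel0 <- c(sel0, hit)
    }
    consider(sort(unique(sel0)))
  } else consider(integer(0))

  root <- lower_bound(integer(0), integer(0))
  queue <- list(list(included = integer(0), excluded = integer(0),
                     bound = root$bound, W = root$W, allowed = root$allowed))
  nodes <- 1L
  status <- "optimal"
  while (length(queue)) {
    if (nodes >= node_limit) { status <- "time-capped"; break }
    bounds <- vapply(queue, `[[`, 0, "bound")
    i <- which.min(bounds)
    node <- queue[[i]]; queue[[i]] <- NULL
    if (node$bound >= incumbent$objective - 1e-9) next
    undecided <- setdiff(node$allowed, node$included)
    if (!length(undecided) || length(node$included) >= hyper$k_max) next
    # branch on the undecided path with the largest relaxed abundance
    tot_w <- rowSums(node$W)
    names(tot_w) <- node$allowed
    w_und <- tot_w[as.character(undecided)]
    p <- undecided[which.max(w_und)]
    for (branch in c(1L, 0L)) {
      inc <- node$included; exc <- node$excluded
      if (branch == 1L) inc <- sort(c(inc, p)) else exc <- sort(c(exc, p))
      if (length(inc) > hyper$k_max) next
      lb <- lower_bound(inc, exc)
      nodes <- nodes + 1L
      consider(inc)
      if (length(inc) == hyper$k_max || length(lb$allowed) == length(inc)) {
        next  # leaf: no free paths remain
      }
      if (lb$bound < incumbent$objective - 1e-9) {
        queue[[length(queue) + 1]] <- list(included = inc, excluded = exc,
                                           bound = lb$bound, W = lb$W,
                                           allowed = lb$allowed)
      }
    }
  }
  .solve_result(graph, Ucand, inc_sel, prov, incumbent, cmax, status, nodes)
}

## prefer lower objective; within ties fewer transcripts, then lexicographic U
.better_solution <- function(obj_new, sel_new, obj_old, sel_old, Ucand) {
  if (obj_new < obj_old - 1e-9) return(TRUE)
  if (obj_new > obj_old + 1e-9) return(FALSE)
  if (length(sel_new) != length(sel_old)) return(length(sel_new) < length(sel_old))
  key <- function(sel) paste(t(Ucand[sel, , drop = FALSE]), collapse = "")
  key(sel_new) < key(sel_old)
}

.solve_result <- function(graph, Ucand, sel, prov, objinfo, cmax, status,
                          nodes) {
  ts <- transcript_set(graph, Ucand[sel, , drop = FALSE], prov[sel])
  structure(list(tset = ts, W = objinfo$W, c = cmax,
                 objective = objinfo$objective,
                 breakdown = list(fit = objinfo$fit, pair = objinfo$pair,
                                  sparsity = objinfo$sparsity),
                 status = status, nodes = nodes),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: %d transcripts, objective %.6g (%s, %d nodes)\n",
              nrow(x$tset$U), x$objective, x$status, x$nodes))
  cat(sprintf("  fit %.6g + pair %.6g + sparsity %.6g\n",
              x$breakdown$fit, x$breakdown$pair, x$breakdown$sparsity))
  invisible(x)
}

#' True (non-proxy) negative log-likelihood of a quantified model
#'
#' Evaluates the exact count NLL at given abundances; used by the
#' statistical tests so their calibration does not inherit proxy error.
#'
#' @param tset a [transcript_set()].
#' @param W abundance matrix (transcripts x samples).
#' @param obs an [observation_set()].
#' @param model a [loss_model()].
#' @param w_intron intron-loss weight.
#' @param samples sample indices to include.
#' @return scalar NLL.
#' @export
model_nll <- function(tset, W, obs, model, w_intron = 1,
                      samples = seq_len(obs$n_samples)) {
  cmax <- .norm_const(obs)
  intron_idx <- which(tset$graph$edges$type == "intron")
  total <- 0
  for (r in samples) {
    w <- if (nrow(tset$U)) W[, r] else numeric(0)
    mu_s <- if (nrow(tset$U)) cmax * as.vector(crossprod(tset$U, w))
            else numeric(ncol(obs$seg_counts))
    total <- total + sum(nll_count(obs$seg_counts[r, ], mu_s, model))
    if (length(intron_idx)) {
      mu_e <- if (nrow(tset$U))
        cmax * as.vector(crossprod(tset$intron_use[, intron_idx, drop = FALSE], w))
      else numeric(length(intron_idx))
      total <- total + w_intron *
        sum(nll_count(obs$intron_counts[r, intron_idx], mu_e, model))
    }
  }
  total
}
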
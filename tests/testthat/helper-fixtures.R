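# Shared fixture builders and independent oracles.  Oracles here are
# deliberately naive (per-base walks, exhaustive enumeration, projected
# gradient) so they do not share code paths with the implementation.

# construct a GAlignments with qname/flag metadata from parallel vectors
make_gal <- function(pos, cigar, chrom = "chr1", qname = NULL, flag = 0L,
                     chrom_len = 100000L) {
  n <- length(pos)
  if (is.null(qname)) qname <- sprintf("r%04d", seq_len(n))
  g <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(rep(chrom, n), levels = chrom)),
    pos = as.integer(pos),
    cigar = cigar,
    strand = S4Vectors::Rle(factor(rep("+", n), levels = c("+", "-", "*"))),
    seqlengths = stats::setNames(chrom_len, chrom))
  S4Vectors::mcols(g)$qname <- qname
  S4Vectors::mcols(g)$flag <- rep_len(as.integer(flag), n)
  g
}

# brute-force per-base coverage walk over a region (1-based genome pos)
oracle_coverage <- function(pos, cigar, region) {
  cov <- numeric(region$end - region$start)
  for (i in seq_along(pos)) {
    p <- pos[i]  # 1-based
    ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    at <- p
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X", "D")) {
        if (type != "D") {
          for (b in at:(at + n - 1)) {
            j <- b - region$start  # 1-based genome -> vector index
            if (j >= 1 && j <= length(cov)) cov[j] <- cov[j] + 1
          }
        }
        at <- at + n
      } else if (type == "N") {
        at <- at + n
      }
      # I/S consume the query only
    }
  }
  cov
}

# independent DP count of initial-to-terminal paths in a segment graph
oracle_path_count <- function(graph) {
  n <- nrow(graph$segments)
  if (n == 0) return(0)
  succ <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    succ[[graph$edges$from[k]]] <- c(succ[[graph$edges$from[k]]],
                                     graph$edges$to[k])
  }
  memo <- rep(NA_real_, n)
  count_from <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    total <- if (graph$segments$is_terminal[i]) 1 else 0
    for (j in succ[[i]]) total <- total + count_from(j)
    memo[i] <<- total
    total
  }
  sum(vapply(which(graph$segments$is_initial), count_from, 0))
}

# hand-rolled breadth-first reachability (a != b) over an edge list
oracle_reachable <- function(edges, n, a, b, dropped = integer(0)) {
  alive <- setdiff(seq_len(n), dropped)
  if (!(a %in% alive) || !(b %in% alive)) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (i %in% alive && j %in% alive) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- rep(FALSE, n); queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == b) return(TRUE)
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  FALSE
}

# projected-gradient minimizer of the proxy loss over one sample
oracle_projected_gradient <- function(tset, obs, model, r, w_intron = 1,
                                      iters = 20000, step = NULL) {
  proxies <- isomip:::.make_proxies(obs, model)
  cmax <- isomip:::.norm_const(obs)
  intron_idx <- which(tset$graph$edges$type == "intron")
  k <- nrow(tset$U)
  fn <- function(w) {
    mu <- cmax * as.vector(crossprod(tset$U, w))
    val <- sum(vapply(seq_along(mu), function(s)
      proxy_eval(proxies$seg[[r]][[s]], mu[s]), 0))
    for (e in intron_idx) {
      mu_e <- cmax * sum(tset$intron_use[, e] * w)
      val <- val + w_intron * proxy_eval(proxies$intron[[r]][[e]], mu_e)
    }
    val
  }
  gr <- function(w) {
    mu <- cmax * as.vector(crossprod(tset$U, w))
    gs <- vapply(seq_along(mu), function(s)
      proxy_eval(proxies$seg[[r]][[s]], mu[s], deriv = TRUE), 0)
    g <- cmax * as.vector(tset$U %*% gs)
    for (e in intron_idx) {
      mu_e <- cmax * sum(tset$intron_use[, e] * w)
      g <- g + w_intron * cmax * tset$intron_use[, e] *
        proxy_eval(proxies$intron[[r]][[e]], mu_e, deriv = TRUE)
    }
    g
  }
  if (is.null(step)) step <- 0.5 / (cmax^2 * max(1, sum(tset$U)))
  w <- rep(0.1, k)
  for (i in seq_len(iters)) {
    w_new <- pmax(0, w - step * gr(w))
    if (fn(w_new) <= fn(w)) w <- w_new else step <- step / 2
    if (step < 1e-14) break
  }
  list(w = w, loss = fn(w))
}

# exhaustive search over all path subsets, each scored by the convex fit
oracle_best_subset <- function(graph, obs, model, hyper, proxies = NULL) {
  paths <- enumerate_paths(graph)
  np <- nrow(paths)
  if (is.null(proxies)) proxies <- isomip:::.make_proxies(obs, model)
  best <- Inf; best_sel <- NULL
  for (msk in 0:(2^np - 1)) {
    sel <- which(bitwAnd(msk, 2^(seq_len(np) - 1)) > 0)
    if (length(sel) > hyper$k_max) next
    ts <- transcript_set(graph, paths[sel, , drop = FALSE])
    q <- quantify_fixed(ts, obs, model, hyper$w_intron, proxies)
    pen <- sum(vapply(seq_len(obs$n_samples), function(r)
      pair_penalty(ts, obs$pair_counts[[r]]), 0))
    obj <- q$total + hyper$w_pair * pen + hyper$w_sparsity * length(sel)
    if (obj < best) { best <- obj; best_sel <- sel }
  }
  list(objective = best, sel = best_sel, paths = paths)
}

# geometric oracle for the 3-cassette toy: a size-3 subset of the cube
# corners explains (total, p) iff p has strictly positive barycentric
# coordinates in the subset's (affine) triangle and lies in its plane
oracle_triple_consistent <- function(p, patterns) {
  A <- rbind(1, t(patterns))
  b <- c(1, p)
  qrA <- qr(A)
  w <- qr.coef(qrA, b)
  if (anyNA(w)) return(FALSE)
  max(abs(A %*% w - b)) < 1e-8 && min(w) > 1e-8
}

# linear two-segment graph (one path), used by the MMO tests
linear_graph <- function(len = 100L) {
  segs <- data.frame(start = c(0L, len), end = c(len, 2L * len))
  add_intron_edges(segs, junctions = NULL,
                   region = list(chrom = "chr1", start = 0L, end = 2L * len))
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b) / max(1, abs(b)), tol)
}
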
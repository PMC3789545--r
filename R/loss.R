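#' Read-count loss model
#'
#' A loss model defines the negative log-likelihood of observing a read
#' count given an expected count under the chosen noise model.  The
#' default (`kind = "nb"`) scores a count against the larger of two
#' likelihoods: a negative-binomial signal component with mean `mu` and
#' variance `mu + dispersion * mu^2`, and a background Poisson component
#' with fixed mean `lambda_bg` that absorbs coverage from false
#' alignments or incomplete RNA processing.  Taking the larger likelihood
#' (the smaller NLL) bounds the cost of explaining a covered segment as
#' noise, so the optimizer is free to leave spurious coverage
#' unexplained.  `kind = "poisson"` drops the quadratic variance term;
#' `kind = "l2"` is the classical squared-deviation loss.
#'
#' @param kind one of `"nb"`, `"poisson"`, `"l2"`.
#' @param dispersion scalar over-dispersion `alpha` in
#'   `var(mu) = mu + alpha * mu^2` (per-library; ignored for `"l2"`).
#' @param dispersion_offset optional additive variance offset, giving
#'   `var(mu) = mu + alpha * mu^2 + offset`.
#' @param lambda_bg mean of the background Poisson component, in reads
#'   per base.
#' @param combine how signal and background components are combined:
#'   `"max"` (larger likelihood wins) or `"mixture"` (weighted sum with
#'   weight `mix_weight` on the background).
#' @param mix_weight background mixture weight, used when
#'   `combine = "mixture"`.
#' @return an object of class `loss_model`.
#' @export
loss_model <- function(kind = c("nb", "poisson", "l2"),
                       dispersion = 0.1,
                       dispersion_offset = 0,
                       lambda_bg = 0.1,
                       combine = c("max", "mixture"),
                       mix_weight = 0.01) {
  kind <- match.arg(kind)
  combine <- match.arg(combine)
  stopifnot(dispersion >= 0, dispersion_offset >= 0, lambda_bg >= 0,
            mix_weight >= 0, mix_weight <= 1)
  structure(list(kind = kind,
                 dispersion = dispersion,
                 dispersion_offset = dispersion_offset,
                 lambda_bg = lambda_bg,
                 combine = combine,
                 mix_weight = mix_weight),
            class = "loss_model")
}

#' @export
print.loss_model <- function(x, ...) {
  cat(sprintf("loss_model: kind=%s dispersion=%g offset=%g lambda_bg=%g combine=%s\n",
              x$kind, x$dispersion, x$dispersion_offset, x$lambda_bg, x$combine))
  invisible(x)
}

## continuous extension of the Poisson NLL via log-gamma
.nll_poisson <- function(v, mu) {
  mu <- pmax(mu, 1e-12)
  -(v * log(mu) - mu - lgamma(v + 1))
}

## continuous extension of the NB NLL (mean mu, var mu + a*mu^2 + o);
## falls back to Poisson when the extra-Poisson variance vanishes
.nll_nb <- function(v, mu, alpha, offset = 0) {
  mu <- pmax(mu, 1e-12)
  v <- rep_len(v, length(mu))
  extra <- alpha * mu^2 + offset
  out <- numeric(length(mu))
  pois <- extra < 1e-12 * pmax(mu, 1)
  if (any(pois)) out[pois] <- .nll_poisson(v[pois], mu[pois])
  if (any(!pois)) {
    m <- mu[!pois]; vv <- v[!pois]
    r <- m^2 / extra[!pois]  # size parameter
    out[!pois] <- -(lgamma(vv + r) - lgamma(r) - lgamma(vv + 1) +
                      r * log(r / (r + m)) + vv * log(m / (r + m)))
  }
  out
}

#' Negative log-likelihood of an observed count
#'
#' Evaluates the loss of observing count `v` when the model expects
#' `mu`.  Non-integer counts (fractional per-base coverage averages) are
#' handled by the continuous log-gamma extension of the pmf.  Finite for
#' all finite nonnegative inputs.
#'
#' @param v observed count(s), `>= 0`.
#' @param mu expected count(s), `>= 0`; recycled against `v`.
#' @param model a [loss_model()].
#' @return numeric vector of nonnegative losses (the L2 kind returns
#'   squared deviations; likelihood kinds return NLLs shifted so the
#'   value is comparable across `mu` for fixed `v`).
#' @export
nll_count <- function(v, mu, model) {
  if (any(v < 0) || any(mu < 0)) stop("nll_count: v and mu must be nonnegative")
  n <- max(length(v), length(mu))
  v <- rep_len(v, n); mu <- rep_len(mu, n)
  if (model$kind == "l2") return((v - mu)^2)
  signal <- if (model$kind == "nb") {
    .nll_nb(v, mu, model$dispersion, model$dispersion_offset)
  } else {
    .nll_poisson(v, mu)
  }
  bg <- .nll_poisson(v, rep_len(model$lambda_bg, n))
  if (model$combine == "max") {
    pmin(signal, bg)
  } else {
    w <- model$mix_weight
    # -log( (1-w) L_signal + w L_bg ), computed stably
    a <- -signal + log1p(-w); b <- -bg + log(w)
    m <- pmax(a, b)
    -(m + log(exp(a - m) + exp(b - m)))
  }
}

#' Convex piecewise-quadratic proxy of the count loss
#'
#' Fits a convex, continuously differentiable piecewise-quadratic
#' surrogate of `nll_count(v, mu)` as a function of `mu`, anchored so
#' that its global minimum sits exactly at `mu = v` with the true NLL
#' value there.  The curvature of each piece is constrained nonnegative
#' and fitted by nonnegative least squares against the true loss on a
#' dense grid, which keeps the surrogate convex while tracking the
#' asymmetry of the NB loss.  The surrogate is what makes each node of
#' the branch-and-bound search a smooth convex program.
#'
#' @param v the observed count the curve is anchored at.
#' @param model a [loss_model()].
#' @param n_pieces number of quadratic pieces (`>= 2`).
#' @param mu_max upper end of the fitted range; defaults to
#'   `max(4 * v, 20)`.
#' @param n_grid fitting grid density.
#' @return an object of class `proxy_curve` with fields `v`, `knots`,
#'   `curv` (per-piece second derivatives), `f0` (value at the minimum)
#'   and `max_dev` (largest absolute deviation from the true loss on the
#'   fitting grid).
#' @export
fit_proxy <- function(v, model, n_pieces = 6, mu_max = NULL, n_grid = 200) {
  if (v < 0) stop("fit_proxy: v must be nonnegative")
  if (n_pieces < 2) stop("fit_proxy: n_pieces must be at least 2")
  if (is.null(mu_max)) mu_max <- max(4 * v, 20)
  if (model$kind == "l2") {
    # exact: a single quadratic IS the loss
    kn <- c(0, mu_max)
    cur <- structure(list(v = v, knots = kn, curv = 2, f0 = 0,
                          max_dev = 0, kind = "l2",
                          kf = (kn - v)^2, kg = 2 * (kn - v)),
                     class = "proxy_curve")
    return(cur)
  }
  f0 <- nll_count(v, v, model)
  # knots: geometric spacing around the anchor, always including 0, v, mu_max
  if (v > 0) {
    lo <- v / 2^seq_len(max(1, floor(n_pieces / 2)) - 1)
    hi <- pmin(v * 2^seq_len(ceiling(n_pieces / 2)), mu_max)
    knots <- sort(unique(c(0, lo, v, hi, mu_max)))
  } else {
    knots <- c(0, mu_max * (2^seq_len(n_pieces) / 2^n_pieces))
    knots <- sort(unique(c(0, knots)))
  }
  grid <- sort(unique(c(seq(0, mu_max, length.out = n_grid), v, knots)))
  target <- nll_count(v, grid, model) - f0
  # relative weighting: the NLL explodes towards mu = 0 for large v, and
  # an unweighted fit would sacrifice the region around the anchor to
  # chase those few huge values
  wt <- 1 / (1 + abs(target))
  M <- .proxy_basis(grid, v, knots)
  fit <- pracma::lsqnonneg(wt * M, wt * target)
  curv <- fit$x
  pred <- as.vector(M %*% curv)
  out <- structure(list(v = v, knots = knots, curv = curv, f0 = f0,
                        max_dev = max(abs(pred - target)), kind = model$kind),
                   class = "proxy_curve")
  # tabulate value/slope at the knots so evaluation is O(1) per point
  out$kf <- f0 + as.vector(.proxy_basis(knots, v, knots) %*% curv)
  out$kg <- vapply(knots, function(k) {
    sum(curv * (pmin(pmax(k, knots[-length(knots)]), knots[-1]) -
                pmin(pmax(v, knots[-length(knots)]), knots[-1])))
  }, 0)
  out
}

## basis value phi_i(mu) = integral over piece i, between anchor v and mu,
## of (mu - u) du; the proxy is f0 + sum_i curv_i * phi_i(mu), so curv_i >= 0
## gives a convex C^1 curve with f'(v) = 0.
.proxy_basis <- function(mu, v, knots) {
  np <- length(knots) - 1
  M <- matrix(0, length(mu), np)
  for (i in seq_len(np)) {
    a <- knots[i]; b <- knots[i + 1]
    # above the anchor: integrate (mu - u) over [max(a, v), min(b, mu)]
    l <- max(a, v); hi <- pmin(b, mu)
    up <- hi > l
    if (any(up)) {
      m <- mu[up]; h <- hi[up]
      M[up, i] <- M[up, i] + (m * (h - l) - (h^2 - l^2) / 2)
    }
    # below the anchor: integrate (u - mu) over [max(a, mu), min(b, v)]
    lo2 <- pmax(a, mu); h2 <- min(b, v)
    dn <- h2 > lo2
    if (any(dn)) {
      m <- mu[dn]; l2 <- lo2[dn]
      M[dn, i] <- M[dn, i] + ((h2^2 - l2^2) / 2 - m * (h2 - l2))
    }
  }
  M
}

#' Evaluate a proxy curve (and optionally its derivative)
#'
#' @param curve a `proxy_curve` from [fit_proxy()].
#' @param mu expected count(s) to evaluate at; values beyond the fitted
#'   range extrapolate with the last piece's quadratic.
#' @param deriv if `TRUE`, return the first derivative instead.
#' @return numeric vector.
#' @export
proxy_eval <- function(curve, mu, deriv = FALSE) {
  if (curve$kind == "l2") {
    if (deriv) return(2 * (mu - curve$v))
    return((mu - curve$v)^2)
  }
  knots <- curve$knots
  if (!is.null(curve$kf)) {
    i <- findInterval(mu, knots, all.inside = TRUE)
    d <- mu - knots[i]
    a <- curve$curv[pmin(i, length(curve$curv))]
    if (deriv) return(curve$kg[i] + a * d)
    return(curve$kf[i] + curve$kg[i] * d + 0.5 * a * d^2)
  }
  curv <- curve$curv; v <- curve$v
  if (deriv) {
    out <- numeric(length(mu))
    for (i in seq_along(curv)) {
      a <- knots[i]; b <- knots[i + 1]
      # f'(mu) = signed measure of [v, mu] inside each piece, weighted by curv
      seg <- pmin(pmax(mu, a), b) - pmin(pmax(v, a), b)
      out <- out + curv[i] * seg
    }
    return(out)
  }
  M <- .proxy_basis(mu, v, knots)
  curve$f0 + as.vector(M %*% curve$curv)
}

#' @export
print.proxy_curve <- function(x, ...) {
  cat(sprintf("proxy_curve: anchor v=%g, %d pieces, max|dev|=%.4g\n",
              x$v, length(x$curv), x$max_dev))
  invisible(x)
}

#' Estimate noise parameters from single-isoform loci
#'
#' Fits the NB dispersion by method-of-moments on per-segment deviations
#' from each locus's mean coverage, using loci known to express a single
#' transcript (so all exonic segments share one expected coverage per
#' sample).  The background Poisson mean is the average coverage of the
#' supplied intronic/intergenic positions.
#'
#' @param loci list of numeric matrices (or vectors), one per
#'   single-transcript locus: per-segment coverage, one row per sample.
#' @param background optional numeric vector of off-exon per-base
#'   coverage values used to fit `lambda_bg`.
#' @param min_loci minimum usable loci before falling back to shipped
#'   defaults (with a warning).
#' @param defaults the fallback [loss_model()].
#' @return a [loss_model()] of kind `"nb"`.
#' @export
estimate_noise_params <- function(loci, background = NULL, min_loci = 10,
                                  defaults = loss_model()) {
  rows <- list()
  for (x in loci) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    for (r in seq_len(nrow(m))) {
      cov <- m[r, ]
      if (length(cov) >= 2 && mean(cov) > 0) {
        rows[[length(rows) + 1]] <- c(mean = mean(cov), var = stats::var(cov))
      }
    }
  }
  lambda <- if (!is.null(background) && length(background)) mean(background)
            else defaults$lambda_bg
  if (length(rows) < min_loci) {
    warning(sprintf("estimate_noise_params: only %d usable loci (< %d); using shipped defaults",
                    length(rows), min_loci))
    out <- defaults
    out$lambda_bg <- lambda
    return(out)
  }
  mm <- do.call(rbind, rows)
  # var = mu + alpha * mu^2  =>  regress (var - mu) on mu^2 through the origin
  y <- mm[, "var"] - mm[, "mean"]
  x2 <- mm[, "mean"]^2
  alpha <- max(0, sum(y * x2) / sum(x2^2))
  loss_model(kind = "nb", dispersion = alpha, lambda_bg = lambda)
}

#' Write / read a loss model as a key-value text file
#' @param model a [loss_model()].
#' @param path file path.
#' @return `read_loss_model` returns a [loss_model()];
#'   `write_loss_model` returns `path` invisibly.
#' @export
write_loss_model <- function(model, path) {
  lines <- c("isomip_loss_model\tv1",
             paste("kind", model$kind, sep = "\t"),
             paste("dispersion", format(model$dispersion, digits = 17), sep = "\t"),
             paste("dispersion_offset", format(model$dispersion_offset, digits = 17), sep = "\t"),
             paste("lambda_bg", format(model$lambda_bg, digits = 17), sep = "\t"),
             paste("combine", model$combine, sep = "\t"),
             paste("mix_weight", format(model$mix_weight, digits = 17), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_loss_model
#' @export
read_loss_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "isomip_loss_model")) {
    stop("read_loss_model: not a loss model file: ", path)
  }
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  loss_model(kind = vals[["kind"]],
             dispersion = as.numeric(vals[["dispersion"]]),
             dispersion_offset = as.numeric(vals[["dispersion_offset"]]),
             lambda_bg = as.numeric(vals[["lambda_bg"]]),
             combine = vals[["combine"]],
             mix_weight = as.numeric(vals[["mix_weight"]]))
}
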
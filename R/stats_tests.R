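#' Likelihood-ratio confidence for each transcript
#'
#' Quantifies how much each transcript contributes to explaining the
#' observed counts: the quantification task is re-solved with the
#' transcript's abundance pinned to zero in every sample (all
#' regularizers off), and the statistic is twice the resulting increase
#' in negative log-likelihood.  NLLs are evaluated with the exact count
#' likelihood at the proxy-optimal abundances, so test calibration does
#' not inherit proxy error.  The statistic is referred to a chi-square
#' distribution with `df` degrees of freedom (default: one freed
#' abundance per sample, `df = R`).
#'
#' @param tset a [transcript_set()].
#' @param obs an [observation_set()].
#' @param model a [loss_model()].
#' @param w_intron intron-loss weight.
#' @param df degrees of freedom; default `obs$n_samples`.
#' @return a data.frame (class `confidence_report`) with one row per
#'   transcript: `transcript`, `statistic`, `df`, `p_value`,
#'   `loss_full`, `loss_restricted`, and one `abundance_<r>` column per
#'   sample.  Empty for an empty transcript set.
#' @export
transcript_confidence <- function(tset, obs, model, w_intron = 1, df = NULL) {
  k <- nrow(tset$U)
  R <- obs$n_samples
  if (is.null(df)) df <- R
  if (k == 0) {
    out <- data.frame(transcript = integer(), statistic = numeric(),
                      df = numeric(), p_value = numeric(),
                      loss_full = numeric(), loss_restricted = numeric())
    class(out) <- c("confidence_report", class(out))
    return(out)
  }
  proxies <- .make_proxies(obs, model)
  full <- quantify_fixed(tset, obs, model, w_intron, proxies)
  nll_full <- model_nll(tset, full$W, obs, model, w_intron)
  stat <- numeric(k); nll_res <- numeric(k)
  for (t in seq_len(k)) {
    sub <- transcript_set(tset$graph, tset$U[-t, , drop = FALSE],
                          tset$provenance[-t])
    fit <- quantify_fixed(sub, obs, model, w_intron, proxies)
    nll_res[t] <- model_nll(sub, fit$W, obs, model, w_intron)
    stat[t] <- max(0, 2 * (nll_res[t] - nll_full))
  }
  out <- data.frame(transcript = seq_len(k), statistic = stat, df = df,
                    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                    loss_full = nll_full, loss_restricted = nll_res)
  ab <- full$W * full$c
  colnames(ab) <- paste0("abundance_", seq_len(R))
  out <- cbind(out, ab)
  class(out) <- c("confidence_report", class(out))
  out
}

## coupled two-sample fit: shared abundances for `tied` transcripts,
## per-sample abundances for the rest; proxy loss, exact gradient
.fit_tied <- function(tset, obs, proxies, samples, tied, w_intron) {
  k <- nrow(tset$U)
  cmax <- .norm_const(obs)
  intron_idx <- which(tset$graph$edges$type == "intron")
  free <- setdiff(seq_len(k), tied)
  m <- length(tied); nf <- length(free)
  npar <- m + 2 * nf
  unpack <- function(theta) {
    W <- matrix(0, k, 2)
    if (m) W[tied, 1] <- W[tied, 2] <- theta[seq_len(m)]
    if (nf) {
      W[free, 1] <- theta[m + seq_len(nf)]
      W[free, 2] <- theta[m + nf + seq_len(nf)]
    }
    W
  }
  has_int <- length(intron_idx) > 0
  int_w <- if (has_int) {
    iw <- numeric(ncol(tset$intron_use)); iw[intron_idx] <- w_intron; iw
  } else NULL
  sample_terms <- function(W, col, r, deriv = FALSE) {
    U <- tset$U
    st_seg <- proxies$stack[[r]]$seg
    st_int <- proxies$stack[[r]]$intron
    mu_s <- cmax * as.vector(crossprod(U, W[, col]))
    if (!deriv) {
      val <- sum(.stack_eval(st_seg, mu_s))
      if (has_int) {
        mu_e <- cmax * as.vector(crossprod(tset$intron_use, W[, col]))
        val <- val + sum(int_w * .stack_eval(st_int, mu_e))
      }
      return(val)
    }
    g <- cmax * as.vector(U %*% .stack_eval(st_seg, mu_s, deriv = TRUE))
    if (has_int) {
      mu_e <- cmax * as.vector(crossprod(tset$intron_use, W[, col]))
      g <- g + cmax * as.vector(tset$intron_use %*%
        (int_w * .stack_eval(st_int, mu_e, deriv = TRUE)))
    }
    g
  }
  fn <- function(theta) {
    W <- unpack(theta)
    sample_terms(W, 1, samples[1]) + sample_terms(W, 2, samples[2])
  }
  gr <- function(theta) {
    W <- unpack(theta)
    g1 <- sample_terms(W, 1, samples[1], deriv = TRUE)
    g2 <- sample_terms(W, 2, samples[2], deriv = TRUE)
    g <- numeric(npar)
    if (m) g[seq_len(m)] <- g1[tied] + g2[tied]
    if (nf) {
      g[m + seq_len(nf)] <- g1[free]
      g[m + nf + seq_len(nf)] <- g2[free]
    }
    g
  }
  theta0 <- rep(mean(obs$seg_counts[samples, ]) / (cmax * max(1, k)),
                npar) + 1e-4
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(factr = 1e3, maxit = 500))
  list(W = unpack(opt$par), loss = opt$value)
}

#' Two-sample test for differential transcript expression
#'
#' Compares the likelihood of a model that quantifies the transcripts
#' independently in the two samples against one that ties the tested
#' transcripts' abundances to be equal across samples.  Twice the NLL
#' difference is referred to a chi-square distribution with one degree
#' of freedom per tested transcript.
#'
#' @param tset a [transcript_set()].
#' @param obs an [observation_set()]; `samples` must select exactly two
#'   of its samples (replicate designs are out of scope).
#' @param model a [loss_model()].
#' @param samples integer vector of length 2.
#' @param subset transcript indices to test (tied under the null);
#'   default all.
#' @param w_intron intron-loss weight.
#' @return list with `statistic`, `df`, `p_value`, `nll_tied`,
#'   `nll_free`, `W_free`, `W_tied`.
#' @export
diff_expression_test <- function(tset, obs, model, samples = c(1, 2),
                                 subset = NULL, w_intron = 1) {
  if (length(samples) != 2) {
    stop("diff_expression_test: exactly two samples must be selected")
  }
  k <- nrow(tset$U)
  if (is.null(subset)) subset <- seq_len(k)
  proxies <- .make_proxies(obs, model)
  free_fit <- .fit_tied(tset, obs, proxies, samples, tied = integer(0),
                        w_intron = w_intron)
  tied_fit <- .fit_tied(tset, obs, proxies, samples, tied = subset,
                        w_intron = w_intron)
  nll_free <- model_nll(tset, .embed_w(free_fit$W, obs, samples), obs, model,
                        w_intron, samples = samples)
  nll_tied <- model_nll(tset, .embed_w(tied_fit$W, obs, samples), obs, model,
                        w_intron, samples = samples)
  stat <- max(0, 2 * (nll_tied - nll_free))
  df <- length(subset)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       nll_tied = nll_tied, nll_free = nll_free,
       W_free = free_fit$W, W_tied = tied_fit$W)
}

## place a two-column W into a full k x R matrix at the selected samples
.embed_w <- function(W2, obs, samples) {
  W <- matrix(0, nrow(W2), obs$n_samples)
  W[, samples[1]] <- W2[, 1]
  W[, samples[2]] <- W2[, 2]
  W
}

#' Write a confidence report as TSV
#' @param report a `confidence_report` from [transcript_confidence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confidence_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
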
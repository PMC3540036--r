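#' Sampling-based Kullback-Leibler specificity of a signature model
#'
#' Estimates the KL divergence (in nats) between the model's normalized
#' sequence distribution (R drawn from the trained rho; an R = 1 promoter
#' conditioned on carrying at least one complete site) and the iid GC
#' background of the same length, by sampling promoters from the model and
#' averaging the log-probability ratio.  The Monte-Carlo standard error of
#' the mean is reported.
#'
#' @param model a [signature_model()].
#' @param n_samples number of sampled promoters (default 10000).
#' @param seed integer seed.
#' @param length promoter length (defaults to the model length contract).
#' @param bits report in bits instead of nats.
#' @return an object of class `kl_estimate` with `nats` (or bits), `se`,
#'   `n_samples` and `model_id`.
#' @export
sampled_kl <- function(model, n_samples = 10000, seed = NULL,
                       length = model$length, bits = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  unit <- if (bits) log(2) else 1
  if (model$params$rho <= 0) {
    # degenerate: the model is the background
    return(structure(list(nats = 0, se = 0, n_samples = n_samples,
                          model_id = model$matrix$name, bits = bits),
                     class = "kl_estimate"))
  }
  pv <- par_vec(model)
  logA <- cpp_log_accept(rep(TRUE, length), pv$w, pv$monosite, pv$mu,
                         pv$omega, pv$tau, pv$lambda, pv$eta)
  lbg <- log(unname(model$bg$emission))
  draws <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    s <- cpp_sample(length, model$matrix$probs, unname(model$bg$emission),
                    pv$monosite, pv$rho, pv$mu, pv$omega, pv$tau, pv$lambda,
                    pv$eta, 10000L)
    if (!s$ok) stop("sampler failed to satisfy the consistency constraint")
    o <- cpp_site_odds(s$seq, rep(FALSE, length), model$matrix$probs,
                       unname(model$bg$emission))
    logB <- cpp_batch_logB(list(o), pv$w, pv$monosite, pv$mu, pv$omega,
                           pv$tau, pv$lambda, pv$eta)[1]
    bgll <- sum(lbg[s$seq])
    lp_cond <- cond_loglik(pv$rho, logB, logA, bgll)
    draws[i] <- (lp_cond - bgll) / unit
  }
  structure(list(nats = mean(draws), se = sd(draws) / sqrt(n_samples),
                 n_samples = n_samples, model_id = model$matrix$name,
                 bits = bits),
            class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("<kl_estimate> %.4f %s (se %.4f, n = %d) [%s]\n", x$nats,
              if (isTRUE(x$bits)) "bits" else "nats", x$se, x$n_samples,
              x$model_id))
  invisible(x)
}

#' Exact Kullback-Leibler specificity by enumeration
#'
#' Computes the same divergence as [sampled_kl()] exactly, by enumerating
#' all `4^L` sequences.  Only feasible for short models; refuses lengths
#' above 10 bp.
#'
#' @inheritParams sampled_kl
#' @return divergence in nats (or bits).
#' @export
exact_kl <- function(model, length = model$length, bits = FALSE) {
  if (length > 10) stop("exact KL enumeration limited to length <= 10")
  pv <- par_vec(model)
  res <- cpp_exact_kl(length, model$matrix$probs,
                      unname(model$bg$emission), pv$monosite, pv$rho, pv$mu,
                      pv$omega, pv$tau, pv$lambda, pv$eta)
  if (abs(res$total_p - 1) > 1e-6) {
    warning(sprintf("model distribution summed to %.8f over all sequences",
                    res$total_p))
  }
  kl <- max(res$kl, 0)
  if (bits) kl / log(2) else kl
}

#' Spacing-agnostic single-site baseline model
#'
#' Builds the comparison model that emits exactly one site per promoter
#' with no strand bias and no spatial restriction: a monosite model with
#' `rho = 1`, `tau = 0.5` and a plateau spanning the whole promoter
#' (mu = length / 2, omega = length, so the logistic edges sit far outside
#' the sequence).  Its KL against background isolates the information
#' carried by the binding site alone at promoter scale; subtracting it
#' from a full model's KL quantifies the contribution of spacing, strand
#' and density.
#'
#' @param matrix a [freq_matrix()].
#' @param bg a [background_model()].
#' @param length promoter length in bp.
#' @return a [signature_model()].
#' @export
single_site_baseline <- function(matrix, bg, length) {
  stopifnot(length >= matrix$width)
  signature_model(matrix, bg,
                  spatial_params(rho = 1, mu = length / 2, omega = length,
                                 tau = 0.5, lambda = 1 / length),
                  variant = "monosite", length = length)
}
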
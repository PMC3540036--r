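new_model_comparison <- function(loglik_full, loglik_null, df,
                                 label = "", flag = NULL) {
  stat <- 2 * (loglik_full - loglik_null)
  if (stat < -1e-6 && is.null(flag)) flag <- "null exceeded full: non-convergence"
  stat <- max(stat, 0)
  structure(list(loglik_full = loglik_full, loglik_null = loglik_null,
                 statistic = stat, df = df,
                 p = pchisq(stat, df = df, lower.tail = FALSE),
                 label = label, flag = flag),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> %s: LRT stat %.3f (df=%d), p = %.4g\n",
    x$label, x$statistic, x$df, x$p))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Likelihood-ratio test for strand bias
#'
#' Compares the full fit against a nested null refit with tau pinned at
#' 0.5 (no strand preference), all other parameters free.  The null is
#' warm-started from the full fit's parameters so that under-optimization
#' inflates, rather than deflates, the null's log-likelihood.  One degree
#' of freedom.
#'
#' @param sequences training promoters.
#' @param fit_full a [em_fit()] result with tau free.
#' @param schedule annealing schedule for the null refit.
#' @param n_starts starts for the null refit (warm start counts as the
#'   first).
#' @param ... further arguments passed to [em_fit()].
#' @return a `model_comparison`.
#' @export
lrt_strand <- function(sequences, fit_full, schedule = anneal_schedule(),
                       n_starts = 1, ...) {
  null_fit <- em_fit(sequences, fit_full$model$matrix, fit_full$model$bg,
                     variant = fit_full$model$variant, n_starts = n_starts,
                     schedule = schedule, init = fit_full$params,
                     fixed = list(tau = 0.5), min_promoters = 0, ...)
  new_model_comparison(fit_full$loglik, null_fit$loglik, df = 1,
                       label = "strand bias (tau = 0.5 null)")
}

#' Likelihood-ratio test for spatial restriction against a uniform null
#'
#' Initial significance test for the spacing parameters: the null pins
#' (mu, omega) to a plateau spanning the whole promoter (mu = L/2,
#' omega = L/2), other parameters free.  Two degrees of freedom.
#'
#' @inheritParams lrt_strand
#' @return a `model_comparison`.
#' @export
lrt_spacing_uniform <- function(sequences, fit_full,
                                schedule = anneal_schedule(), n_starts = 1,
                                ...) {
  L <- max(nchar(sequences))
  null_fit <- em_fit(sequences, fit_full$model$matrix, fit_full$model$bg,
                     variant = fit_full$model$variant, n_starts = n_starts,
                     schedule = schedule, init = fit_full$params,
                     fixed = list(mu = L / 2, omega = L / 2),
                     min_promoters = 0, ...)
  new_model_comparison(fit_full$loglik, null_fit$loglik, df = 2,
                       label = "spatial restriction (uniform null)")
}

#' Scrambling configuration
#'
#' @param min_set_size duplicate the set to at least this many sequences
#'   before scrambling (default 600).
#' @param seg_min,seg_max segment length limits in bp (defaults 5 and 75).
#' @param iterations number of attempted swaps; 1e6 by default
#'   (desk scale), raise to the full 1e8 for production runs.
#' @param border_threshold log2 score at or above which a window counts as
#'   a site when checking segment borders (default 0).
#' @param max_attempts picks tried per segment before the iteration is
#'   skipped.
#' @return an object of class `scramble_config`.
#' @export
scramble_config <- function(min_set_size = 600, seg_min = 5, seg_max = 75,
                            iterations = 1e6, border_threshold = 0,
                            max_attempts = 200) {
  stopifnot(seg_min >= 1, seg_max >= seg_min, iterations >= 1)
  structure(list(min_set_size = min_set_size, seg_min = seg_min,
                 seg_max = seg_max, iterations = iterations,
                 border_threshold = border_threshold,
                 max_attempts = max_attempts),
            class = "scramble_config")
}

#' Spatially scramble a promoter set
#'
#' Destroys positional structure while conserving per-set base composition,
#' per-sequence lengths, and the strength and number of scoring sites.  The
#' set is duplicated to the configured minimum size, then pairs of
#' equal-length segments whose borders are not crossed by any site of
#' border-threshold score (either strand, rescanned against current
#' content) are repeatedly swapped.
#'
#' @param sequences named character vector.
#' @param matrix,bg scoring model for the border checks.
#' @param config a [scramble_config()].
#' @return named character vector of scrambled sequences (the duplicated
#'   set), with attributes `swaps` and `skipped`.
#' @export
scramble_set <- function(sequences, matrix, bg, config = scramble_config()) {
  n0 <- length(sequences)
  reps <- ceiling(config$min_set_size / n0)
  seqs <- rep(sequences, reps)
  names(seqs) <- sprintf("%s_dup%d", rep(names(sequences), reps),
                         rep(seq_len(reps), each = n0))
  if (any(nchar(seqs) < config$seg_min)) {
    stop("segment length range exceeds the shortest sequence")
  }
  enc <- lapply(seqs, function(s) encode_seq(s)$codes)
  lo <- log2_odds_matrix(matrix, bg)
  lorc <- log2_odds_matrix_rc(matrix, bg)
  res <- cpp_scramble(enc, lo, lorc, config$border_threshold,
                      as.integer(config$seg_min),
                      as.integer(min(config$seg_max, min(nchar(seqs)))),
                      config$iterations, as.integer(config$max_attempts))
  out <- vapply(res$seqs, decode_seq, character(1))
  names(out) <- names(seqs)
  attr(out, "swaps") <- res$swaps
  attr(out, "skipped") <- res$skipped
  out
}

#' Spacing control test against scramble-derived values
#'
#' Refits the original data with (mu, omega) pinned to the values trained
#' on the scrambled set, all other parameters free, and compares with the
#' full fit by a two-degree-of-freedom likelihood-ratio test.  A
#' significant result means the spatial restriction in the data exceeds
#' what promoter lengths alone (which the scramble preserves) can explain.
#'
#' @inheritParams lrt_strand
#' @param scrambled_fit a [em_fit()] result trained on [scramble_set()]
#'   output.
#' @return a `model_comparison`.
#' @export
spacing_control_test <- function(sequences, fit_full, scrambled_fit,
                                 schedule = anneal_schedule(), n_starts = 1,
                                 ...) {
  sp <- scrambled_fit$params
  init <- fit_full$params
  null_fit <- em_fit(sequences, fit_full$model$matrix, fit_full$model$bg,
                     variant = fit_full$model$variant, n_starts = n_starts,
                     schedule = schedule, init = init,
                     fixed = list(mu = sp$mu, omega = sp$omega),
                     min_promoters = 0, ...)
  new_model_comparison(fit_full$loglik, null_fit$loglik, df = 2,
                       label = "spacing control (scramble-derived null)")
}

#' Choose between the multisite and monosite variants
#'
#' Site density needs a different model structure, so the variants are
#' compared with an information criterion rather than a nested test: BIC
#' with 5 effective parameters for the multisite model (rho, tau, lambda,
#' mu, omega) and 4 for the monosite model (rho, tau, mu, omega).  Lower
#' BIC wins; at equal log-likelihood the variant with fewer parameters
#' wins.
#'
#' @param fit_multisite,fit_monosite [em_fit()] results on the same data.
#' @param sequences optional training promoters; when given, the expected
#'   number of sites per promoter under the chosen fit is reported.
#' @return an object of class `density_choice` with `choice`, `bic`,
#'   and optionally `expected_sites`.
#' @export
compare_density <- function(fit_multisite, fit_monosite, sequences = NULL) {
  stopifnot(fit_multisite$n_sequences == fit_monosite$n_sequences)
  n <- fit_multisite$n_sequences
  bic <- c(multisite = 5 * log(n) - 2 * fit_multisite$loglik,
           monosite = 4 * log(n) - 2 * fit_monosite$loglik)
  choice <- names(bic)[which.min(bic)] # ties: multisite first... see below
  if (bic["multisite"] == bic["monosite"]) choice <- "monosite"
  chosen <- if (choice == "multisite") fit_multisite else fit_monosite
  es <- if (!is.null(sequences)) {
    expected_sites_per_promoter(chosen, sequences)
  } else {
    NA_real_
  }
  structure(list(choice = choice, bic = bic,
                 loglik = c(multisite = fit_multisite$loglik,
                            monosite = fit_monosite$loglik),
                 expected_sites = es),
            class = "density_choice")
}

#' @export
print.density_choice <- function(x, ...) {
  cat(sprintf("<density_choice> %s (BIC %.2f vs %.2f)\n", x$choice,
              x$bic["multisite"], x$bic["monosite"]))
  if (!is.na(x$expected_sites)) {
    cat(sprintf("expected sites/promoter under chosen fit: %.2f\n",
                x$expected_sites))
  }
  invisible(x)
}

#' Verdict rule of the unbound-region screen
#'
#' A signature is discarded when the median over sets of the per-set
#' maximum trained rho exceeds 0.15, or when any single trained rho
#' exceeds the signature's own rho.
#'
#' @param per_set_max per-set maxima of trained rho.
#' @param all_rho every trained rho across all sets and starts.
#' @param signature_rho the rho of the signature under scrutiny.
#' @return list with `verdict` ("keep" or "discard") and `reason`.
#' @export
screen_verdict <- function(per_set_max, all_rho, signature_rho) {
  med <- median(per_set_max)
  if (med > 0.15) {
    list(verdict = "discard",
         reason = sprintf("median of per-set max rho = %.3f > 0.15", med))
  } else if (any(all_rho > signature_rho)) {
    list(verdict = "discard",
         reason = sprintf("a trained rho (%.3f) exceeds the signature rho (%.3f)",
                          max(all_rho), signature_rho))
  } else {
    list(verdict = "keep",
         reason = sprintf("median of per-set max rho = %.3f <= 0.15", med))
  }
}

#' Unbound-region screen
#'
#' Fits the model to random sets drawn from promoters unbound by the
#' factor in every tested condition.  If a signature can be trained to an
#' appreciable level there, the original signature is suspect (e.g. the
#' matrix matches the background everywhere) and is discarded.
#'
#' @param matrix,bg the factor's scoring model.
#' @param unbound_sequences pool of unbound promoters.
#' @param signature_rho rho of the signature being screened.
#' @param seed integer seed (the screen is deterministic given it).
#' @param n_sets number of random sets (default 20).
#' @param set_size promoters per set (default 20, the training minimum).
#' @param n_starts EM starts per set (default 20).
#' @param variant model variant to fit.
#' @param schedule annealing schedule for the screen fits.
#' @param max_iter EM iteration cap for the screen fits.
#' @return an object of class `screen_result`.
#' @export
unbound_screen <- function(matrix, bg, unbound_sequences, signature_rho,
                           seed = 1, n_sets = 20, set_size = 20,
                           n_starts = 20, variant = "multisite",
                           schedule = anneal_schedule(n_temps = 4, steps = 10),
                           max_iter = 25) {
  if (length(unbound_sequences) < set_size) {
    stop(sprintf("unbound pool (%d) smaller than one screen set (%d)",
                 length(unbound_sequences), set_size))
  }
  set.seed(seed)
  per_set_max <- numeric(n_sets)
  all_rho <- numeric(0)
  for (s in seq_len(n_sets)) {
    idx <- sample(length(unbound_sequences), set_size)
    fit <- em_fit(unbound_sequences[idx], matrix, bg, variant = variant,
                  n_starts = n_starts, schedule = schedule,
                  max_iter = max_iter, min_promoters = 0)
    rhos <- vapply(fit$all_starts, function(st) st$params$rho, numeric(1))
    per_set_max[s] <- max(rhos)
    all_rho <- c(all_rho, rhos)
  }
  v <- screen_verdict(per_set_max, all_rho, signature_rho)
  structure(list(per_set_max = per_set_max,
                 median_max = median(per_set_max), all_rho = all_rho,
                 signature_rho = signature_rho, verdict = v$verdict,
                 reason = v$reason, n_sets = n_sets, set_size = set_size,
                 n_starts = n_starts),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %s (%s); %d sets x %d starts, median max rho = %.3f\n",
    x$verdict, x$reason, x$n_sets, x$n_starts, x$median_max))
  invisible(x)
}

#' Positions of scoring sites in a promoter set
#'
#' Convenience diagnostic: pooled 0-based start positions (and TSS
#' distances) of all windows scoring at or above a threshold, used e.g. to
#' check that scrambling flattens a planted positional distribution.
#'
#' @param sequences named character vector.
#' @param matrix,bg scoring model.
#' @param threshold log2 score cutoff (default 0).
#' @return data.frame with id, start, strand, score, and `p`, the distance
#'   of the site's TSS-proximal end from the TSS.
#' @export
site_positions <- function(sequences, matrix, bg, threshold = 0) {
  w <- matrix$width
  rows <- lapply(names(sequences), function(id) {
    tr <- scan_scores(matrix, bg, sequences[[id]])
    if (nrow(tr) == 0) return(NULL)
    L <- nchar(sequences[[id]])
    hits <- which(tr >= threshold, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    start <- hits[, 1] - 1L
    data.frame(id = id, start = start,
               strand = ifelse(hits[, 2] == 1, "+", "-"),
               score = tr[hits], p = L - start - w)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0))
  }
  out
}
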
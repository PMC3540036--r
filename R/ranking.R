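ranked_frame <- function(ids, scores, method) {
  ord <- order(-scores, ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  out <- data.frame(id = ids, score = scores, rank = rank,
                    method = method, stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Rank promoters by their best single site
#'
#' Score = the maximum log2 log-odds score over all positions and strands.
#' Promoters shorter than the motif get score `-Inf` and rank last.  Ties
#' are broken by promoter id.
#'
#' @param matrix a [freq_matrix()].
#' @param bg a [background_model()].
#' @param promoters named character vector.
#' @return data.frame with columns id, score, rank, method.
#' @export
rank_by_top_site <- function(matrix, bg, promoters) {
  promoters <- auto_names(promoters)
  scores <- vapply(promoters, function(s) {
    tr <- scan_scores(matrix, bg, s)
    if (nrow(tr) == 0) -Inf else max(tr)
  }, numeric(1))
  ranked_frame(names(promoters), unname(scores), "top_site")
}

#' Rank promoters by thermodynamic occupancy
#'
#' Assumes a single protein molecule competed for by every possible site in
#' every promoter.  Each site's affinity is the exponential of its
#' natural-log-odds score; with `Z` the sum of affinities over the whole
#' set, a promoter's score is its share `sum(a_i) / Z` — the probability
#' that the protein is bound somewhere within it.  Scores over the set sum
#' to one.
#'
#' @inheritParams rank_by_top_site
#' @return data.frame with columns id, score, rank, method.
#' @export
rank_by_thermodynamic <- function(matrix, bg, promoters) {
  if (length(promoters) == 0) stop("empty promoter set")
  promoters <- auto_names(promoters)
  ln2 <- log(2)
  aff <- vapply(promoters, function(s) {
    tr <- scan_scores(matrix, bg, s)
    if (nrow(tr) == 0) 0 else sum(exp(tr * ln2))
  }, numeric(1))
  Z <- sum(aff)
  if (Z <= 0) stop("no scorable site in the promoter set")
  ranked_frame(names(promoters), unname(aff / Z), "thermodynamic")
}

#' Rank promoters by signature match
#'
#' Score = posterior regulation probability `E[R]` with the prior rho
#' replaced by 0.5 (a monotone transform of the likelihood ratio, so the
#' choice of override does not change the order).
#'
#' @param model a trained [signature_model()].
#' @param promoters named character vector.
#' @param rho_override prior used for the expectation (default 0.5).
#' @return data.frame with columns id, score, rank, method.
#' @export
rank_by_signature <- function(model, promoters, rho_override = 0.5) {
  promoters <- auto_names(promoters)
  pv <- par_vec(model)
  odds <- odds_set(model, promoters)
  logB <- cpp_batch_logB(odds, pv$w, pv$monosite, pv$mu, pv$omega, pv$tau,
                         pv$lambda, pv$eta)
  scores <- ifelse(is.finite(logB),
                   1 / (1 + exp(log1p(-rho_override) - log(rho_override)
                                - logB)),
                   0)
  ranked_frame(names(promoters), scores, "signature")
}

#' Rank promoters by ChIP binding p-values
#'
#' Score = minus the smallest p-value observed across conditions, so that
#' stronger binding ranks better.  Promoters absent from the table are
#' excluded (with a message).
#'
#' @param pvalue_table data.frame whose first column is the promoter id and
#'   remaining columns are per-condition binding p-values.
#' @param promoters optional character vector restricting and ordering the
#'   universe.
#' @return data.frame with columns id, score, rank, method.
#' @export
rank_by_chip <- function(pvalue_table, promoters = NULL) {
  ids <- as.character(pvalue_table[[1]])
  pmat <- as.matrix(pvalue_table[, -1, drop = FALSE])
  if (!is.null(promoters)) {
    missing <- setdiff(promoters, ids)
    if (length(missing)) {
      message(length(missing), " promoter(s) absent from the p-value table, excluded")
    }
    keep <- ids %in% promoters
    ids <- ids[keep]
    pmat <- pmat[keep, , drop = FALSE]
  }
  scores <- -apply(pmat, 1, min, na.rm = TRUE)
  ranked_frame(ids, unname(scores), "chip")
}

#' Evaluate a ranking against deletion expression changes
#'
#' Takes the top `K` ranked promoters, joins them to per-ORF expression
#' changes measured on factor deletion, and reports their mean change
#' together with a null 95% confidence interval built by repeatedly
#' resampling `K` ORFs at random from the expression dataset.  The ranking
#' is significant when its mean falls outside the interval.  (When
#' expression changes are widespread the null interval itself may exclude
#' zero.)
#'
#' @param ranked a ranking data.frame from one of the `rank_by_*`
#'   functions.
#' @param expression data.frame with columns `orf` and `change` (log fold
#'   change on deletion); non-finite changes are dropped.
#' @param K cutoff (default 50).
#' @param resamples null resampling count (default 5000).
#' @param seed integer seed.
#' @param exclude optional promoter ids (e.g. the training set) removed
#'   from both the ranking and the null pool before evaluation.
#' @return an object of class `eval_result`.
#' @export
evaluate_topk <- function(ranked, expression, K = 50, resamples = 5000,
                          seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  names(expression)[1:2] <- c("orf", "change")
  expression <- expression[is.finite(expression$change), ]
  if (!is.null(exclude)) {
    ranked <- ranked[!ranked$id %in% exclude, ]
    expression <- expression[!expression$orf %in% exclude, ]
  }
  joined <- merge(ranked, expression, by.x = "id", by.y = "orf")
  joined <- joined[order(joined$rank), ]
  k_eff <- min(K, nrow(joined))
  if (k_eff < K) {
    warning(sprintf("only %d ranked ORFs have expression data; evaluating at K = %d",
                    nrow(joined), k_eff))
  }
  if (k_eff == 0) stop("no ranked promoter matches the expression table")
  top <- head(joined, k_eff)
  mean_change <- mean(top$change)
  null_means <- vapply(seq_len(resamples), function(i) {
    mean(sample(expression$change, k_eff, replace = FALSE))
  }, numeric(1))
  ci <- unname(quantile(null_means, c(0.025, 0.975)))
  structure(list(method = ranked$method[1], K = k_eff,
                 mean_change = mean_change, ci = ci,
                 significant = mean_change < ci[1] | mean_change > ci[2],
                 resamples = resamples, top_ids = top$id),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s top-%d mean change %.4f, null 95%% CI [%.4f, %.4f] => %s\n",
    x$method, x$K, x$mean_change, x$ci[1], x$ci[2],
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Bootstrap comparison of two ranking methods
#'
#' Resamples (promoter, expression) pairs jointly with replacement; in each
#' replicate each method's top `K` among the resampled pairs is retrieved
#' and the magnitude of its mean expression change computed.  The p-value
#' is the fraction of replicates in which method B's magnitude is at least
#' method A's (small p: A is reliably stronger).
#'
#' @param rankedA,rankedB rankings over the same promoter universe (A is
#'   the method hypothesized to be stronger).
#' @param expression data.frame with columns `orf` and `change`.
#' @param K cutoff (default 50).
#' @param reps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return list with `p`, `obs_A`, `obs_B` (observed top-K magnitudes) and
#'   `reps`.
#' @export
bootstrap_method_comparison <- function(rankedA, rankedB, expression, K = 50,
                                        reps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  names(expression)[1:2] <- c("orf", "change")
  expression <- expression[is.finite(expression$change), ]
  universe <- sort(intersect(intersect(rankedA$id, rankedB$id),
                             expression$orf))
  n <- length(universe)
  if (n < K) stop("fewer joined promoters than K")
  chg <- setNames(expression$change[match(universe, expression$orf)],
                  universe)
  sA <- setNames(rankedA$score[match(universe, rankedA$id)], universe)
  sB <- setNames(rankedB$score[match(universe, rankedB$id)], universe)
  topk_mean <- function(scores, idx) {
    ord <- order(-scores[idx], universe[idx])
    mean(chg[idx][ord][seq_len(K)])
  }
  all_idx <- seq_len(n)
  obs_A <- abs(topk_mean(sA, all_idx))
  obs_B <- abs(topk_mean(sB, all_idx))
  wins_B <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (abs(topk_mean(sB, idx)) >= abs(topk_mean(sA, idx))) {
      wins_B <- wins_B + 1L
    }
  }
  list(p = wins_B / reps, obs_A = obs_A, obs_B = obs_B, reps = reps)
}

#' Exact binomial sign test for method wins
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, 1/2)`, by exact
#' summation: the chance that one method would beat the other in at least
#' `k` of `n` factors if the two were equivalent.
#'
#' @param k_wins number of wins.
#' @param n_factors number of factors in which either method was
#'   significant.
#' @return exact one-sided p-value.
#' @export
binomial_wins_test <- function(k_wins, n_factors) {
  stopifnot(k_wins >= 0, n_factors >= 1, k_wins <= n_factors)
  sum(choose(n_factors, k_wins:n_factors)) / 2^n_factors
}

#' Positional score-density profile
#'
#' For promoters aligned at the TSS, the sum of positive log2 PWM scores of
#' site starts falling in each 20-bp window of TSS distance, divided by the
#' number of possible site positions contributed to that window by the
#' data.  A background line and 95% band are derived from simulated
#' GC-matched sequence sets with the same length distribution.  Windows
#' reached by no promoter are NA.
#'
#' @param matrix,bg scoring model.
#' @param promoters named character vector.
#' @param window window width in bp (default 20).
#' @param sims number of simulated background sets (default 200).
#' @param seed integer seed.
#' @return data.frame with columns window_start (TSS distance), density,
#'   bg_mean, bg_lo, bg_hi, n_positions.
#' @export
score_density_profile <- function(matrix, bg, promoters, window = 20,
                                  sims = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix$width
  lens <- nchar(promoters)
  maxp <- max(lens) - w
  breaks <- seq(0, maxp + window, by = window)
  nwin <- length(breaks) - 1
  profile_of <- function(seqs) {
    pos_count <- numeric(nwin)
    score_sum <- numeric(nwin)
    for (s in seqs) {
      tr <- scan_scores(matrix, bg, s)
      if (nrow(tr) == 0) next
      L <- nchar(s)
      p <- L - (seq_len(nrow(tr)) - 1) - w # TSS distance per start
      bin <- pmin(p %/% window + 1, nwin)
      for (col in 1:2) {
        sc <- tr[, col]
        pos <- pmax(sc, 0)
        score_sum <- score_sum + vapply(seq_len(nwin), function(b) {
          sum(pos[bin == b])
        }, numeric(1))
      }
      pos_count <- pos_count + 2 * tabulate(bin, nbins = nwin)
    }
    list(density = ifelse(pos_count > 0, score_sum / pos_count, NA_real_),
         n = pos_count)
  }
  obs <- profile_of(promoters)
  sim_dens <- matrix(NA_real_, nrow = sims, ncol = nwin)
  for (i in seq_len(sims)) {
    fake <- vapply(lens, function(L) random_bg_seq(L, bg$gc), character(1))
    sim_dens[i, ] <- profile_of(fake)$density
  }
  data.frame(window_start = breaks[-length(breaks)],
             density = obs$density,
             bg_mean = apply(sim_dens, 2, mean, na.rm = TRUE),
             bg_lo = apply(sim_dens, 2, quantile, probs = 0.025,
                           na.rm = TRUE),
             bg_hi = apply(sim_dens, 2, quantile, probs = 0.975,
                           na.rm = TRUE),
             n_positions = obs$n)
}

#' ROC curve of a ranking against binary binding labels
#'
#' Standard ROC over score thresholds (computed with \pkg{pROC}), using the
#' bound-region convention that a promoter is "bound" when its smallest
#' binding p-value is below 0.05.
#'
#' @param ranked a ranking data.frame.
#' @param bound_labels named logical/0-1 vector of bound status per
#'   promoter id.
#' @return list with `auc` and `curve` (data.frame fpr, tpr).
#' @export
roc_binding <- function(ranked, bound_labels) {
  lab <- bound_labels[ranked$id]
  if (anyNA(lab)) stop("every ranked promoter needs a bound label")
  lab <- as.integer(lab)
  if (length(unique(lab)) < 2) {
    stop("labels are single-class: AUC undefined")
  }
  r <- pROC::roc(response = lab, predictor = ranked$score,
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       curve = data.frame(fpr = 1 - r$specificities,
                          tpr = r$sensitivities))
}
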
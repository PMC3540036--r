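#' Simulated annealing schedule
#'
#' Controls the stochastic M-step used to update the spatial triple
#' (lambda, mu, omega) inside each EM iteration.  Proposals are Gaussian;
#' the lambda proposal scale is relative to its current value, mu and omega
#' scales are in bp.  With `t_init = 0` the annealer degenerates to a
#' greedy hill climb (only improvements accepted).
#'
#' @param t_init initial temperature (log-likelihood units).
#' @param cooling geometric cooling factor in `(0, 1)`.
#' @param n_temps number of temperature levels per annealing run.
#' @param steps proposals per temperature.
#' @param scale_lambda relative proposal sd for lambda.
#' @param scale_mu proposal sd for mu, bp.
#' @param scale_omega proposal sd for omega, bp.
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_init = 2, cooling = 0.9, n_temps = 10,
                            steps = 50, scale_lambda = 0.25, scale_mu = 50,
                            scale_omega = 50) {
  stopifnot(cooling > 0, cooling < 1, steps >= 1, n_temps >= 1, t_init >= 0)
  structure(list(t_init = t_init, cooling = cooling, n_temps = n_temps,
                 steps = steps, scale_lambda = scale_lambda,
                 scale_mu = scale_mu, scale_omega = scale_omega),
            class = "anneal_schedule")
}

#' Analytic M-step for rho
#'
#' Maximum-likelihood update of the signature-carrying fraction: the mean
#' posterior regulation probability over the training promoters.
#'
#' @param e_r numeric vector of per-promoter `E[R]` values.
#' @return updated rho.
#' @export
mstep_rho <- function(e_r) {
  stopifnot(length(e_r) >= 1, all(e_r >= 0), all(e_r <= 1))
  mean(e_r)
}

#' Analytic M-step for tau
#'
#' Maximum-likelihood update of the strand bias: the forward share of the
#' total posterior site-start mass.  Defined as 0.5 when no site mass is
#' present.
#'
#' @param fwd_mass total forward-strand site-start posterior mass.
#' @param rev_mass total reverse-strand site-start posterior mass.
#' @return updated tau.
#' @export
mstep_tau <- function(fwd_mass, rev_mass) {
  tot <- sum(fwd_mass) + sum(rev_mass)
  if (tot <= 0) return(0.5)
  sum(fwd_mass) / tot
}

# total joint loglik over an odds set at given params (internal, hot path)
total_ll <- function(odds, bgll, w, monosite, rho, mu, omega, tau, lambda,
                     eta) {
  logB <- cpp_batch_logB(odds, w, monosite, mu, omega, tau, lambda, eta)
  if (rho <= 0) return(sum(bgll))
  if (rho >= 1) return(sum(bgll + logB))
  sum(bgll + logsumexp2(log(rho) + logB, log1p(-rho)))
}

#' Annealed M-step for the spatial triple
#'
#' Metropolis simulated annealing of (lambda, mu, omega) on the full
#' marginal log-likelihood with rho and tau held fixed.  Out-of-bounds
#' proposals are rejected without evaluation.  The best triple visited
#' (which always includes the incumbent) is returned, so the objective
#' cannot decrease.  Deterministic given the RNG state.
#'
#' @param model a [signature_model()] holding the current parameters.
#' @param sequences named character vector of promoters (or a precomputed
#'   internal odds list).
#' @param schedule an [anneal_schedule()].
#' @param free which of `"lambda"`, `"mu"`, `"omega"` to move.
#' @param mu_max upper bound for mu and omega (defaults to the model
#'   length).
#' @return list with `lambda`, `mu`, `omega`, `loglik` (best visited) and
#'   `n_accepted`.
#' @export
anneal_spatial <- function(model, sequences, schedule = anneal_schedule(),
                           free = c("lambda", "mu", "omega"),
                           mu_max = model$length) {
  odds <- if (is.list(sequences) && !is.null(sequences[[1]]$ef)) sequences
          else odds_set(model, sequences)
  bgll <- vapply(odds, function(o) o$bgll, numeric(1))
  pv <- par_vec(model)
  cur <- c(lambda = pv$lambda, mu = pv$mu, omega = pv$omega)
  f <- function(v) total_ll(odds, bgll, pv$w, pv$monosite, pv$rho, v[["mu"]],
                            v[["omega"]], pv$tau, v[["lambda"]], pv$eta)
  cur_ll <- f(cur)
  best <- cur
  best_ll <- cur_ll
  temp <- schedule$t_init
  n_acc <- 0L
  scales <- c(lambda = schedule$scale_lambda, mu = schedule$scale_mu,
              omega = schedule$scale_omega)
  lo <- c(lambda = 1e-8, mu = 0, omega = 1e-3)
  hi <- c(lambda = 0.999, mu = mu_max, omega = mu_max)
  for (t in seq_len(schedule$n_temps)) {
    for (s in seq_len(schedule$steps)) {
      prop <- cur
      for (nm in free) {
        sd <- if (nm == "lambda") scales[["lambda"]] * cur[["lambda"]]
              else scales[[nm]]
        prop[[nm]] <- prop[[nm]] + rnorm(1, 0, sd)
      }
      if (any(prop < lo[names(prop)]) || any(prop > hi[names(prop)])) next
      ll <- f(prop)
      accept <- if (ll >= cur_ll) TRUE
                else if (temp > 0) runif(1) < exp((ll - cur_ll) / temp)
                else FALSE
      if (accept) {
        cur <- prop
        cur_ll <- ll
        n_acc <- n_acc + 1L
      }
      if (ll > best_ll) {
        best <- prop
        best_ll <- ll
      }
    }
    temp <- temp * schedule$cooling
  }
  list(lambda = best[["lambda"]], mu = best[["mu"]], omega = best[["omega"]],
       loglik = best_ll, n_accepted = n_acc)
}

draw_start <- function(L, fixed, monosite) {
  list(rho = fixed$rho %||% 0.5,
       tau = fixed$tau %||% 0.5,
       lambda = fixed$lambda %||%
         if (monosite) 1 / L else runif(1, 1 / L, 20 / L),
       mu = fixed$mu %||% runif(1, 0, L),
       omega = fixed$omega %||% runif(1, min(25, L / 4), L / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a signature model by EM with annealed M-steps
#'
#' Maximum-likelihood training of the spatial parameters from multiple
#' random starts.  Each EM iteration computes exact posteriors (E-step),
#' updates rho and tau analytically, and updates the spatial triple
#' (lambda, mu, omega) by simulated annealing on the marginal
#' log-likelihood; iteration stops when the log-likelihood improves by less
#' than `tol` or after `max_iter` iterations.  The best start by final
#' log-likelihood wins.  The monosite variant has no density parameter
#' (lambda cancels out of its normalized site-position distribution), so
#' only mu and omega are annealed there.
#'
#' @param sequences named character vector of training promoters.
#' @param matrix a [freq_matrix()].
#' @param bg a [background_model()].
#' @param variant `"multisite"` or `"monosite"`.
#' @param n_starts number of random starts (default 15).
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param tol convergence tolerance on the log-likelihood, nats.
#' @param max_iter maximum EM iterations per start.
#' @param init optional `spatial_params` (or plain list) used as the first
#'   start (warm start).
#' @param fixed named list pinning any of rho, tau, lambda, mu, omega to a
#'   constant (used by the likelihood-ratio controls).
#' @param min_promoters training sets smaller than this trigger a warning.
#' @return an object of class `promsig_fit`: `model` (fitted
#'   [signature_model()]), `params`, `loglik`, `trace`, `start_index`,
#'   `converged`, `all_starts` (per-start params and loglik), `n_params`.
#' @export
em_fit <- function(sequences, matrix, bg = background_model(),
                   variant = c("multisite", "monosite"), n_starts = 15,
                   schedule = anneal_schedule(), seed = NULL, tol = 1e-4,
                   max_iter = 200, init = NULL, fixed = list(),
                   min_promoters = 20, verbose = FALSE) {
  variant <- match.arg(variant)
  monosite <- variant == "monosite"
  if (length(sequences) < 1) stop("at least one training sequence required")
  if (length(sequences) < min_promoters) {
    warning(sprintf("training set has %d promoters; %d or more recommended",
                    length(sequences), min_promoters))
  }
  if (!is.null(seed)) set.seed(seed)
  w <- matrix$width
  dummy_params <- spatial_params(0.5, 1, 1, 0.5, 0.01)
  probe <- signature_model(matrix, bg, dummy_params, variant,
                           length = max(nchar(sequences)))
  odds <- odds_set(probe, sequences)
  if (all(vapply(odds, function(o) !any(o$allow), logical(1)))) {
    stop("no sequence admits a site (all shorter than the motif or masked)")
  }
  bgll <- vapply(odds, function(o) o$bgll, numeric(1))
  Lmax <- max(vapply(odds, function(o) o$L, numeric(1)))
  eta <- 0.1
  free <- setdiff(c("lambda", "mu", "omega"), names(fixed))
  if (monosite) free <- setdiff(free, "lambda")

  run_start <- function(start_params) {
    p <- start_params
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      es <- cpp_batch_estep(odds, w, monosite, p$rho, p$mu, p$omega, p$tau,
                            p$lambda, eta)
      if (is.null(fixed$rho)) p$rho <- mstep_rho(pmin(pmax(es$e_r, 0), 1))
      if (is.null(fixed$tau)) p$tau <- mstep_tau(es$fwd_mass, es$rev_mass)
      if (length(free) > 0) {
        cur_model <- signature_model(
          matrix, bg,
          spatial_params(p$rho, p$mu, p$omega, p$tau, p$lambda, eta),
          variant, length = Lmax)
        ann <- anneal_spatial(cur_model, odds, schedule, free = free,
                              mu_max = Lmax)
        p$lambda <- ann$lambda
        p$mu <- ann$mu
        p$omega <- ann$omega
        ll <- ann$loglik
      } else {
        ll <- total_ll(odds, bgll, w, monosite, p$rho, p$mu, p$omega, p$tau,
                       p$lambda, eta)
      }
      trace <- c(trace, ll)
      if (verbose) message(sprintf("  iter %3d  loglik %.4f", iter, ll))
      if (is.finite(prev) && abs(ll - prev) < tol) {
        converged <- TRUE
        break
      }
      prev <- ll
    }
    list(params = p, loglik = trace[length(trace)], trace = trace,
         converged = converged)
  }

  starts <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    sp <- if (k == 1 && !is.null(init)) {
      ip <- unclass(init)
      st <- list(rho = fixed$rho %||% ip$rho, tau = fixed$tau %||% ip$tau,
                 lambda = fixed$lambda %||% ip$lambda,
                 mu = fixed$mu %||% ip$mu, omega = fixed$omega %||% ip$omega)
      st
    } else {
      draw_start(Lmax, fixed, monosite)
    }
    starts[[k]] <- run_start(sp)
    if (verbose) {
      message(sprintf("start %d/%d: loglik %.4f", k, n_starts,
                      starts[[k]]$loglik))
    }
  }
  lls <- vapply(starts, function(s) s$loglik, numeric(1))
  bi <- which.max(lls)
  bp <- starts[[bi]]$params
  params <- spatial_params(bp$rho, bp$mu, bp$omega, bp$tau, bp$lambda, eta)
  fit <- list(
    model = signature_model(matrix, bg, params, variant, length = Lmax),
    params = params, loglik = lls[bi], trace = starts[[bi]]$trace,
    start_index = bi, converged = starts[[bi]]$converged,
    all_starts = lapply(starts, function(s) {
      list(params = s$params, loglik = s$loglik, converged = s$converged)
    }),
    n_params = length(free) + is.null(fixed$rho) + is.null(fixed$tau),
    n_sequences = length(sequences))
  class(fit) <- "promsig_fit"
  fit
}

#' @export
print.promsig_fit <- function(x, ...) {
  cat(sprintf(
    "<promsig_fit> %s, loglik %.3f after %d iterations (start %d%s)\n",
    x$model$variant, x$loglik, length(x$trace), x$start_index,
    if (x$converged) ", converged" else ", max_iter reached"))
  print(x$params)
  invisible(x)
}

#' Mean expected site count per promoter under a fit
#'
#' @param fit a [em_fit()] result.
#' @param sequences the promoters to evaluate (training set by default is
#'   not stored; pass it explicitly).
#' @return mean of the posterior expected number of sites per promoter.
#' @export
expected_sites_per_promoter <- function(fit, sequences) {
  pv <- par_vec(fit$model)
  odds <- odds_set(fit$model, sequences)
  es <- cpp_batch_estep(odds, pv$w, pv$monosite, pv$rho, pv$mu, pv$omega,
                        pv$tau, pv$lambda, pv$eta)
  mean(es$fwd_mass + es$rev_mass)
}
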
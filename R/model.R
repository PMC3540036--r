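#' Spatial parameters of a promoter signature
#'
#' The five trained parameters of the signature model plus the fixed plateau
#' slope.  Distances are measured in base pairs upstream of the TSS, with
#' position 0 the base adjacent to the TSS; a site's position is the distance
#' of its TSS-proximal end.
#'
#' @param rho fraction of promoters carrying the signature, in `[0, 1]`.
#' @param mu plateau center, bp upstream of the TSS, `>= 0`.
#' @param omega plateau half-width in bp, `> 0`.
#' @param tau forward-strand fraction of site initiations, in `[0, 1]`.
#' @param lambda per-position site initiation rate at the plateau top; must
#'   be `< 1` so the total initiation probability at any position stays
#'   below one.
#' @param eta logistic slope of the plateau edges (fixed, default 0.1).
#' @return an object of class `spatial_params`.
#' @export
spatial_params <- function(rho, mu, omega, tau, lambda, eta = 0.1) {
  stopifnot(is.numeric(rho), rho >= 0, rho <= 1,
            is.numeric(mu), mu >= 0,
            is.numeric(omega), omega > 0,
            is.numeric(tau), tau >= 0, tau <= 1,
            is.numeric(lambda), lambda >= 0,
            is.numeric(eta), eta > 0)
  if (lambda >= 1) {
    stop("lambda must be < 1: total site-initiation probability would reach 1")
  }
  structure(list(rho = rho, mu = mu, omega = omega, tau = tau,
                 lambda = lambda, eta = eta), class = "spatial_params")
}

#' @export
print.spatial_params <- function(x, ...) {
  cat(sprintf(
    "<spatial_params> rho=%.4f mu=%.1f omega=%.1f tau=%.4f lambda=%.5f eta=%.2f\n",
    x$rho, x$mu, x$omega, x$tau, x$lambda, x$eta))
  invisible(x)
}

#' Position-dependent site initiation rate
#'
#' The probability that a site starts at a position whose TSS-proximal end
#' lies `p` bp upstream of the TSS, on the given strand:
#' `lambda * sigma(eta * (p - (mu - omega))) * sigma(eta * ((mu + omega) - p))`
#' times `tau` (forward) or `1 - tau` (reverse), where `sigma` is the
#' logistic function.  This traces an approximately flat plateau of height
#' `lambda` between `mu - omega` and `mu + omega` with logistic edges of
#' slope `eta`.
#'
#' @param params a [spatial_params()].
#' @param p distance(s) in bp upstream of the TSS, `>= 0` (vectorized).
#' @param strand `"fwd"` or `"rev"`.
#' @return numeric vector of probabilities.
#' @export
initiation_rate <- function(params, p, strand = c("fwd", "rev")) {
  strand <- match.arg(strand)
  stopifnot(all(p >= 0))
  g <- params$lambda *
    plogis(params$eta * (p - (params$mu - params$omega))) *
    plogis(params$eta * ((params$mu + params$omega) - p))
  g * if (strand == "fwd") params$tau else (1 - params$tau)
}

#' Construct a promoter signature model
#'
#' Combines a frequency matrix, a background model and spatial parameters
#' into a generative model over promoter sequences.  The `multisite` variant
#' emits one or more non-overlapping sites when the promoter carries the
#' signature; the `monosite` variant emits exactly one, at a position and
#' strand drawn from the normalized plateau distribution (the rate scale
#' `lambda` cancels there, leaving rho, tau, mu and omega as its effective
#' parameters).
#'
#' @param matrix a [freq_matrix()].
#' @param bg a [background_model()].
#' @param params a [spatial_params()].
#' @param variant `"multisite"` or `"monosite"`.
#' @param length promoter length contract in bp (default 1003).
#' @return an object of class `signature_model`.
#' @export
signature_model <- function(matrix, bg, params,
                            variant = c("multisite", "monosite"),
                            length = 1003L) {
  variant <- match.arg(variant)
  stopifnot(inherits(matrix, "freq_matrix"), inherits(bg, "bg_model"),
            inherits(params, "spatial_params"), length >= matrix$width)
  structure(list(matrix = matrix, bg = bg, params = params,
                 variant = variant, length = as.integer(length)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %s, motif '%s' (w=%d), length %d\n",
              x$variant, x$matrix$name, x$matrix$width, x$length))
  print(x$params)
  invisible(x)
}

# precompute per-sequence emission odds and background log-likelihood
seq_odds <- function(model, seq) {
  enc <- encode_seq(seq)
  o <- cpp_site_odds(enc$codes, enc$mask, model$matrix$probs,
                     unname(model$bg$emission))
  keep <- enc$codes > 0L
  o$bgll <- sum(log(unname(model$bg$emission)[enc$codes[keep]]))
  o$L <- length(enc$codes)
  o$allow <- o$ef >= 0
  o
}

odds_set <- function(model, seqs) {
  lapply(seqs, function(s) seq_odds(model, s))
}

par_vec <- function(model) {
  p <- model$params
  list(w = model$matrix$width, monosite = model$variant == "monosite",
       rho = p$rho, mu = p$mu, omega = p$omega, tau = p$tau,
       lambda = p$lambda, eta = p$eta)
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

# joint log P(N, C = 1) from the R=1 odds logB and the background loglik
joint_loglik <- function(rho, logB, bgll) {
  if (rho <= 0) return(bgll)
  if (rho >= 1) return(bgll + logB)
  bgll + logsumexp2(log(rho) + logB, log1p(-rho))
}

# normalized model density: log of rho * P(N | R=1, C=1) + (1-rho) * bg(N),
# with logA = log P(>=1 complete site | R=1)
cond_loglik <- function(rho, logB, logA, bgll) {
  if (rho <= 0 || !is.finite(logB)) {
    return(if (rho >= 1) -Inf else bgll + log1p(-rho))
  }
  if (rho >= 1) return(bgll + logB - logA)
  bgll + logsumexp2(log(rho) + logB - logA, log1p(-rho))
}

#' Log probability that the consistency constraint is satisfied
#'
#' `P(C = 1)` under the model for a given promoter length (and optional
#' initiation-allowance pattern): `rho * P(at least one complete site | R=1)
#' + (1 - rho)`.  Dividing the joint likelihood `P(N, C = 1)` by this
#' constant gives the model's proper (normalized) sequence distribution.
#'
#' @param model a [signature_model()].
#' @param length promoter length (defaults to the model's length contract).
#' @param allow optional logical vector marking positions where a site may
#'   start (defaults to all positions where a site fits).
#' @return log probability (scalar).
#' @export
log_pc1 <- function(model, length = model$length, allow = NULL) {
  pv <- par_vec(model)
  if (is.null(allow)) allow <- rep(TRUE, length)
  la <- cpp_log_accept(allow, pv$w, pv$monosite, pv$mu, pv$omega, pv$tau,
                       pv$lambda, pv$eta)
  if (pv$rho <= 0) return(0)
  if (pv$rho >= 1) return(la)
  logsumexp2(log(pv$rho) + la, log1p(-pv$rho))
}

#' Exact inference over the promoter lattice
#'
#' Runs the forward-backward message passing for one promoter, entirely in
#' log/odds space, and returns the marginal log-likelihood together with the
#' posterior regulation probability and per-position, per-strand posteriors
#' that a binding site starts there.
#'
#' @param model a [signature_model()].
#' @param seq promoter sequence (character scalar, 5'->3', TSS at the right
#'   end; lowercase = masked fill, N = unknown).
#' @return an object of class `lattice_posteriors`: `loglik` (natural-log
#'   joint `P(N, C = 1)`, the quantity EM maximizes), `log_pc1`,
#'   `loglik_cond` (log density of the model's normalized sequence
#'   distribution, the mixture `rho * P(N | R=1, C=1) + (1-rho) * bg(N)`
#'   that [sample_promoter()] draws from), `e_r`, `site_start` (2 x L
#'   matrix, rows fwd/rev), `expected_sites`, and `flag` (non-NULL when
#'   the likelihood is zero, e.g. a monosite model with `rho = 1` on a
#'   sequence shorter than the motif).
#' @export
forward_backward <- function(model, seq) {
  o <- seq_odds(model, seq)
  pv <- par_vec(model)
  post <- cpp_posterior_track(o$ef, o$er, pv$w, pv$monosite, pv$rho, pv$mu,
                              pv$omega, pv$tau, pv$lambda, pv$eta)
  ll <- joint_loglik(pv$rho, post$logB, o$bgll)
  lpc1 <- log_pc1(model, o$L, o$allow)
  logA <- cpp_log_accept(o$allow, pv$w, pv$monosite, pv$mu, pv$omega,
                         pv$tau, pv$lambda, pv$eta)
  e_r <- post$e_r
  flag <- NULL
  if (!is.finite(ll)) flag <- "zero likelihood: no valid state path"
  if (is.na(e_r)) {
    e_r <- if (pv$rho >= 1) NA_real_ else 0
  }
  track <- post$site_start
  rownames(track) <- c("fwd", "rev")
  out <- list(loglik = ll, log_pc1 = lpc1,
              loglik_cond = cond_loglik(pv$rho, post$logB, logA, o$bgll),
              e_r = e_r, site_start = track,
              expected_sites = post$fwd_mass + post$rev_mass,
              fwd_mass = post$fwd_mass, rev_mass = post$rev_mass,
              flag = flag)
  class(out) <- "lattice_posteriors"
  out
}

#' @export
print.lattice_posteriors <- function(x, ...) {
  cat(sprintf(
    "<lattice_posteriors> loglik=%.4f E[R]=%.4f expected sites=%.4f\n",
    x$loglik, x$e_r, x$expected_sites))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Posterior regulation probability E[R]
#'
#' Posterior probability that a promoter carries the signature, optionally
#' with the trained prior `rho` replaced (e.g. by 0.5 for ranking, where the
#' prior is a monotone transform and does not change the order).
#'
#' @inheritParams forward_backward
#' @param rho_override optional replacement for the trained `rho`.
#' @return numeric in `[0, 1]`.
#' @export
posterior_regulation <- function(model, seq, rho_override = NULL) {
  o <- seq_odds(model, seq)
  pv <- par_vec(model)
  rho <- if (is.null(rho_override)) pv$rho else rho_override
  stopifnot(rho >= 0, rho <= 1)
  logB <- cpp_batch_logB(list(o), pv$w, pv$monosite, pv$mu, pv$omega, pv$tau,
                         pv$lambda, pv$eta)[1]
  if (rho <= 0) return(0)
  if (rho >= 1) return(if (is.finite(logB)) 1 else NaN)
  if (!is.finite(logB)) return(0)
  1 / (1 + exp(log1p(-rho) - log(rho) - logB))
}

#' Sample promoters from the model
#'
#' Draws `R ~ Bernoulli(rho)` once per promoter and walks the lattice,
#' emitting background bases or complete matrix blocks at the
#' position-dependent initiation rate; the walk of an `R = 1` promoter is
#' rejection-resampled until it satisfies the consistency constraint
#' (at least one complete site).  Samples therefore follow the mixture
#' `rho * P(N | R=1, C=1) + (1-rho) * bg(N)` — the model's normalized
#' sequence distribution, whose log density `forward_backward()` reports
#' as `loglik_cond`.  Uses R's RNG, so call `set.seed()` for
#' reproducibility.
#'
#' @param model a [signature_model()].
#' @param n number of promoters.
#' @param length promoter length (defaults to the model length contract).
#' @param max_tries rejection budget per promoter.
#' @return list with `seqs` (named character vector) and `truth`
#'   (data.frame: id, regulated, n_sites) plus `sites` (data.frame: id,
#'   start 0-based, strand).
#' @export
sample_promoter <- function(model, n = 1, length = model$length,
                            max_tries = 10000L) {
  pv <- par_vec(model)
  seqs <- character(n)
  reg <- integer(n)
  nsite <- integer(n)
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cpp_sample(length, model$matrix$probs, unname(model$bg$emission),
                    pv$monosite, pv$rho, pv$mu, pv$omega, pv$tau, pv$lambda,
                    pv$eta, max_tries)
    if (!s$ok) {
      stop("sampler failed to satisfy the consistency constraint within ",
           max_tries, " attempts (is lambda = 0 with rho = 1?)")
    }
    seqs[i] <- decode_seq(s$seq)
    reg[i] <- s$r
    nsite[i] <- length(s$starts)
    sites[[i]] <- if (nsite[i]) {
      data.frame(start = s$starts, strand = ifelse(s$strands > 0, "+", "-"))
    } else {
      data.frame(start = integer(0), strand = character(0))
    }
  }
  ids <- sprintf("prom_%04d", seq_len(n))
  names(seqs) <- ids
  site_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (nrow(sites[[i]]) == 0) return(NULL)
    cbind(data.frame(id = ids[i]), sites[[i]])
  }))
  if (is.null(site_df)) {
    site_df <- data.frame(id = character(0), start = integer(0),
                          strand = character(0))
  }
  list(seqs = seqs,
       truth = data.frame(id = ids, regulated = reg, n_sites = nsite),
       sites = site_df)
}

#' Total joint log-likelihood of a promoter set
#'
#' @param model a [signature_model()].
#' @param seqs named character vector of promoters, or a precomputed odds
#'   list from internal use.
#' @return sum over promoters of `log P(N, C = 1)`.
#' @export
model_loglik <- function(model, seqs) {
  odds <- if (is.list(seqs) && !is.null(seqs[[1]]$ef)) seqs else
    odds_set(model, seqs)
  pv <- par_vec(model)
  logB <- cpp_batch_logB(odds, pv$w, pv$monosite, pv$mu, pv$omega, pv$tau,
                         pv$lambda, pv$eta)
  bgll <- vapply(odds, function(o) o$bgll, numeric(1))
  sum(vapply(seq_along(odds),
             function(i) joint_loglik(pv$rho, logB[i], bgll[i]), numeric(1)))
}

#' Brute-force likelihood by path enumeration (test oracle)
#'
#' Computes `log P(N, C = 1)` by explicitly enumerating every legal
#' placement of non-overlapping sites (equivalently, every legal state
#' path), independently of the forward-backward recursion.  Only feasible
#' for small instances; refuses sequences longer than 30 bp or motifs wider
#' than 5 bp.
#'
#' @inheritParams forward_backward
#' @param return_details also return the expected number of sites and E[R].
#' @return log-likelihood, or a list when `return_details = TRUE`.
#' @export
brute_force_likelihood <- function(model, seq, return_details = FALSE) {
  enc <- encode_seq(seq)
  L <- length(enc$codes)
  w <- model$matrix$width
  if (L > 30 || w > 5) {
    stop("instance too large for enumeration (need L <= 30, w <= 5)")
  }
  p <- model$params
  bgv <- unname(model$bg$emission)
  probs <- model$matrix$probs
  monosite <- model$variant == "monosite"
  # per-start candidate info
  ok <- logical(L)
  qf <- numeric(L)
  qr <- numeric(L)
  pf <- numeric(L) # forward site emission prob of block
  pr <- numeric(L)
  for (j in seq_len(L)) {
    if (j + w - 1 > L) next
    block <- enc$codes[j:(j + w - 1)]
    if (any(block == 0) || any(enc$mask[j:(j + w - 1)])) next
    ok[j] <- TRUE
    dist <- L - (j + w - 1) # 1-based: proximal end at j+w-1, p = L-(j+w-1)
    qf[j] <- initiation_rate(p, dist, "fwd")
    qr[j] <- initiation_rate(p, dist, "rev")
    pf[j] <- prod(probs[cbind(seq_len(w), block)])
    pr[j] <- prod(probs[cbind(w:1, 5 - block)])
  }
  bgp <- ifelse(enc$codes == 0, 1, bgv[pmax(enc$codes, 1)])
  total_r1 <- 0
  exp_sites_num <- 0
  if (monosite) {
    # exactly one site, placed by the normalized plateau distribution
    Q <- sum(qf[ok]) + sum(qr[ok])
    if (Q > 0) {
      for (j in which(ok)) {
        rest <- prod(bgp[-(j:(j + w - 1))])
        total_r1 <- total_r1 +
          (qf[j] / Q) * pf[j] * rest + (qr[j] / Q) * pr[j] * rest
      }
    }
    exp_sites_num <- total_r1
  } else {
    # enumerate placements: recursive over next free position
    recurse <- function(i, prob, nsites) {
      # i: next position to assign (1-based)
      if (i > L) {
        if (nsites >= 1) {
          total_r1 <<- total_r1 + prob
          exp_sites_num <<- exp_sites_num + prob * nsites
        }
        return(invisible())
      }
      qt <- if (ok[i]) qf[i] + qr[i] else 0
      # background at i
      recurse(i + 1, prob * (1 - qt) * bgp[i], nsites)
      # site starting at i
      if (ok[i]) {
        recurse(i + w, prob * qf[i] * pf[i], nsites + 1)
        recurse(i + w, prob * qr[i] * pr[i], nsites + 1)
      }
      invisible()
    }
    recurse(1, 1, 0)
  }
  bg_total <- prod(bgp)
  lik <- p$rho * total_r1 + (1 - p$rho) * bg_total
  ll <- if (lik > 0) log(lik) else -Inf
  if (!return_details) return(ll)
  e_r <- if (lik > 0) p$rho * total_r1 / lik else NA_real_
  exp_sites <- if (lik > 0) p$rho * exp_sites_num / lik else NA_real_
  list(loglik = ll, e_r = e_r, expected_sites = exp_sites,
       p_r1_and_accept = total_r1, p_bg = bg_total)
}
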
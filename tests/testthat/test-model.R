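test_that("initiation rate follows the logistic plateau", {
  p <- spatial_params(rho = 0.5, mu = 200, omega = 100, tau = 0.5,
                      lambda = 0.01, eta = 0.1)
  # on the plateau top, both logistic ramps are ~saturated
  expect_equal(initiation_rate(p, 200, "fwd"),
               0.01 * 0.5 * plogis(10) * plogis(10), tolerance = 1e-12)
  # far outside the plateau the rate vanishes
  expect_lt(initiation_rate(p, 600, "fwd"), 1e-10)
  # lambda = 0 shuts initiation off everywhere
  p0 <- spatial_params(0.5, 200, 100, 0.5, 0)
  expect_equal(initiation_rate(p0, 0:500, "fwd"), rep(0, 501))
  # tau = 1 removes the reverse strand
  p1 <- spatial_params(0.5, 200, 100, 1, 0.01)
  expect_equal(initiation_rate(p1, 0:500, "rev"), rep(0, 501))
  # lambda >= 1 would allow a total initiation probability of 1
  expect_error(spatial_params(0.5, 200, 100, 0.5, 1), "lambda")
})

test_that("forward-backward matches the path-enumeration oracle", {
  set.seed(101)
  bg <- background_model()
  for (i in 1:40) {
    w <- sample(2:5, 1)
    L <- sample((w + 2):20, 1)
    m <- rand_matrix(w)
    prm <- spatial_params(runif(1), runif(1, 0, L), runif(1, 1, L),
                          runif(1), runif(1, 0.001, 0.3))
    variant <- sample(c("multisite", "monosite"), 1)
    mod <- signature_model(m, bg, prm, variant, length = L)
    s <- rand_seq(L)
    fb <- forward_backward(mod, s)
    bf <- brute_force_likelihood(mod, s, return_details = TRUE)
    expect_equal(fb$loglik, bf$loglik, tolerance = 1e-9)
    expect_equal(fb$e_r, bf$e_r, tolerance = 1e-9)
    expect_equal(fb$expected_sites, bf$expected_sites, tolerance = 1e-9)
  }
  expect_error(
    brute_force_likelihood(fix_model(length = 50), rand_seq(50)),
    "too large")
})

test_that("degenerate priors give closed-form likelihoods", {
  bg <- background_model()
  m <- fix_matrix(w = 3)
  s <- rand_seq(15)
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  bg_ll <- sum(log(unname(bg$emission)[codes]))

  # rho = 0: pure background, no regulation, no sites
  mod0 <- signature_model(m, bg, spatial_params(0, 5, 3, .5, .05),
                          length = 15)
  fb0 <- forward_backward(mod0, s)
  expect_equal(fb0$loglik, bg_ll, tolerance = 1e-12)
  expect_equal(fb0$e_r, 0)
  expect_equal(fb0$expected_sites, 0)

  # rho = 1: regulation certain
  mod1 <- signature_model(m, bg, spatial_params(1, 5, 3, .5, .05),
                          length = 15)
  expect_equal(forward_backward(mod1, s)$e_r, 1)

  # monosite, rho = 1, sequence shorter than the motif: zero likelihood
  mshort <- signature_model(fix_matrix(w = 5), bg,
                            spatial_params(1, 2, 2, .5, .05),
                            variant = "monosite", length = 5)
  fbs <- forward_backward(mshort, "ACG")
  expect_identical(fbs$loglik, -Inf)
  expect_false(is.null(fbs$flag))

  # multisite, q -> 0: loglik approaches ln(1-rho) + background
  modq <- signature_model(m, bg, spatial_params(.3, 5, 3, .5, 1e-9),
                          length = 15)
  expect_equal(forward_backward(modq, s)$loglik, log(0.7) + bg_ll,
               tolerance = 1e-6)
})

test_that("the conditional model distribution normalizes over all sequences", {
  set.seed(11)
  bg <- background_model()
  for (case in list(list(w = 2, L = 6, variant = "multisite"),
                    list(w = 3, L = 7, variant = "monosite"))) {
    m <- rand_matrix(case$w)
    mod <- signature_model(m, bg,
                           spatial_params(0.4, case$L / 2, case$L / 3, 0.7,
                                          0.1),
                           case$variant, length = case$L)
    tot <- sum(vapply(enumerate_seqs(case$L), function(s) {
      exp(forward_backward(mod, s)$loglik_cond)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-6)
    # and the joint P(seq, C = 1) sums to P(C = 1)
    tot_joint <- sum(vapply(enumerate_seqs(case$L), function(s) {
      exp(forward_backward(mod, s)$loglik)
    }, numeric(1)))
    expect_equal(tot_joint, exp(log_pc1(mod, case$L)), tolerance = 1e-6)
  }
})

test_that("posterior regulation responds to evidence and overrides", {
  set.seed(3)
  mod <- tiny_model(rho = 0.5, mu = 4, omega = 4, lambda = 0.15,
                    length = 12)
  cons <- fix_consensus(mod$matrix)
  # a promoter with the consensus inside the plateau: E[R] > .5
  s_hit <- paste0(rand_seq(4), cons, rand_seq(5))
  expect_gt(posterior_regulation(mod, s_hit, rho_override = 0.5), 0.5)
  # pure background with a weak-lambda model: E[R] < .5
  mod_lo <- tiny_model(rho = 0.5, mu = 4, omega = 4, lambda = 0.001,
                       length = 12)
  anti <- chartr("ACGT", "TGAC", fix_consensus(mod_lo$matrix))
  s_miss <- paste0(anti, anti, anti, anti)
  expect_lt(posterior_regulation(mod_lo, s_miss, rho_override = 0.5), 0.5)
  # overrides pin the posterior at the extremes
  expect_equal(posterior_regulation(mod, s_hit, rho_override = 0), 0)
  expect_equal(posterior_regulation(mod, s_hit, rho_override = 1), 1)
  # cross-check the E[R] Bayes computation against the oracle
  bf <- brute_force_likelihood(mod, s_hit, return_details = TRUE)
  mod5 <- mod
  expect_equal(posterior_regulation(mod, s_hit), bf$e_r, tolerance = 1e-9)
})

test_that("expected site count is monotone in lambda under rho = 1", {
  set.seed(9)
  s <- rand_seq(40)
  prev <- -1
  for (lam in c(0.001, 0.01, 0.05, 0.2)) {
    mod <- signature_model(fix_matrix(w = 4), background_model(),
                           spatial_params(1, 20, 15, 0.5, lam),
                           length = 40)
    es <- forward_backward(mod, s)$expected_sites
    expect_gte(es, prev)
    prev <- es
  }
})

test_that("tau = 0.5 models are indifferent to in-place site strand flips", {
  set.seed(21)
  mod <- fix_model(rho = 1, mu = 20, omega = 15, tau = 0.5, lambda = 0.02,
                   length = 60, w = 6)
  cons <- fix_consensus(mod$matrix)
  # N flanks keep windows from straddling the planted site, so flipping the
  # site in place is an exact symmetry of a tau = 0.5 model
  flank <- paste(rep("N", 27), collapse = "")
  s1 <- paste0(flank, cons, flank)
  s2 <- paste0(flank, revcomp_test_helper(cons), flank)
  expect_equal(forward_backward(mod, s1)$loglik,
               forward_backward(mod, s2)$loglik, tolerance = 1e-9)
  # and an asymmetric model prefers its trained orientation
  mod9 <- fix_model(rho = 1, mu = 20, omega = 15, tau = 0.9, lambda = 0.02,
                    length = 60, w = 6)
  expect_gt(forward_backward(mod9, s1)$loglik,
            forward_backward(mod9, s2)$loglik)
})

test_that("masked fill and N bases emit background and exclude sites", {
  bg <- background_model()
  mod <- fix_model(rho = 1, mu = 10, omega = 20, lambda = 0.05,
                   length = 30, w = 4)
  cons <- fix_consensus(mod$matrix)
  # consensus planted inside a masked stretch cannot rescue the likelihood
  s_masked <- paste0(tolower(paste0(rand_seq(10), cons)), rand_seq(16))
  s_open <- toupper(s_masked)
  fb_m <- forward_backward(mod, s_masked)
  fb_o <- forward_backward(mod, s_open)
  expect_lt(fb_m$loglik, fb_o$loglik)
  expect_equal(sum(fb_m$site_start[, 1:14]), 0) # no site overlaps the mask
  # N scores as background: an all-N sequence has loglik = ln P(C=1-side)
  fb_n <- forward_backward(fix_model(rho = 0, length = 10, w = 3),
                           paste(rep("N", 10), collapse = ""))
  expect_equal(fb_n$loglik, 0) # all emissions marginalized out
})

test_that("sampling is consistent with the model it came from", {
  set.seed(33)
  bg <- background_model()
  # rho = 0: composition converges to the background frequencies
  mod0 <- fix_model(rho = 0, length = 200, w = 4)
  draws <- sample_promoter(mod0, n = 100, length = 200)
  ch <- table(strsplit(paste(draws$seqs, collapse = ""), "")[[1]])
  freq <- ch / sum(ch)
  # 20000 bases: 0.015 is ~4 binomial standard errors
  expect_lt(abs(unname(freq["G"] + freq["C"]) - 0.38), 0.015)
  expect_equal(sum(draws$truth$n_sites), 0)

  # monosite rho = 1: exactly one site per draw
  mod1 <- fix_model(rho = 1, mu = 50, omega = 30, lambda = 0.02,
                    variant = "monosite", length = 150)
  d1 <- sample_promoter(mod1, n = 40, length = 150)
  expect_true(all(d1$truth$n_sites == 1))

  # multisite: empirical site count matches the posterior expectation
  mod <- fix_model(rho = 1, mu = 60, omega = 40, tau = 0.7, lambda = 0.015,
                   length = 150)
  d <- sample_promoter(mod, n = 400, length = 150)
  emp <- mean(d$truth$n_sites)
  post <- mean(vapply(d$seqs, function(s) {
    forward_backward(mod, s)$expected_sites
  }, numeric(1)))
  se <- sd(d$truth$n_sites) / sqrt(400)
  expect_lt(abs(emp - post), 3 * se + 0.05)

  # impossible consistency: rho = 1 with lambda ~ 0 cannot emit a site
  bad <- fix_model(rho = 1, lambda = 1e-12, length = 100)
  expect_error(sample_promoter(bad, n = 1, max_tries = 50), "consistency")

  # determinism
  set.seed(99)
  a <- sample_promoter(mod, n = 3, length = 150)
  set.seed(99)
  b <- sample_promoter(mod, n = 3, length = 150)
  expect_identical(a, b)
})

test_that("model YAML serialization round-trips", {
  mod <- fix_model(rho = 0.37, mu = 123.4, omega = 56.7, tau = 0.81,
                   lambda = 0.0123)
  path <- tempfile(fileext = ".yaml")
  write_model(mod, path)
  back <- read_model(path)
  expect_equal(back$params, mod$params, tolerance = 1e-9)
  expect_equal(back$matrix$probs, mod$matrix$probs, tolerance = 1e-9)
  expect_identical(back$variant, mod$variant)
  expect_identical(back$length, mod$length)
  # posterior tracks export
  s <- sample_promoter(mod, 2, length = 100)
  posts <- lapply(s$seqs, function(q) forward_backward(mod, q))
  tp <- tempfile(fileext = ".tsv")
  write_posterior_track(posts, tp)
  df <- read.table(tp, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 2 * 2 * 100)
  expect_true(all(df$site_start_posterior >= 0 &
                    df$site_start_posterior <= 1))
})
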
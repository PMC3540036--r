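test_that("top-site ranking keys on the scan maximum with id tie-breaks", {
  set.seed(82)
  bg <- background_model()
  m <- fix_matrix(w = 6, p = 0.95)
  cons <- fix_consensus(m)
  hit <- rand_seq(60)
  substr(hit, 20, 25) <- cons
  proms <- c(zz_bg = rand_seq(60), aa_hit = hit, mm_bg2 = rand_seq(60))
  rk <- rank_by_top_site(m, bg, proms)
  expect_identical(rk$id[rk$rank == 1], "aa_hit")
  # ranks are a permutation and scores equal the brute-force track maximum
  expect_setequal(rk$rank, 1:3)
  for (i in seq_len(nrow(rk))) {
    expect_equal(rk$score[i], max(scan_scores(m, bg, proms[[rk$id[i]]])))
  }
  # identical promoters take adjacent, id-ordered ranks
  dup <- c(b_prom = proms[["aa_hit"]], a_prom = proms[["aa_hit"]])
  rk2 <- rank_by_top_site(m, bg, dup)
  expect_identical(rk2$id[order(rk2$rank)], c("a_prom", "b_prom"))
  # shorter than the motif: -Inf, ranked last
  rk3 <- rank_by_top_site(m, bg, c(x = "ACG", y = rand_seq(30)))
  expect_identical(rk3$id[rk3$rank == 2], "x")
  expect_identical(rk3$score[rk3$rank == 2], -Inf)
})

test_that("thermodynamic occupancies form a normalized competition", {
  set.seed(83)
  bg <- background_model()
  m <- fix_matrix(w = 6, p = 0.95)
  cons <- fix_consensus(m)
  # one promoter with a single possible site takes the whole protein
  expect_equal(rank_by_thermodynamic(m, bg, c(only = cons))$score, 1)
  # scores over the set sum to one
  proms <- rand_seq_set(20, 80)
  rk <- rank_by_thermodynamic(m, bg, proms)
  expect_equal(sum(rk$score), 1, tolerance = 1e-12)
  # two consensus sites attract ~twice the occupancy of one
  flank <- rand_seq(20)
  one <- paste0(flank, cons, rand_seq(26))
  two <- paste0(flank, cons, rand_seq(10), cons, rand_seq(10))
  rk2 <- rank_by_thermodynamic(m, bg, c(one = one, two = two))
  ratio <- rk2$score[rk2$id == "two"] / rk2$score[rk2$id == "one"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  expect_error(rank_by_thermodynamic(m, bg, character(0)), "empty")
})

test_that("signature ranking discriminates model promoters from background", {
  set.seed(84)
  mod <- fix_model(rho = 1, mu = 100, omega = 60, tau = 0.7,
                   lambda = 0.02, length = 300)
  hits <- 0
  for (trial in 1:5) {
    d <- sample_promoter(mod, n = 25, length = 300)
    names(d$seqs) <- sprintf("sig_%02d", 1:25)
    bgset <- rand_seq_set(25, 300)
    rk <- rank_by_signature(mod, c(d$seqs, bgset))
    top <- rk$id[rk$rank <= 25]
    hits <- hits + (mean(grepl("^sig", top)) >= 0.8)
  }
  expect_gte(hits, 4)

  # the prior override is a monotone transform: order is unchanged
  proms <- c(sample_promoter(mod, n = 10, length = 300)$seqs,
             rand_seq_set(10, 300, prefix = "bgq"))
  names(proms)[1:10] <- sprintf("sig_%02d", 1:10)
  orders <- lapply(c(0.1, 0.5, 0.9), function(r) {
    rk <- rank_by_signature(mod, proms, rho_override = r)
    rk$id[order(rk$rank)]
  })
  expect_identical(orders[[1]], orders[[2]])
  expect_identical(orders[[2]], orders[[3]])

  # identical promoters get identical scores
  same <- setNames(rep(proms[1], 3), c("a", "b", "c"))
  expect_equal(length(unique(rank_by_signature(mod, same)$score)), 1)
})

test_that("ChIP ranking keys on the smallest p-value across conditions", {
  tab <- data.frame(promoter = c("p1", "p2", "p3"),
                    c1 = c(0.2, 0.5, 0.9),
                    c2 = c(0.01, 0.6, 0.04))
  rk <- rank_by_chip(tab)
  expect_identical(rk$id[order(rk$rank)], c("p1", "p3", "p2"))
  expect_equal(rk$score[rk$id == "p1"], -0.01)
  # permutation of the condition columns changes nothing
  rk2 <- rank_by_chip(tab[, c("promoter", "c2", "c1")])
  expect_identical(rk2[order(rk2$id), ], rk[order(rk$id), ])
  # single condition: rank order is p-value order
  rk3 <- rank_by_chip(tab[, c("promoter", "c1")])
  expect_identical(rk3$id[order(rk3$rank)], c("p1", "p2", "p3"))
  # promoters absent from the table are excluded with a message
  expect_message(rank_by_chip(tab, promoters = c("p1", "p2", "p3", "p4")),
                 "absent")
})

test_that("top-K evaluation calibrates against the resampled null", {
  set.seed(85)
  ranked <- data.frame(id = sprintf("orf%03d", 1:200),
                       score = seq(200, 1), rank = 1:200,
                       method = "signature")
  # all-zero expression: mean 0, never significant
  expr0 <- data.frame(orf = ranked$id, change = 0)
  ev0 <- evaluate_topk(ranked, expr0, K = 50, resamples = 200, seed = 1)
  expect_equal(ev0$mean_change, 0)
  expect_false(ev0$significant)

  # top-K carrying a -2 shift against a standard normal null
  chg <- rnorm(200)
  chg[1:50] <- chg[1:50] - 2
  expr <- data.frame(orf = ranked$id, change = chg)
  ev <- evaluate_topk(ranked, expr, K = 50, resamples = 5000, seed = 2)
  expect_true(ev$significant)
  expect_lt(ev$mean_change, ev$ci[1])

  # the K sweep of cutoffs runs without error
  for (K in c(10, 25, 50, 100, 200)) {
    expect_s3_class(evaluate_topk(ranked, expr, K = K, resamples = 100,
                                  seed = 3), "eval_result")
  }
  # exclusion of a training set drops those ids from ranking and null
  ev_ex <- evaluate_topk(ranked, expr, K = 50, resamples = 100, seed = 4,
                         exclude = sprintf("orf%03d", 1:25))
  expect_false(any(sprintf("orf%03d", 1:25) %in% ev_ex$top_ids))
  # fewer joined ORFs than K: evaluated at reduced K with a warning
  expect_warning(
    evaluate_topk(ranked[1:10, ], expr, K = 50, resamples = 100, seed = 5),
    "K = 10")
})

test_that("bootstrap method comparison separates stronger rankers", {
  set.seed(86)
  n <- 150
  ids <- sprintf("orf%03d", 1:n)
  chg <- rnorm(n)
  chg[1:30] <- chg[1:30] - 2    # strong targets
  chg[31:60] <- chg[31:60] - 1  # weaker targets
  expr <- data.frame(orf = ids, change = chg)
  mk <- function(top_ids) {
    sc <- setNames(rep(0, n), ids)
    sc[top_ids] <- seq(length(top_ids), 1)
    data.frame(id = ids, score = unname(sc[ids]),
               rank = rank(-sc[ids], ties.method = "first"),
               method = "m")
  }
  A <- mk(ids[1:30])   # finds the strong targets
  B <- mk(ids[31:60])  # finds the weak ones
  cmpAB <- bootstrap_method_comparison(A, B, expr, K = 30, reps = 2000,
                                       seed = 7)
  expect_lt(cmpAB$p, 0.05)
  # identical rankings cannot be separated
  cmpAA <- bootstrap_method_comparison(A, A, expr, K = 30, reps = 500,
                                       seed = 8)
  expect_gte(cmpAA$p, 0.99)
  # deterministic given the seed, regardless of promoter input order
  perm <- sample(n)
  cmp2 <- bootstrap_method_comparison(A[perm, ], B[perm, ], expr,
                                      K = 30, reps = 2000, seed = 7)
  expect_equal(cmp2$p, cmpAB$p)
})

test_that("the binomial wins test sums the exact tail", {
  expect_equal(round(binomial_wins_test(12, 15), 4), 0.0176)
  expect_equal(binomial_wins_test(10, 10), 2^-10)
  expect_equal(binomial_wins_test(0, 7), 1)
  expect_error(binomial_wins_test(8, 7))
})

test_that("score-density profiles flag planted plateaus and stay in band on background", {
  set.seed(87)
  bg <- background_model()
  m <- fix_matrix(w = 6, p = 0.95)
  # pure background stays inside the simulated 95% band nearly everywhere
  proms <- rand_seq_set(30, 200)
  prof <- score_density_profile(m, bg, proms, sims = 80, seed = 88)
  inside <- with(prof, density >= bg_lo & density <= bg_hi)
  expect_gte(mean(inside, na.rm = TRUE), 0.9)

  # planted sites raise the density right at the plateau
  mod <- signature_model(m, bg, spatial_params(1, 100, 20, 0.5, 0.05),
                         length = 200)
  d <- sample_promoter(mod, n = 30, length = 200)
  prof2 <- score_density_profile(m, bg, d$seqs, sims = 40, seed = 89)
  peak <- prof2$window_start[which.max(prof2$density)]
  expect_gte(peak, 60)
  expect_lte(peak, 140)

  # an all-N sequence contributes nothing anywhere
  profN <- score_density_profile(m, bg,
                                 c(n1 = paste(rep("N", 100),
                                              collapse = "")),
                                 sims = 5, seed = 90)
  expect_true(all(profN$density == 0 | is.na(profN$density)))
})

test_that("ROC analysis behaves at the fixture extremes", {
  ranked <- data.frame(id = sprintf("p%02d", 1:20), score = seq(20, 1),
                       rank = 1:20, method = "m")
  labels <- setNames(c(rep(TRUE, 10), rep(FALSE, 10)), ranked$id)
  r <- roc_binding(ranked, labels)
  expect_equal(r$auc, 1)
  # inverting the labels mirrors the AUC
  r2 <- roc_binding(ranked, setNames(!labels, names(labels)))
  expect_equal(r2$auc, 0)
  # random scores sit near 1/2
  set.seed(91)
  aucs <- vapply(1:20, function(i) {
    rk <- data.frame(id = names(labels), score = rnorm(20),
                     rank = 1:20, method = "m")
    roc_binding(rk, labels)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
  expect_error(roc_binding(ranked, setNames(rep(TRUE, 20), ranked$id)),
               "single-class")
})
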
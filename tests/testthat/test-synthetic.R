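test_that("planted models are reproducible and respect the scaffold", {
  sc <- scaffold(8, list(`1` = "A"), alphabet = tiny_alphabet(6))
  p1 <- make_planted_model(sc, n_conserved = 2, n_pairs = 3, seed = 5)
  p2 <- make_planted_model(sc, n_conserved = 2, n_pairs = 3, seed = 5)
  expect_identical(p1$potts$h, p2$potts$h)
  expect_identical(p1$potts$J, p2$potts$J)
  expect_identical(p1$planted_pairs, p2$planted_pairs)
  # planted pairs and conserved positions avoid fixed scaffold positions
  expect_false(1 %in% c(p1$planted_pairs$i, p1$planted_pairs$j))
  expect_false(1 %in% p1$conserved$position)
  # coupling symmetry holds
  q <- 6
  with(p1$planted_pairs[1, ], {
    expect_equal(p1$potts$J[(i - 1) * q + a, (j - 1) * q + b],
                 p1$potts$J[(j - 1) * q + b, (i - 1) * q + a])
  })
})

test_that("zero scales produce a near-zero model; planted entries dominate the background", {
  sc <- free_scaffold(L = 6, q = 5)
  p0 <- make_planted_model(sc, n_conserved = 0, n_pairs = 0, field_scale = 0,
                           coupling_scale = 0, background_h_sd = 0,
                           background_j_sd = 0, seed = 1)
  expect_equal(max(abs(p0$potts$h)), 0)
  expect_equal(max(abs(p0$potts$J)), 0)
  p <- make_planted_model(sc, n_conserved = 1, n_pairs = 2, field_scale = 2,
                          coupling_scale = 1, background_j_sd = 0.1, seed = 2)
  q <- 5
  planted_vals <- with(p$planted_pairs,
                       p$potts$J[cbind((i - 1) * q + a, (j - 1) * q + b)])
  bg <- abs(p$potts$J[p$potts$J != 0])
  expect_true(all(abs(planted_vals) > quantile(bg, 0.99)))
})

test_that("exact enumeration reproduces closed-form distributions", {
  sc <- free_scaffold(L = 4, q = 4)
  tab <- enumerate_distribution(zero_potts(sc))
  expect_equal(nrow(tab), 256L)
  expect_equal(tab$prob, rep(1 / 256, 256))
  expect_equal(sum(tab$prob), 1, tolerance = 1e-9)
  # single field h_1(A) = ln 3 on a two-letter alphabet: P(A at 1) = 3/4
  sc2 <- free_scaffold(L = 3, q = 2)
  m <- zero_potts(sc2)
  m$h["A", 1] <- log(3)
  tab2 <- enumerate_distribution(m)
  pA <- sum(tab2$prob[substr(tab2$sequence, 1, 1) == "A"])
  expect_equal(pA, 3 / 4, tolerance = 1e-12)
  # oversized state spaces are refused with the size in the message
  sc_big <- scaffold(12, list(), alphabet = aa_alphabet())
  expect_error(enumerate_distribution(zero_potts(sc_big)), "too large")
})

test_that("enumeration respects fixed scaffold positions", {
  sc <- scaffold(4, list(`2` = "C"), alphabet = tiny_alphabet(4))
  tab <- enumerate_distribution(zero_potts(sc))
  expect_equal(nrow(tab), 64L)
  expect_true(all(substr(tab$sequence, 2, 2) == "C"))
})

test_that("family sampling is seeded and consistent across methods", {
  sc <- free_scaffold(L = 4, q = 4)
  m <- random_potts(sc, h_sd = 0.8, j_sd = 0.2, seed = 71)
  f1 <- sample_family(m, 200, seed = 3, method = "exact_enumeration")
  f2 <- sample_family(m, 200, seed = 3, method = "exact_enumeration")
  expect_identical(f1$sequences, f2$sequences)
  expect_equal(nrow(sample_family(m, 1, seed = 1)$matrix), 1L)
  # exact and long-MC column frequencies agree within 3 sigma
  n <- 3000
  fe <- sample_family(m, n, seed = 5, method = "exact_enumeration")
  fm_e <- frequency_matrix(fe)
  fl <- sample_family(m, n, seed = 6, method = "long_mc")
  fm_l <- frequency_matrix(fl)
  for (i in 1:4) for (a in 1:4) {
    p <- fm_e[i, a]
    se <- sqrt(p * (1 - p) / n * 2)  # both sides are sampled
    expect_lt(abs(fm_l[i, a] - p), 3 * se + 0.015)
  }
})

test_that("a strongly conserved planted position dominates its column", {
  sc <- free_scaffold(L = 6, q = 5)
  p <- make_planted_model(sc, n_conserved = 2, n_pairs = 0, field_scale = 4,
                          seed = 11)
  fam <- sample_family(p, 2000, seed = 12, method = "exact_enumeration")
  fm <- frequency_matrix(fam)
  for (k in seq_len(nrow(p$conserved))) {
    col <- fm[p$conserved$position[k], ]
    expect_equal(names(which.max(col)), p$conserved$residue[k])
  }
})

test_that("the landscape hits the published scale: ~100 nM median, >= 250-fold range", {
  sc <- free_scaffold(L = 8, q = 6)
  ls <- make_landscape(sc, seed = 9)
  set.seed(10)
  seqs <- replicate(10000, random_conformant(sc))
  y <- true_log10_ki(ls, seqs)
  ki <- 10^y  # nM
  expect_gt(quantile(ki, 0.975) / quantile(ki, 0.025), 250)
  expect_gt(median(ki), 20)
  expect_lt(median(ki), 500)
  # zero effects: constant landscape at the intercept
  ls0 <- make_landscape(sc, effect_sd = 0, noise_sd = 0, seed = 9)
  expect_equal(diff(range(true_log10_ki(ls0, seqs[1:50]))), 0)
  # determinism
  ls2 <- make_landscape(sc, seed = 9)
  expect_identical(ls$additive, ls2$additive)
  expect_identical(ls$intercept, ls2$intercept)
})

test_that("observation noise matches the configured log10 sd", {
  sc <- free_scaffold(L = 6, q = 4)
  ls <- make_landscape(sc, noise_sd = 0.15, seed = 13)
  s <- random_conformant(sc)
  obs <- observe_ki(ls, rep(s, 10000), ids = sprintf("o%d", 1:10000), seed = 14)
  expect_true(all(obs$ki > 0))
  sd_hat <- sd(log10(obs$ki))
  expect_lt(abs(sd_hat - 0.15) / 0.15, 0.1)
  # zero noise reproduces the landscape exactly
  ls0 <- make_landscape(sc, noise_sd = 0, seed = 13)
  obs0 <- observe_ki(ls0, s, seed = 15)
  expect_equal(log10(obs0$ki * 1e9), true_log10_ki(ls0, s), tolerance = 1e-12)
})

test_that("sampler KL to the exact table decreases with more samples", {
  sc <- free_scaffold(L = 4, q = 4)
  m <- random_potts(sc, h_sd = 1, j_sd = 0.3, seed = 42)
  ex <- enumerate_distribution(m)
  kl_at <- function(n_rec) {
    cfg <- sampler_config(n_chains = 2, steps = 1000 + n_rec * 5 / 2,
                          burn_in = 1000, thinning = 5, seed = 3,
                          init = "random_scaffold_conformant")
    pool <- sample_sequences(m, sc, cfg)
    emp <- setNames(pool$samples$count / sum(pool$samples$count),
                    pool$samples$sequence)
    e <- emp[ex$sequence]
    e[is.na(e)] <- 0
    # smoothed KL(P || empirical)
    sum(ex$prob * log(ex$prob / pmax(e, 1e-12)))
  }
  expect_lt(kl_at(1e5), kl_at(1e3))
})

test_that("the family benchmark produces 50 unique records on its scaffold", {
  bm <- synthetic_family_benchmark()
  expect_equal(nrow(bm$records), 50L)
  expect_equal(length(unique(bm$records$sequence)), 50L)
  expect_true(all(vapply(bm$records$sequence, is_conformant, logical(1),
                         scaffold = bm$scaffold)))
  expect_true(all(bm$records$ki > 0))
})
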
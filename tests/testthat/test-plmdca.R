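test_that("sequence weights implement similarity down-weighting", {
  sc <- uk18_scaffold()
  distinct <- c("ACSRYEVDCRGRGSACG", "ACDEFGHDCIKLMNPCG", "ACPQRSTDCVWYADECG")
  aln <- msa(c("a", "b", "c"), distinct, sc)
  w <- sequence_weights(aln, 0.8)
  expect_equal(as.vector(w), c(1, 1, 1))
  expect_equal(attr(w, "Meff"), 3)
  # one near-duplicate pair (identity 16/17 >= 0.8) gets half weight each
  aln2 <- msa(c("a", "a2", "b"),
              c("ACSRYEVDCRGRGSACG", "ACSRYEVDCRGRGSPCG", "ACDEFGHDCIKLMNPCG"),
              sc)
  w2 <- sequence_weights(aln2, 0.8)
  expect_equal(as.vector(w2), c(0.5, 0.5, 1))
  # threshold 1.0: only exact self-matches
  expect_equal(as.vector(sequence_weights(aln2, 1.0)), c(1, 1, 1))
  expect_error(sequence_weights(aln2, 0), "\\(0, 1\\]")
})

test_that("the zero model scores L*ln(q) nats per sequence", {
  sc <- free_scaffold(L = 5, q = 6)
  aln <- random_msa(sc, 8, seed = 2)
  z <- zero_potts(sc)
  expect_equal(neg_pseudo_loglik(z, aln, lambda_h = 0, lambda_J = 0),
               5 * log(6), tolerance = 1e-12)
})

test_that("per-position constant shifts of h leave the unregularized objective unchanged", {
  sc <- free_scaffold(L = 5, q = 6)
  aln <- random_msa(sc, 8, seed = 2)
  m <- random_potts(sc, seed = 5)
  f0 <- neg_pseudo_loglik(m, aln, lambda_h = 0, lambda_J = 0)
  m2 <- m
  m2$h[, 3] <- m2$h[, 3] + 1.7
  f1 <- neg_pseudo_loglik(m2, aln, lambda_h = 0, lambda_J = 0)
  expect_equal(f0, f1, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  sc <- free_scaffold(L = 5, q = 6)
  aln <- random_msa(sc, 8, seed = 7)
  idx <- pepdca:::plm_index(5, 6)
  set.seed(8)
  theta <- rnorm(5 * 6 + length(idx$upper), sd = 0.4)
  m <- pepdca:::unpack_potts(theta, sc, idx)
  g <- plm_gradient(m, aln, lambda_h = 0.02, lambda_J = 0.03)
  gt <- c(as.vector(g$h), g$J[idx$upper])
  obj <- function(th) {
    neg_pseudo_loglik(pepdca:::unpack_potts(th, sc, idx), aln,
                      lambda_h = 0.02, lambda_J = 0.03)
  }
  eps <- 1e-5
  fd <- vapply(seq_along(theta), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + eps; tm[k] <- tm[k] - eps
    (obj(tp) - obj(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - gt) / pmax(1, abs(fd))), 1e-5)
})

test_that("h-gradient vanishes at the zero model on column-balanced data", {
  # every residue equally frequent per column: cyclic Latin square
  sc <- free_scaffold(L = 4, q = 4)
  rows <- vapply(0:3, function(s) {
    paste(sc$alphabet$symbols[(s + 0:3) %% 4 + 1], collapse = "")
  }, character(1))
  aln <- msa(sprintf("r%d", 1:4), rows, sc)
  g <- plm_gradient(zero_potts(sc), aln, lambda_h = 0, lambda_J = 0)
  expect_lt(max(abs(g$h)), 1e-12)
})

test_that("the regularizer gradient alone is 2*lambda*parameters", {
  sc <- free_scaffold(L = 4, q = 4)
  rows <- vapply(0:3, function(s) {
    paste(sc$alphabet$symbols[(s + 0:3) %% 4 + 1], collapse = "")
  }, character(1))
  aln <- msa(sprintf("r%d", 1:4), rows, sc)
  m <- random_potts(sc, seed = 9)
  g1 <- plm_gradient(m, aln, lambda_h = 0, lambda_J = 0)
  g2 <- plm_gradient(m, aln, lambda_h = 0.05, lambda_J = 0.07)
  expect_equal(g2$h - g1$h, 2 * 0.05 * m$h, tolerance = 1e-12)
  expect_equal(g2$J - g1$J, 2 * 0.07 * m$J, tolerance = 1e-12)
})

test_that("fitting is deterministic and improves on the zero model", {
  sc <- free_scaffold(L = 5, q = 4)
  aln <- random_msa(sc, 10, seed = 12)
  m1 <- suppressMessages(fit_plmdca(aln, max_iter = 200))
  m2 <- suppressMessages(fit_plmdca(aln, max_iter = 200))
  expect_identical(m1$h, m2$h)
  expect_identical(m1$J, m2$J)
  f_fit <- neg_pseudo_loglik(m1, aln)
  f_zero <- neg_pseudo_loglik(zero_potts(sc), aln)
  expect_lt(f_fit, f_zero)
  # the recorded best-so-far trace is non-increasing
  expect_true(all(diff(cummin(m1$meta$trace)) <= 0))
  expect_true(m1$meta$converged)
})

test_that("scoring is additive in fields and rejects invalid sequences", {
  sc <- free_scaffold(L = 4, q = 4)
  z <- zero_potts(sc)
  expect_equal(score_sequence(z, "ACDA")$score, 0)
  m <- zero_potts(sc)
  m$h["D", 3] <- 1
  s1 <- score_sequence(m, "ACDA")$score
  s2 <- score_sequence(m, "ACCA")$score
  expect_equal(s1 - s2, 1)
  expect_equal(score_sequence(m, "ACDA")$energy, -s1)
  expect_error(score_sequence(m, "ACD"), "length")
  expect_error(score_sequence(m, "ACDW"), "invalid symbol")
})

test_that("zero-sum gauge preserves score differences and is idempotent", {
  sc <- free_scaffold(L = 5, q = 5)
  m <- random_potts(sc, seed = 21)
  zs <- to_zero_sum_gauge(m)
  expect_equal(zs$gauge, "zero_sum")
  # every block has zero row and column sums
  q <- 5
  for (i in 1:4) for (j in (i + 1):5) {
    B <- zs$J[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)]
    expect_lt(max(abs(rowSums(B))), 1e-9)
    expect_lt(max(abs(colSums(B))), 1e-9)
  }
  # idempotent
  zs2 <- to_zero_sum_gauge(zs)
  expect_equal(zs2$J, zs$J, tolerance = 1e-12)
  expect_equal(zs2$h, zs$h, tolerance = 1e-12)
  # score differences preserved over 100 random sequence pairs
  set.seed(22)
  a <- replicate(100, random_conformant(sc))
  b <- replicate(100, random_conformant(sc))
  d_raw <- score_sequences(m, a)$score - score_sequences(m, b)$score
  d_zs <- score_sequences(zs, a)$score - score_sequences(zs, b)$score
  expect_equal(d_raw, d_zs, tolerance = 1e-9)
})

test_that("a constant coupling block vanishes under the zero-sum gauge", {
  sc <- free_scaffold(L = 3, q = 4)
  m <- zero_potts(sc)
  q <- 4
  m$J[1:q, (q + 1):(2 * q)] <- 0.7
  m$J[(q + 1):(2 * q), 1:q] <- 0.7
  zs <- to_zero_sum_gauge(m)
  expect_lt(max(abs(zs$J)), 1e-12)
})

test_that("top_coupled_pairs ranks, tie-breaks, and truncates", {
  sc <- free_scaffold(L = 4, q = 4)
  z <- zero_potts(sc)
  tc <- top_coupled_pairs(z)
  expect_equal(nrow(tc), 6L)
  expect_true(all(tc$frobenius == 0))
  expect_equal(tc$i, c(1, 1, 1, 2, 2, 3))  # lexicographic under ties
  expect_equal(nrow(top_coupled_pairs(z, k = 1)), 1L)
  expect_equal(nrow(top_coupled_pairs(z, k = 99)), 6L)
  m <- random_potts(sc, seed = 30)
  tc2 <- top_coupled_pairs(m, k = 3)
  expect_true(all(diff(tc2$score) <= 0))
  rp <- tc2$residue_pairs[[1]]
  expect_true(all(diff(abs(rp$value)) <= 1e-12))
})

test_that("coupling norms on independent columns shrink as n grows", {
  sc <- free_scaffold(L = 6, q = 4)
  pl <- make_planted_model(sc, n_conserved = 0, n_pairs = 0, field_scale = 0,
                           coupling_scale = 0, background_h_sd = 0.5,
                           background_j_sd = 0, seed = 77)
  fam_small <- sample_family(pl, 200, seed = 78, method = "exact_enumeration")
  fam_big <- sample_family(pl, 2000, seed = 79, method = "exact_enumeration")
  f_small <- suppressMessages(fit_plmdca(fam_small))
  f_big <- suppressMessages(fit_plmdca(fam_big))
  n_small <- median(top_coupled_pairs(f_small, apc = FALSE)$frobenius)
  n_big <- median(top_coupled_pairs(f_big, apc = FALSE)$frobenius)
  expect_lt(n_big, n_small)
})

test_that("planted couplings are recovered in the top APC ranks", {
  bm <- standard_benchmark()
  fit <- suppressMessages(fit_plmdca(bm$msa))
  tc <- top_coupled_pairs(fit)
  planted <- paste(bm$planted$planted_pairs$i, bm$planted$planted_pairs$j)
  ranks <- match(planted, paste(tc$i, tc$j))
  expect_lte(mean(ranks), 5)
})

test_that("model serialization round-trips through JSON", {
  sc <- free_scaffold(L = 4, q = 4)
  m <- random_potts(sc, seed = 31)
  m$meta <- list(lambda_h = 0.01, lambda_J = 0.02, Meff = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_potts(m, path)
  back <- load_potts(path)
  expect_equal(back$h, m$h, ignore_attr = TRUE)
  expect_equal(back$J, m$J)
  expect_equal(back$meta$Meff, 10)
  s <- replicate(5, random_conformant(sc))
  expect_equal(score_sequences(back, s)$score, score_sequences(m, s)$score)
})
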
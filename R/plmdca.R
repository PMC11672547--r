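#' Potts model container
#'
#' A pairwise Markov random field over fixed-length sequences:
#' `S(s) = sum_i h_i(s_i) + sum_{i<j} J_ij(s_i, s_j)` with `P(s) ∝ exp(S(s))`.
#' Fields `h` are stored as a `q x L` matrix (residue by position); couplings
#' `J` as the `(L*q) x (L*q)` block matrix holding every `q x q` pair block
#' symmetrically (`J_ij(a,b) == J_ji(b,a)`) with zero diagonal blocks.
#'
#' @param h `q x L` numeric matrix.
#' @param J `(L*q) x (L*q)` numeric matrix, block-symmetric, zero diagonal
#'   blocks.
#' @param scaffold A [scaffold()].
#' @param gauge `"raw"` or `"zero_sum"`.
#' @param meta List of fit provenance (regularization, optimizer trace, ...).
#' @return A `potts_model`.
#' @export
potts_model <- function(h, J, scaffold, gauge = "raw", meta = list()) {
  q <- scaffold$alphabet$q; L <- scaffold$L
  stopifnot(nrow(h) == q, ncol(h) == L, nrow(J) == L * q, ncol(J) == L * q)
  if (!all(is.finite(h)) || !all(is.finite(J))) abort("non-finite parameters")
  rownames(h) <- scaffold$alphabet$symbols
  structure(list(h = h, J = J, scaffold = scaffold, gauge = gauge, meta = meta),
            class = "potts_model")
}

#' @rdname potts_model
#' @export
zero_potts <- function(scaffold) {
  q <- scaffold$alphabet$q; L <- scaffold$L
  potts_model(matrix(0, q, L), matrix(0, L * q, L * q), scaffold)
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts_model> L = %d, q = %d, gauge = %s%s\n",
              x$scaffold$L, x$scaffold$alphabet$q, x$gauge,
              if (isTRUE(x$meta$converged)) ", converged" else ""))
  invisible(x)
}

# linear indices of the i<j coupling blocks in the big matrix and of their
# transposed images, used to pack/unpack the optimizer's parameter vector
plm_index <- function(L, q) {
  N <- L * q
  up <- vector("list", L * (L - 1) / 2)
  lo <- vector("list", L * (L - 1) / 2)
  k <- 0L
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      k <- k + 1L
      rows <- ((i - 1L) * q + 1L):((i - 1L) * q + q)
      cols <- ((j - 1L) * q + 1L):((j - 1L) * q + q)
      r <- rep(rows, times = q)
      c <- rep(cols, each = q)
      up[[k]] <- (c - 1L) * N + r
      lo[[k]] <- (r - 1L) * N + c
    }
  }
  list(upper = unlist(up), lower = unlist(lo), N = N)
}

pack_potts <- function(model, idx) {
  c(as.vector(model$h), model$J[idx$upper])
}

unpack_potts <- function(theta, scaffold, idx) {
  q <- scaffold$alphabet$q; L <- scaffold$L
  h <- matrix(theta[seq_len(q * L)], q, L)
  J <- matrix(0, idx$N, idx$N)
  tj <- theta[-seq_len(q * L)]
  J[idx$upper] <- tj
  J[idx$lower] <- tj
  potts_model(h, J, scaffold)
}

msa_zero_based <- function(msa) msa$matrix - 1L

#' Similarity-based sequence weights
#'
#' Standard DCA reweighting: `w_m = 1 / |{m' : identity(m, m') >= threshold}|`
#' (self included). The effective alignment size is `Meff = sum(w)`.
#'
#' @param msa An [msa()].
#' @param identity_threshold Real in `(0, 1]`.
#' @return Numeric weights, one per sequence, with `Meff` as an attribute.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.8) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  m <- msa$matrix
  n <- nrow(m); L <- ncol(m)
  counts <- integer(n)
  for (i in seq_len(n)) {
    ident <- rowMeans(m == matrix(m[i, ], n, L, byrow = TRUE))
    counts[i] <- sum(ident >= identity_threshold)
  }
  w <- 1 / counts
  attr(w, "Meff") <- sum(w)
  w
}

#' Regularized negative pseudolikelihood of a Potts model
#'
#' `(1/Meff) sum_m w_m sum_r -log P(s_mr | s_m,-r) + lambda_h ||h||^2 +
#' lambda_J sum_{i<j} ||J_ij||^2`, with the site conditionals computed by a
#' max-shifted softmax.
#'
#' @param model A [potts_model()].
#' @param msa An [msa()] on the same scaffold.
#' @param weights Optional per-sequence weights (default all 1).
#' @param lambda_h,lambda_J Nonnegative L2 strengths (per parameter, on the
#'   Meff-normalized objective).
#' @return Scalar objective value (nats).
#' @export
neg_pseudo_loglik <- function(model, msa, weights = NULL,
                              lambda_h = 0.01, lambda_J = 0.01) {
  check_model_msa(model, msa)
  w <- weights %||% rep(1, nrow(msa$matrix))
  res <- cpp_plm_obj_grad(msa_zero_based(msa), model$h, model$J, w, FALSE)
  res$f + lambda_h * sum(model$h^2) + lambda_J * sum(model$J^2) / 2
}

#' Analytic gradient of the regularized negative pseudolikelihood
#'
#' @inheritParams neg_pseudo_loglik
#' @return List with `h` (`q x L`) and `J` (`Lq x Lq`, parameter gradient for
#'   each unordered pair stored symmetrically in both blocks).
#' @export
plm_gradient <- function(model, msa, weights = NULL,
                         lambda_h = 0.01, lambda_J = 0.01) {
  check_model_msa(model, msa)
  w <- weights %||% rep(1, nrow(msa$matrix))
  res <- cpp_plm_obj_grad(msa_zero_based(msa), model$h, model$J, w, TRUE)
  gJ <- res$grad_J + t(res$grad_J) + 2 * lambda_J * model$J
  list(h = res$grad_h + 2 * lambda_h * model$h, J = gJ)
}

check_model_msa <- function(model, msa) {
  if (model$scaffold$L != msa$scaffold$L ||
      model$scaffold$alphabet$q != msa$scaffold$alphabet$q) {
    abort("model and alignment dimensions do not match")
  }
}

#' Fit a Potts model by regularized pseudolikelihood maximization (plmDCA)
#'
#' Minimizes [neg_pseudo_loglik()] by L-BFGS-B from the zero model with the
#' analytic gradient. The symmetric (joint) pseudolikelihood with a single
#' shared coupling tensor is fitted. Deterministic given data and
#' configuration. Scaffold-fixed columns are retained as ordinary columns
#' (their fields absorb the perfect conservation); they are constrained only
#' at sampling time.
#'
#' @param msa An [msa()] with at least two sequences.
#' @param lambda_h,lambda_J L2 regularization strengths (default 0.01 each —
#'   conventional plmDCA magnitudes, essential in the small-n regime).
#' @param reweight Apply similarity reweighting ([sequence_weights()])?
#'   Default off: the curated families are small and intentionally similar.
#' @param reweight_threshold Identity threshold when `reweight = TRUE`.
#' @param max_iter Optimizer iteration cap.
#' @param tol Convergence tolerance on the projected gradient max-norm.
#' @return A fitted `potts_model` with fit provenance in `$meta`
#'   (`lambda_h`, `lambda_J`, `Meff`, `iterations`, `converged`, `objective`,
#'   `trace` of objective evaluations).
#' @export
fit_plmdca <- function(msa, lambda_h = 0.01, lambda_J = 0.01,
                       reweight = FALSE, reweight_threshold = 0.8,
                       max_iter = 500, tol = 1e-5) {
  if (nrow(msa$matrix) < 2L) abort("need at least two sequences to fit")
  sc <- msa$scaffold
  q <- sc$alphabet$q; L <- sc$L
  w <- if (reweight) sequence_weights(msa, reweight_threshold) else
    rep(1, nrow(msa$matrix))
  meff <- sum(w)
  inform(sprintf("fitting plmDCA: n = %d, Meff = %.2f (reweighting %s)",
                 nrow(msa$matrix), meff, if (reweight) "on" else "off"))
  idx <- plm_index(L, q)
  m0 <- msa_zero_based(msa)
  nh <- q * L
  trace_env <- new.env()
  trace_env$vals <- numeric(0)

  fn <- function(theta) {
    h <- matrix(theta[seq_len(nh)], q, L)
    J <- matrix(0, idx$N, idx$N)
    tj <- theta[-seq_len(nh)]
    J[idx$upper] <- tj
    J[idx$lower] <- tj
    res <- cpp_plm_obj_grad(m0, h, J, w, FALSE)
    val <- res$f + lambda_h * sum(h^2) + lambda_J * sum(tj^2)
    trace_env$vals <- c(trace_env$vals, val)
    val
  }
  gr <- function(theta) {
    h <- matrix(theta[seq_len(nh)], q, L)
    J <- matrix(0, idx$N, idx$N)
    tj <- theta[-seq_len(nh)]
    J[idx$upper] <- tj
    J[idx$lower] <- tj
    res <- cpp_plm_obj_grad(m0, h, J, w, TRUE)
    gJt <- res$grad_J[idx$upper] + res$grad_J[idx$lower] + 2 * lambda_J * tj
    c(as.vector(res$grad_h + 2 * lambda_h * h), gJt)
  }

  theta0 <- numeric(nh + length(idx$upper))
  opt <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = tol, factr = 0))
  converged <- opt$convergence == 0L
  if (!converged) {
    warn(sprintf("plmDCA did not converge within %d iterations (code %d); returning best-so-far model",
                 max_iter, opt$convergence))
  }
  model <- unpack_potts(opt$par, sc, idx)
  model$meta <- list(lambda_h = lambda_h, lambda_J = lambda_J,
                     reweight = reweight,
                     reweight_threshold = if (reweight) reweight_threshold else NA,
                     Meff = meff, iterations = opt$counts[["function"]],
                     converged = converged, objective = opt$value,
                     trace = trace_env$vals)
  model
}

#' Potts score and energy of sequences
#'
#' `S(s) = sum_i h_i(s_i) + sum_{i<j} J_ij(s_i, s_j)`, `E = -S`. Score
#' differences are gauge-invariant.
#'
#' @param model A [potts_model()].
#' @param sequences Character vector of scaffold-conformant sequences.
#' @return Tibble `sequence`, `score`, `energy`.
#' @export
score_sequences <- function(model, sequences) {
  m <- t(vapply(sequences, assert_conformant, integer(model$scaffold$L),
                scaffold = model$scaffold)) - 1L
  s <- as.vector(cpp_score_sequences(m, model$h, model$J))
  tibble(sequence = sequences, score = s, energy = -s)
}

#' @rdname score_sequences
#' @param sequence A single sequence.
#' @export
score_sequence <- function(model, sequence) {
  score_sequences(model, sequence)
}

#' Transform a Potts model to the zero-sum (Ising) gauge
#'
#' Every coupling block is centered so its rows and columns sum to zero; the
#' removed row/column means are absorbed into the fields. Sequence
#' probabilities are unchanged (scores shift by a constant), and the centered
#' coupling norms become comparable across position pairs. Idempotent.
#'
#' @param model A [potts_model()].
#' @return An equivalent `potts_model` with `gauge = "zero_sum"`.
#' @export
to_zero_sum_gauge <- function(model) {
  q <- model$scaffold$alphabet$q; L <- model$scaffold$L
  h <- model$h
  J <- model$J
  for (i in seq_len(L - 1)) {
    ri <- ((i - 1) * q + 1):((i - 1) * q + q)
    for (j in seq(i + 1, L)) {
      rj <- ((j - 1) * q + 1):((j - 1) * q + q)
      B <- J[ri, rj]
      rm <- rowMeans(B); cm <- colMeans(B); g <- mean(B)
      Bp <- B - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + g
      J[ri, rj] <- Bp
      J[rj, ri] <- t(Bp)
      h[, i] <- h[, i] + rm - g
      h[, j] <- h[, j] + cm - g
    }
  }
  potts_model(h, J, model$scaffold, gauge = "zero_sum", meta = model$meta)
}

#' Rank covarying position pairs by coupling strength
#'
#' Pairs are ranked by the Frobenius norm of the zero-sum-gauge coupling
#' block, optionally with the average-product correction
#' `APC_ij = F_ij - F_i. * F_.j / F_..` that removes background signal from
#' uneven per-position coupling mass. Raw models are gauge-fixed first. Ties
#' (e.g. the zero model) fall back to `(i, j)` lexicographic order.
#'
#' @param model A [potts_model()].
#' @param k Number of top pairs to return (all pairs if larger).
#' @param apc Rank by the APC-corrected norm?
#' @return Tibble `i`, `j`, `frobenius`, `apc`, `score` (the ranking key) and
#'   a `residue_pairs` list-column of tibbles `a`, `b`, `value` sorted by
#'   decreasing `|value|`.
#' @export
top_coupled_pairs <- function(model, k = Inf, apc = TRUE) {
  if (model$gauge != "zero_sum") model <- to_zero_sum_gauge(model)
  q <- model$scaffold$alphabet$q; L <- model$scaffold$L
  symbols <- model$scaffold$alphabet$symbols
  Fm <- matrix(0, L, L)
  blocks <- list()
  for (i in seq_len(L - 1)) {
    ri <- ((i - 1) * q + 1):((i - 1) * q + q)
    for (j in seq(i + 1, L)) {
      rj <- ((j - 1) * q + 1):((j - 1) * q + q)
      B <- model$J[ri, rj]
      Fm[i, j] <- Fm[j, i] <- sqrt(sum(B^2))
      blocks[[paste(i, j)]] <- B
    }
  }
  rowm <- rowSums(Fm) / (L - 1)
  overall <- sum(Fm) / (L * (L - 1))
  use_apc <- isTRUE(apc)
  pairs <- tidyr::expand_grid(i = seq_len(L), j = seq_len(L)) |>
    filter(.data$i < .data$j) |>
    mutate(frobenius = purrr::map2_dbl(i, j, ~Fm[.x, .y]),
           apc = if (overall > 0) {
             .data$frobenius - rowm[.data$i] * rowm[.data$j] / overall
           } else .data$frobenius)
  pairs$score <- if (use_apc) pairs$apc else pairs$frobenius
  pairs <- pairs |>
    arrange(desc(.data$score), .data$i, .data$j) |>
    mutate(residue_pairs = purrr::map2(i, j, function(ii, jj) {
      B <- blocks[[paste(ii, jj)]]
      tibble(a = rep(symbols, times = q), b = rep(symbols, each = q),
             value = as.vector(B)) |>
        arrange(desc(abs(.data$value)))
    }))
  head(pairs, n = min(k, nrow(pairs)))
}

#' @export
tidy.potts_model <- function(x, k = Inf, apc = TRUE, ...) {
  top_coupled_pairs(x, k = k, apc = apc) |>
    select(-"residue_pairs")
}

#' @export
glance.potts_model <- function(x, ...) {
  tibble(L = x$scaffold$L, q = x$scaffold$alphabet$q, gauge = x$gauge,
         lambda_h = x$meta$lambda_h %||% NA_real_,
         lambda_J = x$meta$lambda_J %||% NA_real_,
         Meff = x$meta$Meff %||% NA_real_,
         iterations = x$meta$iterations %||% NA_integer_,
         converged = x$meta$converged %||% NA,
         objective = x$meta$objective %||% NA_real_)
}

#' Serialize / load a Potts model as JSON
#'
#' The archive stores the alphabet, scaffold, fields, the `i<j` coupling
#' blocks, gauge tag and fit metadata. The loader validates shapes and
#' restores block symmetry.
#'
#' @param model A [potts_model()].
#' @param path File path.
#' @export
save_potts <- function(model, path) {
  q <- model$scaffold$alphabet$q; L <- model$scaffold$L
  idx <- plm_index(L, q)
  jsonlite::write_json(
    list(alphabet = paste(model$scaffold$alphabet$symbols, collapse = ""),
         scaffold = list(L = L, fixed = as.list(model$scaffold$fixed),
                         name = model$scaffold$name),
         h = model$h, J_upper = model$J[idx$upper],
         gauge = model$gauge,
         meta = model$meta[setdiff(names(model$meta), "trace")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_potts
#' @export
load_potts <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- aa_alphabet(j$alphabet)
  sc <- scaffold(j$scaffold$L, as.list(j$scaffold$fixed),
                 name = j$scaffold$name, alphabet = alpha)
  idx <- plm_index(sc$L, alpha$q)
  theta <- c(as.vector(j$h), j$J_upper)
  model <- unpack_potts(theta, sc, idx)
  model$gauge <- j$gauge
  model$meta <- as.list(j$meta)
  model
}
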
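#' Position frequency matrix of an alignment
#'
#' Computes the (optionally weighted, optionally pseudocounted) per-position
#' residue frequencies underlying a sequence logo:
#' `f[i, a] = (pc + sum_m w_m 1[s_mi = a]) / (q * pc + sum_m w_m)`.
#' Rows always sum to one.
#'
#' @param msa An [msa()].
#' @param pseudocount Nonnegative real added to every (position, residue) count.
#' @param weights Optional positive per-sequence weights (length n). Default:
#'   all 1.
#' @return A `freq_matrix`: `L x q` matrix with position rownames and residue
#'   colnames, plus `pseudocount` and `n_sequences` attributes.
#' @export
frequency_matrix <- function(msa, pseudocount = 0, weights = NULL) {
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  n <- nrow(msa$matrix); L <- ncol(msa$matrix)
  q <- msa$scaffold$alphabet$q
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    abort("weights must be positive and one per sequence")
  }
  f <- matrix(pseudocount, nrow = L, ncol = q,
              dimnames = list(seq_len(L), msa$scaffold$alphabet$symbols))
  for (m in seq_len(n)) {
    idx <- cbind(seq_len(L), msa$matrix[m, ])
    f[idx] <- f[idx] + weights[m]
  }
  f <- f / (q * pseudocount + sum(weights))
  structure(f, class = c("freq_matrix", "matrix", "array"),
            pseudocount = pseudocount, n_sequences = n)
}

#' Build a frequency matrix directly from sequences
#' @param sequences Character vector of conformant sequences.
#' @inheritParams frequency_matrix
#' @param scaffold A [scaffold()].
#' @return A `freq_matrix`.
#' @export
frequency_matrix_of <- function(sequences, scaffold, pseudocount = 0,
                                weights = NULL) {
  frequency_matrix(msa(sprintf("s%d", seq_along(sequences)), sequences, scaffold),
                   pseudocount = pseudocount, weights = weights)
}

#' Per-position information content in bits
#'
#' `IC_i = log2(q) - H_i` with `H_i` the Shannon entropy of row i
#' (`0 * log2(0) := 0`). These are the column heights of the MSA logo; no
#' small-sample correction is applied (the families are tiny, a correction
#' term would dominate the heights).
#'
#' @param fm A `freq_matrix` from [frequency_matrix()].
#' @return Numeric vector, one value per position, in `[0, log2(q)]`.
#' @export
information_content <- function(fm) {
  q <- ncol(fm)
  H <- apply(unclass(fm), 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  unname(log2(q) - H)
}

#' @export
tidy.freq_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(position = rep(seq_len(nrow(m)), times = ncol(m)),
         residue = rep(colnames(m), each = nrow(m)),
         frequency = as.vector(m)) |>
    arrange(.data$position, desc(.data$frequency))
}

#' Export a frequency matrix as TSV (L rows x q columns, header = alphabet)
#' @param fm A `freq_matrix`.
#' @param path Output path.
#' @export
write_freq_tsv <- function(fm, path) {
  readr::write_tsv(as.data.frame(unclass(fm)), path)
  invisible(path)
}

#' Export a JSON logo bundle {freqs, ic_bits, alphabet, scaffold}
#' @param fm A `freq_matrix`.
#' @param scaffold The [scaffold()] the alignment conforms to.
#' @param path Output path.
#' @export
write_logo_json <- function(fm, scaffold, path) {
  jsonlite::write_json(
    list(freqs = unclass(fm), ic_bits = information_content(fm),
         alphabet = colnames(fm),
         scaffold = list(L = scaffold$L, fixed = as.list(scaffold$fixed),
                         name = scaffold$name)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
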
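# shared fixtures, built in code at test time

tiny_alphabet <- function(q = 4) aa_alphabet(substr("ACDEFGHIKLMNPQRSTVWY", 1, q))

free_scaffold <- function(L = 4, q = 4) {
  scaffold(L, list(), name = "free", alphabet = tiny_alphabet(q))
}

# random Potts model with block-symmetric couplings
random_potts <- function(scaffold, h_sd = 1, j_sd = 0.3, seed = 42) {
  q <- scaffold$alphabet$q; L <- scaffold$L
  set.seed(seed)
  h <- matrix(rnorm(q * L, sd = h_sd), q, L)
  J <- matrix(0, L * q, L * q)
  for (i in seq_len(L - 1)) for (j in seq(i + 1, L)) {
    B <- matrix(rnorm(q * q, sd = j_sd), q, q)
    J[((i - 1) * q + 1):(i * q), ((j - 1) * q + 1):(j * q)] <- B
    J[((j - 1) * q + 1):(j * q), ((i - 1) * q + 1):(i * q)] <- t(B)
  }
  potts_model(h, J, scaffold)
}

random_msa <- function(scaffold, n, seed = 1) {
  set.seed(seed)
  msa(sprintf("s%d", seq_len(n)),
      replicate(n, random_conformant(scaffold)),
      scaffold)
}

# tiny five-sequence affinity family on the 17-mer bicyclic scaffold
uk_mini_records <- function() {
  sc <- uk18_scaffold()
  seqs <- c("ACSRYEVDCRGRGSACG",
            "ACDRFVVDCRGRGGPCG",
            "ACSRFEVDCRGRGSVCG",
            "ACDRYVTDCRGRGGACG",
            "ACSRWETDCRGRGSPCG",
            "ACDRFETDCRGRGGVCG")
  affinity_records(sprintf("UK%02d", seq_along(seqs)), seqs,
                   c(53, 120, 35, 230, 88, 400), sc, ki_unit = "nM")
}

expect_rows_sum_to_one <- function(fm) {
  expect_true(all(abs(rowSums(unclass(fm)) - 1) < 1e-9))
}
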
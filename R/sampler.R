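#' Metropolis sampler configuration
#'
#' @param n_chains Number of independent chains. Each chain runs with its own
#'   derived seed (`seed + chain_index`), so the pool is reproducible bitwise
#'   for a fixed seed within this implementation.
#' @param steps Proposals per chain.
#' @param burn_in Initial steps discarded before recording.
#' @param thinning Record the current state every `thinning` steps.
#' @param temperature Effective temperature in the acceptance rule
#'   `min(1, exp((S' - S)/T))`. The default `T = 1` uses the plmDCA score
#'   as-is as the effective energy.
#' @param seed Integer seed.
#' @param init `"random_training_sequence"` (start each chain from a sequence
#'   drawn from `exclude`, keeping chains in the data basin) or
#'   `"random_scaffold_conformant"`.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 50, steps = 2000, burn_in = 500,
                           thinning = 10, temperature = 1, seed = 1,
                           init = c("random_training_sequence",
                                    "random_scaffold_conformant")) {
  init <- match.arg(init)
  if (burn_in < 0 || steps <= burn_in) abort("need steps > burn_in >= 0")
  if (thinning < 1) abort("thinning must be >= 1")
  if (temperature <= 0) abort("temperature must be > 0")
  structure(list(n_chains = as.integer(n_chains), steps = as.integer(steps),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning),
                 temperature = temperature, seed = as.integer(seed),
                 init = init),
            class = "sampler_config")
}

#' Single-site mutation proposal
#'
#' Mutates one uniformly chosen variable position to a uniformly chosen
#' different residue. Fixed scaffold positions are never touched; the
#' proposal is symmetric.
#'
#' @param sequence Scaffold-conformant residue string.
#' @param scaffold A [scaffold()].
#' @return The proposed sequence.
#' @export
propose_mutation <- function(sequence, scaffold) {
  vp <- variable_positions(scaffold)
  pos <- vp[sample.int(length(vp), 1)]
  chars <- strsplit(sequence, "")[[1]]
  alternatives <- setdiff(scaffold$alphabet$symbols, chars[pos])
  chars[pos] <- alternatives[sample.int(length(alternatives), 1)]
  paste(chars, collapse = "")
}

#' One Metropolis step on the Potts score landscape
#'
#' Proposes a single-site mutation and accepts it with probability
#' `min(1, exp((S' - S)/T))`; higher-score proposals are always accepted.
#' The score is updated incrementally in O(L).
#'
#' @param model A [potts_model()].
#' @param current One-row tibble from [score_sequence()] (or any list with
#'   `sequence` and `score`).
#' @param temperature Effective temperature, > 0.
#' @return List with `state` (one-row tibble `sequence`, `score`, `energy`)
#'   and `accepted` flag.
#' @export
metropolis_step <- function(model, current, temperature = 1) {
  if (temperature <= 0) abort("temperature must be > 0")
  if (!is.finite(current$score[1])) abort("non-finite current score")
  sc <- model$scaffold
  q <- sc$alphabet$q
  proposal <- propose_mutation(current$sequence[1], sc)
  cur <- encode_seq(current$sequence[1], sc$alphabet)
  prop <- encode_seq(proposal, sc$alphabet)
  pos <- which(cur != prop)
  delta <- model$h[prop[pos], pos] - model$h[cur[pos], pos]
  others <- setdiff(seq_len(sc$L), pos)
  cols <- (others - 1L) * q + cur[others]
  delta <- delta + sum(model$J[(pos - 1L) * q + prop[pos], cols]) -
    sum(model$J[(pos - 1L) * q + cur[pos], cols])
  accepted <- delta >= 0 || runif(1) < exp(delta / temperature)
  if (accepted) {
    s <- current$score[1] + delta
    list(state = tibble(sequence = proposal, score = s, energy = -s),
         accepted = TRUE)
  } else {
    list(state = tibble(sequence = current$sequence[1],
                        score = current$score[1],
                        energy = -current$score[1]),
         accepted = FALSE)
  }
}

#' Generate scaffold-constrained sequences by Metropolis Monte Carlo
#'
#' Runs `n_chains` independent single-site Metropolis chains on the Potts
#' score landscape, records the post-burn-in thinned states, deduplicates
#' them (first occurrence kept, multiplicity retained as `count`) and flags
#' as `novel` every sequence absent from `exclude` (typically the training
#' set).
#'
#' @param model A [potts_model()].
#' @param scaffold A [scaffold()] (defaults to the model's).
#' @param config A [sampler_config()].
#' @param exclude Character vector of sequences to exclude from the novel set
#'   (and the chain-start pool for `init = "random_training_sequence"`).
#' @return A `sample_pool`: list with `samples` (tibble `sequence`, `score`,
#'   `count`, `novel`), counters `n_proposed`/`n_accepted`, the `config`, and
#'   a `model_hash`. If every sample is excluded the pool is returned empty
#'   with a warning.
#' @export
sample_sequences <- function(model, scaffold = model$scaffold, config = sampler_config(),
                             exclude = character(0)) {
  vp <- variable_positions(scaffold)
  q <- scaffold$alphabet$q
  states <- vector("list", config$n_chains)
  scores <- vector("list", config$n_chains)
  n_prop <- 0L; n_acc <- 0L
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain)
    start_seq <- if (config$init == "random_training_sequence" && length(exclude)) {
      exclude[sample.int(length(exclude), 1)]
    } else {
      random_conformant(scaffold)
    }
    start <- assert_conformant(start_seq, scaffold) - 1L
    res <- cpp_mc_chain(start, model$h, model$J, vp - 1L,
                        config$steps, config$burn_in, config$thinning,
                        config$temperature)
    states[[chain]] <- res$states
    scores[[chain]] <- as.vector(res$scores)
    n_prop <- n_prop + res$n_proposed
    n_acc <- n_acc + res$n_accepted
  }
  mat <- do.call(rbind, states) + 1L
  seqs <- apply(mat, 1, function(r) paste(scaffold$alphabet$symbols[r], collapse = ""))
  rec <- tibble(sequence = seqs, score = unlist(scores))
  samples <- rec |>
    group_by(.data$sequence) |>
    summarise(score = max(.data$score), count = n(), .groups = "drop") |>
    arrange(desc(.data$score), .data$sequence) |>
    mutate(novel = !(.data$sequence %in% exclude))
  if (!any(samples$novel)) {
    warn("no novel sequences after exclusion; returning pool with empty novel set")
  }
  structure(list(samples = samples,
                 n_proposed = n_prop, n_accepted = n_acc,
                 config = config, model_hash = rlang::hash(list(model$h, model$J))),
            class = "sample_pool")
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("<sample_pool> %d unique sequences (%d novel), acceptance %.3f\n",
              nrow(x$samples), sum(x$samples$novel),
              x$n_accepted / x$n_proposed))
  invisible(x)
}

#' @export
as_tibble.sample_pool <- function(x, ...) x$samples

#' Export a sample pool (TSV + JSON sidecar, optional FASTA of the novel set)
#'
#' @param pool A `sample_pool`.
#' @param path Output TSV path (`sequence`, `score`, `count`). A `.json`
#'   sidecar with config, model hash and acceptance stats is written next to
#'   it.
#' @param fasta Optional FASTA path for the novel sequences.
#' @export
write_pool <- function(pool, path, fasta = NULL) {
  readr::write_tsv(pool$samples[, c("sequence", "score", "count")], path)
  jsonlite::write_json(
    list(config = unclass(pool$config), model_hash = pool$model_hash,
         n_proposed = pool$n_proposed, n_accepted = pool$n_accepted,
         acceptance_rate = pool$n_accepted / pool$n_proposed,
         n_unique = nrow(pool$samples), n_novel = sum(pool$samples$novel)),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  if (!is.null(fasta)) {
    novel <- pool$samples$sequence[pool$samples$novel]
    write_fasta(novel, fasta)
  }
  invisible(path)
}
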
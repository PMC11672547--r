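#' Configuration of one in-silico evolution round
#'
#' Bundles the per-stage configurations and a single master seed from which
#' every stage seed is derived (sampler: `seed + 1e6`; regressor:
#' `seed + 2e6`; the plmDCA fit is deterministic and needs none).
#'
#' @param seed Master seed.
#' @param plm List of [fit_plmdca()] arguments (regularization, reweighting,
#'   optimizer budget).
#' @param sampler A [sampler_config()]; its `seed` is overridden by the
#'   derived stage seed.
#' @param regressor A [regressor_config()]; idem.
#' @param spec A [feature_spec()].
#' @param percentile Selection percentile (default 50, the median rule).
#' @param percentile_reference `"generated"` (percentile of the predicted Ki
#'   of the novel pool, the default) or `"training"` (percentile of the
#'   measured training Ki).
#' @param runner_up_fraction,max_candidates Candidate-design rule, see
#'   [design_candidates()].
#' @param logo_pseudocount Pseudocount for the selected-pool logo.
#' @return A `round_config`.
#' @export
round_config <- function(seed = 1, plm = list(), sampler = sampler_config(),
                         regressor = regressor_config(), spec = feature_spec(),
                         percentile = 50,
                         percentile_reference = c("generated", "training"),
                         runner_up_fraction = 0.6, max_candidates = 8,
                         logo_pseudocount = 0) {
  percentile_reference <- match.arg(percentile_reference)
  if (runner_up_fraction <= 0 || runner_up_fraction > 1) {
    abort("runner_up_fraction must be in (0, 1]")
  }
  sampler$seed <- as.integer(seed + 1e6)
  regressor$seed <- as.integer(seed + 2e6)
  structure(list(seed = as.integer(seed), plm = plm, sampler = sampler,
                 regressor = regressor, spec = spec, percentile = percentile,
                 percentile_reference = percentile_reference,
                 runner_up_fraction = runner_up_fraction,
                 max_candidates = as.integer(max_candidates),
                 logo_pseudocount = logo_pseudocount),
            class = "round_config")
}

#' Run one full generation round
#'
#' Fits the Potts model to the family, samples a novel scaffold-constrained
#' pool by Metropolis MC (training sequences excluded), predicts Ki for every
#' novel sequence with the random-forest regressor, keeps the sequences
#' predicted strictly below the configured percentile threshold, and distills
#' the selected pool into a position-frequency logo and consensus design
#' candidates. Fully reproducible from `(records, config)`.
#'
#' @param records Affinity tibble (`id`, `sequence`, `ki` in molar).
#' @param scaffold A [scaffold()].
#' @param config A [round_config()].
#' @return A `generation_result`: `model`, `pool`, `predictions` (tibble
#'   `sequence`, `score`, `predicted_ki`), `threshold` (molar), `selected`,
#'   `logo`, `ic_bits`, `candidates`, and a `manifest` of stage statistics,
#'   seeds and hashes.
#' @export
run_generation_round <- function(records, scaffold, config = round_config()) {
  if (nrow(records) < 5) abort("need at least 5 records")
  aln <- msa(records$id, records$sequence, scaffold)
  model <- rlang::try_fetch(
    do.call(fit_plmdca, c(list(msa = aln), config$plm)),
    error = function(e) abort("stage plmdca failed", parent = e))

  pool <- rlang::try_fetch(
    sample_sequences(model, scaffold, config$sampler,
                     exclude = unique(records$sequence)),
    error = function(e) abort("stage mc_sampler failed", parent = e))
  novel <- pool$samples |> filter(.data$novel)

  rf <- rlang::try_fetch(
    fit_regressor(records, scaffold, config$spec, config$regressor),
    error = function(e) abort("stage affinity_model failed", parent = e))

  if (nrow(novel) == 0) {
    warn("empty novel pool; returning empty selection")
    predictions <- tibble(sequence = character(0), score = numeric(0),
                          predicted_ki = numeric(0))
    threshold <- NA_real_
  } else {
    predictions <- novel |>
      transmute(.data$sequence, .data$score,
                predicted_ki = predict_ki(rf, .data$sequence))
    reference <- switch(config$percentile_reference,
                        generated = predictions$predicted_ki,
                        training = records$ki)
    threshold <- percentile_threshold(reference, config$percentile)
  }
  selected <- predictions |> filter(.data$predicted_ki < threshold)
  if (nrow(selected) == 0 && nrow(predictions) > 0) {
    warn("no sequence predicted strictly below the threshold; empty selection")
  }

  logo <- NULL; ic <- NULL; candidates <- character(0)
  if (nrow(selected) > 0) {
    logo <- frequency_matrix_of(selected$sequence, scaffold,
                                pseudocount = config$logo_pseudocount)
    ic <- information_content(logo)
    candidates <- design_candidates(logo, scaffold,
                                    runner_up_fraction = config$runner_up_fraction,
                                    max_candidates = config$max_candidates)
  }

  manifest <- list(
    seed = config$seed,
    n_records = nrow(records),
    plm = list(Meff = model$meta$Meff, iterations = model$meta$iterations,
               converged = model$meta$converged,
               objective = model$meta$objective,
               lambda_h = model$meta$lambda_h, lambda_J = model$meta$lambda_J),
    sampler = list(seed = config$sampler$seed,
                   n_proposed = pool$n_proposed, n_accepted = pool$n_accepted,
                   acceptance_rate = pool$n_accepted / pool$n_proposed,
                   n_unique = nrow(pool$samples), n_novel = nrow(novel)),
    regressor = list(seed = config$regressor$seed,
                     cv_rmse = rf$report$cv_rmse,
                     train_rmse = rf$report$train_rmse),
    selection = list(percentile = config$percentile,
                     reference = config$percentile_reference,
                     threshold_molar = threshold,
                     n_selected = nrow(selected)),
    model_hash = pool$model_hash)
  manifest$result_hash <- rlang::hash(list(model$h, model$J, pool$samples,
                                           predictions, threshold, selected,
                                           unclass(logo), candidates))
  inform(sprintf(
    "round: n=%d, Meff=%.1f, pool=%d unique (%d novel), threshold=%.3g M, selected=%d, candidates=%d",
    nrow(records), manifest$plm$Meff %||% NA, manifest$sampler$n_unique,
    manifest$sampler$n_novel, threshold, nrow(selected), length(candidates)))
  structure(list(model = model, pool = pool, regressor = rf,
                 predictions = predictions, threshold = threshold,
                 selected = selected, logo = logo, ic_bits = ic,
                 candidates = candidates, manifest = manifest,
                 config = config, scaffold = scaffold),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat(sprintf(
    "<generation_result> pool %d (novel %d) -> selected %d below %.3g M; %d candidates\n",
    nrow(x$pool$samples), sum(x$pool$samples$novel), nrow(x$selected),
    x$threshold, length(x$candidates)))
  invisible(x)
}

#' @export
tidy.generation_result <- function(x, ...) x$selected

#' @export
glance.generation_result <- function(x, ...) {
  tibble(n_records = x$manifest$n_records,
         n_unique = x$manifest$sampler$n_unique,
         n_novel = x$manifest$sampler$n_novel,
         threshold_molar = x$threshold,
         n_selected = nrow(x$selected),
         n_candidates = length(x$candidates),
         cv_rmse = x$manifest$regressor$cv_rmse,
         result_hash = x$manifest$result_hash)
}

#' Suggest hold-out records for the leave-out validation
#'
#' Mirrors the validation design: candidates are records with Ki strictly
#' below the family median, excluding the single most potent record, ordered
#' by increasing Ki and capped at `floor(max_fraction * n)`.
#'
#' @param records Affinity tibble.
#' @param max_fraction Fraction cap in `(0, 0.5]` (the validation removed
#'   about 5% of each family).
#' @param exclude_best Exclude the minimum-Ki record? Default TRUE.
#' @return Character vector of record ids (possibly empty).
#' @export
suggest_holdouts <- function(records, max_fraction = 0.05, exclude_best = TRUE) {
  if (nrow(records) < 3) abort("need at least 3 records")
  if (max_fraction <= 0 || max_fraction > 0.5) {
    abort("max_fraction must be in (0, 0.5]")
  }
  med <- median(records$ki)
  eligible <- records |> filter(.data$ki < med)
  if (exclude_best && nrow(eligible)) {
    best <- records$id[which.min(records$ki)]
    eligible <- eligible |> filter(.data$id != best)
  }
  cap <- floor(max_fraction * nrow(records))
  eligible |> arrange(.data$ki, .data$id) |> head(cap) |> pull("id")
}

#' Leave-out recovery experiment
#'
#' Removes the given records, reruns the full generation round on the
#' depleted family, and reports which held-out sequences the pipeline
#' regenerated de novo in the selected pool, together with their ranks in the
#' novel pool by Potts score and by predicted Ki.
#'
#' @param records Affinity tibble.
#' @param scaffold A [scaffold()].
#' @param held_out_ids Ids to remove (must exist; remaining n >= 5).
#' @param config A [round_config()].
#' @return A `recovery_report`: list with `held_out` (tibble `id`,
#'   `sequence`, `ki`, `in_pool`, `rank_by_score`, `rank_by_predicted_ki`,
#'   `regenerated`), `regenerated_ids`, `pool_size`, `selected_size` and the
#'   underlying `result`.
#' @export
leave_out_experiment <- function(records, scaffold, held_out_ids,
                                 config = round_config()) {
  unknown <- setdiff(held_out_ids, records$id)
  if (length(unknown)) abort(sprintf("unknown held-out id '%s'", unknown[1]))
  held <- records |> filter(.data$id %in% held_out_ids)
  rest <- records |> filter(!.data$id %in% held_out_ids)
  if (nrow(rest) < 5) abort("fewer than 5 records remain after hold-out")
  if (any(held$sequence %in% rest$sequence)) {
    warn("a held-out sequence equals a remaining training sequence; recovery is degenerate for it")
  }
  result <- run_generation_round(rest, scaffold, config)
  preds <- result$predictions |>
    mutate(rank_score = rank(-.data$score, ties.method = "min"),
           rank_pred = rank(.data$predicted_ki, ties.method = "min"))
  held_rep <- held |>
    mutate(in_pool = .data$sequence %in% preds$sequence,
           rank_by_score = preds$rank_score[match(.data$sequence, preds$sequence)],
           rank_by_predicted_ki = preds$rank_pred[match(.data$sequence, preds$sequence)],
           regenerated = .data$sequence %in% result$selected$sequence)
  structure(list(held_out = held_rep,
                 regenerated_ids = held_rep$id[held_rep$regenerated],
                 pool_size = nrow(result$predictions),
                 selected_size = nrow(result$selected),
                 result = result),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> regenerated %d/%d held-out (pool %d, selected %d)\n",
              length(x$regenerated_ids), nrow(x$held_out),
              x$pool_size, x$selected_size))
  invisible(x)
}

#' Frequency-guided candidate design from a selected-pool logo
#'
#' The consensus sequence (top-frequency residue at each variable position,
#' scaffold residues at fixed positions) comes first. Positions where the
#' runner-up frequency reaches `runner_up_fraction` times the top frequency
#' are then expanded combinatorially — in decreasing runner-up-ratio order —
#' until `max_candidates` is reached. Frequency ties break by alphabet order.
#'
#' This is the reproducible part of the published design step; the curation
#' that used target-complex structures is deliberately left to the user, who
#' can inspect the runner-up ratios via [tidy()] of the logo.
#'
#' @param logo A `freq_matrix` of the selected pool.
#' @param scaffold A [scaffold()].
#' @param runner_up_fraction Branching threshold in `(0, 1]`.
#' @param max_candidates Hard cap, >= 1.
#' @return Character vector of candidate sequences, consensus first.
#' @export
design_candidates <- function(logo, scaffold, runner_up_fraction = 0.6,
                              max_candidates = 8) {
  if (max_candidates < 1) abort("max_candidates must be >= 1")
  fm <- unclass(logo)
  symbols <- scaffold$alphabet$symbols
  vp <- variable_positions(scaffold)
  consensus <- character(scaffold$L)
  fixed_pos <- as.integer(names(scaffold$fixed))
  consensus[fixed_pos] <- scaffold$fixed
  branch <- tibble(position = integer(0), runner_up = character(0),
                   ratio = numeric(0))
  for (i in vp) {
    ord <- order(-fm[i, ], seq_len(ncol(fm)))  # alphabet order breaks ties
    top <- ord[1]; second <- ord[2]
    consensus[i] <- symbols[top]
    if (fm[i, top] > 0 && fm[i, second] >= runner_up_fraction * fm[i, top]) {
      branch <- bind_rows(branch,
                          tibble(position = i, runner_up = symbols[second],
                                 ratio = fm[i, second] / fm[i, top]))
    }
  }
  branch <- branch |> arrange(desc(.data$ratio), .data$position)
  candidates <- list(consensus)
  for (b in seq_len(nrow(branch))) {
    if (length(candidates) >= max_candidates) break
    variants <- lapply(candidates, function(ch) {
      ch[branch$position[b]] <- branch$runner_up[b]
      ch
    })
    room <- max_candidates - length(candidates)
    candidates <- c(candidates, variants[seq_len(min(room, length(variants)))])
  }
  vapply(candidates, paste, character(1), collapse = "")
}

#' Potency fold change between two inhibition constants
#'
#' `fold_change(ki_a, ki_b) = ki_a / ki_b` — how many fold more potent `b` is
#' than `a` (dimensionless). `fold_change_label()` rounds to one decimal for
#' reporting.
#'
#' @param ki_a,ki_b Inhibition constants in the same (positive) units.
#' @return Scalar ratio.
#' @examples
#' fold_change(53e-9, 4.3e-9)        # 12.3...
#' fold_change_label(363e-9, 202e-9) # 1.8
#' @export
fold_change <- function(ki_a, ki_b) {
  if (any(c(ki_a, ki_b) <= 0)) abort("inhibition constants must be > 0")
  ki_a / ki_b
}

#' @rdname fold_change
#' @export
fold_change_label <- function(ki_a, ki_b) {
  round(fold_change(ki_a, ki_b), 1)
}

#' Write the artifacts of a generation round to a directory
#'
#' Writes `selected.tsv`, `pool.tsv` (+ JSON sidecar), `logo.tsv`,
#' `logo.json`, `candidates.fasta` and `manifest.json`.
#'
#' @param result A `generation_result`.
#' @param dir Output directory (created if missing).
#' @export
write_generation_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$selected, file.path(dir, "selected.tsv"))
  write_pool(result$pool, file.path(dir, "pool.tsv"))
  if (!is.null(result$logo)) {
    write_freq_tsv(result$logo, file.path(dir, "logo.tsv"))
    write_logo_json(result$logo, result$scaffold, file.path(dir, "logo.json"))
  }
  if (length(result$candidates)) {
    write_fasta(tibble(id = sprintf("candidate%02d", seq_along(result$candidates)),
                       sequence = result$candidates),
                file.path(dir, "candidates.fasta"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
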
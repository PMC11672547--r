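#' Per-residue descriptor constants
#'
#' The packaged table behind the sequence-level descriptors: Kyte–Doolittle
#' hydropathy, average residue mass (Da; peptide molecular weight adds one
#' water), an additive charge model at pH 7.4 (Asp/Glu = -1, Lys/Arg = +1,
#' His = 0) and residue-class indicator columns (aromatic F/W/Y, aliphatic
#' A/V/I/L, polar uncharged C/H/N/Q/S/T/Y, positive K/R, negative D/E,
#' proline).
#'
#' @return Tibble keyed by `residue`.
#' @export
residue_descriptors <- function() {
  path <- system.file("extdata", "residue_descriptors.csv", package = "pepdca")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Feature specification for the affinity regressor
#'
#' Features are the concatenation of a one-hot block over the variable
#' scaffold positions (fixed positions carry no information within a family)
#' and a block of sequence-level physicochemical descriptors.
#'
#' @param use_onehot Include the one-hot block?
#' @param descriptors Character vector of descriptor names, a subset of
#'   `"mean_hydropathy"`, `"net_charge_pH7.4"`, `"molecular_weight"`,
#'   `"aromatic_count"`, `"aliphatic_count"`, `"polar_count"`,
#'   `"positive_count"`, `"negative_count"`, `"proline_count"`.
#' @return A `feature_spec`.
#' @export
feature_spec <- function(use_onehot = TRUE,
                         descriptors = c("mean_hydropathy", "net_charge_pH7.4",
                                         "molecular_weight", "aromatic_count",
                                         "aliphatic_count", "polar_count",
                                         "positive_count", "negative_count",
                                         "proline_count")) {
  known <- c("mean_hydropathy", "net_charge_pH7.4", "molecular_weight",
             "aromatic_count", "aliphatic_count", "polar_count",
             "positive_count", "negative_count", "proline_count")
  bad <- setdiff(descriptors, known)
  if (length(bad)) abort(sprintf("unknown descriptor '%s'", bad[1]))
  structure(list(use_onehot = isTRUE(use_onehot),
                 descriptors = as.character(descriptors)),
            class = "feature_spec")
}

descriptor_values <- function(chars, tab) {
  i <- match(chars, tab$residue)
  miss <- which(is.na(i))
  if (length(miss)) {
    abort(sprintf("no descriptor constants for residue '%s'", chars[miss[1]]))
  }
  c(mean_hydropathy = mean(tab$hydropathy[i]),
    `net_charge_pH7.4` = sum(tab$charge_ph7.4[i]),
    molecular_weight = sum(tab$residue_mass[i]) + 18.0153,
    aromatic_count = sum(tab$aromatic[i]),
    aliphatic_count = sum(tab$aliphatic[i]),
    polar_count = sum(tab$polar[i]),
    positive_count = sum(tab$positive[i]),
    negative_count = sum(tab$negative[i]),
    proline_count = sum(tab$proline[i]))
}

#' Featurize sequences for the affinity regressor
#'
#' @param sequences Character vector of scaffold-conformant sequences.
#' @param scaffold A [scaffold()].
#' @param spec A [feature_spec()].
#' @return Numeric matrix, one row per sequence, with stable column names
#'   (`pos<i>_<residue>` for the one-hot block, descriptor names after).
#' @export
featurize <- function(sequences, scaffold, spec = feature_spec()) {
  vp <- variable_positions(scaffold)
  q <- scaffold$alphabet$q
  symbols <- scaffold$alphabet$symbols
  tab <- residue_descriptors()
  blocks <- list()
  if (spec$use_onehot) {
    oh <- matrix(0, nrow = length(sequences), ncol = length(vp) * q,
                 dimnames = list(NULL, paste0(
                   "pos", rep(vp, each = q), "_", rep(symbols, times = length(vp)))))
  }
  if (length(spec$descriptors)) {
    ds <- matrix(0, nrow = length(sequences), ncol = length(spec$descriptors),
                 dimnames = list(NULL, spec$descriptors))
  }
  for (m in seq_along(sequences)) {
    idx <- assert_conformant(sequences[m], scaffold)
    if (spec$use_onehot) {
      oh[m, (seq_along(vp) - 1L) * q + idx[vp]] <- 1
    }
    if (length(spec$descriptors)) {
      vals <- descriptor_values(symbols[idx], tab)
      ds[m, ] <- vals[spec$descriptors]
    }
  }
  out <- NULL
  if (spec$use_onehot) out <- oh
  if (length(spec$descriptors)) out <- if (is.null(out)) ds else cbind(out, ds)
  out
}
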
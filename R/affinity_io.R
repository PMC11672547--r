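#' Read a peptide affinity table
#'
#' Reads a delimited table with columns `id`, `sequence`, `ki` (header
#' required; TSV or CSV detected from the extension unless `delim` is given),
#' validates every sequence against the scaffold, and normalizes Ki to molar.
#' Inhibition constants must be strictly positive.
#'
#' @param path File path.
#' @param scaffold A [scaffold()].
#' @param ki_unit Unit of the `ki` column: one of `"M"`, `"mM"`, `"uM"`
#'   (aliases `"µM"`, `"μM"`), `"nM"`.
#' @param family Optional family label attached to every record.
#' @param delim Optional field delimiter override.
#' @return Tibble of affinity records: `id`, `sequence`, `ki` (molar),
#'   `family`.
#' @examples
#' \dontrun{
#' read_affinity_table("family.tsv", uk18_scaffold(), ki_unit = "nM")
#' }
#' @export
read_affinity_table <- function(path, scaffold, ki_unit = c("M", "mM", "uM", "nM"),
                                family = NA_character_, delim = NULL) {
  unit <- ki_unit[1]
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          trim_ws = TRUE)
  need <- c("id", "sequence", "ki")
  if (!all(need %in% names(df))) {
    abort(sprintf("affinity table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  affinity_records(df$id, df$sequence, df$ki, scaffold,
                   ki_unit = unit, family = family)
}

#' Assemble validated affinity records
#' @param id,sequence,ki Parallel vectors.
#' @inheritParams read_affinity_table
#' @return Tibble `id`, `sequence`, `ki` (molar), `family`.
#' @export
affinity_records <- function(id, sequence, ki, scaffold, ki_unit = "M",
                             family = NA_character_) {
  ki <- suppressWarnings(as.numeric(ki))
  if (anyNA(ki)) {
    abort(sprintf("non-numeric ki in record '%s'", id[which(is.na(ki))[1]]))
  }
  if (any(ki <= 0)) {
    abort(sprintf("non-positive ki in record '%s'", id[which(ki <= 0)[1]]))
  }
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate id '%s'", id[duplicated(id)][1]))
  }
  for (i in seq_along(sequence)) assert_conformant(sequence[i], scaffold, id = id[i])
  tibble(id = as.character(id), sequence = as.character(sequence),
         ki = ki * ki_unit_factor(ki_unit), family = family)
}

ki_unit_factor <- function(unit) {
  switch(unit,
         "M" = 1, "mM" = 1e-3,
         "uM" = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
         "nM" = 1e-9,
         abort(sprintf("unknown Ki unit '%s'", unit)))
}
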
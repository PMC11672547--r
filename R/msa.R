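#' Fixed-length peptide alignment
#'
#' An `msa` holds equal-length, scaffold-conformant sequences with unique
#' identifiers. The families here are ungapped by construction (phage-display
#' libraries on a fixed template), so gap characters are rejected outright.
#'
#' @param ids Character vector of unique identifiers.
#' @param sequences Character vector of residue strings.
#' @param scaffold A [scaffold()].
#' @return An `msa` object with an `n x L` integer index matrix.
#' @export
msa <- function(ids, sequences, scaffold) {
  if (length(ids) != length(sequences)) abort("ids and sequences differ in length")
  if (length(ids) < 1L) abort("alignment needs at least one sequence")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate id '%s'", ids[duplicated(ids)][1]))
  }
  mat <- t(vapply(seq_along(sequences),
                  function(i) assert_conformant(sequences[i], scaffold, id = ids[i]),
                  integer(scaffold$L)))
  structure(list(ids = as.character(ids), sequences = as.character(sequences),
                 matrix = mat, scaffold = scaffold),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences of length %d on scaffold '%s'\n",
              nrow(x$matrix), x$scaffold$L, x$scaffold$name))
  invisible(x)
}

#' @export
as_tibble.msa <- function(x, ...) {
  tibble(id = x$ids, sequence = x$sequences)
}

#' Read a fixed-length peptide FASTA into an alignment
#'
#' Sequences must match the scaffold (length, fixed residues, alphabet).
#' With `permissive = TRUE` non-conformant records are dropped with a warning
#' that reports how many were removed; otherwise the first offending record
#' raises an error naming it.
#'
#' @param path FASTA file path.
#' @param scaffold A [scaffold()].
#' @param permissive Drop non-conformant records instead of erroring.
#' @return An [msa()].
#' @export
read_fasta <- function(path, scaffold, permissive = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate id '%s' in %s", ids[duplicated(ids)][1], path))
  }
  if (permissive) {
    ok <- vapply(seqs, is_conformant, logical(1), scaffold = scaffold)
    if (any(!ok)) {
      warn(sprintf("dropped %d of %d records not conforming to scaffold '%s'",
                   sum(!ok), length(ok), scaffold$name))
    }
    if (!any(ok)) abort("no scaffold-conformant records left")
    ids <- ids[ok]; seqs <- seqs[ok]
  }
  msa(ids, seqs, scaffold)
}

#' Write sequences as FASTA
#'
#' @param x An [msa()] or a tibble/data.frame with `id` and `sequence`
#'   columns, or a character vector of sequences (ids are generated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "msa")) {
    ids <- x$ids; seqs <- x$sequences
  } else if (is.data.frame(x)) {
    ids <- x$id; seqs <- x$sequence
  } else {
    seqs <- as.character(x)
    ids <- sprintf("seq%d", seq_along(seqs))
  }
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Fraction of identical positions between two equal-length sequences
#'
#' @param a,b Residue strings of equal length.
#' @return Real in `[0, 1]`.
#' @export
hamming_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort(sprintf("length mismatch: %d vs %d", nchar(a), nchar(b)))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
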
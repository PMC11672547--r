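#' Amino-acid alphabets
#'
#' The canonical alphabet is the 20 one-letter amino-acid codes in the fixed
#' order `"ACDEFGHIKLMNPQRSTVWY"`. Restricted alphabets (prefixes of the
#' canonical order, or any explicit symbol set) are used by the synthetic
#' benchmarks where exhaustive enumeration must stay desk-scale.
#'
#' @param symbols Single string or character vector of unique one-character
#'   symbols. Defaults to the 20 canonical residues.
#' @return An `aa_alphabet` object: list with `symbols` (character vector)
#'   and `q` (alphabet size).
#' @examples
#' aa_alphabet()$q            # 20
#' aa_alphabet("ACDE")$q      # 4
#' @export
aa_alphabet <- function(symbols = "ACDEFGHIKLMNPQRSTVWY") {
  if (length(symbols) == 1L && nchar(symbols) > 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) abort("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L)) abort("alphabet symbols must be single characters")
  structure(list(symbols = symbols, q = length(symbols)), class = "aa_alphabet")
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet> q =", x$q, ":", paste(x$symbols, collapse = ""), "\n")
  invisible(x)
}

#' Encode/decode sequences against an alphabet
#'
#' `encode_seq()` maps a residue string to 1-based alphabet indices;
#' `decode_seq()` inverts it. Round-trips are exact.
#'
#' @param x Residue string (`encode_seq`) or integer vector (`decode_seq`).
#' @param alphabet An [aa_alphabet()].
#' @param id Optional record label used in error messages.
#' @return Integer vector of indices, or a single string.
#' @export
encode_seq <- function(x, alphabet = aa_alphabet(), id = NULL) {
  chars <- strsplit(x, "")[[1]]
  idx <- match(chars, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("invalid symbol '%s' at position %d%s",
                  chars[bad], bad,
                  if (is.null(id)) "" else sprintf(" in record '%s'", id)))
  }
  idx
}

#' @rdname encode_seq
#' @export
decode_seq <- function(x, alphabet = aa_alphabet()) {
  paste(alphabet$symbols[x], collapse = "")
}
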
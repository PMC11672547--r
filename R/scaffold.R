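#' Bicyclic peptide scaffold
#'
#' A scaffold is a fixed-length template with immutable positions — for the
#' bicyclic families these are the three cysteines that react with the
#' trivalent linker plus the terminal residues — and freely mutable loop
#' positions. All positions are 1-based.
#'
#' @param L Sequence length in residues.
#' @param fixed Named list/vector mapping position (as name, e.g. `"2"`) to a
#'   single fixed residue. May be empty.
#' @param name Scaffold label.
#' @param alphabet An [aa_alphabet()].
#' @return A `scaffold` object.
#' @examples
#' # the 17-mer two-loop template with three fixed cysteines
#' uk18_scaffold()
#' @export
scaffold <- function(L, fixed = list(), name = "scaffold",
                     alphabet = aa_alphabet()) {
  L <- as.integer(L)
  if (L < 1L) abort("scaffold length must be >= 1")
  fixed <- unlist(fixed)
  if (length(fixed)) {
    pos <- as.integer(names(fixed))
    if (anyNA(pos) || any(pos < 1L | pos > L)) {
      abort("fixed positions must be named with integers in [1, L]")
    }
    if (anyDuplicated(pos)) abort("duplicate fixed positions")
    if (!all(fixed %in% alphabet$symbols)) {
      abort("fixed residues must belong to the alphabet")
    }
    fixed <- setNames(as.character(fixed), pos)[order(pos)]
  } else {
    fixed <- setNames(character(0), integer(0))
  }
  if (length(fixed) >= L) abort("scaffold needs at least one variable position")
  structure(list(L = L, fixed = fixed, name = name, alphabet = alphabet),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold '%s'> L = %d, fixed: %s\n", x$name, x$L,
              if (length(x$fixed)) {
                paste(sprintf("%s:%s", names(x$fixed), x$fixed), collapse = " ")
              } else "none"))
  invisible(x)
}

#' @rdname scaffold
#' @export
uk18_scaffold <- function() {
  scaffold(17L, list(`1` = "A", `2` = "C", `9` = "C", `16` = "C", `17` = "G"),
           name = "UK18")
}

#' Variable (mutable) positions of a scaffold
#' @param scaffold A [scaffold()].
#' @return Integer vector of 1-based positions.
#' @export
variable_positions <- function(scaffold) {
  setdiff(seq_len(scaffold$L), as.integer(names(scaffold$fixed)))
}

#' Test or assert scaffold conformance of a sequence
#'
#' A sequence conforms when it has length `L`, uses only alphabet symbols and
#' carries the fixed residues at the fixed positions.
#'
#' @param x Residue string.
#' @param scaffold A [scaffold()].
#' @param id Optional record label for error messages.
#' @return `is_conformant()`: logical. `assert_conformant()`: the encoded
#'   integer sequence, invisibly erroring otherwise.
#' @export
is_conformant <- function(x, scaffold) {
  if (nchar(x) != scaffold$L) return(FALSE)
  chars <- strsplit(x, "")[[1]]
  if (!all(chars %in% scaffold$alphabet$symbols)) return(FALSE)
  pos <- as.integer(names(scaffold$fixed))
  all(chars[pos] == scaffold$fixed)
}

#' @rdname is_conformant
#' @export
assert_conformant <- function(x, scaffold, id = NULL) {
  lbl <- if (is.null(id)) "sequence" else sprintf("record '%s'", id)
  if (nchar(x) != scaffold$L) {
    abort(sprintf("%s has length %d, scaffold requires %d",
                  lbl, nchar(x), scaffold$L))
  }
  idx <- encode_seq(x, scaffold$alphabet, id = id)
  pos <- as.integer(names(scaffold$fixed))
  if (length(pos)) {
    want <- match(scaffold$fixed, scaffold$alphabet$symbols)
    bad <- which(idx[pos] != want)
    if (length(bad)) {
      abort(sprintf("%s violates fixed position %d (expected %s)",
                    lbl, pos[bad[1]], scaffold$fixed[bad[1]]))
    }
  }
  idx
}

#' Random scaffold-conformant sequence
#' @inheritParams variable_positions
#' @return Residue string drawn uniformly over the variable positions.
#' @export
random_conformant <- function(scaffold) {
  chars <- character(scaffold$L)
  pos <- as.integer(names(scaffold$fixed))
  chars[pos] <- scaffold$fixed
  vp <- variable_positions(scaffold)
  chars[vp] <- sample(scaffold$alphabet$symbols, length(vp), replace = TRUE)
  paste(chars, collapse = "")
}

#' Read/write scaffold JSON ({L, fixed: {pos: residue}, name})
#' @param path File path.
#' @param x A [scaffold()] (for writing).
#' @return `read_scaffold()` returns a scaffold; `write_scaffold()` the path.
#' @export
read_scaffold <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- if (!is.null(j$alphabet)) aa_alphabet(j$alphabet) else aa_alphabet()
  scaffold(j$L, as.list(j$fixed), name = j$name %||% "scaffold",
           alphabet = alpha)
}

#' @rdname read_scaffold
#' @export
write_scaffold <- function(x, path) {
  jsonlite::write_json(
    list(L = x$L, fixed = as.list(x$fixed), name = x$name,
         alphabet = paste(x$alphabet$symbols, collapse = "")),
    path, auto_unbox = TRUE)
  invisible(path)
}
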
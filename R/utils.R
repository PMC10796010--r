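# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Standard amino-acid alphabet
#'
#' The twenty one-letter amino-acid codes plus `X` for unknown residues.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

#' Default hydrophobic residue set
#'
#' The set of residues counted as hydrophobic in the head-tail symmetry
#' analysis: Ala, Val, Leu, Ile, Met, Phe, Trp, Cys.  Tyrosine is excluded
#' by default; pass your own set to the symmetry functions to include it.
#'
#' @return Character vector of one-letter codes.
#' @export
default_hydrophobic_set <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "C")
}

# Coerce to an n x 3 numeric coordinate matrix, with checks.
as_coords <- function(x, arg = "coords") {
  if (inherits(x, "ca_structure")) x <- coords(x)
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(sprintf("'%s' must be an n x 3 coordinate matrix", arg))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop(sprintf("'%s' contains missing coordinates", arg))
  x
}

split_residues <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  strsplit(toupper(s), "")[[1]]
}

check_aa_string <- function(s, arg = "sequence") {
  ch <- split_residues(s)
  bad <- setdiff(unique(ch), aa_alphabet())
  if (length(bad))
    stop(sprintf("'%s' contains characters outside the amino-acid alphabet: %s",
                 arg, paste(bad, collapse = ", ")))
  ch
}

# Deterministic RNG scope: evaluate `expr` under a local seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
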
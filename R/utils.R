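# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; the alphabet is ACGTN (case-insensitive,
#' returned upper case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# complement lookup for single characters
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# cytosine context from a strand-oriented trinucleotide:
# second base G -> CG, third base G -> CHG, otherwise CHH.
context_from_trinucleotide <- function(tri) {
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
}
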
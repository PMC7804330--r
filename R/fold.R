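# Bundled secondary-structure model: maximum-weight non-crossing base
# pairing (G:C = -3, A:U = -2, G:U = -1 kcal/mol, minimum hairpin loop 3 nt)
# solved exactly by dynamic programming in C++. It is deliberately simple
# and fully deterministic so that every structural criterion has an exact,
# backend-independent value; a thermodynamic folding engine can be swapped
# in for real data via the `engine` argument.

#' Fold a sequence into its optimal non-crossing pairing
#'
#' @param sequence DNA/RNA sequence, 8-400 nt (U is treated as T).
#' @param engine folding backend; `"bundled"` is the reference
#'   maximum-weight pairing model. A function `f(sequence)` returning a list
#'   with `dot_bracket` and `mfe_kcal_mol` may be supplied instead.
#' @return a `fold_result` list: `sequence`, `dot_bracket`, `mfe_kcal_mol`.
#' @examples
#' fold("GGGGAAAACCCC")  # four G:C pairs, -12 kcal/mol
#' @export
fold <- function(sequence, engine = "bundled") {
  sequence <- canonical_dna(sequence)
  n <- nchar(sequence)
  if (n < 8 || n > 400)
    stopf("fold() requires 8-400 nt, got %d", n)
  if (!is_acgt(sequence))
    stopf("fold() requires an ACGT/ACGU sequence")
  if (is.function(engine)) {
    r <- engine(sequence)
    return(structure(list(sequence = sequence, dot_bracket = r$dot_bracket,
                          mfe_kcal_mol = r$mfe_kcal_mol),
                     class = "fold_result"))
  }
  r <- .fold_dp(sequence)
  structure(list(sequence = sequence, dot_bracket = r$dot_bracket,
                 mfe_kcal_mol = -as.numeric(r$score)),
            class = "fold_result")
}

#' Pairing table of a dot-bracket structure
#'
#' @param dot_bracket balanced-parenthesis structure string.
#' @return integer vector, `pt[i]` = partner of position i, 0 if unpaired.
#' @export
pairing_table <- function(dot_bracket) {
  ch <- seq_chars(dot_bracket)
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0) stopf("unbalanced dot-bracket string")
  pt
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n",
      sprintf("MFE = %.1f kcal/mol\n", x$mfe_kcal_mol), sep = "")
  invisible(x)
}
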
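## Shared low-level helpers for sequences and dot-bracket structures.

#' Normalize nucleotide sequences to lowercase RNA
#'
#' Uppercase letters are lowercased and t is converted to u, so DNA-alphabet
#' input (reads, adapters) becomes canonical lowercase RNA.
#'
#' @param x character vector of sequences.
#' @return character vector over \code{{a,c,g,u}} (other letters are
#'   preserved and caught by downstream validity checks).
#' @export
normalizeRNA <- function(x) {
  chartr("t", "u", tolower(x))
}

#' Reverse complement of lowercase RNA
#' @param x character vector of lowercase RNA sequences.
#' @return character vector of reverse complements.
#' @export
reverseComplementRNA <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("acgu", "ugca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_to_int <- function(s) {
  match(strsplit(s, "")[[1]], c("a", "c", "g", "u"))
}

#' Pair table of a dot-bracket string
#'
#' @param dotbracket dot-bracket string.
#' @return integer vector: position i holds the 1-based partner of i, or 0.
#' @export
pairTableFromDotBracket <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced structure: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ", stack[1])
  pt
}

dotBracketFromPairTable <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

#' Count terminal (hairpin) loops of a structure
#'
#' A terminal loop is closed by a pair (i, j) with no pair strictly inside.
#'
#' @param structure a [SecondaryStructure-class] or a dot-bracket string.
#' @return integer count of terminal loops.
#' @examples
#' countTerminalLoops("((((...))))")
#' countTerminalLoops("((..))..((..))")
#' @export
countTerminalLoops <- function(structure) {
  pt <- if (is(structure, "SecondaryStructure")) structure@pairTable
        else pairTableFromDotBracket(structure)
  n <- 0L
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i && all(pt[seq(i + 1L, length.out = j - i - 1L)] == 0L))
      n <- n + 1L
  }
  n
}

## Top-level pairs within [a, b] of a pair table.
toplevel_pairs <- function(pt, a, b) {
  out <- list()
  k <- a
  while (k <= b) {
    if (pt[k] > k && pt[k] <= b) {
      out[[length(out) + 1L]] <- c(k, pt[k])
      k <- pt[k] + 1L
    } else k <- k + 1L
  }
  out
}

## Maximal stacked helix runs: list of c(i_start, i_end) on the 5' side,
## with partners pt[i_start] .. pt[i_end] descending contiguously.
helix_runs <- function(pt) {
  runs <- list()
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i) {
      nr <- length(runs)
      if (nr && runs[[nr]][2] == i - 1L && pt[i - 1L] == j + 1L)
        runs[[nr]][2] <- i
      else runs[[length(runs) + 1L]] <- c(i, i)
    }
  }
  runs
}
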
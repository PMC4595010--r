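## Folding: base-pair maximization (surrogate energies) and minimum free
## energy under the packaged nearest-neighbour model, plus the shared
## R-side structure evaluator used as the folder's self-consistency check.

#' Fold by base-pair maximization
#'
#' Dynamic programme maximizing the number of nested base pairs (allowed
#' pairs au, ua, gc, cg, gu, ug; minimum hairpin loop 3 nt).  The reported
#' energy is \code{-1.0 * pair count} in surrogate units, so "lower energy"
#' still means "better structure" when this folder is used as a fast oracle.
#'
#' @param residues RNA sequence (normalized internally).
#' @return A [SecondaryStructure-class]; energy in surrogate units.
#' @examples
#' foldMaxPair("gggaaaccc")
#' @export
foldMaxPair <- function(residues) {
  s <- normalizeRNA(residues)
  stopifnot(nchar(s) >= 1)
  pt <- .nussinov_cpp(seq_to_int(s))
  new("SecondaryStructure", dotbracket = dotBracketFromPairTable(pt),
      pairTable = as.integer(pt), energy = -sum(pt > 0) / 2)
}

#' Fold to the minimum-free-energy structure
#'
#' Zuker-style dynamic programme over the packaged nearest-neighbour
#' parameters (see [energyParameters()] for the exact model): nested
#' structures only, minimum hairpin loop 3 nt, two-sided loops up to 30
#' unpaired nt, affine multiloop cost.  The reported energy always equals
#' [evaluateEnergy()] applied to the returned structure.
#'
#' @param residues RNA sequence.
#' @param params parameter set from [energyParameters()].
#' @return A [SecondaryStructure-class] with energy in kcal/mol (0 for the
#'   open chain).
#' @examples
#' foldMFE("gggcgcaaagcgccc")
#' @export
foldMFE <- function(residues, params = energyParameters()) {
  s <- normalizeRNA(residues)
  stopifnot(nchar(s) >= 1)
  res <- .zuker_cpp(seq_to_int(s), params$stack, params$loops, params$misc)
  new("SecondaryStructure", dotbracket = dotBracketFromPairTable(res$pairs),
      pairTable = as.integer(res$pairs), energy = res$energy)
}

#' Evaluate the free energy of a given structure
#'
#' Loop-decomposition evaluator over the same tables as [foldMFE()]: stacking
#' terms for adjacent pairs, length penalties for hairpin/bulge/internal
#' loops (Ninio asymmetry for internal loops), an affine multiloop term, and
#' a terminal AU/GU penalty at each helix end (charged at every non-stack
#' loop and at exterior branches).  The open chain scores 0.
#'
#' @param residues RNA sequence.
#' @param structure dot-bracket string or [SecondaryStructure-class]; must
#'   match the sequence length, and paired bases must be pairable.
#' @param params parameter set from [energyParameters()].
#' @return Energy in kcal/mol.
#' @examples
#' evaluateEnergy("gggcaaaccc", "(((....)))")
#' @export
evaluateEnergy <- function(residues, structure, params = energyParameters()) {
  s <- normalizeRNA(residues)
  db <- if (is(structure, "SecondaryStructure")) structure@dotbracket
        else structure
  if (nchar(db) != nchar(s))
    stop("structure length (", nchar(db), ") does not match sequence length (",
         nchar(s), ")")
  pt <- if (is(structure, "SecondaryStructure")) structure@pairTable
        else pairTableFromDotBracket(db)
  ch <- strsplit(s, "")[[1]]
  misc <- params$misc
  E <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j <= i) next
    t1 <- pair_type(ch[i], ch[j])
    if (is.na(t1))
      stop("non-pairable bases ", ch[i], ":", ch[j], " paired at (", i, ",",
           j, ")")
    inner <- toplevel_pairs(pt, i + 1L, j - 1L)
    if (!length(inner)) {
      E <- E + loop_penalty(params$loops, misc, "hairpin", j - i - 1L) +
        terminal_au(misc, t1)
    } else if (length(inner) == 1L) {
      k <- inner[[1]][1]; l <- inner[[1]][2]
      t2 <- pair_type(ch[k], ch[l])
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        E <- E + params$stack[t1, t2]
      } else if (l1 == 0L || l2 == 0L) {
        E <- E + loop_penalty(params$loops, misc, "bulge", l1 + l2) +
          terminal_au(misc, t1) + terminal_au(misc, t2)
      } else {
        E <- E + loop_penalty(params$loops, misc, "internal", l1 + l2) +
          min(misc[["ninio_max"]], misc[["ninio_per_nt"]] * abs(l1 - l2)) +
          terminal_au(misc, t1) + terminal_au(misc, t2)
      }
    } else {
      branch_au <- sum(vapply(inner, function(p)
        terminal_au(misc, pair_type(ch[p[1]], ch[p[2]])), numeric(1)))
      unpaired <- (j - i - 1L) - sum(vapply(inner, function(p)
        p[2] - p[1] + 1L, integer(1)))
      E <- E + misc[["ml_init"]] + misc[["ml_branch"]] * (length(inner) + 1L) +
        misc[["ml_unpaired"]] * unpaired + terminal_au(misc, t1) + branch_au
    }
  }
  for (p in toplevel_pairs(pt, 1L, length(pt)))
    E <- E + terminal_au(misc, pair_type(ch[p[1]], ch[p[2]]))
  unname(E)
}
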
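## Nearest-neighbour thermodynamic parameters, shipped as plain-text tables
## under inst/extdata (Turner 2004 stacking and loop-length values).  The
## same tables drive the MFE folder (src/fold.cpp), the R-side structure
## evaluator and the duplex energy, so all three share one source.

.param_cache <- new.env(parent = emptyenv())

PAIR_TYPES <- c("au", "ua", "gc", "cg", "gu", "ug")

#' Nearest-neighbour energy parameter set
#'
#' Loads the packaged stacking-energy and loop-penalty tables (kcal/mol at
#' 37 degrees C).  The model comprises: 6x6 stacking energies over
#' Watson-Crick and G:U pairs; hairpin, bulge and internal-loop penalties by
#' loop length (1-30 nt, Jacobson-Stockmayer extrapolation beyond 30); Ninio
#' asymmetry for internal loops; an affine multiloop term; a terminal AU/GU
#' penalty per helix end; and a duplex initiation penalty.  Terminal
#' mismatches, dangling ends, special tetraloops and coaxial stacking are
#' deliberately excluded, so energies are systematically milder than mfold
#' or ViennaRNA values; all package thresholds are calibrated to this model.
#'
#' @return A list with elements \code{stack} (6x6 matrix, rows = outer pair,
#'   columns = inner pair, in order au, ua, gc, cg, gu, ug), \code{loops}
#'   (31 x 3 matrix: hairpin, bulge, internal by loop size 0-30) and
#'   \code{misc} (named numeric vector of the scalar terms).
#' @examples
#' p <- energyParameters()
#' p$stack["gc", "cg"]
#' @export
energyParameters <- function() {
  if (!is.null(.param_cache$params)) return(.param_cache$params)
  ext <- function(f) system.file("extdata", f, package = "miRquarry",
                                 mustWork = TRUE)
  st <- read.delim(ext("nn_stack.tsv"), stringsAsFactors = FALSE)
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(st$outer, st$inner)] <- st$dG
  lo <- read.delim(ext("nn_loops.tsv"), stringsAsFactors = FALSE)
  loops <- as.matrix(lo[, c("hairpin", "bulge", "internal")])
  rownames(loops) <- lo$size
  mi <- read.delim(ext("nn_misc.tsv"), stringsAsFactors = FALSE)
  misc <- setNames(mi$value, mi$param)
  params <- list(stack = stack, loops = loops, misc = misc)
  .param_cache$params <- params
  params
}

pair_type <- function(x, y) {
  t <- paste0(x, y)
  ifelse(t %in% PAIR_TYPES, t, NA_character_)
}

## loop-length penalty with extrapolation beyond table end
loop_penalty <- function(tab, misc, kind, len) {
  if (len <= 30) return(tab[len + 1L, kind])
  tab[31L, kind] + misc[["loop_extrapolation"]] * misc[["rt"]] * log(len / 30)
}

terminal_au <- function(misc, type) {
  if (is.na(type)) return(0)
  if (type %in% c("au", "ua", "gu", "ug")) misc[["terminal_au"]] else 0
}
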
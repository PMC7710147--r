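# Versioned physical-constant tables. Values are standard 6-decimal
# monoisotopic masses; tests rely on them being bit-stable, so never
# recompute these at run time.

#' Monoisotopic residue masses (Da)
#'
#' Named vector of monoisotopic masses for the 20 canonical amino acid
#' residues. `X` has no defined mass; mass operations on `X`-containing
#' peptides raise an error.
#'
#' @format Named numeric vector, 6-decimal precision.
#' @export
AA_MONO <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Modification mass deltas (Da)
#'
#' Named monoisotopic deltas for the modifications handled by the pipeline.
#' `Hyp` is hydroxyproline (+15.994915, abundant in collagen and itself a
#' cleavage site for the protease), `Phospho` is +79.966331 on S/T/Y and
#' `Carbamidomethyl` (+57.021464 on Cys) is the usual alkylation fixed
#' modification, deliberately absent from nonreduced disulfide digests.
#'
#' @format Named numeric vector.
#' @export
MOD_DELTAS <- c(
  Carbamidomethyl = 57.021464,
  Hyp             = 15.994915,
  Oxidation       = 15.994915,
  Phospho         = 79.966331,
  Acetyl          = 42.010565
)

#' @rdname mass_constants
#' @export
WATER_MONO <- 18.010565

#' Mass constants
#'
#' `WATER_MONO`: monoisotopic mass of water, added once per peptide.
#' `PROTON_MASS`: mass used for m/z to neutral-mass conversion.
#' `HYDROGEN_MONO`: monoisotopic hydrogen; each disulfide bond removes two.
#' `DISULFIDE_DELTA`: mass removed per disulfide bond (2 x H).
#'
#' @name mass_constants
#' @export
PROTON_MASS <- 1.0072765

#' @rdname mass_constants
#' @export
HYDROGEN_MONO <- 1.0078250

#' @rdname mass_constants
#' @export
DISULFIDE_DELTA <- 2 * HYDROGEN_MONO  # 2.015650

#' Human-like background residue frequencies
#'
#' Average residue composition of a well-annotated vertebrate proteome,
#' normalized to sum to 1. Used as the default composition for synthetic
#' proteomes and as the default background for motif enrichment.
#'
#' @format Named numeric vector over the 20 canonical residues.
#' @export
AA_BACKGROUND <- local({
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
         Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
         L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.70,
         S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)
  f / sum(f)
})

# Allowed sequence alphabet: 20 canonical residues plus X (unknown).
AA_ALPHABET <- c(names(AA_MONO), "X")

# Basophilic residue set used by the default cleavage-context modifiers.
BASOPHILIC <- c("K", "R", "H")

GAP_CHAR <- "-"
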
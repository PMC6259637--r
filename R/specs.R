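# Element parameters and ligand topologies for the supported chelate systems.

# First-row bivalent transition metals of the Irving-Williams series with
# experimental data. Zv is the valence-electron count of the NEUTRAL atom
# (3d + 4s), deliberately not adjusted for the 2+ oxidation state; this
# convention is what the connectivity indices are calibrated on.
.metal_table <- data.frame(
  symbol = c("Mn", "Fe", "Co", "Ni", "Cu"),
  Z      = c(25L, 26L, 27L, 28L, 29L),
  Zv     = c(7L, 8L, 9L, 10L, 11L),
  stringsAsFactors = FALSE
)

# Side-chain heavy atoms of each amino acid, attached to the alpha carbon.
# `parent` indexes within the side chain (0 = alpha carbon itself); `nH` is
# the implicit hydrogen count of that carbon.
#   glycine  -H                 (no side-chain heavy atoms)
#   alanine  -CH3
#   valine   -CH(CH3)2
#   leucine  -CH2-CH(CH3)2
.side_chains <- list(
  glycine = data.frame(parent = integer(0), nH = integer(0)),
  alanine = data.frame(parent = 0L, nH = 3L),
  valine  = data.frame(parent = c(0L, 1L, 1L), nH = c(1L, 3L, 3L)),
  leucine = data.frame(parent = c(0L, 1L, 2L, 2L), nH = c(2L, 1L, 3L, 3L))
)

#' Supported metals and ligands
#'
#' The package covers the bivalent first-row transition metals for which the
#' Irving-Williams series has experimental amino-acid chelate data (Zn
#' carries no data and is excluded), and the four aliphatic alpha-amino
#' acids used as ligands.
#'
#' @return Character vector of element symbols / ligand names.
#' @export
supported_metals <- function() .metal_table$symbol

#' @rdname supported_metals
#' @export
supported_ligands <- function() names(.side_chains)

#' Metal atom parameters
#'
#' Returns the atomic number \eqn{Z} and neutral-atom valence-electron count
#' \eqn{Z^v} (3d + 4s electrons) used as vertex weights for a supported
#' metal. These feed the Kier-Hall valence delta
#' \eqn{\delta^v = (Z^v - H)/(Z - Z^v - 1)}.
#'
#' @param symbol Element symbol, one of `supported_metals()`.
#' @return A list with components `symbol`, `Z` and `Zv`.
#' @examples
#' metal_spec("Ni")  # Z = 28, Zv = 10
#' @export
metal_spec <- function(symbol) {
  i <- match(symbol, .metal_table$symbol)
  if (length(symbol) != 1L || is.na(i)) {
    stop("unsupported element: ", paste(symbol, collapse = ", "),
         "; supported metals are ",
         paste(.metal_table$symbol, collapse = ", "), call. = FALSE)
  }
  list(symbol = .metal_table$symbol[i],
       Z = .metal_table$Z[i],
       Zv = .metal_table$Zv[i])
}

#' Amino-acid ligand topology
#'
#' Describes the heavy-atom skeleton of a supported alpha-amino acid as it
#' appears in the chelate: the fixed glycinate-like backbone (amino N, alpha
#' C, carboxyl C, coordinating carboxylate O, pendant carbonyl O) plus the
#' aliphatic side chain attached to the alpha carbon.
#'
#' @param name Ligand name, one of `supported_ligands()`.
#' @return A list with components `name`, `alpha_nH` (hydrogens on the alpha
#'   carbon: 2 for glycine, otherwise 1) and `side_chain` (a data frame with
#'   columns `parent` — 0 for the alpha carbon, otherwise the index of an
#'   earlier side-chain atom — and `nH`).
#' @export
amino_acid_spec <- function(name) {
  if (length(name) != 1L || !name %in% names(.side_chains)) {
    stop("unsupported ligand: ", paste(name, collapse = ", "),
         "; supported ligands are ",
         paste(names(.side_chains), collapse = ", "), call. = FALSE)
  }
  list(name = name,
       alpha_nH = if (name == "glycine") 2L else 1L,
       side_chain = .side_chains[[name]])
}
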
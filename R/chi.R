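# Valence connectivity indices by exhaustive simple-path enumeration.

#' Kier-Hall valence delta of a vertex
#'
#' The valence vertex weight
#' \deqn{\delta^v = \frac{Z^v - H}{Z - Z^v - 1}}
#' where \eqn{Z^v} is the valence-electron count, \eqn{Z} the atomic number
#' and \eqn{H} the number of attached hydrogens. For second-row atoms the
#' denominator is 1, so \eqn{\delta^v} reduces to \eqn{Z^v - H}: 1-4 for
#' primary through quaternary carbon, 3 for an NH2 nitrogen, 5 for a
#' hydroxyl oxygen. For the supported metals the neutral-atom \eqn{Z^v}
#' gives \eqn{\delta^v = Z^v/17} (e.g. 10/17 for Ni), which decreases from
#' Cu to Mn and drives the metal ordering of the indices.
#'
#' @param Z Atomic number(s), or a `"complex_graph"` whose vertices to
#'   weight.
#' @param Zv Valence-electron count(s).
#' @param nH Attached-hydrogen count(s).
#' @return Numeric vector of strictly positive vertex weights.
#' @examples
#' valence_delta(8, 6, 1)   # hydroxyl O: 5
#' valence_delta(7, 5, 2)   # NH2 N: 3
#' valence_delta(28, 10, 0) # Ni: 10/17
#' @export
valence_delta <- function(Z, Zv = NULL, nH = NULL) {
  if (inherits(Z, "complex_graph")) {
    v <- Z$vertices
    Z <- v$Z; Zv <- v$Zv; nH <- v$nH
  }
  num <- Zv - nH
  den <- Z - Zv - 1
  if (any(num <= 0)) {
    stop("vertex with Zv - nH <= 0: valence delta undefined", call. = FALSE)
  }
  if (any(den <= 0)) {
    stop("vertex with Z - Zv - 1 <= 0: unsupported element for valence ",
         "delta", call. = FALSE)
  }
  num / den
}

#' Enumerate all simple paths of a given length
#'
#' Exhaustively lists the simple paths (all vertices distinct) of `n` edges
#' in an undirected graph, each undirected path exactly once, in canonical
#' orientation (the lexicographically smaller endpoint first) and sorted
#' lexicographically, so the result is independent of how the graph's edges
#' were entered.
#'
#' @param g A `"complex_graph"` (any vertex-weighted simple graph works).
#' @param n Path length in edges, `n >= 1`.
#' @return Integer matrix with one path per row and `n + 1` columns of
#'   vertex ids; zero rows if no such path exists.
#' @examples
#' g <- complex_graph("Ni", "glycine", "mono")
#' nrow(enumerate_paths(g, 3))  # 11 paths of length 3
#' @export
enumerate_paths <- function(g, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("path length n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  nv <- nrow(g$vertices)
  adj <- adjacency_list(g)
  paths <- vector("list", 0L)
  # depth-first extension of partial paths; vertices kept distinct
  extend <- function(path, used) {
    if (length(path) == n + 1L) {
      if (path[1L] < path[n + 1L]) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[path[length(path)]]]) {
      if (!used[w]) {
        used[w] <- TRUE
        extend(c(path, w), used)
        used[w] <- FALSE
      }
    }
  }
  for (v in seq_len(nv)) {
    used <- logical(nv)
    used[v] <- TRUE
    extend(v, used)
  }
  if (!length(paths)) return(matrix(integer(0), ncol = n + 1L))
  m <- do.call(rbind, paths)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Valence molecular connectivity index of order n
#'
#' Computes
#' \deqn{{}^{n}\chi^{v} = \sum_{\mathrm{paths}}
#'   \left( \prod_{i \in \mathrm{path}} \delta^v_i \right)^{-1/2}}
#' the sum running over every simple path of `n` edges of the
#' vertex-weighted graph ([enumerate_paths()]), with vertex weights from
#' [valence_delta()]. The default third order — paths of three consecutive
#' bonds — is the descriptor on which the chelate stability models are
#' built.
#'
#' @inheritParams enumerate_paths
#' @param n Path length in edges (default 3).
#' @return A positive number (dimensionless).
#' @examples
#' chi_v(complex_graph("Ni", "glycine", "mono"))  # 1.90 to 2 decimals
#' @export
chi_v <- function(g, n = 3) {
  delta <- valence_delta(g)
  paths <- enumerate_paths(g, n)
  if (!nrow(paths)) return(0)
  sum(apply(paths, 1L, function(p) 1 / sqrt(prod(delta[p]))))
}

#' Connectivity indices for every metal-ligand pair
#'
#' Builds the mono and bis aqua-complex graphs for the cross product of the
#' requested metals and ligands and computes their third-order valence
#' connectivity indices. Pairs without experimental stability constants
#' (e.g. Ni/valine) are included: the Ni row of each ligand is the
#' normalisation reference of the regression models.
#'
#' @param metals,ligands Character vectors of supported metals / ligands.
#' @param n Path length passed to [chi_v()].
#' @return A data frame with columns `metal`, `ligand`, `chi_mono`,
#'   `chi_bis`, one row per pair, in the given order.
#' @export
chi_table <- function(metals = supported_metals(),
                      ligands = supported_ligands(), n = 3) {
  grid <- expand.grid(metal = metals, ligand = ligands,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$chi_mono <- mapply(function(m, l) chi_v(complex_graph(m, l, "mono"), n),
                          grid$metal, grid$ligand)
  grid$chi_bis <- mapply(function(m, l) chi_v(complex_graph(m, l, "bis"), n),
                         grid$metal, grid$ligand)
  grid
}

# single chi lookup with a clear failure mode
chi_lookup <- function(chi, metal, ligand, species) {
  col <- if (species == "mono") "chi_mono" else "chi_bis"
  i <- which(chi$metal == metal & chi$ligand == ligand)
  if (length(i) != 1L) {
    stop("no chi entry for ", metal, "/", ligand, call. = FALSE)
  }
  chi[[col]][i]
}
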
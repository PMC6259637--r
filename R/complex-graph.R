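# Vertex-weighted heavy-atom graphs of the metal(II) amino-acid aqua
# complexes.
#
# Conventions (they are what the connectivity indices are calibrated on):
#  * hydrogen-depleted simple graph: H atoms live only in the per-vertex nH
#    count, bond orders and charges are ignored, coordination bonds are
#    ordinary edges;
#  * the amino acid is an N,O-chelator: the metal binds the amino N and ONE
#    carboxylate oxygen, the second oxygen stays a pendant carbonyl vertex,
#    closing the five-membered ring M-N-Ca-C-O;
#  * remaining coordination sites carry water: the metal is tetracoordinate
#    in the mono complex (N, O, 2 x OH2) and hexacoordinate in the bis
#    complex (2 x N, 2 x O, 2 x OH2); each water O has nH = 2;
#  * deterministic vertex numbering: metal = 1, then per ligand the backbone
#    N, Ca, C(carboxyl), O(coordinating), O(carbonyl) followed by the side
#    chain outward from Ca, then the water oxygens last.

#' Build the graph of a metal(II) amino-acid aqua complex
#'
#' Constructs the vertex-weighted, hydrogen-depleted graph of the mono
#' (\eqn{MB}) or bis (\eqn{MB_2}) chelate of a bivalent transition metal
#' with an aliphatic alpha-amino acid, with the free coordination sites
#' filled by water (two molecules in either species). Each vertex carries
#' the element symbol, atomic number \eqn{Z}, valence-electron count
#' \eqn{Z^v} and attached-hydrogen count used by [valence_delta()].
#'
#' @param metal Element symbol (see [supported_metals()]) or a list as
#'   returned by [metal_spec()].
#' @param ligand Amino-acid name (see [supported_ligands()]) or a list as
#'   returned by [amino_acid_spec()].
#' @param species `"mono"` (one chelate ring, metal degree 4) or `"bis"`
#'   (two rings, metal degree 6).
#' @return An object of class `"complex_graph"`: a list with `vertices` (a
#'   data frame with columns `id`, `element`, `Z`, `Zv`, `nH`), `edges` (a
#'   two-column integer matrix of unordered vertex-id pairs), `species` and
#'   `label`.
#' @examples
#' g <- complex_graph("Ni", "glycine", "mono")
#' g                        # 8 vertices, 8 edges, metal degree 4
#' chi_v(g)                 # third-order valence connectivity index
#' @export
complex_graph <- function(metal, ligand, species = c("mono", "bis")) {
  species <- match.arg(species)
  if (is.character(metal)) metal <- metal_spec(metal)
  if (is.character(ligand)) ligand <- amino_acid_spec(ligand)

  vert <- data.frame(id = 1L, element = metal$symbol, Z = metal$Z,
                     Zv = metal$Zv, nH = 0L, stringsAsFactors = FALSE)
  edges <- matrix(integer(0), ncol = 2L)
  add_vertex <- function(element, Z, Zv, nH) {
    vert <<- rbind(vert, data.frame(id = nrow(vert) + 1L, element = element,
                                    Z = Z, Zv = Zv, nH = as.integer(nH),
                                    stringsAsFactors = FALSE))
    nrow(vert)
  }
  add_edge <- function(i, j) edges <<- rbind(edges, c(min(i, j), max(i, j)))

  n_ligands <- if (species == "mono") 1L else 2L
  for (k in seq_len(n_ligands)) {
    n_amino <- add_vertex("N", 7L, 5L, 2L)
    c_alpha <- add_vertex("C", 6L, 4L, ligand$alpha_nH)
    c_acid  <- add_vertex("C", 6L, 4L, 0L)
    o_coord <- add_vertex("O", 8L, 6L, 0L)
    o_keto  <- add_vertex("O", 8L, 6L, 0L)
    add_edge(1L, n_amino)
    add_edge(1L, o_coord)          # closes the chelate ring M-N-Ca-C-O
    add_edge(n_amino, c_alpha)
    add_edge(c_alpha, c_acid)
    add_edge(c_acid, o_coord)
    add_edge(c_acid, o_keto)
    chain <- c_alpha               # side-chain parents, 0 = alpha carbon
    sc <- ligand$side_chain
    for (s in seq_len(nrow(sc))) {
      v <- add_vertex("C", 6L, 4L, sc$nH[s])
      add_edge(chain[sc$parent[s] + 1L], v)
      chain <- c(chain, v)
    }
  }
  for (w in 1:2) add_edge(1L, add_vertex("O", 8L, 6L, 2L))

  rownames(vert) <- NULL
  structure(list(vertices = vert, edges = edges, species = species,
                 label = sprintf("%s(%s)%s aqua complex", metal$symbol,
                                 ligand$name,
                                 if (species == "bis") "2" else "")),
            class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  deg <- vertex_degrees(x)
  cat(sprintf("<complex_graph> %s\n", x$label))
  cat(sprintf("  %d heavy-atom vertices, %d edges, metal degree %d\n",
              nrow(x$vertices), nrow(x$edges), deg[1L]))
  comp <- table(x$vertices$element)
  cat("  composition:",
      paste(sprintf("%s%d", names(comp), comp), collapse = " "), "\n")
  invisible(x)
}

vertex_degrees <- function(g) {
  tabulate(g$edges, nbins = nrow(g$vertices))
}

adjacency_list <- function(g) {
  nv <- nrow(g$vertices)
  adj <- rep(list(integer(0)), nv)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1L]; j <- g$edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Check the structural invariants of a complex graph
#'
#' Reports (never throws) violations of the invariants every chelate graph
#' must satisfy: simple undirected graph (no loops or duplicate edges),
#' connected, valid vertex weights, and — when the species is declared —
#' metal coordination number 4 (mono) or 6 (bis).
#'
#' @param g A `"complex_graph"` (or any list with the same fields).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_graph <- function(g) {
  out <- character(0)
  v <- g$vertices
  nv <- nrow(v)
  e <- g$edges
  if (any(e < 1L) || any(e > nv)) {
    return("edge endpoint outside vertex range")
  }
  if (any(e[, 1L] == e[, 2L])) out <- c(out, "self-loop present")
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  if (anyDuplicated(key)) out <- c(out, "duplicate (multi-)edge present")
  if (any(v$nH < 0L)) out <- c(out, "negative hydrogen count")
  if (any(v$nH > v$Zv)) out <- c(out, "more hydrogens than valence electrons")
  if (any(v$Z - v$Zv - 1L < 0L)) {
    out <- c(out, "vertex with Z - Zv - 1 < 0 (valence delta undefined)")
  }
  # connectivity by breadth-first search from vertex 1
  if (nv > 0L) {
    adj <- adjacency_list(g)
    seen <- logical(nv); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      nb <- unique(unlist(adj[queue]))
      queue <- nb[!seen[nb]]
      seen[queue] <- TRUE
    }
    if (!all(seen)) out <- c(out, "graph is not connected")
  }
  if (!is.null(g$species)) {
    want <- if (g$species == "mono") 4L else 6L
    if (vertex_degrees(g)[1L] != want) {
      out <- c(out, sprintf("metal degree %d but %s complex requires %d",
                            vertex_degrees(g)[1L], g$species, want))
    }
  }
  out
}

#' Plain-text adjacency-list serialisation of a complex graph
#'
#' The dialect is line-oriented: a header `#vertices <n>`, then one line
#' `id element Z Zv nH` per vertex, a `#edges` marker, then one `i j` line
#' per edge. Comment lines outside the two sections are ignored. The format
#' round-trips [complex_graph()] objects byte-identically and is the entry
#' point for user-supplied graphs.
#'
#' @param g A `"complex_graph"`.
#' @param file Path to write to / read from.
#' @param species Declared coordination species of the graph being read
#'   (`"mono"`, `"bis"`, or `NA` to skip the metal-degree check).
#' @return `write_graph_adjlist()` returns `file` invisibly;
#'   `read_graph_adjlist()` returns a `"complex_graph"`.
#' @export
write_graph_adjlist <- function(g, file) {
  v <- g$vertices
  lines <- c(sprintf("# %s", g$label),
             sprintf("#vertices %d", nrow(v)),
             sprintf("%d %s %d %d %d", v$id, v$element, v$Z, v$Zv, v$nH),
             "#edges",
             sprintf("%d %d", g$edges[, 1L], g$edges[, 2L]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_graph_adjlist
#' @export
read_graph_adjlist <- function(file, species = NA_character_) {
  lines <- trimws(readLines(file))
  hv <- grep("^#vertices", lines)
  he <- grep("^#edges", lines)
  if (length(hv) != 1L || length(he) != 1L || he < hv) {
    stop("malformed adjacency-list file: ", file, call. = FALSE)
  }
  nv <- as.integer(sub("^#vertices\\s+", "", lines[hv]))
  vlines <- lines[(hv + 1L):(he - 1L)]
  vlines <- vlines[nzchar(vlines) & !startsWith(vlines, "#")]
  if (length(vlines) != nv) {
    stop("expected ", nv, " vertex lines, found ", length(vlines),
         call. = FALSE)
  }
  vf <- do.call(rbind, strsplit(vlines, "\\s+"))
  vert <- data.frame(id = as.integer(vf[, 1L]), element = vf[, 2L],
                     Z = as.integer(vf[, 3L]), Zv = as.integer(vf[, 4L]),
                     nH = as.integer(vf[, 5L]), stringsAsFactors = FALSE)
  elines <- if (he < length(lines)) lines[(he + 1L):length(lines)] else character(0)
  elines <- elines[nzchar(elines) & !startsWith(elines, "#")]
  ef <- do.call(rbind, strsplit(elines, "\\s+"))
  edges <- cbind(as.integer(ef[, 1L]), as.integer(ef[, 2L]))
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  structure(list(vertices = vert, edges = edges,
                 species = if (is.na(species)) NULL else species,
                 label = basename(file)),
            class = "complex_graph")
}
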
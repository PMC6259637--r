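# Shared helpers: hand-built graphs, a random-graph generator and an
# independent brute-force path/chi oracle for property tests.

# minimal graph object compatible with enumerate_paths()/chi_v()
make_graph <- function(edges, Z = 6L, Zv = 4L, nH = 3L, nv = max(edges)) {
  structure(list(
    vertices = data.frame(id = seq_len(nv),
                          element = rep("C", nv),
                          Z = rep(as.integer(Z), nv),
                          Zv = rep(as.integer(Zv), nv),
                          nH = rep(as.integer(nH), nv),
                          stringsAsFactors = FALSE),
    edges = cbind(pmin(edges[, 1L], edges[, 2L]),
                  pmax(edges[, 1L], edges[, 2L])),
    species = NULL, label = "test graph"),
    class = "complex_graph")
}

path_graph <- function(nv) make_graph(cbind(1:(nv - 1L), 2:nv))
triangle_graph <- function() make_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))

# random connected simple graph on nv <= 10 vertices with chemically valid
# vertex weights (uses the session RNG; tests set the seed)
random_graph <- function(nv) {
  # random spanning tree, then a few extra edges
  edges <- cbind(2:nv, vapply(2:nv, function(v) sample.int(v - 1L, 1L), 1L))
  all_pairs <- t(combn(nv, 2L))
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  pool <- all_pairs[!paste(all_pairs[, 1L], all_pairs[, 2L]) %in% key, ,
                    drop = FALSE]
  n_extra <- sample.int(min(4L, nrow(pool) + 1L), 1L) - 1L
  if (n_extra > 0L) {
    edges <- rbind(edges, pool[sample.int(nrow(pool), n_extra), ,
                               drop = FALSE])
  }
  g <- make_graph(edges, nv = nv)
  # heteroatom mix: C/N/O with random hydrogen counts keeping deltas valid
  elems <- sample(c("C", "N", "O"), nv, replace = TRUE)
  g$vertices$element <- elems
  g$vertices$Z <- c(C = 6L, N = 7L, O = 8L)[elems]
  g$vertices$Zv <- c(C = 4L, N = 5L, O = 6L)[elems]
  g$vertices$nH <- vapply(g$vertices$Zv, function(zv)
    sample.int(zv, 1L) - 1L, 1L)  # 0 .. Zv-1 keeps Zv - nH >= 1
  g
}

# Independent oracle: test every ordered (n+1)-tuple of distinct vertices
# for path-ness against the edge set, then deduplicate orientations.
oracle_paths <- function(g, n) {
  nv <- nrow(g$vertices)
  ekey <- paste(g$edges[, 1L], g$edges[, 2L])
  is_edge <- function(i, j) paste(min(i, j), max(i, j)) %in% ekey
  tuples <- as.matrix(expand.grid(rep(list(seq_len(nv)), n + 1L)))
  keep <- apply(tuples, 1L, function(tp) {
    length(unique(tp)) == n + 1L && tp[1L] < tp[n + 1L] &&
      all(vapply(seq_len(n), function(k) is_edge(tp[k], tp[k + 1L]), TRUE))
  })
  m <- tuples[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

oracle_chi <- function(g, n) {
  d <- valence_delta(g)
  p <- oracle_paths(g, n)
  if (!nrow(p)) return(0)
  sum(apply(p, 1L, function(row) 1 / sqrt(prod(d[row]))))
}

# relabel the vertices of a graph by a permutation
relabel_graph <- function(g, perm) {
  inv <- order(perm)  # perm[i] = new id of old vertex i
  v <- g$vertices[inv, ]
  v$id <- seq_len(nrow(v))
  rownames(v) <- NULL
  e <- cbind(perm[g$edges[, 1L]], perm[g$edges[, 2L]])
  g$vertices <- v
  g$edges <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  g
}
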
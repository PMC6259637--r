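test_that("mono complex graphs have the expected size and coordination", {
  g <- complex_graph("Ni", "glycine", "mono")
  expect_equal(nrow(g$vertices), 8L)   # M, N, Ca, C, 2 O, 2 water O
  expect_equal(nrow(g$edges), 8L)      # one ring closes: V = E
  deg <- tabulate(g$edges, nrow(g$vertices))
  expect_equal(deg[1L], 4L)            # tetracoordinate metal
  expect_equal(nrow(complex_graph("Ni", "leucine", "mono")$vertices), 12L)
  expect_error(complex_graph("Zn", "glycine"), "unsupported element")
  expect_error(complex_graph("Ni", "serine"), "unsupported ligand")
})

test_that("bis complex graphs have two chelate rings and six-fold metal", {
  g <- complex_graph("Ni", "glycine", "bis")
  expect_equal(nrow(g$vertices), 13L)  # M + 2x5 ligand atoms + 2 water O
  expect_equal(nrow(g$edges), 14L)     # 6 metal bonds + 2x4 ligand bonds
  expect_equal(tabulate(g$edges, 13L)[1L], 6L)
  # valine contributes three side-chain carbons per ligand
  expect_equal(nrow(complex_graph("Co", "valine", "bis")$vertices), 19L)
})

test_that("hydrogen bookkeeping matches the structures", {
  ca_nH <- function(lig) {
    v <- complex_graph("Ni", lig, "mono")$vertices
    v$nH[3L]  # canonical order: metal, N, Ca, ...
  }
  expect_equal(ca_nH("glycine"), 2L)
  expect_equal(ca_nH("alanine"), 1L)
  for (lig in supported_ligands()) {
    g <- complex_graph("Fe", lig, "bis")
    v <- g$vertices
    deg <- tabulate(g$edges, nrow(v))
    # sp3 carbons are tetravalent; the carboxyl carbon (two O neighbours)
    # loses one connection because C=O collapses to a single graph edge
    carbons <- which(v$element == "C")
    n_oxy <- vapply(carbons, function(i) {
      nb <- c(g$edges[g$edges[, 1L] == i, 2L], g$edges[g$edges[, 2L] == i, 1L])
      sum(v$element[nb] == "O")
    }, 0L)
    expect_true(all((deg + v$nH)[carbons[n_oxy == 2L]] == 3L))
    expect_true(all((deg + v$nH)[carbons[n_oxy < 2L]] == 4L))
    waters <- which(v$element == "O" & v$nH == 2L)
    expect_equal(length(waters), 2L)
    expect_true(all(deg[waters] == 1L))
  }
})

test_that("graph topology depends on the ligand only, never the metal", {
  for (lig in supported_ligands()) {
    for (sp in c("mono", "bis")) {
      gs <- lapply(supported_metals(), complex_graph, ligand = lig,
                   species = sp)
      shapes <- lapply(gs, function(g)
        list(nv = nrow(g$vertices), ne = nrow(g$edges),
             deg = sort(tabulate(g$edges, nrow(g$vertices))),
             edges = g$edges))
      for (s in shapes[-1L]) expect_identical(s, shapes[[1L]])
    }
  }
})

test_that("validate_graph reports violations without throwing", {
  g <- complex_graph("Cu", "alanine", "mono")
  expect_identical(validate_graph(g), character(0))

  five <- g
  five$edges <- rbind(five$edges, c(1L, 6L))  # extra metal bond
  expect_match(validate_graph(five), "metal degree 5", all = FALSE)

  disco <- g
  disco$edges <- disco$edges[-c(1L, 2L), , drop = FALSE]
  expect_match(validate_graph(disco), "not connected", all = FALSE)

  loopy <- g
  loopy$edges <- rbind(loopy$edges, c(3L, 3L))
  expect_match(validate_graph(loopy), "self-loop", all = FALSE)
})

test_that("adjacency-list files round-trip graphs and their indices", {
  g <- complex_graph("Mn", "leucine", "bis")
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_graph_adjlist(g, tmp)
  g2 <- read_graph_adjlist(tmp, species = "bis")
  expect_identical(g2$vertices, g$vertices)
  expect_identical(g2$edges, g$edges)
  expect_identical(validate_graph(g2), character(0))
  expect_equal(chi_v(g2), chi_v(g))
})
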
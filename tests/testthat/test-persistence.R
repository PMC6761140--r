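test_that("tiny complexes reduce by hand", {
  # single weighted vertex: one essential component born at its weight
  cc1 <- buildCliqueComplex(fixtureGraph("K1"))
  d1 <- persistenceDiagram(criticalFiltration(cc1, 0.4), cc1)
  expect_equal(diagramPoints(d1),
               data.frame(dim = 0L, birth = 0.4, death = Inf, multiplicity = 1L))

  # one edge with two vertices: later vertex dies into the edge, one
  # essential component remains (sum rule: 2 pairs + 1 essential = 3)
  k2 <- buildCliqueComplex(fixtureGraph("K2"))
  f <- c(0.1, 0.25, 0.3)
  dg <- persistenceDiagram(fullFiltration(k2, f), k2)
  p <- diagramPoints(dg)
  expect_equal(p[is.infinite(p$death), c("dim", "birth")],
               data.frame(dim = 0L, birth = 0.1))
  expect_equal(p[is.finite(p$death), c("birth", "death")],
               data.frame(birth = 0.25, death = 0.3), ignore_attr = TRUE)
})

test_that("reduction pairing matches the dense GF(2) oracle on random complexes", {
  for (seed in 1:10) {
    g <- sampleER(15, 0.3, seed = seed)
    cc <- buildCliqueComplex(g)
    set.seed(seed)
    mf <- assignMorseFunction(cc, vertexFunction(g))
    flt <- fullFiltration(cc, mf)
    ord <- flt@order
    N <- nSimplices(cc)
    pos <- integer(N); pos[ord] <- seq_len(N)
    cols <- lapply(seq_len(N), function(t) {
      gid <- ord[t]
      if (simplexDims(cc)[gid] == 0L) integer(0) else sort(pos[simplexFacets(cc, gid)])
    })
    expect_identical(morseph:::reduce_boundary(cols), oracleReduce(cols))
    # sum rule before zero-persistence dropping
    partner <- oracleReduce(cols)
    expect_equal(2L * sum(partner > 0L) + sum(partner == 0L), N)
  }
})

test_that("Betti numbers match rank-nullity and component counting", {
  expect_equal(unname(morsePipeline(fixtureGraph("K3"))$beta), c(1L, 0L, 0L))
  expect_equal(unname(morsePipeline(fixtureGraph("C4"))$beta), c(1L, 1L))
  for (seed in 1:8) {
    g <- sampleER(30, 0.1, seed = seed)
    res <- morsePipeline(g, seed = seed)
    expect_equal(res$beta, oracleBetti(res$cc))
    expect_equal(res$beta[1L], igraph::components(g)$no)
  }
})

test_that("Euler characteristic is conserved across n, m and beta", {
  for (seed in 1:10) {
    res <- morsePipeline(randomTestGraph(seed + 40), seed = seed)
    alt <- function(v) sum(v * (-1)^(seq_along(v) - 1L))
    expect_equal(alt(res$np), alt(res$beta))
    expect_equal(alt(res$mp), alt(res$beta))
    expect_true(all(res$mp >= res$beta))   # Morse inequalities
  }
})

test_that("persistent Betti numbers count alive classes", {
  empty <- new("PersistenceDiagram",
               points = data.frame(dim = integer(0), birth = numeric(0),
                                   death = numeric(0), multiplicity = integer(0)),
               wN = 1, scheme = "critical", complexDim = 1L)
  expect_equal(unname(persistentBetti(empty, 0.2, 0.5)), c(0L, 0L))

  one <- new("PersistenceDiagram",
             points = data.frame(dim = 0L, birth = 0.1, death = 1.0, multiplicity = 1L),
             wN = 1, scheme = "critical", complexDim = 0L)
  expect_equal(unname(persistentBetti(one, 0.2, 0.5)), 1L)
  expect_error(persistentBetti(one, 0.6, 0.5), "wi")

  # random diagrams against a direct counting oracle
  res <- morsePipeline(sampleER(40, 0.12, seed = 3), seed = 4)
  p <- diagramPoints(res$dgm)
  qs <- quantile(p$birth, c(0.3, 0.7))
  got <- persistentBetti(res$dgm, qs[1], qs[2])
  for (q in 0:res$dgm@complexDim) {
    want <- sum(p$multiplicity[p$dim == q & p$birth <= qs[1] & p$death > qs[2]])
    expect_equal(unname(got[q + 1L]), as.integer(want))
  }
})

test_that("barcodes expand multiplicity and normalize essential deaths to 1", {
  res <- morsePipeline(sampleWS(40, 4, 0.3, seed = 6), seed = 7)
  bc <- barcode(res$dgm)
  p <- diagramPoints(res$dgm, normalized = TRUE)
  expect_equal(nrow(bc), sum(p$multiplicity))
  expect_true(all(bc$death <= 1 & bc$birth >= 0))
  ess <- p[!is.finite(diagramPoints(res$dgm)$death), ]
  expect_true(all(ess$death == 1))
  # round trip: re-aggregating the barcode recovers the diagram multiset
  key <- function(d, b, dd) sort(paste(d, sprintf("%.15g", b), sprintf("%.15g", dd)))
  expect_equal(key(bc$dim, bc$birth, bc$death),
               key(rep(p$dim, p$multiplicity), rep(p$birth, p$multiplicity),
                   rep(p$death, p$multiplicity)))
})

test_that("the 9-vertex fixture reproduces the canonical filtration story", {
  # two triangles, a pendant and a hub: across seeds, a second component is
  # born at the second critical weight and merges at the third, and the
  # independent cycle appears at the fourth (last) critical weight
  tt <- fixtureGraph("twoTriangles")
  for (seed in c(1, 7, 23)) {
    res <- morsePipeline(tt, seed = seed)
    expect_equal(unname(res$mp), c(2L, 2L, 0L))
    cw <- criticalWeights(res$crit)
    expect_equal(length(cw), 4L)
    p <- diagramPoints(res$dgm)
    h0 <- p[p$dim == 0L, ]
    expect_equal(sort(h0$birth), cw[1:2])     # components born at stages 1, 2
    expect_equal(h0$death[h0$birth == cw[2]], cw[3])  # merge at stage 3
    h1 <- p[p$dim == 1L, ]
    expect_equal(h1$birth, cw[4])             # 1-hole born at stage 4
    expect_true(is.infinite(h1$death))
    expect_equal(unname(res$beta), c(1L, 1L, 0L))
  }
})
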
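test_that("entry values take the minimum over the coface closure", {
  # injected weights on a single edge: the heavier vertex enters with the edge
  k2 <- buildCliqueComplex(fixtureGraph("K2"))
  # global order: a, b, {a b}
  f <- c(0.3, 0.2, 0.3)
  ev <- entryValues(k2, f)
  expect_equal(ev, c(0.3, 0.2, 0.3))
  expect_equal(entryValue(k2, f, "a"), 0.3)

  # simplices without proper cofaces keep their own weight
  cc <- buildCliqueComplex(fixtureGraph("C4"))
  set.seed(1)
  f2 <- morseValues(assignMorseFunction(cc, vertexFunction(fixtureGraph("C4"))))
  ev2 <- entryValues(cc, f2)
  top <- which(simplexDims(cc) == complexDim(cc))
  expect_equal(ev2[top], f2[top])

  # brute-force oracle on random complexes
  for (seed in c(21, 22)) {
    g <- sampleER(12, 0.4, seed = seed)
    ccr <- buildCliqueComplex(g)
    set.seed(seed)
    fr <- morseValues(assignMorseFunction(ccr, vertexFunction(g)))
    keys <- simplexKeys(ccr)
    evr <- entryValues(ccr, fr)
    for (id in seq_along(keys)) {
      verts <- strsplit(keys[id], " ")[[1L]]
      closure <- vapply(seq_along(keys), function(j)
        all(verts %in% strsplit(keys[j], " ")[[1L]]), logical(1))
      expect_equal(evr[id], min(fr[closure]))
    }
  }
})

test_that("the critical filtration snaps weights onto the critical subsequence", {
  # two-vertex edge with injected weights: pairing e <-> a leaves only b
  # critical, and everything snaps down to the single critical weight
  k2 <- buildCliqueComplex(fixtureGraph("K2"))
  f <- c(0.3, 0.2, 0.3)   # a, b, {a b}; V_{ab} = {a} so a and the edge pair
  crit <- findCritical(k2, f)
  expect_equal(simplexKeys(k2)[which(crit@isCritical)], "b")
  expect_equal(criticalWeights(crit), 0.2)
  flt <- criticalFiltration(k2, f, crit)
  expect_equal(filtrationWeights(flt), c(0.2, 0.2, 0.2))

  # with the dimension function every simplex is critical and snapping is
  # the identity on dimensions
  cc <- buildCliqueComplex(sampleER(15, 0.3, seed = 31))
  fdim <- as.numeric(simplexDims(cc))
  critd <- findCritical(cc, fdim)
  expect_equal(criticalWeights(critd), as.numeric(0:complexDim(cc)))
  fltd <- criticalFiltration(cc, fdim, critd)
  expect_equal(filtrationWeights(fltd), fdim)

  # single vertex: one step at its own weight
  cc1 <- buildCliqueComplex(fixtureGraph("K1"))
  flt1 <- criticalFiltration(cc1, 0.3)
  expect_equal(filtrationWeights(flt1), 0.3)
})

test_that("all schemes are monotone with faces preceding cofaces", {
  for (seed in 1:8) {
    g <- randomTestGraph(seed, nmax = 40)
    cc <- buildCliqueComplex(g)
    set.seed(seed)
    mf <- assignMorseFunction(cc, vertexFunction(g))
    crit <- findCritical(cc, mf)
    for (flt in list(criticalFiltration(cc, mf, crit), fullFiltration(cc, mf),
                     dimensionFiltration(cc))) {
      fw <- filtrationWeights(flt)
      dims <- simplexDims(cc)
      for (id in which(dims > 0L))
        expect_true(all(fw[simplexFacets(cc, id)] <= fw[id]))
      pos <- integer(length(fw)); pos[flt@order] <- seq_along(fw)
      for (id in which(dims > 0L))
        expect_true(all(pos[simplexFacets(cc, id)] < pos[id]))
      expect_true(all(fw / flt@wN >= 0 & fw / flt@wN <= 1))
    }
    # step-count reduction: critical steps <= full steps
    expect_lte(length(unique(filtrationWeights(criticalFiltration(cc, mf, crit)))),
               length(unique(filtrationWeights(fullFiltration(cc, mf)))))
  }
})

test_that("full and critical filtrations give the same diagram after snapping", {
  for (seed in 1:20) {
    g <- randomTestGraph(seed + 900, nmax = 50)
    cc <- buildCliqueComplex(g)
    set.seed(seed)
    mf <- assignMorseFunction(cc, vertexFunction(g))
    crit <- findCritical(cc, mf)
    dcrit <- persistenceDiagram(criticalFiltration(cc, mf, crit), cc)
    dfull <- persistenceDiagram(fullFiltration(cc, mf), cc)
    snapped <- snapDiagram(dfull, crit)
    expect_equal(diagramPoints(snapped), diagramPoints(dcrit))
  }
})

test_that("the dimension filtration has d + 1 steps and finds the circle's hole", {
  cc <- buildCliqueComplex(fixtureGraph("K3"))
  flt <- dimensionFiltration(cc)
  expect_equal(sort(unique(filtrationWeights(flt))), c(0, 1, 2))

  c4 <- buildCliqueComplex(fixtureGraph("C4"))
  flt4 <- dimensionFiltration(c4)
  expect_equal(length(unique(filtrationWeights(flt4))), complexDim(c4) + 1L)
  dg <- persistenceDiagram(flt4, c4)
  p <- diagramPoints(dg)
  h1 <- p[p$dim == 1L, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)        # born with the edges
  expect_true(is.infinite(h1$death))  # never dies
})
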
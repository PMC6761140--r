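test_that("vertex weights decrease with degree and stay in their bands", {
  g1 <- fixtureGraph("K1")
  v <- vertexFunction(g1, seed = 1)
  expect_gt(v, 0); expect_lt(v, 0.5)

  # hub of degree 5 vs pendant of degree 1 in the 9-vertex fixture
  tt <- fixtureGraph("twoTriangles")
  gv <- vertexFunction(tt, seed = 2)
  expect_lt(gv["v7"], 0.5)               # deg_max vertex: (0, 0.5)
  expect_gt(gv["v8"], 4); expect_lt(gv["v8"], 4.5)
  expect_gt(gv["v8"], gv["v7"])

  # regular graph: ordering determined solely by noise, all values in (0, 0.5)
  ring <- sampleWS(20, 4, 0, seed = 3)
  gr <- vertexFunction(ring, seed = 4)
  expect_true(all(gr > 0 & gr < 0.5))
  expect_false(anyDuplicated(gr) > 0)
})

test_that("the construction pairs the path and triangle as in the hand traces", {
  # P3: both edges pair with their pendant endpoint; only the middle vertex
  # survives as critical, for every noise draw
  p3 <- fixtureGraph("P3")
  cc <- buildCliqueComplex(p3)
  for (seed in 1:20) {
    set.seed(seed)
    gv <- vertexFunction(p3)
    mf <- assignMorseFunction(cc, gv)
    expect_true(isTRUE(isDiscreteMorse(cc, mf)))
    crit <- findCritical(cc, mf)
    expect_equal(unname(criticalCounts(crit)), c(1L, 0L))
    expect_equal(simplexKeys(cc)[which(crit@isCritical)], "b")
  }

  # K3 with injected increasing vertex weights: whichever edge loses the
  # race for vertex c falls back, the triangle absorbs it, and only the
  # minimum vertex stays critical
  k3 <- fixtureGraph("K3")
  cck <- buildCliqueComplex(k3)
  for (seed in 1:20) {
    set.seed(seed)
    gv <- c(a = 0.1, b = 0.2, c = 0.3)
    mf <- assignMorseFunction(cck, gv)
    expect_true(isTRUE(isDiscreteMorse(cck, mf)))
    crit <- findCritical(cck, mf)
    expect_equal(simplexKeys(cck)[which(crit@isCritical)], "a")
  }

  # single vertex: f = g, nothing paired
  cc1 <- buildCliqueComplex(fixtureGraph("K1"))
  gv1 <- c(a = 0.25)
  mf1 <- assignMorseFunction(cc1, gv1)
  expect_equal(morseValues(mf1), 0.25)
  expect_true(all(is.na(pairedFaces(mf1))))
  expect_equal(unname(criticalCounts(findCritical(cc1, mf1))), 1L)
})

test_that("the Morse condition checker agrees with a brute-force set computation", {
  g <- sampleER(15, 0.35, seed = 8)
  cc <- buildCliqueComplex(g)
  set.seed(9)
  f <- morseValues(assignMorseFunction(cc, vertexFunction(g)))
  keys <- simplexKeys(cc); dims <- simplexDims(cc)
  # brute force U and V per simplex from the definitions
  for (id in seq_along(keys)) {
    verts <- strsplit(keys[id], " ")[[1L]]
    U <- sum(vapply(seq_along(keys), function(j)
      dims[j] == dims[id] + 1L && all(verts %in% strsplit(keys[j], " ")[[1L]]) &&
        f[j] <= f[id], logical(1)))
    V <- if (dims[id] == 0L) 0L else
      sum(vapply(simplexFacets(cc, id), function(j) f[id] <= f[j], logical(1)))
    expect_lte(U, 1L); expect_lte(V, 1L)
    expect_false(U > 0L && V > 0L)  # Forman exclusion
  }
  expect_true(isTRUE(isDiscreteMorse(cc, f)))
})

test_that("dimension function is Morse with every simplex critical; constants are not", {
  cc <- buildCliqueComplex(sampleER(12, 0.4, seed = 2))
  fdim <- as.numeric(simplexDims(cc))
  expect_true(isTRUE(isDiscreteMorse(cc, fdim)))
  crit <- findCritical(cc, fdim)
  expect_equal(unname(criticalCounts(crit)), unname(simplexCounts(cc)))

  cck <- buildCliqueComplex(fixtureGraph("K3"))
  ok <- isDiscreteMorse(cck, rep(1, nSimplices(cck)))
  expect_false(isTRUE(ok))
  viol <- attr(ok, "violations")
  expect_true(any(viol$set == "V" & viol$size == 2))
})

test_that("constructed functions are Morse with matched pairing across generators", {
  for (seed in 1:15) {
    g <- randomTestGraph(seed)
    cc <- buildCliqueComplex(g)
    set.seed(seed + 500)
    mf <- assignMorseFunction(cc, vertexFunction(g))
    expect_true(isTRUE(isDiscreteMorse(cc, mf)))
    # weights never fall below the facet maximum, equality only for pairs
    f <- morseValues(mf)
    for (id in which(simplexDims(cc) > 0L)) {
      fac <- simplexFacets(cc, id)
      expect_gte(f[id], max(f[fac]))
      if (f[id] == max(f[fac])) expect_false(is.na(pairedFaces(mf)[id]))
    }
    # pairing is a matching: each simplex consumed at most once
    pf <- pairedFaces(mf)
    expect_false(any(duplicated(pf[!is.na(pf)])))
    expect_setequal(which(mf@flagged), pf[!is.na(pf)])
  }
})

test_that("reproducibility: same seeds give bit-identical Morse functions", {
  g <- sampleER(40, 0.1, seed = 6)
  cc <- buildCliqueComplex(g)
  a <- assignMorseFunction(cc, vertexFunction(g, seed = 1), seed = 2)
  b <- assignMorseFunction(cc, vertexFunction(g, seed = 1), seed = 2)
  expect_identical(morseValues(a), morseValues(b))
  expect_identical(pairedFaces(a), pairedFaces(b))
})

test_that("the optimality indicator covers its closed-form cases", {
  expect_equal(optimalityMu(c(3, 2), c(3, 2), c(1, 0)), 0)       # all critical
  expect_equal(optimalityMu(c(3, 2), c(1, 0), c(1, 0)), 1)       # optimal
  expect_equal(optimalityMu(c(3, 2), c(1, 0), c(1)), 1)          # P3 hand trace
  expect_warning(mu <- optimalityMu(1, 1, 1), "degenerate")
  expect_equal(mu, 1)
  expect_error(optimalityMu(c(2), c(1), c(5)), "exceeds")
})
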
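# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths on small inputs.

# rank of a 0/1 matrix over GF(2) by plain Gaussian elimination
gf2Rank <- function(M) {
  M <- M %% 2L
  if (!length(M)) return(0L)
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1L & seq_len(nrow(M)) > r)
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    hit <- which(M[, j] == 1L & seq_len(nrow(M)) != r)
    if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] + rep(M[r, ], each = length(hit))) %% 2L
    if (r == nrow(M)) break
  }
  r
}

# dense boundary matrix of dimension p (rows: (p-1)-simplices, cols: p-simplices)
denseBoundary <- function(cc, p) {
  np <- simplexCounts(cc)
  M <- matrix(0L, nrow = np[p], ncol = np[p + 1L])
  fi <- cc@facetIdx[[p + 1L]] - cc@offsets[p]
  for (i in seq_len(nrow(fi))) M[fi[i, ], i] <- 1L
  M
}

# Betti numbers by rank-nullity over GF(2): beta_p = n_p - rank d_p - rank d_{p+1}
oracleBetti <- function(cc) {
  d <- complexDim(cc)
  np <- as.integer(simplexCounts(cc))
  ranks <- c(0L, vapply(seq_len(max(d, 0L)), function(p) gf2Rank(denseBoundary(cc, p)), integer(1)), 0L)
  vapply(0:d, function(p) np[p + 1L] - ranks[p + 1L] - ranks[p + 2L], integer(1))
}

# independent dense left-to-right GF(2) column reduction; returns the same
# partner encoding as the package kernel
oracleReduce <- function(cols) {
  n <- length(cols)
  M <- matrix(0L, n, n)
  for (j in seq_len(n)) M[cols[[j]], j] <- 1L
  partner <- integer(n)
  lowOf <- integer(n)
  low <- function(j) { w <- which(M[, j] == 1L); if (length(w)) max(w) else 0L }
  for (j in seq_len(n)) {
    repeat {
      l <- low(j)
      if (l == 0L || lowOf[l] == 0L) break
      M[, j] <- (M[, j] + M[, lowOf[l]]) %% 2L
    }
    l <- low(j)
    if (l > 0L) { lowOf[l] <- j; partner[l] <- j; partner[j] <- -l }
  }
  partner
}

# exhaustive bottleneck / q-Wasserstein over all augmented bijections for
# tiny diagrams given as (birth, death) matrices
oracleMatchCosts <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  cost <- function(a, b) max(abs(a[1] - b[1]), abs(a[2] - b[2]))
  proj <- function(a) (a[2] - a[1]) / 2
  subsets <- function(n, k) if (k == 0L) list(integer(0)) else combn(n, k, simplify = FALSE)
  allCosts <- list()
  for (k in 0:min(nx, ny)) {
    for (S in subsets(nx, k)) for (T in subsets(ny, k)) {
      perms <- if (k == 0L) list(integer(0)) else asplit(permMatrix(k), 1)
      for (pm in perms) {
        matched <- if (k) vapply(seq_len(k), function(i) cost(X[S[i], ], Y[T[pm[i]], ]), numeric(1)) else numeric(0)
        diagX <- if (nx > k) vapply(setdiff(seq_len(nx), S), function(i) proj(X[i, ]), numeric(1)) else numeric(0)
        diagY <- if (ny > k) vapply(setdiff(seq_len(ny), T), function(i) proj(Y[i, ]), numeric(1)) else numeric(0)
        allCosts[[length(allCosts) + 1L]] <- c(matched, diagX, diagY)
      }
    }
  }
  allCosts
}

permMatrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- permMatrix(k - 1L)
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

oracleBottleneck <- function(X, Y) {
  cs <- oracleMatchCosts(X, Y)
  if (!length(cs)) return(0)
  min(vapply(cs, function(v) if (length(v)) max(v) else 0, numeric(1)))
}

oracleWasserstein <- function(X, Y, q) {
  cs <- oracleMatchCosts(X, Y)
  if (!length(cs)) return(0)
  min(vapply(cs, function(v) sum(v^q), numeric(1)))^(1 / q)
}

# small random diagram as a normalized data.frame
randomDiagramDF <- function(npts) {
  if (npts == 0L)
    return(data.frame(dim = integer(0), birth = numeric(0), death = numeric(0)))
  b <- runif(npts, 0, 0.8)
  data.frame(dim = 0L, birth = b, death = pmin(1, b + runif(npts, 0.01, 0.6)))
}

# full pipeline shortcut used across test files
morsePipeline <- function(graph, cap = 3, seed = 1) {
  set.seed(seed)
  cc <- buildCliqueComplex(graph, cap = cap)
  g <- vertexFunction(graph)
  mf <- assignMorseFunction(cc, g)
  crit <- findCritical(cc, mf)
  flt <- criticalFiltration(cc, mf, crit)
  dgm <- persistenceDiagram(flt, cc)
  list(cc = cc, g = g, mf = mf, crit = crit, flt = flt, dgm = dgm,
       np = as.integer(simplexCounts(cc)), mp = as.integer(criticalCounts(crit)),
       beta = as.integer(bettiNumbers(dgm)))
}

# a small seeded graph drawn from a mixed pool of generators
randomTestGraph <- function(seed, nmax = 60) {
  set.seed(seed)
  n <- sample(5:nmax, 1)
  kind <- sample(c("er", "ws", "ba"), 1)
  switch(kind,
    er = sampleER(n, runif(1, 0.05, 0.3)),
    ws = sampleWS(n, 4, runif(1)),
    ba = sampleBA(n, sample(1:3, 1)))
}
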
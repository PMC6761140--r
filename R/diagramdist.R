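# normalize input to a multiplicity-expanded (birth, death) matrix inside
# the unit square; accepts a PersistenceDiagram, or a data.frame/matrix of
# already-normalized points (columns birth, death, optional dim and
# multiplicity)
unitPoints <- function(x, dims = NULL) {
  if (is(x, "PersistenceDiagram")) {
    p <- diagramPoints(x, normalized = TRUE)
  } else {
    p <- as.data.frame(x)
    if (!all(c("birth", "death") %in% names(p)))
      stop("diagram input needs birth and death columns")
    if (is.null(p$multiplicity)) p$multiplicity <- rep(1L, nrow(p))
    if (is.null(p$dim)) p$dim <- rep(0L, nrow(p))
  }
  if (!is.null(dims)) p <- p[p$dim %in% dims, , drop = FALSE]
  if (nrow(p)) {
    if (any(!is.finite(p$death)))
      stop("diagram points must have finite deaths; normalize essential classes first")
    if (any(p$birth >= p$death))
      stop("diagram points must satisfy birth < death")
    idx <- rep(seq_len(nrow(p)), p$multiplicity)
    cbind(birth = p$birth[idx], death = p$death[idx])
  } else {
    cbind(birth = numeric(0), death = numeric(0))
  }
}

#' Bottleneck distance between persistence diagrams
#'
#' Exact infimum, over all bijections between the diagonal-augmented
#' diagrams, of the maximum sup-norm displacement.  Computed by binary
#' search over the finite set of candidate costs (pairwise point costs and
#' diagonal-projection costs) with a bipartite-matching feasibility test.
#' Diagrams are compared on the normalized scale, pooled across all
#' dimensions by default (the whole-complex persistence diagram), so the
#' result lies in [0, 1].
#'
#' @param x,y [PersistenceDiagram-class] objects, or data.frames of
#'   normalized points with columns `birth` and `death`.
#' @param dims optional integer vector restricting the comparison to these
#'   homology dimensions.
#' @return the bottleneck distance.
#' @export
bottleneckDistance <- function(x, y, dims = NULL) {
  px <- unitPoints(x, dims)
  py <- unitPoints(y, dims)
  bottleneck_cpp(px[, "birth"], px[, "death"], py[, "birth"], py[, "death"])
}

#' q-Wasserstein distance between persistence diagrams
#'
#' Minimum over diagonal-augmented bijections of the sum of q-th powers of
#' sup-norm displacements, to the power 1/q; solved exactly as a min-cost
#' assignment.  Intended for desk-scale diagrams (the assignment solver is
#' cubic in the number of points).
#'
#' @inheritParams bottleneckDistance
#' @param q order, >= 1.
#' @return the q-Wasserstein distance.
#' @export
wassersteinDistance <- function(x, y, q = 1, dims = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q < 1) stop("q must be >= 1")
  px <- unitPoints(x, dims)
  py <- unitPoints(y, dims)
  wasserstein_cpp(px[, "birth"], px[, "death"], py[, "birth"], py[, "death"], q)
}

#' Per-dimension diagram distances
#'
#' @inheritParams bottleneckDistance
#' @param metric one of "bottleneck", "w1", "w2".
#' @return named numeric vector, one distance per homology dimension
#'   present in either diagram.
#' @export
perDimensionDistance <- function(x, y, metric = c("bottleneck", "w1", "w2")) {
  metric <- match.arg(metric)
  dx <- if (is(x, "PersistenceDiagram")) diagramPoints(x)$dim else as.data.frame(x)$dim
  dy <- if (is(y, "PersistenceDiagram")) diagramPoints(y)$dim else as.data.frame(y)$dim
  dims <- sort(unique(c(dx, dy)))
  vapply(dims, function(p) switch(metric,
    bottleneck = bottleneckDistance(x, y, dims = p),
    w1 = wassersteinDistance(x, y, q = 1, dims = p),
    w2 = wassersteinDistance(x, y, q = 2, dims = p)), numeric(1)) |>
    setNames(paste0("H", dims))
}

#' Mean diagram distance between model networks
#'
#' Generates `replicates` seeded samples of each model, runs the full
#' discrete-Morse persistence pipeline on each, and reports for every model
#' pair the mean and standard error of the chosen distance between the
#' whole-complex persistence diagrams: over all replicates^2 cross pairs
#' for two distinct models, and over all unordered pairs of distinct
#' replicates for a model against itself.
#'
#' @param specs named list of model specifications (see [modelSpec()] and
#'   [defaultModelSpecs()]).
#' @param replicates samples per model (>= 2).
#' @param seed integer seed controlling generation and Morse noise.
#' @param metric one of "bottleneck", "w1", "w2".
#' @param cap clique-complex dimension cap.
#' @return data.frame with columns modelA, modelB, mean, se, npairs, and the
#'   per-replicate diagrams in attribute `"diagrams"`.
#' @export
modelDistanceMatrix <- function(specs = defaultModelSpecs(), replicates = 10,
                                seed = 1, metric = c("bottleneck", "w1", "w2"),
                                cap = 3) {
  metric <- match.arg(metric)
  if (replicates < 2) stop("replicates must be >= 2")
  diag_list <- modelDiagrams(specs, replicates, seed, cap)
  distFun <- switch(metric,
    bottleneck = bottleneckDistance,
    w1 = function(a, b) wassersteinDistance(a, b, q = 1),
    w2 = function(a, b) wassersteinDistance(a, b, q = 2))
  nm <- names(specs)
  rows <- list()
  for (a in seq_along(nm)) {
    for (b in seq.int(a, length(nm))) {
      da <- diag_list[[nm[a]]]; db <- diag_list[[nm[b]]]
      d <- if (a == b) {
        pairs <- utils::combn(replicates, 2)
        apply(pairs, 2, function(ij) distFun(da[[ij[1]]], db[[ij[2]]]))
      } else {
        as.vector(vapply(seq_len(replicates), function(i)
          vapply(seq_len(replicates), function(j) distFun(da[[i]], db[[j]]),
                 numeric(1)), numeric(replicates)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        modelA = nm[a], modelB = nm[b], mean = mean(d),
        se = stats::sd(d) / sqrt(length(d)), npairs = length(d))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "diagrams") <- diag_list
  out
}

# run the generation -> complex -> Morse -> critical filtration ->
# persistence pipeline for each model replicate; returns a named list of
# lists of diagrams
modelDiagrams <- function(specs, replicates, seed, cap = 3) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * length(specs) * replicates),
                  ncol = 2L)
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  row <- 0L
  for (m in names(specs)) {
    out[[m]] <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      row <- row + 1L
      g <- generateModel(specs[[m]], seed = seeds[row, 1L])
      out[[m]][[r]] <- analyzeNetwork(g, cap = cap, seed = seeds[row, 2L])$diagram
    }
  }
  out
}
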
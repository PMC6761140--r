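#' Entry values of simplices under level subcomplexes
#'
#' The level subcomplex K(r) contains every simplex of weight at most r
#' together with all faces of such simplices, so a simplex alpha enters the
#' filtration at the minimum weight over all simplices containing it
#' (including itself).
#'
#' @param complex a [CliqueComplex-class] object.
#' @param f a [MorseFunction-class] object or per-simplex weight vector.
#' @return numeric vector of entry values in global-id order.
#' @export
entryValues <- function(complex, f) {
  stopifnot(is(complex, "CliqueComplex"))
  ev <- morseValues(f)
  if (length(ev) != nSimplices(complex))
    stop("f must assign a weight to every simplex of the complex")
  d <- complexDim(complex)
  if (d < 1L) return(ev)
  for (s in rev(seq_len(d + 1L)[-1L])) {       # propagate minima top-down
    fi <- complex@facetIdx[[s]]
    cof <- rep(complex@offsets[s] + seq_len(complex@np[s]), times = s)
    agg <- tapply(ev[cof], as.vector(fi), min)
    ids <- as.integer(names(agg))
    ev[ids] <- pmin(ev[ids], as.numeric(agg))
  }
  ev
}

#' Entry value of one simplex
#' @inheritParams entryValues
#' @param simplex vertex labels (or space-joined key) of a simplex in the
#'   complex.
#' @return the minimum weight over the simplex and all its cofaces.
#' @export
entryValue <- function(complex, f, simplex) {
  entryValues(complex, f)[simplexIndex(complex, simplex)]
}

newFiltration <- function(complex, fw, wN, scheme) {
  ord <- order(fw, seq_along(fw), method = "radix")  # ties: dimension-major global id
  flt <- new("Filtration", weights = fw, order = as.integer(ord),
             wN = wN, scheme = scheme)
  inc <- incidencePairs(complex)
  if (length(inc$face) && any(fw[inc$face] > fw[inc$coface]))
    stop("internal error: filtration weights are not monotone")
  flt
}

#' Critical-weight filtration
#'
#' Snaps the entry value of every simplex up to the smallest critical
#' weight at least as large; since homology can only change at critical
#' weights, the persistence diagram is unchanged while the number of
#' filtration steps drops from the number of distinct weights to the
#' number of distinct critical weights.  Simplices entering after the last
#' critical weight are assigned the last critical weight, which completes
#' the complex in the final step without altering any nonzero-persistence
#' point.
#'
#' @param complex a [CliqueComplex-class] object.
#' @param f a [MorseFunction-class] object (discrete Morse).
#' @param critical the matching [CriticalSet-class]; computed from `f` when
#'   omitted.
#' @return a [Filtration-class] object with scheme "critical".
#' @export
criticalFiltration <- function(complex, f, critical = NULL) {
  stopifnot(is(complex, "CliqueComplex"))
  fv <- morseValues(f)
  if (nSimplices(complex) == 0L)
    return(new("Filtration", weights = numeric(0), order = integer(0),
               wN = 1, scheme = "critical"))
  if (is.null(critical)) critical <- findCritical(complex, f)
  cw <- criticalWeights(critical)
  if (!length(cw)) stop("critical weight sequence is empty")
  ev <- entryValues(complex, fv)
  j <- findInterval(ev, cw, left.open = TRUE) + 1L  # smallest cw >= entry value
  fw <- cw[pmin(j, length(cw))]
  newFiltration(complex, fw, wN = 1 + max(fv), scheme = "critical")
}

#' Full-weight filtration
#'
#' One filtration step per distinct weight value; each simplex enters at
#' its entry value.  Persistent homology agrees with the critical-weight
#' filtration after snapping births and deaths to critical weights.
#'
#' @inheritParams criticalFiltration
#' @return a [Filtration-class] object with scheme "full".
#' @export
fullFiltration <- function(complex, f) {
  stopifnot(is(complex, "CliqueComplex"))
  fv <- morseValues(f)
  if (nSimplices(complex) == 0L)
    return(new("Filtration", weights = numeric(0), order = integer(0),
               wN = 1, scheme = "full"))
  newFiltration(complex, entryValues(complex, fv), wN = 1 + max(fv), scheme = "full")
}

#' Dimension-function filtration
#'
#' The baseline scheme in which each simplex enters at its dimension:
#' vertices first, then edges, triangles, tetrahedra.  Every simplex is
#' critical for the dimension function, so this filtration has exactly
#' d + 1 steps and its optimality indicator is 0.  Weights are normalized
#' by the complex dimension so the filtration index runs over [0, 1].
#'
#' @param complex a [CliqueComplex-class] object.
#' @return a [Filtration-class] object with scheme "dimension".
#' @export
dimensionFiltration <- function(complex) {
  stopifnot(is(complex, "CliqueComplex"))
  if (nSimplices(complex) == 0L)
    return(new("Filtration", weights = numeric(0), order = integer(0),
               wN = 1, scheme = "dimension"))
  fw <- as.numeric(simplexDims(complex))
  newFiltration(complex, fw, wN = max(1, complexDim(complex)), scheme = "dimension")
}

#' Filtration weights
#' @param x a [Filtration-class] object.
#' @param normalized divide by the normalization constant?
#' @return numeric vector in global-id order.
#' @export
filtrationWeights <- function(x, normalized = FALSE) {
  stopifnot(is(x, "Filtration"))
  if (normalized) x@weights / x@wN else x@weights
}

#' Normalization constant of a filtration or diagram
#' @param x a [Filtration-class] or [PersistenceDiagram-class] object.
#' @return w_N = 1 + max Morse weight (Morse schemes) or the complex
#'   dimension (dimension scheme).
#' @export
normConstant <- function(x) {
  stopifnot(is(x, "Filtration") || is(x, "PersistenceDiagram"))
  x@wN
}

#' Snap a diagram to a critical-weight sequence
#'
#' Maps every finite birth and death to the smallest critical weight at
#' least as large (values beyond the last critical weight map to the last
#' one), drops the points that become zero-persistence and re-merges
#' multiplicities.  Applying this to the diagram of the full-weight
#' filtration reproduces the diagram of the critical-weight filtration.
#'
#' @param diagram a [PersistenceDiagram-class] object.
#' @param cw strictly increasing critical-weight sequence (or a
#'   [CriticalSet-class]).
#' @return a [PersistenceDiagram-class] object.
#' @export
snapDiagram <- function(diagram, cw) {
  stopifnot(is(diagram, "PersistenceDiagram"))
  if (is(cw, "CriticalSet")) cw <- criticalWeights(cw)
  snap <- function(v) {
    fin <- is.finite(v)
    j <- findInterval(v[fin], cw, left.open = TRUE) + 1L
    v[fin] <- cw[pmin(j, length(cw))]
    v
  }
  p <- diagram@points
  p$birth <- snap(p$birth)
  p$death <- snap(p$death)
  p <- p[p$birth < p$death, , drop = FALSE]
  new("PersistenceDiagram", points = mergeMultiplicity(p), wN = diagram@wN,
      scheme = "critical", complexDim = diagram@complexDim)
}
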
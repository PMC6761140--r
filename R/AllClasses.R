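#' Clique complex of a simple graph
#'
#' All cliques of an undirected simple graph up to a dimension cap, stored
#' per dimension in lexicographic order of their sorted vertex tuples,
#' together with facet incidence.  A p-simplex is a set of p+1 vertices
#' spanning a complete subgraph; the complex is closed under taking faces.
#' Simplices are addressed by a global integer id: ids are contiguous,
#' dimension-major (all vertices first, then edges, ...), lexicographic
#' within a dimension.
#'
#' @slot simplexTab list with one character matrix per dimension; row i of
#'   element p+1 holds the sorted vertex labels of the i-th p-simplex.
#' @slot keys list of character vectors; space-joined vertex tuples, used
#'   for lookup.
#' @slot facetIdx list; for p >= 1, an integer matrix (n_p x (p+1)) of
#'   global ids of the facets ((p-1)-faces) of each p-simplex.
#' @slot offsets integer; cumulative simplex counts, so global id of the
#'   i-th p-simplex is offsets[p+1] + i.
#' @slot np integer vector of simplex counts per dimension.
#' @slot cap integer; construction cap on the dimension.
#' @slot vertexDegree named numeric; degrees of the vertices in the source
#'   graph (used by the degree-based vertex function).
#'
#' @seealso [buildCliqueComplex()]
#' @export
setClass("CliqueComplex", representation(
  simplexTab  = "list",
  keys        = "list",
  facetIdx    = "list",
  offsets     = "integer",
  np          = "integer",
  cap         = "integer",
  vertexDegree = "numeric"
))

setValidity("CliqueComplex", function(object) {
  np <- object@np
  if (length(np) && any(np <= 0L)) return("np must be positive for every stored dimension")
  if (!identical(object@offsets, cumsum(c(0L, np))[seq_along(np)]) && length(np))
    return("offsets inconsistent with np")
  for (s in seq_along(np)) {
    tab <- object@simplexTab[[s]]
    if (!is.matrix(tab) || nrow(tab) != np[s] || ncol(tab) != s)
      return(sprintf("simplex table for dimension %d has wrong shape", s - 1L))
    if (s >= 2L) {
      fi <- object@facetIdx[[s]]
      if (!is.matrix(fi) || nrow(fi) != np[s] || ncol(fi) != s)
        return(sprintf("facet index for dimension %d has wrong shape", s - 1L))
      if (anyNA(fi)) return("facet index contains NA: complex not closed under faces")
    }
  }
  TRUE
})

#' Discrete Morse function on a clique complex
#'
#' A per-simplex real weight f together with the pairing bookkeeping of the
#' construction: a non-critical simplex assigned in the pairing branch
#' records its paired maximal face, and a simplex consumed as such a face is
#' flagged.  The function satisfies, for every simplex, |U| <= 1 and
#' |V| <= 1 where U collects cofacets of lower-or-equal weight and V facets
#' of greater-or-equal weight.
#'
#' @slot values numeric; weight per global simplex id.
#' @slot pairedFace integer; global id of the paired maximal face, NA for
#'   vertices and for simplices assigned in the noise branch.
#' @slot flagged logical; TRUE when the simplex has been consumed as the
#'   paired face of one of its cofacets.
#' @slot seed integer of length 0 or 1; RNG seed used, if supplied.
#'
#' @seealso [assignMorseFunction()], [isDiscreteMorse()]
#' @export
setClass("MorseFunction", representation(
  values     = "numeric",
  pairedFace = "integer",
  flagged    = "logical",
  seed       = "integer"
))

setValidity("MorseFunction", function(object) {
  n <- length(object@values)
  if (length(object@pairedFace) != n || length(object@flagged) != n)
    return("values, pairedFace and flagged must have equal length")
  TRUE
})

#' Critical simplices of a discrete Morse function
#'
#' @slot isCritical logical per global simplex id; TRUE when both the U and
#'   V sets of the simplex are empty.
#' @slot mp integer; number of critical p-simplices per dimension.
#' @slot weights numeric; strictly increasing sequence of distinct weights
#'   of the critical simplices (the critical weights).
#'
#' @seealso [findCritical()]
#' @export
setClass("CriticalSet", representation(
  isCritical = "logical",
  mp         = "integer",
  weights    = "numeric"
))

setValidity("CriticalSet", function(object) {
  if (is.unsorted(object@weights, strictly = TRUE)) return("critical weights must be strictly increasing")
  if (sum(object@mp) != sum(object@isCritical)) return("mp inconsistent with isCritical")
  TRUE
})

#' Filtration of a clique complex
#'
#' A monotone per-simplex filtration weight together with a compatible
#' total order (weight, then dimension, then lexicographic) in which faces
#' precede cofaces, and the normalization constant used for barcode output.
#'
#' @slot weights numeric filtration weight per global simplex id.
#' @slot order integer permutation of global ids sorted by
#'   (weight, dimension, lexicographic tuple).
#' @slot wN numeric; normalization constant (1 + max Morse weight for
#'   Morse-based schemes; the complex dimension for the dimension scheme).
#' @slot scheme character; one of "critical", "full", "dimension".
#'
#' @seealso [criticalFiltration()], [fullFiltration()], [dimensionFiltration()]
#' @export
setClass("Filtration", representation(
  weights = "numeric",
  order   = "integer",
  wN      = "numeric",
  scheme  = "character"
))

setValidity("Filtration", function(object) {
  if (length(object@order) != length(object@weights)) return("order and weights must match")
  if (!object@scheme %in% c("critical", "full", "dimension")) return("unknown scheme")
  if (length(object@wN) != 1L || !is.finite(object@wN) || object@wN <= 0)
    return("wN must be a positive number")
  TRUE
})

#' Persistence diagram
#'
#' Multiset of (dimension, birth, death) points with multiplicities, on the
#' raw filtration-weight scale; essential classes have death = Inf and are
#' mapped to a normalized death of 1 on output.  Zero-persistence pairs are
#' dropped at construction.
#'
#' @slot points data.frame with columns dim, birth, death, multiplicity.
#' @slot wN numeric; normalization constant carried from the filtration.
#' @slot scheme character; filtration scheme the diagram was computed from.
#' @slot complexDim integer; dimension of the filtered complex.
#'
#' @seealso [persistenceDiagram()], [diagramPoints()], [barcode()]
#' @export
setClass("PersistenceDiagram", representation(
  points     = "data.frame",
  wN         = "numeric",
  scheme     = "character",
  complexDim = "integer"
))

setValidity("PersistenceDiagram", function(object) {
  p <- object@points
  need <- c("dim", "birth", "death", "multiplicity")
  if (!all(need %in% names(p))) return("points must have columns dim, birth, death, multiplicity")
  if (nrow(p)) {
    if (any(p$birth >= p$death)) return("every point must satisfy birth < death")
    if (any(p$multiplicity < 1L)) return("multiplicities must be >= 1")
  }
  TRUE
})

setMethod("show", "CliqueComplex", function(object) {
  np <- object@np
  cat(sprintf("CliqueComplex: dimension %d (cap %d), %d simplices\n",
              length(np) - 1L, object@cap, sum(np)))
  if (length(np))
    cat("  n_p:", paste(sprintf("%d-simplices: %d", seq_along(np) - 1L, np), collapse = ", "), "\n")
})

setMethod("show", "MorseFunction", function(object) {
  cat(sprintf("MorseFunction on %d simplices: %d pairings, weight range [%.4g, %.4g]\n",
              length(object@values), sum(!is.na(object@pairedFace)),
              if (length(object@values)) min(object@values) else NA,
              if (length(object@values)) max(object@values) else NA))
})

setMethod("show", "CriticalSet", function(object) {
  cat(sprintf("CriticalSet: %d critical simplices, %d distinct critical weights\n",
              sum(object@isCritical), length(object@weights)))
  cat("  m_p:", paste(object@mp, collapse = ", "), "\n")
})

setMethod("show", "Filtration", function(object) {
  cat(sprintf("Filtration (%s): %d simplices, %d steps, w_N = %.4g\n",
              object@scheme, length(object@weights),
              length(unique(object@weights)), object@wN))
})

setMethod("show", "PersistenceDiagram", function(object) {
  p <- object@points
  cat(sprintf("PersistenceDiagram (%s scheme): %d points (%d with multiplicity), %d essential\n",
              object@scheme, sum(p$multiplicity), nrow(p),
              sum(p$multiplicity[is.infinite(p$death)])))
  if (nrow(p)) {
    tab <- tapply(p$multiplicity, factor(p$dim, levels = 0:object@complexDim), sum, default = 0L)
    cat("  per dimension:", paste(sprintf("H%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})
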
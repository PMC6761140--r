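#' Build the clique complex of a simple graph
#'
#' Enumerates every clique of the graph with at most `cap + 1` vertices and
#' stores it as a simplex, per dimension, in lexicographic order of the
#' sorted vertex tuples, together with the facet incidence needed by the
#' Morse construction and the boundary matrices.  The complex is closed
#' under faces by construction (every subset of a clique is a clique).
#'
#' @param graph an igraph object with vertex names (a simple graph; see
#'   [readEdgelist()] and the generators).
#' @param cap maximum simplex dimension to construct (default 3, i.e.
#'   cliques of up to 4 vertices).
#' @return a [CliqueComplex-class] object.
#' @examples
#' cc <- buildCliqueComplex(fixtureGraph("K3"))
#' simplexCounts(cc)   # 3 vertices, 3 edges, 1 triangle
#' @export
buildCliqueComplex <- function(graph, cap = 3L) {
  stopifnot(igraph::is_igraph(graph))
  cap <- as.integer(cap)
  if (cap < 0L) stop("cap must be >= 0")
  nv <- igraph::vcount(graph)
  if (nv == 0L)
    return(new("CliqueComplex", simplexTab = list(), keys = list(),
               facetIdx = list(), offsets = integer(0), np = integer(0),
               cap = cap, vertexDegree = numeric(0)))
  graph <- sortGraphVertices(graph)
  vnames <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  names(deg) <- vnames
  cl <- igraph::cliques(graph, min = 1L, max = cap + 1L)
  sizes <- lengths(cl)
  d <- max(sizes) - 1L
  simplexTab <- vector("list", d + 1L)
  keys <- vector("list", d + 1L)
  np <- integer(d + 1L)
  for (s in seq_len(d + 1L)) {
    idx <- which(sizes == s)
    m <- matrix(vnames[unlist(cl[idx], use.names = FALSE)], ncol = s, byrow = TRUE)
    if (s > 1L) m <- t(apply(m, 1L, sort, method = "radix"))
    ord <- do.call(order, c(lapply(seq_len(s), function(j) m[, j]),
                            list(method = "radix")))
    m <- m[ord, , drop = FALSE]
    simplexTab[[s]] <- m
    keys[[s]] <- do.call(paste, c(lapply(seq_len(s), function(j) m[, j]), list(sep = " ")))
    np[s] <- nrow(m)
  }
  offsets <- cumsum(c(0L, np))[seq_len(d + 1L)]
  facetIdx <- vector("list", d + 1L)
  for (s in seq_len(d + 1L)[-1L]) {
    m <- simplexTab[[s]]
    fi <- matrix(NA_integer_, nrow = np[s], ncol = s)
    for (j in seq_len(s)) {
      fk <- do.call(paste, c(lapply(seq_len(s)[-j], function(col) m[, col]), list(sep = " ")))
      fi[, j] <- match(fk, keys[[s - 1L]]) + offsets[s - 1L]
    }
    facetIdx[[s]] <- fi
  }
  new("CliqueComplex", simplexTab = simplexTab, keys = keys, facetIdx = facetIdx,
      offsets = offsets, np = np, cap = cap, vertexDegree = deg)
}

#' Simplex counts per dimension
#' @param x a [CliqueComplex-class] object.
#' @return named integer vector n_p for p = 0..dim.
#' @export
simplexCounts <- function(x) {
  stopifnot(is(x, "CliqueComplex"))
  if (!length(x@np)) return(setNames(integer(0), character(0)))
  setNames(x@np, paste0("p", seq_along(x@np) - 1L))
}

#' Dimension of a clique complex
#' @param x a [CliqueComplex-class] object.
#' @return the maximum simplex dimension present (-1 for an empty complex).
#' @export
complexDim <- function(x) {
  stopifnot(is(x, "CliqueComplex"))
  length(x@np) - 1L
}

#' Number of simplices in a complex
#' @param x a [CliqueComplex-class] object.
#' @return total simplex count.
#' @export
nSimplices <- function(x) sum(simplexCounts(x))

#' Simplex labels in global-id order
#' @param x a [CliqueComplex-class] object.
#' @return character vector of space-joined sorted vertex tuples.
#' @export
simplexKeys <- function(x) {
  stopifnot(is(x, "CliqueComplex"))
  unlist(x@keys, use.names = FALSE) %||% character(0)
}

#' Simplex dimensions in global-id order
#' @param x a [CliqueComplex-class] object.
#' @return integer vector of per-simplex dimensions.
#' @export
simplexDims <- function(x) {
  stopifnot(is(x, "CliqueComplex"))
  rep(seq_along(x@np) - 1L, x@np)
}

#' Global id of a simplex
#' @param x a [CliqueComplex-class] object.
#' @param simplex character vector of vertex labels (any order), or a single
#'   space-joined key.
#' @return integer global id.
#' @export
simplexIndex <- function(x, simplex) {
  stopifnot(is(x, "CliqueComplex"))
  if (length(simplex) == 1L && grepl(" ", simplex)) simplex <- strsplit(simplex, " ")[[1L]]
  s <- length(simplex)
  key <- paste(sort(simplex, method = "radix"), collapse = " ")
  if (s > length(x@np)) stop("simplex not in complex: ", key)
  i <- match(key, x@keys[[s]])
  if (is.na(i)) stop("simplex not in complex: ", key)
  x@offsets[s] + i
}

#' Facets of a simplex
#' @param x a [CliqueComplex-class] object.
#' @param id global simplex id.
#' @return integer vector of global ids of the (dim-1)-faces (empty for a
#'   vertex).
#' @export
simplexFacets <- function(x, id) {
  p <- simplexDims(x)[id]
  if (p == 0L) return(integer(0))
  x@facetIdx[[p + 1L]][id - x@offsets[p + 1L], ]
}

#' Cofacets of a simplex
#' @param x a [CliqueComplex-class] object.
#' @param id global simplex id.
#' @return integer vector of global ids of the (dim+1)-simplices having the
#'   simplex as a face.
#' @export
simplexCofacets <- function(x, id) {
  inc <- incidencePairs(x)
  inc$coface[inc$face == id]
}

# all (facet, cofacet) incidence pairs as parallel integer vectors of
# global ids; the backbone of the Morse condition checks
incidencePairs <- function(x) {
  d <- complexDim(x)
  if (d < 1L) return(list(face = integer(0), coface = integer(0)))
  face <- vector("list", d); coface <- vector("list", d)
  for (s in seq_len(d + 1L)[-1L]) {
    fi <- x@facetIdx[[s]]
    face[[s - 1L]] <- as.vector(fi)
    coface[[s - 1L]] <- rep(x@offsets[s] + seq_len(x@np[s]), times = s)
  }
  list(face = unlist(face), coface = unlist(coface))
}

#' Dump the simplices of a complex to a text file
#'
#' One simplex per line as comma-joined sorted labels, in global-id order
#' (stable across runs).
#' @param x a [CliqueComplex-class] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
dumpSimplices <- function(x, path) {
  writeLines(gsub(" ", ",", simplexKeys(x), fixed = TRUE), path)
  invisible(path)
}
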
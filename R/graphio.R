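#' Read an unweighted, undirected simple graph from an edge list
#'
#' Each non-empty, non-comment line must contain at least two
#' whitespace-separated vertex labels; tokens beyond the second are ignored.
#' Self-loops are dropped and duplicate edges (in either order) collapsed,
#' so the result is always a simple graph.  Vertices are exactly the
#' endpoints occurring in the file (including endpoints of dropped
#' self-loops); isolated vertices can be supplied through `vertices`.
#'
#' @param path path to a text edge list. Lines starting with `#` are skipped.
#' @param vertices optional character vector (or path to a one-label-per-line
#'   file) of additional vertex labels, e.g. isolated vertices that a bare
#'   edge list cannot express.
#' @return an [igraph::igraph] object with sorted vertex names.
#' @examples
#' tf <- tempfile()
#' writeLines(c("a a", "a b", "b a"), tf)
#' g <- readEdgelist(tf)
#' igraph::vcount(g); igraph::ecount(g)
#' @export
readEdgelist <- function(path, vertices = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop(sprintf("parse error: line %d of '%s' has fewer than two tokens", keep[bad[1L]], path))
  if (length(toks)) {
    em <- cbind(vapply(toks, `[[`, character(1), 1L),
                vapply(toks, `[[`, character(1), 2L))
  } else {
    em <- matrix(character(0), ncol = 2L)
  }
  if (!is.null(vertices) && length(vertices) == 1L && file.exists(vertices))
    vertices <- readLines(vertices, warn = FALSE)
  vertices <- setdiff(unique(c(as.character(vertices %||% character(0)), as.vector(em))), "")
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(vertices, igraph::V(g)$name)),
                            name = setdiff(vertices, igraph::V(g)$name))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  sortGraphVertices(g)
}

#' Write a graph as a plain-text edge list
#'
#' One edge per line, two tab-separated vertex labels, rows sorted; reading
#' the file back with [readEdgelist()] recovers the same edge set.
#'
#' @param graph an igraph object with vertex names.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1L], el[, 2L], method = "radix"), , drop = FALSE]
  }
  ok <- tryCatch({
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write edge list to ", path)
  invisible(path)
}

# canonical vertex ordering (C-locale radix sort) so runs are reproducible
sortGraphVertices <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nm
  }
  igraph::permute(g, match(nm, sort(nm, method = "radix")))
}

vertexLabels <- function(g) sort(igraph::V(g)$name, method = "radix")

#' Write a persistence diagram to TSV
#'
#' Tab-separated table with header `dim birth death multiplicity`, rows
#' sorted by (dim, birth, death), preceded by `#`-comment lines recording
#' the normalization constant and scheme.  Values are printed with 17
#' significant digits so the file round-trips losslessly through
#' [readDiagram()].
#'
#' @param diagram a [PersistenceDiagram-class] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDiagram <- function(diagram, path) {
  stopifnot(is(diagram, "PersistenceDiagram"))
  p <- diagram@points
  hdr <- c(sprintf("# w_N: %.17g", diagram@wN),
           sprintf("# scheme: %s", diagram@scheme),
           sprintf("# complex_dim: %d", diagram@complexDim),
           "dim\tbirth\tdeath\tmultiplicity")
  rows <- if (nrow(p)) {
    o <- order(p$dim, p$birth, p$death, method = "radix")
    sprintf("%d\t%.17g\t%.17g\t%d", p$dim[o], p$birth[o], p$death[o], p$multiplicity[o])
  } else character(0)
  ok <- tryCatch({ writeLines(c(hdr, rows), path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write diagram to ", path)
  invisible(path)
}

#' Read a persistence diagram written by [writeDiagram()]
#'
#' @param path path to a diagram TSV.
#' @return a [PersistenceDiagram-class] object.
#' @export
readDiagram <- function(path) {
  if (!file.exists(path)) stop("cannot read diagram: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1L]) else default
  }
  wN <- as.numeric(meta("w_N", "1"))
  scheme <- meta("scheme", "critical")
  cdim <- as.integer(meta("complex_dim", "0"))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) <= 1L) {
    pts <- data.frame(dim = integer(0), birth = numeric(0),
                      death = numeric(0), multiplicity = integer(0))
  } else {
    toks <- strsplit(body[-1L], "\t", fixed = TRUE)
    pts <- data.frame(
      dim          = as.integer(vapply(toks, `[[`, character(1), 1L)),
      birth        = as.numeric(vapply(toks, `[[`, character(1), 2L)),
      death        = as.numeric(vapply(toks, `[[`, character(1), 3L)),
      multiplicity = as.integer(vapply(toks, `[[`, character(1), 4L)))
  }
  new("PersistenceDiagram", points = pts, wN = wN, scheme = scheme, complexDim = cdim)
}
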
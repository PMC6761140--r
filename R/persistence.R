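# merge identical (dim, birth, death) rows, summing multiplicities, and
# sort by (dim, birth, death)
mergeMultiplicity <- function(p) {
  if (!nrow(p)) {
    return(data.frame(dim = integer(0), birth = numeric(0),
                      death = numeric(0), multiplicity = integer(0)))
  }
  key <- paste(p$dim, sprintf("%.17g", p$birth), sprintf("%.17g", p$death))
  mult <- tapply(p$multiplicity, key, sum)
  first <- !duplicated(key)
  out <- data.frame(dim = p$dim[first], birth = p$birth[first],
                    death = p$death[first],
                    multiplicity = as.integer(mult[key[first]]))
  out <- out[order(out$dim, out$birth, out$death, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persistent homology of a filtration
#'
#' Builds the boundary matrix over GF(2) in filtration order and applies
#' the standard left-to-right column reduction; each reduced column with a
#' lowest one pairs a birth simplex with the simplex that kills its class,
#' unpaired zero columns are essential classes.  Points of zero
#' persistence (equal birth and death weight) are dropped; essential
#' classes carry death = Inf and normalize to 1.
#'
#' @param filtration a [Filtration-class] object.
#' @param complex the [CliqueComplex-class] the filtration was built on.
#' @return a [PersistenceDiagram-class] object.
#' @export
persistenceDiagram <- function(filtration, complex) {
  stopifnot(is(filtration, "Filtration"), is(complex, "CliqueComplex"))
  N <- nSimplices(complex)
  if (length(filtration@weights) != N)
    stop("filtration does not match the complex")
  fw <- filtration@weights
  dims <- simplexDims(complex)
  d <- complexDim(complex)
  ord <- filtration@order
  pos <- integer(N); pos[ord] <- seq_len(N)
  cols <- vector("list", N)
  for (t in seq_len(N)) {
    gid <- ord[t]
    fac <- if (dims[gid] == 0L) integer(0) else simplexFacets(complex, gid)
    cols[[t]] <- sort(pos[fac])
  }
  partner <- reduce_boundary(cols)
  bi <- which(partner > 0L)
  dj <- partner[bi]
  gb <- ord[bi]; gd <- ord[dj]
  pts <- data.frame(dim = dims[gb], birth = fw[gb], death = fw[gd],
                    multiplicity = rep(1L, length(gb)))
  pts <- pts[pts$birth < pts$death, , drop = FALSE]
  ess <- ord[which(partner == 0L)]
  if (length(ess))
    pts <- rbind(pts, data.frame(dim = dims[ess], birth = fw[ess],
                                 death = Inf, multiplicity = rep(1L, length(ess))))
  new("PersistenceDiagram", points = mergeMultiplicity(pts),
      wN = filtration@wN, scheme = filtration@scheme,
      complexDim = max(d, 0L))
}

#' Points of a persistence diagram
#'
#' @param x a [PersistenceDiagram-class] object.
#' @param normalized if TRUE, divide births and deaths by the normalization
#'   constant and map essential deaths to exactly 1, placing the diagram in
#'   the unit square.
#' @return data.frame with columns dim, birth, death, multiplicity.
#' @export
diagramPoints <- function(x, normalized = FALSE) {
  stopifnot(is(x, "PersistenceDiagram"))
  p <- x@points
  if (normalized && nrow(p)) {
    p$birth <- p$birth / x@wN
    p$death <- ifelse(is.finite(p$death), p$death / x@wN, 1)
  } else if (normalized) {
    p$birth <- numeric(0); p$death <- numeric(0)
  }
  p
}

#' Betti numbers from a persistence diagram
#'
#' beta_p is the number of essential p-classes of a complete filtration of
#' the complex, i.e. the rank of the p-th homology group of the full
#' complex over GF(2).  When the complex dimension equals the construction
#' cap, the top-dimension value can be affected by the missing
#' higher-dimensional simplices.
#'
#' @param x a [PersistenceDiagram-class] object.
#' @return named integer vector beta_p for p = 0..complex dimension.
#' @export
bettiNumbers <- function(x) {
  stopifnot(is(x, "PersistenceDiagram"))
  p <- x@points
  ess <- p[is.infinite(p$death), , drop = FALSE]
  b <- vapply(0:x@complexDim, function(q) sum(ess$multiplicity[ess$dim == q]), numeric(1))
  setNames(as.integer(b), paste0("p", 0:x@complexDim))
}

#' Persistent Betti numbers
#'
#' Counts, per dimension, the classes born at or before w_i that are still
#' alive strictly after w_j.
#'
#' @param x a [PersistenceDiagram-class] object.
#' @param wi,wj weights with wi <= wj, on the raw filtration-weight scale.
#' @return named integer vector over dimensions 0..complex dimension.
#' @export
persistentBetti <- function(x, wi, wj) {
  stopifnot(is(x, "PersistenceDiagram"))
  if (wi > wj) stop("wi must be <= wj")
  p <- x@points
  sel <- p$birth <= wi & p$death > wj
  b <- vapply(0:x@complexDim, function(q) sum(p$multiplicity[sel & p$dim == q]), numeric(1))
  setNames(as.integer(b), paste0("p", 0:x@complexDim))
}

#' Barcode intervals of a persistence diagram
#'
#' Normalized [birth, death] intervals per dimension, multiplicity expanded
#' to repeated rows, sorted by (dim, birth, death); essential classes end
#' at exactly 1.
#'
#' @param x a [PersistenceDiagram-class] object.
#' @return data.frame with columns dim, birth, death.
#' @export
barcode <- function(x) {
  p <- diagramPoints(x, normalized = TRUE)
  idx <- rep(seq_len(nrow(p)), p$multiplicity)
  out <- data.frame(dim = p$dim[idx], birth = p$birth[idx], death = p$death[idx])
  out <- out[order(out$dim, out$birth, out$death, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
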
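## Multilevel force-directed layout in the FMMM spirit: matching-based
## coarsening, seeded random placement at the coarsest level, then per-level
## force refinement with locally approximated repulsion. Forces follow the
## Fruchterman-Reingold pair: attraction d^2/l along edges, repulsion
## C*l^2/d between node pairs closer than a cutoff of 3*l (beyond the
## cutoff repulsion is zero; this local truncation, computed on a spatial
## grid for larger graphs, replaces the multipole far-field of the original
## algorithm at the same asymptotic cost). The corresponding potential
##   E = sum_edges d^3/(3l) + sum_pairs C*l^2 * (log(rc) - log(d))  [d < rc]
## is minimised; a refinement sweep is only accepted when it does not
## increase E (backtracking on the step size otherwise), so the energy
## trace is non-increasing within each level. For an isolated dyad the
## balance d^2/l = C*l^2/d gives the equilibrium distance d* = C^(1/3)*l.

.N_EXACT <- 200L   # brute-force pair enumeration below this size, grid above

## Undirected simple edge list (index pairs) for layout purposes.
.layoutEdges <- function(ids, edges) {
  if (!nrow(edges)) return(matrix(integer(), ncol = 2))
  a <- match(edges$source, ids); b <- match(edges$target, ids)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- lo != hi
  m <- unique(cbind(lo[keep], hi[keep]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Coarsen a graph by repeated edge matching
#'
#' Builds the multilevel hierarchy used by [layoutGraph()]: at each level a
#' maximal matching (greedy, in deterministic edge order) merges matched
#' node pairs; coarsening stops when a level has at most `stopSize` nodes
#' or no merge is possible (for example on an edgeless graph).
#'
#' @param graph A [TypedGraph-class].
#' @param stopSize Target size of the coarsest level (at least 2).
#' @return List with `levels` (each: `ids` character vector and `edges`
#'   2-column index matrix) ordered finest first, and `maps` (for each
#'   non-finest level, a named character vector mapping finer ids to
#'   coarser ids).
#' @export
coarsenGraph <- function(graph, stopSize = 10L) {
  if (stopSize < 2L) bpStop("preconditionError", "stopSize must be >= 2")
  ids <- graphNodes(graph)$id
  em <- .layoutEdges(ids, graphEdges(graph))
  levels <- list(list(ids = ids, edges = em))
  maps <- list()
  repeat {
    cur <- levels[[length(levels)]]
    n <- length(cur$ids)
    if (n <= stopSize || !nrow(cur$edges)) break
    matched <- logical(n)
    partner <- integer(n)
    for (i in seq_len(nrow(cur$edges))) {
      a <- cur$edges[i, 1]; b <- cur$edges[i, 2]
      if (!matched[a] && !matched[b]) {
        matched[a] <- matched[b] <- TRUE
        partner[a] <- b; partner[b] <- a
      }
    }
    if (!any(matched)) break
    coarse <- integer(n); nextId <- 0L
    for (i in seq_len(n)) {
      if (coarse[i]) next
      nextId <- nextId + 1L
      coarse[i] <- nextId
      if (matched[i]) coarse[partner[i]] <- nextId
    }
    if (nextId >= n) break
    cids <- sprintf("m%d.%d", length(levels), seq_len(nextId))
    map <- stats::setNames(cids[coarse], cur$ids)
    ce <- unique(cbind(pmin(coarse[cur$edges[, 1]], coarse[cur$edges[, 2]]),
                       pmax(coarse[cur$edges[, 1]], coarse[cur$edges[, 2]])))
    ce <- ce[ce[, 1] != ce[, 2], , drop = FALSE]
    if (nrow(ce)) ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
    levels[[length(levels) + 1L]] <- list(ids = cids, edges = ce)
    maps[[length(maps) + 1L]] <- map
  }
  list(levels = levels, maps = maps)
}

## Repulsion pair list: index pairs closer than the cutoff. Brute force for
## small n; spatial grid with cell side = cutoff for larger n.
.repulsionPairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  if (n <= .N_EXACT) {
    idx <- utils::combn(n, 2)
    d2 <- rowSums((pos[idx[1, ], , drop = FALSE] -
                   pos[idx[2, ], , drop = FALSE])^2)
    keep <- d2 < cutoff^2
    return(t(idx[, keep, drop = FALSE]))
  }
  cell <- apply(floor(sweep(pos, 2, apply(pos, 2, min)) / cutoff), 1,
                paste, collapse = ",")
  ## neighbour-cell offsets
  dims <- ncol(pos)
  offs <- as.matrix(expand.grid(rep(list(-1:1), dims)))
  coords <- floor(sweep(pos, 2, apply(pos, 2, min)) / cutoff)
  byCell <- split(seq_len(n), cell)
  keyOf <- function(m) apply(m, 1, paste, collapse = ",")
  out <- list()
  for (k in names(byCell)) {
    here <- byCell[[k]]
    base <- coords[here[1], ]
    nbKeys <- keyOf(sweep(offs, 2, -base))
    cand <- unlist(byCell[intersect(nbKeys, names(byCell))], use.names = FALSE)
    for (i in here) {
      j <- cand[cand > i]
      if (!length(j)) next
      d2 <- colSums((t(pos[j, , drop = FALSE]) - pos[i, ])^2)
      jj <- j[d2 < cutoff^2]
      if (length(jj)) out[[length(out) + 1L]] <- cbind(i, jj)
    }
  }
  if (!length(out)) matrix(integer(), ncol = 2) else do.call(rbind, out)
}

#' Total layout energy of a coordinate assignment
#'
#' The potential minimised by [layoutGraph()]: cubic spring energy along
#' edges plus truncated logarithmic repulsion between node pairs within the
#' cutoff (3 times the natural edge length).
#'
#' @param graph A [TypedGraph-class].
#' @param coords Numeric matrix of coordinates, rownames = node ids.
#' @param params A [LayoutParams-class].
#' @return Numeric scalar (non-negative).
#' @export
layoutEnergy <- function(graph, coords, params = layoutParams()) {
  ids <- graphNodes(graph)$id
  pos <- coords[ids, , drop = FALSE]
  em <- .layoutEdges(ids, graphEdges(graph))
  .energy(pos, em, params@edgeLength, params@repulsion)
}

.energy <- function(pos, em, ell, C) {
  e <- 0
  if (nrow(em)) {
    d <- sqrt(rowSums((pos[em[, 1], , drop = FALSE] -
                       pos[em[, 2], , drop = FALSE])^2))
    e <- e + sum(d^3) / (3 * ell)
  }
  rc <- 3 * ell
  pr <- .repulsionPairs(pos, rc)
  if (nrow(pr)) {
    d <- sqrt(rowSums((pos[pr[, 1], , drop = FALSE] -
                       pos[pr[, 2], , drop = FALSE])^2))
    d <- pmax(d, 1e-9)
    e <- e + C * ell^2 * sum(log(rc) - log(d))
  }
  e
}

.forces <- function(pos, em, ell, C) {
  F <- matrix(0, nrow(pos), ncol(pos))
  if (nrow(em)) {
    delta <- pos[em[, 2], , drop = FALSE] - pos[em[, 1], , drop = FALSE]
    d <- pmax(sqrt(rowSums(delta^2)), 1e-9)
    f <- delta * (d / ell)            # unit * d^2/ell
    for (k in seq_len(nrow(em))) {
      F[em[k, 1], ] <- F[em[k, 1], ] + f[k, ]
      F[em[k, 2], ] <- F[em[k, 2], ] - f[k, ]
    }
  }
  rc <- 3 * ell
  pr <- .repulsionPairs(pos, rc)
  if (nrow(pr)) {
    delta <- pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE]
    d <- pmax(sqrt(rowSums(delta^2)), 1e-9)
    f <- delta * (C * ell^2 / d^2)    # unit * C*ell^2/d
    for (k in seq_len(nrow(pr))) {
      F[pr[k, 1], ] <- F[pr[k, 1], ] + f[k, ]
      F[pr[k, 2], ] <- F[pr[k, 2], ] - f[k, ]
    }
  }
  F
}

## One level of refinement. Returns list(pos, energies, sweeps).
.refine <- function(pos, em, params, t0) {
  ell <- params@edgeLength; C <- params@repulsion
  t <- t0
  energies <- .energy(pos, em, ell, C)
  sweeps <- 0L
  for (it in seq_len(params@maxIter)) {
    F <- .forces(pos, em, ell, C)
    fn <- pmax(sqrt(rowSums(F^2)), 1e-12)
    accepted <- FALSE
    for (bt in 1:12) {
      step <- F * (pmin(fn, t) / fn)
      cand <- pos + step
      eNew <- .energy(cand, em, ell, C)
      if (eNew <= energies[length(energies)] + 1e-9) {
        maxDisp <- max(sqrt(rowSums(step^2)))
        pos <- cand
        energies <- c(energies, eNew)
        sweeps <- sweeps + 1L
        t <- t * 0.95
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
    if (maxDisp < params@tol) break
  }
  list(pos = pos, energies = energies, sweeps = sweeps)
}

#' Compute a 2D or 3D force-directed layout
#'
#' Multilevel scheme: [coarsenGraph()] hierarchy, seeded uniform placement
#' of the coarsest level in a cube of side `edgeLength * sqrt(n)`, then
#' per-level refinement sweeps (energy non-increasing; see the package
#' vignette) with prolongation of coarse positions to the finer level. The
#' result is centred at the origin. Identical inputs and seed give
#' bit-identical coordinates.
#'
#' @param graph A non-empty [TypedGraph-class].
#' @param dims 2 (default) or 3.
#' @param params A [LayoutParams-class].
#' @param seed Integer random seed (default 42; always logged in the result).
#' @return A [LayoutResult-class].
#' @export
#' @examples
#' g <- typedGraph(data.frame(id = c("a", "b"), biopaxClass = "Protein",
#'                            label = c("a", "b"), uri = c("u:a", "u:b")),
#'                 data.frame(source = "a", target = "b",
#'                            kind = "participant", directed = FALSE))
#' res <- layoutGraph(g, dims = 2, seed = 42)
#' dist(layoutCoords(res))  # ~ 1 (the natural edge length)
layoutGraph <- function(graph, dims = 2L, params = layoutParams(), seed = 42L) {
  if (!nrow(graphNodes(graph)))
    bpStop("preconditionError", "cannot lay out an empty graph")
  if (!dims %in% c(2L, 3L))
    bpStop("preconditionError", "dims must be 2 or 3")
  dims <- as.integer(dims)
  ids <- graphNodes(graph)$id
  ell <- params@edgeLength

  if (length(ids) == 1L) {
    coords <- matrix(0, 1, dims, dimnames = list(ids, NULL))
    return(new("LayoutResult", coordinates = coords, dims = dims,
               seed = as.integer(seed), iterationsUsed = 0L,
               energyTrace = list()))
  }

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  h <- coarsenGraph(graph, params@stopSize)
  nlev <- length(h$levels)
  coarse <- h$levels[[nlev]]
  n0 <- length(coarse$ids)
  side <- ell * sqrt(n0)
  pos <- matrix(stats::runif(n0 * dims, -side / 2, side / 2), n0, dims)
  rownames(pos) <- coarse$ids

  trace <- vector("list", nlev)
  totalSweeps <- 0L
  for (lv in seq(nlev, 1L)) {
    level <- h$levels[[lv]]
    if (lv < nlev) {
      ## prolongate: children inherit the coarse position plus a small
      ## seeded jitter to break ties between merged partners
      map <- h$maps[[lv]]
      jitter <- matrix(stats::runif(length(level$ids) * dims,
                                    -ell / 10, ell / 10),
                       length(level$ids), dims)
      pos <- pos[unname(map[level$ids]), , drop = FALSE] + jitter
      rownames(pos) <- level$ids
    }
    r <- .refine(pos, level$edges, params, t0 = ell)
    pos <- r$pos
    trace[[nlev - lv + 1L]] <- r$energies
    totalSweeps <- totalSweeps + r$sweeps
  }
  pos <- sweep(pos, 2, colMeans(pos))
  pos <- pos[ids, , drop = FALSE]
  new("LayoutResult", coordinates = pos, dims = dims, seed = as.integer(seed),
      iterationsUsed = totalSweeps, energyTrace = trace)
}
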
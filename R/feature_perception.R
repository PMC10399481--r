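#' Feature-perception rule set
#'
#' Tunable rules for deriving pharmacophore annotation points from a 3D
#' structure. The defaults implement a deterministic, format-driven scheme:
#' donors at N/O atoms bearing explicit hydrogens, aromatic centroids from
#' SDF aromatic bond flags (with a planarity fallback), and hydrophobic
#' centroids from maximal carbon/halogen clusters.
#'
#' @param min_cluster_size Minimum atom count of a hydrophobic cluster
#'   (default 3).
#' @param planarity_tol Maximum deviation (Angstrom) from the least-squares
#'   ring plane for the aromaticity fallback (default 0.10).
#' @param ring_size Integer range of ring sizes eligible as aromatic
#'   (default 5 to 7).
#' @return A `perception_rules` list.
#' @export
perception_rules <- function(min_cluster_size = 3L, planarity_tol = 0.10,
                             ring_size = c(5L, 7L)) {
  stopifnot(min_cluster_size >= 1L, planarity_tol >= 0,
            length(ring_size) == 2L, ring_size[1] <= ring_size[2])
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 planarity_tol = planarity_tol,
                 ring_size = as.integer(ring_size)),
            class = "perception_rules")
}

#' Smallest set of smallest rings
#'
#' Computes a minimum cycle basis of the molecule's bond graph (SSSR):
#' for every bond the shortest cycle through it is found by breadth-first
#' search, candidates are sorted by length, and a maximal GF(2)-independent
#' subset of size m - n + c (the cyclomatic number) is kept.
#'
#' @param mol A [molecule3d()].
#' @return List of integer vectors, each a ring as atom indices in cycle
#'   order; rings sorted by their smallest member index. Acyclic molecules
#'   give an empty list.
#' @export
ring_perception <- function(mol) {
  validate_molecule3d(mol)
  b <- mol$bonds
  n <- nrow(mol$atoms)
  m <- nrow(b)
  if (m == 0L) return(list())
  adj <- adjacency_list(mol)
  # cyclomatic number = m - n + number of connected components
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  rank_target <- m - n + cid
  if (rank_target <= 0L) return(list())

  edge_id <- function(i, j) paste(pmin(i, j), pmax(i, j))
  all_ids <- edge_id(b$a1, b$a2)

  # shortest cycle through each edge: BFS from a1 to a2 avoiding the edge
  candidates <- list()
  for (e in seq_len(m)) {
    src <- b$a1[e]; dst <- b$a2[e]
    prev <- integer(n); seen <- logical(n)
    seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if ((v == src && w == dst) || (v == dst && w == src)) next
        if (!seen[w]) {
          seen[w] <- TRUE; prev[w] <- v
          if (w == dst) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (found) {
      path <- dst
      while (path[1L] != src) path <- c(prev[path[1L]], path)
      candidates[[length(candidates) + 1L]] <- path  # cycle order; edge dst-src closes it
    }
  }
  if (!length(candidates)) return(list())
  # deduplicate by edge set, sort by length then smallest member
  edgesets <- lapply(candidates, function(cyc) {
    p <- c(cyc, cyc[1L])
    sort(vapply(seq_along(cyc), function(i) edge_id(p[i], p[i + 1L]), ""))
  })
  keykeep <- !duplicated(vapply(edgesets, paste, "", collapse = "|"))
  candidates <- candidates[keykeep]; edgesets <- edgesets[keykeep]
  ord <- order(lengths(candidates),
               vapply(candidates, function(x) min(as.integer(x)), 0L),
               vapply(candidates, paste, "", collapse = " "))
  candidates <- candidates[ord]; edgesets <- edgesets[ord]

  # GF(2) Gaussian elimination over edge-incidence vectors
  basis <- matrix(0L, nrow = 0L, ncol = m)
  pivots <- integer()
  rings <- list()
  for (k in seq_along(candidates)) {
    vec <- as.integer(all_ids %in% edgesets[[k]])
    v <- vec
    for (r in seq_len(nrow(basis)))
      if (v[pivots[r]] == 1L) v <- (v + basis[r, ]) %% 2L
    if (any(v == 1L)) {
      basis <- rbind(basis, v)
      pivots <- c(pivots, which(v == 1L)[1L])
      rings[[length(rings) + 1L]] <- candidates[[k]]
      if (length(rings) == rank_target) break
    }
  }
  rings[order(vapply(rings, function(x) min(as.integer(x)), 0L))]
}

halogens <- c("F", "Cl", "Br", "I")

#' Perceive pharmacophore annotation points
#'
#' Derives the ligand-side feature points that the matcher assigns to query
#' features:
#' \describe{
#'   \item{donor}{one point at each N or O atom with at least one bonded
#'     (explicit) hydrogen, placed on the heavy atom;}
#'   \item{aromatic}{one point at the centroid of each ring of eligible size
#'     whose bonds all carry the SDF aromatic flag, or — when no ring bond is
#'     flagged — whose atoms fit a least-squares plane within the planarity
#'     tolerance;}
#'   \item{hydrophobic}{one point at the centroid of each maximal connected
#'     cluster of carbon/halogen atoms (cluster size above the minimum) none
#'     of which is bonded to N, O or a formally charged atom.}
#' }
#'
#' Molecules without explicit hydrogens are processed with a warning, since
#' donor features cannot be perceived.
#'
#' @param mol A [molecule3d()].
#' @param rules A [perception_rules()] object.
#' @return `data.frame` with columns `kind`, `x`, `y`, `z` and a list column
#'   `atoms` (source atom indices). Zero rows is a valid result.
#' @export
perceive_features <- function(mol, rules = perception_rules()) {
  validate_molecule3d(mol)
  a <- mol$atoms
  adj <- adjacency_list(mol)
  xyz <- coords3d(mol)
  if (!any(a$element == "H"))
    warning("molecule '", mol$id,
            "' has no explicit hydrogens; donor features cannot be perceived")

  kinds <- character(); pos <- matrix(numeric(), ncol = 3)
  src <- list()
  add <- function(kind, p, atoms) {
    kinds <<- c(kinds, kind)
    pos <<- rbind(pos, p)
    src[[length(src) + 1L]] <<- atoms
  }

  # donors: N/O with >=1 explicit H neighbour, point on the heavy atom
  for (i in which(a$element %in% c("N", "O"))) {
    nb <- adj[[i]]
    if (length(nb) && any(a$element[nb] == "H"))
      add("donor", xyz[i, ], i)
  }

  # aromatic ring centroids
  ring_ok <- function(cyc) {
    sz <- length(cyc)
    if (sz < rules$ring_size[1] || sz > rules$ring_size[2]) return(FALSE)
    p <- c(cyc, cyc[1L])
    b <- mol$bonds
    arom <- logical(sz)
    for (i in seq_len(sz)) {
      hit <- which((b$a1 == p[i] & b$a2 == p[i + 1L]) |
                   (b$a2 == p[i] & b$a1 == p[i + 1L]))
      arom[i] <- length(hit) > 0 && b$aromatic[hit[1L]]
    }
    if (all(arom)) return(TRUE)
    if (any(arom)) return(FALSE)
    # flag-free fallback: least-squares planarity
    pts <- xyz[cyc, , drop = FALSE]
    ctr <- colMeans(pts)
    cen <- sweep(pts, 2L, ctr)
    normal <- svd(cen)$v[, 3L]
    max(abs(cen %*% normal)) <= rules$planarity_tol
  }
  for (cyc in ring_perception(mol)) {
    if (ring_ok(cyc))
      add("aromatic", colMeans(xyz[cyc, , drop = FALSE]), cyc)
  }

  # hydrophobic clusters: maximal connected sets of qualifying C/halogen atoms
  qual <- a$element %in% c("C", halogens) & a$charge == 0L
  for (i in which(qual)) {
    nb <- adj[[i]]
    if (length(nb) &&
        (any(a$element[nb] %in% c("N", "O")) || any(a$charge[nb] != 0L)))
      qual[i] <- FALSE
  }
  visited <- logical(nrow(a))
  for (s in which(qual)) {
    if (visited[s]) next
    clu <- s; visited[s] <- TRUE; queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (qual[w] && !visited[w]) {
        visited[w] <- TRUE; clu <- c(clu, w); queue <- c(queue, w)
      }
    }
    if (length(clu) >= rules$min_cluster_size)
      add("hydrophobic", colMeans(xyz[clu, , drop = FALSE]), sort(clu))
  }

  if (!length(kinds))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), atoms = I(list())))
  out <- data.frame(kind = kinds, x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  out$atoms <- I(src)
  rownames(out) <- NULL
  out
}
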
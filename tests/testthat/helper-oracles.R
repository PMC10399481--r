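# Independent oracles used to cross-check package computations. These
# deliberately use different algorithms from the implementation:
# quaternion (Horn) superposition instead of SVD (Kabsch), explicit
# permutation enumeration instead of recursive DFS, and direct formula
# re-evaluation for the enrichment statistics.

# Horn's closed-form quaternion solution for the optimal proper rotation
# superposing X onto Y (row vectors). Returns the minimal RMSD.
horn_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  S <- t(Xc) %*% Yc
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-z*w),   2*(x*z+y*w),
    2*(x*y+z*w),   1-2*(x^2+z^2), 2*(y*z-x*w),
    2*(x*z-y*w),   2*(y*z+x*w),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  aligned <- Xc %*% t(R)
  list(rmsd = sqrt(mean(rowSums((aligned - Yc)^2))),
       aligned = sweep(aligned, 2, cy, "+"))
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# brute-force matcher: scores every injective type-compatible assignment
# explicitly and returns the minimal qualifying RMSD (or NA)
oracle_match_rmsd <- function(query, points, mode = "superpose",
                              cutoff = 1.0) {
  kinds <- vapply(query$features, `[[`, "", "kind")
  centers <- do.call(rbind, lapply(query$features, `[[`, "center"))
  radii <- vapply(query$features, `[[`, 0, "radius")
  P <- as.matrix(points[, c("x", "y", "z")])
  # assignments = cartesian product of per-kind permutations of candidates
  maps_per_kind <- list()
  for (k in unique(kinds)) {
    slots <- which(kinds == k)
    cand <- which(points$kind == k)
    if (length(cand) < length(slots)) return(NA_real_)
    sub <- if (length(cand) > 1) utils::combn(cand, length(slots),
                                              simplify = FALSE)
           else list(cand)
    maps <- list()
    for (cc in sub) for (p in perms(cc))
      maps[[length(maps) + 1L]] <- stats::setNames(p, slots)
    maps_per_kind[[k]] <- maps
  }
  grids <- expand.grid(lapply(maps_per_kind, seq_along))
  best <- NA_real_
  for (g in seq_len(nrow(grids))) {
    assign <- integer(length(kinds))
    for (k in names(maps_per_kind)) {
      mp <- maps_per_kind[[k]][[grids[g, k]]]
      assign[as.integer(names(mp))] <- mp
    }
    X <- P[assign, , drop = FALSE]
    if (mode == "superpose") {
      h <- horn_rmsd(X, centers)
      r <- h$rmsd; al <- h$aligned
    } else {
      r <- sqrt(mean(rowSums((X - centers)^2))); al <- X
    }
    if (r <= cutoff &&
        all(sqrt(rowSums((al - centers)^2)) <= radii + 1e-9) &&
        (is.na(best) || r < best))
      best <- r
  }
  best
}

# all simple cycles of a small undirected graph, by DFS from each root
enumerate_cycles <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  cycles <- list()
  seen <- character()
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!w %in% path && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  cycles
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-z*w),   2*(x*z+y*w),
    2*(x*y+z*w),   1-2*(x^2+z^2), 2*(y*z-x*w),
    2*(x*z-y*w),   2*(y*z+x*w),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

rigid_transform_points <- function(P, R, t) sweep(P %*% t(R), 2, t, "+")

# random annotation-point table with the given kind counts
random_points <- function(n_donor, n_aromatic, n_hydrophobic, scale = 5) {
  kinds <- c(rep("donor", n_donor), rep("aromatic", n_aromatic),
             rep("hydrophobic", n_hydrophobic))
  n <- length(kinds)
  data.frame(kind = kinds,
             x = stats::runif(n, -scale, scale),
             y = stats::runif(n, -scale, scale),
             z = stats::runif(n, -scale, scale))
}

# a benzene hexagon molecule (optionally with ring hydrogens), centred at ctr
make_benzene <- function(ctr = c(0, 0, 0), with_h = FALSE, flags = TRUE) {
  ang <- (0:5) * pi / 3
  atoms <- data.frame(element = rep("C", 6), charge = 0L,
                      x = ctr[1] + 1.39 * cos(ang),
                      y = ctr[2] + 1.39 * sin(ang),
                      z = ctr[3])
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1),
                      order = if (flags) 4L else 1L,
                      aromatic = flags)
  if (with_h) {
    atoms <- rbind(atoms, data.frame(element = rep("H", 6), charge = 0L,
                                     x = ctr[1] + 2.48 * cos(ang),
                                     y = ctr[2] + 2.48 * sin(ang),
                                     z = ctr[3]))
    bonds <- rbind(bonds, data.frame(a1 = 1:6, a2 = 7:12, order = 1L,
                                     aromatic = FALSE))
  }
  molecule3d("benzene", atoms, bonds)
}

make_hexane <- function() {
  molecule3d("n-hexane",
             data.frame(element = rep("C", 6), charge = 0L,
                        x = 1.54 * (0:5), y = rep(c(0, 0.5), 3), z = 0),
             data.frame(a1 = 1:5, a2 = 2:6, order = 1L, aromatic = FALSE))
}

make_methanol <- function() {
  molecule3d("methanol",
             data.frame(element = c("C", "O", "H", "H", "H", "H"),
                        charge = 0L,
                        x = c(0, 1.43, 1.75, -0.5, -0.5, -0.5),
                        y = c(0, 0, 0.9, 0.9, -0.9, 0),
                        z = c(0, 0, 0, 0, 0, 1)),
             data.frame(a1 = c(1, 2, 1, 1, 1), a2 = c(2, 3, 4, 5, 6),
                        order = 1L, aromatic = FALSE))
}

# random realizable screening count tuples (D, A, Ht, Ha)
random_gh_tuple <- function() {
  D <- sample(10:2000, 1)
  A <- sample(seq_len(D - 1), 1)
  Ht <- sample(seq_len(D), 1)
  lo <- max(0, Ht - (D - A))   # inactive hits cannot exceed inactives
  hi <- min(Ht, A)
  Ha <- if (lo == hi) lo else sample(lo:hi, 1)
  c(D = D, A = A, Ht = Ht, Ha = Ha)
}
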
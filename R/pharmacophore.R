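#' Pharmacophore feature sphere
#'
#' A typed tolerance sphere: the query is satisfied when a ligand annotation
#' point of the same kind lies inside the sphere after placement.
#'
#' @param kind One of `"donor"`, `"aromatic"`, `"hydrophobic"`.
#' @param center Numeric xyz (Angstrom).
#' @param radius Tolerance radius in Angstrom (> 0; default 1.0).
#' @return A `pharmacophore_feature`.
#' @export
pharmacophore_feature <- function(kind, center, radius = 1.0) {
  kind <- match.arg(kind, c("donor", "aromatic", "hydrophobic"))
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)), radius > 0)
  structure(list(kind = kind, center = center, radius = radius),
            class = "pharmacophore_feature")
}

#' Pharmacophore query
#'
#' An ordered set of feature spheres. A molecule matches only when every
#' feature is satisfied simultaneously by distinct annotation points.
#'
#' @param name Query label.
#' @param features List of [pharmacophore_feature()] objects (at least one).
#' @return A `pharmacophore_query`.
#' @export
pharmacophore_query <- function(name, features) {
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, TRUE, "pharmacophore_feature")))
  structure(list(name = name, features = features),
            class = "pharmacophore_query")
}

#' @export
print.pharmacophore_query <- function(x, ...) {
  cat("<pharmacophore_query>", x$name, "-", length(x$features), "features:",
      paste(vapply(x$features, `[[`, "", "kind"), collapse = ", "), "\n")
  invisible(x)
}

query_centers <- function(query)
  do.call(rbind, lapply(query$features, `[[`, "center"))

query_kinds <- function(query) vapply(query$features, `[[`, "", "kind")

query_radii <- function(query) vapply(query$features, `[[`, 0, "radius")

#' Read / write a pharmacophore query as JSON
#'
#' Schema: `{"name": str, "features": [{"kind": "donor|aromatic|hydrophobic",
#' "center": [x,y,z], "radius": r}]}`.
#'
#' @param path JSON file path.
#' @return [read_query_json()] returns a `pharmacophore_query`;
#'   [write_query_json()] returns `path` invisibly.
#' @export
read_query_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  feats <- lapply(j$features, function(f)
    pharmacophore_feature(f$kind, unlist(f$center), f$radius))
  pharmacophore_query(j$name, feats)
}

#' @rdname read_query_json
#' @param query A `pharmacophore_query` to serialise.
#' @export
write_query_json <- function(query, path) {
  j <- list(name = query$name,
            features = lapply(query$features, function(f)
              list(kind = f$kind, center = f$center, radius = f$radius)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The packaged four-feature example query
#'
#' A synthetic dual-screening query with the feature typing used for the
#' CARM1-style model — one hydrogen-bond donor, two aromatic centres and one
#' hydrophobic centroid — arranged as a near-tetrahedron with edge lengths
#' between 4 and 8 Angstrom. The coordinates are illustrative constructs,
#' not a reconstruction of any crystal-structure-derived model.
#'
#' @param radius Feature tolerance radius in Angstrom (default 1.0).
#' @return A `pharmacophore_query` with 4 features.
#' @export
example_query <- function(radius = 1.0) {
  pharmacophore_query("CARM1-style-4feat", list(
    pharmacophore_feature("donor",       c(0.0, 0.0, 0.0), radius),
    pharmacophore_feature("aromatic",    c(4.5, 0.0, 0.0), radius),
    pharmacophore_feature("aromatic",    c(2.2, 4.2, 0.0), radius),
    pharmacophore_feature("hydrophobic", c(2.3, 1.6, 3.9), radius)))
}

# least-squares rigid superposition of X onto Y (row vectors), proper
# rotation only; no dimension checks (internal)
kabsch_core <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)      # X %*% R aligns onto Y
  t_vec <- cy - as.numeric(cx %*% R)
  aligned <- sweep(X %*% R, 2L, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((aligned - Y)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, aligned = aligned)
}

#' Match a pharmacophore query against annotation points
#'
#' Enumerates every injective, type-compatible assignment of ligand
#' annotation points to query features. In `superpose` mode each assignment
#' is scored by the RMSD after optimal least-squares rigid superposition
#' (proper rotation only — reflections are rejected so chirality is never
#' erased) of the mapped points onto the feature centers; in `in_place` mode
#' the RMSD is computed on the raw coordinates. The minimal-RMSD assignment
#' satisfying both the RMSD cutoff and per-feature sphere containment is
#' returned; ties are broken by the lexicographically smallest mapping.
#'
#' @param query A [pharmacophore_query()].
#' @param points Annotation points from [perceive_features()].
#' @param mode `"superpose"` (default) or `"in_place"`.
#' @param rmsd_cutoff Maximum acceptable RMSD in Angstrom (> 0; default 1.0).
#' @param max_assignments Combinatorial guard: if the number of injective
#'   assignments exceeds this ceiling an error of class
#'   `dualphore_capacity_error` is raised instead of silently truncating.
#' @param compound_id Optional label copied into the result.
#' @return A `match_result` list with elements `compound_id`, `matched`,
#'   `rmsd` (Angstrom, `NA` when unmatched), `mapping` (feature index ->
#'   annotation point row), and `transform` (list with `rotation`,
#'   `translation`).
#' @export
match_query <- function(query, points, mode = c("superpose", "in_place"),
                        rmsd_cutoff = 1.0, max_assignments = 1e6,
                        compound_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(rmsd_cutoff > 0)
  kinds <- query_kinds(query)
  centers <- query_centers(query)
  radii <- query_radii(query)
  nf <- length(kinds)

  no_match <- structure(
    list(compound_id = compound_id, matched = FALSE, rmsd = NA_real_,
         mapping = NULL, transform = NULL),
    class = "match_result")
  if (nrow(points) == 0L) return(no_match)

  cand <- lapply(kinds, function(k) which(points$kind == k))
  if (any(lengths(cand) == 0L)) return(no_match)

  # assignment count bound: product over kinds of falling factorials
  n_assign <- 1
  for (k in unique(kinds)) {
    nk <- sum(points$kind == k)
    mk <- sum(kinds == k)
    if (nk < mk) return(no_match)
    n_assign <- n_assign * prod(nk - seq_len(mk) + 1)
  }
  if (n_assign > max_assignments)
    stop(structure(class = c("dualphore_capacity_error", "error", "condition"),
                   list(message = sprintf(
                     "assignment count %.3g exceeds ceiling %.3g",
                     n_assign, max_assignments), call = NULL)))

  P <- as.matrix(points[, c("x", "y", "z")])
  best <- NULL
  assign <- integer(nf)
  used <- logical(nrow(points))

  score_assignment <- function(idx) {
    X <- P[idx, , drop = FALSE]
    if (mode == "superpose") {
      fit <- kabsch_core(X, centers)
      list(rmsd = fit$rmsd, aligned = fit$aligned,
           transform = list(rotation = fit$rotation,
                            translation = fit$translation))
    } else {
      list(rmsd = sqrt(mean(rowSums((X - centers)^2))), aligned = X,
           transform = list(rotation = diag(3), translation = c(0, 0, 0)))
    }
  }

  recurse <- function(f) {
    if (f > nf) {
      sc <- score_assignment(assign)
      if (sc$rmsd <= rmsd_cutoff &&
          all(sqrt(rowSums((sc$aligned - centers)^2)) <= radii + 1e-9)) {
        if (is.null(best) || sc$rmsd < best$rmsd - 1e-12 ||
            (abs(sc$rmsd - best$rmsd) <= 1e-12 &&
             lex_less(assign, best$mapping)))
          best <<- list(rmsd = sc$rmsd, mapping = assign,
                        transform = sc$transform)
      }
      return(invisible())
    }
    for (p in cand[[f]]) {
      if (!used[p]) {
        used[p] <<- TRUE; assign[f] <<- p
        recurse(f + 1L)
        used[p] <<- FALSE
      }
    }
  }
  recurse(1L)

  if (is.null(best)) return(no_match)
  structure(list(compound_id = compound_id, matched = TRUE,
                 rmsd = best$rmsd, mapping = best$mapping,
                 transform = best$transform),
            class = "match_result")
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Screen a molecule library against a pharmacophore query
#'
#' Runs [perceive_features()] then [match_query()] on every molecule and
#' returns the matched compounds only, preserving library order. Molecules
#' that trip the combinatorial guard are logged and counted in the
#' `failures` attribute, never fatal.
#'
#' @inheritParams match_query
#' @param mols List of [molecule3d()] objects.
#' @param rules A [perception_rules()] object.
#' @return List of matched `match_result`s with attribute `failures`
#'   (character vector of compound ids that could not be evaluated).
#' @export
screen_library <- function(query, mols, rules = perception_rules(),
                           mode = c("superpose", "in_place"),
                           rmsd_cutoff = 1.0, max_assignments = 1e6) {
  mode <- match.arg(mode)
  hits <- list()
  failures <- character()
  for (mol in mols) {
    res <- tryCatch(
      match_query(query,
                  suppressWarnings(perceive_features(mol, rules)),
                  mode = mode, rmsd_cutoff = rmsd_cutoff,
                  max_assignments = max_assignments,
                  compound_id = mol$id),
      dualphore_capacity_error = function(e) {
        failures <<- c(failures, mol$id)
        NULL
      })
    if (!is.null(res) && res$matched) hits[[length(hits) + 1L]] <- res
  }
  attr(hits, "failures") <- failures
  hits
}

#' Compound ids of a hit list
#'
#' @param hits Result of [screen_library()].
#' @return Character vector of matched compound ids, in library order.
#' @export
hit_ids <- function(hits) vapply(hits, `[[`, "", "compound_id")
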
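#' Synthetic-data generator settings
#'
#' One settings object drives every generator so a whole pipeline run is a
#' pure function of the seed. The defaults define the package's reference
#' study conditions: a validation library of 10 planted actives and 100
#' decoys with 0.2 Angstrom feature jitter (a reduced-scale emulation of a
#' decoy-set validation of ~1500 molecules), docking scores scattered around
#' per-target cutoffs, a 4-parameter logistic dose-response (IC50 10 nM,
#' Hill 1) with 2 percent noise, and a 200-residue alpha-carbon trajectory
#' with a rigid core and 5x-floppier termini recorded every 10 ps.
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   generator output.
#' @param n_actives,n_decoys Library composition.
#' @param feature_jitter Gaussian displacement (Angstrom, per coordinate) of
#'   planted fragments around the query feature centers.
#' @param score List: `cutoffs` (named kcal/mol vector per target), `sd`
#'   (spread around the cutoff), `margin` (minimum clearance from the
#'   cutoff), `passers` (named list of compound ids planted to pass each
#'   target).
#' @param dose List: `ic50` (molar), `hill`, `top`, `bottom`, `noise_pct`
#'   (percent of the dynamic range), `concentrations` (molar),
#'   `replicates` (default 3, matching triplicate assay wells).
#' @param traj List: `n_residues`, `n_frames`, `core_sigma` (Angstrom,
#'   per coordinate), `terminal_multiplier`, `n_terminal` (floppy residues
#'   at each end), `frame_interval` (ps).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, n_actives = 10L, n_decoys = 100L,
                           feature_jitter = 0.2,
                           score = list(), dose = list(), traj = list()) {
  stopifnot(feature_jitter >= 0, n_actives >= 0, n_decoys >= 0)
  score <- utils::modifyList(list(
    cutoffs = c(CARM1 = -11.3, HDAC2 = -11.7), sd = 0.3, margin = 0.05,
    passers = list()), score)
  dose <- utils::modifyList(list(
    ic50 = 1e-8, hill = 1, top = 100, bottom = 0, noise_pct = 2,
    concentrations = 10^seq(-10, -6, length.out = 8), replicates = 3L),
    dose)
  traj <- utils::modifyList(list(
    n_residues = 200L, n_frames = 100L, core_sigma = 0.15,
    terminal_multiplier = 5, n_terminal = 5L, frame_interval = 10),
    traj)
  structure(list(seed = as.integer(seed), n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 feature_jitter = feature_jitter,
                 score = score, dose = dose, traj = traj),
            class = "generator_spec")
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- minimal hand-built fragment geometries ---------------------------------
# regular benzene hexagon (C-C 1.39 A) with ring hydrogens, in the xy-plane
frag_benzene <- function(center) {
  ang <- (0:5) * pi / 3
  cpos <- cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
                center[3])
  hpos <- cbind(center[1] + 2.48 * cos(ang), center[2] + 2.48 * sin(ang),
                center[3])
  atoms <- data.frame(element = c(rep("C", 6), rep("H", 6)), charge = 0L,
                      x = c(cpos[, 1], hpos[, 1]),
                      y = c(cpos[, 2], hpos[, 2]),
                      z = c(cpos[, 3], hpos[, 3]))
  bonds <- rbind(
    data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4L, aromatic = TRUE),
    data.frame(a1 = 1:6, a2 = 7:12, order = 1L, aromatic = FALSE))
  list(atoms = atoms, bonds = bonds, attach = 1L)
}

# hydroxyl: donor O at the feature point, explicit H at 0.96 A
frag_hydroxyl <- function(center) {
  atoms <- data.frame(element = c("O", "H"), charge = 0L,
                      x = center[1] + c(0, 0.96), y = center[2],
                      z = center[3])
  bonds <- data.frame(a1 = 1L, a2 = 2L, order = 1L, aromatic = FALSE)
  list(atoms = atoms, bonds = bonds, attach = 1L)
}

# three-carbon cluster (1.54 A spacing) centred on the feature point
frag_alkyl <- function(center) {
  atoms <- data.frame(element = rep("C", 3), charge = 0L,
                      x = center[1] + c(-1.54, 0, 1.54), y = center[2],
                      z = center[3])
  bonds <- data.frame(a1 = 1:2, a2 = 2:3, order = 1L, aromatic = FALSE)
  list(atoms = atoms, bonds = bonds, attach = 1L)
}

fragment_for <- function(kind, center) {
  switch(kind,
         donor = frag_hydroxyl(center),
         aromatic = frag_benzene(center),
         hydrophobic = frag_alkyl(center))
}

# assemble fragments into one connected molecule through a C-O hub; the hub
# carbon is bonded to an oxygen so the perception rules exclude it from
# hydrophobic clusters and the planted centroids stay on target
assemble_fragments <- function(id, kinds, centers, hub_pos) {
  atoms <- data.frame(element = "C", charge = 0L, x = hub_pos[1],
                      y = hub_pos[2], z = hub_pos[3])
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                      aromatic = logical())
  attach_idx <- integer()
  for (i in seq_along(kinds)) {
    fr <- fragment_for(kinds[i], centers[i, ])
    off <- nrow(atoms)
    atoms <- rbind(atoms, fr$atoms)
    fb <- fr$bonds
    fb$a1 <- fb$a1 + off; fb$a2 <- fb$a2 + off
    bonds <- rbind(bonds, fb)
    attach_idx <- c(attach_idx, fr$attach + off)
  }
  for (a in attach_idx)
    bonds <- rbind(bonds, data.frame(a1 = 1L, a2 = a, order = 1L,
                                     aromatic = FALSE))
  if (!"donor" %in% kinds) {
    # bare (H-free) oxygen keeps the hub carbon out of hydrophobic clusters
    atoms <- rbind(atoms, data.frame(element = "O", charge = 0L,
                                     x = hub_pos[1], y = hub_pos[2],
                                     z = hub_pos[3] + 1.4))
    bonds <- rbind(bonds, data.frame(a1 = 1L, a2 = nrow(atoms), order = 1L,
                                     aromatic = FALSE))
  }
  molecule3d(id, atoms, bonds)
}

#' Generate an activity-labelled screening library
#'
#' Actives are built by planting, at each query feature center plus Gaussian
#' jitter, a minimal chemical fragment that feature perception maps back to
#' that feature kind (hydroxyl for donors, a benzene hexagon for aromatic
#' centres, a three-carbon cluster for hydrophobic centroids), joined into
#' one molecule through an inert hub. Decoys omit every fragment of one
#' feature kind required by the query (a kind whose annotation points cannot
#' arise from the remaining fragments) and scramble the surviving fragments,
#' so they can never satisfy the full query.
#'
#' @param query A [pharmacophore_query()].
#' @param spec A [generator_spec()].
#' @return A [labeled_library()]. If the jitter is large relative to the
#'   feature radii the library carries attribute
#'   `containment_warning = TRUE`.
#' @export
gen_labeled_library <- function(query, spec = generator_spec()) {
  stopifnot(inherits(query, "pharmacophore_query"),
            inherits(spec, "generator_spec"))
  kinds <- query_kinds(query)
  centers <- query_centers(query)
  hub <- colMeans(centers) + c(0, 0, 8)
  box_lo <- apply(centers, 2, min) - 5
  box_hi <- apply(centers, 2, max) + 5

  deletable <- unique(kinds)
  # dropping only the alkyl cluster leaves ring-derived hydrophobic points;
  # in that case the rings are dropped too (handled below)
  with_local_seed(spec$seed, {
    mols <- vector("list", spec$n_actives + spec$n_decoys)
    labels <- character()
    for (i in seq_len(spec$n_actives)) {
      jit <- matrix(stats::rnorm(length(kinds) * 3, 0, spec$feature_jitter),
                    ncol = 3)
      id <- sprintf("ACT-%03d", i)
      mols[[i]] <- assemble_fragments(id, kinds, centers + jit, hub)
      labels[id] <- "active"
    }
    for (j in seq_len(spec$n_decoys)) {
      drop_kind <- sample(deletable, 1L)
      keep <- kinds != drop_kind
      if (drop_kind == "hydrophobic") keep <- keep & kinds != "aromatic"
      id <- sprintf("DEC-%03d", j)
      nk <- sum(keep)
      if (nk > 0L) {
        rnd <- matrix(stats::runif(nk * 3, box_lo, box_hi), ncol = 3,
                      byrow = TRUE)
        mols[[spec$n_actives + j]] <-
          assemble_fragments(id, kinds[keep], rnd, hub)
      } else {
        mols[[spec$n_actives + j]] <-
          assemble_fragments(id, character(), centers[0, , drop = FALSE],
                             hub + stats::runif(3, -5, 5))
      }
      labels[id] <- "inactive"
    }
    lib <- labeled_library(mols, labels)
    min_radius <- min(query_radii(query))
    if (spec$feature_jitter > min_radius / 3)
      attr(lib, "containment_warning") <- TRUE
    lib
  })
}

#' Generate a dual-target docking score table
#'
#' Full factorial compound x target coverage: compounds planted as passers
#' for a target draw energies strictly below that target's cutoff, all
#' others strictly above, with a configurable spread and clearance margin.
#'
#' @param compound_ids Character vector of compounds.
#' @param targets Named numeric vector of per-target cutoffs (kcal/mol);
#'   default `spec$score$cutoffs`.
#' @param passers Named list (by target) of compound ids planted to pass;
#'   default `spec$score$passers`. Must be subsets of `compound_ids`.
#' @param spec A [generator_spec()].
#' @return A [score_table()].
#' @export
gen_score_table <- function(compound_ids, targets = NULL, passers = NULL,
                            spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(targets)) targets <- spec$score$cutoffs
  if (is.null(passers)) passers <- spec$score$passers
  for (t in names(passers))
    if (!all(passers[[t]] %in% compound_ids))
      stop("planted passers for ", t, " are not all in compound_ids")
  sd <- spec$score$sd; margin <- spec$score$margin
  with_local_seed(spec$seed + 1L, {
    rows <- list()
    for (t in names(targets)) {
      pass <- compound_ids %in% passers[[t]]
      e <- numeric(length(compound_ids))
      e[pass] <- targets[[t]] - margin - abs(stats::rnorm(sum(pass), 0, sd))
      e[!pass] <- targets[[t]] + margin + abs(stats::rnorm(sum(!pass), 0, sd))
      rows[[t]] <- data.frame(compound_id = compound_ids, target_id = t,
                              binding_energy = round(e, 2))
    }
    score_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })
}

#' Generate a dose-response data set
#'
#' Samples percent-inhibition responses from the four-parameter logistic at
#' the spec's concentrations, adding Gaussian noise scaled to
#' `noise_pct` percent of the dynamic range (`top - bottom`). At the IC50
#' the noise-free response is exactly `(top + bottom) / 2`.
#'
#' @param spec A [generator_spec()].
#' @return A [dose_response_data()].
#' @export
gen_dose_response <- function(spec = generator_spec()) {
  d <- spec$dose
  conc <- rep(d$concentrations, each = d$replicates)
  mu <- d$bottom + (d$top - d$bottom) / (1 + (d$ic50 / conc)^d$hill)
  with_local_seed(spec$seed + 2L, {
    resp <- mu + stats::rnorm(length(mu), 0,
                              d$noise_pct / 100 * (d$top - d$bottom))
    dose_response_data(conc, resp)
  })
}

#' Generate a jittered alpha-carbon trajectory
#'
#' One alpha carbon per residue along a helical reference curve; every frame
#' is the reference plus isotropic Gaussian jitter of scale `core_sigma` per
#' coordinate, multiplied by `terminal_multiplier` for the `n_terminal`
#' residues at each chain end — a rigid core with floppy termini.
#'
#' @param spec A [generator_spec()].
#' @return A [trajectory()].
#' @export
gen_trajectory <- function(spec = generator_spec()) {
  p <- spec$traj
  n <- p$n_residues
  i <- seq_len(n)
  ref <- cbind(2.3 * cos(i * 100 * pi / 180),
               2.3 * sin(i * 100 * pi / 180),
               1.5 * i)
  sigma <- rep(p$core_sigma, n)
  term <- c(seq_len(p$n_terminal), n - seq_len(p$n_terminal) + 1L)
  sigma[term] <- sigma[term] * p$terminal_multiplier
  meta <- data.frame(atom_name = "CA", res_index = i, res_name = "ALA",
                     is_ca = TRUE)
  with_local_seed(spec$seed + 3L, {
    frames <- lapply(seq_len(p$n_frames), function(k)
      ref + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3))
    trajectory(meta, frames, p$frame_interval)
  })
}
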
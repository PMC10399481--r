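#' Construct a 3D small-molecule object
#'
#' `molecule3d` is the screening substrate used throughout the package: an
#' ordered atom list with Cartesian coordinates in Angstrom, a bond list, and
#' a free-form property map (used e.g. to carry docking scores inside SDF
#' tags).
#'
#' @param id Character label for the molecule (SDF title line).
#' @param atoms `data.frame` with columns `element` (symbol), `charge`
#'   (integer formal charge) and `x`, `y`, `z` (Angstrom).
#' @param bonds `data.frame` with columns `a1`, `a2` (1-based atom indices),
#'   `order` (integer; 4 denotes aromatic) and `aromatic` (logical). May have
#'   zero rows.
#' @param properties Named character vector of SDF data tags.
#'
#' @return An object of class `molecule3d`.
#' @export
molecule3d <- function(id, atoms, bonds = NULL, properties = character()) {
  if (is.null(bonds)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical())
  }
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (nrow(bonds) > 0 && is.null(bonds$aromatic))
    bonds$aromatic <- bonds$order == 4L
  mol <- structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         properties = properties),
    class = "molecule3d")
  validate_molecule3d(mol)
  mol
}

#' Validate molecule invariants
#'
#' Checks the structural invariants every `molecule3d` must satisfy: at least
#' one atom, finite coordinates, bond indices referencing existing atoms, no
#' self-bonds and no duplicate bonds.
#'
#' @param mol A `molecule3d`.
#' @return `mol`, invisibly. Errors if an invariant is violated.
#' @export
validate_molecule3d <- function(mol) {
  if (nrow(mol$atoms) < 1L)
    stop("molecule '", mol$id, "': must have at least 1 atom")
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("molecule '", mol$id, "': non-finite coordinates")
  b <- mol$bonds
  if (nrow(b) > 0) {
    n <- nrow(mol$atoms)
    if (any(b$a1 < 1L | b$a1 > n | b$a2 < 1L | b$a2 > n))
      stop("molecule '", mol$id, "': bond index out of range")
    if (any(b$a1 == b$a2))
      stop("molecule '", mol$id, "': self-bond")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key))
      stop("molecule '", mol$id, "': duplicate bond")
  }
  invisible(mol)
}

#' @export
print.molecule3d <- function(x, ...) {
  cat("<molecule3d>", x$id, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds")
  if (length(x$properties))
    cat(",", length(x$properties), "properties")
  cat("\n")
  invisible(x)
}

coords3d <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

# neighbour index list from the bond table
adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  adj
}

#' Read an SDF (V2000) file
#'
#' Parses a multi-record SDF file into a list of [molecule3d()] objects.
#' Atom order, explicit hydrogens and data tags are preserved. Only the
#' V2000 connection-table dialect is supported.
#'
#' @param path Path to an existing SDF file.
#' @return List of `molecule3d`, one per `$$$$`-terminated record.
#' @seealso [write_sdf()]
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$
  recs <- list()
  start <- 1L
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "$$$$") {
      recs[[length(recs) + 1L]] <- lines[start:(i - 1L)]
      start <- i + 1L
    }
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)]))))
    recs[[length(recs) + 1L]] <- lines[start:length(lines)]
  lapply(seq_along(recs), function(k) parse_sdf_record(recs[[k]], k))
}

parse_sdf_record <- function(rl, recno) {
  fail <- function(...) stop("SDF record ", recno, ": ", ..., call. = FALSE)
  if (length(rl) < 4L) fail("truncated record header")
  id <- trimws(rl[1L])
  counts <- rl[4L]
  n_at <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bd <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_at) || is.na(n_bd) || n_at < 0L || n_bd < 0L)
    fail("malformed counts line: '", counts, "'")
  need <- 4L + n_at + n_bd
  if (length(rl) < need) fail("counts line declares ", n_at, " atoms / ",
                              n_bd, " bonds but record is shorter")
  atom_lines <- rl[4L + seq_len(n_at)]
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  x <- num(substr(atom_lines, 1L, 10L))
  y <- num(substr(atom_lines, 11L, 20L))
  z <- num(substr(atom_lines, 21L, 30L))
  el <- trimws(substr(atom_lines, 31L, 34L))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    fail("unreadable atom line (expected ", n_at, " atom lines)")
  atoms <- data.frame(element = el, charge = 0L, x = x, y = y, z = z)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                      aromatic = logical())
  if (n_bd > 0L) {
    bl <- rl[4L + n_at + seq_len(n_bd)]
    a1 <- suppressWarnings(as.integer(substr(bl, 1L, 3L)))
    a2 <- suppressWarnings(as.integer(substr(bl, 4L, 6L)))
    bo <- suppressWarnings(as.integer(substr(bl, 7L, 9L)))
    if (any(is.na(a1) | is.na(a2) | is.na(bo))) fail("unreadable bond line")
    if (any(a1 < 1L | a1 > n_at | a2 < 1L | a2 > n_at))
      fail("dangling bond index")
    bonds <- data.frame(a1 = a1, a2 = a2, order = bo, aromatic = bo == 4L)
  }
  # charges from M  CHG lines; properties from > <tag> blocks
  rest <- if (length(rl) > need) rl[(need + 1L):length(rl)] else character()
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    np <- f[1L]
    for (j in seq_len(np))
      atoms$charge[f[2L * j]] <- f[2L * j + 1L]
  }
  props <- character()
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], ">")) {
      tag <- sub(".*<([^>]*)>.*", "\\1", rest[i])
      vals <- character()
      i <- i + 1L
      while (i <= length(rest) && nzchar(trimws(rest[i]))) {
        vals <- c(vals, rest[i])
        i <- i + 1L
      }
      props[tag] <- paste(vals, collapse = "\n")
    }
    i <- i + 1L
  }
  validate_molecule3d(molecule3d(id, atoms, bonds, props))
}

#' Write molecules to an SDF (V2000) file
#'
#' Emits one V2000 record per molecule with coordinates at 4 decimal places,
#' formal charges as `M  CHG` lines and property tags as SDF data blocks.
#'
#' @param mols List of [molecule3d()] objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  out <- character()
  for (mol in mols) {
    validate_molecule3d(mol)
    a <- mol$atoms
    b <- mol$bonds
    out <- c(out, mol$id, "  dualphore", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$element))
    if (nrow(b) > 0) {
      ord <- ifelse(b$aromatic, 4L, b$order)
      out <- c(out, sprintf("%3d%3d%3d  0", b$a1, b$a2, ord))
    }
    chg <- which(a$charge != 0L)
    for (i in chg)
      out <- c(out, sprintf("M  CHG  1 %3d %3d", i, a$charge[i]))
    out <- c(out, "M  END")
    for (tag in names(mol$properties))
      out <- c(out, paste0(">  <", tag, ">"), mol$properties[[tag]], "")
    out <- c(out, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a docking score table
#'
#' Reads a CSV of docking binding free energies with the exact header
#' `compound_id,target_id,binding_energy`. Energies are in kcal/mol; more
#' negative values indicate stronger predicted binding.
#'
#' @param path CSV file path.
#' @return `data.frame` of class `score_table` with one row per
#'   (compound, target) pair.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_table(df)
}

#' Construct/validate a score table
#'
#' @param df `data.frame` with columns `compound_id`, `target_id`,
#'   `binding_energy` (kcal/mol).
#' @return The validated `score_table`.
#' @export
score_table <- function(df) {
  need <- c("compound_id", "target_id", "binding_energy")
  if (!identical(names(df)[seq_along(need)], need))
    stop("score table must have columns ", paste(need, collapse = ","))
  if (nrow(df) > 0) {
    if (!is.numeric(df$binding_energy) || any(!is.finite(df$binding_energy)))
      stop("non-numeric or non-finite binding_energy")
    key <- paste(df$compound_id, df$target_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate (compound, target) pair: ", dup)
    }
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; if missing,
#'   lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
dualphore_example <- function(file = NULL) {
  d <- system.file("extdata", package = "dualphore")
  if (is.null(file)) return(list.files(d))
  p <- file.path(d, file)
  if (!file.exists(p)) stop("no packaged example file '", file, "'")
  p
}
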
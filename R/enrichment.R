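#' Guener-Henry enrichment statistics
#'
#' Computes the full goodness-of-hit statistics table from the four
#' screening counts: database size `D`, total actives `A`, total hits `Ht`
#' and active hits `Ha`. The composite score is
#' \deqn{GH = \frac{Ha\,(3A + Ht)}{4\,Ht\,A}\left(1 - \frac{Ht - Ha}{D - A}\right)}
#' which ranges from 0 (null model) to 1 (ideal retrieval). Also reported:
#' percent yield of actives (100 Ha/Ht), percent ratio of actives
#' (100 Ha/A), enrichment factor E = (Ha D)/(Ht A), false negatives A - Ha
#' and false positives Ht - Ha.
#'
#' @param D Total molecules in the database.
#' @param A Total actives in the database (0 < A < D).
#' @param Ht Total hits (> 0).
#' @param Ha Active hits (0 <= Ha <= min(Ht, A)).
#' @return An `enrichment_stats` list carrying the counts, the
#'   full-precision statistics (`yield_pct`, `ratio_pct`, `E`, `FN`, `FP`,
#'   `GH`) and a `presentation` sub-list with conventional rounding (GH to
#'   2 decimals, E and the percentages to integers).
#' @examples
#' gh_statistics(D = 1500, A = 16, Ht = 19, Ha = 16)
#' @export
gh_statistics <- function(D, A, Ht, Ha) {
  stopifnot(length(D) == 1L, length(A) == 1L, length(Ht) == 1L,
            length(Ha) == 1L)
  if (!(D > A)) stop("undefined GH: D must exceed A (zero denominator)")
  if (!(A > 0)) stop("A must be positive")
  if (Ht <= 0) stop("undefined statistics: Ht must be positive")
  if (Ha < 0 || Ha > Ht || Ha > A)
    stop("Ha must satisfy 0 <= Ha <= min(Ht, A)")
  if (Ht > D) stop("Ht cannot exceed D")
  if (Ht - Ha > D - A)
    stop("inactive hits (Ht - Ha) cannot exceed inactives (D - A)")

  yield <- 100 * Ha / Ht
  ratio <- 100 * Ha / A
  E <- (Ha * D) / (Ht * A)
  FN <- A - Ha
  FP <- Ht - Ha
  GH <- (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))

  structure(list(
    D = D, A = A, Ht = Ht, Ha = Ha,
    yield_pct = yield, ratio_pct = ratio, E = E, FN = FN, FP = FP, GH = GH,
    presentation = list(yield_pct = round(yield), ratio_pct = round(ratio),
                        E = round(E), FN = FN, FP = FP, GH = round(GH, 2)),
    quality = if (GH >= 0.7) "excellent" else "below-excellent"),
    class = "enrichment_stats")
}

#' @export
print.enrichment_stats <- function(x, ...) {
  p <- x$presentation
  cat("Enrichment validation (Guener-Henry)\n")
  cat(sprintf("  Total molecules in database (D)  %d\n", x$D))
  cat(sprintf("  Total actives in database (A)    %d\n", x$A))
  cat(sprintf("  Total hits (Ht)                  %d\n", x$Ht))
  cat(sprintf("  Active hits (Ha)                 %d\n", x$Ha))
  cat(sprintf("  %% Yield of actives               %d%%\n", p$yield_pct))
  cat(sprintf("  %% Ratio of actives               %d%%\n", p$ratio_pct))
  cat(sprintf("  Enrichment factor (E)            %d\n", p$E))
  cat(sprintf("  False negatives (A - Ha)         %d\n", p$FN))
  cat(sprintf("  False positives (Ht - Ha)        %d\n", p$FP))
  cat(sprintf("  Goodness of hit score (GH)       %.2f  [%s]\n",
              p$GH, x$quality))
  invisible(x)
}

#' Activity-labelled molecule library
#'
#' @param molecules List of [molecule3d()] objects.
#' @param labels Named character vector mapping every compound id to
#'   `"active"` or `"inactive"`.
#' @return A `labeled_library`.
#' @export
labeled_library <- function(molecules, labels) {
  ids <- vapply(molecules, `[[`, "", "id")
  if (!all(ids %in% names(labels)))
    stop("every molecule must be labelled; missing: ",
         paste(utils::head(setdiff(ids, names(labels))), collapse = ", "))
  if (!all(labels %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'")
  structure(list(molecules = molecules, labels = labels[ids]),
            class = "labeled_library")
}

#' @export
print.labeled_library <- function(x, ...) {
  cat("<labeled_library>", length(x$molecules), "molecules (",
      sum(x$labels == "active"), "active /",
      sum(x$labels == "inactive"), "inactive )\n")
  invisible(x)
}

#' Read an activity-label CSV
#'
#' @param path CSV with columns `compound_id,label`.
#' @return Named character vector of labels.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "label") %in% names(df)))
    stop("labels CSV must have columns compound_id,label")
  stats::setNames(df$label, df$compound_id)
}

#' Validate a pharmacophore query against a labelled library
#'
#' Screens the library with the query, derives the confusion counts from
#' the activity labels and returns the Guener-Henry statistics.
#'
#' @param query A [pharmacophore_query()].
#' @param lib A [labeled_library()] with at least one active.
#' @inheritParams screen_library
#' @return An `enrichment_stats` object (see [gh_statistics()]).
#' @export
validate_query <- function(query, lib, rules = perception_rules(),
                           mode = c("superpose", "in_place"),
                           rmsd_cutoff = 1.0, max_assignments = 1e6) {
  stopifnot(inherits(lib, "labeled_library"))
  if (!length(lib$molecules)) stop("library is empty")
  D <- length(lib$molecules)
  A <- sum(lib$labels == "active")
  if (A == 0L) stop("library contains no actives")
  hits <- screen_library(query, lib$molecules, rules = rules,
                         mode = match.arg(mode), rmsd_cutoff = rmsd_cutoff,
                         max_assignments = max_assignments)
  ids <- hit_ids(hits)
  Ht <- length(ids)
  Ha <- sum(lib$labels[ids] == "active")
  gh_statistics(D = D, A = A, Ht = Ht, Ha = Ha)
}
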
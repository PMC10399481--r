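#' Docking-energy threshold rule
#'
#' @param target_id Target label, e.g. `"CARM1"` or `"HDAC2"`.
#' @param cutoff Binding-energy cutoff in kcal/mol (more negative = stronger
#'   binding).
#' @param strict If `TRUE` (default) a compound passes iff energy < cutoff;
#'   otherwise energy <= cutoff.
#' @return A `threshold_rule`.
#' @export
threshold_rule <- function(target_id, cutoff, strict = TRUE) {
  stopifnot(is.finite(cutoff))
  structure(list(target_id = as.character(target_id), cutoff = cutoff,
                 strict = isTRUE(strict)),
            class = "threshold_rule")
}

#' Apply an energy threshold to a score table
#'
#' Selects the compounds whose binding free energy for the rule's target
#' satisfies the cutoff, preserving the input row order.
#'
#' @param scores A [score_table()] (or data.frame with its columns).
#' @param rule A [threshold_rule()].
#' @return Character vector of passing compound ids.
#' @export
apply_threshold <- function(scores, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  scores <- score_table(as.data.frame(scores))
  sub <- scores[scores$target_id == rule$target_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no score records for target '", rule$target_id, "'")
  pass <- if (rule$strict) sub$binding_energy < rule$cutoff
          else sub$binding_energy <= rule$cutoff
  sub$compound_id[pass]
}

#' Run the dual-target screening cascade
#'
#' The screening funnel: pharmacophore hits are filtered by per-target
#' docking-energy thresholds, the per-target survivor lists are intersected,
#' and the intersection is ranked (ascending, i.e. strongest predicted
#' binders first) by the summed binding energy across the rule targets
#' (default) or per target. Ties are broken lexicographically by compound
#' id.
#'
#' @param hits Character vector of pharmacophore hit ids, or `NULL` to use
#'   the whole score-table universe (for score tables that were computed
#'   only for pharmacophore hits in the first place).
#' @param scores A [score_table()].
#' @param rules List of [threshold_rule()] objects (at least one).
#' @param rank_key `"sum_energy"` (default) or `"per_target"` (ranks by the
#'   first rule's target energy).
#' @return A `cascade_result` with `stage_survivors` (ordered list:
#'   `pharmacophore`, one entry per rule, `intersection`) and `final_ranked`
#'   (data.frame `compound_id`, `score`).
#' @export
run_cascade <- function(hits, scores, rules,
                        rank_key = c("sum_energy", "per_target")) {
  rank_key <- match.arg(rank_key)
  if (inherits(rules, "threshold_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, TRUE, "threshold_rule")))
  scores <- score_table(as.data.frame(scores))
  universe <- unique(scores$compound_id)
  base <- if (is.null(hits)) universe else intersect(hits, universe)

  stage <- list(pharmacophore = base)
  surv <- base
  per_rule <- list()
  for (r in rules) {
    ids <- apply_threshold(scores, r)
    nm <- sprintf("%s%s%g", r$target_id, if (r$strict) "<" else "<=",
                  r$cutoff)
    per_rule[[nm]] <- intersect(base, ids)
    stage[[nm]] <- per_rule[[nm]]
  }
  inter <- Reduce(intersect, per_rule, accumulate = FALSE)
  stage$intersection <- inter

  if (length(inter)) {
    tgts <- vapply(rules, `[[`, "", "target_id")
    if (rank_key == "sum_energy") {
      key <- vapply(inter, function(id)
        sum(scores$binding_energy[scores$compound_id == id &
                                  scores$target_id %in% tgts]), 0)
    } else {
      key <- vapply(inter, function(id)
        scores$binding_energy[scores$compound_id == id &
                              scores$target_id == tgts[1L]][1L], 0)
    }
    ord <- order(key, inter)
    final <- data.frame(compound_id = inter[ord], score = key[ord])
  } else {
    final <- data.frame(compound_id = character(), score = numeric())
  }
  structure(list(stage_survivors = stage, final_ranked = final,
                 rank_key = rank_key),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  for (nm in names(x$stage_survivors))
    cat(sprintf("  %-28s %d survivors\n", nm,
                length(x$stage_survivors[[nm]])))
  if (nrow(x$final_ranked)) {
    cat("  final ranking (", x$rank_key, "):\n", sep = "")
    for (i in seq_len(nrow(x$final_ranked)))
      cat(sprintf("   %2d. %-10s %8.2f kcal/mol\n", i,
                  x$final_ranked$compound_id[i], x$final_ranked$score[i]))
  }
  invisible(x)
}
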
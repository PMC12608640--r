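#' Panel assignment
#'
#' A candidate diagnostic panel: a non-empty set of up-regulated members and
#' a disjoint non-empty set of down-regulated members. Directions are fixed
#' per miRNA from the validation contrast before any search; the search
#' explores subsets, never direction flips.
#'
#' @param up,down character vectors of feature ids.
#' @return list of class `panel_assignment` with sorted `up` and `down`.
#' @export
panel_assignment <- function(up, down) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (!length(up) || !length(down))
    stop("a panel needs at least one up-regulated and one down-regulated member")
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint: ",
         paste(intersect(up, down), collapse = ", "))
  structure(list(up = up, down = down), class = "panel_assignment")
}

#' @export
print.panel_assignment <- function(x, ...) {
  cat("panel: up {", paste(x$up, collapse = ", "), "} / down {",
      paste(x$down, collapse = ", "), "}\n")
  invisible(x)
}

panel_id <- function(panel) {
  paste0("up:", paste(panel$up, collapse = ";"),
         "|down:", paste(panel$down, collapse = ";"))
}

panel_size <- function(panel) length(panel$up) + length(panel$down)

#' Up-down ratio score
#'
#' The per-sample UDR of a panel with up-members \eqn{U} (size N) and
#' down-members \eqn{D} (size M) on linear expression \eqn{E}:
#' \deqn{UDR(s) = \frac{\frac{1}{N}\sum_{f \in U} E(f, s)}
#'                     {\frac{1}{M}\sum_{f \in D} E(f, s)}}
#' Up-regulated members raise the score in cases, down-regulated members
#' lower its denominator, so higher UDR is more case-like. The ratio is
#' invariant to any common positive rescaling of the expression matrix.
#' Samples with a missing value in any panel member get `NA` (skipped, with
#' a warning); with `type = "log"` the score is the difference of mean log2
#' expressions instead (a sensitivity-analysis variant).
#'
#' @param expr an `expr_matrix` of scale `"linear"` (see [linearize()]).
#' @param panel a [panel_assignment()].
#' @param samples sample ids to score; defaults to all columns.
#' @param type `"ratio"` (the UDR) or `"log"` (log2-scale difference of
#'   means).
#' @param warn_missing warn when samples are skipped for missing members.
#' @return named numeric vector of scores (NA for skipped samples).
#' @examples
#' m <- expr_matrix(matrix(c(8, 2, 6), 3, 1,
#'        dimnames = list(c("a", "b", "c"), "S1")), scale = "linear")
#' udr_score(m, panel_assignment("a", c("b", "c")))  # 8 / mean(2, 6) = 2
#' @export
udr_score <- function(expr, panel, samples = colnames(expr),
                      type = c("ratio", "log"), warn_missing = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(panel, "panel_assignment"))
  type <- match.arg(type)
  if (expr_scale(expr) != "linear")
    stop("UDR requires linear scale; see linearize()")
  members <- c(panel$up, panel$down)
  absent <- setdiff(members, rownames(expr))
  if (length(absent))
    stop("panel member(s) absent from the expression matrix: ",
         paste(absent, collapse = ", "))
  up <- unclass(expr)[panel$up, samples, drop = FALSE]
  dn <- unclass(expr)[panel$down, samples, drop = FALSE]
  scores <- if (type == "ratio") colMeans(up) / colMeans(dn)
            else colMeans(log2(up)) - colMeans(log2(dn))
  if (anyNA(scores) && warn_missing)
    warning(sum(is.na(scores)), " sample(s) skipped: missing panel member values")
  stats::setNames(scores, samples)
}

#' Assign panel directions from validation results
#'
#' @param results differential data.frame with `feature_id` and `direction`
#'   (e.g. from [validate_candidates()], typically subset to the validated
#'   markers).
#' @return list with `up` and `down` character vectors.
#' @export
assign_directions <- function(results) {
  if (any(results$direction == "flat"))
    stop("flat feature(s) cannot be assigned a panel direction: ",
         paste(results$feature_id[results$direction == "flat"], collapse = ", "))
  up <- results$feature_id[results$direction == "up"]
  down <- results$feature_id[results$direction == "down"]
  if (!length(up) || !length(down))
    stop("the UDR needs at least one up- and one down-regulated marker ",
         "(got ", length(up), " up, ", length(down), " down)")
  list(up = sort(up), down = sort(down))
}

#' Enumerate all panels over an up/down assignment
#'
#' Cartesian product of the non-empty subsets of the up set with the
#' non-empty subsets of the down set:
#' \eqn{(2^{|up|} - 1)(2^{|down|} - 1)} panels.
#'
#' @param up,down character vectors of directed marker ids.
#' @param max_panels guard against combinatorial blow-up.
#' @return list of [panel_assignment()] objects.
#' @export
enumerate_panels <- function(up, down, max_panels = 4096) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (!length(up) || !length(down)) stop("both direction sets must be non-empty")
  n_panels <- (2^length(up) - 1) * (2^length(down) - 1)
  if (n_panels > max_panels)
    stop("exhaustive enumeration of ", n_panels,
         " panels exceeds max_panels = ", max_panels,
         "; use backward_search() instead")
  subsets <- function(s) {
    idx <- unlist(lapply(seq_along(s), function(k)
      utils::combn(s, k, simplify = FALSE)), recursive = FALSE)
    idx
  }
  out <- list()
  for (u in subsets(up))
    for (d in subsets(down))
      out[[length(out) + 1L]] <- panel_assignment(u, d)
  out
}

#' Evaluate one panel on one cohort
#'
#' Scores every contrast sample with the UDR and computes the ROC with the
#' NSCLC contrast group as cases. Samples with missing panel members are
#' skipped and listed in `skipped`.
#'
#' @param expr an `expr_matrix` of scale `"linear"`.
#' @param meta a `sample_meta`.
#' @param panel a [panel_assignment()].
#' @param stages NSCLC stage set forming the case group.
#' @param type UDR variant, see [udr_score()].
#' @param ci,n_boot,seed bootstrap-interval controls, see [roc_auc()].
#' @param cohort_tag label recorded on the evaluation.
#' @return list of class `panel_evaluation`: `panel`, `udr_scores` (named,
#'   evaluable samples only), `roc` (a `roc_result`), `skipped`,
#'   `cohort_tag`.
#' @export
evaluate_panel <- function(expr, meta, panel, stages = c("I", "II"),
                           type = "ratio", ci = FALSE, n_boot = 2000,
                           seed = NULL, cohort_tag = "cohort") {
  stopifnot(inherits(meta, "sample_meta"))
  grp <- contrast_samples(meta, stages)
  case <- intersect(colnames(expr), grp$case)
  ctrl <- intersect(colnames(expr), grp$control)
  ids <- c(case, ctrl)
  if (!length(ids)) stop("no contrast samples present in the matrix")
  scores <- udr_score(expr, panel, samples = ids, type = type,
                      warn_missing = FALSE)
  keep <- !is.na(scores)
  is_case <- ids %in% case
  if (sum(keep & is_case) < 2 || sum(keep & !is_case) < 2)
    stop("fewer than 2 evaluable samples in a contrast group")
  roc <- roc_auc(scores[keep], is_case[keep], ci = ci, n_boot = n_boot,
                 seed = seed)
  structure(list(panel = panel, udr_scores = scores[keep], roc = roc,
                 skipped = ids[!keep], cohort_tag = cohort_tag),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("panel [%d up + %d down] on %s: AUC = %.3f (n = %d + %d)\n",
              length(x$panel$up), length(x$panel$down), x$cohort_tag,
              x$roc$auc, x$roc$n_case, x$roc$n_control))
  invisible(x)
}

#' Sequential backward panel search
#'
#' Greedy elimination over the panel members: starting from the full
#' assignment, each step removes the single member (keeping at least one up
#' and one down member) whose removal yields the largest AUC, breaking ties
#' by the lexicographically smallest feature id; the search stops when no
#' removal strictly increases the AUC or no removal is legal. Deterministic.
#'
#' @param expr an `expr_matrix` of scale `"linear"`.
#' @param meta a `sample_meta`.
#' @param full_up,full_down the full directed marker sets.
#' @param stages NSCLC stage set forming the case group.
#' @param type UDR variant, see [udr_score()].
#' @param cohort_tag label recorded on the evaluations.
#' @return list of `panel_evaluation` objects: the elimination path, full
#'   panel first, final panel last.
#' @export
backward_search <- function(expr, meta, full_up, full_down,
                            stages = c("I", "II"), type = "ratio",
                            cohort_tag = "cohort") {
  panel <- panel_assignment(full_up, full_down)
  ev <- function(p) evaluate_panel(expr, meta, p, stages = stages, type = type,
                                   ci = FALSE, cohort_tag = cohort_tag)
  path <- list(ev(panel))
  repeat {
    current <- path[[length(path)]]
    members <- c(if (length(current$panel$up) > 1) current$panel$up,
                 if (length(current$panel$down) > 1) current$panel$down)
    if (!length(members)) break
    members <- sort(members)
    cand <- lapply(members, function(m)
      ev(panel_assignment(setdiff(current$panel$up, m),
                          setdiff(current$panel$down, m))))
    aucs <- vapply(cand, function(e) e$roc$auc, numeric(1))
    best <- which.max(aucs)  # ties: first index = lexicographically smallest id
    if (aucs[best] <= current$roc$auc) break
    path[[length(path) + 1L]] <- cand[[best]]
  }
  path
}

#' Parsimony-based panel selection
#'
#' Among a collection of evaluated panels, keep those whose AUC is within
#' `parsimony_epsilon` of the best AUC and order them by preference:
#' smallest panel first, then higher AUC, then lexicographic member order —
#' formalizing "high AUC with the relatively small number of constituent
#' miRNAs".
#'
#' @param evaluations list of `panel_evaluation` objects.
#' @param parsimony_epsilon AUC band below the maximum.
#' @return the selected evaluations, ranked.
#' @export
select_optimal <- function(evaluations, parsimony_epsilon = 0.02) {
  if (!length(evaluations)) stop("no panel evaluations supplied")
  aucs <- vapply(evaluations, function(e) e$roc$auc, numeric(1))
  best <- max(aucs)
  keep <- which(aucs >= best - parsimony_epsilon)
  sizes <- vapply(evaluations[keep], function(e) panel_size(e$panel), numeric(1))
  ids <- vapply(evaluations[keep], function(e) panel_id(e$panel), character(1))
  keep <- keep[order(sizes, -aucs[keep], ids)]
  evaluations[keep]
}
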
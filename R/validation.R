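#' Spike-in delta-Ct normalization
#'
#' Converts raw qPCR Ct values to spike-in-normalized abundances:
#' \eqn{\Delta Ct(f, s) = Ct(spike, s) - Ct(f, s)} for every feature except
#' the spike-in row, which is removed from the output. Higher delta-Ct means
#' higher abundance; one cycle is one doubling, so delta-Ct is a log2-scale
#' quantity. Adding any constant to every Ct of a sample (spike included)
#' leaves delta-Ct unchanged.
#'
#' @param x an `expr_matrix` of scale `"ct"`.
#' @param spike_in_id identifier of the spike-in row; it must be present and
#'   contain no missing values.
#' @return An `expr_matrix` of scale `"delta_ct"` without the spike-in row.
#' @export
normalize_delta_ct <- function(x, spike_in_id = "cel-miR-2-3p") {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) != "ct") stop("delta-Ct normalization requires ct scale")
  if (!spike_in_id %in% rownames(x))
    stop("spike-in row \"", spike_in_id, "\" is absent from the Ct matrix")
  spike <- unclass(x)[spike_in_id, ]
  if (anyNA(spike))
    stop("spike-in row \"", spike_in_id, "\" contains missing values")
  rest <- unclass(x)[setdiff(rownames(x), spike_in_id), , drop = FALSE]
  vals <- sweep(-rest, 2, spike, "+")
  expr_matrix(vals, scale = "delta_ct")
}

#' Convert an expression matrix to the linear scale
#'
#' The UDR ratio requires strictly positive linear expression. Delta-Ct is
#' exponentiated (\eqn{2^{\Delta Ct}}); counts are CPM normalized with a
#' pseudocount; linear input passes through.
#'
#' @param x an `expr_matrix`.
#' @param pseudocount pseudocount for the counts branch.
#' @return An `expr_matrix` of scale `"linear"`.
#' @export
linearize <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  switch(expr_scale(x),
         linear = x,
         delta_ct = expr_matrix(2^unclass(x), scale = "linear"),
         counts = cpm_normalize(x, pseudocount = pseudocount),
         stop("raw Ct values must be delta-Ct normalized first; see normalize_delta_ct()"))
}

#' Validate candidate markers on the qPCR cohort
#'
#' Per candidate: Mann-Whitney U test and fold change on delta-Ct values for
#' the early-stage (default I-II) vs benign contrast. A candidate is
#' `validated` when `p < val_p_max` and `fc_linear >= val_fc_min`,
#' `undetermined` when its missing-value rate exceeds `undetermined_max` in
#' either group (such markers are excluded from the validated subset), and
#' `rejected` otherwise.
#'
#' @param delta_ct an `expr_matrix` of scale `"delta_ct"`.
#' @param meta a `sample_meta`.
#' @param candidates a [candidate_set()] or character vector of feature ids.
#' @param stages NSCLC stage set forming the case group.
#' @param config a [udr_config()].
#' @return data.frame with columns `feature_id`, `log2_fc`, `fc_linear`,
#'   `direction`, `p_value`, `test`, `status`; the validated subset is
#'   `feature_id[status == "validated"]`.
#' @export
validate_candidates <- function(delta_ct, meta, candidates,
                                stages = c("I", "II"), config = udr_config()) {
  stopifnot(inherits(delta_ct, "expr_matrix"), inherits(meta, "sample_meta"))
  if (expr_scale(delta_ct) != "delta_ct")
    stop("validation requires delta_ct scale; see normalize_delta_ct()")
  feats <- if (inherits(candidates, "candidate_set")) candidates$members
           else as.character(candidates)
  if (!length(feats)) stop("candidate set is empty")
  missing_feats <- setdiff(feats, rownames(delta_ct))
  if (length(missing_feats))
    stop("candidate(s) absent from the delta-Ct matrix: ",
         paste(missing_feats, collapse = ", "))
  grp <- contrast_samples(meta, stages)
  case <- intersect(colnames(delta_ct), grp$case)
  ctrl <- intersect(colnames(delta_ct), grp$control)
  if (!length(case) || !length(ctrl))
    stop("both contrast groups must be non-empty")
  rows <- lapply(feats, function(f) {
    xc <- unclass(delta_ct)[f, case]
    xb <- unclass(delta_ct)[f, ctrl]
    if (mean(is.na(xc)) > config$undetermined_max ||
        mean(is.na(xb)) > config$undetermined_max) {
      out <- differential_row(f, NA_real_, NA_real_, "mann_whitney")
      out$status <- "undetermined"
      return(out)
    }
    fc <- qpcr_fold_change(xc, xb)
    p <- mann_whitney(xc, xb)$p
    out <- differential_row(f, fc$log2_fc, p, "mann_whitney")
    out$status <- if (p < config$val_p_max && fc$fc_linear >= config$val_fc_min)
      "validated" else "rejected"
    out
  })
  res <- do.call(rbind, rows)
  if (config$adjust_p) {
    res$p_value <- stats::p.adjust(res$p_value, "BH")
    res$status[res$status == "validated" & res$p_value >= config$val_p_max] <-
      "rejected"
  }
  res[order(res$feature_id), , drop = FALSE]
}

#' Per-marker ROC on delta-Ct values
#'
#' Computes one ROC per feature for the case-vs-benign contrast. Scores are
#' oriented so the reported AUC is never below 0.5: when the raw AUC (case
#' scored by delta-Ct directly) falls below 0.5 the sign is flipped and the
#' orientation recorded as `"case_low"`. The unoriented AUC is reported
#' alongside. Constant scores yield AUC 0.5 with `degenerate = TRUE`.
#'
#' @param delta_ct an `expr_matrix` of scale `"delta_ct"` (or `"linear"`).
#' @param meta a `sample_meta`.
#' @param features feature ids to evaluate; defaults to all rows.
#' @param stages NSCLC stage set forming the case group.
#' @param ci,n_boot,seed bootstrap-interval controls, see [roc_auc()].
#' @return named list of `roc_result` objects, each with extra fields
#'   `feature_id`, `orientation` (`"case_high"`/`"case_low"`) and `auc_raw`.
#' @export
per_marker_roc <- function(delta_ct, meta, features = rownames(delta_ct),
                           stages = c("I", "II"), ci = TRUE, n_boot = 2000,
                           seed = NULL) {
  stopifnot(inherits(delta_ct, "expr_matrix"), inherits(meta, "sample_meta"))
  if (!expr_scale(delta_ct) %in% c("delta_ct", "linear"))
    stop("per-marker ROC requires delta_ct or linear scale")
  grp <- contrast_samples(meta, stages)
  case <- intersect(colnames(delta_ct), grp$case)
  ctrl <- intersect(colnames(delta_ct), grp$control)
  if (!length(case) || !length(ctrl))
    stop("both contrast groups must be non-empty")
  ids <- c(case, ctrl)
  is_case <- c(rep(TRUE, length(case)), rep(FALSE, length(ctrl)))
  out <- lapply(features, function(f) {
    sc <- unclass(delta_ct)[f, ids]
    raw <- roc_auc(sc, is_case, ci = FALSE)
    flip <- raw$auc < 0.5
    r <- roc_auc(if (flip) -sc else sc, is_case, ci = ci, n_boot = n_boot,
                 seed = if (is.null(seed)) NULL else sub_seed(seed, f))
    r$feature_id <- f
    r$orientation <- if (flip) "case_low" else "case_high"
    r$auc_raw <- raw$auc
    r
  })
  stats::setNames(out, features)
}
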
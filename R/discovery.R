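#' Prevalence filter
#'
#' Removes every feature whose fraction of zero-count samples is strictly
#' greater than `max_zero_frac`. The cascade applies this twice (0.50, then
#' 0.45) for audit parity with the two-pass screen it mirrors; since the
#' thresholds are nested the composition equals a single 0.45 pass.
#'
#' @param x an `expr_matrix` of scale `"counts"`.
#' @param max_zero_frac maximum tolerated zero fraction (strict inequality).
#' @return The filtered `expr_matrix`; the number of removed features is
#'   attached as attribute `"n_removed"`.
#' @export
prevalence_filter <- function(x, max_zero_frac) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) != "counts")
    stop("prevalence filtering requires counts scale")
  if (max_zero_frac < 0 || max_zero_frac > 1)
    stop("max_zero_frac must be a fraction in [0, 1]")
  zf <- rowMeans(unclass(x) == 0, na.rm = TRUE)
  keep <- zf <= max_zero_frac
  out <- x[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Counts-per-million normalization
#'
#' \eqn{CPM = count / librarysize \times 10^6 + pseudocount}. Library sizes
#' default to the column sums of the matrix passed in, so the filter should
#' be given the matrix whose totals define sequencing depth (or explicit
#' `libsizes`). The pseudocount keeps the output strictly positive, as the
#' linear scale (and the UDR ratio) requires.
#'
#' @param x an `expr_matrix` of scale `"counts"`.
#' @param libsizes per-sample library sizes; defaults to `colSums(x)`.
#' @param pseudocount added to every CPM value (default 1).
#' @return An `expr_matrix` of scale `"linear"`.
#' @export
cpm_normalize <- function(x, libsizes = colSums(x), pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) != "counts") stop("CPM normalization requires counts scale")
  if (any(libsizes <= 0)) stop("every sample must have a positive library size")
  vals <- sweep(unclass(x), 2, libsizes, "/") * 1e6 + pseudocount
  expr_matrix(vals, scale = "linear")
}

#' Dual differential testing on the discovery cohort
#'
#' Runs the two discovery arms on a (filtered) count matrix for one
#' case-vs-benign contrast: (A) the exact conditional negative-binomial test
#' with a pooled method-of-moments dispersion and CPM-based log2 fold
#' changes, and (B) the Mann-Whitney U test on log2-CPM values (rank tests
#' are invariant to the monotone log transform; it is applied for
#' consistency of reporting).
#'
#' @param x an `expr_matrix` of scale `"counts"` (already prevalence
#'   filtered).
#' @param meta a `sample_meta` covering the columns of `x`.
#' @param stages NSCLC stage set forming the case group.
#' @param config a [udr_config()] (supplies the pseudocount and BH switch).
#' @param libsizes per-sample library sizes; defaults to `colSums(x)`.
#' @return list with `edge` and `mw`: data.frames with columns
#'   `feature_id`, `log2_fc`, `fc_linear`, `direction`, `p_value`, `test`,
#'   plus the pooled `dispersion` used (attribute on `edge`).
#' @export
discovery_de <- function(x, meta, stages = c("I", "II"), config = udr_config(),
                         libsizes = colSums(x)) {
  stopifnot(inherits(x, "expr_matrix"), inherits(meta, "sample_meta"))
  if (expr_scale(x) != "counts") stop("discovery testing requires counts scale")
  grp <- contrast_samples(meta, stages)
  case <- intersect(colnames(x), grp$case)
  ctrl <- intersect(colnames(x), grp$control)
  if (length(case) < 2 || length(ctrl) < 2)
    stop("both contrast groups need at least 2 samples (case: ",
         length(case), ", control: ", length(ctrl), ")")
  names(libsizes) <- colnames(x)
  sub <- unclass(x)[, c(case, ctrl), drop = FALSE]
  ls_sub <- libsizes[c(case, ctrl)]
  disp <- estimate_dispersion(sub, ls_sub)$common
  cpm <- unclass(cpm_normalize(x, libsizes = libsizes,
                               pseudocount = config$pseudocount))
  lfc <- log2(rowMeans(cpm[, case, drop = FALSE])) -
    log2(rowMeans(cpm[, ctrl, drop = FALSE]))
  n_case <- length(case)
  edge <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    res <- exact_nb_test(sub[i, seq_len(n_case)],
                         sub[i, -seq_len(n_case)], ls_sub, disp)
    differential_row(rownames(sub)[i],
                     if (res$flat) 0 else lfc[i], res$p, "exact_nb")
  }))
  logcpm <- log2(cpm)
  mw <- do.call(rbind, lapply(rownames(sub), function(f) {
    res <- mann_whitney(logcpm[f, case], logcpm[f, ctrl])
    differential_row(f, lfc[f], res$p, "mann_whitney")
  }))
  if (config$adjust_p) {
    edge$p_value <- stats::p.adjust(edge$p_value, "BH")
    mw$p_value <- stats::p.adjust(mw$p_value, "BH")
  }
  attr(edge, "dispersion") <- disp
  list(edge = edge, mw = mw)
}

#' Candidate set
#'
#' @param members character vector of candidate feature ids.
#' @param provenance per-member tag, `"dual_test"` or `"literature"`.
#' @param excluded data.frame with `feature_id`, `reason` for features
#'   removed by the stage-consistency rule.
#' @return list of class `candidate_set`.
#' @export
candidate_set <- function(members, provenance, excluded =
                            data.frame(feature_id = character(),
                                       reason = character())) {
  members <- as.character(members)
  if (length(provenance) != length(members))
    stop("provenance must be defined for every member")
  if (any(members %in% excluded$feature_id))
    stop("members and excluded sets must be disjoint")
  structure(list(members = members,
                 provenance = stats::setNames(as.character(provenance), members),
                 excluded = excluded),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d members (%d dual-test, %d literature), %d excluded\n",
              length(x$members), sum(x$provenance == "dual_test"),
              sum(x$provenance == "literature"), nrow(x$excluded)))
  invisible(x)
}

#' Candidate selection from the dual-test intersection
#'
#' Implements the discovery end-game: intersect the hits of the two
#' differential arms, drop features that are not consistently significant
#' when all NSCLC stages are pooled against benign (stage-consistency rule;
#' with `config$stage_rule = "per_stage"` every stage must pass separately),
#' then add literature-supported candidates (deduplicated, tagged
#' `"literature"`). Order of the input sets never affects the result; the
#' members are returned sorted.
#'
#' @param edge_hits,mw_hits character vectors of significant feature ids
#'   from the count-test and rank-sum arms (thresholds already applied).
#' @param stagewise_p named numeric vector (or, for `per_stage`, a named list
#'   of vectors per stage) of p-values for the stages I-IV vs benign
#'   contrast.
#' @param literature character vector of literature candidates; entries
#'   absent from `universe` are kept but flagged with a warning.
#' @param config a [udr_config()].
#' @param universe optional character vector of all measured feature ids,
#'   used only to flag unknown literature entries.
#' @return A [candidate_set()].
#' @export
select_candidates <- function(edge_hits, mw_hits, stagewise_p,
                              literature = character(), config = udr_config(),
                              universe = NULL) {
  common <- sort(intersect(unique(edge_hits), unique(mw_hits)))
  pick <- function(v, f) if (f %in% names(v)) v[[f]] else NA_real_
  p_of <- function(f) {
    if (is.list(stagewise_p) && !is.data.frame(stagewise_p)) {
      vapply(stagewise_p, pick, numeric(1), f = f)
    } else pick(stagewise_p, f)
  }
  fails <- vapply(common, function(f) {
    p <- p_of(f)
    if (all(is.na(p))) return(FALSE)
    if (config$stage_rule == "per_stage") any(p >= config$mw_p_max, na.rm = TRUE)
    else any(!is.na(p)) && p[!is.na(p)][1] >= config$mw_p_max
  }, logical(1))
  excluded <- data.frame(feature_id = common[fails],
                         reason = rep("stage_consistency", sum(fails)),
                         stringsAsFactors = FALSE)
  kept <- common[!fails]
  literature <- sort(unique(as.character(literature)))
  if (!is.null(universe)) {
    unknown <- setdiff(literature, universe)
    if (length(unknown))
      warning("literature candidate(s) absent from the expression universe: ",
              paste(unknown, collapse = ", "))
  }
  lit_new <- setdiff(literature, kept)
  lit_new <- setdiff(lit_new, excluded$feature_id)
  members <- sort(c(kept, lit_new))
  provenance <- ifelse(members %in% kept, "dual_test", "literature")
  candidate_set(members, provenance, excluded)
}

#' Apply hit thresholds to a differential table
#'
#' @param de a differential data.frame (from [discovery_de()]).
#' @param p_max p-value cutoff (strict).
#' @param fc_min minimum |log2 fold change| (strict); `NULL` for no FC gate.
#' @return character vector of significant feature ids.
#' @export
de_hits <- function(de, p_max, fc_min = NULL) {
  ok <- de$p_value < p_max
  if (!is.null(fc_min)) ok <- ok & abs(de$log2_fc) > fc_min
  de$feature_id[ok & !is.na(ok)]
}
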
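#' Pipeline configuration
#'
#' Builds a validated run configuration. Defaults encode the filtering
#' cascade of the motivating study: a two-pass prevalence filter (zero-count
#' fraction strictly above 0.50, then 0.45), the dual discovery-stage
#' criteria (exact NB test p < 0.05 with |log2 FC| > 2.0, Mann-Whitney
#' p < 0.05), the qPCR validation gate (Mann-Whitney p < 0.05 and linear
#' fold change >= 1.5), and a parsimony band of 0.02 AUC for panel
#' selection.
#'
#' @param prevalence_stage1,prevalence_stage2 maximum tolerated zero-count
#'   fraction in the first and second prevalence pass (strict inequality).
#' @param edge_fc_min minimum |log2 fold change| (strict) for the count-based
#'   differential test arm.
#' @param edge_p_max,mw_p_max,val_p_max p-value cutoffs (strict) for the
#'   count test, discovery rank-sum test and validation rank-sum test.
#' @param val_fc_min minimum linear fold change (inclusive) in validation.
#' @param parsimony_epsilon AUC band below the best panel within which a
#'   smaller panel is preferred.
#' @param spike_in_id identifier of the exogenous spike-in row in Ct input
#'   (default the nematode control miRNA cel-miR-2-3p).
#' @param pseudocount added to CPM values before log/ratio operations.
#' @param stage_grouping named list mapping analysis labels to stage sets;
#'   `early` drives the main contrast, `all` drives the stage-consistency
#'   exclusion.
#' @param stage_rule `"pooled"` tests stages I-IV pooled against benign for
#'   the consistency exclusion; `"per_stage"` requires each stage separately
#'   to reach significance.
#' @param literature character vector of literature-supported candidates
#'   injected after the dual-test intersection.
#' @param undetermined_max maximum tolerated missing-value fraction per group
#'   in validation before a marker is reported undetermined.
#' @param adjust_p apply Benjamini-Hochberg adjustment to differential
#'   p-values before thresholding (off by default; the cascade filters on
#'   raw p-values).
#' @param n_boot bootstrap resamples for AUC confidence intervals.
#' @param seed integer seed controlling every stochastic step.
#' @return A list of class `udr_config`.
#' @export
udr_config <- function(prevalence_stage1 = 0.50,
                       prevalence_stage2 = 0.45,
                       edge_fc_min = 2.0,
                       edge_p_max = 0.05,
                       mw_p_max = 0.05,
                       val_fc_min = 1.5,
                       val_p_max = 0.05,
                       parsimony_epsilon = 0.02,
                       spike_in_id = "cel-miR-2-3p",
                       pseudocount = 1,
                       stage_grouping = list(early = c("I", "II"),
                                             all = c("I", "II", "III", "IV")),
                       stage_rule = c("pooled", "per_stage"),
                       literature = c("miR-497-5p", "miR-21-5p", "miR-205-5p"),
                       undetermined_max = 0.5,
                       adjust_p = FALSE,
                       n_boot = 2000,
                       seed = 1L) {
  stage_rule <- match.arg(stage_rule)
  cfg <- list(prevalence_stage1 = prevalence_stage1,
              prevalence_stage2 = prevalence_stage2,
              edge_fc_min = edge_fc_min, edge_p_max = edge_p_max,
              mw_p_max = mw_p_max, val_fc_min = val_fc_min,
              val_p_max = val_p_max, parsimony_epsilon = parsimony_epsilon,
              spike_in_id = spike_in_id, pseudocount = pseudocount,
              stage_grouping = stage_grouping, stage_rule = stage_rule,
              literature = literature, undetermined_max = undetermined_max,
              adjust_p = isTRUE(adjust_p), n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  frac <- c("prevalence_stage1", "prevalence_stage2", "undetermined_max")
  for (f in frac)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be a fraction in [0, 1]")
  for (p in c("edge_p_max", "mw_p_max", "val_p_max"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop(p, " must lie in (0, 1)")
  if (cfg$parsimony_epsilon < 0) stop("parsimony_epsilon must be >= 0")
  if (cfg$edge_fc_min < 0) stop("edge_fc_min must be >= 0")
  if (cfg$val_fc_min < 1) stop("val_fc_min is a linear ratio and must be >= 1")
  if (cfg$pseudocount < 0) stop("pseudocount must be >= 0")
  if (cfg$n_boot < 0) stop("n_boot must be >= 0")
  class(cfg) <- "udr_config"
  cfg
}

#' Read a configuration file
#'
#' Accepts YAML or JSON with flat keys matching the arguments of
#' [udr_config()]; unspecified keys take the defaults.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated `udr_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(udr_config)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(udr_config, vals)
}

#' Write a configuration file
#'
#' @param cfg a `udr_config`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "udr_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
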
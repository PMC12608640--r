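#' Run the full panel-selection pipeline
#'
#' Sequences the stages on whatever inputs are supplied:
#' \enumerate{
#'   \item \strong{Discovery} (needs `discovery_counts` + `discovery_meta`):
#'     two-pass prevalence filter, CPM normalization, dual differential
#'     testing (exact NB + Mann-Whitney) of early-stage NSCLC vs benign,
#'     stage-consistency screen, literature injection; writes
#'     `de_discovery.tsv` and `candidates.tsv`.
#'   \item \strong{Validation} (needs `validation_ct` + `validation_meta`):
#'     spike-in delta-Ct normalization, per-candidate fold-change/rank-sum
#'     filter and per-marker ROC; writes `de_validation.tsv`.
#'   \item \strong{Optimization}: directions from the validated markers,
#'     exhaustive panel enumeration (backward search when the space exceeds
#'     the exhaustive cap), parsimony selection; writes
#'     `panel_evaluations.tsv`, `panel_scores.tsv`, `roc_points.tsv`.
#'   \item \strong{Report}: `cohort_summary.tsv` for every cohort present.
#' }
#' When no discovery input is given the optimization runs on the validation
#' candidates alone (and vice versa validation outputs are absent for a
#' discovery-only run). Every filter logs before/after feature counts; the
#' whole run is a pure function of (inputs, config, seed).
#'
#' @param config a [udr_config()] (or path to a YAML/JSON config).
#' @param discovery_counts,discovery_meta paths to the discovery counts TSV
#'   and metadata CSV (or the objects themselves).
#' @param validation_ct,validation_meta paths to the validation Ct TSV and
#'   metadata CSV (or the objects themselves).
#' @param candidates optional explicit candidate ids for a validation-only
#'   run; defaults to the discovery candidates, or all measured features.
#' @param outdir output directory, created if needed.
#' @return (invisibly) list with the stage results and a `log` character
#'   vector; the TSV outputs land in `outdir`.
#' @export
run_pipeline <- function(config = udr_config(),
                         discovery_counts = NULL, discovery_meta = NULL,
                         validation_ct = NULL, validation_meta = NULL,
                         candidates = NULL, outdir = ".") {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "udr_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  tsv <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  as_expr <- function(x, scale) if (is.character(x)) read_expression(x, scale) else x
  as_meta <- function(x) if (is.character(x)) read_metadata(x) else x

  res <- list(log = NULL)
  early <- config$stage_grouping$early
  all_stages <- config$stage_grouping$all

  ## ---- discovery ----
  if (!is.null(discovery_counts)) {
    if (is.null(discovery_meta)) stop("discovery counts supplied without metadata")
    counts <- as_expr(discovery_counts, "counts")
    dmeta <- as_meta(discovery_meta)
    say("discovery: %d miRNAs x %d samples", nrow(counts), ncol(counts))
    f1 <- prevalence_filter(counts, config$prevalence_stage1)
    say("prevalence filter (zero fraction > %.2f): %d -> %d miRNAs",
        config$prevalence_stage1, nrow(counts), nrow(f1))
    f2 <- prevalence_filter(f1, config$prevalence_stage2)
    say("prevalence filter (zero fraction > %.2f): %d -> %d miRNAs",
        config$prevalence_stage2, nrow(f1), nrow(f2))
    libsizes <- colSums(counts)
    de <- discovery_de(f2, dmeta, stages = early, config = config,
                       libsizes = libsizes)
    edge_hits <- de_hits(de$edge, config$edge_p_max, config$edge_fc_min)
    mw_hits <- de_hits(de$mw, config$mw_p_max)
    say("differential arms (stages %s vs benign): %d NB hits, %d rank-sum hits, %d common",
        paste(early, collapse = "+"), length(edge_hits), length(mw_hits),
        length(intersect(edge_hits, mw_hits)))
    stagewise <- if (config$stage_rule == "pooled") {
      deA <- discovery_de(f2, dmeta, stages = all_stages, config = config,
                          libsizes = libsizes)
      stats::setNames(deA$mw$p_value, deA$mw$feature_id)
    } else {
      stats::setNames(lapply(all_stages, function(st) {
        d <- discovery_de(f2, dmeta, stages = st, config = config,
                          libsizes = libsizes)
        stats::setNames(d$mw$p_value, d$mw$feature_id)
      }), all_stages)
    }
    cand <- select_candidates(edge_hits, mw_hits, stagewise,
                              literature = config$literature, config = config,
                              universe = rownames(counts))
    say("candidates: %d members (%d excluded by stage consistency, %d literature)",
        length(cand$members), nrow(cand$excluded),
        sum(cand$provenance == "literature"))
    both <- rbind(de$edge, de$mw)
    tsv(both, "de_discovery.tsv")
    cand_df <- rbind(
      data.frame(feature_id = cand$members,
                 provenance = unname(cand$provenance),
                 excluded_reason = "", stringsAsFactors = FALSE),
      if (nrow(cand$excluded))
        data.frame(feature_id = cand$excluded$feature_id,
                   provenance = "dual_test",
                   excluded_reason = cand$excluded$reason,
                   stringsAsFactors = FALSE))
    tsv(cand_df, "candidates.tsv")
    res$discovery <- list(filtered = f2, de = de, candidates = cand)
    res$discovery_expr <- cpm_normalize(f2, libsizes = libsizes,
                                        pseudocount = config$pseudocount)
    res$discovery_meta <- dmeta
    if (is.null(candidates)) candidates <- cand$members
  }

  ## ---- validation ----
  if (!is.null(validation_ct)) {
    if (is.null(validation_meta)) stop("validation Ct supplied without metadata")
    ct <- as_expr(validation_ct, "ct")
    vmeta <- as_meta(validation_meta)
    dct <- normalize_delta_ct(ct, config$spike_in_id)
    feats <- intersect(candidates %||% rownames(dct), rownames(dct))
    say("validation: %d candidates measured on %d samples", length(feats),
        ncol(dct))
    vres <- validate_candidates(dct, vmeta, feats, stages = early,
                                config = config)
    rocs <- per_marker_roc(dct, vmeta, feats, stages = early,
                           n_boot = config$n_boot, seed = config$seed)
    vtab <- merge(vres, data.frame(
      feature_id = vapply(rocs, `[[`, character(1), "feature_id"),
      auc = vapply(rocs, `[[`, numeric(1), "auc"),
      ci_low = vapply(rocs, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(rocs, `[[`, numeric(1), "ci_high"),
      stringsAsFactors = FALSE), by = "feature_id")
    say("validated markers: %d of %d (p < %.3g and FC >= %.2f); %d undetermined",
        sum(vtab$status == "validated"), nrow(vtab), config$val_p_max,
        config$val_fc_min, sum(vtab$status == "undetermined"))
    tsv(vtab, "de_validation.tsv")
    res$validation <- list(results = vtab, rocs = rocs)
    res$validation_expr <- linearize(dct)
    res$validation_meta <- vmeta
    roc_pts <- do.call(rbind, lapply(rocs, function(r)
      data.frame(feature_id = r$feature_id, fpr = r$points$fpr,
                 tpr = r$points$tpr, stringsAsFactors = FALSE)))
    tsv(roc_pts, "roc_points.tsv")
  }

  ## ---- optimization ----
  dir_src <- if (!is.null(res$validation)) {
    res$validation$results[res$validation$results$status == "validated", ]
  } else if (!is.null(res$discovery)) {
    d <- res$discovery$de$mw
    d[d$feature_id %in% res$discovery$candidates$members &
        d$direction != "flat", ]
  }
  if (!is.null(dir_src) && nrow(dir_src) &&
      any(dir_src$direction == "up") && any(dir_src$direction == "down")) {
    dirs <- assign_directions(dir_src)
    say("optimization: %d up / %d down markers", length(dirs$up),
        length(dirs$down))
    cohorts <- list()
    if (!is.null(res$validation))
      cohorts$validation <- list(expr = res$validation_expr,
                                 meta = res$validation_meta)
    if (!is.null(res$discovery))
      cohorts$discovery <- list(expr = res$discovery_expr,
                                meta = res$discovery_meta)
    n_space <- (2^length(dirs$up) - 1) * (2^length(dirs$down) - 1)
    eval_rows <- list(); score_rows <- list(); res$optimization <- list()
    for (tag in names(cohorts)) {
      co <- cohorts[[tag]]
      evs <- if (n_space <= 4096) {
        lapply(enumerate_panels(dirs$up, dirs$down),
               function(p) evaluate_panel(co$expr, co$meta, p, stages = early,
                                          ci = FALSE, cohort_tag = tag))
      } else {
        say("panel space of %d exceeds the exhaustive cap; backward search", n_space)
        backward_search(co$expr, co$meta, dirs$up, dirs$down, stages = early,
                        cohort_tag = tag)
      }
      top <- select_optimal(evs, config$parsimony_epsilon)
      say("%s cohort: %d panels evaluated, best AUC %.3f; %d within the %.3g parsimony band",
          tag, length(evs), max(vapply(evs, function(e) e$roc$auc, numeric(1))),
          length(top), config$parsimony_epsilon)
      # bootstrap CI only for the selected panels, at full resolution
      top <- lapply(top, function(e) {
        e$roc <- roc_auc(e$udr_scores,
                         names(e$udr_scores) %in%
                           contrast_samples(co$meta, early)$case,
                         ci = config$n_boot > 0, n_boot = config$n_boot,
                         seed = sub_seed(config$seed, panel_id(e$panel)))
        e
      })
      res$optimization[[tag]] <- list(evaluations = evs, selected = top)
      eval_rows[[tag]] <- do.call(rbind, lapply(evs, function(e) {
        sel <- vapply(top, function(t) panel_id(t$panel) == panel_id(e$panel),
                      logical(1))
        ci_l <- if (any(sel)) top[[which(sel)[1]]]$roc$ci_low else NA_real_
        ci_h <- if (any(sel)) top[[which(sel)[1]]]$roc$ci_high else NA_real_
        data.frame(cohort = tag,
                   panel_members = paste(c(paste0("up:", e$panel$up),
                                           paste0("down:", e$panel$down)),
                                         collapse = ";"),
                   n_up = length(e$panel$up), n_down = length(e$panel$down),
                   auc = e$roc$auc, ci_low = ci_l, ci_high = ci_h,
                   n_evaluable = e$roc$n_case + e$roc$n_control,
                   selected = any(sel), stringsAsFactors = FALSE)
      }))
      score_rows[[tag]] <- do.call(rbind, lapply(top, function(e)
        data.frame(cohort = tag, sample_id = names(e$udr_scores),
                   panel_id = panel_id(e$panel), udr = unname(e$udr_scores),
                   stringsAsFactors = FALSE)))
    }
    tsv(do.call(rbind, eval_rows), "panel_evaluations.tsv")
    tsv(do.call(rbind, score_rows), "panel_scores.tsv")
  }

  ## ---- report ----
  summaries <- list()
  if (!is.null(res$discovery_meta))
    summaries$discovery <- cbind(cohort = "discovery",
                                 cohort_summary(res$discovery_meta))
  if (!is.null(res$validation_meta))
    summaries$validation <- cbind(cohort = "validation",
                                  cohort_summary(res$validation_meta))
  if (length(summaries)) tsv(do.call(rbind, summaries), "cohort_summary.tsv")
  res$log <- log
  writeLines(log, file.path(outdir, "pipeline_log.txt"))
  invisible(res)
}
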
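#' Mann-Whitney U test
#'
#' Two-sided rank-sum test used throughout the cascade (discovery arm B and
#' the qPCR validation filter). The statistic is
#' \eqn{U = \#\{(x_i, y_j): x_i > y_j\} + \tfrac12 \#\{x_i = y_j\}}.
#' For small untied samples (\eqn{n_1 + n_2 \le 12}, no ties) the p-value is
#' exact, computed from the full null distribution of U; otherwise the normal
#' approximation with midrank tie correction and continuity correction is
#' used. The exact two-sided p-value is the null probability of a U at least
#' as far from \eqn{n_1 n_2 / 2} as the observed one.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0)
    stop("both groups must be non-empty after dropping missing values")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  m <- n1 * n2 / 2
  if (n1 + n2 <= 12 && !ties) {
    u_all <- 0:(n1 * n2)
    d <- stats::dwilcox(u_all, n1, n2)
    p <- sum(d[abs(u_all - m) >= abs(U - m) - 1e-12])
    method <- "exact"
  } else {
    n <- n1 + n2
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sd_u <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sd_u == 0) {
      p <- 1
    } else {
      z <- (U - m - sign(U - m) * 0.5) / sd_u
      if (abs(U - m) <= 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Exact conditional negative-binomial test for two groups of counts
#'
#' Tests equality of relative abundance of one feature between two groups of
#' count samples. Conditional on the overall feature total \eqn{s}, the
#' group-1 total follows (dispersion 0, the Poisson limit) a binomial with
#' success probability \eqn{N_1 / (N_1 + N_2)} where \eqn{N_g} is the summed
#' library size of group \eqn{g}; with dispersion \eqn{\phi > 0} each group
#' total is moment-matched to a negative binomial (size
#' \eqn{N_g^2 / (\phi \sum_s l_s^2)}, exact under equal within-group library
#' sizes) and the conditional distribution is enumerated. The two-sided
#' p-value doubles the smaller tail, capped at 1.
#'
#' This is a deliberately transparent stand-in for an edgeR-style exact test:
#' total-count normalization and a single common dispersion, no TMM or
#' conditional-likelihood machinery.
#'
#' @param counts1,counts2 non-negative integer counts per sample.
#' @param libsizes per-sample library sizes, group 1 followed by group 2
#'   (length `length(counts1) + length(counts2)`).
#' @param dispersion common negative-binomial dispersion (>= 0).
#' @return list with `p` and `flat` (`TRUE` when the feature has zero total
#'   count, in which case `p = 1`).
#' @examples
#' exact_nb_test(5, 0, c(1e6, 1e6), dispersion = 0)  # p = 2 * (1/2)^5
#' @export
exact_nb_test <- function(counts1, counts2, libsizes, dispersion = 0) {
  if (any(counts1 < 0, counts2 < 0) ||
      any(c(counts1, counts2) != floor(c(counts1, counts2))))
    stop("counts must be non-negative integers")
  n1 <- length(counts1); n2 <- length(counts2)
  if (length(libsizes) != n1 + n2)
    stop("libsizes must cover group 1 then group 2")
  if (any(libsizes <= 0)) stop("library sizes must be positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  ls1 <- libsizes[seq_len(n1)]; ls2 <- libsizes[n1 + seq_len(n2)]
  s1 <- sum(counts1); s <- s1 + sum(counts2)
  if (s == 0) return(list(p = 1, flat = TRUE))
  N1 <- sum(ls1); N2 <- sum(ls2)
  if (dispersion == 0) {
    logf <- function(k) stats::dbinom(k, s, N1 / (N1 + N2), log = TRUE)
    center <- s * N1 / (N1 + N2)
    spread <- sqrt(max(1, s * N1 * N2 / (N1 + N2)^2))
  } else {
    lambda <- s / (N1 + N2)
    mu1 <- lambda * N1; mu2 <- lambda * N2
    size1 <- N1^2 / (dispersion * sum(ls1^2))
    size2 <- N2^2 / (dispersion * sum(ls2^2))
    logf <- function(k) stats::dnbinom(k, mu = mu1, size = size1, log = TRUE) +
      stats::dnbinom(s - k, mu = mu2, size = size2, log = TRUE)
    center <- s * N1 / (N1 + N2)
    spread <- sqrt(mu1 * (1 + mu1 / size1) + 1)
  }
  if (s <= 20000) {
    ks <- 0:s
  } else {
    lo <- max(0, floor(center - 40 * spread))
    hi <- min(s, ceiling(center + 40 * spread))
    ks <- min(lo, s1):max(hi, s1)
  }
  lp <- logf(ks)
  lp <- lp - max(lp)
  w <- exp(lp)
  total <- sum(w)
  p_low <- sum(w[ks <= s1]) / total
  p_high <- sum(w[ks >= s1]) / total
  list(p = min(1, 2 * min(p_low, p_high)), flat = FALSE)
}

#' Method-of-moments dispersion estimate
#'
#' Per-feature negative-binomial dispersion on library-size-scaled counts:
#' \eqn{\hat\phi_f = \max(0, (s_f^2 - \bar m_f) / \bar m_f^2)} where
#' \eqn{\bar m_f} and \eqn{s_f^2} are the mean and variance of the counts
#' rescaled to the mean library size. The pooled common dispersion is the
#' median over features with non-zero mean.
#'
#' @param counts counts matrix (features x samples) or `expr_matrix` of
#'   scale `"counts"`.
#' @param libsizes per-sample library sizes; defaults to column sums.
#' @return list with `per_feature` (named vector) and `common` (scalar).
#' @export
estimate_dispersion <- function(counts, libsizes = colSums(counts)) {
  if (inherits(counts, "expr_matrix") && expr_scale(counts) != "counts")
    stop("dispersion estimation requires counts scale")
  counts <- unclass(counts)
  if (ncol(counts) < 2) stop("at least 2 samples are required")
  if (any(libsizes <= 0)) stop("library sizes must be positive")
  y <- sweep(counts, 2, libsizes, "/") * mean(libsizes)
  m <- rowMeans(y)
  v <- apply(y, 1, stats::var)
  phi <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  names(phi) <- rownames(counts)
  common <- if (any(m > 0)) stats::median(phi[m > 0]) else 0
  list(per_feature = phi, common = common)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC is the tie-adjusted probability that a random case outscores a random
#' control, \eqn{(\mathrm{concordant} + 0.5\,\mathrm{tied})/(n_1 n_2)},
#' identical to the trapezoidal area under the empirical ROC curve. The 95%
#' confidence interval is a stratified bootstrap percentile interval
#' (cases and controls resampled separately).
#'
#' @param scores numeric score per sample (higher = more case-like).
#' @param is_case logical, `TRUE` for cases.
#' @param ci compute the bootstrap interval (skipped when `FALSE`).
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional integer making the bootstrap reproducible without
#'   touching the caller's RNG stream.
#' @return An object of class `roc_result`: list with `points` (data.frame
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control`, `degenerate` (all scores tied).
#' @export
roc_auc <- function(scores, is_case, ci = TRUE, n_boot = 2000, conf = 0.95,
                    seed = NULL) {
  keep <- !is.na(scores)
  scores <- scores[keep]; is_case <- is_case[keep]
  if (!length(scores)) stop("all scores are missing")
  if (!is.logical(is_case)) stop("`is_case` must be logical")
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  auc_of <- function(sc, cs) {
    r <- rank(sc)
    (sum(r[cs]) - sum(cs) * (sum(cs) + 1) / 2) / (sum(cs) * sum(!cs))
  }
  auc <- auc_of(scores, is_case)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; cs <- is_case[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- tapply(cs, grp, sum); fp <- tapply(!cs, grp, sum)
  points <- data.frame(fpr = c(0, cumsum(fp) / n2),
                       tpr = c(0, cumsum(tp) / n1))
  ci_low <- ci_high <- NA_real_
  if (ci && n_boot > 0) {
    idx_case <- which(is_case); idx_ctrl <- which(!is_case)
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx_case, n1, replace = TRUE),
             sample(idx_ctrl, n2, replace = TRUE))
      auc_of(scores[i], is_case[i])
    }, numeric(1)))
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
    ci_low <- min(qs[1], auc); ci_high <- max(qs[2], auc)
  }
  structure(list(points = points, auc = auc, ci_low = ci_low,
                 ci_high = ci_high, n_case = n1, n_control = n2,
                 degenerate = length(unique(scores)) == 1L),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_case, x$n_control))
  invisible(x)
}

#' Fold change from delta-Ct values
#'
#' Delta-Ct is already a log2-scale abundance (one PCR cycle is one
#' doubling), so the log2 fold change of case versus control is simply the
#' difference of group means; the linear fold change is \eqn{2^{|\Delta\Delta
#' Ct|}} and is therefore always >= 1, with the sign carried by `direction`.
#'
#' @param delta_ct_case,delta_ct_control numeric vectors of normalized
#'   delta-Ct values (missing values dropped).
#' @return list with `log2_fc`, `fc_linear`, `direction`
#'   (`"up"`, `"down"` or `"flat"`).
#' @export
qpcr_fold_change <- function(delta_ct_case, delta_ct_control) {
  x <- delta_ct_case[!is.na(delta_ct_case)]
  y <- delta_ct_control[!is.na(delta_ct_control)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  lfc <- mean(x) - mean(y)
  list(log2_fc = lfc,
       fc_linear = 2^abs(lfc),
       direction = if (lfc > 0) "up" else if (lfc < 0) "down" else "flat")
}

#' Assemble a differential-result table row
#'
#' @param feature_id identifier.
#' @param log2_fc log2 fold change, case vs control.
#' @param p_value two-sided p-value.
#' @param test name of the test that produced `p_value`.
#' @return one-row data.frame with the derived `fc_linear` and `direction`.
#' @keywords internal
differential_row <- function(feature_id, log2_fc, p_value, test) {
  data.frame(feature_id = feature_id, log2_fc = log2_fc,
             fc_linear = 2^abs(log2_fc),
             direction = if (is.na(log2_fc) || log2_fc == 0) "flat"
                         else if (log2_fc > 0) "up" else "down",
             p_value = p_value, test = test, stringsAsFactors = FALSE)
}

#' Cohort summary table
#'
#' Demographic/clinical summary in the layout conventional for a clinical
#' "Table 1": per-variable counts with percentages (one decimal) for the
#' whole cohort, the benign group and the NSCLC group, plus a between-group
#' p-value (rank-sum for age; chi-squared with continuity correction for 2x2
#' categorical variables, replaced by Fisher's exact test when any expected
#' cell is below 5). Stage and histology are tabulated within the NSCLC
#' group only, with no test.
#'
#' @param meta a `sample_meta` data.frame.
#' @return data.frame with columns `variable`, `level`, `overall_n`,
#'   `overall_pct`, `benign_n`, `benign_pct`, `nsclc_n`, `nsclc_pct`,
#'   `p_value`, `test`. For `variable == "age"` the `*_n` columns hold the
#'   group means (`level == "mean"`) and standard deviations
#'   (`level == "sd"`); percentage columns are `NA` there.
#' @export
cohort_summary <- function(meta) {
  stopifnot(inherits(meta, "sample_meta"))
  if (!nrow(meta)) stop("empty cohort")
  ben <- meta[meta$group == "benign", , drop = FALSE]
  can <- meta[meta$group == "nsclc", , drop = FALSE]
  both <- nrow(ben) > 0 && nrow(can) > 0
  pct <- function(n, d) if (d > 0) round(100 * n / d, 1) else NA_real_

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  age_p <- if (both && sum(!is.na(ben$age)) > 0 && sum(!is.na(can$age)) > 0)
    mann_whitney(can$age, ben$age)$p else NA_real_
  gm <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  gs <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)
  add(variable = "age", level = "mean",
      overall_n = gm(meta$age), overall_pct = NA_real_,
      benign_n = gm(ben$age), benign_pct = NA_real_,
      nsclc_n = gm(can$age), nsclc_pct = NA_real_,
      p_value = age_p, test = "mann_whitney")
  add(variable = "age", level = "sd",
      overall_n = gs(meta$age), overall_pct = NA_real_,
      benign_n = gs(ben$age), benign_pct = NA_real_,
      nsclc_n = gs(can$age), nsclc_pct = NA_real_,
      p_value = NA_real_, test = NA_character_)

  cat_p <- function(col, levels) {
    if (!both) return(list(p = NA_real_, test = NA_character_))
    tab <- rbind(vapply(levels, function(l) sum(ben[[col]] == l, na.rm = TRUE),
                        numeric(1)),
                 vapply(levels, function(l) sum(can[[col]] == l, na.rm = TRUE),
                        numeric(1)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(list(p = NA_real_, test = NA_character_))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      list(p = stats::fisher.test(tab)$p.value, test = "fisher_exact")
    } else {
      list(p = suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value),
           test = "chi_squared")
    }
  }

  for (spec in list(list(col = "sex", levels = c("male", "female")),
                    list(col = "smoking", levels = c("yes", "no")),
                    list(col = "comorbidity", levels = c("yes", "no")))) {
    tst <- cat_p(spec$col, spec$levels)
    for (i in seq_along(spec$levels)) {
      l <- spec$levels[i]
      add(variable = spec$col, level = l,
          overall_n = sum(meta[[spec$col]] == l, na.rm = TRUE),
          overall_pct = pct(sum(meta[[spec$col]] == l, na.rm = TRUE), nrow(meta)),
          benign_n = sum(ben[[spec$col]] == l, na.rm = TRUE),
          benign_pct = pct(sum(ben[[spec$col]] == l, na.rm = TRUE), nrow(ben)),
          nsclc_n = sum(can[[spec$col]] == l, na.rm = TRUE),
          nsclc_pct = pct(sum(can[[spec$col]] == l, na.rm = TRUE), nrow(can)),
          p_value = if (i == 1) tst$p else NA_real_,
          test = if (i == 1) tst$test else NA_character_)
    }
  }

  if (nrow(can)) {
    for (st in c("I", "II", "III", "IV")) {
      n <- sum(can$stage == st)
      add(variable = "stage", level = st,
          overall_n = NA_real_, overall_pct = NA_real_,
          benign_n = NA_real_, benign_pct = NA_real_,
          nsclc_n = n, nsclc_pct = pct(n, nrow(can)),
          p_value = NA_real_, test = NA_character_)
    }
    if (!is.null(can$histology) && any(!is.na(can$histology))) {
      for (h in c("adeno", "sqcc", "nos")) {
        n <- sum(can$histology == h, na.rm = TRUE)
        add(variable = "histology", level = h,
            overall_n = NA_real_, overall_pct = NA_real_,
            benign_n = NA_real_, benign_pct = NA_real_,
            nsclc_n = n, nsclc_pct = pct(n, nrow(can)),
            p_value = NA_real_, test = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}
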
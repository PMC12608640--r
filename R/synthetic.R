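#' Synthetic cohort design
#'
#' Describes a simulated serum cohort: group sizes, per-feature generative
#' parameters, NGS depth range and the qPCR spike-in level. The same design
#' drives both generators so an NGS-like discovery cohort and a qPCR-like
#' validation cohort can be simulated under one planted truth.
#'
#' Per-feature parameters (columns of `features`):
#' \describe{
#'   \item{feature_id}{unique miRNA identifier.}
#'   \item{baseline}{mean abundance: delta-Ct units for the qPCR generator,
#'     relative abundance weight (normalized internally to a proportion) for
#'     the count generator.}
#'   \item{effect_log2fc}{planted case-vs-benign log2 shift for early-stage
#'     (I-II) NSCLC samples.}
#'   \item{effect_late_log2fc}{shift for stage III-IV samples; defaults to
#'     `effect_log2fc`. Setting it to 0 plants an early-only signal and
#'     exercises the stage-consistency exclusion.}
#'   \item{sigma}{within-group standard deviation on the delta-Ct (log2)
#'     scale; qPCR generator only.}
#'   \item{dispersion}{negative-binomial dispersion; count generator only
#'     (0 = Poisson).}
#'   \item{zero_prob}{structural-zero probability; count generator only.}
#' }
#'
#' @param n_benign number of benign (control) samples.
#' @param n_stage named integer vector of NSCLC sample counts per stage,
#'   e.g. `c(I = 10, II = 10, III = 10, IV = 10)`.
#' @param features data.frame of per-feature parameters (see Details);
#'   missing optional columns take defaults
#'   (`effect_log2fc = 0`, `effect_late_log2fc = effect_log2fc`,
#'   `sigma = 1`, `dispersion = 0.2`, `zero_prob = 0`).
#' @param libsize_range two-element numeric, uniform range of NGS library
#'   sizes per sample.
#' @param spike_in_ct fixed Ct of the exogenous spike-in row.
#' @param spike_in_id identifier of the spike-in row.
#' @param seed integer seed; all draws are deterministic functions of
#'   `(seed, feature_id)` so adding a feature never perturbs the others.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_benign,
                             n_stage = c(I = 0, II = 0, III = 0, IV = 0),
                             features,
                             libsize_range = c(5e5, 2e6),
                             spike_in_ct = 21,
                             spike_in_id = "cel-miR-2-3p",
                             seed = 1L) {
  stopifnot(is.data.frame(features), "feature_id" %in% names(features))
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id))
    stop("feature_ids must be unique")
  if (is.null(features$baseline)) features$baseline <- 0
  if (is.null(features$effect_log2fc)) features$effect_log2fc <- 0
  if (is.null(features$effect_late_log2fc))
    features$effect_late_log2fc <- features$effect_log2fc
  if (is.null(features$sigma)) features$sigma <- 1
  if (is.null(features$dispersion)) features$dispersion <- 0.2
  if (is.null(features$zero_prob)) features$zero_prob <- 0
  if (any(features$sigma <= 0)) stop("sigma must be > 0")
  if (any(features$dispersion < 0)) stop("dispersion must be >= 0")
  if (any(features$zero_prob < 0 | features$zero_prob >= 1))
    stop("zero_prob must lie in [0, 1)")
  n_stage <- n_stage[c("I", "II", "III", "IV")]
  n_stage[is.na(n_stage)] <- 0
  names(n_stage) <- c("I", "II", "III", "IV")
  if (n_benign < 0 || any(n_stage < 0)) stop("sample counts must be >= 0")
  structure(list(n_benign = as.integer(n_benign),
                 n_stage = as.integer(n_stage) |> stats::setNames(names(n_stage)),
                 features = features,
                 libsize_range = libsize_range,
                 spike_in_ct = spike_in_ct,
                 spike_in_id = spike_in_id,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

design_meta <- function(design, prefix = "SYN") {
  n_stage <- design$n_stage
  n <- design$n_benign + sum(n_stage)
  if (n == 0) stop("design contains zero samples")
  groups <- c(rep("benign", design$n_benign), rep("nsclc", sum(n_stage)))
  stages <- c(rep("none", design$n_benign), rep(names(n_stage), n_stage))
  demo <- with_seed(sub_seed(design$seed, "demographics"), list(
    age = round(stats::rnorm(n, 72, 10), 1),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.68, 0.32)),
    smoking = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.66, 0.34)),
    comorbidity = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.11, 0.89))
  ))
  sample_meta(data.frame(
    sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
    group = groups, stage = stages, age = demo$age, sex = demo$sex,
    smoking = demo$smoking, comorbidity = demo$comorbidity,
    stringsAsFactors = FALSE))
}

design_effects <- function(design) {
  # per-feature planted log2 shift for each sample (0 for benign)
  f <- design$features
  early <- c(rep(0, design$n_benign),
             rep(c(1, 1, 0, 0), design$n_stage))
  late <- c(rep(0, design$n_benign),
            rep(c(0, 0, 1, 1), design$n_stage))
  outer(f$effect_log2fc, early) + outer(f$effect_late_log2fc, late)
}

#' Simulate a qPCR cohort (Ct scale)
#'
#' For sample \eqn{s} in group \eqn{g}, feature \eqn{f}:
#' \deqn{Ct(f, s) = Ct_{spike} - (baseline_f + effect_f \cdot 1[g\ case]
#'   + N(0, \sigma_f))}
#' so that after spike-in normalization the delta-Ct values are normal with
#' the planted group shift on the log2 scale. The spike-in row is included
#' with constant Ct. Deterministic given the design seed; each feature draws
#' from its own seed-derived stream.
#'
#' @param design a [synthetic_design()].
#' @return list with `expr` (an `expr_matrix`, scale `"ct"`, spike-in row
#'   first) and `meta` (a `sample_meta`).
#' @export
gen_qpcr_cohort <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  meta <- design_meta(design)
  n <- nrow(meta)
  f <- design$features
  eff <- design_effects(design)
  vals <- matrix(NA_real_, nrow(f) + 1L, n)
  vals[1L, ] <- design$spike_in_ct
  for (i in seq_len(nrow(f))) {
    noise <- with_seed(sub_seed(design$seed, paste0("qpcr:", f$feature_id[i])),
                       stats::rnorm(n, 0, f$sigma[i]))
    vals[i + 1L, ] <- design$spike_in_ct - (f$baseline[i] + eff[i, ] + noise)
  }
  rownames(vals) <- c(design$spike_in_id, f$feature_id)
  colnames(vals) <- meta$sample_id
  list(expr = expr_matrix(vals, scale = "ct"), meta = meta)
}

#' Simulate an NGS count cohort
#'
#' Library sizes are uniform in `libsize_range`; feature baselines are
#' normalized to relative proportions \eqn{\pi_f}. Counts are structural
#' zeros with probability `zero_prob`, otherwise negative binomial with mean
#' \eqn{l_s \pi_f 2^{effect_f \cdot 1[case]}} and the feature's dispersion
#' (Poisson when dispersion is 0). Deterministic given the design seed, with
#' per-feature streams.
#'
#' @param design a [synthetic_design()].
#' @return list with `expr` (an `expr_matrix`, scale `"counts"`) and `meta`.
#' @export
gen_ngs_cohort <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  f <- design$features
  if (!nrow(f)) stop("design has an empty feature list")
  meta <- design_meta(design)
  n <- nrow(meta)
  libsizes <- with_seed(sub_seed(design$seed, "libsizes"),
                        round(stats::runif(n, design$libsize_range[1],
                                           design$libsize_range[2])))
  prop <- f$baseline / sum(f$baseline)
  eff <- design_effects(design)
  vals <- matrix(0, nrow(f), n)
  for (i in seq_len(nrow(f))) {
    mu <- libsizes * prop[i] * 2^eff[i, ]
    vals[i, ] <- with_seed(
      sub_seed(design$seed, paste0("ngs:", f$feature_id[i])), {
        cnt <- if (f$dispersion[i] == 0) stats::rpois(n, mu)
               else stats::rnbinom(n, mu = mu, size = 1 / f$dispersion[i])
        zero <- stats::runif(n) < f$zero_prob[i]
        cnt[zero] <- 0
        cnt
      })
  }
  rownames(vals) <- f$feature_id
  colnames(vals) <- meta$sample_id
  attr_ls <- libsizes
  out <- expr_matrix(vals, scale = "counts")
  attr(out, "design_libsizes") <- attr_ls
  list(expr = out, meta = meta)
}

#' Effect size matching a target single-marker AUC
#'
#' Under the equal-variance normal model (control \eqn{N(0, \sigma^2)}, case
#' \eqn{N(\beta, \sigma^2)}) the population AUC is
#' \eqn{\Phi(\beta / (\sqrt{2}\sigma))}; inverting gives
#' \eqn{\beta = \sqrt{2}\,\sigma\,\Phi^{-1}(A)}.
#'
#' @param target_auc desired AUC, in (0.5, 1).
#' @param sigma within-group standard deviation (delta-Ct units).
#' @return effect size in delta-Ct (log2) units.
#' @examples
#' calibrate_effect_from_auc(0.830)  # ~1.3494
#' @export
calibrate_effect_from_auc <- function(target_auc, sigma = 1) {
  if (any(target_auc <= 0.5) || any(target_auc >= 1))
    stop("target_auc must lie strictly between 0.5 and 1")
  if (sigma <= 0) stop("sigma must be > 0")
  sqrt(2) * sigma * stats::qnorm(target_auc)
}

#' Effect size matching a target rank-sum p-value
#'
#' Inverts the normal approximation of the Mann-Whitney z-statistic for a
#' normal location-shift model: finds the shift for which the expected z
#' equals \eqn{\Phi^{-1}(1 - p/2)}. The expected U is
#' \eqn{n_1 n_2 \Phi(\beta/(\sqrt{2}\sigma))}.
#'
#' @param target_p desired two-sided p-value, in (0, 1).
#' @param n1,n2 group sizes.
#' @param sigma within-group standard deviation.
#' @return effect size in delta-Ct (log2) units.
#' @export
calibrate_effect_from_p <- function(target_p, n1, n2, sigma = 1) {
  if (any(target_p <= 0) || any(target_p >= 1))
    stop("target_p must lie strictly in (0, 1)")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (sigma <= 0) stop("sigma must be > 0")
  z <- stats::qnorm(1 - target_p / 2)
  sd_u <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_xy <- pmin(1 - 1e-12, 0.5 + z * sd_u / (n1 * n2))
  sqrt(2) * sigma * stats::qnorm(p_xy)
}
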
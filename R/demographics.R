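#' Reference cohort demographics
#'
#' Reconstructs the per-group clinical margins of the two serum cohorts the
#' pipeline is built around: a 76-sample NGS discovery cohort (16 benign /
#' 60 NSCLC) and a 75-sample qPCR validation cohort (35 benign / 40 NSCLC)
#' of patients with benign pulmonary nodules or stage I-IV NSCLC.
#'
#' Only the per-group margins of each variable are fixed (they determine
#' every percentage and 2x2 test in [cohort_summary()]); the joint assignment
#' of attributes to individual samples is an arbitrary deterministic one.
#' Ages are deterministic normal quantiles matching each group's reported
#' mean and standard deviation.
#'
#' @param set `"discovery"` or `"validation"`.
#' @return A `sample_meta` data.frame (with `histology` for NSCLC samples).
#' @examples
#' meta <- cohort_demographics("discovery")
#' subset(cohort_summary(meta), variable == "sex")
#' @export
cohort_demographics <- function(set = c("discovery", "validation")) {
  set <- match.arg(set)
  spec <- if (set == "discovery") list(
    benign = list(n = 16, male = 10, smoker = 8, comorbid = 3,
                  age_mean = 72.8, age_sd = 9.7),
    nsclc = list(n = 60, male = 42, smoker = 42, comorbid = 6,
                 age_mean = 74.0, age_sd = 10.5,
                 stages = c(I = 19, II = 8, III = 12, IV = 21),
                 histology = c(adeno = 28, sqcc = 31, nos = 1))
  ) else list(
    benign = list(n = 35, male = 23, smoker = 22, comorbid = 4,
                  age_mean = 70.5, age_sd = 12.2),
    nsclc = list(n = 40, male = 29, smoker = 29, comorbid = 4,
                 age_mean = 75.3, age_sd = 10.8,
                 stages = c(I = 10, II = 10, III = 10, IV = 10),
                 histology = c(adeno = 22, sqcc = 18, nos = 0))
  )
  blom_ages <- function(n, mean, sd) {
    q <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
    round(mean + sd * q, 1)
  }
  mk <- function(g, s, prefix) {
    n <- s$n
    data.frame(
      sample_id = sprintf("%s_%s_%02d", prefix, g, seq_len(n)),
      group = g,
      stage = if (g == "benign") rep("none", n)
              else rep(names(s$stages), s$stages),
      age = blom_ages(n, s$age_mean, s$age_sd),
      sex = rep(c("male", "female"), c(s$male, n - s$male)),
      smoking = rep(c("yes", "no"), c(s$smoker, n - s$smoker)),
      comorbidity = rep(c("yes", "no"), c(s$comorbid, n - s$comorbid)),
      histology = if (g == "benign") rep(NA_character_, n)
                  else rep(names(s$histology), s$histology),
      stringsAsFactors = FALSE)
  }
  prefix <- if (set == "discovery") "D" else "V"
  sample_meta(rbind(mk("benign", spec$benign, prefix),
                    mk("nsclc", spec$nsclc, prefix)))
}
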
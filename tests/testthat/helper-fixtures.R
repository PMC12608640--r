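# Shared fixtures and independent oracles.

# Brute-force Mann-Whitney oracle: U by direct pair counting, two-sided p by
# full enumeration of all C(n1+n2, n1) group assignments of the pooled values.
mw_oracle <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  m <- n1 * length(y) / 2
  us <- apply(utils::combn(length(pooled), n1), 2, function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  list(U = U, p = mean(abs(us - m) >= abs(U - m) - 1e-12))
}

# Trapezoidal area under an ROC point set (independent of the rank formula).
trapezoid_auc <- function(points) {
  with(points, sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

# Minimal counts fixture with prescribed zero fractions per feature.
counts_with_zero_fracs <- function(zero_fracs, n_samples) {
  vals <- t(vapply(zero_fracs, function(zf) {
    n0 <- round(zf * n_samples)
    c(rep(0, n0), rep(5, n_samples - n0))
  }, numeric(n_samples)))
  rownames(vals) <- paste0("miR-", seq_along(zero_fracs))
  colnames(vals) <- paste0("S", seq_len(n_samples))
  expr_matrix(vals, scale = "counts")
}

# qPCR design with planted early-stage effects (delta-Ct/log2 units).
planted_qpcr_design <- function(effects, sigma, n_benign, n_early,
                                n_late = c(III = 0, IV = 0), seed = 1,
                                baseline = -4) {
  synthetic_design(
    n_benign = n_benign,
    n_stage = c(I = ceiling(n_early / 2), II = floor(n_early / 2),
                n_late["III"], n_late["IV"]),
    features = data.frame(feature_id = names(effects),
                          baseline = baseline,
                          effect_log2fc = unname(effects),
                          sigma = sigma, stringsAsFactors = FALSE),
    seed = seed)
}

# Simple metadata for two plain groups (benign vs stage-I cases).
two_group_meta <- function(n_case, n_control, prefix = "S") {
  sample_meta(data.frame(
    sample_id = paste0(prefix, seq_len(n_case + n_control)),
    group = rep(c("nsclc", "benign"), c(n_case, n_control)),
    stage = rep(c("I", ""), c(n_case, n_control)),
    age = 70, sex = "male", smoking = "no", comorbidity = "no",
    stringsAsFactors = FALSE))
}
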
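#' Sample metadata
#'
#' Per-sample clinical records for a cohort of patients with benign pulmonary
#' nodules (controls) or stage I-IV non-small cell lung cancer. The stage /
#' group consistency rule is enforced: benign samples carry no stage, NSCLC
#' samples carry exactly one of stages I-IV.
#'
#' @param df data.frame with columns `sample_id`, `group` (`benign`/`nsclc`),
#'   `stage` (`I`..`IV`, or empty/`none` for benign), `age`, `sex`
#'   (`male`/`female`), `smoking` (`yes`/`no`), `comorbidity` (`yes`/`no`),
#'   and optionally `histology` (`adeno`/`sqcc`/`nos`, NSCLC only).
#' @return A validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(df) {
  req <- c("sample_id", "group", "stage", "age", "sex", "smoking", "comorbidity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$group <- tolower(as.character(df$group))
  bad <- setdiff(unique(df$group), c("benign", "nsclc"))
  if (length(bad))
    stop("unknown group token: ", paste(bad, collapse = ", "))
  st <- as.character(df$stage)
  st[is.na(st) | st == ""] <- "none"
  bad <- setdiff(unique(st), c("I", "II", "III", "IV", "none"))
  if (length(bad))
    stop("unknown stage token: ", paste(bad, collapse = ", "))
  viol <- (df$group == "benign" & st != "none") |
          (df$group == "nsclc" & st == "none")
  if (any(viol))
    stop("group/stage inconsistency for sample(s): ",
         paste(df$sample_id[viol], collapse = ", "),
         " (benign must have no stage; nsclc must have stage I-IV)")
  df$stage <- factor(st, levels = c("I", "II", "III", "IV", "none"))
  df$age <- as.numeric(df$age)
  for (col in c("sex", "smoking", "comorbidity"))
    df[[col]] <- tolower(as.character(df[[col]]))
  bad <- setdiff(unique(df$sex), c("male", "female", NA))
  if (length(bad)) stop("unknown sex token: ", paste(bad, collapse = ", "))
  for (col in c("smoking", "comorbidity")) {
    bad <- setdiff(unique(df[[col]]), c("yes", "no", NA))
    if (length(bad)) stop("unknown ", col, " token: ", paste(bad, collapse = ", "))
  }
  if (!is.null(df$histology)) {
    h <- tolower(as.character(df$histology))
    h[h == ""] <- NA
    bad <- setdiff(unique(h), c("adeno", "sqcc", "nos", NA))
    if (length(bad)) stop("unknown histology token: ", paste(bad, collapse = ", "))
    df$histology <- h
  }
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns `sample_id,group,stage,age,sex,smoking,comorbidity`
#'   (plus optional `histology`). An empty `stage` field means "no stage"
#'   (benign samples).
#' @return A `sample_meta` data.frame; see [sample_meta()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  sample_meta(df)
}

#' Write sample metadata to CSV
#'
#' @param meta a `sample_meta` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_meta"))
  out <- as.data.frame(meta)
  out$stage <- ifelse(out$stage == "none", "", as.character(out$stage))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split sample ids by contrast
#'
#' Resolves a case-vs-control contrast against the metadata: cases are the
#' NSCLC samples in the given stage set, controls are the benign samples.
#'
#' @param meta a `sample_meta` data.frame.
#' @param stages character vector of NSCLC stages forming the case group
#'   (default early-stage, `c("I", "II")`).
#' @return list with `case` and `control` sample-id vectors.
#' @export
contrast_samples <- function(meta, stages = c("I", "II")) {
  stopifnot(inherits(meta, "sample_meta"))
  stages <- match.arg(as.character(stages), c("I", "II", "III", "IV"),
                      several.ok = TRUE)
  list(case = meta$sample_id[meta$group == "nsclc" & meta$stage %in% stages],
       control = meta$sample_id[meta$group == "benign"])
}
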
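#' Expression matrix with a declared measurement scale
#'
#' The central container of the pipeline: a numeric feature-by-sample matrix
#' (miRNAs in rows, serum samples in columns) tagged with the scale its
#' values live on. Downstream operations dispatch on the scale tag so that,
#' for example, a prevalence filter refuses delta-Ct input and the UDR score
#' refuses anything that is not strictly positive linear expression.
#'
#' Scales:
#' \describe{
#'   \item{counts}{raw NGS read counts; non-negative integers.}
#'   \item{ct}{qPCR cycle-threshold values, including the spike-in row.}
#'   \item{delta_ct}{spike-in normalized abundance,
#'     \eqn{\Delta Ct = Ct_{spike} - Ct_{miRNA}}; one cycle is one doubling,
#'     so delta-Ct is a log2-scale abundance.}
#'   \item{linear}{strictly positive linear relative expression
#'     (CPM + pseudocount, or \eqn{2^{\Delta Ct}}).}
#' }
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   `NA` marks a missing measurement (e.g. undetermined qPCR wells).
#' @param feature_ids character vector of unique miRNA identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param scale one of `"counts"`, `"ct"`, `"delta_ct"`, `"linear"`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `scale` attribute.
#' @examples
#' m <- expr_matrix(matrix(0:5, nrow = 3,
#'                         dimnames = list(paste0("miR-", 1:3), c("S1", "S2"))),
#'                  scale = "counts")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale = c("counts", "ct", "delta_ct", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(feature_ids) && nrow(values) == 0) feature_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0) sample_ids <- character(0)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  v <- values[!is.na(values)]
  if (scale == "counts" && length(v) &&
      (any(v < 0) || any(v != floor(v))))
    stop("scale \"counts\" requires non-negative integer values")
  if (scale == "linear" && length(v) && any(v <= 0))
    stop("scale \"linear\" requires strictly positive values")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "scale")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  n <- min(nrow(x), 6L)
  m <- min(ncol(x), 6L)
  if (n && m) print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

with_scale <- function(values, scale) {
  expr_matrix(values, scale = scale)
}

#' Read an expression table
#'
#' Reads a tab-separated feature-by-sample table: first column feature IDs,
#' header row sample IDs, empty cells denoting missing measurements
#' (e.g. undetermined qPCR wells).
#'
#' @param path path to a TSV file.
#' @param scale declared measurement scale (see [expr_matrix()]).
#' @return An [expr_matrix()].
#' @seealso [write_expression()] for the inverse.
#' @export
read_expression <- function(path, scale = c("counts", "ct", "delta_ct", "linear")) {
  scale <- match.arg(scale)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] == "")
    stop("malformed header in ", path, ": first column must name the feature id")
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = "",
                          quote = "", comment.char = "")
  if (ncol(df) != length(header))
    stop("malformed header in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    k <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell for feature ", ids[k[1]], ", sample ",
         colnames(df)[-1][k[2]], ": \"", vals[k[1], k[2]], "\"")
  }
  storage.mode(num) <- "double"
  rownames(num) <- ids
  colnames(num) <- colnames(df)[-1]
  expr_matrix(num, scale = scale)
}

#' Write an expression table
#'
#' Inverse of [read_expression()]: round-trips values, ordering and
#' missingness exactly (missing cells are written as empty fields).
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE, digits = 15,
                                                 scientific = FALSE))
  lines <- c(paste(c("feature_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], fmt(unclass(x)[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
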
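#' Convert methylation beta values to M-values
#'
#' The M-value is the log2 ratio of methylated to unmethylated intensity,
#' \code{log2(beta / (1 - beta))}. Betas are clipped to
#' \code{[epsilon, 1 - epsilon]} before the transform so boundary values map to
#' finite M-values. Regression on the M scale is preferred because its variance
#' is approximately constant across the methylation range, whereas beta-value
#' variance is compressed near 0 and 1.
#'
#' @param beta Numeric vector or matrix of methylation fractions in [0, 1].
#'   Missing values are propagated.
#' @param epsilon Clip bound in (0, 0.5); betas are clamped to
#'   \code{[epsilon, 1 - epsilon]}. Default \code{1e-6}.
#' @return M-values with the same shape (and dimnames) as \code{beta}.
#' @seealso [m_to_beta()] for the inverse.
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0, epsilon < 0.5)
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad))
    stop("beta values outside [0, 1] at position(s): ",
         paste(label_positions(beta, bad), collapse = ", "))
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (!is.null(dim(beta))) {
    dim(out) <- dim(beta)
    dimnames(out) <- dimnames(beta)
  }
  out
}

#' Convert M-values back to methylation beta values
#'
#' Inverse of [beta_to_m()]: \code{2^m / (1 + 2^m)}. Round-trips betas in
#' \code{[epsilon, 1 - epsilon]} to within 1e-12.
#'
#' @param m Numeric vector or matrix of finite M-values (NA allowed).
#' @return Methylation fractions in (0, 1), same shape as \code{m}.
#' @export
m_to_beta <- function(m) {
  if (any(!is.na(m) & !is.finite(m)))
    stop("non-finite M-values supplied")
  stats::plogis(m * log(2))
}

# human-readable "probe/sample" labels for offending matrix entries
label_positions <- function(x, idx) {
  if (is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x))) {
    rc <- arrayInd(idx, dim(x))
    paste0(rownames(x)[rc[, 1]], "/", colnames(x)[rc[, 2]])
  } else if (!is.null(names(x))) {
    names(x)[idx]
  } else {
    as.character(idx)
  }
}

#' Validate a beta-value matrix
#'
#' Checks that a probes-by-samples matrix has unique probe and sample
#' identifiers and that all non-missing values lie in [0, 1].
#'
#' @param mat Numeric matrix, probes in rows (rownames = probe ids), samples in
#'   columns (colnames = sample ids).
#' @return The matrix, invisibly, on success; otherwise an error naming the
#'   offending probe/sample.
#' @export
validate_beta_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("probe ids (rownames) must be present and unique")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("sample ids (colnames) must be present and unique")
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1))
  if (length(bad))
    stop("beta values outside [0, 1] at: ",
         paste(utils::head(label_positions(mat, bad), 5L), collapse = ", "))
  invisible(mat)
}

#' Read a beta-value matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of probe ids.
#'
#' @param path Path to a TSV file.
#' @return Validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  validate_beta_matrix(mat)
  mat
}

#' Write a beta-value matrix as tab-separated text
#'
#' @param mat Probes x samples numeric matrix with dimnames.
#' @param path Output file path.
#' @param metadata Optional named character vector written as leading
#'   \code{# key=value} comment lines.
#' @return \code{path}, invisibly.
#' @export
write_beta_matrix <- function(mat, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_metadata_header(con, metadata)
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_metadata_header <- function(con, metadata) {
  if (length(metadata))
    writeLines(paste0("# ", names(metadata), "=", unname(metadata)), con)
}

#' Read and validate a sample sheet
#'
#' Comma-separated text with one row per sample. Required columns:
#' \code{sample_id}, \code{smoking_status} (\code{"never"} or
#' \code{"current"}), \code{cigarettes_per_day}, \code{years_smoked},
#' \code{pack_years}, \code{age}, \code{sex}, \code{race}; optional
#' \code{cotinine} and \code{cell_type}.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(df)
  df
}

#' Validate sample-sheet invariants
#'
#' Never-smokers must have zero cigarettes/day, years smoked and pack-years;
#' pack-years must equal (cigarettes/day / 20) x years smoked within rounding;
#' ages must be positive.
#'
#' @param sheet Sample-sheet data.frame.
#' @param tol Tolerance for the pack-years consistency check.
#' @return The sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet, tol = 0.05) {
  req <- c("sample_id", "smoking_status", "cigarettes_per_day",
           "years_smoked", "pack_years", "age", "sex", "race")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  if (!all(sheet$smoking_status %in% c("never", "current")))
    stop("smoking_status must be 'never' or 'current'")
  nev <- sheet$smoking_status == "never"
  if (any(sheet$cigarettes_per_day[nev] != 0 | sheet$years_smoked[nev] != 0 |
          sheet$pack_years[nev] != 0))
    stop("never-smokers must have zero cigarettes_per_day, years_smoked, pack_years")
  expect_py <- sheet$cigarettes_per_day / 20 * sheet$years_smoked
  if (any(abs(sheet$pack_years - expect_py) > tol))
    stop("pack_years inconsistent with cigarettes_per_day and years_smoked for: ",
         paste(utils::head(sheet$sample_id[abs(sheet$pack_years - expect_py) > tol], 5L),
               collapse = ", "))
  if (any(sheet$age <= 0)) stop("age must be positive")
  invisible(sheet)
}

#' Read a probe annotation table
#'
#' Tab-separated columns \code{probe_id}, \code{chromosome}, \code{position}
#' (1-based) and \code{exclude} (logical or 0/1; probes overlapping common
#' SNPs are typically flagged for exclusion).
#'
#' @param path Path to a TSV file.
#' @return data.frame with a logical \code{exclude} column.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("probe_id", "chromosome", "position", "exclude")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  if (any(df$position <= 0)) stop("positions must be positive (1-based)")
  df$exclude <- as.logical(df$exclude)
  df
}

#' Export probe annotation as BED
#'
#' Converts the 1-based probe coordinates to 0-based half-open BED intervals
#' of width 1.
#'
#' @param annotation Annotation data.frame (see [read_probe_annotation()]).
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
annotation_to_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chromosome,
                    annotation$position - 1L,
                    annotation$position,
                    annotation$probe_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter probes flagged for exclusion
#'
#' Drops probes whose annotation \code{exclude} flag is set (e.g. probes with
#' a common SNP at the interrogated CpG). Probes absent from the annotation
#' are retained with a warning rather than dropped, on the assumption of an
#' incomplete manifest. Retained probe order and values are untouched.
#'
#' @param mat Beta matrix (probes x samples).
#' @param annotation Annotation data.frame with \code{probe_id} and
#'   \code{exclude} columns.
#' @return The filtered matrix, with attribute \code{n_removed} giving the
#'   number of probes dropped.
#' @export
filter_probes <- function(mat, annotation) {
  validate_beta_matrix(mat)
  excl <- annotation$probe_id[as.logical(annotation$exclude)]
  unknown <- setdiff(rownames(mat), annotation$probe_id)
  if (length(unknown))
    warning(length(unknown), " probe(s) absent from annotation; retained")
  keep <- !(rownames(mat) %in% excl)
  if (!any(keep))
    warning("all probes flagged for exclusion; returning empty matrix")
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
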
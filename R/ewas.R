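#' Epigenome-wide association of methylation with smoking exposure
#'
#' The central fitting function. For every probe, beta values are transformed
#' to M-values and regressed on the chosen exposure plus covariates by Huber
#' robust regression ([huber_fit()]); p-values come from the t reference
#' distribution with n - p degrees of freedom. When composition estimates are
#' supplied, all but one cell-type column (the largest-mean type, to avoid
#' simplex collinearity) enter the design as covariates — the cell-count
#' adjustment that separates within-cell methylation change from shifts in
#' leukocyte composition. Group delta-beta and a Welch t-test are computed
#' per probe on the beta scale, and results are ranked by ascending p-value.
#'
#' @param betas Beta matrix (probes x samples); column names must match
#'   \code{sheet$sample_id}. Missing betas are dropped per probe.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param exposure One of \code{"status"} (current vs never indicator),
#'   \code{"pack_years"}, \code{"years_smoked"}, \code{"cigarettes_per_day"}.
#' @param covariates Sheet columns to adjust for; categorical columns are
#'   one-hot encoded against their first level.
#' @param compositions Optional \code{composition_estimate} (or data.frame of
#'   \code{sample_id} + weight columns) for cell-count adjustment.
#' @param alpha Family-wise error level for the Bonferroni threshold.
#' @param epsilon Beta clip bound for the M transform.
#' @param huber_k,maxit,tol Robust-fit settings, see [huber_fit()].
#' @return Object of class \code{ewas}: list with \code{results} (data.frame
#'   with \code{probe_id}, \code{exposure_coefficient}, \code{standard_error},
#'   \code{t_statistic}, \code{p_value}, \code{delta_beta}, \code{ttest_p},
#'   \code{n_used}, \code{rank}, sorted by p), \code{threshold} (Bonferroni at
#'   \code{alpha}), \code{n_tests}, \code{exposure}, \code{dropped_celltype},
#'   \code{call}.
#' @seealso [summary.ewas()], [plot.ewas()], [stratified_rank_change()]
#' @export
ewas <- function(betas, sheet, exposure = c("status", "pack_years",
                                            "years_smoked", "cigarettes_per_day"),
                 covariates = c("age", "sex", "race"), compositions = NULL,
                 alpha = 0.05, epsilon = 1e-6,
                 huber_k = 1.345, maxit = 50L, tol = 1e-8) {
  exposure <- match.arg(exposure)
  validate_beta_matrix(betas)
  miss <- setdiff(colnames(betas), sheet$sample_id)
  if (length(miss)) stop("samples absent from sheet: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  sheet <- sheet[match(colnames(betas), sheet$sample_id), ]
  des <- build_design(sheet, exposure, covariates, compositions)
  X <- des$X
  M <- beta_to_m(betas, epsilon)
  n_probes <- nrow(M)
  res <- matrix(NA_real_, n_probes, 5,
                dimnames = list(rownames(M),
                                c("coef", "se", "t", "p", "n")))
  for (i in seq_len(n_probes)) {
    y <- M[i, ]
    ok <- !is.na(y)
    fit <- huber_fit(X[ok, , drop = FALSE], y[ok], k = huber_k,
                     maxit = maxit, tol = tol)
    res[i, ] <- c(fit$coefficients["exposure"], fit$se["exposure"],
                  fit$t["exposure"], fit$p_value["exposure"], sum(ok))
  }
  cur <- sheet$smoking_status == "current"
  gd <- if (sum(cur) >= 2 && sum(!cur) >= 2) {
    group_delta_beta(betas, sheet)
  } else {  # single-group data (e.g. smokers-only duration runs)
    data.frame(delta_beta = NA_real_, p_value = NA_real_)
  }
  out <- data.frame(probe_id = rownames(M),
                    exposure_coefficient = res[, "coef"],
                    standard_error = res[, "se"],
                    t_statistic = res[, "t"],
                    p_value = res[, "p"],
                    delta_beta = gd$delta_beta,
                    ttest_p = gd$p_value,
                    n_used = res[, "n"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$probe_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(list(results = out,
                 n_tests = n_probes,
                 alpha = alpha,
                 threshold = bonferroni_threshold(n_probes, alpha),
                 exposure = exposure,
                 covariates = covariates,
                 dropped_celltype = des$dropped_celltype,
                 call = match.call()),
            class = "ewas")
}

# design matrix: intercept + exposure + one-hot covariates (+ composition
# columns minus the largest-mean cell type)
build_design <- function(sheet, exposure, covariates, compositions) {
  expo <- switch(exposure,
                 status = as.numeric(sheet$smoking_status == "current"),
                 sheet[[exposure]])
  df <- data.frame(exposure = expo)
  for (cv in covariates) {
    if (!cv %in% names(sheet)) stop("covariate not in sheet: ", cv)
    df[[cv]] <- if (is.character(sheet[[cv]])) factor(sheet[[cv]]) else sheet[[cv]]
  }
  dropped <- NULL
  if (!is.null(compositions)) {
    comp <- as.data.frame(compositions)
    wcols <- setdiff(names(comp), c("sample_id", "residual_norm"))
    comp <- comp[match(sheet$sample_id, comp$sample_id), wcols, drop = FALSE]
    if (anyNA(comp)) stop("compositions missing for some samples")
    dropped <- wcols[which.max(colMeans(comp))]
    for (wc in setdiff(wcols, dropped)) df[[wc]] <- comp[[wc]]
  }
  X <- stats::model.matrix(~ ., df)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]], collapse = ", "))
  list(X = X, dropped_celltype = dropped)
}

#' Group delta-beta and Welch t-test per probe
#'
#' For each probe: mean beta among current smokers minus mean beta among
#' never-smokers, with the unequal-variance (Welch) two-sided t-test of the
#' group difference.
#'
#' @param betas Beta matrix (probes x samples).
#' @param sheet Sample sheet; both smoking-status groups need >= 2 samples.
#' @return data.frame: \code{probe_id}, \code{delta_beta}, \code{t_statistic},
#'   \code{p_value}.
#' @export
group_delta_beta <- function(betas, sheet) {
  sheet <- sheet[match(colnames(betas), sheet$sample_id), ]
  cur <- sheet$smoking_status == "current"
  if (sum(cur) < 2 || sum(!cur) < 2)
    stop("both smoking-status groups need at least 2 samples")
  tt <- apply(betas, 1, function(y) {
    ht <- tryCatch(stats::t.test(y[cur], y[!cur]), error = function(e) NULL)
    if (is.null(ht)) {  # both groups (near-)constant
      d <- mean(y[cur], na.rm = TRUE) - mean(y[!cur], na.rm = TRUE)
      c(d, if (d == 0) 0 else sign(d) * Inf, if (d == 0) 1 else 0)
    } else {
      c(ht$estimate[1] - ht$estimate[2], ht$statistic, ht$p.value)
    }
  })
  data.frame(probe_id = rownames(betas),
             delta_beta = tt[1, ], t_statistic = tt[2, ], p_value = tt[3, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests Number of tests actually performed (probes retained after
#'   filtering).
#' @param alpha Family-wise error level.
#' @return \code{alpha / n_tests}.
#' @examples
#' bonferroni_threshold(485577, 0.05)  # ~1.03e-7, the 450K genome-wide line
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

#' Per-group descriptive summary with smoker-minus-nonsmoker differences
#'
#' Group means and SDs for numeric variables (e.g. blood-count percentages or
#' estimated cell fractions) plus the difference current minus never, the
#' usual cohort-characteristics table.
#'
#' @param data data.frame with a \code{smoking_status} column (or merged via
#'   \code{sheet}) and the variables of interest.
#' @param variables Character vector of numeric columns to summarize;
#'   defaults to all numeric columns.
#' @param digits Rounding applied to means, SDs and differences.
#' @return data.frame: \code{variable}, \code{mean_never}, \code{sd_never},
#'   \code{mean_current}, \code{sd_current}, \code{difference}.
#' @export
group_summary <- function(data, variables = NULL, digits = 1) {
  if (!"smoking_status" %in% names(data))
    stop("data must contain smoking_status")
  cur <- data$smoking_status == "current"
  if (!any(cur) || !any(!cur)) stop("both groups must be non-empty")
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    data.frame(variable = v,
               mean_never = round(mean(x[!cur], na.rm = TRUE), digits),
               sd_never = round(stats::sd(x[!cur], na.rm = TRUE), digits),
               mean_current = round(mean(x[cur], na.rm = TRUE), digits),
               sd_current = round(stats::sd(x[cur], na.rm = TRUE), digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$difference <- round(out$mean_current - out$mean_never, digits)
  out
}

#' @export
print.ewas <- function(x, ...) {
  cat("Smoking EWAS (robust regression on M-values)\n")
  cat("  exposure:", x$exposure, " covariates:",
      paste(x$covariates, collapse = ", "), "\n")
  if (!is.null(x$dropped_celltype))
    cat("  composition-adjusted (dropped", x$dropped_celltype,
        "to avoid collinearity)\n")
  nsig <- sum(x$results$p_value < x$threshold)
  cat("  probes tested:", x$n_tests,
      " Bonferroni threshold:", format(x$threshold, digits = 4),
      " significant:", nsig, "\n")
  invisible(x)
}

#' Summarize an EWAS fit
#'
#' @param object An \code{ewas} object.
#' @param n_top Number of top-ranked probes to display.
#' @param ... Unused.
#' @return The object, invisibly; prints the significant-count summary and
#'   top probes.
#' @export
summary.ewas <- function(object, n_top = 10, ...) {
  print(object)
  cat("\nTop probes by p-value:\n")
  df <- utils::head(object$results, n_top)
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  invisible(object)
}

#' Exposure coefficients of an EWAS fit
#' @param object An \code{ewas} object.
#' @param ... Unused.
#' @return Named vector of per-probe exposure coefficients (M-value units per
#'   exposure unit), in ranked order.
#' @export
coef.ewas <- function(object, ...) {
  stats::setNames(object$results$exposure_coefficient,
                  object$results$probe_id)
}

#' Volcano plot of an EWAS fit
#'
#' Delta-beta against -log10 p, with the Bonferroni line.
#'
#' @param x An \code{ewas} object.
#' @param ... Passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.ewas <- function(x, ...) {
  r <- x$results
  sig <- r$p_value < x$threshold
  graphics::plot(r$delta_beta, -log10(r$p_value),
                 xlab = "delta beta (current - never)",
                 ylab = expression(-log[10] ~ p),
                 pch = 20, col = ifelse(sig, "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(x$threshold), lty = 2)
  invisible(x)
}

#' Write EWAS results as tab-separated text
#'
#' Writes the full ranked table, and optionally the Bonferroni-significant
#' subset alongside with the threshold recorded in the metadata header.
#'
#' @param fit An \code{ewas} object.
#' @param path Output TSV path.
#' @param significant_path Optional path for the significant subset.
#' @param metadata Optional extra \code{# key=value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_ewas <- function(fit, path, significant_path = NULL, metadata = NULL) {
  meta <- c(exposure = fit$exposure, n_tests = fit$n_tests,
            alpha = fit$alpha, bonferroni_threshold = fit$threshold, metadata)
  con <- file(path, "w"); on.exit(close(con))
  write_metadata_header(con, meta)
  utils::write.table(fit$results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(significant_path)) {
    con2 <- file(significant_path, "w")
    write_metadata_header(con2, meta)
    utils::write.table(fit$results[fit$results$p_value < fit$threshold, ],
                       con2, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con2)
  }
  invisible(path)
}
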
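#' Per-cell-type smoking effect profiles for candidate CpGs
#'
#' For each candidate probe and each supplied matrix (purified cell types,
#' and mixtures such as whole blood or PBMC treated as additional columns),
#' computes the smoker-minus-nonsmoker delta-beta and the Welch t-test
#' p-value via [group_delta_beta()].
#'
#' @param matrices Named list of beta matrices sharing the candidate probes
#'   (names become the profile columns).
#' @param sheet Sample sheet covering every matrix's samples.
#' @param probes Candidate probe ids; must be present in all matrices.
#' @return Object of class \code{celltype_profile}: list with \code{delta}
#'   and \code{p} (probes x matrices numeric matrices) and \code{cell_types}.
#' @export
celltype_association <- function(matrices, sheet, probes) {
  for (nm in names(matrices)) {
    miss <- setdiff(probes, rownames(matrices[[nm]]))
    if (length(miss))
      stop("probe(s) absent from matrix '", nm, "': ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  delta <- p <- matrix(NA_real_, length(probes), length(matrices),
                       dimnames = list(probes, names(matrices)))
  for (nm in names(matrices)) {
    gd <- group_delta_beta(matrices[[nm]][probes, , drop = FALSE], sheet)
    delta[, nm] <- gd$delta_beta
    p[, nm] <- gd$p_value
  }
  structure(list(delta = delta, p = p, cell_types = names(matrices)),
            class = "celltype_profile")
}

#' @export
print.celltype_profile <- function(x, digits = 3, ...) {
  cat("Cell-type effect profiles:", nrow(x$delta), "probes x",
      ncol(x$delta), "matrices (", paste(x$cell_types, collapse = ", "), ")\n")
  cat("delta beta:\n")
  print(round(utils::head(x$delta, 8), digits))
  invisible(x)
}

#' @describeIn celltype_association Flatten a profile to a data.frame
#'   (\code{probe_id}, then \code{delta_*} and \code{p_*} columns).
#' @param x A \code{celltype_profile}.
#' @param ... Unused.
#' @export
as.data.frame.celltype_profile <- function(x, ...) {
  d <- as.data.frame(x$delta)
  names(d) <- paste0("delta_", names(d))
  pp <- as.data.frame(x$p)
  names(pp) <- paste0("p_", names(pp))
  cbind(data.frame(probe_id = rownames(x$delta), stringsAsFactors = FALSE),
        d, pp)
}

#' Hierarchically cluster cell-type effect profiles
#'
#' Agglomerative clustering of probes by similarity of their per-cell-type
#' effect sizes (\code{mode = "delta"}) or significance patterns
#' (\code{mode = "neglog10p"}). Rows are pre-sorted by probe id so the result
#' is invariant to input order; ties in merge heights are resolved by
#' \code{\link[stats]{hclust}}'s deterministic rules on that canonical order.
#'
#' @param profile A \code{celltype_profile}.
#' @param mode Cluster on signed delta-beta or on -log10 p.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   \code{"average"}).
#' @param metric Distance metric for [stats::dist()] (default
#'   \code{"euclidean"}).
#' @param k Number of flat clusters to cut.
#' @param absolute Cluster on absolute values instead of signed.
#' @param columns Which profile columns to use (default: all).
#' @return List: \code{hclust} (the tree), \code{labels} (named cluster
#'   vector from [stats::cutree()]), \code{newick} (tree in Newick text).
#' @export
cluster_profiles <- function(profile, mode = c("delta", "neglog10p"),
                             linkage = "average", metric = "euclidean",
                             k = 2, absolute = FALSE, columns = NULL) {
  mode <- match.arg(mode)
  mat <- if (mode == "delta") profile$delta else -log10(profile$p)
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  if (nrow(mat) < 2) stop("need at least 2 profiles to cluster")
  if (anyNA(mat)) stop("profiles contain missing entries")
  if (absolute) mat <- abs(mat)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  labels <- stats::cutree(hc, k = k)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, labels = labels,
       newick = ape::write.tree(phy))
}

#' Classify a probe's cross-cell-type response pattern
#'
#' Rule-based label from the per-cell-type significance indicator vector
#' (p <= alpha). Rules are evaluated most-specific first:
#' \code{pan_cell} (all types significant), \code{myeloid} (all myeloid
#' significant, no lymphoid), \code{myeloid_plus_B} (myeloid + B, no T — the
#' AHRR-like granulocyte/monocyte/B profile), \code{T_only},
#' \code{monocyte_only}, \code{lymphoid} (significant only within T/B/NK —
#' the GPR15-like profile), \code{none}. Mixture columns (whole blood, PBMC)
#' are ignored; lineage membership comes from \code{lineages}.
#'
#' @param profile A \code{celltype_profile}, or a named numeric vector /
#'   matrix of per-cell-type p-values.
#' @param alpha Per-test significance level (default 0.05, unadjusted, as
#'   appropriate for a small purified-cell study).
#' @param lineages Named list mapping \code{myeloid}, \code{B}, \code{T},
#'   \code{NK} to cell-type labels; defaults recognize CD14/CD15/CD19/CD4T/
#'   CD8T/CD2T/CD56 style labels.
#' @return Character vector of pattern labels (one per probe).
#' @export
classify_response_pattern <- function(profile, alpha = 0.05, lineages = NULL) {
  p <- if (inherits(profile, "celltype_profile")) profile$p else profile
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list("probe", names(p)))
  if (is.null(lineages)) lineages <- default_lineages(colnames(p))
  celltype_cols <- unlist(lineages, use.names = FALSE)
  p <- p[, intersect(colnames(p), celltype_cols), drop = FALSE]
  myeloid <- intersect(lineages$myeloid, colnames(p))
  bcols <- intersect(lineages$B, colnames(p))
  tcols <- intersect(lineages$T, colnames(p))
  nkcols <- intersect(lineages$NK, colnames(p))
  mono <- intersect(c("CD14", "Mono"), colnames(p))
  apply(p <= alpha, 1, function(s) {
    sig <- names(s)[s]
    if (!length(sig)) return("none")
    if (all(s)) return("pan_cell")
    if (length(myeloid) && all(s[myeloid]) && !any(s[c(bcols, tcols, nkcols)]))
      return("myeloid")
    if (length(myeloid) && all(s[myeloid]) && length(bcols) && all(s[bcols]) &&
        !any(s[tcols]))
      return("myeloid_plus_B")
    if (length(tcols) && any(s[tcols]) && all(sig %in% tcols))
      return("T_only")
    if (length(mono) && all(sig %in% mono))
      return("monocyte_only")
    if (all(sig %in% c(tcols, bcols, nkcols)))
      return("lymphoid")
    "none"
  })
}

#' Predict the whole-blood delta-beta from cell-type effects
#'
#' Composition-weighted mixture arithmetic: the expected whole-blood group
#' difference is
#' \deqn{\Delta = \sum_c w_c^{smoker} \beta_c^{smoker} -
#'       \sum_c w_c^{never} \beta_c^{never}.}
#' With equal compositions across groups this reduces to
#' \eqn{\sum_c w_c \Delta_c}; with zero within-cell effects it isolates the
#' purely compositional contribution
#' \eqn{\sum_c (w_c^{smoker} - w_c^{never}) \beta_c}. This is how
#' cell-restricted effects are attenuated (or compositional shifts
#' masquerade as effects) in whole-blood measurements.
#'
#' @param beta_smoker,beta_never Probes x cell-types matrices of group mean
#'   betas per cell type.
#' @param w_smoker,w_never Named group mean composition weights (each on the
#'   probability simplex).
#' @return Named vector of predicted whole-blood delta-beta per probe.
#' @export
predict_wholeblood_delta <- function(beta_smoker, beta_never,
                                     w_smoker, w_never) {
  check_simplex <- function(w, nm) {
    if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6)
      stop(nm, " weights must be non-negative and sum to 1")
  }
  check_simplex(w_smoker, "smoker")
  check_simplex(w_never, "never")
  cts <- colnames(beta_smoker)
  if (!is.null(names(w_smoker))) w_smoker <- w_smoker[cts]
  if (!is.null(names(w_never))) w_never <- w_never[cts]
  drop(beta_smoker %*% w_smoker - beta_never %*% w_never)
}

#' Regress methylation on serum cotinine
#'
#' Ordinary least squares of per-sample beta values at one probe on
#' (optionally log2-transformed) serum cotinine, the biochemical marker of
#' recent smoking dose.
#'
#' @param betas Numeric vector of beta values (one probe across samples).
#' @param cotinine Serum cotinine in ng/mL, same order.
#' @param log_transform Regress on log2(cotinine) (default TRUE).
#' @param floor Detection floor applied before the log (default 0.1 ng/mL).
#' @return List: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (two-sided slope test), \code{n}.
#' @export
cotinine_regression <- function(betas, cotinine, log_transform = TRUE,
                                floor = 0.1) {
  ok <- !is.na(betas) & !is.na(cotinine)
  if (sum(ok) < 3) stop("need at least 3 complete samples")
  x <- cotinine[ok]
  if (log_transform) x <- log2(pmax(x, floor))
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  y <- betas[ok]
  if (stats::var(y) < 1e-20)  # constant response: flat line, no fit to explain
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p_value = 1,
                n = sum(ok)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = sum(ok))
}

#' Delta-delta-Ct expression fold change
#'
#' Classic qPCR relative quantification: per sample,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} (normalization to the
#' housekeeping gene), \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta
#' Ct}_{calibrator}} against the mean of the calibrator (never-smoker) group
#' within the same cell type and target gene, and fold change
#' \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param records data.frame with columns \code{sample_id}, \code{cell_type},
#'   \code{target_gene}, \code{ct_target}, \code{ct_reference}.
#' @param calibrator_samples Sample ids forming the calibrator group (e.g.
#'   never-smokers); must be non-empty within every cell type / gene stratum.
#' @return \code{records} with added \code{delta_ct}, \code{delta_delta_ct}
#'   and \code{fold_change} columns.
#' @export
ddct_fold_change <- function(records, calibrator_samples) {
  req <- c("sample_id", "cell_type", "target_gene", "ct_target", "ct_reference")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_reference)))
    stop("cycle thresholds must be finite; missing reference gene for sample(s): ",
         paste(utils::head(records$sample_id[!is.finite(records$ct_reference)], 3),
               collapse = ", "))
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop("cycle thresholds must be positive")
  records$delta_ct <- records$ct_target - records$ct_reference
  strata <- interaction(records$cell_type, records$target_gene, drop = TRUE)
  calib <- records$sample_id %in% calibrator_samples
  records$delta_delta_ct <- NA_real_
  for (st in levels(strata)) {
    in_st <- strata == st
    if (!any(in_st & calib))
      stop("no calibrator samples in stratum ", st)
    ref <- mean(records$delta_ct[in_st & calib])
    records$delta_delta_ct[in_st] <- records$delta_ct[in_st] - ref
  }
  records$fold_change <- 2^(-records$delta_delta_ct)
  records
}
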
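#' Select lineage-discriminating probes from a reference panel
#'
#' For each cell type, scores every probe by the gap between that type's
#' baseline beta and the mean baseline of all other types, and keeps the
#' \code{k_per_type} largest gaps in each direction (hypermethylated and
#' hypomethylated in that type). Selection is deterministic; ties are broken
#' by lexicographic probe id.
#'
#' @param panel A \code{ref_panel} (or any list with a \code{baseline}
#'   probes x cell-types matrix).
#' @param k_per_type Probes to keep per cell type in each direction
#'   (default 50 hyper + 50 hypo).
#' @return Character vector of unique probe ids (union over types and
#'   directions), in panel order.
#' @export
select_discriminating_probes <- function(panel, k_per_type = 50) {
  if (k_per_type < 1) stop("k_per_type must be >= 1")
  base <- panel$baseline
  k <- ncol(base)
  if (nrow(base) < k_per_type)
    stop("panel has ", nrow(base), " probes; need at least ", k_per_type,
         " candidates per direction")
  chosen <- character(0)
  ids <- rownames(base)
  for (j in seq_len(k)) {
    gap <- base[, j] - rowMeans(base[, -j, drop = FALSE])
    hyper <- ids[order(-gap, ids)][seq_len(k_per_type)]
    hypo <- ids[order(gap, ids)][seq_len(k_per_type)]
    chosen <- c(chosen, hyper, hypo)
  }
  ids[ids %in% chosen]
}

# Exact minimization of ||b - R w||^2 over the probability simplex
# (w >= 0, sum w = 1), by enumerating support sets: for each candidate
# support solve the equality-constrained least squares via the KKT system,
# keep feasible solutions, return the global minimum. Exact (to linear-solve
# precision) for panels of up to ~12 cell types, which covers leukocyte
# reference panels.
simplex_lsq <- function(R, b, sum_to_one = TRUE) {
  k <- ncol(R)
  if (k > 14) stop("simplex solver supports at most 14 cell types")
  if (!sum_to_one) {
    # relax to sum(w) <= 1 via a zero-signal slack component
    R <- cbind(R, 0)
    colnames(R)[k + 1] <- ".slack"
    k <- k + 1
  }
  best <- NULL
  best_obj <- Inf
  for (code in seq_len(2^k - 1)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    Rs <- R[, S, drop = FALSE]
    m <- length(S)
    KKT <- rbind(cbind(2 * crossprod(Rs), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * crossprod(Rs, b), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_len(m)]
    if (any(w < -1e-10)) next
    w <- pmax(w, 0)
    w <- w / sum(w)
    obj <- sum((b - Rs %*% w)^2)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- numeric(k)
      best[S] <- w
    }
  }
  if (is.null(best)) stop("simplex least-squares failed to find a solution")
  if (!sum_to_one) best <- best[-k]
  list(weights = best, objective = best_obj)
}

#' Estimate leukocyte composition by constrained projection
#'
#' Projects each mixed sample's betas at discriminating probes onto the
#' reference panel: minimizes \eqn{\|\beta - R w\|^2} subject to \eqn{w \ge 0}
#' and \eqn{\sum w = 1}. This is the reference-based composition estimate
#' used to adjust whole-blood association models for cell-count differences.
#' The solver enumerates constraint support sets and is exact; on noiseless
#' mixtures of panel columns it recovers the true weights.
#'
#' @param betas Beta matrix (probes x samples) or a single named beta vector;
#'   probes must cover the selected panel probes. Missing values at selected
#'   probes are imputed as the panel row mean (a message reports the count).
#' @param panel A \code{ref_panel}.
#' @param probes Probe ids to use; default
#'   \code{select_discriminating_probes(panel, k_per_type)}.
#' @param k_per_type Passed to [select_discriminating_probes()] when
#'   \code{probes} is NULL.
#' @param sum_to_one If \code{FALSE}, relax the equality to \eqn{\sum w \le 1}
#'   (for samples possibly containing cells absent from the panel).
#' @return Object of class \code{composition_estimate}: data.frame with
#'   \code{sample_id}, one weight column per cell type and
#'   \code{residual_norm}.
#' @export
estimate_composition <- function(betas, panel, probes = NULL, k_per_type = 50,
                                 sum_to_one = TRUE) {
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1,
                                           dimnames = list(names(betas), "sample1"))
  if (is.null(probes)) {
    if (!isTRUE(panel$usable_for_deconvolution))
      stop("panel has no discriminating probes and is unusable for deconvolution")
    probes <- select_discriminating_probes(panel, k_per_type)
  }
  miss <- setdiff(probes, rownames(betas))
  if (length(miss)) stop("sample matrix lacks ", length(miss),
                         " selected probe(s), e.g. ", miss[1])
  R <- panel$baseline[probes, , drop = FALSE]
  # collinear reference columns make weights unidentifiable
  cc <- stats::cor(R)
  dup <- which(cc > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(dup))
    stop("reference panel columns are collinear: ",
         paste(colnames(R)[dup[1, 1]], colnames(R)[dup[1, 2]], sep = " ~ "))
  B <- betas[probes, , drop = FALSE]
  if (anyNA(B)) {
    n_imp <- sum(is.na(B))
    rmean <- rowMeans(R)
    for (j in seq_len(ncol(B))) {
      na <- is.na(B[, j])
      B[na, j] <- rmean[na]
    }
    message("imputed ", n_imp, " missing beta value(s) with panel row means")
  }
  fits <- lapply(seq_len(ncol(B)), function(j) simplex_lsq(R, B[, j], sum_to_one))
  w <- do.call(rbind, lapply(fits, `[[`, "weights"))
  colnames(w) <- colnames(R)
  out <- data.frame(sample_id = colnames(B), w,
                    residual_norm = sqrt(vapply(fits, `[[`, 0, "objective")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("composition_estimate", "data.frame")
  attr(out, "probes") <- probes
  attr(out, "sum_to_one") <- sum_to_one
  out
}

#' @export
print.composition_estimate <- function(x, digits = 3, ...) {
  cat("Leukocyte composition estimates for", nrow(x), "sample(s) over",
      length(attr(x, "probes")), "reference probes\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Write composition estimates as comma-separated text
#' @param estimates A \code{composition_estimate}.
#' @param path Output CSV path.
#' @param metadata Optional named vector of \code{# key=value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_composition <- function(estimates, path, metadata = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  write_metadata_header(con, metadata)
  utils::write.table(as.data.frame(estimates), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
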
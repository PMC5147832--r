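#' Stratified rank-change analysis of smoking-duration effects
#'
#' Identifies CpGs whose association with years of smoking differs between
#' heavy and light smokers. The candidate set is the \code{top_k} probes by
#' any-smoking p-value from a prior EWAS. Current smokers are split at
#' \code{cpd_cutoff} cigarettes/day (at/above = heavy); within each stratum a
#' duration model (years smoked as exposure, same covariate set) is fitted
#' per probe, probes are ranked by ascending p within stratum (ties broken by
#' probe id), and the rank change (light rank minus heavy rank) is reported,
#' sorted descending — probes near the top are strongly duration-associated
#' in heavy smokers but not in light smokers.
#'
#' @param betas Beta matrix (probes x samples) covering all current smokers.
#' @param sheet Sample sheet.
#' @param anysmoking An \code{ewas} object (or its \code{results} data.frame)
#'   from the any-smoking analysis, used to pick the candidate probes.
#' @param top_k Candidate probes (default 1000).
#' @param cpd_cutoff Heavy/light split in cigarettes/day; \code{NULL} uses
#'   the rounded within-run median among current smokers (default 22).
#' @param covariates Covariate columns for the within-stratum duration model.
#' @param compositions Optional composition estimates retained in the
#'   stratified models (set \code{NULL} to drop).
#' @param ... Robust-fit settings passed to [huber_fit()].
#' @return data.frame: \code{probe_id}, \code{p_light}, \code{p_heavy},
#'   \code{rank_light}, \code{rank_heavy}, \code{rank_change},
#'   \code{abs_rank_change}, sorted by descending \code{rank_change}.
#' @export
stratified_rank_change <- function(betas, sheet, anysmoking, top_k = 1000,
                                   cpd_cutoff = 22,
                                   covariates = c("age", "sex", "race"),
                                   compositions = NULL, ...) {
  res <- if (inherits(anysmoking, "ewas")) anysmoking$results else anysmoking
  if (top_k > nrow(res))
    stop("top_k (", top_k, ") exceeds available probes (", nrow(res), ")")
  top <- res$probe_id[order(res$p_value, res$probe_id)][seq_len(top_k)]
  missing_probes <- setdiff(top, rownames(betas))
  if (length(missing_probes))
    stop("candidate probes missing from matrix: ",
         paste(utils::head(missing_probes, 3), collapse = ", "))
  smokers <- sheet[sheet$smoking_status == "current", ]
  if (is.null(cpd_cutoff))
    cpd_cutoff <- round(stats::median(smokers$cigarettes_per_day))
  heavy_ids <- smokers$sample_id[smokers$cigarettes_per_day >= cpd_cutoff]
  light_ids <- smokers$sample_id[smokers$cigarettes_per_day < cpd_cutoff]
  if (!length(heavy_ids) || !length(light_ids))
    stop("empty stratum at cutoff ", cpd_cutoff, " cigarettes/day (",
         length(light_ids), " light, ", length(heavy_ids), " heavy)")
  p_stratum <- function(ids) {
    sub_sheet <- sheet[sheet$sample_id %in% ids, ]
    sub <- betas[top, sub_sheet$sample_id, drop = FALSE]
    des <- build_design(sub_sheet, "years_smoked", covariates, compositions)
    M <- beta_to_m(sub)
    vapply(seq_len(nrow(M)), function(i) {
      y <- M[i, ]; ok <- !is.na(y)
      huber_fit(des$X[ok, , drop = FALSE], y[ok], ...)$p_value[["exposure"]]
    }, 0)
  }
  p_light <- p_stratum(light_ids)
  p_heavy <- p_stratum(heavy_ids)
  rank_light <- order(order(p_light, top))
  rank_heavy <- order(order(p_heavy, top))
  out <- data.frame(probe_id = top, p_light = p_light, p_heavy = p_heavy,
                    rank_light = rank_light, rank_heavy = rank_heavy,
                    rank_change = rank_light - rank_heavy,
                    stringsAsFactors = FALSE)
  out$abs_rank_change <- abs(out$rank_change)
  out <- out[order(-out$rank_change, out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "cpd_cutoff") <- cpd_cutoff
  attr(out, "n_light") <- length(light_ids)
  attr(out, "n_heavy") <- length(heavy_ids)
  out
}

#' Write stratified rank-change results as tab-separated text
#' @param result Output of [stratified_rank_change()].
#' @param path Output TSV path.
#' @param metadata Optional named vector of \code{# key=value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_rank_change <- function(result, path, metadata = NULL) {
  meta <- c(cpd_cutoff = attr(result, "cpd_cutoff"),
            n_light = attr(result, "n_light"),
            n_heavy = attr(result, "n_heavy"), metadata)
  con <- file(path, "w"); on.exit(close(con))
  write_metadata_header(con, meta)
  utils::write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
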
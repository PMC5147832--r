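#' @title Synthetic smoking-cohort generator
#' @description Generates reference methylomes, subject covariates, planted
#'   lineage-specific smoking effects, per-cell-type beta matrices and mixed
#'   whole-blood/PBMC matrices with known ground truth, for validating the
#'   association and deconvolution machinery.
#' @name simulate
NULL

# derive a reproducible per-stage substream seed from a single global seed
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}

default_cell_types <- function() c("CD14", "CD15", "CD19", "CD4T", "CD8T", "CD56")

# lineage membership used by the effect classes and pattern rules
default_lineages <- function(cell_types = default_cell_types()) {
  list(myeloid  = intersect(cell_types, c("CD14", "CD15", "Mono", "Neu", "Gran", "Eos")),
       B        = intersect(cell_types, c("CD19", "Bcell")),
       T        = intersect(cell_types, c("CD4T", "CD8T", "CD2T", "Tcell")),
       NK       = intersect(cell_types, c("CD56", "NK")))
}

#' Simulate subject-level covariates
#'
#' Draws a sample sheet for a cohort of never- and current smokers. For
#' current smokers, cigarettes/day spans light and heavy use around
#' \code{cpd_cutoff}, years smoked is positive, pack-years is exactly
#' (cigarettes/day / 20) x years, and serum cotinine rises stochastically with
#' cigarettes/day; never-smokers have zero exposure and near-zero cotinine.
#' Ages, sex and race are drawn from distributions resembling a mid-life
#' adult blood-draw cohort.
#'
#' @param n_never,n_current Numbers of never- and current smokers.
#' @param heavy_fraction Proportion of current smokers at or above
#'   \code{cpd_cutoff} cigarettes/day.
#' @param cpd_cutoff Heavy-smoking cutoff in cigarettes/day (default 22, the
#'   within-cohort median split used throughout the package).
#' @param seed Integer seed; identical seeds give identical sheets.
#' @return A sample-sheet data.frame passing [validate_sample_sheet()].
#' @export
simulate_subjects <- function(n_never = 81, n_current = 172,
                              heavy_fraction = 0.5, cpd_cutoff = 22,
                              seed = 1) {
  if (n_never < 0 || n_current < 0) stop("subject counts must be non-negative")
  set.seed(substream_seed(seed, 1L))
  n <- n_never + n_current
  status <- rep(c("never", "current"), c(n_never, n_current))
  heavy <- rep(FALSE, n)
  cpd <- numeric(n)
  yrs <- numeric(n)
  cur <- status == "current"
  if (any(cur)) {
    heavy[cur] <- stats::runif(n_current) < heavy_fraction
    cpd[cur & heavy] <- sample(seq(cpd_cutoff, cpd_cutoff + 38), sum(cur & heavy), replace = TRUE)
    cpd[cur & !heavy] <- sample(seq(max(1, cpd_cutoff - 17), cpd_cutoff - 1),
                                sum(cur & !heavy), replace = TRUE)
    yrs[cur] <- round(pmin(pmax(stats::rnorm(n_current, 17, 8.5), 2), 42))
  }
  cot <- numeric(n)
  cot[!cur] <- round(stats::rexp(sum(!cur), rate = 1 / 3.8), 1)
  cot[cur] <- round(cpd[cur] * 8 * exp(stats::rnorm(sum(cur), 0, 0.35)), 1)
  sheet <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    smoking_status = status,
    cigarettes_per_day = cpd,
    years_smoked = yrs,
    pack_years = cpd / 20 * yrs,
    cotinine = cot,
    age = pmin(pmax(round(stats::rnorm(n, 35, 9)), 19), 65),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race = sample(c("Caucasian", "AfricanAmerican"), n, replace = TRUE,
                  prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Simulate a cell-type reference methylation panel
#'
#' Builds per-cell-type mean beta baselines over \code{n_probes} probes. For
#' each cell type, \code{n_discriminating} probes are lineage markers: half
#' hypermethylated in that type (beta near 0.9 there, near 0.1 elsewhere) and
#' half the reverse. Remaining probes share a bimodal baseline (CpGs are
#' mostly near-unmethylated or near-methylated), jittered per cell type on
#' the logit scale by \code{celltype_sd} to mimic broad cross-lineage
#' methylome differences.
#'
#' @param n_probes Total probes (must be at least cell types x
#'   \code{n_discriminating}).
#' @param cell_types Character vector of cell-type labels.
#' @param n_discriminating Marker probes per cell type (0 yields a panel
#'   flagged unusable for deconvolution).
#' @param celltype_sd Logit-scale SD of per-type baseline jitter on
#'   non-marker probes.
#' @param seed Integer seed.
#' @return An object of class \code{ref_panel}: list with \code{baseline}
#'   (probes x cell types beta matrix), \code{cell_types},
#'   \code{discriminating} (list of marker probe ids per type).
#' @export
simulate_reference_panel <- function(n_probes = 2000,
                                     cell_types = default_cell_types(),
                                     n_discriminating = 40,
                                     celltype_sd = 0.5,
                                     seed = 1) {
  k <- length(cell_types)
  if (anyDuplicated(cell_types)) stop("cell_types must be unique")
  if (n_probes < k * n_discriminating)
    stop("need at least ", k * n_discriminating, " probes for ",
         n_discriminating, " markers in each of ", k, " cell types")
  set.seed(substream_seed(seed, 2L))
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  base <- matrix(NA_real_, n_probes, k, dimnames = list(probe_ids, cell_types))
  # shared baseline: bimodal with a mid-methylation shoulder (array betas
  # pile up near 0 and 1 with a minority of intermediate CpGs), then
  # per-type logit jitter
  comp <- sample(1:3, n_probes, replace = TRUE, prob = c(0.375, 0.375, 0.25))
  common <- c(stats::rbeta(n_probes, 5, 45),
              stats::rbeta(n_probes, 45, 5),
              stats::rbeta(n_probes, 8, 8))[seq_len(n_probes) + (comp - 1L) * n_probes]
  eta <- stats::qlogis(common)
  for (j in seq_len(k))
    base[, j] <- stats::plogis(eta + stats::rnorm(n_probes, 0, celltype_sd))
  disc <- stats::setNames(vector("list", k), cell_types)
  if (n_discriminating > 0) {
    idx <- matrix(seq_len(k * n_discriminating), ncol = k)
    for (j in seq_len(k)) {
      pid <- idx[, j]
      hyper <- pid[seq_len(ceiling(n_discriminating / 2))]
      hypo <- setdiff(pid, hyper)
      base[hyper, ] <- matrix(stats::runif(length(hyper) * k, 0.03, 0.09),
                              length(hyper), k)
      base[hyper, j] <- stats::runif(length(hyper), 0.91, 0.97)
      base[hypo, ] <- matrix(stats::runif(length(hypo) * k, 0.91, 0.97),
                             length(hypo), k)
      base[hypo, j] <- stats::runif(length(hypo), 0.03, 0.09)
      disc[[j]] <- probe_ids[pid]
    }
  }
  structure(list(baseline = base, cell_types = cell_types,
                 probe_ids = probe_ids, discriminating = disc,
                 usable_for_deconvolution = n_discriminating > 0),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference methylation panel:", nrow(x$baseline), "probes x",
      length(x$cell_types), "cell types (",
      paste(x$cell_types, collapse = ", "), ")\n")
  nd <- lengths(x$discriminating)
  cat("Discriminating probes per type:",
      if (length(nd)) paste(nd, collapse = "/") else "none", "\n")
  invisible(x)
}

#' Plant smoking effects on probes
#'
#' Assigns effect classes to randomly chosen probes and emits the truth table
#' used by [simulate_celltype_betas()]. Effect classes follow the lineage
#' taxonomy of smoking-responsive CpGs: \code{pan_cell} (all types),
#' \code{myeloid} (monocytes + granulocytes), \code{myeloid_plus_B} (the
#' AHRR-like profile), \code{lymphoid} (T + B, the GPR15-like profile),
#' \code{T_only}, \code{monocyte_only} (MYO1G-like hypermethylation), and
#' \code{duration_heavy} (methylation drifts with years smoked, only among
#' heavy smokers). All effects are on the natural-logit scale of beta.
#'
#' @param panel A \code{ref_panel}; marker probes are never used for effects.
#' @param n_per_class Named integer vector of probe counts per effect class
#'   (classes omitted default to 0; remaining probes are null).
#' @param effect_sizes Named numeric vector of logit-scale effect sizes per
#'   class. Defaults: myeloid and myeloid_plus_B -1.5 (roughly a -24 point
#'   beta drop from a 0.85 baseline), lymphoid and T_only -0.8 (roughly -10
#'   points), pan_cell -1.0, monocyte_only +0.8.
#' @param duration_slope Logit units per year smoked for
#'   \code{duration_heavy} probes (applied only at/above the heavy cutoff).
#' @param seed Integer seed.
#' @return data.frame: \code{probe_id}, \code{effect_class}, one effect
#'   column per cell type, \code{duration_slope}.
#' @export
simulate_effect_truth <- function(panel,
                                  n_per_class = c(myeloid_plus_B = 10, lymphoid = 10),
                                  effect_sizes = c(pan_cell = -1.0, myeloid = -1.5,
                                                   myeloid_plus_B = -1.5, lymphoid = -0.8,
                                                   T_only = -0.8, monocyte_only = 0.8),
                                  duration_slope = -0.05,
                                  seed = 1) {
  classes <- c("pan_cell", "myeloid", "myeloid_plus_B", "lymphoid",
               "T_only", "monocyte_only", "duration_heavy")
  if (!all(names(n_per_class) %in% classes))
    stop("unknown effect class: ",
         paste(setdiff(names(n_per_class), classes), collapse = ", "))
  set.seed(substream_seed(seed, 3L))
  ct <- panel$cell_types
  lin <- default_lineages(ct)
  targets <- list(
    pan_cell = ct,
    myeloid = lin$myeloid,
    myeloid_plus_B = c(lin$myeloid, lin$B),
    lymphoid = c(lin$T, lin$B),
    T_only = lin$T,
    monocyte_only = intersect(ct, c("CD14", "Mono")),
    duration_heavy = ct)
  # effects are planted on mid-methylation probes: CpGs saturated near 0 or 1
  # cannot show the large beta shifts of smoking-responsive loci, whose
  # baselines sit in the intermediate range
  mid <- rowMeans(panel$baseline) >= 0.25 & rowMeans(panel$baseline) <= 0.75
  pool <- setdiff(panel$probe_ids[mid], unlist(panel$discriminating))
  need <- sum(n_per_class)
  if (need > length(pool))
    stop("not enough mid-methylation non-marker probes for planted effects (",
         length(pool), " available, ", need, " needed)")
  chosen <- sample(pool, need)
  truth <- data.frame(probe_id = panel$probe_ids,
                      effect_class = "null",
                      stringsAsFactors = FALSE)
  eff <- matrix(0, length(panel$probe_ids), length(ct),
                dimnames = list(panel$probe_ids, ct))
  slope <- numeric(length(panel$probe_ids))
  at <- 0L
  for (cl in names(n_per_class)) {
    nc <- n_per_class[[cl]]
    if (nc == 0) next
    ids <- chosen[at + seq_len(nc)]; at <- at + nc
    truth$effect_class[match(ids, truth$probe_id)] <- cl
    if (cl == "duration_heavy") {
      slope[match(ids, truth$probe_id)] <- duration_slope
    } else {
      eff[ids, targets[[cl]]] <- effect_sizes[[cl]]
    }
  }
  cbind(truth, as.data.frame(eff), duration_slope = slope)
}

#' Synthesize per-cell-type beta matrices with planted effects
#'
#' For subject i, cell type c, probe p:
#' \deqn{beta = logit^{-1}( logit(baseline_{pc}) + smoker_i * effect_{pc} +
#'   heavy_i * years_i * slope_p + N(0, noise\_sd) )}
#' where \code{heavy_i} indicates cigarettes/day at or above
#' \code{cpd_cutoff}. Noise is on the logit scale, keeping betas strictly in
#' (0, 1) and mimicking the heteroskedastic noise of beta values. With zero
#' noise and a null probe the baseline is reproduced exactly.
#'
#' @param panel A \code{ref_panel}.
#' @param sheet Sample sheet (see [simulate_subjects()]).
#' @param truth Effect truth table from [simulate_effect_truth()]; its effect
#'   columns must match the panel's cell types.
#' @param noise_sd Logit-scale noise SD (default 0.35).
#' @param cpd_cutoff Heavy-smoking cutoff for duration effects.
#' @param seed Integer seed.
#' @return Named list of beta matrices (probes x samples), one per cell type.
#' @export
simulate_celltype_betas <- function(panel, sheet, truth, noise_sd = 0.35,
                                    cpd_cutoff = 22, seed = 1) {
  stopifnot(noise_sd >= 0)
  truth_ct <- setdiff(names(truth),
                      c("probe_id", "effect_class", "duration_slope"))
  if (!setequal(truth_ct, panel$cell_types))
    stop("truth cell types (", paste(truth_ct, collapse = ", "),
         ") do not match panel (", paste(panel$cell_types, collapse = ", "), ")")
  if (!identical(truth$probe_id, panel$probe_ids))
    truth <- truth[match(panel$probe_ids, truth$probe_id), ]
  set.seed(substream_seed(seed, 4L))
  n <- nrow(sheet)
  p <- length(panel$probe_ids)
  smoker <- as.numeric(sheet$smoking_status == "current")
  heavy_years <- ifelse(sheet$cigarettes_per_day >= cpd_cutoff,
                        sheet$years_smoked, 0)
  out <- stats::setNames(vector("list", length(panel$cell_types)),
                         panel$cell_types)
  for (ct in panel$cell_types) {
    shift <- outer(truth[[ct]], smoker) +
      outer(truth$duration_slope, heavy_years)
    if (noise_sd > 0)
      shift <- shift + matrix(stats::rnorm(p * n, 0, noise_sd), p, n)
    base <- panel$baseline[, ct]
    mat <- ifelse(shift == 0, base,
                  stats::plogis(stats::qlogis(base) + shift))
    dimnames(mat) <- list(panel$probe_ids, sheet$sample_id)
    out[[ct]] <- mat
  }
  out
}

# Dirichlet draws via independent gammas
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate per-sample leukocyte compositions
#'
#' Draws cell-type weight vectors from group-specific Dirichlet
#' distributions. Default means put granulocytes at ~51% of whole blood in
#' never-smokers and shift smokers toward more granulocytes and fewer
#' lymphocytes, the direction seen in smokers' blood counts.
#'
#' @param sheet Sample sheet.
#' @param mean_never,mean_current Named mean weight vectors (sum to 1) per
#'   group, over the same cell types.
#' @param concentration Dirichlet concentration (larger = less within-group
#'   spread).
#' @param seed Integer seed.
#' @return data.frame \code{sample_id} + one weight column per cell type;
#'   rows sum to 1.
#' @export
simulate_compositions <- function(sheet,
                                  mean_never = c(CD14 = 0.08, CD15 = 0.51, CD19 = 0.08,
                                                 CD4T = 0.20, CD8T = 0.09, CD56 = 0.04),
                                  mean_current = c(CD14 = 0.08, CD15 = 0.54, CD19 = 0.08,
                                                   CD4T = 0.185, CD8T = 0.08, CD56 = 0.035),
                                  concentration = 150,
                                  seed = 1) {
  stopifnot(abs(sum(mean_never) - 1) < 1e-9, abs(sum(mean_current) - 1) < 1e-9,
            identical(names(mean_never), names(mean_current)))
  set.seed(substream_seed(seed, 5L))
  n <- nrow(sheet)
  w <- matrix(NA_real_, n, length(mean_never),
              dimnames = list(sheet$sample_id, names(mean_never)))
  cur <- sheet$smoking_status == "current"
  if (any(!cur)) w[!cur, ] <- rdirichlet(sum(!cur), mean_never * concentration)
  if (any(cur)) w[cur, ] <- rdirichlet(sum(cur), mean_current * concentration)
  data.frame(sample_id = sheet$sample_id, w, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mix cell-type matrices into a whole-blood (or PBMC) matrix
#'
#' Per probe and sample, the mixed beta is the exact convex combination of
#' the cell-type betas with that sample's composition weights. For PBMC
#' synthesis the granulocyte weight is multiplied by a retention factor
#' (granulocytes are largely lost during PBMC preparation) and the weights
#' renormalized before mixing.
#'
#' @param matrices Named list of beta matrices sharing a probe set, one per
#'   cell type.
#' @param compositions data.frame from [simulate_compositions()] (or any
#'   \code{sample_id} + weight columns table; rows on the simplex).
#' @param pbmc Logical; synthesize a PBMC-like mixture.
#' @param granulocyte Cell-type label treated as granulocytes for PBMC
#'   depletion.
#' @param retention Granulocyte retention factor in [0, 1] for PBMC.
#' @return Beta matrix (probes x samples).
#' @export
mix_to_whole_blood <- function(matrices, compositions, pbmc = FALSE,
                               granulocyte = "CD15", retention = 0.05) {
  cts <- names(matrices)
  probe_sets <- lapply(matrices, rownames)
  for (i in seq_along(matrices))
    if (!identical(probe_sets[[i]], probe_sets[[1]]))
      stop("probe sets differ between cell-type matrices: ",
           cts[1], " vs ", cts[i], " (e.g. ",
           paste(utils::head(c(setdiff(probe_sets[[1]], probe_sets[[i]]),
                               setdiff(probe_sets[[i]], probe_sets[[1]])), 3L),
                 collapse = ", "), ")")
  miss <- setdiff(cts, names(compositions))
  if (length(miss)) stop("compositions lack weight column(s): ",
                         paste(miss, collapse = ", "))
  w <- as.matrix(compositions[, cts, drop = FALSE])
  rownames(w) <- compositions$sample_id
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-9))
    stop("composition weights must be non-negative and sum to 1")
  if (pbmc) {
    if (granulocyte %in% cts) w[, granulocyte] <- w[, granulocyte] * retention
    w <- w / rowSums(w)
  }
  samples <- colnames(matrices[[1]])
  w <- w[samples, , drop = FALSE]
  out <- matrix(0, nrow(matrices[[1]]), length(samples),
                dimnames = list(rownames(matrices[[1]]), samples))
  for (ct in cts)
    out <- out + matrices[[ct]] * rep(w[, ct], each = nrow(out))
  out
}

#' Simulate a complete cohort with known truth
#'
#' Convenience wrapper chaining [simulate_subjects()],
#' [simulate_reference_panel()], [simulate_effect_truth()],
#' [simulate_celltype_betas()], [simulate_compositions()] and
#' [mix_to_whole_blood()]. A single seed fans out to per-stage substreams so
#' each stage is independently reproducible.
#'
#' @param n_never,n_current Cohort sizes (defaults 81 / 172).
#' @param n_probes Probes on the simulated array.
#' @param n_per_class Planted effect counts per class (see
#'   [simulate_effect_truth()]).
#' @param noise_sd Logit-scale noise SD for cell-type betas.
#' @param cpd_cutoff Heavy-smoking cutoff (cigarettes/day).
#' @param heavy_fraction Proportion of heavy smokers.
#' @param n_discriminating Marker probes per cell type in the panel.
#' @param celltype_sd Cross-type baseline jitter SD (logit).
#' @param duration_slope Logit/year slope for duration_heavy probes.
#' @param effect_sizes Per-class logit effect sizes.
#' @param compositions_args Extra arguments for [simulate_compositions()].
#' @param pbmc Also synthesize a PBMC mixture.
#' @param seed Integer seed.
#' @return List: \code{sheet}, \code{panel}, \code{truth},
#'   \code{celltype_betas}, \code{compositions}, \code{whole_blood}, and
#'   \code{pbmc} (if requested).
#' @export
simulate_cohort <- function(n_never = 81, n_current = 172, n_probes = 2000,
                            n_per_class = c(myeloid_plus_B = 10, lymphoid = 10),
                            noise_sd = 0.35, cpd_cutoff = 22,
                            heavy_fraction = 0.5, n_discriminating = 40,
                            celltype_sd = 0.5, duration_slope = -0.05,
                            effect_sizes = c(pan_cell = -1.0, myeloid = -1.5,
                                             myeloid_plus_B = -1.5, lymphoid = -0.8,
                                             T_only = -0.8, monocyte_only = 0.8),
                            compositions_args = list(), pbmc = FALSE,
                            seed = 1) {
  sheet <- simulate_subjects(n_never, n_current, heavy_fraction, cpd_cutoff, seed)
  panel <- simulate_reference_panel(n_probes, n_discriminating = n_discriminating,
                                    celltype_sd = celltype_sd, seed = seed)
  truth <- simulate_effect_truth(panel, n_per_class, effect_sizes,
                                 duration_slope, seed)
  mats <- simulate_celltype_betas(panel, sheet, truth, noise_sd, cpd_cutoff, seed)
  comp <- do.call(simulate_compositions,
                  c(list(sheet = sheet, seed = seed), compositions_args))
  wb <- mix_to_whole_blood(mats, comp)
  out <- list(sheet = sheet, panel = panel, truth = truth,
              celltype_betas = mats, compositions = comp, whole_blood = wb)
  if (pbmc) out$pbmc <- mix_to_whole_blood(mats, comp, pbmc = TRUE)
  out
}

#' Write an effect-truth table as tab-separated text
#' @param truth Truth table from [simulate_effect_truth()].
#' @param path Output path.
#' @param metadata Optional named vector of \code{# key=value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_effect_truth <- function(truth, path, metadata = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  write_metadata_header(con, metadata)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
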
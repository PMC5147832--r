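profile_from_matrices <- function(noise_sd, seed, n_per_class, n_probes = 120) {
  sim <- simulate_cohort(n_never = 14, n_current = 20, n_probes = n_probes,
                         n_per_class = n_per_class, noise_sd = noise_sd,
                         n_discriminating = 4, seed = seed)
  probes <- sim$truth$probe_id[sim$truth$effect_class != "null"]
  mats <- c(sim$celltype_betas, list(whole_blood = sim$whole_blood))
  list(sim = sim,
       profile = celltype_association(mats, sim$sheet, probes))
}

test_that("cell-type association reflects the planted lineage structure", {
  pf <- profile_from_matrices(noise_sd = 0, seed = 61,
                              n_per_class = c(lymphoid = 3, myeloid = 3))
  prof <- pf$profile
  truth <- pf$sim$truth
  ly <- truth$probe_id[truth$effect_class == "lymphoid"]
  my <- truth$probe_id[truth$effect_class == "myeloid"]
  expect_true(all(abs(prof$delta[ly, c("CD4T", "CD8T", "CD19")]) > 0.02))
  expect_true(all(prof$delta[ly, c("CD14", "CD15")] == 0))
  expect_true(all(abs(prof$delta[my, c("CD14", "CD15")]) > 0.04))
  expect_true(all(prof$delta[my, c("CD4T", "CD8T", "CD19", "CD56")] == 0))
  # myeloid effect attenuated in whole blood by the lymphoid weight fraction
  expect_true(all(abs(prof$delta[my, "whole_blood"]) <
                    apply(abs(prof$delta[my, c("CD14", "CD15")]), 1, max)))
  expect_error(celltype_association(pf$sim$celltype_betas, pf$sim$sheet,
                                    c(ly, "cgMISSING")), "cgMISSING")
})

test_that("null profiles show no systematically small p-values", {
  sim <- simulate_cohort(n_never = 25, n_current = 25, n_probes = 150,
                         n_per_class = c(), noise_sd = 0.35,
                         n_discriminating = 4, seed = 62)
  prof <- celltype_association(sim$celltype_betas, sim$sheet,
                               sample(rownames(sim$whole_blood), 100))
  expect_gt(min(colMeans(prof$p)), 0.3)  # uniform p has mean 0.5
  expect_lt(mean(prof$p <= 0.05), 0.12)
})

test_that("clustering merges identical rows first and is order invariant", {
  delta <- rbind(cgA = c(0.1, 0.1, 0, 0), cgB = c(0.1, 0.1, 0, 0),
                 cgC = c(-0.3, 0.2, 0.5, 0.1))
  colnames(delta) <- c("CD14", "CD15", "CD4T", "CD19")
  prof <- structure(list(delta = delta, p = delta * 0 + 0.5,
                         cell_types = colnames(delta)),
                    class = "celltype_profile")
  cl <- cluster_profiles(prof, k = 2)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$labels[["cgA"]], cl$labels[["cgB"]])
  expect_false(cl$labels[["cgA"]] == cl$labels[["cgC"]])
  expect_match(cl$newick, "cgA")

  prof_perm <- prof
  prof_perm$delta <- prof$delta[c(3, 1, 2), ]
  prof_perm$p <- prof$p[c(3, 1, 2), ]
  cl2 <- cluster_profiles(prof_perm, k = 2)
  expect_identical(cl$hclust$merge, cl2$hclust$merge)
  expect_identical(cl$labels, cl2$labels)

  one <- structure(list(delta = delta[1, , drop = FALSE], p = delta[1, , drop = FALSE]),
                   class = "celltype_profile")
  expect_error(cluster_profiles(one), "at least 2")
})

test_that("two planted classes are recovered by the 2-cluster cut", {
  agree <- vapply(1:5, function(s) {
    pf <- profile_from_matrices(noise_sd = 0.1, seed = 70 + s,
                                n_per_class = c(myeloid = 10, lymphoid = 10))
    cl <- cluster_profiles(pf$profile, k = 2,
                           columns = pf$sim$panel$cell_types)
    truth_lab <- pf$sim$truth$effect_class[
      match(names(cl$labels), pf$sim$truth$probe_id)]
    tab <- table(truth_lab, cl$labels)
    sum(apply(tab, 1, max)) / sum(tab)
  }, 0)
  expect_true(all(agree >= 0.95))
})

test_that("response-pattern rules label the canonical profiles", {
  cts <- c("CD14", "CD15", "CD19", "CD4T", "CD8T", "CD56")
  pv <- function(sig) setNames(ifelse(cts %in% sig, 0.01, 0.5), cts)
  # AHRR-like: myeloid plus B
  expect_equal(unname(classify_response_pattern(pv(c("CD14", "CD15", "CD19")))),
               "myeloid_plus_B")
  # GPR15-like: T and B
  expect_equal(unname(classify_response_pattern(pv(c("CD4T", "CD8T", "CD19")))),
               "lymphoid")
  expect_equal(unname(classify_response_pattern(pv(cts))), "pan_cell")
  expect_equal(unname(classify_response_pattern(pv(c("CD14", "CD15")))), "myeloid")
  expect_equal(unname(classify_response_pattern(pv(c("CD4T", "CD8T")))), "T_only")
  expect_equal(unname(classify_response_pattern(pv("CD4T"))), "T_only")
  expect_equal(unname(classify_response_pattern(pv("CD14"))), "monocyte_only")
  expect_equal(unname(classify_response_pattern(pv("CD19"))), "lymphoid")
  expect_equal(unname(classify_response_pattern(pv(character(0)))), "none")
  # total over all 2^6 indicator vectors
  grid <- expand.grid(rep(list(c(0.01, 0.5)), 6))
  colnames(grid) <- cts
  labs <- classify_response_pattern(as.matrix(grid))
  expect_true(all(labs %in% c("pan_cell", "myeloid", "myeloid_plus_B",
                              "lymphoid", "T_only", "monocyte_only", "none")))
})

test_that("pattern labels on the simulator match planted classes", {
  pf <- profile_from_matrices(noise_sd = 0.1, seed = 64,
                              n_per_class = c(myeloid_plus_B = 6, lymphoid = 6,
                                              T_only = 6))
  labs <- classify_response_pattern(pf$profile, alpha = 0.01)
  truth_lab <- pf$sim$truth$effect_class[
    match(names(labs), pf$sim$truth$probe_id)]
  expect_gt(mean(labs == truth_lab), 0.8)
})

test_that("whole-blood delta prediction is exact mixture arithmetic", {
  # one affected type with delta d and weight w, equal compositions
  cts <- c("CD14", "CD15", "CD4T")
  bs <- matrix(c(0.3, 0.5, 0.5), 1, dimnames = list("cg1", cts))
  bn <- matrix(c(0.5, 0.5, 0.5), 1, dimnames = list("cg1", cts))
  w <- c(CD14 = 0.2, CD15 = 0.5, CD4T = 0.3)
  expect_equal(unname(predict_wholeblood_delta(bs, bn, w, w)), 0.2 * -0.2)

  # zero within-cell deltas but shifted composition
  b <- matrix(c(0.2, 0.8, 0.5), 1, dimnames = list("cg1", cts))
  ws <- c(CD14 = 0.1, CD15 = 0.6, CD4T = 0.3)
  wn <- c(CD14 = 0.2, CD15 = 0.4, CD4T = 0.4)
  expect_equal(unname(predict_wholeblood_delta(b, b, ws, wn)),
               sum((ws - wn) * b[1, ]))
  expect_error(predict_wholeblood_delta(bs, bn, w * 2, w), "sum to 1")
})

test_that("noiseless prediction reproduces the observed whole-blood delta", {
  sim <- simulate_cohort(n_never = 10, n_current = 12, n_probes = 100,
                         n_per_class = c(myeloid = 4, lymphoid = 4),
                         noise_sd = 0, n_discriminating = 4, seed = 65,
                         compositions_args = list(
                           mean_current = c(CD14 = 0.08, CD15 = 0.51, CD19 = 0.08,
                                            CD4T = 0.20, CD8T = 0.09, CD56 = 0.04),
                           concentration = 1e9))
  cur <- sim$sheet$smoking_status == "current"
  cts <- sim$panel$cell_types
  bs <- sapply(cts, function(ct) rowMeans(sim$celltype_betas[[ct]][, cur]))
  bn <- sapply(cts, function(ct) rowMeans(sim$celltype_betas[[ct]][, !cur]))
  ws <- colMeans(sim$compositions[cur, cts])
  wn <- colMeans(sim$compositions[!cur, cts])
  ws <- ws / sum(ws); wn <- wn / sum(wn)
  pred <- predict_wholeblood_delta(bs, bn, ws, wn)
  obs <- rowMeans(sim$whole_blood[, cur]) - rowMeans(sim$whole_blood[, !cur])
  expect_equal(unname(pred), unname(obs), tolerance = 1e-9)
  # attenuation law under (near-)equal compositions, on affected probes
  deltas <- bs - bn
  planted <- sim$truth$probe_id[sim$truth$effect_class != "null"]
  expect_true(all(abs(pred[planted]) <=
                    apply(abs(deltas[planted, , drop = FALSE]), 1, max) + 1e-6))
})

test_that("cotinine regression matches closed-form least squares", {
  x <- c(1, 2, 4, 8, 16)
  y <- c(0.9, 0.8, 0.6, 0.45, 0.2)
  fit <- cotinine_regression(y, x, log_transform = TRUE)
  lx <- log2(x)
  slope_hat <- sum((lx - mean(lx)) * (y - mean(y))) / sum((lx - mean(lx))^2)
  expect_equal(fit$slope, slope_hat)
  expect_equal(fit$intercept, mean(y) - slope_hat * mean(lx))

  perfect <- suppressWarnings(cotinine_regression(0.9 - 0.1 * log2(x), x))
  expect_equal(perfect$r_squared, 1)
  flat <- cotinine_regression(rep(0.5, 5), x)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)
  expect_error(cotinine_regression(y, rep(3, 5)), "zero variance")
  expect_error(cotinine_regression(y[1:2], x[1:2]), "at least 3")
})

test_that("delta-delta-Ct fold changes follow the textbook identities", {
  rec <- data.frame(sample_id = c("N1", "N2", "S1", "S2", "S3"),
                    cell_type = "CD14", target_gene = "AHRR",
                    ct_target = c(24, 26, 24, 22, 28),
                    ct_reference = c(20, 22, 21, 19, 22))
  out <- ddct_fold_change(rec, calibrator_samples = c("N1", "N2"))
  # calibrator mean delta-Ct is 4; delta-delta-Ct of 0 / -1 / +2 map to FC 1 / 2 / 0.25
  expect_equal(out$delta_delta_ct, c(0, 0, -1, -1, 2))
  expect_equal(out$fold_change, c(1, 1, 2, 2, 0.25))
  # calibrator-group mean fold change at the group mean delta-Ct is 1
  calib_mean_ddct <- mean(out$delta_delta_ct[out$sample_id %in% c("N1", "N2")])
  expect_equal(2^(-calib_mean_ddct), 1)

  # adding a constant to both cycle thresholds of a sample changes nothing
  rec2 <- rec
  rec2$ct_target <- rec2$ct_target + 3
  rec2$ct_reference <- rec2$ct_reference + 3
  out2 <- ddct_fold_change(rec2, c("N1", "N2"))
  expect_equal(out2$fold_change, out$fold_change)

  bad <- rec; bad$ct_reference[3] <- NA
  expect_error(ddct_fold_change(bad, c("N1", "N2")), "S1")
  expect_error(ddct_fold_change(rec, "GHOST"), "no calibrator")
})
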
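test_that("simulated subjects satisfy the exposure invariants and are reproducible", {
  s1 <- simulate_subjects(n_never = 30, n_current = 50, seed = 5)
  s2 <- simulate_subjects(n_never = 30, n_current = 50, seed = 5)
  s3 <- simulate_subjects(n_never = 30, n_current = 50, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_silent(validate_sample_sheet(s1))
  cur <- s1$smoking_status == "current"
  expect_equal(s1$pack_years, s1$cigarettes_per_day / 20 * s1$years_smoked)
  expect_true(all(s1$years_smoked[cur] > 0))
  # cotinine tracks dose: smokers well above never-smokers
  expect_gt(min(tapply(s1$cotinine, cur, mean)[["TRUE"]]),
            max(s1$cotinine[!cur]))
  expect_gt(cor(s1$cigarettes_per_day[cur], s1$cotinine[cur]), 0.3)

  only_current <- simulate_subjects(n_never = 0, n_current = 10, seed = 1)
  expect_true(all(only_current$smoking_status == "current"))
  expect_error(simulate_subjects(n_never = -1, n_current = 5), "non-negative")
})

test_that("reference panel construction separates lineage markers", {
  p <- simulate_reference_panel(n_probes = 100, cell_types = c("CD14", "CD19"),
                                n_discriminating = 2, seed = 3)
  p2 <- simulate_reference_panel(n_probes = 100, cell_types = c("CD14", "CD19"),
                                 n_discriminating = 2, seed = 3)
  expect_identical(p$baseline, p2$baseline)
  for (ct in p$cell_types) {
    for (pr in p$discriminating[[ct]]) {
      other <- setdiff(p$cell_types, ct)
      expect_gte(abs(p$baseline[pr, ct] - mean(p$baseline[pr, other])), 0.8)
    }
  }
  expect_true(all(p$baseline >= 0 & p$baseline <= 1))

  p0 <- simulate_reference_panel(n_probes = 50, n_discriminating = 0, seed = 1)
  expect_false(p0$usable_for_deconvolution)
  expect_error(simulate_reference_panel(n_probes = 10, n_discriminating = 5),
               "at least")
})

test_that("planted effects land in the intended cell types", {
  panel <- simulate_reference_panel(n_probes = 300, n_discriminating = 10, seed = 2)
  truth <- simulate_effect_truth(panel, n_per_class = c(myeloid = 3, lymphoid = 3,
                                                        duration_heavy = 2),
                                 seed = 2)
  expect_true(all(truth$effect_class[rowSums(abs(truth[panel$cell_types])) == 0 &
                                     truth$duration_slope == 0] == "null"))
  my <- truth[truth$effect_class == "myeloid", ]
  expect_true(all(my$CD14 == -1.5 & my$CD15 == -1.5))
  expect_true(all(my$CD4T == 0 & my$CD19 == 0))
  ly <- truth[truth$effect_class == "lymphoid", ]
  expect_true(all(ly$CD4T == -0.8 & ly$CD8T == -0.8 & ly$CD19 == -0.8))
  expect_true(all(ly$CD14 == 0 & ly$CD15 == 0))
  du <- truth[truth$effect_class == "duration_heavy", ]
  expect_true(all(du$duration_slope == -0.05))
  expect_true(all(as.matrix(du[panel$cell_types]) == 0))
  # planted probes never overlap deconvolution markers
  expect_length(intersect(truth$probe_id[truth$effect_class != "null"],
                          unlist(panel$discriminating)), 0)
  expect_error(simulate_effect_truth(panel, n_per_class = c(bogus = 1)),
               "unknown effect class")
})

test_that("noiseless synthesis reproduces baselines and planted shifts exactly", {
  panel <- simulate_reference_panel(n_probes = 200, n_discriminating = 5, seed = 9)
  sheet <- simulate_subjects(n_never = 6, n_current = 6, heavy_fraction = 0.5,
                             seed = 9)
  truth <- simulate_effect_truth(panel, n_per_class = c(myeloid = 2,
                                                        duration_heavy = 2),
                                 seed = 9)
  mats <- simulate_celltype_betas(panel, sheet, truth, noise_sd = 0, seed = 9)
  null_probes <- truth$probe_id[truth$effect_class == "null"]
  for (ct in panel$cell_types)
    expect_identical(mats[[ct]][null_probes, ],
                     matrix(panel$baseline[null_probes, ct],
                            length(null_probes), nrow(sheet),
                            dimnames = dimnames(mats[[ct]][null_probes, ])))
  # myeloid probes: smokers shifted down in CD14/CD15, untouched in T cells
  cur <- sheet$smoking_status == "current"
  my <- truth$probe_id[truth$effect_class == "myeloid"]
  for (pr in my) {
    expect_lt(mean(mats$CD14[pr, cur]), mean(mats$CD14[pr, !cur]))
    expect_lt(mean(mats$CD15[pr, cur]), mean(mats$CD15[pr, !cur]))
    expect_equal(mean(mats$CD4T[pr, cur]), mean(mats$CD4T[pr, !cur]))
    # exact logit arithmetic
    expect_equal(unname(qlogis(mats$CD14[pr, cur]) -
                          qlogis(panel$baseline[pr, "CD14"])),
                 rep(-1.5, sum(cur)), tolerance = 1e-9)
  }
  # duration probes decrease linearly with years among heavy smokers only
  heavy <- sheet$cigarettes_per_day >= 22
  du <- truth$probe_id[truth$effect_class == "duration_heavy"][1]
  shift <- qlogis(mats$CD14[du, ]) - qlogis(panel$baseline[du, "CD14"])
  expect_equal(unname(shift[heavy]), -0.05 * sheet$years_smoked[heavy],
               tolerance = 1e-9)
  expect_equal(unname(shift[!heavy]), rep(0, sum(!heavy)), tolerance = 1e-12)
  expect_true(all(vapply(mats, function(m) all(m > 0 & m < 1), TRUE)))

  bad <- truth; names(bad)[names(bad) == "CD14"] <- "CD99"
  expect_error(simulate_celltype_betas(panel, sheet, bad, seed = 1),
               "do not match panel")
})

test_that("whole-blood mixing is an exact convex combination", {
  probes <- sprintf("cg%08d", 1:5)
  samples <- c("A", "B")
  m1 <- matrix(0.2, 5, 2, dimnames = list(probes, samples))
  m2 <- matrix(0.6, 5, 2, dimnames = list(probes, samples))
  comp <- data.frame(sample_id = samples, X = c(0.3, 1), Y = c(0.7, 0))
  wb <- mix_to_whole_blood(list(X = m1, Y = m2), comp)
  expect_equal(unname(wb[, "A"]), rep(0.3 * 0.2 + 0.7 * 0.6, 5))  # 0.48
  expect_equal(unname(wb[, "B"]), rep(0.2, 5))  # single-type identity

  # pbmc with retention 0 removes granulocytes and renormalizes
  comp2 <- data.frame(sample_id = samples, CD15 = c(0.5, 0.5), Y = c(0.5, 0.5))
  pb <- mix_to_whole_blood(list(CD15 = m1, Y = m2), comp2, pbmc = TRUE,
                           retention = 0)
  expect_equal(unname(pb[1, ]), c(0.6, 0.6))

  m3 <- m2; rownames(m3)[1] <- "cgX"
  expect_error(mix_to_whole_blood(list(X = m1, Y = m3), comp),
               "probe sets differ")
  badcomp <- data.frame(sample_id = samples, X = c(0.5, 1), Y = c(0.7, 0))
  expect_error(mix_to_whole_blood(list(X = m1, Y = m2), badcomp), "sum to 1")
})

test_that("mixing conserves the weighted sum on full synthetic cohorts", {
  sim <- simulate_cohort(n_never = 5, n_current = 7, n_probes = 150,
                         n_discriminating = 5, noise_sd = 0, seed = 4)
  manual <- Reduce(`+`, lapply(sim$panel$cell_types, function(ct)
    sim$celltype_betas[[ct]] *
      rep(sim$compositions[[ct]], each = nrow(sim$whole_blood))))
  expect_equal(sim$whole_blood, manual, tolerance = 1e-12)
})

test_that("empirical smoker delta at planted probes matches the mapped logit effect", {
  sim <- simulate_cohort(n_never = 100, n_current = 150, n_probes = 250,
                         n_per_class = c(myeloid_plus_B = 5), noise_sd = 0.35,
                         n_discriminating = 5, seed = 12)
  cur <- sim$sheet$smoking_status == "current"
  pr <- sim$truth$probe_id[sim$truth$effect_class == "myeloid_plus_B"]
  for (p in pr) {
    for (ct in c("CD14", "CD15", "CD19")) {
      x <- sim$celltype_betas[[ct]][p, ]
      obs <- mean(x[cur]) - mean(x[!cur])
      # expected beta-scale delta from the logit effect, by Monte Carlo over
      # the same noise law (independent draws = independent oracle)
      set.seed(1000 + match(p, pr))
      eta <- qlogis(sim$panel$baseline[p, ct]) + rnorm(40000, 0, 0.35)
      expected <- mean(plogis(eta - 1.5)) - mean(plogis(eta))
      se <- sqrt(var(x[cur]) / sum(cur) + var(x[!cur]) / sum(!cur))
      expect_lt(abs(obs - expected), 3 * se + 0.005)
    }
  }
})
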
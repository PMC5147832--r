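# shared fixtures and independent oracles

# small beta matrix with named probes/samples
toy_beta_matrix <- function(n_probes = 10, n_samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
              dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

# numeric vector with exactly the requested mean and SD
vector_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  v <- rnorm(n)
  mean + sd * as.numeric(scale(v))
}

# Welch two-sample t from first principles (independent of stats::t.test)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force simplex grid search for the deconvolution objective (3 types)
grid_search_composition <- function(R, b, step = 0.005) {
  stopifnot(ncol(R) == 3)
  g <- seq(0, 1, by = step)
  W <- expand.grid(w1 = g, w2 = g)
  W$w3 <- 1 - W$w1 - W$w2
  W <- as.matrix(W[W$w3 >= -1e-12, ])
  W[, 3] <- pmax(W[, 3], 0)
  obj <- colSums((as.numeric(b) - R %*% t(W))^2)
  i <- which.min(obj)
  list(weights = W[i, ], objective = obj[i], all_objectives = obj)
}

# minimal sample sheet for hand-built matrices
toy_sheet <- function(status, sample_ids = sprintf("S%03d", seq_along(status)),
                      cpd = ifelse(status == "current", 20, 0),
                      years = ifelse(status == "current", 10, 0)) {
  data.frame(sample_id = sample_ids, smoking_status = status,
             cigarettes_per_day = cpd, years_smoked = years,
             pack_years = cpd / 20 * years,
             cotinine = ifelse(status == "current", 200, 1),
             age = seq(30, length.out = length(status)),
             sex = rep(c("male", "female"), length.out = length(status)),
             race = rep(c("Caucasian", "AfricanAmerican"),
                        length.out = length(status)),
             stringsAsFactors = FALSE)
}
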
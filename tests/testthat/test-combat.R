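# Simulated two-batch tables following the location/scale batch model:
# x = mu_f + gamma_f(batch) + delta_f(batch) * eps, with heterogeneous
# per-feature baselines so the empirical-Bayes priors are well conditioned.
make_batch_data <- function(n_per = 200, shift = 2, scale = 1.5, p = 5,
                            age_slope = 0) {
  n <- 2 * n_per
  batch <- rep(c("siteA", "siteB"), each = n_per)
  age <- runif(n, 20, 70)
  base_sd <- seq(0.5, 3, length.out = p)
  eps <- matrix(rnorm(n * p), n, p) %*% diag(base_sd)
  mu <- matrix(rep(seq(10, 50, length.out = p), each = n), n, p) +
    age_slope * age
  x <- mu + eps
  idx <- batch == "siteB"
  x[idx, ] <- mu[idx, ] + shift + eps[idx, ] * scale
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, batch = batch, age = age)
}

std_mean_diff <- function(x, batch) {
  a <- x[batch == "siteA", , drop = FALSE]
  b <- x[batch == "siteB", , drop = FALSE]
  abs(colMeans(a) - colMeans(b)) /
    sqrt((apply(a, 2, var) + apply(b, 2, var)) / 2)
}

var_ratio <- function(x, batch) {
  apply(x[batch == "siteA", , drop = FALSE], 2, var) /
    apply(x[batch == "siteB", , drop = FALSE], 2, var)
}

test_that("a single batch yields the identity model", {
  set.seed(1)
  x <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_warning(model <- fit_combat(x, rep("only", 10)), "single batch")
  expect_true(model$identity)
  expect_lt(max(abs(apply_combat(model, x, rep("only", 10)) - x)), 1e-8)
})

test_that("planted location/scale batch effects are removed", {
  res <- vapply(1:10, function(s) {
    set.seed(500 + s)
    d <- make_batch_data(n_per = 200, shift = 2, scale = 1.5)
    harm <- combat(d$x, d$batch)
    c(std_mean_diff(harm, d$batch), var_ratio(harm, d$batch))
  }, numeric(10))
  smd_mean <- rowMeans(res)[1:5]
  vr_mean <- rowMeans(res)[6:10]
  expect_lt(max(smd_mean), 0.05)
  expect_true(all(vr_mean > 0.9 & vr_mean < 1.1))
  # before harmonization the planted effects are an order of magnitude larger
  set.seed(501)
  d <- make_batch_data(n_per = 200, shift = 2, scale = 1.5)
  expect_gt(min(std_mean_diff(d$x, d$batch)), 0.3)
  expect_true(all(var_ratio(d$x, d$batch) < 0.6))
})

test_that("a covariate slope survives harmonization of a confounded design", {
  set.seed(42)
  n_per <- 250
  batch <- rep(c("siteA", "siteB"), each = n_per)
  # batch-confounded age: siteB is older on average
  age <- c(runif(n_per, 20, 50), runif(n_per, 40, 70))
  eps <- matrix(rnorm(2 * n_per * 3), ncol = 3)
  x <- 0.5 * age + eps
  x[batch == "siteB", ] <- 0.5 * age[batch == "siteB"] + 3 +
    eps[batch == "siteB", ] * 1.4
  colnames(x) <- paste0("f", 1:3)
  harm <- combat(x, batch, covariates = cbind(age = age))
  slope <- coef(lm(harm[, 1] ~ age))[["age"]]
  expect_lt(abs(slope - 0.5) / 0.5, 0.10)
})

test_that("harmonization output matches the reference empirical-Bayes ComBat", {
  skip_if_not_installed("sva")
  set.seed(7)
  d <- make_batch_data(n_per = 60, shift = 1.5, scale = 1.3, p = 5)
  mod <- stats::model.matrix(~ d$age)
  suppressMessages(
    ref <- t(sva::ComBat(dat = t(d$x), batch = d$batch, mod = mod,
                         par.prior = TRUE, prior.plots = FALSE)))
  mine <- combat(d$x, d$batch, covariates = cbind(age = d$age))
  expect_lt(max(abs(mine - ref)) / sd(d$x), 1e-3)
})

test_that("apply_combat is row-equivariant and guards its contracts", {
  set.seed(9)
  d <- make_batch_data(n_per = 40)
  model <- fit_combat(d$x, d$batch)
  harm <- apply_combat(model, d$x, d$batch)
  perm <- sample.int(nrow(d$x))
  harm_perm <- apply_combat(model, d$x[perm, ], d$batch[perm])
  expect_equal(harm_perm, harm[perm, ])
  expect_error(apply_combat(model, d$x, rep("siteC", nrow(d$x))), "unseen")
  bad <- d$x
  colnames(bad) <- rev(colnames(bad))
  expect_error(apply_combat(model, bad, d$batch), "feature")
  expect_error(fit_combat(d$x, c("a", rep("b", nrow(d$x) - 1))), "< 2")
})

test_that("constant features pass through untouched with a warning", {
  set.seed(11)
  d <- make_batch_data(n_per = 30, p = 3)
  x <- cbind(d$x, const = 5)
  expect_warning(harm <- combat(x, d$batch), "zero variance")
  expect_equal(unname(harm[, "const"]), rep(5, nrow(x)))
})

test_that("harmonization is near-idempotent", {
  # the empirical-Bayes shrinkage leaves a small residual on refit, so exact
  # idempotence is not attainable; the residual stays below 1% of the scale
  set.seed(13)
  d <- make_batch_data(n_per = 150, shift = 2, scale = 1.5)
  once <- combat(d$x, d$batch)
  twice <- combat(once, d$batch)
  expect_lt(max(abs(twice - once)) / sd(once), 0.01)
})

test_that("global feature means move by well under the feature scale", {
  set.seed(15)
  d <- make_batch_data(n_per = 120, shift = 1, scale = 1.2)
  age_c <- d$age - mean(d$age)
  harm <- combat(d$x, d$batch, covariates = cbind(age = age_c))
  rel <- abs(colMeans(harm) - colMeans(d$x)) / apply(d$x, 2, sd)
  expect_lt(max(rel), 0.01)
})

test_that("mean_only mode adjusts locations but leaves scales untouched", {
  set.seed(17)
  d <- make_batch_data(n_per = 100, shift = 2, scale = 1.5)
  harm <- combat(d$x, d$batch, mode = "mean_only")
  expect_lt(max(std_mean_diff(harm, d$batch)), 0.15)
  expect_lt(max(std_mean_diff(harm, d$batch)),
            min(std_mean_diff(d$x, d$batch)))
  # per-batch variances unchanged, exactly
  for (b in c("siteA", "siteB")) {
    expect_equal(apply(harm[d$batch == b, ], 2, var),
                 apply(d$x[d$batch == b, ], 2, var))
  }
})

test_that("the fitted model round-trips through JSON", {
  set.seed(19)
  d <- make_batch_data(n_per = 40)
  model <- fit_combat(d$x, d$batch, covariates = cbind(age = d$age))
  path <- withr::local_tempfile(fileext = ".json")
  combat_write_json(model, path)
  model2 <- combat_read_json(path)
  h1 <- apply_combat(model, d$x, d$batch, cbind(age = d$age))
  h2 <- apply_combat(model2, d$x, d$batch, cbind(age = d$age))
  expect_equal(h2, h1, tolerance = 1e-12)
})

test_that("PCA diagnostic shows the center separation shrinking", {
  set.seed(21)
  d <- make_batch_data(n_per = 80, shift = 3, scale = 1.2, p = 6)
  harm <- combat(d$x, d$batch)
  diag <- pca_diagnostic(d$x, harm, d$batch)
  expect_lt(diag$separation["after"], diag$separation["before"])
  same <- pca_diagnostic(d$x, d$x, d$batch)
  expect_identical(same$before, same$after)
  # warns once per panel (before and after are both single-feature)
  expect_warning(
    expect_warning(pca_diagnostic(d$x[, 1, drop = FALSE],
                                  harm[, 1, drop = FALSE], d$batch),
                   "rank-deficient"),
    "rank-deficient")
})

test_that("covariates collinear with batch are rejected", {
  set.seed(23)
  d <- make_batch_data(n_per = 30)
  dummy <- as.numeric(d$batch == "siteB")
  expect_error(fit_combat(d$x, d$batch, covariates = cbind(dup = dummy)),
               "rank deficient")
})
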
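test_that("standardization uses sample SD and relativizes fitness to mean 1", {
  df <- data.frame(
    individual_id = c("a", "b", "c"), population = "P", morph = "L",
    treatment = "C", flowering_onset = c(1, 2, 3), plant_height = c(2, 1, 3),
    n_flowers = c(4, 6, 5), corolla_tube_length = c(9, 10, 8),
    corolla_tube_width = c(3, 4, 3.5), fruit_production = c(1, 2, 3),
    seeds_per_fruit = c(5, 5, 5), female_fitness = c(0, 10, 5),
    stringsAsFactors = FALSE)
  std <- standardize_group(df, traits = "flowering_onset")
  # sample SD of (1,2,3) is 1, so z is (-1, 0, 1)
  expect_equal(unname(std$z[, "flowering_onset"]), c(-1, 0, 1))
  # fitness (0, 10, 5): mean 5 -> w = (0, 2, 1)
  expect_equal(std$w, c(0, 2, 1))

  g <- tiny_table(n_per_cell = 15, seed = 8)
  one <- split_groups(g)[[1]]
  std <- standardize_group(one)
  expect_lt(max(abs(colMeans(std$z))), 1e-10)
  expect_lt(max(abs(apply(std$z, 2, stats::var) - 1)), 1e-8)
  expect_lt(abs(mean(std$w) - 1), 1e-10)

  one$corolla_tube_width <- 3
  expect_error(standardize_group(one), "corolla_tube_width.*zero variance")
})

test_that("fit_ols matches closed forms and handles degenerate designs", {
  set.seed(21)
  # constant response: zero slopes, zero R^2
  z <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_ols(rep(1, 20), z)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)

  # single predictor: scalar simple-regression formulas
  x <- rnorm(30); y <- 1 + 0.5 * x + rnorm(30, 0, 0.3)
  fit <- fit_ols(y, cbind(x = x))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(unname(fit$coefficients["x"]), slope, tolerance = 1e-12)
  expect_equal(unname(fit$se["x"]),
               sqrt(fit$rss / fit$df_residual / sxx), tolerance = 1e-12)

  expect_error(fit_ols(y, cbind(x = x, x2 = x)), "singular design.*x2")
  expect_error(fit_ols(y[1:3], cbind(x = x[1:3], z = rnorm(3), w = rnorm(3))),
               "insufficient data")
})

test_that("fit_ols recovers known gradients in repeated simulations", {
  beta <- c(0.2, -0.15, 0.3, 0, 0.1)
  n <- 1000
  hits <- 0L
  total <- 0L
  set.seed(99)
  for (rep in 1:200) {
    z <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("t", 1:5)))
    w <- 1 + drop(z %*% beta) + rnorm(n, 0, 0.5)
    fit <- fit_ols(w, z)
    inside <- abs(fit$coefficients[-1] - beta) <= 3 * fit$se[-1]
    hits <- hits + sum(inside)
    total <- total + 5L
  }
  expect_gte(hits / total, 0.99)
})

test_that("fit_ols agrees with lm on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:80, 1); p <- sample(2:6, 1)
    z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    fit <- fit_ols(y, z)
    ref <- summary(stats::lm(y ~ z))
    expect_equal(unname(fit$coefficients), unname(ref$coefficients[, 1]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(ref$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$p), unname(ref$coefficients[, 4]),
                 tolerance = 1e-10)
  }
})

test_that("vif matches its closed form and flags collinearity", {
  # exactly orthogonal columns -> VIF exactly 1
  z <- cbind(a = rep(c(1, -1), 20), b = rep(c(1, 1, -1, -1), 10))
  expect_equal(unname(vif(z)), c(1, 1), tolerance = 1e-12)

  # sample correlation exactly 0.6 -> VIF = 1/(1 - 0.36) = 1.5625
  set.seed(5)
  x <- as.numeric(scale(rnorm(50)))
  e <- rnorm(50)
  e <- as.numeric(scale(e - x * sum(e * x) / sum(x * x)))
  y <- 0.6 * x + sqrt(1 - 0.36) * e
  expect_equal(unname(vif(cbind(x = x, y = y))), c(1.5625, 1.5625),
               tolerance = 1e-10)

  # duplicated column -> infinite VIF, not an exception
  expect_equal(unname(vif(cbind(x = x, x2 = x))), c(Inf, Inf))
})

test_that("vif agrees with the car reference implementation", {
  set.seed(13)
  z <- MASS::mvrnorm(100, rep(0, 4),
                     0.5 * diag(4) + 0.5,
                     empirical = FALSE)
  colnames(z) <- paste0("x", 1:4)
  y <- rnorm(100)
  dat <- data.frame(y = y, z)
  ref <- car::vif(stats::lm(y ~ x1 + x2 + x3 + x4, data = dat))
  expect_equal(unname(vif(z)), unname(ref), tolerance = 1e-8)
})

test_that("estimate_gradients recovers a noiseless linear fitness surface", {
  beta <- c(0.2, -0.1, 0.3, 0, 0.1)
  tab <- noiseless_group(n = 40, beta = beta)
  g <- estimate_gradients(tab)
  expect_equal(g$beta, beta, tolerance = 1e-8)
  expect_equal(g$n, rep(40L, 5), ignore_attr = TRUE)
  # noiseless: standard errors collapse, p ~ 0 for nonzero gradients
  expect_lt(max(g$se), 1e-8)
})

test_that("standardized gradients are invariant to trait rescaling", {
  tab <- tiny_table(n_per_cell = 20, seed = 31)
  g1 <- estimate_gradients(tab)
  df <- as.data.frame(tab)
  df$plant_height <- df$plant_height * 37.2
  g2 <- estimate_gradients(study_table(df))
  expect_equal(g2$beta, g1$beta, tolerance = 1e-8)
  expect_equal(g2$se, g1$se, tolerance = 1e-8)
})

test_that("cross-product terms are appended with their VIFs on request", {
  tab <- tiny_table(n_per_cell = 30, pops = "P1", seed = 17)
  g <- estimate_gradients(tab, include_cross_products = TRUE)
  per_group <- table(paste(g$population, g$morph, g$treatment))
  expect_true(all(per_group == 15))  # 5 linear + 10 pairwise products
  expect_true(all(g$vif >= 1))
  expect_true("corolla_tube_length:corolla_tube_width" %in% g$trait)
})

test_that("strata smaller than 8 records are refused for fitting", {
  tab <- tiny_table(n_per_cell = 7, seed = 19)
  expect_error(estimate_gradients(tab), "fewer than 8")
})
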
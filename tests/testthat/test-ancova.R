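test_that("build_design produces the expected interaction columns", {
  df <- data.frame(f = rep(c("a", "b"), 3), x = c(1, 2, 3, 4, 5, 6),
                   stringsAsFactors = FALSE)
  d <- build_design(df, covariates = "x", factors = list(f = c("a", "b")),
                    blocks = list(x = "trait", f = "f", `x:f` = c("trait", "f")))
  # intercept + factor + covariate + product = 4 model columns
  expect_equal(ncol(d$X) + 1, 4)
  # hand-built oracle on the n = 6 toy
  expect_equal(unname(d$X[, "x"]), df$x)
  expect_equal(unname(d$X[, "fb"]), as.numeric(df$f == "b"))
  expect_equal(unname(d$X[, "x:fb"]), df$x * (df$f == "b"))

  # 4-level population x 5 traits -> (4-1) x 5 = 15 columns
  tab <- simulate_cohort(default_config(), seed = 2, n_override = 12)
  sel <- prepare_selection_data(tab)
  d2 <- build_design(sel, covariates = floral_traits(),
                     factors = list(population = attr(sel, "population_levels")),
                     blocks = list(`trait:population` = c("trait", "population")))
  expect_equal(ncol(d2$X), 15)
})

test_that("rank-deficient designs are reported with the aliased columns", {
  df <- data.frame(x = rnorm(10), y = NA)
  df$y <- 2 * df$x
  expect_error(
    build_design(df, covariates = c("x", "y"), factors = list(),
                 blocks = list(x = "trait")),
    "aliased")
})

test_that("nested-model F reduces to t^2 for single columns and 0 for equal fits", {
  set.seed(7)
  z <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 1 + 0.3 * z[, 1] + rnorm(50)
  full <- fit_ols(y, z)
  same <- test_block(full, full)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  reduced <- fit_ols(y, z[, -2])
  tb <- test_block(full, reduced)
  expect_equal(tb$F, unname(full$t["x2"])^2, tolerance = 1e-10)
  expect_equal(tb$p, unname(full$p["x2"]), tolerance = 1e-10)
  expect_error(test_block(reduced, full), "not nested")
})

test_that("nested-model F p-values are uniform under the null", {
  set.seed(1234)
  pvals <- replicate(500, {
    z <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(40)
    full <- fit_ols(y, z)
    reduced <- fit_ols(y, z[, 1, drop = FALSE])
    test_block(full, reduced)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Model A block tests match a Type-III lm oracle", {
  tab <- simulate_cohort(default_config(), seed = 5, n_override = 25)
  ma <- ancova_model_a(tab)
  sel <- prepare_selection_data(
    study_table(as.data.frame(tab)[tab$treatment == "C", ],
                population_levels = attr(tab, "population_levels")))
  sel$population <- factor(sel$population,
                           levels = attr(sel, "population_levels"))
  sel$morph <- factor(sel$morph, levels = c("L", "S"))
  traits <- floral_traits()
  rhs <- paste0("(", paste(traits, collapse = "+"), ")")
  form <- stats::as.formula(paste(
    "w ~", rhs, "+ population + morph +", rhs, ":population +", rhs,
    ":morph +", rhs, ":population:morph"))
  fit <- stats::lm(form, data = sel)
  ref <- car::Anova(fit, type = "III", singular.ok = FALSE)
  get_ref <- function(term) ref[term, "F value"]
  # block test oracle: nested comparison on R's own model matrix, dropping
  # the five two-way trait:morph columns
  X <- stats::model.matrix(fit)
  asn <- attr(X, "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  two_way <- match(paste0(traits, ":morph"), labs)
  keep <- !(asn %in% two_way)
  red <- stats::lm.fit(X[, keep, drop = FALSE], sel$w)
  rss_f <- sum(stats::residuals(fit)^2)
  rss_r <- sum(red$residuals^2)
  df_f <- fit$df.residual
  F_ref <- ((rss_r - rss_f) / 5) / (rss_f / df_f)
  expect_equal(ma$F[ma$term == "trait:morph"], F_ref, tolerance = 1e-8)
  # per-trait single-column tests: F equals the Type-III per-term F
  expect_equal(ma$F[ma$term == "trait:morph[corolla_tube_length]"],
               get_ref("corolla_tube_length:morph"), tolerance = 1e-8)
  expect_equal(ma$F[ma$term == "trait:morph[flowering_onset]"],
               get_ref("flowering_onset:morph"), tolerance = 1e-8)
})

test_that("Model A and Model B reproduce the study's design dimensions", {
  tab <- simulate_cohort(default_config(), seed = 3)
  ma <- ancova_model_a(tab)
  mb <- ancova_model_b(tab)
  # 739 C-plants minus 45 parameters; 1485 plants minus 86 parameters
  expect_equal(attr(ma, "df_residual"), 694)
  expect_equal(attr(mb, "df_residual"), 1399)
  expect_setequal(
    ma$term[!grepl("\\[", ma$term)],
    c("trait", "population", "morph", "trait:population", "trait:morph",
      "trait:population:morph"))
  expect_true(all(c("trait:pollination", "trait:population:pollination",
                    "trait:morph:pollination",
                    "trait:population:morph:pollination") %in% mb$term))
  expect_true(all(mb$F >= 0) && all(mb$p >= 0 & mb$p <= 1))
})

test_that("trait-by-morph differences in selection are detected with power", {
  # corolla tube length gradient differs between morphs (L: -0.2, S: +0.05)
  cfg <- default_config()
  for (key in names(cfg$cells)) {
    cl <- cfg$cells[[key]]
    beta <- c(0, 0, 0.15, if (cl$morph == "L") -0.2 else 0.05, 0.15)
    names(beta) <- floral_traits()
    cfg$cells[[key]]$beta_C <- beta
    cfg$cells[[key]]$beta_HP <- beta
  }
  hits <- 0L
  for (s in 1:40) {
    tab <- simulate_cohort(cfg, seed = 1000 + s)
    ma <- ancova_model_a(tab)
    p <- ma$p[ma$term == "trait:morph[corolla_tube_length]"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 40, 0.8)
})

test_that("delta-beta equals the treatment-interaction coefficient and is 0 on mirrored arms", {
  # duplicated data: HP arm is an exact copy of the C arm
  tab_c <- as.data.frame(tiny_table(n_per_cell = 20, pops = "P1", seed = 23))
  tab_c <- tab_c[tab_c$treatment == "C", ]
  tab_hp <- tab_c
  tab_hp$treatment <- "HP"
  tab_hp$individual_id <- paste0(tab_hp$individual_id, "-hp")
  tab <- study_table(rbind(tab_c, tab_hp))
  g <- estimate_gradients(tab)
  db <- delta_beta(g, tab)
  expect_equal(db$delta_beta, rep(0, nrow(db)), tolerance = 1e-12)

  tab2 <- simulate_cohort(default_config(), seed = 8, n_override = 30)
  db2 <- delta_beta(estimate_gradients(tab2), tab2)
  expect_lt(max(abs(db2$delta_beta - db2$delta_model)), 1e-10)
  expect_equal(db2$n_C, rep(30L, nrow(db2)), ignore_attr = TRUE)
})

test_that("statistics are invariant to row order", {
  tab <- simulate_cohort(default_config(), seed = 10, n_override = 20)
  set.seed(1)
  perm <- study_table(as.data.frame(tab)[sample(nrow(tab)), ],
                      population_levels = attr(tab, "population_levels"))
  g1 <- estimate_gradients(tab); g2 <- estimate_gradients(perm)
  expect_lt(max(abs(g1$beta - g2$beta)), 1e-10)
  m1 <- ancova_model_b(tab); m2 <- ancova_model_b(perm)
  expect_lt(max(abs(m1$F - m2$F)), 1e-10)
})

test_that("factorial ANOVA matches aov and the t-test on classic cases", {
  # one-way, two groups: F equals the squared equal-variance t statistic
  set.seed(77)
  df <- data.frame(g = rep(c("a", "b"), each = 12),
                   y = c(rnorm(12, 1), rnorm(12, 1.6)))
  res <- factorial_anova(df, "y", "g")
  tt <- stats::t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(res$F[res$term == "g"], unname(tt$statistic)^2,
               tolerance = 1e-10)

  # noiseless equal cell means -> all F = 0
  flat <- expand.grid(a = c("x", "y"), b = c("u", "v"))
  flat$y <- 5
  res0 <- factorial_anova(rbind(flat, flat), "y", c("a", "b"))
  expect_equal(res0$F, rep(0, 3), ignore_attr = TRUE)

  # balanced 2x2x2 with integer responses vs aov (types coincide when balanced)
  toy <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"),
                     rep = 1:3, stringsAsFactors = FALSE)
  set.seed(9)
  toy$y <- as.numeric(sample(1:20, nrow(toy), replace = TRUE))
  res3 <- factorial_anova(toy, "y", c("a", "b", "c"))
  ref <- summary(stats::aov(y ~ a * b * c, data = toy))[[1]]
  ref_terms <- trimws(rownames(ref))
  for (term in res3$term) {
    expect_equal(res3$F[res3$term == term], ref[match(term, ref_terms), "F value"],
                 tolerance = 1e-8, label = paste("F for", term))
  }

  # log10 transform of a response with zeros requires an offset
  df0 <- data.frame(g = rep(c("a", "b"), 6), y = c(0, 2:12))
  expect_error(factorial_anova(df0, "y", "g", log10_transform = TRUE),
               "offset")
  expect_s3_class(factorial_anova(df0, "y", "g", log10_transform = TRUE,
                                  offset = 1), "anova_result")
})

test_that("proportion explained is the delta-to-net ratio in percent", {
  expect_equal(proportion_explained(0.13, 0.17), 76.5)
  expect_equal(proportion_explained(0.146, 0.174), 83.9)
  expect_equal(proportion_explained(0.2, 0.2), 100)
  expect_true(is.na(proportion_explained(0.1, 0)))
  tab <- simulate_cohort(default_config(), seed = 12, n_override = 25)
  db <- delta_beta(estimate_gradients(tab), tab)
  pe <- proportion_explained(db)
  expect_equal(pe, round(100 * db$delta_beta / db$beta_C, 1))
})
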
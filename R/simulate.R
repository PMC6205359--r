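#' Published group summaries of the field study
#'
#' Summary statistics of the four-population (BGTC 1/2, PNP 1/2), two-morph
#' (L/S), two-treatment (C/HP) field experiment on *Primula secundiflora*
#' that parameterize the synthetic cohort generator: per-cell floral trait
#' means/SDs and sample sizes, and per-group female reproductive performance
#' (fruit production, seeds per fruit, total seed fitness) with pollen
#' limitation and its reported bootstrap CI.
#'
#' @return A data frame.
#' @export
published_trait_summary <- function() {
  utils::read.csv(system.file("extdata", "floral_trait_summary.csv",
                              package = "primsel"),
                  stringsAsFactors = FALSE)
}

#' @rdname published_trait_summary
#' @export
published_fitness_summary <- function() {
  utils::read.csv(system.file("extdata", "fitness_summary.csv",
                              package = "primsel"),
                  stringsAsFactors = FALSE)
}

## Standardized-scale gradient scenario per population x morph, encoding the
## sign/magnitude pattern of the field results: positive flower-number and
## tube-width gradients everywhere, negative tube-length gradients in L-morph
## syrphid-fly (BGTC) cells, and pollinator-mediated components (delta)
## concentrated where the study detected them.
gradient_scenario <- function() {
  traits <- floral_traits()
  sc <- list(
    list("BGTC1", "L", c(0,     0, 0.15, -0.123, 0.170), c(0,     0, -0.10, -0.108, 0.130)),
    list("BGTC2", "L", c(0,     0, 0.15, -0.167, 0.174), c(0,     0,  0,    -0.250, 0.146)),
    list("PNP1",  "L", c(0.10,  0, 0.15,  0,     0.150), c(0,     0,  0.10,  0,     0.112)),
    list("PNP2",  "L", c(0,     0, 0.15,  0,     0.150), c(0,     0,  0,     0,     0.130)),
    list("BGTC1", "S", c(0,     0, 0.15,  0,     0.150), c(0,     0,  0,     0,     0)),
    list("BGTC2", "S", c(0.222, 0, 0.15,  0,     0.150), c(0.173, 0,  0,     0,     0)),
    list("PNP1",  "S", c(0,     0, 0.15,  0,     0.150), c(0,     0,  0.146, 0,     0.114)),
    list("PNP2",  "S", c(0,     0, 0.15,  0,     0.150), c(0,     0,  0,     0,     0.126)))
  do.call(rbind, lapply(sc, function(s) {
    data.frame(population = s[[1]], morph = s[[2]], trait = traits,
               beta_C = s[[3]], delta = s[[4]], stringsAsFactors = FALSE)
  }))
}

default_trait_corr <- function() {
  traits <- floral_traits()
  R <- diag(5)
  dimnames(R) <- list(traits, traits)
  R["corolla_tube_length", "corolla_tube_width"] <- 0.2
  R["corolla_tube_width", "corolla_tube_length"] <- 0.2
  R["plant_height", "n_flowers"] <- 0.3
  R["n_flowers", "plant_height"] <- 0.3
  R
}

#' Default simulation scenario mirroring the field study
#'
#' Builds the 16-cell (4 populations x 2 morphs x 2 treatments) scenario:
#' per-cell sample sizes and trait means/SDs from the published trait
#' summary; hand-pollination mean fitness and pollen limitation derived from
#' the published fitness summary (PL = 1 - mean_C/mean_HP, unrounded);
#' standardized-scale gradients beta_C and beta_HP = beta_C - delta from the
#' encoded result pattern. Trait correlations default to 0.2 between the two
#' corolla dimensions and 0.3 between height and flower number; fitness
#' noise is multiplicative-scale normal with coefficient of variation 0.5.
#'
#' @param fitness_noise_cv Coefficient of variation of the fitness noise.
#' @return A `sim_config` list with one `cells` entry per
#'   population.morph.treatment stratum.
#' @export
default_config <- function(fitness_noise_cv = 0.5) {
  traits <- floral_traits()
  ts <- published_trait_summary()
  fs <- published_fitness_summary()
  grad <- gradient_scenario()
  pops <- unique(fs$population)
  cells <- list()
  for (pop in pops) for (mo in morph_levels()) {
    f <- fs[fs$population == pop & fs$morph == mo, ]
    g <- grad[grad$population == pop & grad$morph == mo, ]
    beta_c <- stats::setNames(g$beta_C, g$trait)[traits]
    beta_hp <- beta_c - stats::setNames(g$delta, g$trait)[traits]
    pl <- 1 - f$fitness_C_mean / f$fitness_HP_mean
    for (tr_arm in treatment_levels()) {
      cell <- ts[ts$population == pop & ts$morph == mo & ts$treatment == tr_arm, ]
      cell <- cell[match(traits, cell$trait), ]
      key <- paste(pop, mo, tr_arm, sep = ".")
      cells[[key]] <- list(
        population = pop, morph = mo, treatment = tr_arm,
        n = cell$n[1],
        trait_means = stats::setNames(cell$mean, traits),
        trait_sds = stats::setNames(cell$sd, traits),
        trait_corr = default_trait_corr(),
        mean_fitness_HP = f$fitness_HP_mean,
        pl = pl,
        beta_C = beta_c, beta_HP = beta_hp,
        fitness_noise_cv = fitness_noise_cv,
        mean_seeds_per_fruit =
          if (tr_arm == "C") f$spf_C_mean else f$spf_HP_mean)
    }
  }
  structure(list(cells = cells, trait_names = traits,
                 population_levels = pops,
                 rounding = list(n_flowers = "integer_ge_1",
                                 flowering_onset = "0.1_day")),
            class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks each cell: positive n and SDs, symmetric positive-definite unit
#' diagonal trait correlation, pl < 1, positive hand-pollination mean
#' fitness, and the fitness-positivity margin 1 + 3 * sum(|beta|) > 0.
#'
#' @param config A `sim_config`.
#' @return Invisibly `TRUE`; errors on the first violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (key in names(config$cells)) {
    cl <- config$cells[[key]]
    if (cl$n < 1) stop("cell ", key, ": n must be positive")
    if (any(cl$trait_sds <= 0)) stop("cell ", key, ": non-positive trait SD")
    R <- cl$trait_corr
    if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
      stop("cell ", key, ": trait_corr must be symmetric with unit diagonal")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("cell ", key, ": trait_corr is not positive-definite")
    }
    if (cl$pl >= 1) stop("cell ", key, ": pl must be < 1")
    if (cl$mean_fitness_HP <= 0) stop("cell ", key, ": mean_fitness_HP must be positive")
    beta <- if (cl$treatment == "C") cl$beta_C else cl$beta_HP
    if (1 + 3 * sum(abs(beta)) <= 0) stop("cell ", key, ": fitness margin violated")
  }
  invisible(TRUE)
}

#' Simulate a study cohort
#'
#' Per cell: traits are drawn from a multivariate normal with the configured
#' moments, clipped to be positive and rounded (flower number to an integer
#' >= 1, flowering onset to 0.1 day); within-cell z-scores are computed from
#' the realized (post-rounding) sample; fitness is
#' W = max(0, mu_W * (1 + sum(beta_i z_i)) + eps) with eps ~ N(0,
#' (cv * mu_W)^2), where mu_W = mean_fitness_HP * (1 - pl) in C cells and
#' mean_fitness_HP in HP cells, and beta is the arm's gradient vector.
#' Fruit production and seeds per fruit are decomposed so their product
#' equals W (fruits = min(n_flowers, max(1, round(W / target seeds per
#' fruit))); seeds_per_fruit = W / fruits). The fraction of fitness draws
#' clipped at zero is recorded in the `clip_rate` attribute.
#'
#' @param config A `sim_config`.
#' @param seed Integer RNG seed.
#' @param n_override Optional single n applied to every cell.
#' @return A `study_table` with attributes `seed` and `clip_rate`.
#' @export
simulate_cohort <- function(config, seed, n_override = NULL) {
  validate_config(config)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  traits <- config$trait_names
  n_clipped <- 0L
  n_total <- 0L
  rows <- lapply(names(config$cells), function(key) {
    cl <- config$cells[[key]]
    n <- if (is.null(n_override)) cl$n else n_override
    D <- diag(cl$trait_sds)
    Sigma <- D %*% cl$trait_corr %*% D
    Z <- MASS::mvrnorm(n, mu = cl$trait_means, Sigma = Sigma)
    colnames(Z) <- traits
    Z <- pmax(Z, 1e-3)
    Z[, "n_flowers"] <- pmax(1, round(Z[, "n_flowers"]))
    Z[, "flowering_onset"] <- round(Z[, "flowering_onset"], 1)
    zstd <- scale(Z)
    beta <- if (cl$treatment == "C") cl$beta_C else cl$beta_HP
    mu <- cl$mean_fitness_HP * if (cl$treatment == "C") (1 - cl$pl) else 1
    raw <- mu * (1 + drop(zstd %*% beta)) +
      stats::rnorm(n, 0, cl$fitness_noise_cv * mu)
    n_clipped <<- n_clipped + sum(raw < 0)
    n_total <<- n_total + n
    W <- pmax(0, raw)
    fruits <- ifelse(W > 0,
                     pmin(Z[, "n_flowers"],
                          pmax(1, round(W / cl$mean_seeds_per_fruit))),
                     0)
    spf <- ifelse(fruits > 0, W / fruits, 0)
    data.frame(
      individual_id = sprintf("%s-%s-%s-%04d", cl$population, cl$morph,
                              cl$treatment, seq_len(n)),
      population = cl$population, morph = cl$morph, treatment = cl$treatment,
      flowering_onset = Z[, "flowering_onset"],
      plant_height = Z[, "plant_height"],
      n_flowers = Z[, "n_flowers"],
      corolla_tube_length = Z[, "corolla_tube_length"],
      corolla_tube_width = Z[, "corolla_tube_width"],
      fruit_production = fruits, seeds_per_fruit = spf,
      female_fitness = W, stringsAsFactors = FALSE)
  })
  out <- study_table(do.call(rbind, rows),
                     population_levels = config$population_levels)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "clip_rate") <- n_clipped / n_total
  out
}

#' Configured truth aligned to the estimator's output keys
#'
#' One row per (population, morph, trait) with the configured beta_C,
#' beta_HP, their difference (the pollinator-mediated component), the
#' group's pollen limitation and hand-pollination mean fitness, plus the
#' configured per-arm trait means/SDs in wide columns.
#'
#' @param config A `sim_config`.
#' @return Data frame of configured truths.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  traits <- config$trait_names
  keys <- names(config$cells)
  pm <- unique(do.call(rbind, lapply(config$cells, function(cl)
    data.frame(population = cl$population, morph = cl$morph,
               stringsAsFactors = FALSE))))
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    pop <- pm$population[i]; mo <- pm$morph[i]
    cl_c <- config$cells[[paste(pop, mo, "C", sep = ".")]]
    cl_h <- config$cells[[paste(pop, mo, "HP", sep = ".")]]
    if (is.null(cl_c) || is.null(cl_h)) {
      return(NULL)
    }
    data.frame(population = pop, morph = mo, trait = traits,
               beta_C = unname(cl_c$beta_C[traits]),
               beta_HP = unname(cl_c$beta_HP[traits]),
               delta_beta = unname(cl_c$beta_C[traits] - cl_c$beta_HP[traits]),
               pl = cl_c$pl, mean_fitness_HP = cl_c$mean_fitness_HP,
               mean_C = unname(cl_c$trait_means[traits]),
               sd_C = unname(cl_c$trait_sds[traits]),
               mean_HP = unname(cl_h$trait_means[traits]),
               sd_HP = unname(cl_h$trait_sds[traits]),
               n_C = cl_c$n, n_HP = cl_h$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Override every cell's sample size
#'
#' @param config A `sim_config`.
#' @param n New per-cell sample size.
#' @return The modified `sim_config`.
#' @export
override_cell_n <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  for (key in names(config$cells)) config$cells[[key]]$n <- n
  config
}

#' Remove the pollinator-mediated component from a scenario
#'
#' Sets beta_HP = beta_C in every cell (pollen limitation is kept), giving
#' a null scenario for calibrating the trait x pollination tests.
#'
#' @param config A `sim_config`.
#' @return The modified `sim_config`.
#' @export
equalize_gradients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (key in names(config$cells)) {
    config$cells[[key]]$beta_HP <- config$cells[[key]]$beta_C
  }
  config
}

#' Serialize / restore a simulation configuration as JSON
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- as.character(raw$trait_names)
  cells <- lapply(raw$cells, function(cl) {
    R <- as.matrix(cl$trait_corr)
    dimnames(R) <- list(traits, traits)
    list(population = as.character(cl$population),
         morph = as.character(cl$morph),
         treatment = as.character(cl$treatment),
         n = as.numeric(cl$n),
         trait_means = stats::setNames(as.numeric(unlist(cl$trait_means)), traits),
         trait_sds = stats::setNames(as.numeric(unlist(cl$trait_sds)), traits),
         trait_corr = R,
         mean_fitness_HP = as.numeric(cl$mean_fitness_HP),
         pl = as.numeric(cl$pl),
         beta_C = stats::setNames(as.numeric(unlist(cl$beta_C)), traits),
         beta_HP = stats::setNames(as.numeric(unlist(cl$beta_HP)), traits),
         fitness_noise_cv = as.numeric(cl$fitness_noise_cv),
         mean_seeds_per_fruit = as.numeric(cl$mean_seeds_per_fruit))
  })
  structure(list(cells = cells, trait_names = traits,
                 population_levels = as.character(raw$population_levels),
                 rounding = raw$rounding),
            class = "sim_config")
}
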
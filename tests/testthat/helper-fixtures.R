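# Small in-code fixtures shared across test files.

# A valid random study table with every design cell populated.
tiny_table <- function(n_per_cell = 10, pops = c("P1", "P2"), seed = 1) {
  set.seed(seed)
  grid <- expand.grid(population = pops, morph = c("L", "S"),
                      treatment = c("C", "HP"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    n <- n_per_cell
    nf <- sample(5:20, n, replace = TRUE)
    data.frame(
      individual_id = paste(g$population, g$morph, g$treatment,
                            seq_len(n), sep = "-"),
      population = g$population, morph = g$morph, treatment = g$treatment,
      flowering_onset = round(runif(n, 150, 165), 1),
      plant_height = round(runif(n, 20, 50), 1),
      n_flowers = nf,
      corolla_tube_length = round(runif(n, 8, 11), 2),
      corolla_tube_width = round(runif(n, 2.5, 4), 2),
      fruit_production = pmin(nf, rpois(n, 5)),
      seeds_per_fruit = round(runif(n, 40, 110), 1),
      female_fitness = round(runif(n, 10, 1500), 1),
      stringsAsFactors = FALSE)
  })
  study_table(do.call(rbind, rows))
}

# One synthetic stratum with a known linear trait-fitness relation.
noiseless_group <- function(n = 40, beta = c(0.2, -0.1, 0.3, 0, 0.1),
                            mu = 500, seed = 3) {
  set.seed(seed)
  traits <- floral_traits()
  df <- data.frame(
    individual_id = paste0("id", seq_len(n)),
    population = "P1", morph = "L", treatment = "C",
    flowering_onset = runif(n, 150, 165),
    plant_height = runif(n, 20, 50),
    n_flowers = sample(5:25, n, replace = TRUE),
    corolla_tube_length = runif(n, 8, 11),
    corolla_tube_width = runif(n, 2.5, 4),
    fruit_production = 0L, seeds_per_fruit = 0,
    female_fitness = 0, stringsAsFactors = FALSE)
  z <- scale(as.matrix(df[traits]))
  df$female_fitness <- pmax(0, mu * (1 + drop(z %*% beta)))
  df$fruit_production <- pmin(df$n_flowers, 3L)
  df$seeds_per_fruit <- df$female_fitness / df$fruit_production
  study_table(df)
}

# A two-cell (single population x morph, both arms) scenario for
# pollen-limitation simulations, taken from the default scenario.
single_group_config <- function(pop = "BGTC1", mo = "L") {
  cfg <- default_config()
  keep <- paste(pop, mo, c("C", "HP"), sep = ".")
  cfg$cells <- cfg$cells[keep]
  cfg$population_levels <- pop
  cfg
}
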
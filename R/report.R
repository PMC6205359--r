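#' Three-tier significance annotation
#'
#' `"*"` for p < 0.05, `"(*)"` for 0.05 <= p < 0.1 (marginal), `"ns"`
#' otherwise — the annotation scheme used in the gradient figures.
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Ordered pair strictly inside (0, 1); default
#'   `c(0.05, 0.1)`.
#' @return Character vector of symbols.
#' @export
annotate_significance <- function(p, thresholds = c(0.05, 0.1)) {
  if (length(thresholds) != 2 || any(thresholds <= 0) ||
      any(thresholds >= 1) || thresholds[1] >= thresholds[2]) {
    stop("thresholds must be an increasing pair strictly inside (0, 1)")
  }
  ifelse(p < thresholds[1], "*",
         ifelse(p < thresholds[2], "(*)", "ns"))
}

#' Run the full selection analysis on a cohort
#'
#' One call producing every analysis artifact: the per-stratum gradient
#' table, ANCOVA Models A and B, the pollinator-mediated contrasts
#' (delta-beta) and the pollen-limitation report.
#'
#' @param table A `study_table`.
#' @param traits Ordered trait names.
#' @param n_boot Bootstrap iterations for pollen limitation.
#' @param seed Master seed for the stochastic stages.
#' @param test_type ANCOVA test type (`"marginal"` or `"sequential"`).
#' @return List with elements `gradients`, `model_a`, `model_b`,
#'   `delta_beta`, `pollen_limitation`, `seed`.
#' @export
analyze_cohort <- function(table, traits = floral_traits(), n_boot = 1000,
                           seed, test_type = "marginal") {
  stopifnot(inherits(table, "study_table"))
  if (missing(seed)) stop("a seed is required for the bootstrap stage")
  gradients <- estimate_gradients(table, traits)
  res <- list(
    gradients = gradients,
    model_a = ancova_model_a(table, traits, test_type = test_type),
    model_b = ancova_model_b(table, traits, test_type = test_type),
    delta_beta = delta_beta(gradients, table, traits),
    pollen_limitation = pollen_limitation_report(table, n_boot = n_boot,
                                                 seed = seed),
    seed = as.integer(seed))
  class(res) <- "primsel_analysis"
  res
}

#' Publication-style gradient table
#'
#' Per stratum and trait: beta formatted as estimate +/- SE with the
#' three-tier significance symbol.
#'
#' @param gradients A `gradient_table`.
#' @param digits Decimals for the estimates.
#' @return Data frame: population, morph, treatment, trait, n, estimate,
#'   annotation.
#' @export
format_gradient_table <- function(gradients, digits = 3) {
  data.frame(
    population = gradients$population, morph = gradients$morph,
    treatment = gradients$treatment, trait = gradients$trait,
    n = gradients$n,
    estimate = sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                       gradients$beta, gradients$se),
    annotation = annotate_significance(gradients$p),
    stringsAsFactors = FALSE)
}

#' Publication-style pollen limitation table
#'
#' One row per population x morph: PL with its bootstrap CI, matching the
#' layout of the study's reproductive-performance table.
#'
#' @param pl_table A `pollen_limitation_table`.
#' @param digits Decimals (default 3, the published precision).
#' @return Data frame.
#' @export
format_pl_table <- function(pl_table, digits = 3) {
  data.frame(
    morph = pl_table$morph, population = pl_table$population,
    n_C = pl_table$n_C, n_HP = pl_table$n_HP,
    pl = round(pl_table$pl, digits),
    ci = sprintf(paste0("(%.", digits, "f, %.", digits, "f)"),
                 pl_table$ci_low, pl_table$ci_high),
    stringsAsFactors = FALSE)
}

#' Write the analysis artifacts to a directory
#'
#' Emits each artifact as TSV and JSON with deterministic content (the
#' bootstrap seeds are recorded in the pollen-limitation table), so a rerun
#' with identical inputs and seeds is byte-identical.
#'
#' @param analysis Result of [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "primsel_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list(
    gradients = as.data.frame(analysis$gradients),
    model_a = as.data.frame(analysis$model_a),
    model_b = as.data.frame(analysis$model_b),
    delta_beta = as.data.frame(analysis$delta_beta),
    pollen_limitation = as.data.frame(analysis$pollen_limitation))
  paths <- character(0)
  for (name in names(artifacts)) {
    tsv <- file.path(dir, paste0(name, ".tsv"))
    json <- file.path(dir, paste0(name, ".json"))
    utils::write.table(artifacts[[name]], tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(artifacts[[name]], json, digits = NA, pretty = TRUE)
    paths <- c(paths, tsv, json)
  }
  summary <- file.path(dir, "summary.md")
  con <- file(summary, "w")
  on.exit(close(con))
  writeLines(c(
    "# Selection analysis summary",
    "",
    paste0("Master seed: ", analysis$seed),
    "",
    "## Pollen limitation (per population x morph)",
    "",
    knit_simple_table(format_pl_table(analysis$pollen_limitation)),
    "",
    "## Directional selection gradients (beta ± SE)",
    "",
    knit_simple_table(format_gradient_table(analysis$gradients)),
    "",
    "## Pollinator-mediated selection (delta-beta = beta_C - beta_HP)",
    "",
    knit_simple_table(data.frame(
      population = analysis$delta_beta$population,
      morph = analysis$delta_beta$morph,
      trait = analysis$delta_beta$trait,
      delta_beta = round(analysis$delta_beta$delta_beta, 3),
      annotation = annotate_significance(analysis$delta_beta$p),
      stringsAsFactors = FALSE))), con)
  invisible(c(paths, summary))
}

## Minimal markdown table renderer (no external dependency).
knit_simple_table <- function(df) {
  cells <- rbind(names(df), apply(df, 2, as.character))
  widths <- apply(nchar(cells), 2, max)
  pad <- function(row) paste0(
    "| ", paste(mapply(formatC, row, width = widths), collapse = " | "), " |")
  c(pad(cells[1, ]),
    paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|"),
    apply(cells[-1, , drop = FALSE], 1, pad))
}
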
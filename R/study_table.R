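#' Canonical analysis columns of a study table
#'
#' Column order used by [read_study_table()] and [write_study_table()]:
#' one row per marked plant, with the experimental design factors
#' (population, floral morph L/S, pollination treatment C = open pollination
#' vs HP = supplemental hand pollination), the five floral traits, and the
#' female-fitness components (fruit production, mean seeds per fruit, total
#' seed production).
#'
#' @return Character vector of canonical column names.
#' @export
study_table_columns <- function() {
  c("individual_id", "population", "morph", "treatment",
    "flowering_onset", "plant_height", "n_flowers",
    "corolla_tube_length", "corolla_tube_width",
    "fruit_production", "seeds_per_fruit", "female_fitness")
}

#' The five floral traits under selection
#'
#' Flowering onset (Julian day), plant height (cm), number of flowers,
#' corolla tube length (mm) and corolla tube width (mm), in the fixed order
#' used throughout the package.
#'
#' @return Character vector of five trait column names.
#' @export
floral_traits <- function() {
  c("flowering_onset", "plant_height", "n_flowers",
    "corolla_tube_length", "corolla_tube_width")
}

morph_levels <- function() c("L", "S")
treatment_levels <- function() c("C", "HP")

#' Construct a validated study table
#'
#' Validates a data frame of individual plant records against the design
#' invariants (morph in {L, S}, treatment in {C, HP}, strictly positive finite
#' traits, non-negative fitness, fruit production no larger than flower
#' number, unique individual ids) and attaches factor-level registries.
#' Rows with missing values in any analysis column are dropped with a
#' message; rows with invalid values raise an error citing the offending
#' rows.
#'
#' @param df Data frame containing at least [study_table_columns()].
#' @param population_levels Optional character vector fixing the population
#'   level order (reference level first). Defaults to first-appearance order.
#' @return A `study_table` (data frame subclass) with attributes
#'   `population_levels`, `morph_levels`, `treatment_levels`, `n_dropped`.
#' @export
study_table <- function(df, population_levels = NULL) {
  cols <- study_table_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("study table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[cols]
  if (nrow(df) == 0) stop("study table is empty")

  for (col in c("individual_id", "population", "morph", "treatment")) {
    df[[col]] <- as.character(df[[col]])
  }

  ## attrition handling: incomplete records are unusable in any analysis
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("study_table: dropped ", n_dropped, " row(s) with missing values")
    df <- df[complete, , drop = FALSE]
    if (nrow(df) == 0) stop("study table is empty after dropping incomplete rows")
  }

  problems <- character(0)
  bad <- function(idx, what) {
    if (any(idx)) {
      problems <<- c(problems, paste0(
        what, " in row(s) ", paste(utils::head(which(idx), 5), collapse = ", "),
        if (sum(idx) > 5) paste0(" (and ", sum(idx) - 5, " more)") else ""))
    }
  }
  bad(!df$morph %in% morph_levels(), "morph not in {L, S}")
  bad(!df$treatment %in% treatment_levels(), "treatment not in {C, HP}")
  for (tr in floral_traits()) {
    bad(!is.finite(df[[tr]]) | df[[tr]] <= 0, paste0("non-positive ", tr))
  }
  bad(!is.finite(df$female_fitness) | df$female_fitness < 0,
      "negative female_fitness")
  bad(!is.finite(df$fruit_production) | df$fruit_production < 0 |
        df$fruit_production != round(df$fruit_production),
      "fruit_production not a non-negative integer")
  bad(df$n_flowers != round(df$n_flowers), "non-integer n_flowers")
  bad(df$fruit_production > df$n_flowers, "fruit_production > n_flowers")
  bad(!is.finite(df$seeds_per_fruit) | df$seeds_per_fruit < 0,
      "negative seeds_per_fruit")
  bad(duplicated(df$individual_id), "duplicate individual_id")
  if (length(problems) > 0) {
    stop("invalid study table:\n  ", paste(problems, collapse = "\n  "))
  }

  seen <- unique(df$population)
  if (is.null(population_levels)) {
    population_levels <- seen
  } else if (!all(seen %in% population_levels)) {
    stop("unregistered population level(s): ",
         paste(setdiff(seen, population_levels), collapse = ", "))
  }

  rownames(df) <- NULL
  structure(df,
            population_levels = population_levels,
            morph_levels = morph_levels(),
            treatment_levels = treatment_levels(),
            n_dropped = n_dropped,
            class = c("study_table", "data.frame"))
}

#' Read a study table from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), for files whose
#'   headers differ from [study_table_columns()].
#' @param population_levels Passed to [study_table()].
#' @return A validated `study_table`.
#' @export
read_study_table <- function(path, schema = NULL, population_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty study table file: ", path)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      stop("schema maps to column(s) absent from file: ",
           paste(missing_src, collapse = ", "))
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(study_table_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(study_table_columns(),
                      c("individual_id", "population", "morph", "treatment"))
  for (col in num_cols) {
    if (!is.numeric(raw[[col]])) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(parsed) & !is.na(raw[[col]]) &
                     trimws(raw[[col]]) != "" & raw[[col]] != "NA")
      if (length(bad) > 0) {
        stop("non-numeric value in column '", col, "' at data row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      raw[[col]] <- parsed
    }
  }
  study_table(raw, population_levels = population_levels)
}

#' Write a study table to CSV
#'
#' Writes the canonical columns with full-precision numeric formatting
#' (`%.17g`), so that a read/write round trip reproduces every field
#' bit-for-bit.
#'
#' @param table A `study_table`.
#' @param path Output file path.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  if (nrow(table) == 0) stop("refusing to write an empty study table")
  out <- as.data.frame(table)[study_table_columns()]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratum labels for each record
#'
#' @param table A `study_table`.
#' @param full If `TRUE` (default) the stratum is population x morph x
#'   treatment (the standardization unit); otherwise population x morph.
#' @return Character vector of group labels like `"BGTC1.L.C"`.
#' @export
group_key <- function(table, full = TRUE) {
  if (full) paste(table$population, table$morph, table$treatment, sep = ".")
  else paste(table$population, table$morph, sep = ".")
}

#' Split a study table into its standardization strata
#'
#' @inheritParams group_key
#' @return Named list of data frames, one per stratum, in registry order.
#' @export
split_groups <- function(table, full = TRUE) {
  keys <- group_key(table, full = full)
  pops <- attr(table, "population_levels")
  if (full) {
    ordered <- as.vector(t(outer(
      pops, as.vector(outer(morph_levels(), treatment_levels(),
                            paste, sep = ".")), paste, sep = ".")))
  } else {
    ordered <- as.vector(t(outer(pops, morph_levels(), paste, sep = ".")))
  }
  present <- ordered[ordered %in% unique(keys)]
  lapply(stats::setNames(present, present),
         function(k) as.data.frame(table)[keys == k, , drop = FALSE])
}

#' Aggregate flower-level corolla measurements to individuals
#'
#' Each individual's corolla tube length and width were measured on its first
#' one to three open flowers; the per-individual trait is the unweighted mean
#' over the measured flowers. Non-corolla fields are untouched.
#'
#' @param flowers Data frame with columns `individual_id`, `flower_index`
#'   (1-3), `corolla_tube_length`, `corolla_tube_width`.
#' @param base A `study_table` whose corolla columns will be replaced.
#' @return A `study_table` with per-individual corolla means.
#' @export
aggregate_flowers <- function(flowers, base) {
  stopifnot(inherits(base, "study_table"))
  need <- c("individual_id", "flower_index",
            "corolla_tube_length", "corolla_tube_width")
  missing_cols <- setdiff(need, names(flowers))
  if (length(missing_cols) > 0) {
    stop("flower table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(flowers$flower_index < 1 | flowers$flower_index > 3)) {
    stop("flower_index must be between 1 and 3")
  }
  orphans <- setdiff(unique(flowers$individual_id), base$individual_id)
  if (length(orphans) > 0) {
    stop("flower rows reference unknown individual(s): ",
         paste(orphans, collapse = ", "))
  }
  len <- tapply(flowers$corolla_tube_length, flowers$individual_id, mean)
  wid <- tapply(flowers$corolla_tube_width, flowers$individual_id, mean)
  df <- as.data.frame(base)
  idx <- match(names(len), df$individual_id)
  df$corolla_tube_length[idx] <- as.numeric(len)
  df$corolla_tube_width[idx] <- as.numeric(wid)
  study_table(df, population_levels = attr(base, "population_levels"))
}
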
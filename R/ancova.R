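#' Prepare within-stratum standardized data for pooled models
#'
#' Computes relative fitness and z-scored traits separately within each
#' population x morph x treatment stratum (the standardization unit of the
#' selection analysis) and returns one pooled data frame carrying the design
#' factors alongside the standardized covariates.
#'
#' @param table A `study_table`.
#' @param traits Ordered trait names.
#' @return Data frame with columns `population`, `morph`, `treatment`, `w`,
#'   and one standardized column per trait.
#' @export
prepare_selection_data <- function(table, traits = floral_traits()) {
  stopifnot(inherits(table, "study_table"))
  groups <- split_groups(table, full = TRUE)
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    std <- standardize_group(g, traits, group = key)
    out <- data.frame(population = g$population, morph = g$morph,
                      treatment = g$treatment, w = std$w,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(std$z))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "population_levels") <- attr(table, "population_levels")
  out
}

## Expand one model term ("trait" or a factor name) into labelled columns.
## Treatment coding gives reference-level semantics (used by the ANCOVA
## models); sum-to-zero coding gives classical main-effect tests (used by
## the descriptive factorial ANOVA).
term_columns <- function(df, term, covariates, factors,
                         coding = c("treatment", "sum")) {
  coding <- match.arg(coding)
  if (term == "trait") {
    cols <- lapply(covariates, function(cv) df[[cv]])
    names(cols) <- covariates
    return(cols)
  }
  if (!term %in% names(factors)) stop("unknown model term: ", term)
  levs <- factors[[term]]
  present <- levs %in% unique(df[[term]])
  if (!all(present)) {
    message("build_design: dropping unused level(s) of ", term, ": ",
            paste(levs[!present], collapse = ", "))
    levs <- levs[present]
  }
  if (length(levs) < 2) {
    stop("factor '", term, "' has fewer than two observed levels")
  }
  if (coding == "treatment") {
    cols <- lapply(levs[-1], function(l) as.numeric(df[[term]] == l))
    names(cols) <- paste0(term, levs[-1])
  } else {
    last <- levs[length(levs)]
    cols <- lapply(levs[-length(levs)], function(l)
      as.numeric(df[[term]] == l) - as.numeric(df[[term]] == last))
    names(cols) <- paste0(term, levs[-length(levs)])
  }
  cols
}

#' Build a model design matrix from covariates, factors and term blocks
#'
#' Treatment (reference-level) coding for factors; interaction columns are
#' elementwise products of the constituent main-effect columns. The term
#' `"trait"` in a block expands over all covariates. Column labels are
#' deterministic (`cov:factorLevel:...`).
#'
#' @param df Data frame (typically from [prepare_selection_data()]).
#' @param covariates Character vector of covariate column names.
#' @param factors Named list of factor level vectors (reference level first).
#' @param blocks Named list; each element is a character vector of terms
#'   (`"trait"` and/or factor names) defining one block of columns.
#' @param coding Factor coding: `"treatment"` (reference level, default) or
#'   `"sum"` (sum-to-zero).
#' @return List with `X` (matrix, no intercept), `assign` (block name per
#'   column) and `blocks` (the block definitions).
#' @export
build_design <- function(df, covariates, factors, blocks,
                         coding = "treatment") {
  all_cols <- list()
  assign <- character(0)
  for (bname in names(blocks)) {
    terms <- blocks[[bname]]
    parts <- lapply(terms, term_columns, df = df,
                    covariates = covariates, factors = factors,
                    coding = coding)
    idx <- expand.grid(lapply(parts, seq_along), KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(idx))) {
      vecs <- mapply(function(part, i) part[[i]], parts, as.numeric(idx[r, ]),
                     SIMPLIFY = FALSE)
      labs <- mapply(function(part, i) names(part)[i], parts,
                     as.numeric(idx[r, ]))
      col <- Reduce(`*`, vecs)
      lab <- paste(labs, collapse = ":")
      all_cols[[lab]] <- col
      assign <- c(assign, bname)
    }
  }
  X <- do.call(cbind, all_cols)
  colnames(X) <- names(all_cols)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    aliased <- c("(Intercept)", colnames(X))[qx$pivot[(qx$rank + 1):(ncol(X) + 1)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, assign = assign, blocks = blocks)
}

#' Nested-model F test
#'
#' F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f), with the p-value
#' from the F distribution on (df_r - df_f, df_f). Identical models give
#' F = 0, p = 1.
#'
#' @param full,reduced `linear_fit` objects on the same rows, with the
#'   reduced model's columns a subset of the full model's.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
test_block <- function(full, reduced) {
  stopifnot(inherits(full, "linear_fit"), inherits(reduced, "linear_fit"))
  if (full$n != reduced$n) stop("models fitted on different rows")
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested: reduced model has terms absent from full")
  }
  df1 <- reduced$df_residual - full$df_residual
  if (df1 == 0) return(list(F = 0, df1 = 0L, df2 = full$df_residual, p = 1))
  if (df1 < 0) stop("models are not nested: reduced has more parameters")
  num <- max(0, (reduced$rss - full$rss) / df1)
  F <- if (num == 0) 0 else num / (full$rss / full$df_residual)
  list(F = F, df1 = as.integer(df1), df2 = as.integer(full$df_residual),
       p = stats::pf(F, df1, full$df_residual, lower.tail = FALSE))
}

## Marginal (drop-one-block) or sequential (add-one-block) F table.
anova_block_table <- function(w, design, test_type = c("marginal", "sequential")) {
  test_type <- match.arg(test_type)
  full <- fit_ols(w, design$X)
  bnames <- names(design$blocks)
  rows <- list()
  if (test_type == "marginal") {
    for (b in bnames) {
      keep <- design$assign != b
      reduced <- fit_ols(w, design$X[, keep, drop = FALSE])
      tb <- test_block(full, reduced)
      rows[[b]] <- data.frame(term = b, df1 = tb$df1, df2 = tb$df2,
                              F = tb$F, p = tb$p, stringsAsFactors = FALSE)
    }
  } else {
    prev <- fit_ols(w, matrix(numeric(0), nrow = length(w), ncol = 0))
    included <- rep(FALSE, ncol(design$X))
    for (b in bnames) {
      included <- included | design$assign == b
      cur <- fit_ols(w, design$X[, included, drop = FALSE])
      df1 <- prev$df_residual - cur$df_residual
      num <- max(0, (prev$rss - cur$rss) / df1)
      F <- if (num == 0) 0 else num / (full$rss / full$df_residual)
      rows[[b]] <- data.frame(term = b, df1 = as.integer(df1),
                              df2 = full$df_residual, F = F,
                              p = stats::pf(F, df1, full$df_residual,
                                            lower.tail = FALSE),
                              stringsAsFactors = FALSE)
      prev <- cur
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fit = full, design = design,
            rss = full$rss, df_residual = full$df_residual,
            class = c("anova_result", "data.frame"))
}

## Per-trait tests of one interaction block: F test of the columns of that
## block that involve the given covariate, against the full model.
per_trait_tests <- function(anova_res, covariates, block) {
  design <- attr(anova_res, "design")
  full <- attr(anova_res, "fit")
  w_len <- full$n
  rows <- list()
  for (cv in covariates) {
    in_block <- design$assign == block
    lab <- colnames(design$X)
    involves <- startsWith(lab, paste0(cv, ":")) | lab == cv
    drop <- in_block & involves
    if (!any(drop)) next
    reduced_X <- design$X[, !drop, drop = FALSE]
    reduced <- fit_ols(attr_full_response(full), reduced_X)
    tb <- test_block(full, reduced)
    rows[[cv]] <- data.frame(term = paste0(block, "[", cv, "]"),
                             df1 = tb$df1, df2 = tb$df2, F = tb$F, p = tb$p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## Reconstruct the response from a linear_fit (fitted + residuals).
attr_full_response <- function(fit) fit$fitted + fit$residuals

#' ANCOVA Model A: variation in net directional selection
#'
#' Open-pollination (C) data only. Relative fitness is modelled on the five
#' standardized traits, population, morph, and the trait x population,
#' trait x morph and trait x population x morph interactions. A significant
#' trait x population block indicates net directional selection varies among
#' populations; trait x morph, between morphs. Block F tests are marginal
#' (drop one block from the full model); per-trait single-trait tests within
#' each interaction block are appended.
#'
#' @param table A `study_table` (rows with treatment C are used).
#' @param traits Ordered trait names.
#' @param test_type `"marginal"` (default) or `"sequential"`.
#' @return An `anova_result` data frame: term, df1, df2, F, p.
#' @export
ancova_model_a <- function(table, traits = floral_traits(),
                           test_type = "marginal") {
  stopifnot(inherits(table, "study_table"))
  tab_c <- as.data.frame(table)[table$treatment == "C", , drop = FALSE]
  if (nrow(tab_c) == 0) stop("no open-pollination (C) rows")
  tab_c <- study_table(tab_c,
                       population_levels = attr(table, "population_levels"))
  cells <- table(tab_c$population, tab_c$morph)
  if (length(unique(tab_c$population)) < 2 || length(unique(tab_c$morph)) < 2) {
    stop("Model A needs at least two populations and both morphs")
  }
  if (any(cells < 8)) stop("population x morph cell(s) too small for Model A")
  df <- prepare_selection_data(tab_c, traits)
  factors <- list(population = attr(df, "population_levels"),
                  morph = morph_levels())
  blocks <- list(
    trait = "trait",
    population = "population",
    morph = "morph",
    `trait:population` = c("trait", "population"),
    `trait:morph` = c("trait", "morph"),
    `trait:population:morph` = c("trait", "population", "morph"))
  design <- build_design(df, traits, factors, blocks)
  res <- anova_block_table(df$w, design, test_type)
  extra <- do.call(rbind, lapply(
    c("trait:population", "trait:morph", "trait:population:morph"),
    function(b) per_trait_tests(res, traits, b)))
  out <- rbind(as.data.frame(res), extra)
  rownames(out) <- NULL
  structure(out, fit = attr(res, "fit"), design = design,
            rss = attr(res, "rss"), df_residual = attr(res, "df_residual"),
            class = c("anova_result", "data.frame"))
}

#' ANCOVA Model B: variation in pollinator-mediated selection
#'
#' Both pollination treatments. Model A's terms plus pollination (C vs HP,
#' HP as the reference level) and all its trait interactions up to
#' trait x population x morph x pollination. A significant
#' trait x population x pollination block indicates pollinator-mediated
#' selection varies among populations; trait x morph x pollination, between
#' morphs.
#'
#' @inheritParams ancova_model_a
#' @return An `anova_result` data frame.
#' @export
ancova_model_b <- function(table, traits = floral_traits(),
                           test_type = "marginal") {
  stopifnot(inherits(table, "study_table"))
  arms <- table(paste(table$population, table$morph), table$treatment)
  if (!all(c("C", "HP") %in% colnames(arms)) || any(arms < 8)) {
    stop("Model B needs both treatments (>= 8 records) in every population x morph cell")
  }
  df <- prepare_selection_data(table, traits)
  factors <- list(population = attr(df, "population_levels"),
                  morph = morph_levels(),
                  treatment = c("HP", "C"))
  blocks <- list(
    trait = "trait",
    population = "population",
    morph = "morph",
    pollination = "treatment",
    `trait:population` = c("trait", "population"),
    `trait:morph` = c("trait", "morph"),
    `trait:pollination` = c("trait", "treatment"),
    `trait:population:morph` = c("trait", "population", "morph"),
    `trait:population:pollination` = c("trait", "population", "treatment"),
    `trait:morph:pollination` = c("trait", "morph", "treatment"),
    `trait:population:morph:pollination` =
      c("trait", "population", "morph", "treatment"))
  design <- build_design(df, traits, factors, blocks)
  res <- anova_block_table(df$w, design, test_type)
  extra <- do.call(rbind, lapply(
    c("trait:pollination", "trait:population:pollination",
      "trait:morph:pollination"),
    function(b) per_trait_tests(res, traits, b)))
  out <- rbind(as.data.frame(res), extra)
  rownames(out) <- NULL
  structure(out, fit = attr(res, "fit"), design = design,
            rss = attr(res, "rss"), df_residual = attr(res, "df_residual"),
            class = c("anova_result", "data.frame"))
}

#' Pollinator-mediated selection contrast per population and morph
#'
#' Delta-beta = beta_C - beta_HP per trait, with the p-value of the
#' trait x pollination interaction from a per-(population, morph) model in
#' which every term is interacted with treatment (HP reference, so the
#' interaction coefficient equals beta_C - beta_HP exactly under the
#' within-treatment standardization). `delta_model`, the fitted interaction
#' coefficient, is reported alongside the subtraction as a numerical
#' cross-check of that identity.
#'
#' @param gradients A `gradient_table` from [estimate_gradients()].
#' @param table The `study_table` the gradients came from.
#' @param traits Ordered trait names.
#' @return A `delta_beta_table` data frame: population, morph, trait,
#'   beta_C, beta_HP, delta_beta, delta_model, p, n_C, n_HP.
#' @export
delta_beta <- function(gradients, table, traits = floral_traits()) {
  stopifnot(inherits(table, "study_table"))
  groups <- split_groups(table, full = FALSE)
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    pop <- g$population[1]; mo <- g$morph[1]
    for (arm in c("C", "HP")) {
      has <- any(gradients$population == pop & gradients$morph == mo &
                   gradients$treatment == arm)
      if (!has || !any(g$treatment == arm)) {
        stop("missing ", arm, " arm for group ", key)
      }
    }
    gc <- gradients[gradients$population == pop & gradients$morph == mo &
                      gradients$treatment == "C", ]
    gh <- gradients[gradients$population == pop & gradients$morph == mo &
                      gradients$treatment == "HP", ]
    beta_c <- stats::setNames(gc$beta, gc$trait)[traits]
    beta_h <- stats::setNames(gh$beta, gh$trait)[traits]

    ## fully treatment-interacted model on within-arm standardized data
    parts <- lapply(c("HP", "C"), function(arm) {
      sub <- g[g$treatment == arm, , drop = FALSE]
      std <- standardize_group(sub, traits, group = paste(key, arm, sep = "."))
      cbind(data.frame(w = std$w, is_c = as.numeric(arm == "C")),
            as.data.frame(std$z))
    })
    dat <- do.call(rbind, parts)
    zc <- as.matrix(dat[traits]) * dat$is_c
    colnames(zc) <- paste0(traits, ":C")
    X <- cbind(as.matrix(dat[traits]), `pollinationC` = dat$is_c, zc)
    fit <- fit_ols(dat$w, X)
    inter <- fit$coefficients[paste0(traits, ":C")]
    pint <- fit$p[paste0(traits, ":C")]
    data.frame(population = pop, morph = mo, trait = traits,
               beta_C = unname(beta_c), beta_HP = unname(beta_h),
               delta_beta = unname(beta_c - beta_h),
               delta_model = unname(inter), p = unname(pint),
               n_C = sum(g$treatment == "C"), n_HP = sum(g$treatment == "HP"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delta_beta_table", "data.frame")
  out
}

#' Factorial ANOVA on (optionally log10-transformed) responses
#'
#' Full-factorial fixed-effects ANOVA over the listed design factors, used
#' descriptively for trait and fitness differences among populations, morphs
#' and treatments. Block F tests are marginal by default (sequential
#' available); the one-factor case reduces to a one-way ANOVA.
#'
#' @param table Data frame (e.g. a `study_table`).
#' @param response Response column name.
#' @param factors Character vector of factor column names.
#' @param log10_transform Apply log10(x + offset) to the response.
#' @param offset Added before the log; required > -min(x) when transforming
#'   a response with zeros (e.g. fitness of fruitless plants).
#' @param test_type `"marginal"` (default) or `"sequential"`.
#' @return An `anova_result` data frame.
#' @export
factorial_anova <- function(table, response, factors,
                            log10_transform = FALSE, offset = 0,
                            test_type = "marginal") {
  df <- as.data.frame(table)
  y <- df[[response]]
  if (is.null(y)) stop("unknown response column: ", response)
  if (log10_transform) {
    if (any(y + offset <= 0)) {
      stop("response has values <= 0 after offset ", offset,
           "; supply a positive offset for log10 transform")
    }
    y <- log10(y + offset)
  }
  flevels <- lapply(stats::setNames(factors, factors),
                    function(f) unique(as.character(df[[f]])))
  blocks <- list()
  for (k in seq_along(factors)) {
    combos <- utils::combn(factors, k, simplify = FALSE)
    for (cb in combos) blocks[[paste(cb, collapse = ":")]] <- cb
  }
  design <- build_design(df, covariates = character(0),
                         factors = flevels, blocks = blocks, coding = "sum")
  anova_block_table(y, design, test_type)
}

#' Proportion of net selection explained by pollinators
#'
#' 100 * delta_beta / beta_C, the share of the open-pollination gradient
#' attributable to pollinator-mediated selection. Undefined (NA) when
#' beta_C is zero.
#'
#' @param delta Either a `delta_beta_table` or a numeric vector of
#'   delta-beta values.
#' @param gradients Ignored for tables (beta_C is taken from `delta`);
#'   for numeric `delta`, the matching beta_C values.
#' @param digits Rounding of the reported percentage (default 1).
#' @return Numeric vector of percentages.
#' @export
proportion_explained <- function(delta, gradients = NULL, digits = 1) {
  if (inherits(delta, "delta_beta_table")) {
    d <- delta$delta_beta
    b <- delta$beta_C
  } else {
    d <- as.numeric(delta)
    b <- as.numeric(gradients)
    if (length(b) != length(d)) stop("delta and beta_C lengths differ")
  }
  out <- ifelse(b == 0, NA_real_, 100 * d / b)
  round(out, digits)
}
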
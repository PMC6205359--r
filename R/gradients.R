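#' Standardize traits and relativize fitness within one stratum
#'
#' Following the Lande-Arnold convention, traits are z-scored (mean 0,
#' sample variance 1, n-1 divisor) and fitness divided by its stratum mean,
#' separately within each population x morph x treatment stratum. Relative
#' fitness uses the untransformed fitness values.
#'
#' @param records Data frame of records from a single stratum.
#' @param traits Ordered trait names; default [floral_traits()].
#' @param group Optional stratum label used in error messages.
#' @return List with `z` (n x length(traits) matrix), `w` (relative fitness),
#'   `trait_names`, `n`, `group`.
#' @export
standardize_group <- function(records, traits = floral_traits(), group = NULL) {
  if (is.null(group)) {
    group <- paste(unique(paste(records$population, records$morph,
                                records$treatment, sep = ".")),
                   collapse = "+")
  }
  n <- nrow(records)
  if (n < length(traits) + 2) {
    stop("stratum ", group, ": only ", n, " records; need at least ",
         length(traits) + 2)
  }
  z <- matrix(NA_real_, n, length(traits),
              dimnames = list(NULL, traits))
  for (tr in traits) {
    x <- records[[tr]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("stratum ", group, ": trait '", tr, "' has zero variance")
    }
    z[, tr] <- (x - mean(x)) / s
  }
  mw <- mean(records$female_fitness)
  if (!is.finite(mw) || mw <= 0) {
    stop("stratum ", group, ": mean fitness is not positive")
  }
  list(z = z, w = records$female_fitness / mw,
       trait_names = traits, n = n, group = group)
}

#' Ordinary least squares with coefficient inference
#'
#' QR-based least-squares fit of `w` on `z` plus an intercept. Standard
#' errors come from the residual variance (RSS / residual df) times the
#' diagonal of the inverse cross-product matrix; p-values are two-sided
#' from the t distribution on the residual df.
#'
#' @param w Response vector (relative fitness).
#' @param z Predictor matrix with column names (standardized traits and,
#'   optionally, design columns).
#' @return A `linear_fit` list: `coefficients`, `se`, `t`, `p`, `rss`,
#'   `df_residual`, `r_squared`, `n`, `fitted`, `residuals`.
#' @export
fit_ols <- function(w, z) {
  z <- as.matrix(z)
  n <- length(w)
  if (nrow(z) != n) stop("response and predictors have different lengths")
  if (ncol(z) > 0 && is.null(colnames(z))) {
    colnames(z) <- paste0("x", seq_len(ncol(z)))
  }
  X <- cbind(`(Intercept)` = 1, z)
  p <- ncol(X)
  if (n <= p) {
    stop("insufficient data: n = ", n, " rows for ", p, " parameters")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("singular design: aliased column(s) ",
         paste(aliased, collapse = ", "))
  }
  coef <- qr.coef(qx, w)
  fitted <- drop(X %*% coef)
  res <- w - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  xtx_inv <- chol2inv(R)
  se <- stats::setNames(sqrt(pmax(diag(xtx_inv), 0) * sigma2), colnames(X))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((w - mean(w))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(list(coefficients = coef, se = se, t = tval, p = pval,
                 rss = rss, df_residual = df,
                 r_squared = max(0, min(1, r2)), n = n,
                 fitted = fitted, residuals = res,
                 terms = colnames(X)),
            class = "linear_fit")
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing column j on all other
#' columns plus an intercept. Perfectly collinear columns get `Inf` rather
#' than an error.
#'
#' @param z Predictor matrix with at least two columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2) stop("vif needs at least two predictor columns")
  if (nrow(z) <= ncol(z) + 1) stop("vif needs n > columns + 1")
  out <- stats::setNames(numeric(ncol(z)), colnames(z))
  for (j in seq_len(ncol(z))) {
    y <- z[, j]
    X <- cbind(1, z[, -j, drop = FALSE])
    qx <- qr(X)
    res <- qr.resid(qx, y)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  pmax(out, 1)
}

#' Estimate directional selection gradients per stratum
#'
#' Fits relative fitness on the standardized traits separately within each
#' population x morph x treatment stratum, giving the directional selection
#' gradient beta (per trait SD, relative-fitness scale) with SE, t, p and
#' VIF. With `include_cross_products = TRUE` all 10 pairwise products of
#' standardized traits are appended to estimate correlational selection
#' (gamma), the configuration under which the field data showed VIFs above
#' 10 and which is therefore not the default path.
#'
#' @param table A `study_table`.
#' @param traits Ordered trait names.
#' @param include_cross_products Add pairwise z_i * z_j product terms.
#' @return A `gradient_table` data frame: population, morph, treatment,
#'   trait, n, beta, se, t, p, vif.
#' @export
estimate_gradients <- function(table, traits = floral_traits(),
                               include_cross_products = FALSE) {
  stopifnot(inherits(table, "study_table"))
  groups <- split_groups(table, full = TRUE)
  small <- names(groups)[vapply(groups, nrow, 0L) < 8]
  if (length(small) > 0) {
    stop("stratum(s) with fewer than 8 records: ",
         paste(small, collapse = ", "))
  }
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    std <- tryCatch(standardize_group(g, traits, group = key),
                    error = function(e) stop(conditionMessage(e), call. = FALSE))
    z <- std$z
    if (include_cross_products) {
      pairs <- utils::combn(traits, 2)
      prod_mat <- apply(pairs, 2, function(pr) z[, pr[1]] * z[, pr[2]])
      colnames(prod_mat) <- apply(pairs, 2, paste, collapse = ":")
      z <- cbind(z, prod_mat)
    }
    fit <- fit_ols(std$w, z)
    v <- vif(z)
    terms <- colnames(z)
    data.frame(population = g$population[1], morph = g$morph[1],
               treatment = g$treatment[1], trait = terms,
               n = std$n,
               beta = unname(fit$coefficients[terms]),
               se = unname(fit$se[terms]),
               t = unname(fit$t[terms]),
               p = unname(fit$p[terms]),
               vif = unname(v[terms]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gradient_table", "data.frame")
  out
}
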
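#' Pollen limitation point estimate
#'
#' PL = 1 - mean(fitness under open pollination) / mean(fitness under
#' supplemental hand pollination): the proportional female-fitness deficit
#' attributable to inadequate pollen receipt. PL <= 1 always; PL = 0 when
#' the arms are identical on average.
#'
#' @param fitness_C Fitness vector of open-pollinated individuals.
#' @param fitness_HP Fitness vector of hand-pollinated individuals.
#' @return Scalar PL.
#' @export
pollen_limitation_point <- function(fitness_C, fitness_HP) {
  if (length(fitness_C) == 0 || length(fitness_HP) == 0) {
    stop("both treatment arms must be nonempty")
  }
  m_hp <- mean(fitness_HP)
  if (!is.finite(m_hp) || m_hp <= 0) {
    stop("pollen limitation undefined: hand-pollination mean fitness is not positive")
  }
  1 - mean(fitness_C) / m_hp
}

#' Bootstrap confidence interval for pollen limitation
#'
#' Individuals are resampled with replacement independently within each
#' treatment arm; PL is recomputed per iterate and the 95% interval taken
#' from the bootstrap distribution (percentile method by default, BCa
#' optionally). Iterates whose resampled hand-pollination mean is zero are
#' redrawn and counted. Deterministic under a fixed seed.
#'
#' @inheritParams pollen_limitation_point
#' @param n_boot Number of bootstrap iterations (>= 100; the field analysis
#'   used 1000).
#' @param seed Integer RNG seed, recorded in the result.
#' @param method `"percentile"` (default) or `"bca"`.
#' @param conf Confidence level (default 0.95).
#' @return A `pollen_limitation_estimate` list: `pl`, `ci_low`, `ci_high`,
#'   `n_C`, `n_HP`, `n_boot`, `seed`, `method`, `n_redrawn`.
#' @export
pollen_limitation_bootstrap <- function(fitness_C, fitness_HP,
                                        n_boot = 1000, seed,
                                        method = c("percentile", "bca"),
                                        conf = 0.95) {
  method <- match.arg(method)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (missing(seed)) stop("a seed is required for the bootstrap")
  pl <- pollen_limitation_point(fitness_C, fitness_HP)
  n_c <- length(fitness_C); n_h <- length(fitness_HP)
  set.seed(as.integer(seed))
  reps <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      mc <- mean(fitness_C[sample.int(n_c, n_c, replace = TRUE)])
      mh <- mean(fitness_HP[sample.int(n_h, n_h, replace = TRUE)])
      if (mh > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    reps[b] <- 1 - mc / mh
  }
  alpha <- (1 - conf) / 2
  if (method == "percentile") {
    ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  } else {
    ## BCa: bias correction from the bootstrap distribution, acceleration
    ## from a jackknife over both arms
    z0 <- stats::qnorm(mean(reps < pl) + 0.5 * mean(reps == pl))
    jack <- c(
      vapply(seq_len(n_c), function(i)
        pollen_limitation_point(fitness_C[-i], fitness_HP), 0),
      vapply(seq_len(n_h), function(i)
        pollen_limitation_point(fitness_C, fitness_HP[-i]), 0))
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * sum((jm - jack)^2)^1.5
    a <- if (den == 0) 0 else num / den
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    ci <- stats::quantile(reps, adj, names = FALSE)
  }
  structure(list(pl = pl, ci_low = ci[1], ci_high = ci[2],
                 n_C = n_c, n_HP = n_h, n_boot = n_boot,
                 seed = as.integer(seed), method = method,
                 n_redrawn = n_redrawn),
            class = "pollen_limitation_estimate")
}

#' Pollen limitation per population and morph
#'
#' One bootstrap PL estimate per population x morph group (both treatment
#' arms required), with per-group sub-seeds drawn deterministically from
#' the master seed.
#'
#' @param table A `study_table`.
#' @param n_boot Bootstrap iterations per group.
#' @param seed Master RNG seed.
#' @param method Interval method, see [pollen_limitation_bootstrap()].
#' @return Data frame (class `pollen_limitation_table`): population, morph,
#'   n_C, n_HP, pl, ci_low, ci_high, n_boot, seed, method.
#' @export
pollen_limitation_report <- function(table, n_boot = 1000, seed,
                                     method = "percentile") {
  stopifnot(inherits(table, "study_table"))
  if (missing(seed)) stop("a seed is required for the bootstrap")
  groups <- split_groups(table, full = FALSE)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
  rows <- mapply(function(g, key, sub_seed) {
    fc <- g$female_fitness[g$treatment == "C"]
    fh <- g$female_fitness[g$treatment == "HP"]
    if (length(fc) == 0 || length(fh) == 0) {
      stop("missing treatment arm in group ", key)
    }
    est <- pollen_limitation_bootstrap(fc, fh, n_boot = n_boot,
                                       seed = sub_seed, method = method)
    data.frame(population = g$population[1], morph = g$morph[1],
               n_C = est$n_C, n_HP = est$n_HP, pl = est$pl,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_boot = n_boot, seed = sub_seed, method = method,
               stringsAsFactors = FALSE)
  }, groups, names(groups), sub_seeds, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "master_seed") <- as.integer(seed)
  class(out) <- c("pollen_limitation_table", "data.frame")
  out
}
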
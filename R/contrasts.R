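# Island-contrast statistics on development-environment records:
# normality screen, Kruskal-Wallis omnibus, Dunn's post hoc test with
# Bonferroni correction, and Hedges' g with bootstrap confidence intervals.

#' Hedges' g standardized effect size
#'
#' Cohen's d on the pooled standard deviation, multiplied by the
#' small-sample correction `J = 1 - 3 / (4 (n1 + n2) - 9)`. Appropriate
#' when group sizes are small (<= 50). Undefined (NA, with a warning) when
#' both groups have zero variance.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A list with `g`, `d`, `J`, `pooled_sd`, `n1`, `n2`.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp == 0) {
    if (mean(x) == mean(y)) {
      d <- 0
    } else {
      warning("zero pooled variance with unequal means: g undefined")
      d <- NA_real_
    }
  } else {
    d <- (mean(x) - mean(y)) / sp
  }
  list(g = J * d, d = d, J = J, pooled_sd = sp, n1 = n1, n2 = n2)
}

#' Effect-size magnitude class
#'
#' Cohen's benchmark bands with exclusive lower bounds: negligible
#' (|g| < 0.2), small (< 0.5), medium (< 0.8), large (>= 0.8).
#'
#' @param g Hedges' g (vectorized).
#' @return Character vector of classes.
#' @export
magnitude_class <- function(g) {
  as.character(cut(abs(g), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
                   labels = c("negligible", "small", "medium", "large"),
                   right = FALSE))
}

#' Percentile bootstrap confidence interval for Hedges' g
#'
#' Resamples both groups with replacement, recomputes g, and returns the
#' percentile interval. Seeded for reproducibility.
#'
#' @param x,y Numeric samples.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return `c(lower, upper)`.
#' @export
hedges_g_ci <- function(x, y, n_boot = 2000, conf = 0.95, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gs <- vapply(seq_len(n_boot), function(b) {
    xb <- sample(x, replace = TRUE)
    yb <- sample(y, replace = TRUE)
    suppressWarnings(hedges_g(xb, yb)$g)
  }, numeric(1))
  unname(quantile(gs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE))
}

#' Dunn's post hoc test for all group pairs
#'
#' Rank-based pairwise z statistics following a Kruskal-Wallis omnibus,
#' with the usual tie correction and Bonferroni adjustment over all pairs:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor).
#' @return Data.frame with columns `group1`, `group2`, `z`, `p`,
#'   `p_bonferroni`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_bonferroni = pmin(p * ncol(pairs), 1), row.names = NULL)
}

#' Island contrasts of a development-environment variable
#'
#' The full assessment chain for one variable of the per-larva
#' development-environment table: a Lilliefors (Kolmogorov-Smirnov with
#' estimated parameters) normality screen per island, a tie-corrected
#' Kruskal-Wallis omnibus test of the island effect, Dunn's pairwise post
#' hoc z tests with Bonferroni correction, and Hedges' g effect sizes with
#' seeded percentile-bootstrap confidence intervals and Cohen magnitude
#' classes.
#'
#' @param records A [dev_env_records()] data.frame (or any data.frame with
#'   an `island` column).
#' @param variable Name of the numeric column to contrast.
#' @param n_boot Bootstrap resamples for the g confidence intervals.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @param min_n Minimum records per island; islands below it are dropped.
#' @return A list with `variable`, `normality` (island, n, lilliefors_p,
#'   normal flag), `kruskal` (statistic, df, p_value), and `pairwise`
#'   (island pair, Dunn z and Bonferroni p, g, CI bounds, magnitude).
#' @export
island_contrasts <- function(records, variable, n_boot = 2000, conf = 0.95,
                             seed = 1L, min_n = 2) {
  stopifnot(variable %in% names(records))
  keep <- names(which(table(records$island) >= max(min_n, 2)))
  if (length(keep) < 2) {
    stop("island contrasts need >= 2 islands with >= ", max(min_n, 2),
         " records each")
  }
  records <- records[records$island %in% keep, ]
  vals <- records[[variable]]
  grp <- factor(records$island)

  normality <- do.call(rbind, lapply(levels(grp), function(isl) {
    x <- vals[grp == isl]
    p <- if (length(unique(x)) >= 5) {
      tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
    } else NA_real_
    data.frame(island = isl, n = length(x), lilliefors_p = p,
               normal = !is.na(p) & p >= 0.05)
  }))

  kw <- kruskal.test(vals, grp)
  dunn <- dunn_test(vals, grp)

  pairwise <- dunn
  pairwise$g <- NA_real_
  pairwise$ci_lower <- NA_real_
  pairwise$ci_upper <- NA_real_
  for (i in seq_len(nrow(pairwise))) {
    x <- vals[grp == pairwise$group1[i]]
    y <- vals[grp == pairwise$group2[i]]
    pairwise$g[i] <- suppressWarnings(hedges_g(x, y)$g)
    ci <- hedges_g_ci(x, y, n_boot = n_boot, conf = conf,
                      seed = iteration_seed(seed, i))
    pairwise$ci_lower[i] <- ci[1]
    pairwise$ci_upper[i] <- ci[2]
  }
  pairwise$magnitude <- magnitude_class(pairwise$g)
  names(pairwise)[names(pairwise) %in% c("group1", "group2")] <-
    c("island1", "island2")

  list(variable = variable, normality = normality,
       kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pairwise)
}
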
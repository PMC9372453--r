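#' One-way ANOVA partition of a cohort trait
#'
#' Fixed-effects decomposition of, for example, per-sample 2C genome sizes
#' by species: F statistic, degrees of freedom, the fraction of the total
#' sum of squares explained by group identity, and the F-distribution
#' p-value. Fitting is delegated to [stats::aov()].
#'
#' @param values numeric vector (one value per sample).
#' @param groups group labels, same length; at least two distinct groups and
#'   at least one residual degree of freedom are required.
#' @return List with `F`, `df_between`, `df_within`, `variance_explained`
#'   (SS_between / SS_total, in [0, 1]) and `p`.
#' @examples
#' gs <- c(999.98, 989.23, 1055.93, 1227.92, 1126.64, 1096.44, 1104.84)
#' sp <- c("An", "An", "Vi", "Ro", "Ri", "Ri", "Ri")
#' anova_partition(gs, sp)
#' @export
anova_partition <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (length(values) <= nlevels(groups))
    stop("no residual degrees of freedom (n must exceed the group count)")
  tab <- summary(aov(values ~ groups))[[1]]
  ssb <- tab["groups", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  f <- tab["groups", "F value"]
  p <- tab["groups", "Pr(>F)"]
  # constant response: the 0/0 ratio is noise, report a null partition
  if (ssb + ssw <= 1e-12 * max(1, mean(values)^2) * length(values)) {
    ssb <- ssw <- 0; f <- 0; p <- 1
  }
  if (is.na(f)) { f <- 0; p <- 1 }
  list(F = unname(f),
       df_between = unname(tab["groups", "Df"]),
       df_within = unname(tab["Residuals", "Df"]),
       variance_explained = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
       p = unname(p))
}

#' Label-permutation check of an ANOVA partition
#'
#' Re-runs [anova_partition()] on `n_perm` uniformly random permutations of
#' the group labels to ask whether the observed F and variance-explained
#' values are unlikely to occur by chance. Exceedance p-values use the
#' add-one estimator (1 + #\{perm >= obs\}) / (1 + n_perm), which never
#' returns zero; the one-sided 95% quantiles of the permutation
#' distributions are reported alongside.
#'
#' @inheritParams anova_partition
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; results are reproducible given the seed.
#' @return List with `observed` (the unpermuted [anova_partition()]),
#'   `p_F`, `p_variance_explained`, `q95_F`, `q95_variance_explained`,
#'   and `n_perm`.
#' @export
permutation_check <- function(values, groups, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  obs <- anova_partition(values, groups)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    a <- anova_partition(values, g)
    c(a$F, a$variance_explained)
  }, numeric(2))
  list(observed = obs,
       p_F = (1 + sum(perm[1, ] >= obs$F)) / (1 + n_perm),
       p_variance_explained =
         (1 + sum(perm[2, ] >= obs$variance_explained)) / (1 + n_perm),
       q95_F = unname(quantile(perm[1, ], 0.95, type = 7)),
       q95_variance_explained = unname(quantile(perm[2, ], 0.95, type = 7)),
       n_perm = as.integer(n_perm))
}
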
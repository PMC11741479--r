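#' Subject-by-condition table for fully within-subject designs
#'
#' Builds the analysis unit of the statistical framework: one value per
#' subject per cell of a complete crossing of 1--3 within-subject factors
#' (trial-level data should be averaged to condition means per subject
#' first).
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector (length 1--3) of factor column names.
#' @return Object of class `sc_table`: `y` (array, subjects x factor
#'   levels), `subjects`, `factors` (named list of level labels).
#' @export
subject_condition_table <- function(data, dv, subject, factors) {
  stopifnot(is.data.frame(data), length(factors) >= 1, length(factors) <= 3)
  miss <- setdiff(c(dv, subject, factors), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  subj <- factor(data[[subject]])
  fl <- lapply(factors, function(f) factor(data[[f]]))
  names(fl) <- factors
  idx <- c(list(subject = subj), fl)
  counts <- table(idx)
  if (any(counts != 1L))
    stop("incomplete design: need exactly one value per subject per cell")
  y <- tapply(data[[dv]], idx, mean)
  structure(list(y = y, subjects = levels(subj),
                 factors = lapply(fl, levels)),
            class = "sc_table")
}

# marginal sum-of-squares term over array dims `dims` (integer vector; 0 = grand)
ss_marginal <- function(y, dims) {
  N <- length(y)
  if (length(dims) == 0L) return(sum(y)^2 / N)
  margin <- apply(y, dims, sum)
  n_per <- N / length(margin)
  sum(margin^2) / n_per
}

# all non-empty subsets of 1..k, mains first then by order
subsets_of <- function(k) {
  out <- list()
  for (size in seq_len(k))
    out <- c(out, utils::combn(k, size, simplify = FALSE))
  out
}

#' Repeated-measures ANOVA (fully within-subject, 1--3 factors)
#'
#' Classical balanced-design sum-of-squares partitioning for complete
#' within-subject designs: every effect (main effects and all
#' interactions) is tested against its own subject-by-effect interaction
#' error term. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#' No sphericity correction is applied; validity of p-values is supplied by
#' the permutation procedure ([permutation_p()]).
#'
#' @param table An [subject_condition_table()].
#' @return Data frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `pes` (partial eta squared), `ss_effect`, `ss_error`.
#' @export
rm_anova <- function(table) {
  stopifnot(inherits(table, "sc_table"))
  y <- table$y
  nf <- length(table$factors)
  n_subj <- dim(y)[1]
  if (n_subj < 2) stop("need at least 2 subjects")
  fdims <- seq_len(nf) + 1L  # array dims holding the factors (dim 1 = subject)
  ss_term <- function(dims) {
    # SS of the term spanned by `dims` via inclusion-exclusion over sub-margins
    subs <- c(list(integer(0)), if (length(dims)) subsets_of(length(dims)))
    tot <- 0
    for (u in subs)
      tot <- tot + (-1)^(length(dims) - length(u)) * ss_marginal(y, dims[u])
    tot
  }
  effects <- subsets_of(nf)
  rows <- lapply(effects, function(ef) {
    dims <- fdims[ef]
    ss_e <- ss_term(dims)
    ss_err <- ss_term(c(1L, dims))
    df1 <- prod(dim(y)[dims] - 1L)
    df2 <- df1 * (n_subj - 1L)
    ms_err <- ss_err / df2
    Fv <- if (ms_err > 0) (ss_e / df1) / ms_err else 0
    data.frame(effect = paste(names(table$factors)[ef], collapse = ":"),
               F = Fv, df1 = df1, df2 = df2,
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               ss_effect = ss_e, ss_error = ss_err,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired-samples t test with effect size
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences `d = a - b`,
#' with `d_z = mean(d)/sd(d) = t/sqrt(n)`.
#'
#' @param a,b Equal-length paired measurement vectors (n >= 2).
#' @return List with `t`, `df`, `d_z`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  d <- a - b
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences; t is undefined")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, d_z = t / sqrt(n), mean_diff = mean(d))
}

#' Permutation p-value by within-subject shuffling
#'
#' Generates the null distribution of an arbitrary statistic by
#' independently permuting each subject's condition-cell values (all cells
#' jointly) and recomputing the statistic on every shuffle. The p-value is
#' the proportion of null statistics greater than or equal to the observed
#' one (set `plus_one = TRUE` for the (b+1)/(m+1) variant). Deterministic
#' given `seed` (Mersenne-Twister); the caller's RNG state is restored on
#' exit.
#'
#' @param table An [subject_condition_table()].
#' @param statistic Function `sc_table -> scalar`. Use a statistic that is
#'   large under the alternative (e.g. `F`, or `|t|` for two-sided tests).
#' @param seed Integer seed for the shuffling.
#' @param n_iter Number of shuffles (default 1000).
#' @param plus_one Use the add-one p-value variant (default FALSE: exact
#'   proportion rule).
#' @return Object of class `perm_result`: `observed`, `null` (length
#'   `n_iter`), `p`, `seed`, `n_iter`.
#' @export
permutation_p <- function(table, statistic, seed, n_iter = 1000,
                          plus_one = FALSE) {
  stopifnot(inherits(table, "sc_table"), is.function(statistic))
  force(seed)  # evaluate before snapshotting the caller's RNG state
  observed <- statistic(table)
  dims <- dim(table$y)
  n_subj <- dims[1]
  n_cells <- prod(dims[-1])
  Y <- matrix(table$y, n_subj, n_cells)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  null_stats <- numeric(n_iter)
  tbl_i <- table
  for (i in seq_len(n_iter)) {
    Yp <- Y
    for (s in seq_len(n_subj))
      Yp[s, ] <- Y[s, sample.int(n_cells)]
    tbl_i$y <- array(Yp, dims)
    null_stats[i] <- statistic(tbl_i)
  }
  p <- if (plus_one) (sum(null_stats >= observed) + 1) / (n_iter + 1)
  else mean(null_stats >= observed)
  structure(list(observed = observed, null = null_stats, p = p,
                 seed = seed, n_iter = n_iter),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4g, p = %.4g (%d shuffles, seed %d)\n",
              x$observed, x$p, x$n_iter, x$seed))
  invisible(x)
}

#' Permuted paired t test
#'
#' Permutation p-value for a paired t test by within-subject label
#' shuffling: swapping a subject's two condition labels flips the sign of
#' its difference, so the null distribution is generated as a vectorized
#' sign flip of the paired differences. Statistic `|t|` (two-sided,
#' default) or signed `t` (one-sided, `a > b`); counting rule
#' `p = mean(null >= observed)`. Deterministic given `seed`.
#'
#' @param a,b Paired per-subject condition means.
#' @param seed Integer seed.
#' @param n_iter Number of shuffles (default 1000).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return A `perm_result` with the parametric test attached as
#'   `$parametric` (from [paired_t()]).
#' @export
perm_paired_t <- function(a, b, seed, n_iter = 1000,
                          alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  force(seed)
  par <- paired_t(a, b)
  d <- a - b
  n <- length(d)
  observed <- if (alternative == "two.sided") abs(par$t) else par$t
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  # swapping the two labels within a subject flips the sign of its
  # difference, so the within-subject shuffle is a vectorized sign flip
  S <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
  mu <- drop(S %*% d) / n
  ssq <- sum(d^2)
  s2 <- pmax((ssq - n * mu^2) / (n - 1), 0)
  tt <- mu / sqrt(s2 / n)
  tt[s2 == 0] <- 0
  null_stats <- if (alternative == "two.sided") abs(tt) else tt
  structure(list(observed = observed, null = null_stats,
                 p = mean(null_stats >= observed), seed = seed,
                 n_iter = n_iter, parametric = par),
            class = "perm_result")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment (delegating to [stats::p.adjust()]) plus the
#' rejection set at level `q`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical vector).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Within-subject standard error of the mean
#'
#' Cousineau-Morey procedure: remove each subject's grand mean, add back
#' the group grand mean, compute the per-cell SEM of the adjusted values,
#' and scale by the Morey bias correction `sqrt(C/(C-1))` for C cells.
#'
#' @param table An [subject_condition_table()].
#' @return Numeric vector (length C) of corrected per-cell SEMs, named by
#'   cell.
#' @export
within_subject_sem <- function(table) {
  stopifnot(inherits(table, "sc_table"))
  dims <- dim(table$y)
  C <- prod(dims[-1])
  if (C < 2) stop("within-subject SEM needs at least 2 cells")
  n <- dims[1]
  Y <- matrix(table$y, n, C)
  adj <- Y - rowMeans(Y) + mean(Y)
  sem <- apply(adj, 2, stats::sd) / sqrt(n) * sqrt(C / (C - 1))
  cell_labels <- do.call(expand.grid, table$factors)
  names(sem) <- apply(cell_labels, 1, paste, collapse = ".")
  sem
}

#' Minimal sample size for a paired t test
#'
#' Smallest number of subjects n >= 2 such that the power of a paired
#' (one-sample-on-differences) t test reaches `power`, computed from the
#' noncentral t distribution with noncentrality `d_z * sqrt(n)` and
#' `n - 1` degrees of freedom.
#'
#' @param d_z Standardized paired effect size (mean difference / SD of
#'   differences), > 0.
#' @param alpha Type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @param tail `"one.sided"` or `"two.sided"`.
#' @param n_max Search bound (default 10000).
#' @return Integer minimal sample size.
#' @export
paired_t_min_n <- function(d_z, alpha = 0.05, power = 0.80,
                           tail = c("one.sided", "two.sided"),
                           n_max = 10000L) {
  tail <- match.arg(tail)
  stopifnot(d_z > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    if (paired_t_power(n, d_z, alpha, tail) >= power) return(as.integer(n))
  }
  stop("no n <= n_max reaches the requested power")
}

#' Power of a paired t test at a given sample size
#'
#' @param n Number of subjects (>= 2).
#' @param d_z Standardized paired effect size.
#' @param alpha Type-I error rate.
#' @param tail `"one.sided"` or `"two.sided"`.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, d_z, alpha = 0.05,
                           tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  df <- n - 1
  ncp <- d_z * sqrt(n)
  if (tail == "one.sided") {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp = ncp)) + stats::pt(-crit, df, ncp = ncp)
  }
}
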
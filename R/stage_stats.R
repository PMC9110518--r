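#' Kruskal-Wallis rank test with explicit tie correction
#'
#' The omnibus H statistic is computed from average midranks,
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \tfrac{N+1}{2})^2,}
#' with the tie correction \eqn{C = 1 - \sum_t (t^3 - t)/(N^3 - N)} over tie
#' groups of size t. The p-value is the chi-square upper tail of `H/C` on
#' `k - 1` degrees of freedom. With every observation identical, `H = 0` and
#' `p = 1`.
#'
#' @param groups A list of (>= 2) non-empty numeric vectors; total N >= 3.
#' @return An object of class `kw_result`: fields `H` (uncorrected), `df`,
#'   `p`, `tie_correction`, `H_corrected`, `n` (group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_bonespectq("kruskal_wallis needs at least 2 groups", "input_error")
  groups <- lapply(groups, as.numeric)
  n <- lengths(groups)
  if (any(n == 0L))
    stop_bonespectq("every group must be non-empty", "input_error")
  N <- sum(n)
  if (N < 3L)
    stop_bonespectq("total sample size must be at least 3", "input_error")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)                       # midranks
  g <- rep(seq_len(k), n)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {                           # all values identical
    res <- list(H = 0, df = k - 1L, p = 1, tie_correction = 1,
                H_corrected = 0, n = as.integer(n))
    return(structure(res, class = "kw_result"))
  }
  Hc <- H / C
  structure(list(H = H, df = k - 1L,
                 p = stats::pchisq(Hc, df = k - 1, lower.tail = FALSE),
                 tie_correction = C, H_corrected = Hc, n = as.integer(n)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g (tie-corrected %.4g), df = %d, p = %.4g\n",
              x$H, x$H_corrected, x$df, x$p))
  invisible(x)
}

# Standardized pairwise rank-sum statistic for groups x, y (midranks,
# tie-corrected null variance). Returns t = (R_x - E)/sqrt(V); 0 when V = 0.
pairwise_rank_stat <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  Rx <- sum(r[seq_len(nx)])
  E <- nx * (N + 1) / 2
  V <- nx * ny / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (Rx - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' Implements the Steel-Dwass(-Critchlow-Fligner) procedure: for each pair of
#' groups the two-sample rank-sum statistic is computed on that pair alone,
#' standardized with its tie-corrected null mean and variance into `t`, and
#' referred to the studentized-range distribution with `k` groups and
#' infinite degrees of freedom: `p_adj = P(Q_{k,Inf} >= sqrt(2) * |t|)`. With
#' `k = 2` this reduces exactly to the two-sided normal-approximation
#' rank-sum test.
#'
#' The permutation method instead permutes the pooled sample across all
#' groups `n_perm` times, recomputes the maximum over pairs of `|t|` per
#' draw, and estimates each pair's adjusted p as the upper-tail frequency of
#' that maximum against the observed `|t|` (single-step max-T adjustment).
#'
#' @param groups A list of (>= 2) numeric vectors.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of permutation draws (>= 10000 recommended).
#' @param seed Integer seed, required for the permutation path.
#' @return A `data.frame` of class `steel_dwass_result`: columns `group_a`,
#'   `group_b`, `t_statistic`, `p_adjusted`, `unreliable` (TRUE when a group
#'   has fewer than 2 observations).
#' @export
steel_dwass <- function(groups, method = c("asymptotic", "permutation"),
                        n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop_bonespectq("steel_dwass needs at least 2 groups", "input_error")
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  n <- lengths(groups)
  labs <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups))) names(groups) <- labs
  small <- any(n < 2L)
  if (small)
    warning("group with fewer than 2 observations: results flagged unreliable")
  pairs <- utils::combn(k, 2)
  t_obs <- apply(pairs, 2, function(ij)
    pairwise_rank_stat(groups[[ij[1]]], groups[[ij[2]]]))
  if (method == "asymptotic") {
    p_adj <- stats::ptukey(sqrt(2) * abs(t_obs), nmeans = k, df = Inf,
                           lower.tail = FALSE)
  } else {
    if (is.null(seed))
      stop_bonespectq("permutation method requires an explicit seed",
                      "input_error")
    pooled <- unlist(groups, use.names = FALSE)
    gidx <- rep(seq_len(k), n)
    max_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        perm <- sample(pooled)
        max(abs(apply(pairs, 2, function(ij)
          pairwise_rank_stat(perm[gidx == ij[1]], perm[gidx == ij[2]]))))
      }, numeric(1))
    })
    p_adj <- vapply(abs(t_obs), function(t0)
      (1 + sum(max_null >= t0 - 1e-12)) / (n_perm + 1), numeric(1))
  }
  out <- data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
                    t_statistic = t_obs, p_adjusted = pmin(p_adj, 1),
                    unreliable = small, stringsAsFactors = FALSE)
  class(out) <- c("steel_dwass_result", "data.frame")
  out
}

#' Per-stage median and interquartile range of a metric
#'
#' Quantiles use the linear-interpolation convention between order statistics
#' (`stats::quantile` type 7); the `formatted` column renders the field's
#' usual "median [q1-q3]" presentation.
#'
#' @param cohort A cohort `data.frame` with a `stage` column.
#' @param metric Name of a numeric column of `cohort`.
#' @return A `data.frame` with one row per stage: `stage`, `n`, `median`,
#'   `q1`, `q3`, `formatted`.
#' @export
summarize_by_stage <- function(cohort, metric) {
  if (!metric %in% names(cohort))
    stop_bonespectq(sprintf("unknown metric: %s", metric), "input_error")
  stages <- sort(unique(cohort$stage))
  rows <- lapply(stages, function(s) {
    v <- cohort[[metric]][cohort$stage == s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(stage = s, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               formatted = sprintf("%.2f [%.2f-%.2f]", q[2], q[1], q[3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare quantitative metrics across clinical stages
#'
#' For each requested metric: per-stage median/IQR summaries, the
#' Kruskal-Wallis omnibus test, and Steel-Dwass all-pairs results (always
#' computed, reported as post hoc). Significance is flagged at `alpha`
#' (two-sided, no multiplicity adjustment across metrics).
#'
#' @param cohort A cohort `data.frame` with `stage` plus metric columns.
#' @param metrics Character vector of metric column names.
#' @param alpha Significance level (default 0.05).
#' @param posthoc_method Passed to [steel_dwass()] as `method`.
#' @param seed Seed for the permutation post hoc path.
#' @return An object of class `stage_report`: a named list (one element per
#'   metric) of lists with `summary`, `kw`, `posthoc`, `significant`; plus
#'   attributes `alpha` and `stages`.
#' @export
stage_comparison_report <- function(cohort,
                                    metrics = c("rsuv_max", "rsuv_mean",
                                                "mbv_cm3", "rtbu"),
                                    alpha = 0.05,
                                    posthoc_method = "asymptotic",
                                    seed = NULL) {
  if (!"stage" %in% names(cohort))
    stop_bonespectq("cohort must carry a stage column", "input_error")
  if (alpha <= 0 || alpha >= 1)
    stop_bonespectq("alpha must lie in (0, 1)", "input_error")
  stages <- sort(unique(cohort$stage))
  if (length(stages) < 2L)
    stop_bonespectq("at least 2 stages required for comparison", "input_error")
  out <- lapply(metrics, function(m) {
    if (!m %in% names(cohort))
      stop_bonespectq(sprintf("unknown metric: %s", m), "input_error")
    groups <- split(cohort[[m]], cohort$stage)
    kw <- kruskal_wallis(groups)
    ph <- suppressWarnings(
      steel_dwass(groups, method = posthoc_method, seed = seed))
    list(summary = summarize_by_stage(cohort, m), kw = kw, posthoc = ph,
         significant = kw$p < alpha)
  })
  names(out) <- metrics
  structure(out, class = "stage_report", alpha = alpha, stages = stages)
}

#' @export
print.stage_report <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("== %s ==\n", m))
    s <- x[[m]]$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  stage %s (n=%d): %s\n", s$stage[i], s$n[i],
                  s$formatted[i]))
    cat(sprintf("  KW p = %.4g%s\n", x[[m]]$kw$p,
                if (x[[m]]$significant) " *" else ""))
    ph <- x[[m]]$posthoc
    for (i in seq_len(nrow(ph)))
      cat(sprintf("  post hoc %s vs %s: p = %.4g\n", ph$group_a[i],
                  ph$group_b[i], ph$p_adjusted[i]))
  }
  invisible(x)
}

#' Long-format table for boxplot-style external plotting
#'
#' @param cohort A cohort `data.frame` with `stage` plus metric columns.
#' @param metrics Metric column names.
#' @return A `data.frame` with columns `stage`, `metric`, `value`.
#' @export
cohort_long <- function(cohort, metrics = c("rsuv_max", "rsuv_mean",
                                            "mbv_cm3", "rtbu")) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(stage = cohort$stage, metric = m, value = cohort[[m]],
               stringsAsFactors = FALSE)))
}
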
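# Inferential layer: one-way fixed-effects ANOVA, the Student-Newman-Keuls
# stepwise post hoc on ordered group means, a Pearson chi-squared test of
# proportions, and an a-priori sample-size helper from the noncentral-F
# power function.

# Internal: coerce input to a named list of numeric vectors. Accepts a
# (named) list, or a long data.frame with columns `group` and `value`.
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      stop("long-format data needs columns 'group' and 'value'")
    }
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups)) stop("groups must be a list or long data.frame")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' One-way fixed-effects analysis of variance
#'
#' Classical between/within decomposition with the p-value from the upper
#' tail of the F distribution. Degenerate data with zero within-group
#' variance and equal means return `F = 0, p = 1`.
#'
#' @param groups named list of numeric vectors (each of length >= 2), or a
#'   long data.frame with columns `group` and `value`.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  g <- as_group_list(groups)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2)) stop("each group needs n >= 2")
  ni <- lengths(g)
  df_b <- length(g) - 1L
  df_w <- sum(ni) - length(g)
  means <- vapply(g, mean, numeric(1))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0) {
    if (max(means) - min(means) == 0) {
      return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
    }
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  }
  fit <- stats::oneway.test(value ~ group,
                            data = data.frame(
                              value = unlist(g, use.names = FALSE),
                              group = factor(rep(names(g), ni))),
                            var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = as.integer(unname(fit$parameter[1])),
       df_within = as.integer(unname(fit$parameter[2])),
       p = unname(fit$p.value))
}

#' Student-Newman-Keuls post hoc test on ordered group means
#'
#' Stepwise studentized-range procedure: group means are ordered; the
#' span of stretch r is compared with `qtukey(1 - alpha, r, df_within) *
#' sqrt(MSW / n_h)` where `n_h` is the harmonic mean of the two group
#' sizes in the comparison (Kramer adjustment). A non-significant span
#' blocks every comparison nested inside it, which keeps the procedure
#' coherent.
#'
#' @inheritParams one_way_anova
#' @param alpha per-step significance level; default 0.05.
#' @return object of class `snk_test`: list with `pairs` (data.frame of
#'   the significantly different ordered pairs: `group_lo`, `group_hi`,
#'   `diff`, `span_r`, `q`, `q_crit`), `means` (sorted), `msw`,
#'   `df_within`, `alpha`.
#' @export
snk_test <- function(groups, alpha = 0.05) {
  g <- as_group_list(groups)
  if (length(g) < 2) stop("need at least 2 groups")
  if (any(lengths(g) < 2)) stop("each group needs n >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  ni <- lengths(g)
  means <- vapply(g, mean, numeric(1))
  df_w <- sum(ni) - length(g)
  msw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) / df_w
  ord <- order(means)
  m <- means[ord]; n <- ni[ord]
  kk <- length(m)
  res <- list()
  if (msw > 0) {
    # widest spans first; a retained (non-significant) span blocks every
    # comparison nested inside it
    retained <- matrix(numeric(), 0, 2)
    for (r in kk:2) {
      for (i in seq_len(kk - r + 1L)) {
        j <- i + r - 1L
        if (nrow(retained) &&
            any(retained[, 1] <= i & retained[, 2] >= j)) next
        nh <- 2 / (1 / n[i] + 1 / n[j])
        q_obs <- (m[j] - m[i]) / sqrt(msw / nh)
        q_crit <- stats::qtukey(1 - alpha, r, df_w)
        if (q_obs > q_crit) {
          res[[length(res) + 1L]] <- data.frame(
            group_lo = names(m)[i], group_hi = names(m)[j],
            diff = m[j] - m[i], span_r = r, q = q_obs, q_crit = q_crit,
            stringsAsFactors = FALSE)
        } else {
          retained <- rbind(retained, c(i, j))
        }
      }
    }
  }
  pairs <- if (length(res)) unique(do.call(rbind, res)) else
    data.frame(group_lo = character(), group_hi = character(),
               diff = numeric(), span_r = integer(), q = numeric(),
               q_crit = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, means = m, msw = msw, df_within = df_w,
                 alpha = alpha),
            class = "snk_test")
}

#' @export
print.snk_test <- function(x, ...) {
  cat(sprintf("<snk_test> %d groups, df_within = %d, alpha = %g\n",
              length(x$means), x$df_within, x$alpha))
  if (nrow(x$pairs)) {
    cat("significantly different pairs:\n")
    print(x$pairs, row.names = FALSE)
  } else {
    cat("no significantly different pairs\n")
  }
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table of counts
#'
#' No continuity correction by default; set `yates = TRUE` for the Yates
#' correction.
#'
#' @param table 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @param yates apply the continuity correction.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_squared_proportions <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive")
  }
  fit <- stats::chisq.test(tab, correct = yates)
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Power of a balanced one-way ANOVA
#'
#' Noncentral-F power at effect size f (Cohen's f), with noncentrality
#' `lambda = f^2 * n_groups * n` for n observations per group.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param n per-group sample size (>= 2).
#' @param n_groups number of groups (>= 2).
#' @param alpha test size; default 0.05.
#' @return power in (0, 1).
#' @export
anova_power <- function(effect_size_f, n, n_groups, alpha = 0.05) {
  stopifnot(effect_size_f > 0, n >= 2, n_groups >= 2,
            alpha > 0, alpha < 1)
  df1 <- n_groups - 1
  df2 <- n_groups * (n - 1)
  lambda <- effect_size_f^2 * n_groups * n
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A-priori per-group sample size for a one-way ANOVA
#'
#' Smallest per-group n whose noncentral-F power reaches the requested
#' power. Monotone in effect size, alpha and power.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param n_groups number of groups (>= 2).
#' @param alpha test size in (0, 1); default 0.05.
#' @param power target power in (0, 1); default 0.80.
#' @param max_n search ceiling; default 1e6.
#' @return integer per-group sample size (>= 2).
#' @export
anova_n_per_group <- function(effect_size_f, n_groups, alpha = 0.05,
                              power = 0.80, max_n = 1e6) {
  stopifnot(effect_size_f > 0, n_groups >= 2,
            alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (n <= max_n) {
    if (anova_power(effect_size_f, n, n_groups, alpha) >= power) {
      return(n)
    }
    n <- n + 1L
  }
  stop("requested power unreachable within n <= ", max_n)
}
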
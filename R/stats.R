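as_group_list <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("group", "value") %in% names(x)))
      stop_phb("data frame input needs columns 'group' and 'value'")
    x <- split(x$value, x$group)
  }
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop_phb("group values must be a named list or a (group, value) data frame")
  lapply(x, as.numeric)
}

drop_censored <- function(groups) {
  n_bad <- sum(vapply(groups, function(v) sum(!is.finite(v)), integer(1)))
  if (n_bad > 0) {
    warning(sprintf(
      "excluding %d censored/non-finite t50 value(s) from the comparison",
      n_bad), call. = FALSE)
    groups <- lapply(groups, function(v) v[is.finite(v)])
  }
  groups
}

#' One-way analysis of variance across blend groups
#'
#' Classical between/within F-test on `(k - 1, N - k)` degrees of freedom,
#' computed through [stats::lm()]. Censored (non-finite) values are
#' excluded with a warning; every group must retain at least 2 values.
#'
#' @param group_values named list of numeric vectors (one per blend), or a
#'   data frame with columns `group` and `value`.
#' @return A list: `F`, `p`, `df`, `ms_within`, `means`, `n`.
#' @export
one_way_anova <- function(group_values) {
  groups <- drop_censored(as_group_list(group_values))
  if (length(groups) < 2L) stop_phb("need at least 2 groups")
  if (any(lengths(groups) < 2L))
    stop_phb("every group needs at least 2 usable values")
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  y <- unlist(groups, use.names = FALSE)
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(between = tab$Df[1], within = tab$Df[2]),
       ms_within = tab$`Mean Sq`[2],
       means = vapply(groups, mean, numeric(1)),
       n = lengths(groups))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range test on every pair of groups with the pooled
#' within-group variance; for unbalanced designs the Tukey-Kramer standard
#' error is used. p-values come from the studentized range distribution on
#' `(k, N - k)`.
#'
#' @inheritParams one_way_anova
#' @param alpha family significance level (default 0.05).
#' @return A data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of `group2` minus mean of `group1`), `q`, `p`, `reject`.
#' @export
tukey_hsd <- function(group_values, alpha = 0.05) {
  groups <- drop_censored(as_group_list(group_values))
  aov1 <- one_way_anova(groups)
  k <- length(groups); dfw <- unname(aov1$df["within"])
  nm <- names(groups)
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    diff = NA_real_, q = NA_real_, p = NA_real_,
                    reject = NA)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- aov1$means[i2] - aov1$means[i1]
    se <- sqrt(aov1$ms_within / 2 * (1 / aov1$n[i1] + 1 / aov1$n[i2]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    out$diff[j] <- unname(d); out$q[j] <- unname(q); out$p[j] <- p
    out$reject[j] <- p < alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "means") <- aov1$means
  out
}

#' Compact letter display from pairwise decisions
#'
#' Insert-and-absorb algorithm: starting from one letter shared by all
#' groups, each significantly different pair splits every letter class
#' containing both; classes that become subsets of another are absorbed,
#' keeping the letter count minimal. Two groups share a letter iff their
#' pair is not rejected.
#'
#' @param tukey_pairs data frame from [tukey_hsd()] (columns `group1`,
#'   `group2`, `reject`).
#' @param means optional named group means used to order the letters;
#'   defaults to the means recorded by [tukey_hsd()].
#' @return Named character vector of letter sets, one per group.
#' @export
compact_letters <- function(tukey_pairs, means = NULL) {
  means <- means %||% attr(tukey_pairs, "means")
  nm <- unique(c(tukey_pairs$group1, tukey_pairs$group2))
  nm <- if (is.null(means)) nm else names(sort(means[nm]))
  cols <- list(nm)
  for (j in which(tukey_pairs$reject)) {
    a <- tukey_pairs$group1[j]; b <- tukey_pairs$group2[j]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      } else nxt <- c(nxt, list(col))
    }
    nxt <- nxt[lengths(nxt) > 0]
    keep <- rep(TRUE, length(nxt))
    for (i1 in seq_along(nxt)) for (i2 in seq_along(nxt)) {
      if (i1 != i2 && keep[i1] && keep[i2] &&
          all(nxt[[i1]] %in% nxt[[i2]]) &&
          (length(nxt[[i1]]) < length(nxt[[i2]]) || i1 > i2))
        keep[i1] <- FALSE
    }
    cols <- nxt[keep]
  }
  cols <- cols[order(vapply(cols, function(col) min(match(col, nm)),
                            numeric(1)))]
  lett <- make_letters(length(cols))
  out <- vapply(nm, function(g) {
    paste(lett[vapply(cols, function(col) g %in% col, logical(1))],
          collapse = "")
  }, character(1))
  out
}

make_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, paste0(rep(letters, each = 26), letters))[seq_len(n)]
}

#' Compare replicate t50 values across blends
#'
#' One-way ANOVA on per-replicate t50 values followed by Tukey HSD and a
#' compact letter display, the presentation used for blend comparisons:
#' two blends differ significantly iff they share no letter.
#'
#' @param t50_table data frame with columns `blend` and `t50` (hours; `NA`
#'   for censored replicates, which are excluded with a warning), or a
#'   named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return An object of class `group_comparison`: `anova`, `tukey`,
#'   `letters`, `means`, `alpha`.
#' @export
compare_t50 <- function(t50_table, alpha = 0.05) {
  groups <- if (is.data.frame(t50_table)) {
    if (!all(c("blend", "t50") %in% names(t50_table)))
      stop_phb("t50_table needs columns 'blend' and 't50'")
    split(t50_table$t50, t50_table$blend)
  } else as_group_list(t50_table)
  groups <- drop_censored(groups)
  aov1 <- one_way_anova(groups)
  tk <- tukey_hsd(groups, alpha = alpha)
  structure(list(anova = aov1, tukey = tk,
                 letters = compact_letters(tk), means = aov1$means,
                 alpha = alpha, groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("t50 comparison across blends\n")
  cat(sprintf("  one-way ANOVA: F(%d, %d) = %.*g, p = %.3g\n",
              x$anova$df["between"], x$anova$df["within"], digits,
              x$anova$F, x$anova$p))
  tab <- data.frame(blend = names(x$means),
                    mean_t50_h = round(unname(x$means), 2),
                    n = unname(x$anova$n),
                    letters = unname(x$letters[names(x$means)]))
  print(tab[order(tab$mean_t50_h), ], row.names = FALSE)
  cat(sprintf("  blends sharing no letter differ at alpha = %g (Tukey HSD)\n",
              x$alpha))
  invisible(x)
}
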
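#' One-way ANOVA with Bonferroni post-hoc pairwise comparisons
#'
#' Classical one-way ANOVA across age groups followed by all pairwise
#' comparisons using the pooled ANOVA mean-square error, each raw p value
#' multiplied by the number of pairs and capped at 1 (classical Bonferroni
#' post-hoc). Significance is flagged at alpha = 0.05.
#'
#' @param groups named list of numeric vectors, one per group (e.g. per-age
#'   per-retina totals); at least two groups of n >= 2 finite values.
#' @param alpha significance level (default 0.05).
#' @return object of class \code{group_comparison}: list with \code{F},
#'   \code{p}, \code{df}, \code{pairwise} (data.frame: group1, group2,
#'   mean_diff, t, p_raw, p_adj, significant), \code{group_means},
#'   \code{alpha}.
#' @export
anova_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs n >= 2")
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("group values must be finite")
  grp <- factor(rep(names(groups), sizes), levels = names(groups))

  k <- length(groups)
  N <- length(vals)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(unlist(lapply(groups, function(g) sum((g - mean(g))^2))))
  ssb <- sum(sizes * (means - mean(vals))^2)
  if (sse == 0 && ssb == 0) {
    stop("degenerate variance: all groups constant with equal means")
  }
  df1 <- k - 1L
  df2 <- N - k
  mse <- sse / df2
  Fstat <- if (mse == 0) Inf else (ssb / df1) / mse
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)

  pairs <- combn(names(groups), 2)
  npairs <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   mean_diff = NA_real_, t = NA_real_, p_raw = NA_real_,
                   p_adj = NA_real_, significant = NA)
  for (j in seq_len(npairs)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(mse * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    diffm <- means[[g2]] - means[[g1]]
    tval <- if (se == 0) sign(diffm) * Inf else diffm / se
    praw <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
    pw$mean_diff[j] <- diffm
    pw$t[j] <- tval
    pw$p_raw[j] <- praw
    pw$p_adj[j] <- min(1, praw * npairs)
  }
  pw$significant <- pw$p_adj < alpha
  structure(list(F = Fstat, p = p, df = c(df1, df2), mse = mse,
                 group_means = means, pairwise = pw, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  pw <- x$pairwise
  for (j in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: diff %.4g, p_adj = %.4g%s\n",
                pw$group1[j], pw$group2[j], pw$mean_diff[j], pw$p_adj[j],
                if (isTRUE(pw$significant[j])) " *" else ""))
  }
  invisible(x)
}

#' Age-group comparison table for a cohort summary
#'
#' Runs \code{\link{anova_bonferroni}} per (compartment, class) on per-retina
#' totals and returns a tidy report with significance stars at P < 0.05.
#'
#' @param retina_totals data.frame with columns \code{age}, \code{retina},
#'   \code{compartment}, \code{class}, \code{total}.
#' @param alpha significance level.
#' @return data.frame keyed by (compartment, class) with F, p and the
#'   Bonferroni-adjusted p of each age pair, plus a \code{stars} column.
#' @export
compare_age_groups <- function(retina_totals, alpha = 0.05) {
  stopifnot(all(c("age", "retina", "compartment", "class", "total") %in%
                  names(retina_totals)))
  keys <- unique(retina_totals[, c("compartment", "class")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- retina_totals$compartment == keys$compartment[i] &
      retina_totals$class == keys$class[i]
    sub <- retina_totals[sel, ]
    groups <- split(sub$total, sub$age)
    names(groups) <- paste0(names(groups), "mo")
    res <- tryCatch(anova_bonferroni(groups, alpha),
                    error = function(e) NULL)
    if (is.null(res)) next
    row <- data.frame(compartment = keys$compartment[i],
                      class = keys$class[i],
                      F = res$F, p = res$p,
                      stars = if (res$p < alpha) "*" else "")
    for (j in seq_len(nrow(res$pairwise))) {
      nm <- paste0("p_adj_", res$pairwise$group1[j], "_vs_",
                   res$pairwise$group2[j])
      row[[nm]] <- res$pairwise$p_adj[j]
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
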
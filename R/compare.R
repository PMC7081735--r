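#' Compare group thickness means by one-way ANOVA with Bonferroni post hoc
#'
#' Standard one-way ANOVA across groups of per-animal volume thickness
#' means, followed by all pairwise two-sample t-tests (pooled variance) with
#' Bonferroni correction: each raw p-value is multiplied by the number of
#' pairs and capped at 1. Significance is assessed at `alpha`.
#'
#' @param groups named list of numeric vectors, one per group; at least two
#'   groups with at least two values each.
#' @param alpha significance level reported alongside (default 0.05).
#' @return list of class `"group_comparison"` with elements `anova` (one-row
#'   data frame: `F`, `df_between`, `df_within`, `p`), `pairwise` (data
#'   frame: `group1`, `group2`, `mean_diff`, `p`, `p_bonferroni`,
#'   `significant`) and `alpha`.
#' @examples
#' group_compare(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
group_compare <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_analysis("at least two groups are required")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop_analysis("every group needs at least two values")
  }
  if (!all(vapply(groups, function(g) is.numeric(g) && all(is.finite(g)),
                  logical(1)))) {
    stop_analysis("group values must be finite numerics")
  }

  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  an <- data.frame(
    F = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p = tab[["Pr(>F)"]][1]
  )

  pairs <- utils::combn(names(groups), 2L)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x <- groups[[g1]]; y <- groups[[g2]]
    p <- if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      # both groups internally constant: t-test is degenerate
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }
    data.frame(group1 = g1, group2 = g2,
               mean_diff = mean(x) - mean(y),
               p = p, p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  }))
  pw$significant <- pw$p_bonferroni < alpha

  structure(list(anova = an, pairwise = pw, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (alpha = %g)\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p,
              x$alpha))
  cat("Bonferroni-adjusted pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
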
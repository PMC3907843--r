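#' Compare SRM abundance between groups
#'
#' Two groups are compared with a Welch (unequal-variance) t-test,
#' several groups with a one-way ANOVA followed by Bonferroni and Scheffe
#' pairwise decisions at `alpha`. Percent data can be transformed with
#' the arcsine-square-root (values in `[0, 100]`), or positive data with
#' the natural log, before testing; reported group means and standard
#' errors stay on the original scale.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param transform `"none"`, `"arcsine-sqrt"` or `"log"`.
#' @param alpha significance level for the post-hoc decisions.
#' @return a [GroupComparison-class].
#' @export
compareGroups <- function(samples,
                          transform = c("none", "arcsine-sqrt", "log"),
                          alpha = 0.05) {
  transform <- match.arg(transform)
  if (length(samples) < 2) stop("need at least two groups")
  if (any(vapply(samples, length, 1L) < 2))
    stop("each group needs at least two observations")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  tr <- switch(transform,
    none = identity,
    `arcsine-sqrt` = function(x) {
      if (any(x < 0 | x > 100))
        stop("arcsine-sqrt transform requires percent values in [0, 100]")
      asin(sqrt(x / 100))
    },
    log = function(x) {
      if (any(x <= 0)) stop("log transform requires positive values")
      log(x)
    })
  trans <- lapply(samples, tr)
  groups <- data.frame(
    group = names(samples),
    n = vapply(samples, length, 1L),
    mean = vapply(samples, mean, 1),
    se = vapply(samples, function(x) stats::sd(x) / sqrt(length(x)), 1))
  rownames(groups) <- NULL
  emptyPH <- data.frame(group1 = character(), group2 = character(),
                        pBonferroni = numeric(),
                        rejectBonferroni = logical(),
                        rejectScheffe = logical())
  if (length(samples) == 2) {
    if (all(vapply(trans, stats::sd, 1) == 0) &&
        isTRUE(all.equal(mean(trans[[1]]), mean(trans[[2]]))))
      return(new("GroupComparison", design = "two-group",
                 transform = transform, groups = groups, statistic = 0,
                 df = sum(groups$n) - 2, pValue = 1, postHoc = emptyPH,
                 alpha = alpha))
    if (all(vapply(trans, stats::sd, 1) == 0))
      stop("both groups constant with different means: test degenerate")
    tt <- stats::t.test(trans[[1]], trans[[2]], var.equal = FALSE)
    new("GroupComparison", design = "two-group", transform = transform,
        groups = groups, statistic = unname(tt$statistic),
        df = unname(tt$parameter), pValue = tt$p.value,
        postHoc = emptyPH, alpha = alpha)
  } else {
    y <- unlist(trans, use.names = FALSE)
    gf <- factor(rep(names(samples), vapply(samples, length, 1L)),
                 levels = names(samples))
    if (stats::sd(y) == 0)
      stop("all values identical across groups: ANOVA degenerate")
    fit <- stats::aov(y ~ gf)
    an <- summary(fit)[[1]]
    Fval <- an$`F value`[1]
    dfs <- an$Df
    mse <- an$`Mean Sq`[2]
    k <- length(samples)
    N <- length(y)
    pw <- stats::pairwise.t.test(y, gf, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    means <- tapply(y, gf, mean)
    ns <- tapply(y, gf, length)
    combos <- utils::combn(names(samples), 2)
    ph <- do.call(rbind, lapply(seq_len(ncol(combos)), function(c2) {
      g1 <- combos[1, c2]; g2 <- combos[2, c2]
      pB <- pw$p.value[g2, g1]
      if (is.na(pB)) pB <- pw$p.value[g1, g2]
      ## Scheffe: reject when the pairwise F exceeds (k-1) F_alpha
      Fpair <- (means[g1] - means[g2])^2 /
        (mse * (1 / ns[g1] + 1 / ns[g2]))
      crit <- (k - 1) * stats::qf(1 - alpha, k - 1, N - k)
      data.frame(group1 = g1, group2 = g2, pBonferroni = pB,
                 rejectBonferroni = pB < alpha,
                 rejectScheffe = unname(Fpair) > crit)
    }))
    rownames(ph) <- NULL
    new("GroupComparison", design = "multi-group", transform = transform,
        groups = groups, statistic = Fval,
        df = as.numeric(dfs), pValue = an$`Pr(>F)`[1],
        postHoc = ph, alpha = alpha)
  }
}

#' Pearson correlation between two image-derived quantities
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom. Used, e.g., for the
#' association between SRM area and precipitate area across images.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `r`, `p`, `n`, `df`.
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation degenerate")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}
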
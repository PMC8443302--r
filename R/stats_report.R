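# Condition-level statistics mirroring the study's reporting conventions:
# one-way ANOVA with significance stars, Tukey-fence outlier flags (flagged,
# never removed), and per-condition summary tables.

#' Significance stars for a p value
#' @param p p value in `[0, 1]`.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or `""`.
#' @export
p_stars <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' One-way ANOVA across condition samples
#'
#' Classical fixed-effects one-way ANOVA via `stats::lm`/`stats::anova`.
#' Each sample is one condition with one value per device. A zero
#' total-variance input returns `F = 0, p = 1` with a flag rather than
#' failing.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return an `AnovaResult`: list with `F`, `df_between`, `df_within`,
#'   `p`, `stars`, `zero_variance`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs n >= 2; got n = ",
         paste(ns, collapse = ", "))
  values <- unlist(groups, use.names = FALSE)
  stopifnot(all(is.finite(values)))
  cond <- factor(rep(seq_along(groups), ns))
  if (stats::var(values) == 0) {
    res <- list(F = 0, df_between = length(groups) - 1L,
                df_within = length(values) - length(groups),
                p = 1, stars = "", zero_variance = TRUE)
    class(res) <- "AnovaResult"
    return(res)
  }
  tab <- stats::anova(stats::lm(values ~ cond))
  Fv <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }
  structure(list(F = Fv, df_between = tab$Df[1L], df_within = tab$Df[2L],
                 p = p, stars = p_stars(p), zero_variance = FALSE),
            class = "AnovaResult")
}

#' Flag outliers by the Tukey IQR fence
#'
#' Values outside `[Q1 - mult*IQR, Q3 + mult*IQR]` are flagged; flagged
#' values stay in every downstream analysis (they are plotted as crosses,
#' not excluded). Quartiles use the default quantile definition.
#'
#' @param values numeric vector.
#' @param mult fence multiplier (default 1.5).
#' @return logical vector of flags (all `FALSE`, with a warning, if
#'   `n < 4`).
#' @export
flag_outliers <- function(values, mult = 1.5) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 4L) {
    warning("n < 4: too few values to flag outliers")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - mult * iqr | values > q[2L] + mult * iqr
}

#' Summarise conditions and pairwise significance
#'
#' Per condition: n, mean, median, min, max, outlier count; plus a
#' pairwise ANOVA star matrix (two-group ANOVA, equivalent to the squared
#' pooled-variance t test). No multiple-testing correction by default,
#' matching per-figure unadjusted reporting; `bonferroni = TRUE` scales
#' the pairwise p values by the number of comparisons.
#'
#' @param samples named list of numeric vectors.
#' @param fence_mult Tukey fence multiplier (default 1.5).
#' @param bonferroni apply Bonferroni correction to pairwise p values.
#' @return list with `table` (data.frame), `pairwise` (data.frame of
#'   group1, group2, F, p, stars).
#' @export
summarize_conditions <- function(samples, fence_mult = 1.5,
                                 bonferroni = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  tab <- do.call(rbind, lapply(names(samples), function(nm) {
    v <- samples[[nm]]
    fl <- if (length(v) >= 4L) flag_outliers(v, fence_mult)
          else rep(FALSE, length(v))
    data.frame(condition = nm, n = length(v), mean = mean(v),
               median = stats::median(v), min = min(v), max = max(v),
               n_outliers = sum(fl))
  }))
  pairs <- if (length(samples) >= 2L) utils::combn(names(samples), 2L)
           else matrix(character(), 2L, 0L)
  n_cmp <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(n_cmp), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    a <- one_way_anova(samples[c(g1, g2)])
    p <- if (bonferroni) min(1, a$p * n_cmp) else a$p
    data.frame(group1 = g1, group2 = g2, F = a$F, p = p,
               stars = p_stars(p))
  }))
  if (is.null(pairwise))
    pairwise <- data.frame(group1 = character(), group2 = character(),
                           F = numeric(), p = numeric(), stars = character())
  list(table = tab, pairwise = pairwise)
}
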
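## Group statistics used for bloom-colour comparisons: Kruskal-Wallis with
## Dunn's post hoc pairwise tests, Pearson correlation and ordinary
## least-squares fits against log10 abundance.

.as_groups <- function(values, groups) {
  if (is.list(values) && missing(groups)) {
    g <- rep(names(values) %||% as.character(seq_along(values)),
             lengths(values))
    values <- unlist(values, use.names = FALSE)
    groups <- g
  }
  groups <- as.factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0))
    stop("every group needs at least one observation", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (length(values) < 3) stop("need at least three observations total",
                               call. = FALSE)
  list(values = as.numeric(values), groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kruskal-Wallis rank-sum test across groups
#'
#' Rank-based H statistic with the standard mid-rank tie correction and a
#' chi-square p-value on k-1 degrees of freedom (via
#' [stats::kruskal.test()]). Accepts either a named list of numeric
#' vectors or a value vector plus a group vector.
#'
#' @param values numeric vector of observations, or a named list of
#'   numeric vectors (one per group).
#' @param groups group labels (ignored when `values` is a list).
#' @return A list with `h` (the H statistic), `p`, `df` and `n`.
#' @examples
#' kruskalWallis(list(a = 1:3, b = 4:6, c = 7:9))$h  # 7.2
#' @export
kruskalWallis <- function(values, groups) {
  d <- .as_groups(values, groups)
  kt <- stats::kruskal.test(d$values, d$groups)
  list(h = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter), n = length(d$values))
}

#' Dunn's post hoc pairwise comparisons of mean ranks
#'
#' Pairwise z statistics on the groups' mean ranks with the pooled-rank
#' tie correction, following a Kruskal-Wallis test. The z statistic for a
#' pair (i, j) is `(Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tied value groups. Two-sided
#' p-values are adjusted across all `k(k-1)/2` comparisons, by Bonferroni
#' by default (Holm available).
#'
#' @inheritParams kruskalWallis
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return A data.frame with columns `group_a`, `group_b`, `z`, `p`,
#'   `p_adjusted`, `stars`.
#' @export
dunnPosthoc <- function(values, groups, adjust = c("bonferroni", "holm",
                                                   "none")) {
  adjust <- match.arg(adjust)
  d <- .as_groups(values, groups)
  x <- d$values; g <- d$groups
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (12 * (n - 1))
  meanrank <- tapply(r, g, mean)
  sizes <- tabulate(g, nbins = nlevels(g))
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tiecorr) *
               (1 / sizes[i] + 1 / sizes[j]))
    if (se == 0) 0 else (meanrank[i] - meanrank[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = if (adjust == "none") "none"
                                       else adjust)
  data.frame(group_a = lev[pairs[1, ]], group_b = lev[pairs[2, ]],
             z = as.numeric(z), p = p, p_adjusted = p_adj,
             stars = significanceStars(p_adj), stringsAsFactors = FALSE)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length numeric vectors (n >= 3) with non-zero
#'   variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least three observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}

#' Ordinary least squares of a response on log10 abundance
#'
#' Fits `response ~ log10(abundance)` and returns the slope, r-squared and
#' the slope's two-sided p-value; the regression used to relate
#' reflectance or IRF to cell density or biovolume.
#'
#' @param response numeric response vector.
#' @param abundance positive abundances (cells ml-1 or um^3 ml-1).
#' @return A list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
fitLogAbundance <- function(response, abundance) {
  if (length(response) != length(abundance))
    stop("response and abundance must have equal length", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("abundances must be positive", call. = FALSE)
  fit <- stats::lm(response ~ log10(abundance))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(response))
}

#' Significance stars at 0.05 / 0.01 / 0.001
#'
#' @param p numeric vector of p-values.
#' @return Character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Two-way ANOVA interface for pigment abundances (not implemented)
#'
#' Bloom-colour studies occasionally report a two-way ANOVA on pigment
#' abundances, but with a single sampling campaign the second factor and
#' the error structure of such a design are not identifiable from the
#' inputs this package models, so no defensible implementation exists
#' here. This stub documents the intended interface and always signals an
#' error; use [kruskalWallis()] plus [dunnPosthoc()] for the supported
#' group comparisons, or [stats::aov()] directly once a full factorial
#' design is available.
#'
#' @param data a data.frame with columns `pigment`, `color_group`, `value`.
#' @return Never returns; signals a "not implemented" error.
#' @export
pigmentTwoWayAnova <- function(data) {
  stop("two-way ANOVA of pigment abundances is not implemented: the ",
       "factorial design is not identifiable from single-campaign data; ",
       "see ?pigmentTwoWayAnova", call. = FALSE)
}
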
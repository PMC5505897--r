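# Shared statistical primitives: Benjamini-Hochberg step-up, one-way
# ANOVA and Tukey HSD. ANOVA and Tukey are computed with the base stats
# machinery; the wrappers add input validation and explicit conventions
# for degenerate (zero-variance) inputs.

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: for ordered p-values, `q_(i) = min_{j >= i}
#' m * p_(j) / j`, capped at 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA not allowed).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of the
#' between-group to the within-group mean square, with a p-value from the
#' F distribution. When the between-group sum of squares is exactly zero
#' (identical group means) the convention `F = 0`, `p = 1` is used; when
#' the within-group sum of squares is zero but group means differ,
#' `F = Inf`, `p = 0`.
#'
#' @param values numeric response vector, or a list of per-group sample
#'   vectors (in which case `groups` is ignored).
#' @param groups group label per value.
#' @return A list with `F`, `p`, `df` (numerator, denominator degrees of
#'   freedom) and `groupMeans`.
#' @examples
#' anovaOneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @importFrom stats aov pf
#' @export
anovaOneway <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(names2(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 1L)) stop("every group needs >= 1 value")
  n <- length(values)
  if (n - nlevels(groups) < 1L) {
    stop("need >= 1 error degree of freedom", call. = FALSE)
  }
  gm <- tapply(values, groups, mean)
  df1 <- nlevels(groups) - 1L
  df2 <- n - nlevels(groups)
  ssb <- sum(table(groups) * (gm - mean(values))^2)
  # exact degenerate checks (aov's QR leaves O(1e-30) residual noise)
  ssw <- sum(vapply(split(values, groups),
                    function(v) sum((v - mean(v))^2), 0))
  if (ssb == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2), groupMeans = gm))
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df = c(df1, df2), groupMeans = gm))
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1L]]
  list(F = s[1L, "F value"], p = s[1L, "Pr(>F)"], df = c(df1, df2),
       groupMeans = gm)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  nm
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted p-values for every group pair, using the
#' pooled within-group variance from the one-way ANOVA fit. With zero
#' pooled variance the convention is p = 1 for identical pairs and p = 0
#' for pairs with different means.
#'
#' @inheritParams anovaOneway
#' @return A data.frame with `pair` (e.g. `"DR-AL"`), `diff` (difference
#'   of group means), and `padj`.
#' @examples
#' tukeyHsd(list(AL = c(70, 71, 72), DR = c(60, 61, 62)))
#' @importFrom stats aov TukeyHSD
#' @export
tukeyHsd <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(names2(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) - nlevels(groups) < 1L) {
    stop("need >= 1 error degree of freedom", call. = FALSE)
  }
  wss <- sum(vapply(split(values, groups),
                    function(v) sum((v - mean(v))^2), 0))
  if (wss == 0) {
    # zero pooled variance: exact means decide each pair directly
    gm <- tapply(values, groups, mean)
    pr <- utils::combn(levels(groups), 2L)
    d <- gm[pr[2L, ]] - gm[pr[1L, ]]
    return(data.frame(pair = paste(pr[2L, ], pr[1L, ], sep = "-"),
                      diff = unname(d), padj = as.numeric(d == 0)))
  }
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             padj = tk[, "p adj"], row.names = NULL)
}
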
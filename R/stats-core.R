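#' Two-sample Student's t-test
#'
#' Thin wrapper around [stats::t.test()] exposing the classic
#' pooled-variance Student's test (the default) and the Welch variant,
#' returning the statistic, degrees of freedom and two-sided p-value.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @return A list with components `t`, `df` and `p`.
#' @details When both samples have zero variance and equal means the test
#'   is degenerate; by convention `t = 0`, `p = 1` is returned.
#' @examples
#' student_t(c(5.1, 4.9, 5.0), c(6.2, 6.0, 6.1))
#' @export
student_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate data: equal means are maximally consistent with the
    # null, unequal means maximally inconsistent
    df0 <- length(a) + length(b) - 2L
    if (mean(a) == mean(b)) return(list(t = 0, df = df0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df0, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA over a list of groups, via
#' [stats::lm()]/[stats::anova()].
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return A list with components `F`, `df1`, `df2`, `p`, plus per-group
#'   `means` and `n`, and the residual mean square `mse` (used by
#'   [duncan_mrt()]).
#' @details If all observations are identical the decomposition is
#'   degenerate; `F = 0`, `p = 1` is returned by convention.
#' @examples
#' one_way_anova(list(a = rnorm(5), b = rnorm(5, 2), c = rnorm(5)))
#' @export
one_way_anova <- function(groups) {
  groups <- validate_groups(groups, min_groups = 2L)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df2 <- length(y) - length(groups)
  if (stats::var(y) == 0) {
    return(list(F = 0, df1 = length(groups) - 1L, df2 = df2, p = 1,
                means = vapply(groups, mean, 0), n = lengths(groups),
                mse = 0))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"],
       means = vapply(groups, mean, 0), n = lengths(groups),
       mse = tab[2, "Mean Sq"])
}

#' Duncan's multiple range test
#'
#' Post-hoc letter grouping of group means after a one-way ANOVA, using
#' Duncan's sequential studentized-range criterion. Critical points are
#' computed from the studentized range distribution ([stats::qtukey()])
#' at Duncan's protection level `1 - (1 - alpha)^(p - 1)` for a stretch
#' of `p` ordered means, so no tabulated values are needed and any error
#' degrees of freedom are supported.
#'
#' @param groups Named list of numeric vectors (>= 1 group).
#' @param alpha Significance level for each pairwise protection step
#'   (default 0.05).
#' @return A data frame with one row per group, sorted by decreasing
#'   mean: `group`, `mean`, `n`, `letters`. Groups sharing a letter are
#'   not significantly different under Duncan's criterion.
#' @details With unequal group sizes the harmonic mean of the sizes in
#'   each compared stretch is used in the standard error, the usual
#'   approximation for unbalanced designs. A single group is lettered
#'   `"a"` without any test.
#' @examples
#' set.seed(1)
#' duncan_mrt(list(lo = rnorm(5), hi = rnorm(5, 8), mid = rnorm(5, 4)))
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  groups <- validate_groups(groups, min_groups = 1L)
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ns <- ns[ord]
  if (k == 1L) {
    return(data.frame(group = names(means), mean = unname(means),
                      n = unname(ns), letters = "a",
                      stringsAsFactors = FALSE))
  }
  fit <- one_way_anova(groups)
  mse <- fit$mse
  df2 <- fit$df2

  # significant[i, j]: means i..j (ordered) span a significant range
  signif_pair <- function(i, j) {
    if (mse == 0) return(means[i] != means[j])
    p <- j - i + 1L
    nh <- p / sum(1 / ns[i:j])           # harmonic mean n of the stretch
    crit <- stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df2,
                          lower.tail = TRUE) * sqrt(mse / nh)
    (means[i] - means[j]) > crit
  }

  # Duncan's stepwise rule: a stretch is declared non-significant (and not
  # subdivided further) as soon as its range fails the critical value.
  nonsig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) nonsig[i, i] <- TRUE
  for (span in 1:(k - 1L)) {
    for (i in seq_len(k - span)) {
      j <- i + span
      if ((i > 1L && nonsig[i - 1L, j]) || (j < k && nonsig[i, j + 1L])) {
        nonsig[i, j] <- TRUE              # contained in a retained stretch
      } else {
        nonsig[i, j] <- !signif_pair(i, j)
      }
    }
  }
  # maximal non-significant stretches become letters
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    stretches[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && keep[i] &&
          stretches[[j]][1] <= stretches[[i]][1] &&
          stretches[[j]][2] >= stretches[[i]][2] &&
          !identical(stretches[[i]], stretches[[j]])) keep[i] <- FALSE
    }
  }
  stretches <- unique(stretches[keep])
  lett <- character(k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    idx <- rng[1]:rng[2]
    lett[idx] <- paste0(lett[idx], letters[((s - 1L) %% 26L) + 1L])
  }
  data.frame(group = names(means), mean = unname(means), n = unname(ns),
             letters = lett, stringsAsFactors = FALSE)
}

# shared validation for grouped samples
validate_groups <- function(groups, min_groups) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop("need at least ", min_groups, " group(s)", call. = FALSE)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (any(vapply(groups, function(x) anyNA(x) || any(!is.finite(x)), TRUE)))
    stop("observations must be finite and non-missing", call. = FALSE)
  groups
}

#' Round half away from zero
#'
#' Percentage reporting uses half-up rounding (so 72.66 -> 72.7), unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
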
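new_stat_result <- function(route, omnibus, comparisons, group_means,
                            degenerate = FALSE) {
  structure(list(route = route, omnibus = omnibus, comparisons = comparisons,
                 group_means = group_means, degenerate = degenerate,
                 transform = "none"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("Route:", x$route,
      if (x$transform != "none") paste0("(", x$transform, "-transformed)"),
      "\n")
  if (x$degenerate) cat("  [degenerate input: omnibus undefined]\n")
  print(x$omnibus)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("Post hoc:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`; with a single comparison the raw p is returned
#' unchanged.
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-values, bounded by 1 and never below the raw p.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' One-way ANOVA with Dunnett's many-to-one post hoc
#'
#' Omnibus F with (k-1, N-k) degrees of freedom, followed by Dunnett
#' comparisons of every dose group against the labeled control at familywise
#' alpha. All-constant input (zero residual variance and equal means) is
#' flagged degenerate rather than producing a spurious statistic.
#'
#' @param data Data frame.
#' @param value,group Column names of response and grouping factor.
#' @param control Control group label; defaults to the factor's first level.
#'   An absent label is an error.
#' @return A `stat_result`: `omnibus` tibble (statistic, df1, df2,
#'   p_value), `comparisons` tibble (comparison, estimate, p_adj),
#'   `group_means`.
#' @export
one_way_dunnett <- function(data, value, group, control = NULL) {
  stopifnot(all(c(value, group) %in% names(data)))
  g <- factor(data[[group]])
  if (!is.null(control)) {
    if (!control %in% levels(g)) {
      stop("control group '", control, "' not present")
    }
    g <- stats::relevel(g, ref = control)
  }
  y <- data[[value]]
  d <- data.frame(y = y, g = g)
  means <- tapply(y, g, mean)
  if (stats::sd(y) == 0) {
    return(new_stat_result(
      "parametric",
      tibble::tibble(statistic = NA_real_, df1 = nlevels(g) - 1,
                     df2 = length(y) - nlevels(g), p_value = NA_real_),
      NULL, means, degenerate = TRUE
    ))
  }
  fit <- stats::aov(y ~ g, data = d)
  an <- stats::anova(fit)
  omnibus <- tibble::tibble(
    statistic = an[1, "F value"], df1 = an[1, "Df"], df2 = an[2, "Df"],
    p_value = an[1, "Pr(>F)"]
  )
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(glht)
  comparisons <- tibble::tibble(
    comparison = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    p_adj = unname(as.vector(sm$test$pvalues))
  )
  new_stat_result("parametric", omnibus, comparisons, means)
}

#' Two-way factorial ANOVA with Sidak or Tukey cell comparisons
#'
#' Full-effects model `value ~ A * B` (interaction included) by default;
#' `model = "additive"` drops the interaction. Post hocs follow the two
#' configurations used for factorial dose designs: Sidak-adjusted
#' comparisons of factor A levels within each level of B, or Tukey all-pairs
#' of factor B within each level of A.
#'
#' @param data Data frame.
#' @param value Response column name.
#' @param factors Character vector of the two crossed factor column names
#'   `c(A, B)`.
#' @param posthoc `"sidak_within_b"`, `"tukey_within_a"`, or `"none"`.
#' @param model `"full"` (interaction) or `"additive"`.
#' @return A `stat_result`; `omnibus` has one row per model term.
#' @export
two_way_factorial <- function(data, value, factors,
                              posthoc = c("sidak_within_b", "tukey_within_a",
                                          "none"),
                              model = c("full", "additive")) {
  posthoc <- match.arg(posthoc)
  model <- match.arg(model)
  stopifnot(length(factors) == 2, all(c(value, factors) %in% names(data)))
  d <- data.frame(
    y = data[[value]],
    A = factor(data[[factors[1]]]),
    B = factor(data[[factors[2]]])
  )
  cell_n <- table(d$A, d$B)
  if (model == "full") {
    if (any(cell_n == 0)) {
      stop("empty cell(s): interaction model needs every A x B cell filled")
    }
    if (all(cell_n < 2)) {
      stop("interaction model needs >= 2 replicates in at least one cell")
    }
    fit <- stats::aov(y ~ A * B, data = d)
  } else {
    fit <- stats::aov(y ~ A + B, data = d)
  }
  an <- stats::anova(fit)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  omnibus <- tibble::tibble(
    term = gsub("A", factors[1], gsub("B", factors[2], terms[keep])),
    statistic = an[keep, "F value"], df1 = an[keep, "Df"],
    df2 = an["Residuals", "Df"], p_value = an[keep, "Pr(>F)"]
  )
  comparisons <- NULL
  if (posthoc == "sidak_within_b") {
    emm <- emmeans::emmeans(fit, ~ A | B)
    prs <- summary(graphics::pairs(emm, adjust = "sidak"))
    comparisons <- tibble::tibble(
      comparison = paste(prs$contrast, "|", prs$B),
      estimate = prs$estimate, p_adj = prs$p.value
    )
  } else if (posthoc == "tukey_within_a") {
    emm <- emmeans::emmeans(fit, ~ B | A)
    prs <- summary(graphics::pairs(emm, adjust = "tukey"))
    comparisons <- tibble::tibble(
      comparison = paste(prs$contrast, "|", prs$A),
      estimate = prs$estimate, p_adj = prs$p.value
    )
  }
  means <- tapply(d$y, list(d$A, d$B), mean)
  res <- new_stat_result("two_way", omnibus, comparisons, means)
  res$model <- model
  res
}

# Studentized maximum modulus distribution function:
# P(max_i |T_i| <= q) for k independent-numerator t variates sharing one
# chi-square denominator with df degrees of freedom.
psmm <- function(q, k, df) {
  if (q <= 0) return(0)
  if (!is.finite(df)) return((2 * stats::pnorm(q) - 1)^k)
  # s = chi_df / sqrt(df); chi density evaluated on the log scale to stay
  # finite at large df
  dens <- function(s) {
    x <- s * sqrt(df)
    exp(0.5 * log(df) + (1 - df / 2) * log(2) + (df - 1) * log(x) -
          x^2 / 2 - lgamma(df / 2))
  }
  f <- function(s) (2 * stats::pnorm(q * s) - 1)^k * dens(s)
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' Brown-Forsythe and Welch ANOVA with Dunnett T3 post hoc
#'
#' Heteroscedasticity-robust omnibus tests: Welch's ANOVA
#' ([stats::oneway.test()] with `var.equal = FALSE`) and the Brown-Forsythe
#' F* statistic (between-group sum of squares over
#' `sum((1 - n_i/N) s_i^2)`, with Satterthwaite denominator df). Pairwise
#' comparisons use Dunnett's T3: Welch t statistics referred to the
#' studentized maximum modulus distribution with the family size and each
#' pair's own Welch-Satterthwaite df.
#'
#' @inheritParams one_way_dunnett
#' @return A `stat_result`; `omnibus` has rows "welch" and
#'   "brown_forsythe".
#' @export
welch_bf_dunnett_t3 <- function(data, value, group) {
  stopifnot(all(c(value, group) %in% names(data)))
  g <- factor(data[[group]])
  y <- data[[value]]
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups")
  ns <- tapply(y, g, length)
  if (any(ns < 2)) stop("every group needs n >= 2")
  means <- tapply(y, g, mean)
  vars <- tapply(y, g, stats::var)
  N <- length(y)

  if (all(vars == 0)) {
    return(new_stat_result(
      "welch_bf",
      tibble::tibble(test = c("welch", "brown_forsythe"),
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p_value = NA_real_),
      NULL, means, degenerate = TRUE
    ))
  }

  w <- stats::oneway.test(y ~ g, var.equal = FALSE)

  grand <- mean(y)
  bf_num <- sum(ns * (means - grand)^2)
  ci <- (1 - ns / N) * vars
  bf_den <- sum(ci)
  bf_stat <- bf_num / bf_den
  cprop <- ci / bf_den
  bf_df2 <- 1 / sum(cprop^2 / (ns - 1))
  bf_p <- stats::pf(bf_stat, k - 1, bf_df2, lower.tail = FALSE)

  omnibus <- tibble::tibble(
    test = c("welch", "brown_forsythe"),
    statistic = c(unname(w$statistic), bf_stat),
    df1 = c(unname(w$parameter[1]), k - 1),
    df2 = c(unname(w$parameter[2]), bf_df2),
    p_value = c(w$p.value, bf_p)
  )

  lv <- levels(g)
  prs <- utils::combn(lv, 2)
  m <- ncol(prs)
  comparisons <- lapply(seq_len(m), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    se2a <- vars[[a]] / ns[[a]]; se2b <- vars[[b]] / ns[[b]]
    se <- sqrt(se2a + se2b)
    est <- means[[a]] - means[[b]]
    if (se == 0) {
      return(tibble::tibble(comparison = paste(a, "-", b), estimate = est,
                            statistic = if (est == 0) 0 else Inf,
                            df = NA_real_,
                            p_adj = if (est == 0) 1 else 0))
    }
    tstat <- est / se
    df <- (se2a + se2b)^2 /
      (se2a^2 / (ns[[a]] - 1) + se2b^2 / (ns[[b]] - 1))
    tibble::tibble(comparison = paste(a, "-", b), estimate = est,
                   statistic = tstat, df = df,
                   p_adj = 1 - psmm(abs(tstat), m, df))
  })
  new_stat_result("welch_bf", omnibus, dplyr::bind_rows(comparisons), means)
}

#' Kruskal-Wallis fallback route
#'
#' @inheritParams one_way_dunnett
#' @return A `stat_result` wrapping [stats::kruskal.test()].
#' @export
kruskal_route <- function(data, value, group) {
  g <- factor(data[[group]])
  y <- data[[value]]
  kw <- stats::kruskal.test(y ~ g)
  new_stat_result(
    "kruskal",
    tibble::tibble(statistic = unname(kw$statistic),
                   df1 = unname(kw$parameter), df2 = NA_real_,
                   p_value = kw$p.value),
    NULL, tapply(y, g, mean)
  )
}
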
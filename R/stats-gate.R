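#' Assumption-gated routing of a group comparison to a test family
#'
#' Reproduces a pre-registered decision tree: Shapiro-Wilk per group and
#' Levene's test (F type, mean-centered, outliers included) at alpha 0.05
#' decide the route. Both pass: parametric ANOVA. Normality fails: the data
#' are log-transformed and re-tested; if normality still fails (or the data
#' are not strictly positive) the route is Kruskal-Wallis. Normality holds
#' (possibly after log) but variance homogeneity fails: Welch /
#' Brown-Forsythe with Dunnett T3. Groups too small for Shapiro-Wilk (n < 3)
#' route nonparametric with a warning. Sphericity (Mauchly /
#' Greenhouse-Geisser) applies only to repeated-measures designs and is
#' inert for the between-subjects designs handled here.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor. For two-way designs `group` may name two columns.
#' @param design `"one_way"` or `"two_way"`.
#' @param alpha Gate significance level, fixed at 0.05 by convention.
#' @return A list of class `stat_plan`: `route` (one of "parametric",
#'   "welch_bf", "kruskal"), `posthoc`, `transform` ("none" or "log"),
#'   `assumptions` (Levene p, per-group Shapiro p, before and after
#'   transform), `design`, `alpha`, and `audit` — a character log of every
#'   gate decision.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(30), g = rep(letters[1:3], each = 10))
#' gate(d, "y", "g")$route
gate <- function(data, value, group, design = c("one_way", "two_way"),
                 alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(is.data.frame(data), all(c(value, group) %in% names(data)))
  y <- data[[value]]
  g <- interaction(data[group], drop = TRUE)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tapply(y, g, length) < 2)) stop("need >= 2 observations per group")
  audit <- character(0)
  log_note <- function(msg) audit <<- c(audit, msg)

  shapiro_by_group <- function(yy) {
    ns <- tapply(yy, g, length)
    if (any(ns < 3)) return(NULL) # too small for Shapiro-Wilk
    vapply(split(yy, g), function(v) {
      if (stats::sd(v) == 0) return(0) # degenerate: constant group
      stats::shapiro.test(v)$p.value
    }, numeric(1))
  }
  levene_p <- function(yy) {
    # F-type Levene, mean-centered, outliers included
    car::leveneTest(yy ~ g, center = mean)[1, "Pr(>F)"]
  }

  transform <- "none"
  sw <- shapiro_by_group(y)
  if (is.null(sw)) {
    log_note("groups too small for Shapiro-Wilk: routed nonparametric")
    warning("group size < 3: Shapiro-Wilk unavailable, routing to ",
            "Kruskal-Wallis")
    plan <- list(route = "kruskal", posthoc = "none", transform = "none",
                 assumptions = list(shapiro_p = NULL, levene_p = NA_real_),
                 design = design, alpha = alpha, audit = audit)
    class(plan) <- "stat_plan"
    return(plan)
  }
  sw_raw <- sw
  normal <- all(sw > alpha)
  log_note(sprintf("Shapiro-Wilk (raw): min p = %.4g -> %s", min(sw),
                   if (normal) "pass" else "violated"))
  y_used <- y
  if (!normal) {
    if (all(y > 0)) {
      y_log <- log(y)
      sw_log <- shapiro_by_group(y_log)
      if (all(sw_log > alpha)) {
        transform <- "log"
        y_used <- y_log
        sw <- sw_log
        normal <- TRUE
        log_note(sprintf(
          "log-transform restored normality (min p = %.4g)", min(sw_log)))
      } else {
        log_note(sprintf(
          "log-transform did not restore normality (min p = %.4g)",
          min(sw_log)))
      }
    } else {
      log_note("nonpositive values: log-transform unavailable")
    }
  }
  if (!normal) {
    log_note("normality violated -> Kruskal-Wallis route")
    plan <- list(route = "kruskal", posthoc = "none", transform = "none",
                 assumptions = list(shapiro_p = sw_raw,
                                    levene_p = levene_p(y)),
                 design = design, alpha = alpha, audit = audit)
    class(plan) <- "stat_plan"
    return(plan)
  }
  lev <- levene_p(y_used)
  homoscedastic <- lev > alpha
  log_note(sprintf("Levene (F type, mean-centered): p = %.4g -> %s", lev,
                   if (homoscedastic) "pass" else "violated"))
  if (!homoscedastic) {
    route <- "welch_bf"
    posthoc <- "dunnett_t3"
    log_note("variance heterogeneity -> Brown-Forsythe & Welch + Dunnett T3")
  } else {
    route <- "parametric"
    posthoc <- if (design == "one_way") "dunnett" else "sidak"
    log_note(paste0("assumptions met -> parametric ANOVA + ",
                    if (design == "one_way") "Dunnett" else "Sidak"))
  }
  plan <- list(route = route, posthoc = posthoc, transform = transform,
               assumptions = list(shapiro_p = sw_raw, levene_p = lev),
               design = design, alpha = alpha, audit = audit)
  class(plan) <- "stat_plan"
  plan
}

#' @export
print.stat_plan <- function(x, ...) {
  cat("Statistical plan (", x$design, " design)\n", sep = "")
  cat("  route:    ", x$route, "\n  posthoc:  ", x$posthoc,
      "\n  transform:", x$transform, "\n  audit:\n", sep = "")
  for (a in x$audit) cat("   -", a, "\n")
  invisible(x)
}

#' Execute a gated plan on one-way data
#'
#' Dispatches to the route chosen by [gate()]: [one_way_dunnett()],
#' [welch_bf_dunnett_t3()], or Kruskal-Wallis. When the plan's transform is
#' `"log"`, analysis runs on log values and group means are back-transformed
#' (geometric means) for display.
#'
#' @param plan A `stat_plan` from [gate()].
#' @param data,value,group As in [gate()].
#' @param control Control group label (for Dunnett-style comparisons).
#' @return A `stat_result` (see [one_way_dunnett()]).
#' @export
execute_plan <- function(plan, data, value, group, control = NULL) {
  stopifnot(inherits(plan, "stat_plan"))
  if (plan$transform == "log") data[[value]] <- log(data[[value]])
  res <- switch(plan$route,
    parametric = one_way_dunnett(data, value, group, control),
    welch_bf = welch_bf_dunnett_t3(data, value, group),
    kruskal = kruskal_route(data, value, group)
  )
  res$transform <- plan$transform
  if (plan$transform == "log") {
    res$group_means <- exp(res$group_means) # geometric means of raw data
  }
  res
}
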
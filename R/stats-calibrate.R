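#' Simulated null type-I error of a routed test family
#'
#' Monte-Carlo calibration harness: simulates data under the null hypothesis
#' of the named route, runs the package's own test implementation on every
#' replicate, and returns the fraction of replicates with any rejection at
#' `alpha` — the familywise type-I error for post hoc families, the omnibus
#' type-I error for single-statistic routes.
#'
#' Routes and their null models:
#' * `"one_way_dunnett"`: k equal-variance normal groups; rejection = any
#'   Dunnett-adjusted p < alpha.
#' * `"two_way_interaction"`: crossed factorial with no effects; rejection =
#'   interaction F p < alpha.
#' * `"welch"`: heteroscedastic groups (per-group `sds`); rejection = Welch
#'   omnibus p < alpha.
#' * `"dunnett_t3"`: heteroscedastic groups; rejection = any T3-adjusted
#'   p < alpha.
#' * `"kruskal"`: equal shifted exponential groups; rejection = omnibus
#'   p < alpha.
#' * `"anova_hetero"`: classic equal-variance ANOVA applied (wrongly) to
#'   heteroscedastic unbalanced groups — a negative control expected to
#'   exceed nominal alpha.
#'
#' @param route One of the routes above.
#' @param n_sims Number of simulated null datasets.
#' @param seed Master seed (each replicate derives its own substream).
#' @param k Number of groups (one-way routes).
#' @param n_per_group Observations per group; recycled to length `k`.
#' @param sds Per-group standard deviations; recycled to length `k`.
#' @param levels_a,levels_b,n_per_cell Two-way design shape.
#' @param alpha Nominal level.
#' @return List: `type_i_error`, `n_sims`, `route`, `alpha`.
#' @export
calibrate_route <- function(route = c("one_way_dunnett",
                                      "two_way_interaction", "welch",
                                      "dunnett_t3", "kruskal",
                                      "anova_hetero"),
                            n_sims = 2000, seed = 1, k = 3,
                            n_per_group = 10, sds = 1,
                            levels_a = 2, levels_b = 3, n_per_cell = 5,
                            alpha = 0.05) {
  route <- match.arg(route)
  n_per_group <- rep_len(n_per_group, k)
  sds <- rep_len(sds, k)
  g <- factor(rep(seq_len(k), times = n_per_group))
  sd_vec <- rep(sds, times = n_per_group)

  sim_one <- function() {
    switch(route,
      one_way_dunnett = {
        d <- data.frame(y = stats::rnorm(length(g), 0, sd_vec), g = g)
        res <- one_way_dunnett(d, "y", "g", control = "1")
        any(res$comparisons$p_adj < alpha)
      },
      two_way_interaction = {
        d <- expand.grid(A = factor(seq_len(levels_a)),
                         B = factor(seq_len(levels_b)),
                         rep = seq_len(n_per_cell))
        d$y <- stats::rnorm(nrow(d))
        res <- two_way_factorial(d, "y", c("A", "B"), posthoc = "none")
        p <- res$omnibus$p_value[grepl(":", res$omnibus$term)]
        p < alpha
      },
      welch = {
        d <- data.frame(y = stats::rnorm(length(g), 0, sd_vec), g = g)
        res <- welch_bf_dunnett_t3(d, "y", "g")
        res$omnibus$p_value[res$omnibus$test == "welch"] < alpha
      },
      dunnett_t3 = {
        d <- data.frame(y = stats::rnorm(length(g), 0, sd_vec), g = g)
        res <- welch_bf_dunnett_t3(d, "y", "g")
        any(res$comparisons$p_adj < alpha)
      },
      kruskal = {
        d <- data.frame(y = stats::rexp(length(g)), g = g)
        res <- kruskal_route(d, "y", "g")
        res$omnibus$p_value < alpha
      },
      anova_hetero = {
        d <- data.frame(y = stats::rnorm(length(g), 0, sd_vec), g = g)
        an <- stats::anova(stats::aov(y ~ g, data = d))
        an[1, "Pr(>F)"] < alpha
      }
    )
  }

  rejections <- withr::with_seed(as.integer(seed),
                                 vapply(seq_len(n_sims),
                                        function(i) sim_one(), logical(1)))
  list(type_i_error = mean(rejections), n_sims = n_sims, route = route,
       alpha = alpha)
}
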
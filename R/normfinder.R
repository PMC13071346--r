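#' Model-based reference-gene stability (NormFinder-style)
#'
#' Ranks candidate housekeeping genes by a stability value combining
#' intergroup expression bias and intragroup variance, estimated by a two-way
#' variance decomposition on the Ct scale (Ct is already log2 of quantity up
#' to affine terms, so no transformation is applied).
#'
#' For each candidate gene i and experimental group g the model is
#' `ct = alpha_ig + beta_gk + eps`, where `beta_gk` is a per-sample effect
#' common to all genes (shared loading/biology) and `eps` has gene-specific
#' intragroup variance. The intergroup bias of gene i in group g is the
#' gene-by-group interaction `d_ig = (m_ig - m_i..) - (m_.g - m_...)`; the
#' intragroup variance is estimated from replicate residuals after removing
#' the per-sample effect, with the usual small-panel bias correction (needs
#' >= 3 candidates; with exactly 2 the per-sample effect is unidentifiable
#' and the plain per-(gene, group) sample variance is used instead). The
#' stability value of gene i is the mean over groups of
#' `|d_ig| + sqrt(var_ig / n_g)`; the lowest value wins, ties broken
#' alphabetically with a warning.
#'
#' @param table A Ct table ([as_ct_table()]).
#' @param candidates Character vector (>= 2) of candidate gene names.
#' @param group_vars Columns whose combination defines an experimental group
#'   (default status x dose).
#' @return A list of class `normfinder_result`: `stability` tibble (gene,
#'   stability, mean intragroup variance), `bias` tibble (gene, group,
#'   intergroup bias in Ct), `selected_gene`.
#' @export
#' @examples
#' truth <- ct_ground_truth(seed = 7, replicate_sd = 0.1,
#'   hk_bias = c("GAPDH.Diff" = 1))
#' tab <- generate_ct_table(truth, n_reps = 3)
#' normfinder_stability(tab)$selected_gene
normfinder_stability <- function(table,
                                 candidates = c("B-ACTIN", "PGK1", "GAPDH"),
                                 group_vars = c("group", "dose_mM")) {
  table <- as_ct_table(table)
  candidates <- sort(unique(candidates))
  present <- intersect(candidates, unique(table$gene))
  if (length(present) < 2) stop("need >= 2 candidate genes present in table")
  tab <- table[table$gene %in% present, , drop = FALSE]
  tab$grp <- interaction(tab[group_vars], drop = TRUE, sep = "|")
  groups <- levels(tab$grp)
  if (length(groups) < 2) stop("need >= 2 experimental groups")

  n_gene <- length(present)
  # cell means m[i, g] and per-cell replicate counts / variances
  m <- matrix(NA_real_, n_gene, length(groups),
              dimnames = list(present, groups))
  v_raw <- m  # plain per-(gene,group) sample variance
  n_rep <- m
  resid_var <- m  # residual variance after per-sample effect removal
  for (g in groups) {
    sub <- tab[tab$grp == g, , drop = FALSE]
    # align replicates across genes within the group
    wide <- tapply(sub$ct, list(sub$replicate, sub$gene), mean)
    wide <- wide[, present, drop = FALSE]
    complete <- stats::complete.cases(wide)
    if (sum(complete) < 2) {
      stop("group '", g, "' needs >= 2 replicates complete for all candidates")
    }
    wide <- wide[complete, , drop = FALSE]
    n_k <- nrow(wide)
    m[, g] <- colMeans(wide)
    n_rep[, g] <- n_k
    v_raw[, g] <- apply(wide, 2, stats::var)
    if (n_gene >= 3) {
      # residual after removing per-sample effect (row means)
      r <- sweep(wide, 1, rowMeans(wide)) # y_igk - ybar_.gk
      r <- sweep(r, 2, colMeans(r))       # ... - (ybar_ig. - ybar_.g.)
      s2 <- colSums(r^2) / (n_k - 1)
      # unbiased gene-specific variance given the shared-row-mean subtraction
      u <- sum(s2)
      resid_var[, g] <- pmax(
        (s2 - u / (n_gene * (n_gene - 1))) * n_gene / (n_gene - 2), 0
      )
    }
  }
  intra_var <- if (n_gene >= 3) resid_var else v_raw

  # gene-by-group interaction: bias in Ct units
  gene_mean <- rowMeans(m)
  grp_mean <- colMeans(m)
  grand <- mean(m)
  bias <- sweep(sweep(m, 1, gene_mean), 2, grp_mean - grand)

  per_group <- abs(bias) + sqrt(intra_var / n_rep)
  stability <- rowMeans(per_group)

  ord <- order(stability, names(stability))
  best <- names(stability)[ord[1]]
  near_tie <- sum(abs(stability - stability[ord[1]]) < 1e-12) > 1
  if (near_tie) {
    warning("stability tie among candidates; selected alphabetically: ", best)
  }

  structure(
    list(
      stability = tibble::tibble(
        gene = names(stability)[ord],
        stability = unname(stability[ord]),
        intragroup_variance = unname(rowMeans(intra_var)[ord])
      ),
      bias = tibble::tibble(
        gene = rep(rownames(bias), times = ncol(bias)),
        group = rep(colnames(bias), each = nrow(bias)),
        bias_ct = as.vector(bias)
      ),
      selected_gene = best
    ),
    class = "normfinder_result"
  )
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("Reference-gene stability (lower = more stable)\n")
  print(x$stability)
  cat("selected:", x$selected_gene, "\n")
  invisible(x)
}
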
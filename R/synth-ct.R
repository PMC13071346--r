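#' Ground truth for a synthetic qPCR Ct table
#'
#' Defines the true relative-expression structure that [generate_ct_table()]
#' realizes: per-(gene, group, dose) fold changes relative to the calibrator,
#' replicate noise, and optional group-wise bias of individual housekeeping
#' candidates (an unstable reference gene).
#'
#' The default design mirrors a differentiation-by-dose exposure experiment:
#' groups are \{UnDiff, Diff\} x \{0, 7, 35 mM\} with three biological
#' replicates downstream.
#'
#' @param genes Character vector of target genes.
#' @param hk_genes Housekeeping candidates (always generated; first one is
#'   unbiased unless `hk_bias` says otherwise).
#' @param statuses Differentiation status labels.
#' @param doses Doses in mM; the first is the calibrator dose.
#' @param fold_change Named numeric vector of true fold changes, names
#'   `"gene.status.dose"` (e.g. `"NRXN1a.Diff.35" = 0.25`); unnamed cells
#'   default to 1. All values must be positive; the calibrator cell
#'   (first status, first dose under the cross convention) must be 1.
#' @param replicate_sd Ct-unit standard deviation of i.i.d. replicate noise
#'   (>= 0).
#' @param hk_bias Named numeric vector, names `"hkgene.status"` or
#'   `"hkgene.status.dose"`, giving Ct offsets that make a housekeeping
#'   candidate group-unstable.
#' @param convention Calibrator convention the truth is expressed in;
#'   `"cross"` (default) fixes the first-status/first-dose cell at 1,
#'   `"within"` fixes each status's first-dose cell at 1.
#' @param seed Master seed; [generate_ct_table()] is deterministic given it.
#' @return A list of class `ct_ground_truth`.
#' @export
ct_ground_truth <- function(genes = c("NRXN1a", "NRXN2b", "NRXN3b"),
                            hk_genes = c("B-ACTIN", "PGK1", "GAPDH"),
                            statuses = c("UnDiff", "Diff"),
                            doses = c(0, 7, 35),
                            fold_change = NULL,
                            replicate_sd = 0.2,
                            hk_bias = NULL,
                            convention = c("cross", "within"),
                            seed = 1L) {
  convention <- match.arg(convention)
  stopifnot(replicate_sd >= 0, length(genes) >= 1, length(doses) >= 2)
  cells <- expand.grid(gene = genes, group = statuses, dose_mM = doses,
                       stringsAsFactors = FALSE)
  key <- paste(cells$gene, cells$group, cells$dose_mM, sep = ".")
  fc <- stats::setNames(rep(1, nrow(cells)), key)
  if (!is.null(fold_change)) {
    if (any(fold_change <= 0)) stop("fold changes must be positive")
    unknown <- setdiff(names(fold_change), key)
    if (length(unknown)) {
      stop("unknown fold_change cell(s): ", paste(unknown, collapse = ", "))
    }
    fc[names(fold_change)] <- fold_change
  }
  cal_dose <- doses[1]
  if (convention == "cross") {
    cal_key <- paste(genes, statuses[1], cal_dose, sep = ".")
  } else {
    cal_key <- as.vector(outer(genes, statuses,
                               function(g, s) paste(g, s, cal_dose, sep = ".")))
  }
  if (any(fc[cal_key] != 1)) {
    stop("true fold change of every calibrator group must be 1")
  }
  structure(
    list(
      genes = genes, hk_genes = hk_genes, statuses = statuses, doses = doses,
      fold_change = fc, replicate_sd = replicate_sd,
      hk_bias = hk_bias %||% stats::setNames(numeric(0), character(0)),
      convention = convention, seed = as.integer(seed)
    ),
    class = "ct_ground_truth"
  )
}

hk_bias_for <- function(truth, hk, status, dose) {
  b <- truth$hk_bias
  k2 <- paste(hk, status, sep = ".")
  k3 <- paste(hk, status, dose, sep = ".")
  out <- 0
  if (k2 %in% names(b)) out <- out + b[[k2]]
  if (k3 %in% names(b)) out <- out + b[[k3]]
  out
}

#' Generate a synthetic Ct table from ground truth
#'
#' Housekeeping candidates amplify at `base_ct` plus any configured group
#' bias; target genes amplify at `base_ct + baseline_dct - log2(FC)`, so the
#' expected delta-Ct of a (gene, group) cell against an unbiased housekeeping
#' gene equals the calibrator mean delta-Ct minus log2 of the true fold
#' change, and the ddCt pipeline recovers `fold_change` exactly at zero
#' noise. Replicate noise is i.i.d. Gaussian in Ct units; the generator is
#' deterministic given `truth$seed` (user RNG state is untouched).
#'
#' @param truth A [ct_ground_truth()] object.
#' @param n_reps Biological replicates per cell (>= 2).
#' @param base_ct Housekeeping Ct level (cycles, default 20).
#' @param baseline_dct Target-vs-housekeeping delta-Ct at the calibrator
#'   (default 2 cycles).
#' @return A Ct table tibble ([as_ct_table()]).
#' @export
generate_ct_table <- function(truth, n_reps = 3, base_ct = 20,
                              baseline_dct = 2) {
  stopifnot(inherits(truth, "ct_ground_truth"))
  if (n_reps < 2) stop("n_reps must be >= 2")
  cells <- expand.grid(
    gene = c(truth$hk_genes, truth$genes),
    group = truth$statuses, dose_mM = truth$doses,
    stringsAsFactors = FALSE
  )
  withr::with_seed(truth$seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      g <- cells$gene[i]; s <- cells$group[i]; d <- cells$dose_mM[i]
      if (g %in% truth$hk_genes) {
        mu <- base_ct + hk_bias_for(truth, g, s, d)
      } else {
        fc <- truth$fold_change[[paste(g, s, d, sep = ".")]]
        mu <- base_ct + baseline_dct - log2(fc)
      }
      tibble::tibble(
        gene = g, group = s, dose_mM = d, replicate = seq_len(n_reps),
        ct = mu + stats::rnorm(n_reps, 0, truth$replicate_sd)
      )
    })
  })
  as_ct_table(dplyr::bind_rows(rows))
}
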
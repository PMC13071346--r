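#' Validate and normalize a Ct table
#'
#' A Ct table is a tidy tibble with one row per technical observation and
#' columns `gene` (character), `group` (differentiation status, e.g. "UnDiff"
#' or "Diff"), `dose_mM` (numeric, nonnegative), `replicate` (identifier
#' pairing target and housekeeping wells) and `ct` (cycles, > 0).
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble.
#' @export
as_ct_table <- function(x) {
  need <- c("gene", "group", "dose_mM", "replicate", "ct")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("Ct table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  x$gene <- as.character(x$gene)
  x$group <- as.character(x$group)
  x$dose_mM <- as.numeric(x$dose_mM)
  bad <- !is.na(x$ct) & x$ct <= 0
  if (any(bad)) stop("Ct values must be positive")
  if (any(x$dose_mM < 0)) stop("dose_mM must be nonnegative")
  x
}

#' Per-replicate delta-Ct against a housekeeping gene
#'
#' Pairs each target-gene observation with the housekeeping observation of the
#' same (group, dose, replicate) and returns `dct = ct_target - ct_reference`.
#' Rows with no matching reference replicate, or with missing Ct on either
#' side (e.g. no amplification), are dropped with a warning — never imputed.
#'
#' @param table A Ct table (see [as_ct_table()]).
#' @param hk_gene Name of the housekeeping gene used as reference.
#' @return A tibble with columns gene, group, dose_mM, replicate, dct.
#' @export
delta_ct <- function(table, hk_gene) {
  table <- as_ct_table(table)
  if (!hk_gene %in% table$gene) {
    stop("housekeeping gene '", hk_gene, "' not present in table")
  }
  ref <- table[table$gene == hk_gene,
               c("group", "dose_mM", "replicate", "ct")]
  names(ref)[names(ref) == "ct"] <- "ct_ref"
  tgt <- table[table$gene != hk_gene, , drop = FALSE]
  merged <- dplyr::left_join(tgt, ref,
                             by = c("group", "dose_mM", "replicate"))
  dropped <- is.na(merged$ct_ref) | is.na(merged$ct)
  if (any(dropped)) {
    warning(sum(dropped), " row(s) dropped: missing target or reference Ct")
    merged <- merged[!dropped, , drop = FALSE]
  }
  tibble::tibble(
    gene = merged$gene, group = merged$group, dose_mM = merged$dose_mM,
    replicate = merged$replicate, dct = merged$ct - merged$ct_ref
  )
}

#' Calibrator mean delta-Ct per gene
#'
#' Two calibrator conventions are supported. `"cross"` uses the mean delta-Ct
#' of the untreated undifferentiated group (0 mM UnDiff) for every gene,
#' putting all groups on one scale in which the 0 mM UnDiff fold change is 1.
#' `"within"` uses the 0 mM group of the same differentiation status, so each
#' status is referenced to its own untreated control.
#'
#' @param dct Output of [delta_ct()].
#' @param convention `"within"` or `"cross"`.
#' @param control_group Status label of the cross-convention calibrator
#'   (default "UnDiff").
#' @param control_dose Calibrator dose in mM (default 0).
#' @return A tibble with columns gene, group (NA for cross convention) and
#'   calibrator_mean_dct.
#' @export
select_calibrator <- function(dct, convention = c("within", "cross"),
                              control_group = "UnDiff", control_dose = 0) {
  convention <- match.arg(convention)
  genes <- unique(dct$gene)
  if (convention == "cross") {
    cal <- dct[dct$group == control_group & dct$dose_mM == control_dose, ]
    out <- dplyr::summarise(
      dplyr::group_by(cal, .data$gene),
      calibrator_mean_dct = mean(.data$dct), n_cal = dplyr::n(),
      .groups = "drop"
    )
    absent <- setdiff(genes, out$gene)
    if (length(absent)) {
      stop("calibrator group (", control_group, ", ", control_dose,
           " mM) absent for gene(s): ", paste(absent, collapse = ", "))
    }
    out$group <- NA_character_
  } else {
    cal <- dct[dct$dose_mM == control_dose, ]
    out <- dplyr::summarise(
      dplyr::group_by(cal, .data$gene, .data$group),
      calibrator_mean_dct = mean(.data$dct), n_cal = dplyr::n(),
      .groups = "drop"
    )
    want <- unique(dct[, c("gene", "group")])
    miss <- dplyr::anti_join(want, out, by = c("gene", "group"))
    if (nrow(miss)) {
      stop("0 mM calibrator absent for: ",
           paste(paste(miss$gene, miss$group), collapse = "; "))
    }
  }
  out[, c("gene", "group", "calibrator_mean_dct", "n_cal")]
}

#' Fold change from replicate delta-Ct values
#'
#' Per replicate, `FC = efficiency^-(dct - calibrator_mean_dct)` (the ddCt
#' rule with the classic efficiency of 2); the group fold change is the
#' arithmetic mean of the replicate fold changes. Evaluated at the calibrator
#' group's own mean delta-Ct the fold change is exactly 1.
#'
#' @param dct_values Numeric vector of per-replicate delta-Ct values for one
#'   (gene, group) cell.
#' @param calibrator_mean_dct Mean delta-Ct of the calibrator group.
#' @param efficiency Amplification efficiency (default 2).
#' @param summary `"mean_fc"` (default; mean of per-replicate fold changes,
#'   matching per-point replicate displays) or `"fc_of_mean"`
#'   (`efficiency^-mean(ddct)`).
#' @return List with `fold_change` (scalar) and `replicate_fc` (vector).
#' @export
fold_change <- function(dct_values, calibrator_mean_dct, efficiency = 2,
                        summary = c("mean_fc", "fc_of_mean")) {
  summary <- match.arg(summary)
  stopifnot(is.numeric(dct_values), is.finite(calibrator_mean_dct),
            efficiency > 0)
  ddct <- dct_values - calibrator_mean_dct
  rep_fc <- efficiency^(-ddct)
  fc <- if (summary == "mean_fc") mean(rep_fc) else efficiency^(-mean(ddct))
  list(fold_change = fc, replicate_fc = rep_fc, ddct = ddct)
}

#' Relative quantification of a Ct table by the delta-delta-Ct method
#'
#' Full pipeline: per-replicate delta-Ct against the housekeeping gene,
#' calibrator selection under the requested convention, and per-(gene, group,
#' dose) fold changes.
#'
#' @inheritParams delta_ct
#' @inheritParams select_calibrator
#' @inheritParams fold_change
#' @param hk_gene Housekeeping gene; `"auto"` selects the most stable
#'   candidate among `hk_candidates` via [normfinder_stability()].
#' @param hk_candidates Candidate housekeeping genes used when
#'   `hk_gene = "auto"`.
#' @return A tibble with one row per (gene, group, dose): fold_change,
#'   per-cell replicate count, calibrator mean delta-Ct, convention and the
#'   housekeeping gene used.
#' @export
#' @examples
#' truth <- ct_ground_truth(genes = "NRXN1a",
#'   fold_change = c("NRXN1a.Diff.35" = 0.25), seed = 1, replicate_sd = 0)
#' tab <- generate_ct_table(truth, n_reps = 3)
#' ddct_quantify(tab, hk_gene = "B-ACTIN", convention = "cross")
ddct_quantify <- function(table, hk_gene = "auto",
                          convention = c("within", "cross"),
                          hk_candidates = c("B-ACTIN", "PGK1", "GAPDH"),
                          efficiency = 2,
                          summary = c("mean_fc", "fc_of_mean"),
                          control_group = "UnDiff", control_dose = 0) {
  convention <- match.arg(convention)
  summary <- match.arg(summary)
  table <- as_ct_table(table)
  if (identical(hk_gene, "auto")) {
    cand <- intersect(hk_candidates, unique(table$gene))
    if (length(cand) < 2) {
      stop("hk_gene = 'auto' needs >= 2 candidate genes present in table")
    }
    stab <- normfinder_stability(table, candidates = cand)
    hk_gene <- stab$selected_gene
  }
  dct <- delta_ct(table, hk_gene)
  cal <- select_calibrator(dct, convention, control_group, control_dose)
  cells <- dplyr::group_by(dct, .data$gene, .data$group, .data$dose_mM)
  cells <- dplyr::summarise(cells, dct_list = list(.data$dct),
                            n = dplyr::n(), .groups = "drop")
  if (convention == "cross") {
    cells <- dplyr::left_join(cells, cal[, c("gene", "calibrator_mean_dct")],
                              by = "gene")
  } else {
    cells <- dplyr::left_join(
      cells, cal[, c("gene", "group", "calibrator_mean_dct")],
      by = c("gene", "group")
    )
  }
  fc <- vapply(seq_len(nrow(cells)), function(i) {
    fold_change(cells$dct_list[[i]], cells$calibrator_mean_dct[i],
                efficiency, summary)$fold_change
  }, numeric(1))
  tibble::tibble(
    gene = cells$gene, group = cells$group, dose_mM = cells$dose_mM,
    fold_change = fc, n_reps = cells$n,
    calibrator_mean_dct = cells$calibrator_mean_dct,
    convention = convention, hk_gene = hk_gene
  )
}

#' Read / write Ct tables as CSV
#'
#' @param path File path.
#' @return `read_ct_table()` returns a validated Ct table tibble.
#' @export
read_ct_table <- function(path) {
  as_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ct_table
#' @param table Ct table to write.
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(as_ct_table(table), path, row.names = FALSE)
  invisible(path)
}
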
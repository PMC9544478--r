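#' Relative quantification by the delta-delta-Ct method
#'
#' Computes per-sample fold change of a target relative to a reference gene
#' and a control sample: technical-replicate Ct values are averaged,
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample - dCt_control`, and
#' `fold = 2^-ddCt` (amplification efficiency fixed at perfect doubling).
#' Replicate SDs are combined in quadrature through both differences and
#' mapped to the fold scale by the delta method
#' (`fold_sd = fold * ln(2) * sd_ddCt`).
#'
#' @param plate A tibble with columns `sample`, `gene`, `ct` (one row per
#'   technical replicate; a `replicate` column is allowed and ignored).
#' @param control Control sample id (e.g. the wild type).
#' @param target Target gene name (default `"ONSEN"`).
#' @param reference Reference gene name (default `"ACTIN2"`).
#' @return A tibble per sample: `sample`, `dct`, `ddct`, `fold`, `fold_sd`,
#'   `n_replicates`. The control row has `fold = 1`.
#' @examples
#' plate <- tidyr::expand_grid(sample = c("Col0", "hc31"),
#'                             gene = c("ONSEN", "ACTIN2"), replicate = 1:3)
#' plate$ct <- ifelse(plate$gene == "ACTIN2", 24,
#'                    ifelse(plate$sample == "hc31", 17, 20))
#' fold_change_ddct(plate, control = "Col0") # hc31 fold = 8
#' @export
fold_change_ddct <- function(plate, control, target = "ONSEN",
                             reference = "ACTIN2") {
  stopifnot(all(c("sample", "gene", "ct") %in% names(plate)))
  if (any(plate$ct <= 0, na.rm = TRUE)) abort("Ct values must be positive.")
  if (!control %in% plate$sample) {
    abort(sprintf("Control sample '%s' not present in the plate.", control))
  }
  per_gene <- plate %>%
    dplyr::filter(.data$gene %in% c(target, reference)) %>%
    dplyr::group_by(.data$sample, .data$gene) %>%
    dplyr::summarise(mean_ct = mean(.data$ct), sd_ct = sd(.data$ct),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(sd_ct = dplyr::coalesce(.data$sd_ct, 0)) # single replicate
  dct <- per_gene %>%
    tidyr::pivot_wider(names_from = "gene",
                       values_from = c("mean_ct", "sd_ct", "n"))
  tcol <- paste0("mean_ct_", target); rcol <- paste0("mean_ct_", reference)
  if (!tcol %in% names(dct)) abort(sprintf("No Ct values for target gene '%s'.", target))
  if (!rcol %in% names(dct) || any(is.na(dct[[rcol]]))) {
    abort(sprintf("Missing reference gene '%s' Ct for sample(s): %s.", reference,
                  paste(dct$sample[is.na(dct[[paste0("mean_ct_", reference)]])],
                        collapse = ", ")))
  }
  dct <- dct %>%
    dplyr::mutate(
      dct = .data[[tcol]] - .data[[rcol]],
      sd_dct = sqrt(.data[[paste0("sd_ct_", target)]]^2 +
                    .data[[paste0("sd_ct_", reference)]]^2))
  ctrl <- dct[dct$sample == control, ]
  dct %>%
    dplyr::mutate(
      ddct = .data$dct - ctrl$dct,
      sd_ddct = sqrt(.data$sd_dct^2 + ctrl$sd_dct^2),
      fold = 2^(-.data$ddct),
      fold_sd = .data$fold * log(2) * .data$sd_ddct,
      n_replicates = .data[[paste0("n_", target)]]) %>%
    dplyr::select("sample", "dct", "ddct", "fold", "fold_sd", "n_replicates")
}

#' Convert a qPCR fold change to a genomic copy estimate
#'
#' Scales the fold change by the wild-type baseline copy number and rounds to
#' whole copies. The default baseline of 8 ONSEN copies is the value implied
#' by the published arithmetic (an 8-fold increase corresponding to ~64
#' copies); it is exposed because the baseline is never measured directly.
#'
#' @param fold Fold change(s), strictly positive.
#' @param wt_copies Wild-type baseline copy number.
#' @return Integer copy estimates.
#' @examples
#' copies_from_fold(8)   # 64
#' copies_from_fold(2.5) # 20
#' @export
copies_from_fold <- function(fold, wt_copies = 8) {
  if (any(is.na(fold)) || any(fold <= 0)) abort("`fold` must be > 0.")
  as.integer(round(fold * wt_copies))
}
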
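#' Spike-in normalized delta-delta-Ct fold change
#'
#' Classic ddCt with an exogenous spike-in (e.g. firefly luciferase mRNA
#' added per cell) as the normalizer, assuming ideal doubling per cycle:
#' `ddCt = (Ct_target,sample - Ct_spike,sample) - (Ct_target,ref -
#' Ct_spike,ref)` and fold change `2^(-ddCt)`. Because the spike-in is
#' added in constant amount per cell, the fold change reports per-cell
#' abundance even when equal RNA mass is processed per sample.
#'
#' @param ct_target_sample,ct_spike_sample Target and spike-in Ct in the
#'   sample of interest.
#' @param ct_target_ref,ct_spike_ref Target and spike-in Ct in the
#'   reference sample.
#' @return One-row tibble with `ddct`, `fold` and `log2_fold`
#'   (vectorized).
#' @examples
#' ddct_fold(20, 18, 22, 19) # fold = 2
#' @export
ddct_fold <- function(ct_target_sample, ct_spike_sample,
                      ct_target_ref, ct_spike_ref) {
  cts <- cbind(ct_target_sample, ct_spike_sample, ct_target_ref, ct_spike_ref)
  if (any(!is.finite(cts))) {
    stop("all Ct values must be finite; the spike-in measurement is mandatory",
         call. = FALSE)
  }
  ddct <- (ct_target_sample - ct_spike_sample) - (ct_target_ref - ct_spike_ref)
  tibble::tibble(ddct = ddct, fold = 2^(-ddct), log2_fold = -ddct)
}

#' Summarize a Ct table into spike-normalized fold changes
#'
#' Technical/biological replicate Cts are averaged per
#' (condition, target) before the ddCt computation; each condition must
#' carry a spike-in measurement.
#'
#' @param ct_table Tibble with columns `sample`, `condition`, `target`,
#'   `ct`, `is_spike`.
#' @param reference_condition Condition serving as the ddCt reference.
#' @return Tibble with one row per (condition, target), columns `condition`,
#'   `target`, `ddct`, `fold`, `log2_fold`.
#' @export
ddct_table <- function(ct_table, reference_condition) {
  need <- c("sample", "condition", "target", "ct", "is_spike")
  stopifnot(all(need %in% names(ct_table)))
  if (!reference_condition %in% ct_table$condition) {
    stop("reference condition `", reference_condition, "` not in table",
         call. = FALSE)
  }
  means <- ct_table |>
    dplyr::group_by(.data$condition, .data$target, .data$is_spike) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  spikes <- means[means$is_spike, c("condition", "ct")]
  names(spikes)[2] <- "ct_spike"
  if (!all(unique(means$condition) %in% spikes$condition)) {
    stop("missing spike-in measurement for some condition; ",
         "the spike is mandatory under this scheme", call. = FALSE)
  }
  targets <- means[!means$is_spike, ] |>
    dplyr::left_join(spikes, by = "condition")
  ref <- targets[targets$condition == reference_condition,
                 c("target", "ct", "ct_spike")]
  names(ref)[2:3] <- c("ct_ref", "ct_spike_ref")
  targets |>
    dplyr::inner_join(ref, by = "target") |>
    dplyr::mutate(ddct_fold(.data$ct, .data$ct_spike,
                            .data$ct_ref, .data$ct_spike_ref)) |>
    dplyr::select("condition", "target", "ddct", "fold", "log2_fold")
}

#' RIP enrichment corrected for immunoprecipitated protein level
#'
#' RNA immunoprecipitation fold enrichment over the control IP, divided by
#' the relative amount of bait protein recovered in the IP (from
#' densitometry of the IP western), so differences in pulled-down protein
#' do not masquerade as RNA-binding differences.
#'
#' @param fold_vs_control_ip mRNA fold enrichment over the control IP
#'   (positive).
#' @param protein_ratio Bait protein level in this IP relative to the
#'   comparator (positive).
#' @return One-row tibble with `corrected_fold` and `corrected_log2`
#'   (vectorized).
#' @examples
#' rip_corrected_fold(4, 2) # corrected fold 2, log2 = 1
#' @export
rip_corrected_fold <- function(fold_vs_control_ip, protein_ratio) {
  if (any(fold_vs_control_ip <= 0) || any(protein_ratio <= 0)) {
    stop("fold and protein ratio must be positive", call. = FALSE)
  }
  cf <- fold_vs_control_ip / protein_ratio
  tibble::tibble(corrected_fold = cf, corrected_log2 = log2(cf))
}

#' One-sample t-test against a hypothetical mean
#'
#' The figure-legend test: `t = (mean - mu) / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom; one-tailed p-values are directioned (e.g. "greater
#' than 0" for log2 RIP enrichment, where sub-baseline values are not
#' meaningful).
#'
#' @param values Numeric vector, `n >= 2`, non-zero variance.
#' @param mu Hypothetical mean.
#' @param tails `"two"` (default) or `"one"`.
#' @param direction For one-tailed tests, `"greater"` or `"less"`.
#' @return One-row tibble with `estimate`, `t`, `df`, `p`.
#' @examples
#' one_sample_test(c(1, 2, 3), mu = 0)
#' @export
one_sample_test <- function(values, mu, tails = c("two", "one"),
                            direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("undefined-test error: zero variance", call. = FALSE)
  t <- (mean(values) - mu) / (s / sqrt(n))
  df <- n - 1L
  p <- if (tails == "two") {
    2 * stats::pt(-abs(t), df)
  } else if (direction == "greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    stats::pt(t, df)
  }
  tibble::tibble(estimate = mean(values), t = t, df = df, p = p)
}

#' Densitometry ratio normalized to a loading control
#'
#' `(band / loading) / (ref_band / ref_loading)`: band intensity relative
#' to the loading control (e.g. calnexin), expressed relative to the
#' reference sample, which maps to 1 by construction.
#'
#' @param band,loading Band and loading-control intensities of the sample.
#' @param ref_band,ref_loading Same for the reference sample.
#' @return Normalized ratio (vectorized).
#' @examples
#' densitometry_ratio(10, 5, 4, 4) # 2
#' @export
densitometry_ratio <- function(band, loading, ref_band, ref_loading) {
  vals <- cbind(band, loading, ref_band, ref_loading)
  if (any(vals <= 0)) stop("intensities must be positive", call. = FALSE)
  (band / loading) / (ref_band / ref_loading)
}
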
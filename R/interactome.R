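#' Assemble an IP-MS experiment
#'
#' Bundles and validates the three tables of a label-free IP-MS comparison:
#' a wide intensity table (one row per protein, one column per sample;
#' zero or `NA` marks a non-detection), sample metadata and protein metadata.
#'
#' @param intensities Tibble with a `protein` column plus one numeric column
#'   per sample; non-negative intensities, `NA` or 0 = missing.
#' @param samples Tibble with `sample`, `group`, `replicate`.
#' @param proteins Tibble with `protein`, `n_peptides`, `is_decoy`,
#'   `is_contaminant`.
#' @return A validated `ipms_experiment` list.
#' @export
ipms_experiment <- function(intensities, samples, proteins) {
  stopifnot("protein" %in% names(intensities),
            all(c("sample", "group", "replicate") %in% names(samples)),
            all(c("protein", "n_peptides", "is_decoy", "is_contaminant") %in%
                  names(proteins)))
  if (!all(samples$sample %in% names(intensities))) {
    stop("config error: sample metadata lists samples missing from the ",
         "intensity table", call. = FALSE)
  }
  if (length(unique(samples$group)) < 1L) stop("config error: no groups", call. = FALSE)
  if (!all(intensities$protein %in% proteins$protein)) {
    stop("intensity table contains proteins without metadata", call. = FALSE)
  }
  mat <- as.matrix(intensities[samples$sample])
  if (any(mat < 0, na.rm = TRUE)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(intensities = intensities, samples = samples,
                 proteins = proteins),
            class = "ipms_experiment")
}

#' @export
print.ipms_experiment <- function(x, ...) {
  cat(sprintf("IP-MS experiment: %d proteins x %d samples (%s)\n",
              nrow(x$intensities), nrow(x$samples),
              paste(sprintf("%s x%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

ipms_matrix <- function(x) {
  m <- as.matrix(x$intensities[x$samples$sample])
  rownames(m) <- x$intensities$protein
  m[!is.na(m) & m == 0] <- NA # zero intensity is a non-detection
  m
}

#' Filter decoys, contaminants and sparsely detected proteins
#'
#' Removes decoy and contaminant entries, then keeps only proteins detected
#' (non-missing intensity) in at least `min_detected` replicates of at least
#' one experimental group.
#'
#' @param x An [ipms_experiment()].
#' @param min_detected Minimum detections within one group (default 2).
#' @return The filtered `ipms_experiment`.
#' @export
filter_proteins <- function(x, min_detected = 2L) {
  stopifnot(inherits(x, "ipms_experiment"))
  meta <- x$proteins[match(x$intensities$protein, x$proteins$protein), ]
  keep_flag <- !(meta$is_decoy | meta$is_contaminant)
  m <- ipms_matrix(x)
  groups <- split(seq_len(nrow(x$samples)), x$samples$group)
  detected_any <- Reduce(`|`, lapply(groups, function(cols) {
    rowSums(!is.na(m[, cols, drop = FALSE])) >= min_detected
  }))
  keep <- keep_flag & detected_any
  ipms_experiment(x$intensities[keep, , drop = FALSE], x$samples,
                  x$proteins[x$proteins$protein %in% x$intensities$protein[keep], ,
                             drop = FALSE])
}

#' Impute missing intensities from a downshifted normal
#'
#' Standard missing-not-at-random imputation for label-free proteomics:
#' working on log2 intensities, each missing value in sample `s` is replaced
#' by a draw from `Normal(m_s - downshift_sd * s_s, (width_sd * s_s)^2)`,
#' where `m_s` and `s_s` are the mean and SD of the observed log2 values of
#' that sample. Defaults (downshift 1.8 SD, width 0.3 SD) follow the common
#' label-free convention.
#'
#' @param x An [ipms_experiment()] (raw intensity scale).
#' @param downshift_sd,width_sd Downshift and width in sample-SD units.
#' @param seed Integer seed; imputation is reproducible.
#' @return An `ipms_experiment` whose intensity table holds complete log2
#'   intensities, with attribute `imputed` (logical matrix of imputed cells).
#' @export
impute_missing <- function(x, downshift_sd = 1.8, width_sd = 0.3, seed = 1L) {
  stopifnot(inherits(x, "ipms_experiment"))
  m <- ipms_matrix(x)
  if (!isTRUE(attr(x, "log2"))) m <- log2(m)
  glob_mu <- mean(m, na.rm = TRUE)
  glob_sd <- stats::sd(m[!is.na(m)])
  imputed <- is.na(m)
  set.seed(seed)
  for (j in seq_len(ncol(m))) {
    nas <- which(is.na(m[, j]))
    if (!length(nas)) next
    obs <- m[!is.na(m[, j]), j]
    if (length(obs) < 2L) {
      warning("sample ", colnames(m)[j],
              " has <2 observed values; using global mean/SD for imputation")
      mu <- glob_mu; s <- glob_sd
    } else {
      mu <- mean(obs); s <- stats::sd(obs)
    }
    m[nas, j] <- stats::rnorm(length(nas), mu - downshift_sd * s, width_sd * s)
  }
  out <- x
  out$intensities <- dplyr::bind_cols(
    tibble::tibble(protein = x$intensities$protein),
    tibble::as_tibble(m)
  )
  attr(out, "log2") <- TRUE
  attr(out, "imputed") <- imputed
  out
}

#' Per-protein differential enrichment between two groups
#'
#' Two-sample Student's t-test (equal variance by default; `welch = TRUE`
#' for unequal) on log2 intensities, per protein, with Benjamini-Hochberg
#' FDR across tested proteins. The log2 fold change is the difference of
#' group means of log2 intensities, i.e. the log2 ratio of geometric means,
#' reported alongside the linear `fold` ratio.
#'
#' @param x An imputed [ipms_experiment()] (see [impute_missing()]); a raw
#'   matrix is log2-transformed on the fly (missing values must be absent).
#' @param group_a,group_b Group labels; fold changes are `group_a` over
#'   `group_b`.
#' @param welch Use Welch's unequal-variance t-test.
#' @return Tibble with one row per protein: `protein`, `log2FC`, `fold`,
#'   `p`, `q`, `n_peptides`, `zero_variance` flag and per-group imputed
#'   fractions when available.
#' @export
differential_enrichment <- function(x, group_a, group_b, welch = FALSE) {
  stopifnot(inherits(x, "ipms_experiment"))
  m <- as.matrix(x$intensities[x$samples$sample])
  rownames(m) <- x$intensities$protein
  if (!isTRUE(attr(x, "log2"))) {
    if (anyNA(m) || any(m == 0)) {
      stop("intensities contain missing values; run impute_missing() first",
           call. = FALSE)
    }
    m <- log2(m)
  }
  ca <- x$samples$sample[x$samples$group == group_a]
  cb <- x$samples$sample[x$samples$group == group_b]
  if (length(ca) < 2L || length(cb) < 2L) {
    stop("both groups need >= 2 replicates for testing", call. = FALSE)
  }
  imp <- attr(x, "imputed")
  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    va <- m[i, ca]; vb <- m[i, cb]
    zv <- stats::sd(va) == 0 && stats::sd(vb) == 0
    p <- if (zv) 1 else stats::t.test(va, vb, var.equal = !welch)$p.value
    tibble::tibble(
      protein = rownames(m)[i],
      log2FC = mean(va) - mean(vb),
      p = p, zero_variance = zv,
      imputed_frac_a = if (is.null(imp)) NA_real_ else mean(imp[i, ca]),
      imputed_frac_b = if (is.null(imp)) NA_real_ else mean(imp[i, cb])
    )
  })
  rows |>
    dplyr::mutate(
      fold = 2^.data$log2FC,
      q = stats::p.adjust(.data$p, method = "BH"),
      n_peptides = x$proteins$n_peptides[match(.data$protein, x$proteins$protein)]
    ) |>
    dplyr::select("protein", "log2FC", "fold", "p", "q", "n_peptides",
                  "zero_variance", "imputed_frac_a", "imputed_frac_b")
}

#' Call interactors from enrichment rows
#'
#' A protein is called an interactor when all three default criteria hold
#' strictly: at least `min_peptides` unique peptides, fold enrichment over
#' the control greater than `fc_threshold`, and FDR `q` below
#' `fdr_threshold`. Boundary equality fails.
#'
#' @param rows Output of [differential_enrichment()] against the control
#'   group.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold on `q` (default 0.05).
#' @param min_peptides Minimum unique peptides (default 2).
#' @return `rows` with a logical `called` column and the criteria snapshot
#'   in attributes.
#' @export
call_interactors <- function(rows, fc_threshold = 2, fdr_threshold = 0.05,
                             min_peptides = 2L) {
  out <- dplyr::mutate(
    rows,
    called = .data$n_peptides >= min_peptides &
      .data$fold > fc_threshold &
      .data$q < fdr_threshold
  )
  attr(out, "criteria") <- list(fc_threshold = fc_threshold,
                                fdr_threshold = fdr_threshold,
                                min_peptides = min_peptides)
  out
}

#' Proteins preferentially enriched in one bait over another
#'
#' Applies the looser, raw-p criterion used when contrasting the two bait
#' IPs directly (rather than bait vs control): fold greater than
#' `fc_threshold` and unadjusted `p` below `p_threshold`.
#'
#' @param rows Output of [differential_enrichment()] between the two bait
#'   groups.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @return Character vector of protein ids.
#' @export
preferential_set <- function(rows, fc_threshold = 2, p_threshold = 0.05) {
  if (nrow(rows) == 0L) return(character())
  rows$protein[rows$fold > fc_threshold & rows$p < p_threshold]
}

#' Volcano plot of IP-MS enrichment
#'
#' @param rows Output of [differential_enrichment()], optionally after
#'   [call_interactors()].
#' @return A ggplot object: log2 fold change vs -log10 p, interactor calls
#'   highlighted when present.
#' @export
plot_enrichment_volcano <- function(rows) {
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$log2FC,
                                          y = -log10(.data$p)))
  if ("called" %in% names(rows)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$called),
                                 alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "firebrick"),
                                   name = "interactor")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, colour = "grey40")
  }
  p + ggplot2::labs(x = "log2 fold change (geometric-mean ratio)",
                    y = expression(-log[10]~italic(p))) +
    ggplot2::theme_minimal()
}
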
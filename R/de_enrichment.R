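#' Classify genes of a differential-expression table
#'
#' Applies the strict published criteria: a gene passes the expression
#' filter when `baseMean > 10`; it is differentially expressed when
#' additionally `|log2FC| > 0.263` (fold change > 1.2) and `p < 0.05`, with
#' the sign of `log2FC` deciding up vs down. All inequalities are strict,
#' so a gene sitting exactly on a boundary is `unchanged`.
#'
#' @param table Tibble with columns `gene`, `baseMean`, `log2FC`, `pvalue`.
#'   Duplicate gene ids collapse to the most significant record with a
#'   warning.
#' @param base_mean_min,lfc_min,p_max Thresholds; defaults are the published
#'   criteria.
#' @return The table with a `label` factor column in
#'   `c("up", "down", "unchanged", "filtered")`.
#' @examples
#' classify_degs(tibble::tibble(gene = "a", baseMean = 100,
#'                              log2FC = 0.5, pvalue = 0.01))
#' @export
classify_degs <- function(table, base_mean_min = 10, lfc_min = 0.263,
                          p_max = 0.05) {
  need <- c("gene", "baseMean", "log2FC", "pvalue")
  if (!all(need %in% names(table))) {
    stop("schema error: DE table needs columns ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(table$pvalue)) || any(table$pvalue <= 0 | table$pvalue > 1)) {
    stop("value error: p-values must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(table$gene)) {
    warning("duplicate gene identifiers collapsed to the most significant record")
    table <- table |>
      dplyr::arrange(.data$pvalue) |>
      dplyr::distinct(.data$gene, .keep_all = TRUE)
  }
  table |>
    dplyr::mutate(
      label = factor(
        dplyr::case_when(
          .data$baseMean <= base_mean_min ~ "filtered",
          abs(.data$log2FC) > lfc_min & .data$pvalue < p_max &
            .data$log2FC > 0 ~ "up",
          abs(.data$log2FC) > lfc_min & .data$pvalue < p_max ~ "down",
          TRUE ~ "unchanged"
        ),
        levels = c("up", "down", "unchanged", "filtered")
      )
    )
}

#' Gene-set overlap statistics (hypergeometric / representation factor)
#'
#' Overlap of a query set with an annotation set inside a finite universe:
#' `x = |query & annotation|`; the representation factor is
#' `x * N / (n * m)` (observed overlap over the overlap expected under
#' independence); `p_right = P(X >= x)` for the hypergeometric draw of `n`
#' from a universe of `N` with `m` successes.
#'
#' @param query,annotation,universe Character vectors of gene identifiers
#'   (deduplicated); `query` and `annotation` are intersected with
#'   `universe`.
#' @return One-row tibble with `x`, `n`, `m`, `N`, `representation_factor`,
#'   `p_right`.
#' @examples
#' overlap_fet(letters[1:20], letters[1:10], letters)
#' @export
overlap_fet <- function(query, annotation, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  annotation <- intersect(unique(annotation), universe)
  n <- length(query); m <- length(annotation)
  x <- length(intersect(query, annotation))
  rf <- if (n == 0L || m == 0L) 0 else x * N / (n * m)
  p <- stats::phyper(x - 1L, m, N - m, n, lower.tail = FALSE)
  tibble::tibble(x = x, n = n, m = m, N = N,
                 representation_factor = rf, p_right = p)
}

#' Integer percentage with half-away-from-zero rounding
#'
#' `round(100 * numerator / denominator)` to the nearest integer, halves
#' away from zero (so 90/111 is 81, 27/77 is 35).
#'
#' @param numerator,denominator Non-negative integers, `denominator >= 1`,
#'   `numerator <= denominator`; vectorized.
#' @return Integer percent.
#' @examples
#' percent_of(90, 111) # 81
#' @export
percent_of <- function(numerator, denominator) {
  if (any(denominator < 1)) stop("denominator must be >= 1", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param log2fc Numeric log2 fold change.
#' @return `2^log2fc`.
#' @examples
#' log2fc_to_fc(0.263) # 1.2 (2 s.f.)
#' @export
log2fc_to_fc <- function(log2fc) 2^log2fc

#' TOP / ribosomal-protein maintenance report
#'
#' Summarizes how each gene set behaves in a classified DE table: how many
#' members are detected, the count and percentage in each DEG class, and a
#' hypergeometric overlap test of the set against a chosen DEG class. The
#' universe is the set of genes passing the expression filter (label other
#' than `filtered`), the natural background for a detected-gene contingency
#' analysis.
#'
#' @param degs Classified table from [classify_degs()].
#' @param gene_sets Named list of character vectors (e.g.
#'   `list(TOP = ..., RP = ...)`). Identifiers absent from the table are
#'   dropped with a warning.
#' @param against DEG class to test enrichment against (default `"down"`).
#' @return Tibble with one row per gene set: `set`, `detected`, `n_up`,
#'   `n_down`, `n_unchanged`, `pct_up`, `pct_down`,
#'   `representation_factor`, `p_right`.
#' @export
maintenance_report <- function(degs, gene_sets, against = "down") {
  stopifnot("label" %in% names(degs), is.list(gene_sets))
  against <- match.arg(against, c("up", "down"))
  universe <- degs$gene[degs$label != "filtered"]
  class_genes <- degs$gene[degs$label == against]
  purrr::imap_dfr(gene_sets, function(members, set_name) {
    members <- unique(members)
    missing <- setdiff(members, degs$gene)
    if (length(missing)) {
      warning(sprintf("%d/%d identifiers of set `%s` absent from the table; %s",
                      length(missing), length(members), set_name,
                      "analysis restricted to the intersection"))
    }
    detected <- intersect(members, universe)
    nd <- length(detected)
    lab <- degs$label[match(detected, degs$gene)]
    if (nd == 0L) {
      return(tibble::tibble(set = set_name, detected = 0L, n_up = 0L,
                            n_down = 0L, n_unchanged = 0L,
                            pct_up = NA_integer_, pct_down = NA_integer_,
                            representation_factor = NA_real_,
                            p_right = NA_real_))
    }
    fet <- overlap_fet(class_genes, detected, universe)
    tibble::tibble(
      set = set_name, detected = nd,
      n_up = sum(lab == "up"), n_down = sum(lab == "down"),
      n_unchanged = sum(lab == "unchanged"),
      pct_up = percent_of(sum(lab == "up"), nd),
      pct_down = percent_of(sum(lab == "down"), nd),
      representation_factor = fet$representation_factor,
      p_right = fet$p_right
    )
  })
}

#' Read a gene set from a one-identifier-per-line text file
#'
#' @param path Text file path; blank lines and duplicates dropped.
#' @return Character vector of identifiers.
#' @export
read_gene_set <- function(path) {
  ids <- readr::read_lines(path)
  unique(ids[nzchar(trimws(ids))])
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene`, `baseMean`, `log2FC`, `pvalue`.
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "baseMean", "log2FC", "pvalue")
  if (!all(need %in% names(tab))) {
    stop("schema error: DE table needs columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab
}

#' MA-style plot of a classified DE table
#'
#' @param degs Output of [classify_degs()].
#' @param highlight Optional character vector of genes (e.g. a TOP list) to
#'   emphasize.
#' @return A ggplot object.
#' @export
plot_deg_ma <- function(degs, highlight = NULL) {
  p <- ggplot2::ggplot(degs, ggplot2::aes(x = log10(.data$baseMean + 1),
                                          y = .data$log2FC,
                                          colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            unchanged = "grey70",
                                            filtered = "grey90")) +
    ggplot2::labs(x = "log10 baseMean", y = "log2 fold change") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(data = degs[degs$gene %in% highlight, ],
                                 colour = "goldenrod", size = 1.4)
  }
  p
}
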
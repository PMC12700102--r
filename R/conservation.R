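#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA (protein); all rows must be the same length,
#'   gaps as `-`.
#' @param reference_id Identifier of the reference (e.g. human) row.
#' @return Tibble with columns `id`, `seq` and an attribute `reference_id`.
#' @export
read_msa <- function(path, reference_id) {
  msa <- read_protein_fasta(path)
  validate_msa(msa, reference_id)
}

validate_msa <- function(msa, reference_id) {
  stopifnot(all(c("id", "seq") %in% names(msa)))
  widths <- nchar(msa$seq)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  if (!reference_id %in% msa$id) {
    stop("reference_id `", reference_id, "` not found in alignment", call. = FALSE)
  }
  attr(msa, "reference_id") <- reference_id
  msa
}

#' Per-column conservation of a multiple sequence alignment
#'
#' For each alignment column where the reference row carries a residue, the
#' score is the fraction of non-reference rows whose residue equals the
#' reference residue; gaps in non-reference rows count as mismatches, and
#' columns gapped in the reference are skipped. Positions are reported on
#' the ungapped reference coordinate system.
#'
#' @param msa Alignment tibble from [read_msa()], or any tibble with `id`,
#'   `seq` plus a `reference_id` attribute (or pass `reference_id`).
#' @param reference_id Reference row id; defaults to the attribute set by
#'   [read_msa()].
#' @return Tibble with `position` (1-based on the reference sequence),
#'   `column` (alignment column), `score` in `[0, 1]`.
#' @export
column_conservation <- function(msa, reference_id = attr(msa, "reference_id")) {
  msa <- validate_msa(msa, reference_id)
  if (nrow(msa) < 2L) stop("conservation needs >= 2 alignment rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(msa$seq, ""))
  ref <- mat[match(reference_id, msa$id), ]
  others <- mat[msa$id != reference_id, , drop = FALSE]
  keep <- which(ref != "-")
  score <- vapply(keep, function(j) mean(others[, j] == ref[j]), numeric(1))
  tibble::tibble(position = seq_along(keep), column = keep, score = score)
}

# one-sided Mann-Whitney U (H1: `inside` stochastically greater than
# `outside`), ties as half-wins. Returns U and the right-tail p computed by
# full enumeration of column-to-group assignments when feasible (exact under
# ties), by the exact tie-free null otherwise, falling back to the normal
# approximation with tie correction.
mw_one_sided <- function(inside, outside, enum_cap = 2e5) {
  n1 <- length(inside); n2 <- length(outside)
  if (n1 == 0L || n2 == 0L) stop("empty in/out group", call. = FALSE)
  U <- sum(outer(inside, outside, function(a, b) (a > b) + 0.5 * (a == b)))
  pooled <- c(inside, outside)
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    warning("all scores tied; Mann-Whitney p set to 0.5")
    return(list(U = U, p = 0.5, method = "degenerate-ties"))
  }
  if (choose(n1 + n2, n1) <= enum_cap) {
    idx <- utils::combn(n1 + n2, n1)
    stats_all <- apply(idx, 2L, function(k) {
      a <- pooled[k]; b <- pooled[-k]
      sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
    })
    p <- mean(stats_all >= U - 1e-9)
    return(list(U = U, p = p, method = "exact-enumeration"))
  }
  if (!ties && n1 * n2 <= 1e4) {
    # P(U >= u) for the tie-free exact null
    p <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    return(list(U = U, p = p, method = "exact-wilcoxon"))
  }
  r <- rank(pooled)
  tie_tab <- table(r)
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = stats::pnorm(z, lower.tail = FALSE),
       method = "normal-approximation")
}

#' Test whether a region is more conserved than the rest of the sequence
#'
#' One-sided Mann-Whitney comparison of per-column conservation scores,
#' with the fixed alternative that columns outside the region are less
#' conserved than those inside it. Small problems are solved by full
#' enumeration of group assignments (exact under ties); tie-free problems
#' up to `n_in * n_out = 10000` use the exact Mann-Whitney null; larger
#' problems use the normal approximation with mid-rank tie correction.
#'
#' Optional column weights (e.g. down-weighting columns inside RG dipeptides
#' by their background frequency in the proteome) are applied by weighted
#' resampling: in each of `n_resamples` replicates, columns are resampled
#' with probability proportional to their weight, the exact test is run on
#' the replicate, and the reported p is the mean replicate p-value.
#'
#' @param profile Conservation profile from [column_conservation()].
#' @param region One-row region tibble on reference coordinates.
#' @param weights Optional non-negative per-column weights, same length as
#'   `nrow(profile)`.
#' @param n_resamples Number of weighted resampling replicates.
#' @param seed Seed for the weighted resampling path.
#' @return A `region_conservation` object; see [tidy.region_conservation()].
#' @export
region_conservation_test <- function(profile, region, weights = NULL,
                                     n_resamples = 200L, seed = 1L) {
  stopifnot(all(c("position", "score") %in% names(profile)), nrow(region) == 1L)
  inside_idx <- profile$position >= region$start & profile$position <= region$end
  if (!any(inside_idx) || all(inside_idx)) {
    stop("region must overlap the profile and leave columns outside it",
         call. = FALSE)
  }
  if (is.null(weights)) {
    res <- mw_one_sided(profile$score[inside_idx], profile$score[!inside_idx])
    weighting <- "unweighted"
  } else {
    if (length(weights) != nrow(profile) || any(weights < 0)) {
      stop("weights must be non-negative and one per profile column", call. = FALSE)
    }
    set.seed(seed)
    ps <- replicate(n_resamples, {
      k <- sample.int(nrow(profile), nrow(profile), replace = TRUE, prob = weights)
      ins <- inside_idx[k]
      if (!any(ins) || all(ins)) return(NA_real_)
      mw_one_sided(profile$score[k][ins], profile$score[k][!ins])$p
    })
    res <- list(U = NA_real_, p = mean(ps, na.rm = TRUE),
                method = "weighted-resampling")
    weighting <- sprintf("weighted column resampling, %d replicates, seed %d",
                         n_resamples, seed)
  }
  structure(list(U = res$U, p_one_sided = res$p,
                 alternative = "outside less conserved than inside",
                 n_in = sum(inside_idx), n_out = sum(!inside_idx),
                 method = res$method, weighting = weighting),
            class = "region_conservation")
}

#' @export
print.region_conservation <- function(x, ...) {
  cat("Region conservation test (one-sided Mann-Whitney)\n")
  cat(sprintf("  alternative: %s\n", x$alternative))
  cat(sprintf("  n_in = %d, n_out = %d, U = %s\n", x$n_in, x$n_out,
              format(x$U)))
  cat(sprintf("  p = %.4g  [%s; %s]\n", x$p_one_sided, x$method, x$weighting))
  invisible(x)
}

#' Tidy a region conservation test
#'
#' @param x A `region_conservation` object.
#' @param ... Unused.
#' @return One-row tibble with `U`, `p_one_sided`, group sizes and method.
#' @method tidy region_conservation
#' @export
tidy.region_conservation <- function(x, ...) {
  tibble::tibble(U = x$U, p_one_sided = x$p_one_sided,
                 alternative = x$alternative, n_in = x$n_in, n_out = x$n_out,
                 method = x$method, weighting = x$weighting)
}

#' @rdname tidy.region_conservation
#' @method glance region_conservation
#' @export
glance.region_conservation <- function(x, ...) {
  tibble::tibble(p_one_sided = x$p_one_sided, n_in = x$n_in, n_out = x$n_out)
}
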
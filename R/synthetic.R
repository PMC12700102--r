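#' Synthetic protein with a planted RG-rich region
#'
#' Draws i.i.d. background residues (uniform over the 20 standard letters by
#' default) and plants a given number of non-overlapping RG dipeptides at
#' uniformly chosen positions inside the region, emulating an RG-rich
#' domain embedded in a long, otherwise unbiased protein.
#'
#' @param length Protein length in residues (default 2000).
#' @param planted_region One-row [region()] receiving the planted
#'   dipeptides (default aa 951-1050, a 100-aa central region).
#' @param planted_rg Number of planted RG dipeptides (default 10).
#' @param background_freqs Optional named residue-probability vector; equal
#'   frequencies when `NULL`.
#' @param seed Integer seed; generation is deterministic.
#' @return List with `seq` (the sequence) and `truth` (tibble of planted
#'   dipeptide start positions plus the region bounds as attributes).
#' @export
synth_protein <- function(length = 2000L, planted_region = region(951L, 1050L),
                          planted_rg = 10L, background_freqs = NULL,
                          seed = 1L) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(background_freqs)) {
    background_freqs <- stats::setNames(rep(1 / 20, 20), aas)
  }
  rs <- planted_region$start; re <- planted_region$end
  if (re > length) stop("planted region out of sequence bounds", call. = FALSE)
  if (2L * planted_rg > region_length(planted_region)) {
    stop("region too small for ", planted_rg, " non-overlapping RG dipeptides",
         call. = FALSE)
  }
  set.seed(seed)
  x <- sample(names(background_freqs), length, replace = TRUE,
              prob = background_freqs)
  # rejection-sample non-overlapping dipeptide start positions in the region
  starts <- integer(0)
  cand <- rs:(re - 1L)
  repeat {
    starts <- sort(sample(cand, planted_rg))
    if (planted_rg <= 1L || all(diff(starts) >= 2L)) break
  }
  x[starts] <- "R"
  x[starts + 1L] <- "G"
  list(
    seq = paste(x, collapse = ""),
    truth = structure(
      tibble::tibble(planted_start = starts),
      region_start = rs, region_end = re, seed = seed
    )
  )
}

#' Synthetic multiple sequence alignment with a conserved region
#'
#' The reference row is drawn uniformly; every non-reference residue matches
#' the reference with a column-specific probability (`p_match_in` inside the
#' region, `p_match_out` elsewhere), otherwise it is a uniformly chosen
#' different residue. No gaps are introduced, so reference positions equal
#' alignment columns.
#'
#' @param n_rows Number of alignment rows including the reference
#'   (default 10).
#' @param n_cols Alignment length (default 660).
#' @param inside_region One-row [region()] of conserved columns (default
#'   301-360, 60 columns).
#' @param p_match_in,p_match_out Match probabilities inside/outside the
#'   region (defaults 0.9 / 0.5).
#' @param seed Integer seed.
#' @return List with `msa` (tibble `id`, `seq`, reference `ref`) and
#'   `truth` (the generating probabilities and region).
#' @export
synth_msa <- function(n_rows = 10L, n_cols = 660L,
                      inside_region = region(301L, 360L),
                      p_match_in = 0.9, p_match_out = 0.5, seed = 1L) {
  stopifnot(n_rows >= 2L, p_match_out >= 0, p_match_in <= 1,
            p_match_out <= p_match_in)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  ref <- sample(aas, n_cols, replace = TRUE)
  p_col <- ifelse(seq_len(n_cols) >= inside_region$start &
                    seq_len(n_cols) <= inside_region$end,
                  p_match_in, p_match_out)
  rows <- vapply(seq_len(n_rows - 1L), function(i) {
    match <- stats::runif(n_cols) < p_col
    out <- ref
    mism <- which(!match)
    # uniformly random *different* residue at mismatches
    out[mism] <- vapply(ref[mism], function(r) sample(setdiff(aas, r), 1L),
                        character(1))
    paste(out, collapse = "")
  }, character(1))
  msa <- tibble::tibble(
    id = c("ref", paste0("sp", seq_len(n_rows - 1L))),
    seq = c(paste(ref, collapse = ""), rows)
  )
  attr(msa, "reference_id") <- "ref"
  list(msa = msa,
       truth = tibble::tibble(region_start = inside_region$start,
                              region_end = inside_region$end,
                              p_match_in = p_match_in,
                              p_match_out = p_match_out, seed = seed))
}

#' Synthetic IP-MS intensity matrix with planted interactors
#'
#' Log-normal baseline intensities shared across samples; planted proteins
#' are multiplied by `fold` in the bait group; multiplicative log-normal
#' measurement noise at coefficient of variation `cv`; values below each
#' sample's `mnar_quantile` intensity quantile are censored to missing
#' (missing-not-at-random, the pattern that motivates downshifted
#' imputation). Peptide counts are at least 1, and at least 2 for planted
#' proteins.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param n_replicates Replicates per group (default 3).
#' @param n_planted Planted bait-specific interactors (default 20).
#' @param fold Linear enrichment of planted proteins in the bait group
#'   (default 4).
#' @param cv Measurement coefficient of variation (default 0.05).
#' @param mnar_quantile Per-sample censoring quantile (default 0.2).
#' @param groups Names of the bait and control groups.
#' @param seed Integer seed.
#' @return List with `experiment` (an [ipms_experiment()]) and `truth`
#'   (tibble `protein`, `is_interactor`, `true_fold`).
#' @export
synth_ipms <- function(n_proteins = 200L, n_replicates = 3L, n_planted = 20L,
                       fold = 4, cv = 0.05, mnar_quantile = 0.2,
                       groups = c("bait", "control"), seed = 1L) {
  stopifnot(n_planted <= n_proteins, length(groups) == 2L)
  set.seed(seed)
  prot <- sprintf("P%04d", seq_len(n_proteins))
  planted <- seq_len(n_planted)
  base_log2 <- stats::rnorm(n_proteins, mean = 25, sd = 2)
  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = n_replicates), "_",
                    rep(seq_len(n_replicates), 2L)),
    group = rep(groups, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L)
  )
  eff <- matrix(0, n_proteins, nrow(samples))
  eff[planted, samples$group == groups[1]] <- log2(fold)
  noise_sd_log2 <- sqrt(log(1 + cv^2)) / log(2)
  m <- 2^(base_log2 + eff +
            matrix(stats::rnorm(n_proteins * nrow(samples), 0, noise_sd_log2),
                   n_proteins))
  # per-sample MNAR censoring below the stated intensity quantile
  for (j in seq_len(ncol(m))) {
    m[m[, j] < stats::quantile(m[, j], mnar_quantile), j] <- NA
  }
  colnames(m) <- samples$sample
  intensities <- dplyr::bind_cols(tibble::tibble(protein = prot),
                                  tibble::as_tibble(m))
  npep <- 1L + stats::rpois(n_proteins, 3)
  npep[planted] <- pmax(npep[planted], 2L)
  proteins <- tibble::tibble(protein = prot, n_peptides = npep,
                             is_decoy = FALSE, is_contaminant = FALSE)
  list(
    experiment = ipms_experiment(intensities, samples, proteins),
    truth = tibble::tibble(protein = prot,
                           is_interactor = seq_len(n_proteins) %in% planted,
                           true_fold = ifelse(seq_len(n_proteins) %in% planted,
                                              fold, 1))
  )
}

#' Synthetic DE table with a global starvation downshift and maintained TOP set
#'
#' Models the per-cell reality and the equal-mass observation of a
#' starvation RNA-seq experiment. Per cell, non-TOP genes are scaled by
#' `global_drop` in the starved condition and TOP genes by
#' `top_maintenance`. Libraries are then rescaled to equal total (equal-mass
#' loading), which masks the global reduction: genes that truly dropped by
#' the global factor appear unchanged, while genes maintained per cell
#' appear increased by about `log2(1/global_drop)`. Counts are
#' negative-binomial at the given dispersion; the observed table carries
#' `baseMean` (mean normalized count), `log2FC` (starved vs fed) and a
#' Welch t-test p-value on log2 counts.
#'
#' @param n_genes Number of genes (default 10000).
#' @param top_fraction Fraction of genes in the TOP set (default 0.01).
#' @param global_drop Per-cell scale factor of non-TOP genes under
#'   starvation, in (0, 1] (default 0.4).
#' @param top_maintenance Per-cell scale factor of TOP genes (default 1).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param n_replicates Replicates per condition (default 3).
#' @param total_counts Library size of the equal-mass libraries
#'   (default 2e6).
#' @param seed Integer seed.
#' @return List with `observed` (DE table: `gene`, `baseMean`, `log2FC`,
#'   `pvalue`), `true` (per-gene true per-cell log2 fold change), and
#'   `top_genes` (the TOP identifiers).
#' @export
synth_de <- function(n_genes = 10000L, top_fraction = 0.01, global_drop = 0.4,
                     top_maintenance = 1, dispersion = 0.05,
                     n_replicates = 3L, total_counts = 2e6, seed = 1L) {
  stopifnot(global_drop > 0, global_drop <= 1,
            top_maintenance >= global_drop)
  set.seed(seed)
  gene <- sprintf("gene%05d", seq_len(n_genes))
  n_top <- max(1L, round(top_fraction * n_genes))
  is_top <- seq_len(n_genes) <= n_top
  base <- 2^stats::rnorm(n_genes, mean = 6, sd = 2) # per-cell abundance, fed
  starved <- base * ifelse(is_top, top_maintenance, global_drop)
  sim_counts <- function(abund) {
    frac <- abund / sum(abund) # equal-mass loading: compositions only
    mu <- frac * total_counts
    matrix(stats::rnbinom(n_genes * n_replicates, mu = mu,
                          size = 1 / dispersion),
           n_genes, n_replicates)
  }
  cf <- sim_counts(base)
  cs <- sim_counts(starved)
  lf <- log2(cf + 0.5); ls <- log2(cs + 0.5)
  pvals <- vapply(seq_len(n_genes), function(i) {
    if (stats::sd(lf[i, ]) == 0 && stats::sd(ls[i, ]) == 0) return(1)
    stats::t.test(ls[i, ], lf[i, ])$p.value
  }, numeric(1))
  observed <- tibble::tibble(
    gene = gene,
    baseMean = rowMeans(cbind(cf, cs)),
    log2FC = rowMeans(ls) - rowMeans(lf),
    pvalue = pmin(pmax(pvals, .Machine$double.xmin), 1)
  )
  true <- tibble::tibble(
    gene = gene, is_top = is_top,
    true_log2fc = log2(ifelse(is_top, top_maintenance, global_drop))
  )
  list(observed = observed, true = true, top_genes = gene[is_top])
}

#' Synthetic spike-in qPCR Ct table
#'
#' Ct values follow `baseline - log2(abundance) + Normal(0, noise_sd)`;
#' the spike-in transcript is present in constant amount per sample, so its
#' Ct is constant up to noise. Per-cell target abundance is 1 in the
#' reference condition and `true_folds[target]` in the treated condition.
#'
#' @param targets Character vector of target genes.
#' @param true_folds Numeric vector of per-cell fold changes (treated vs
#'   reference), recycled against `targets`.
#' @param noise_sd Ct noise SD in cycles (default 0.2).
#' @param spike_ct Spike-in baseline Ct (default 18).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param conditions Names of the reference and treated conditions.
#' @param seed Integer seed.
#' @return List with `ct_table` (columns `sample`, `condition`, `target`,
#'   `ct`, `is_spike`) and `truth` (`target`, `true_fold`).
#' @export
synth_qpcr <- function(targets, true_folds, noise_sd = 0.2, spike_ct = 18,
                       n_replicates = 3L, conditions = c("NT", "starved"),
                       seed = 1L) {
  stopifnot(noise_sd >= 0, length(conditions) == 2L)
  true_folds <- rep_len(true_folds, length(targets))
  set.seed(seed)
  baseline <- stats::setNames(stats::runif(length(targets), 22, 28), targets)
  grid <- tidyr::expand_grid(
    condition = conditions, replicate = seq_len(n_replicates),
    target = c(targets, ".spike")
  )
  ct_table <- grid |>
    dplyr::mutate(
      sample = paste0(.data$condition, "_", .data$replicate),
      is_spike = .data$target == ".spike",
      abundance = dplyr::case_when(
        .data$is_spike ~ 1,
        .data$condition == conditions[1] ~ 1,
        TRUE ~ true_folds[match(.data$target, targets)]
      ),
      ct = ifelse(.data$is_spike, spike_ct, baseline[.data$target]) -
        log2(.data$abundance) +
        stats::rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    dplyr::select("sample", "condition", "target", "ct", "is_spike")
  list(ct_table = ct_table,
       truth = tibble::tibble(target = targets, true_fold = true_folds))
}
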
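test_that("detection filter keeps >=2-replicate proteins, drops decoys/contaminants", {
  filt <- filter_proteins(toy_ipms())
  kept <- filt$intensities$protein
  expect_true("kept2of3" %in% kept)   # 2/3 in one group suffices
  expect_false("one_per_group" %in% kept) # 1 per group everywhere
  expect_false("decoy" %in% kept)
  expect_false("contam" %in% kept)
  expect_true("full" %in% kept)
})

test_that("ipms_experiment validates its three tables", {
  x <- toy_ipms()
  expect_error(ipms_experiment(x$intensities, x$samples[0, ], x$proteins),
               "no groups")
  bad_samples <- dplyr::mutate(x$samples, sample = paste0("z", sample))
  expect_error(ipms_experiment(x$intensities, bad_samples, x$proteins),
               "missing from the intensity")
})

test_that("downshifted-normal imputation matches its stated distribution", {
  # one sample with mean 25, sd 2 on log2 scale, many missing cells
  set.seed(1)
  n <- 20000L
  obs <- stats::rnorm(n, 25, 2)
  intens <- tibble::tibble(
    protein = sprintf("p%05d", 1:(2 * n)),
    s1 = 2^c(obs, rep(NA_real_, n)),
    s2 = 2^stats::rnorm(2 * n, 25, 2)
  )
  samples <- tibble::tibble(sample = c("s1", "s2"), group = c("g", "g"),
                            replicate = 1:2)
  proteins <- tibble::tibble(protein = intens$protein, n_peptides = 2L,
                             is_decoy = FALSE, is_contaminant = FALSE)
  x <- ipms_experiment(intens, samples, proteins)
  imp <- impute_missing(x, downshift_sd = 1.8, width_sd = 0.3, seed = 9)
  vals <- imp$intensities$s1[attr(imp, "imputed")[, "s1"]]
  m_s <- mean(obs); s_s <- stats::sd(obs)
  se <- (0.3 * s_s) / sqrt(n)
  expect_lt(abs(mean(vals) - (m_s - 1.8 * s_s)), 3 * se)
  expect_lt(abs(stats::sd(vals) - 0.3 * s_s), 0.01)
})

test_that("imputation is deterministic given the seed and a no-op when complete", {
  gen <- synth_ipms(n_proteins = 60, seed = 21)
  x <- filter_proteins(gen$experiment)
  i1 <- impute_missing(x, seed = 5)
  i2 <- impute_missing(x, seed = 5)
  expect_identical(i1$intensities, i2$intensities)
  i3 <- impute_missing(x, seed = 6)
  expect_false(identical(i1$intensities, i3$intensities))

  complete <- i1 # already complete; a second pass must not alter values
  expect_equal(impute_missing(complete, seed = 1)$intensities,
               complete$intensities)
})

test_that("differential enrichment: log2FC is the log geometric-mean ratio and antisymmetric", {
  gen <- synth_ipms(n_proteins = 80, n_planted = 8, seed = 2)
  x <- impute_missing(filter_proteins(gen$experiment), seed = 2)
  ab <- differential_enrichment(x, "bait", "control")
  ba <- differential_enrichment(x, "control", "bait")
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$fold, 2^ab$log2FC)

  # identical groups give log2FC 0 and zero-variance flags
  intens <- tibble::tibble(protein = c("a", "b"),
                           g1 = c(4, 8), g2 = c(4, 8),
                           h1 = c(4, 8), h2 = c(4, 8))
  samples <- tibble::tibble(sample = c("g1", "g2", "h1", "h2"),
                            group = c("g", "g", "h", "h"), replicate = c(1:2, 1:2))
  proteins <- tibble::tibble(protein = c("a", "b"), n_peptides = 2L,
                             is_decoy = FALSE, is_contaminant = FALSE)
  x0 <- ipms_experiment(intens, samples, proteins)
  rows0 <- differential_enrichment(x0, "g", "h")
  expect_equal(rows0$log2FC, c(0, 0))
  expect_true(all(rows0$zero_variance))
  expect_equal(rows0$p, c(1, 1))
})

test_that("BH q-values equal the hand step-up formula", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(31)
  for (i in 1:10) {
    p <- stats::runif(sample(2:10, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_by_hand(p))
  }
  # and the pipeline's q column is BH over its own p column
  gen <- synth_ipms(n_proteins = 50, seed = 3)
  rows <- gen$experiment |>
    filter_proteins() |>
    impute_missing(seed = 3) |>
    differential_enrichment("bait", "control")
  expect_equal(rows$q, bh_by_hand(rows$p))
})

test_that("interactor calls apply all three strict criteria", {
  rows <- tibble::tibble(
    protein = c("pass", "fold_at_boundary", "few_peptides", "high_q"),
    log2FC = c(1.5, 1.0, 3, 3),
    fold = 2^c(1.5, 1.0, 3, 3),
    p = c(0.001, 0.001, 0.001, 0.2),
    q = c(0.01, 0.01, 0.01, 0.3),
    n_peptides = c(3L, 3L, 1L, 3L)
  )
  called <- call_interactors(rows)
  expect_equal(called$called, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(called, "criteria")$fc_threshold, 2)
})

test_that("preferential set uses raw p, not FDR", {
  rows <- tibble::tibble(protein = c("a", "b", "c"),
                         log2FC = c(1.1, 1.1, 0.5),
                         fold = 2^c(1.1, 1.1, 0.5),
                         p = c(0.04, 0.06, 0.01),
                         q = c(0.2, 0.2, 0.05),
                         n_peptides = 3L)
  expect_equal(preferential_set(rows), "a")
  expect_equal(preferential_set(rows[0, ]), character())
})

test_that("planted interactors are recovered with high sensitivity and low FDP", {
  perf <- vapply(1:20, function(s) {
    gen <- synth_ipms(seed = s) # defaults: 200 proteins, 20 planted, 4-fold
    rows <- gen$experiment |>
      filter_proteins() |>
      impute_missing(seed = s) |>
      differential_enrichment("bait", "control") |>
      call_interactors()
    truth <- gen$truth$protein[gen$truth$is_interactor]
    called <- rows$protein[rows$called]
    c(sens = length(intersect(called, truth)) / length(truth),
      fdp = if (length(called)) length(setdiff(called, truth)) / length(called)
            else 0)
  }, numeric(2))
  expect_gte(mean(perf["sens", ]), 0.9)
  expect_lte(mean(perf["fdp", ]), 0.1)
})

test_that("fold-change estimates center on the planted 4-fold effect", {
  ok <- vapply(1:10, function(s) {
    gen <- synth_ipms(seed = 100 + s)
    rows <- gen$experiment |>
      filter_proteins() |>
      impute_missing(seed = s) |>
      differential_enrichment("bait", "control")
    # restrict to planted proteins quantified without imputation: a
    # censored control intensity rightly inflates the estimated enrichment
    keep <- rows$protein %in% gen$truth$protein[gen$truth$is_interactor] &
      rows$imputed_frac_a == 0 & rows$imputed_frac_b == 0
    mean(rows$log2FC[keep] > 1.8 & rows$log2FC[keep] < 2.2)
  }, numeric(1))
  expect_gte(mean(ok), 0.95)
})

test_that("null IP-MS data yields a false-positive rate within the FDR target", {
  fp <- vapply(1:25, function(s) {
    gen <- synth_ipms(n_planted = 0L, fold = 1, seed = 200 + s)
    rows <- gen$experiment |>
      filter_proteins() |>
      impute_missing(seed = s) |>
      differential_enrichment("bait", "control") |>
      call_interactors()
    mean(rows$called)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
})
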
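de_row <- function(baseMean, log2FC, pvalue, gene = "g") {
  tibble::tibble(gene = gene, baseMean = baseMean, log2FC = log2FC,
                 pvalue = pvalue)
}

test_that("DEG classification applies the printed criteria strictly", {
  expect_equal(as.character(classify_degs(de_row(100, 0.5, 0.01))$label), "up")
  expect_equal(as.character(classify_degs(de_row(5, 2.0, 0.001))$label),
               "filtered")
  expect_equal(as.character(classify_degs(de_row(50, 0.263, 0.01))$label),
               "unchanged") # strict boundary on |log2FC|
  expect_equal(as.character(classify_degs(de_row(10, 2, 0.001))$label),
               "filtered") # strict boundary on baseMean
  expect_equal(as.character(classify_degs(de_row(50, -0.5, 0.01))$label),
               "down")
  expect_equal(as.character(classify_degs(de_row(50, -0.5, 0.05))$label),
               "unchanged") # strict boundary on p
})

test_that("classification errors on bad schema or p-values and collapses duplicates", {
  expect_error(classify_degs(tibble::tibble(gene = "g", baseMean = 1)),
               "schema")
  expect_error(classify_degs(de_row(50, 1, 0)), "value error")
  expect_error(classify_degs(de_row(50, 1, 1.5)), "value error")
  dup <- dplyr::bind_rows(de_row(50, 1, 0.01), de_row(50, -1, 0.001))
  expect_warning(out <- classify_degs(dup), "duplicate")
  expect_equal(nrow(out), 1L)
  expect_equal(as.character(out$label), "down") # most significant kept
})

test_that("labels partition the table", {
  gen <- synth_de(n_genes = 400, seed = 8)
  degs <- classify_degs(gen$observed)
  expect_equal(sum(table(degs$label)), nrow(degs))
})

test_that("overlap statistics match closed form and brute-force enumeration", {
  # representation factor closed form
  u <- sprintf("g%04d", 1:1000)
  res <- overlap_fet(u[1:20], u[c(1:10, 101:140)], u)
  expect_equal(res$x, 10L)
  expect_equal(res$representation_factor, 10 * 1000 / (20 * 50))

  # disjoint sets
  d <- overlap_fet(u[1:5], u[6:10], u[1:100])
  expect_equal(d$representation_factor, 0)
  expect_equal(d$p_right, 1)

  # exhaustive enumeration for all small universes
  set.seed(17)
  for (i in 1:12) {
    N <- sample(4:12, 1)
    n <- sample(1:(N - 1), 1)
    m <- sample(1:(N - 1), 1)
    univ <- sprintf("x%02d", 1:N)
    res <- overlap_fet(univ[1:n], univ[1:m], univ)
    expect_equal(res$p_right, enum_overlap_p(res$x, n, m, N))
  }
  expect_error(overlap_fet("a", "a", character()), "empty universe")
})

test_that("representation factor exceeds 1 exactly when overlap beats expectation", {
  set.seed(23)
  for (i in 1:20) {
    N <- sample(20:60, 1)
    univ <- as.character(1:N)
    q <- sample(univ, sample(2:10, 1))
    a <- sample(univ, sample(2:10, 1))
    res <- overlap_fet(q, a, univ)
    expect_equal(res$representation_factor > 1,
                 res$x > res$n * res$m / res$N)
  }
})

test_that("percentages reproduce the printed values with half-up rounding", {
  expect_equal(percent_of(90, 111), 81L)
  expect_equal(percent_of(75, 77), 97L)
  expect_equal(percent_of(27, 77), 35L)
  expect_equal(percent_of(31, 111), 28L)
  expect_equal(percent_of(1, 200), 1L)   # 0.5 rounds away from zero
  expect_error(percent_of(5, 0), "denominator")
  expect_error(percent_of(5, 4), "numerator")
})

test_that("log2FC threshold converts to the printed fold change", {
  expect_equal(signif(log2fc_to_fc(0.263), 2), 1.2)
  expect_equal(log2fc_to_fc(1), 2)
  expect_equal(log2fc_to_fc(0), 1)
})

test_that("maintenance report counts, percentages and enrichment behave", {
  degs <- classify_degs(tibble::tibble(
    gene = sprintf("g%02d", 1:40),
    baseMean = c(rep(100, 36), rep(5, 4)),
    log2FC = c(rep(-1, 10), rep(1, 6), rep(0, 20), rep(-1, 4)),
    pvalue = c(rep(0.001, 16), rep(0.5, 20), rep(0.001, 4))
  ))
  top <- sprintf("g%02d", 1:10) # all of these are "down"
  rep1 <- maintenance_report(degs, list(TOP = top))
  expect_equal(rep1$detected, 10L)
  expect_equal(rep1$n_down, 10L)
  expect_equal(rep1$pct_down, 100L)
  expect_lt(rep1$p_right, 1e-4)

  # undetected set: empty report row with a warning
  expect_warning(rep2 <- maintenance_report(degs, list(none = c("z1", "z2"))),
                 "absent")
  expect_equal(rep2$detected, 0L)

  # filtered genes are excluded from the universe and the detected counts
  expect_warning(rep3 <- maintenance_report(degs, list(f = sprintf("g%02d", 37:40))),
                 NA)
  expect_equal(rep3$detected, 0L)
})

test_that("planted TOP down-rate is recovered within binomial error", {
  rate <- 0.3
  n_top <- 100
  set.seed(55)
  genes <- sprintf("g%04d", 1:2000)
  is_top <- seq_along(genes) <= n_top
  down <- c(stats::runif(n_top) < rate,
            stats::runif(2000 - n_top) < 0.05)
  degs <- classify_degs(tibble::tibble(
    gene = genes, baseMean = 100,
    log2FC = ifelse(down, -1, 0),
    pvalue = ifelse(down, 0.001, 0.5)
  ))
  rep <- maintenance_report(degs, list(TOP = genes[is_top]))
  ci <- stats::binom.test(round(rate * n_top), n_top)$conf.int
  expect_gte(rep$pct_down / 100, ci[1])
  expect_lte(rep$pct_down / 100, ci[2])
})

test_that("gene set and DE table readers round-trip", {
  gs <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("RPS3", "RPS6", "", "RPS3"), gs)
  expect_equal(read_gene_set(gs), c("RPS3", "RPS6"))

  det <- withr::local_tempfile(fileext = ".tsv")
  tab <- de_row(100, 0.5, 0.01)
  readr::write_tsv(tab, det)
  expect_equal(read_de_table(det), tab)
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "g"), bad)
  expect_error(read_de_table(bad), "schema")
})
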
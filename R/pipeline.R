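#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the analysis arc — dipeptide/motif statistics, conservation
#' testing, IP-MS enrichment, DE/TOP maintenance, and spike-in qPCR
#' quantification — over files named in a configuration list (or YAML
#' file). Only stages whose inputs are configured run; each stage writes
#' its TSV output under `out_dir`, and a single JSON manifest records the
#' fully resolved configuration, the seed, input checksums and the stages
#' completed. On any error, partially written outputs are removed.
#'
#' Configuration keys (all paths; thresholds default to the published
#' criteria of the owning functions):
#' * `motif`: `fasta`, `regions`, optional `pair`
#' * `conservation`: `msa`, `reference_id`, `region_start`, `region_end`
#' * `interactome`: `matrix`, `samples`, `proteins`, `group_a`, `group_b`
#' * `de`: `table`, named gene-set files under `sets`
#' * `qpcr`: `table`, `reference_condition`
#'
#' @param config List or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed forwarded to every stochastic step.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  inputs <- pipeline_inputs(config)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stages <- character(0)
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tab, path)
    written <<- c(written, path)
    path
  }
  result <- tryCatch({
    if (!is.null(config$motif)) {
      fa <- read_protein_fasta(config$motif$fasta)
      regions <- read_regions(config$motif$regions)
      pair <- config$motif$pair %||% "RG"
      out <- purrr::map_dfr(seq_len(nrow(fa)), function(i) {
        regs <- regions[regions$seq_id == fa$id[i], ]
        if (nrow(regs) == 0L) return(NULL)
        dplyr::bind_cols(tibble::tibble(seq_id = fa$id[i]),
                         region_pair_enrichment(fa$seq[i], regs, pair))
      })
      bias <- purrr::map_dfr(seq_len(nrow(fa)), function(i) {
        dplyr::bind_cols(tibble::tibble(seq_id = fa$id[i]),
                         tidy(dipeptide_bias_test(fa$seq[i], pair)))
      })
      emit(out, "motif_region_enrichment.tsv")
      emit(bias, "dipeptide_bias.tsv")
      stages <- c(stages, "motif")
    }
    if (!is.null(config$conservation)) {
      cc <- config$conservation
      msa <- read_msa(cc$msa, cc$reference_id)
      prof <- column_conservation(msa)
      tst <- region_conservation_test(
        prof, region(cc$region_start, cc$region_end), seed = seed
      )
      emit(prof, "conservation_profile.tsv")
      emit(tidy(tst), "conservation_test.tsv")
      stages <- c(stages, "conservation")
    }
    if (!is.null(config$interactome)) {
      ci <- config$interactome
      expt <- ipms_experiment(
        readr::read_tsv(ci$matrix, show_col_types = FALSE),
        readr::read_tsv(ci$samples, show_col_types = FALSE),
        readr::read_tsv(ci$proteins, show_col_types = FALSE)
      )
      rows <- expt |>
        filter_proteins() |>
        impute_missing(seed = seed) |>
        differential_enrichment(ci$group_a, ci$group_b) |>
        call_interactors()
      emit(rows, "interactome_enrichment.tsv")
      stages <- c(stages, "interactome")
    }
    if (!is.null(config$de)) {
      cd <- config$de
      degs <- classify_degs(read_de_table(cd$table))
      sets <- purrr::map(cd$sets, read_gene_set)
      rep <- maintenance_report(degs, sets)
      emit(degs, "deg_classification.tsv")
      emit(rep, "maintenance_report.tsv")
      stages <- c(stages, "de")
    }
    if (!is.null(config$qpcr)) {
      cq <- config$qpcr
      ct <- readr::read_tsv(cq$table, show_col_types = FALSE)
      emit(ddct_table(ct, cq$reference_condition), "qpcr_fold_changes.tsv")
      stages <- c(stages, "qpcr")
    }
    TRUE
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("toppreserve")),
    seed = seed,
    stages_completed = stages,
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)),
    output_checksums = as.list(tools::md5sum(written))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

pipeline_inputs <- function(config) {
  unlist(c(
    config$motif[c("fasta", "regions")],
    config$conservation["msa"],
    config$interactome[c("matrix", "samples", "proteins")],
    config$de["table"], config$de$sets,
    config$qpcr["table"]
  ), use.names = FALSE)
}
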
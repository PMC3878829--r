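# Pipeline orchestration: a one-shot runner that executes the enabled
# stages (trim -> annotate -> filter -> diffexp -> targets) from a single
# configuration, writing per-stage outputs and a run log. Analyses can also
# enter mid-way with a pre-computed count table instead of FASTQ input.

config_error <- function(msg) {
  stop(structure(class = c("srnapipe_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

data_error <- function(msg) {
  stop(structure(class = c("srnapipe_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

default_stages <- function() {
  list(trim = TRUE, annotate = TRUE, filter = FALSE, diffexp = FALSE,
       targets = FALSE)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(paste0("config file not found: ",
                                                  config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML path")
  config
}

validate_pipeline_config <- function(config) {
  stages <- utils::modifyList(default_stages(), config$stages %||% list())
  if (!any(unlist(stages))) config_error("no stage enabled")
  has_fastq <- !is.null(config$input$samples)
  has_table <- !is.null(config$input$count_table)
  if (stages$trim && !has_fastq) {
    config_error("stage 'trim' requires input$samples (FASTQ files)")
  }
  if (stages$annotate) {
    if (!has_fastq) config_error("stage 'annotate' requires input$samples")
    if (is.null(config$annotate$libraries)) {
      config_error("stage 'annotate' requires annotate$libraries")
    }
  }
  if ((stages$filter || stages$diffexp) && !stages$annotate && !has_table) {
    config_error(paste0("stage '", if (stages$filter) "filter" else "diffexp",
                        "' needs the 'annotate' stage or input$count_table"))
  }
  if (stages$diffexp &&
      (is.null(config$diffexp$test) || is.null(config$diffexp$control))) {
    config_error("stage 'diffexp' requires diffexp$test and diffexp$control")
  }
  if (stages$targets && is.null(config$targets$utrs)) {
    config_error("stage 'targets' requires targets$utrs (FASTA)")
  }
  stages
}

pipeline_adapter_spec <- function(cfg) {
  adapter_spec(cfg$adapters %||% cfg$adapter %||%
                 "TGGAATTCTCGGGTGCCAAGG",
               max_error_rate = cfg$error_rate %||% 0.1,
               min_overlap = cfg$min_overlap %||% 3L)
}

pipeline_libraries <- function(cfg) {
  libs <- list()
  for (cl in names(cfg$libraries)) {
    path <- cfg$libraries[[cl]]
    if (!file.exists(path)) data_error(paste0("library FASTA not found: ",
                                              path))
    libs[[cl]] <- read_fasta(path, rna_class = cl, name = cl)
  }
  # cascade priority: conventional class order, then any extra names
  ord <- c(intersect(RNA_CLASSES, names(libs)),
           setdiff(names(libs), RNA_CLASSES))
  libs[ord]
}

#' Run the small RNA analysis pipeline
#'
#' Executes the enabled stages in dependency order (trim, annotate,
#' filter, diffexp, targets) from a configuration list or YAML file,
#' writing each stage's outputs and a timestamped log under `out_dir`. A
#' pre-computed count table (`input$count_table`) may replace FASTQ input
#' to enter the pipeline mid-way.
#'
#' Configuration keys (all stage blocks optional unless the stage is
#' enabled): `stages` (logical flags per stage); `input$samples` (list of
#' `name`/`fastq`/`group`); `input$count_table`; `trim`
#' (`adapters`, `error_rate`, `min_overlap`, `min_length`, `min_quality`);
#' `annotate` (`libraries`: named class -> FASTA path, `mismatches`);
#' `filter` (`min_count` or `percentile`); `diffexp` (`test`, `control`,
#' `fc_threshold`, `p_threshold`, `correction`, `use_adjusted_p`);
#' `targets` (`utrs`, `mirnas`, `site_types`, `min_sites`).
#'
#' @param config A configuration list or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the count table, DE results, per-sample
#'   reports and the paths of all written files.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  stages <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  outputs <- character()
  logf("pipeline start; stages: %s",
       paste(names(stages)[unlist(stages)], collapse = ", "))

  samples <- config$input$samples
  sample_reads <- list()
  if (stages$trim || stages$annotate) {
    spec <- pipeline_adapter_spec(config$trim)
    min_length <- config$trim$min_length %||% 15L
    min_quality <- config$trim$min_quality %||% 20
    for (s in samples) {
      if (!file.exists(s$fastq)) {
        data_error(paste0("FASTQ not found: ", s$fastq))
      }
      reads <- read_fastq(s$fastq)
      pp <- preprocess_reads(reads, spec, min_length = min_length,
                             min_quality = min_quality)
      sample_reads[[s$name]] <- pp$reads
      rep <- pp$report
      logf("trim %s: input %d kept %d short %d low-quality %d",
           s$name, rep$n_input, rep$n_kept, rep$n_discarded_short,
           rep$n_discarded_quality)
      fq_out <- file.path(out_dir, paste0(s$name, ".trimmed.fastq"))
      write_fastq(pp$reads, fq_out)
      hist_out <- file.path(out_dir, paste0(s$name, ".lengths.tsv"))
      write.table(rep$length_histogram, hist_out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs <- c(outputs, fq_out, hist_out)
    }
  }

  tab <- NULL
  if (stages$annotate) {
    libs <- pipeline_libraries(config$annotate)
    cc <- cascade_config(libs,
                         max_mismatches = unlist(config$annotate$mismatches))
    per_sample <- list()
    summaries <- list()
    for (nm in names(sample_reads)) {
      ann <- cascade_annotate(collapse_reads(sample_reads[[nm]]), cc)
      per_sample[[nm]] <- ann$counts
      smry <- ann$summary
      smry$sample <- nm
      summaries[[nm]] <- smry
      logf("annotate %s: %s", nm,
           paste(sprintf("%s=%g", smry$library, smry$reads), collapse = " "))
    }
    tab <- merge_sample_counts(per_sample)
    tsv <- file.path(out_dir, "counts.tsv")
    write_count_table(tab, tsv)
    sum_tsv <- file.path(out_dir, "annotation_summary.tsv")
    write.table(do.call(rbind, summaries), sum_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, tsv, sum_tsv)
  } else if (!is.null(config$input$count_table)) {
    if (!file.exists(config$input$count_table)) {
      data_error(paste0("count table not found: ", config$input$count_table))
    }
    tab <- read_count_table(config$input$count_table)
    logf("loaded count table: %d features x %d samples", nrow(tab),
         length(sample_columns(tab)))
  }

  if (stages$filter) {
    n0 <- nrow(tab)
    if (!is.null(config$filter$min_count)) {
      tab <- min_count_filter(tab, config$filter$min_count)
    } else if (!is.null(config$filter$percentile)) {
      tab <- percentile_filter(tab, config$filter$percentile)
    } else {
      config_error("stage 'filter' requires filter$min_count or filter$percentile")
    }
    logf("filter: %d -> %d features", n0, nrow(tab))
    tsv <- file.path(out_dir, "counts.filtered.tsv")
    write_count_table(tab, tsv)
    outputs <- c(outputs, tsv)
  }

  de <- NULL
  if (stages$diffexp) {
    cfg <- config$diffexp
    if (!all(c(cfg$test, cfg$control) %in% sample_columns(tab))) {
      data_error("diffexp test/control sample not present in count table")
    }
    params <- de_params(fc_threshold = cfg$fc_threshold %||% 1.5,
                        p_threshold = cfg$p_threshold %||% 0.05,
                        use_adjusted_p = cfg$use_adjusted_p %||% FALSE,
                        correction = cfg$correction)
    de <- differential_expression(tab, cfg$test, cfg$control, params)
    smry <- summary(de)
    logf("diffexp %s vs %s: up %d down %d unchanged %d (%.1f%%), k=%g",
         cfg$test, cfg$control, smry$n_up, smry$n_down, smry$n_unchanged,
         smry$pct_unchanged, smry$correction_k)
    de_tsv <- file.path(out_dir, "de_results.tsv")
    write.table(de, de_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    sum_tsv <- file.path(out_dir, "de_summary.tsv")
    write.table(as.data.frame(smry[c("n_up", "n_down", "n_unchanged",
                                     "pct_unchanged", "correction_k")]),
                sum_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, de_tsv, sum_tsv)
    if (length(sample_columns(tab)) >= 2L) {
      cl <- hierarchical_cluster(tab)
      nwk <- file.path(out_dir, "samples.newick")
      writeLines(cl$newick, nwk)
      outputs <- c(outputs, nwk)
    }
  }

  if (stages$targets) {
    cfg <- config$targets
    utrs <- read_fasta(cfg$utrs, rna_class = "mRNA", name = "utrs")
    mirnas <- if (!is.null(cfg$mirnas)) {
      read_fasta(cfg$mirnas, rna_class = "miRNA", name = "mirnas")
    } else if (!is.null(de)) {
      # predict targets of up/down-called miRNAs from the annotate stage
      called <- de$feature_id[de$call != "unchanged" &
                                de$rna_class == "miRNA"]
      if (!length(called)) NULL else {
        libs <- pipeline_libraries(config$annotate)
        mir <- libs[["miRNA"]]
        keep <- mir$ids %in% called
        ref_library("de_mirnas", "miRNA", mir$ids[keep], mir$seqs[keep])
      }
    } else {
      config_error("stage 'targets' requires targets$mirnas or a diffexp run")
    }
    if (!is.null(mirnas)) {
      params <- seed_match_params(
        site_types = cfg$site_types %||% SITE_TYPES,
        min_sites_per_utr = cfg$min_sites %||% 1L)
      tg <- predict_targets(mirnas, utrs, params)
      tg_tsv <- file.path(out_dir, "targets.tsv")
      write.table(tg, tg_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, tg_tsv)
      logf("targets: %d (miRNA, UTR) pairs", nrow(tg))
    } else {
      logf("targets: no differentially expressed miRNAs; nothing to scan")
    }
  }

  logf("pipeline done")
  invisible(list(count_table = tab, de = de, outputs = outputs,
                 log = log_path))
}
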
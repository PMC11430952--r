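# End-to-end orchestration: annotate -> (user-supplied MSA) -> distances
# -> group summaries -> taxonomy report. Alignment itself is an explicit
# external step: the pipeline writes trimmed FASTA for the user to align
# and resumes from a provided MSA.

#' Pipeline configuration
#'
#' @param input_fasta Raw ITS records to annotate (FASTA path).
#' @param msa_fasta Optional aligned FASTA to resume distance analyses from.
#' @param partition_file Optional partition table for the MSA (required
#'   with `method = "ml"`).
#' @param tree_file,group_file Optional Newick tree and tip-to-group TSV
#'   for the taxonomy stage.
#' @param out_dir Output directory (created if absent).
#' @param method Distance method(s): `"p"`, `"ml"` or `"both"`.
#' @param window Motif search window (nt).
#' @param bp_min,pp_min Support thresholds for group evaluation.
#' @param species_threshold Delimitation threshold on p-distance.
#' @param seed Global seed echoed into outputs.
#' @param verbose Emit progress messages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_fasta = NULL, msa_fasta = NULL,
                            partition_file = NULL, tree_file = NULL,
                            group_file = NULL, out_dir = "gyrits_out",
                            method = c("p", "ml", "both"), window = 120L,
                            bp_min = 75, pp_min = 0.95,
                            species_threshold = 0.013, seed = 1L,
                            verbose = TRUE) {
  method <- match.arg(method)
  assert_scalar_number(window, "window", lower = 7)
  assert_scalar_number(bp_min, "bp_min", lower = 0, upper = 100)
  assert_scalar_number(pp_min, "pp_min", lower = 0, upper = 1)
  assert_scalar_number(species_threshold, "species_threshold", lower = 0, upper = 1)
  structure(list(input_fasta = input_fasta, msa_fasta = msa_fasta,
                 partition_file = partition_file, tree_file = tree_file,
                 group_file = group_file, out_dir = out_dir, method = method,
                 window = as.integer(window), bp_min = bp_min, pp_min = pp_min,
                 species_threshold = species_threshold,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order: motif QC and annotation of the
#' raw records, distance matrices and group summaries on a user-provided
#' MSA, and monophyly/delimitation reports on a user-provided tree. Every
#' run echoes its configuration (with an MD5 stamp) into the output
#' directory; the log records counts and one line per QC flag raised.
#' Inputs are never modified; all outputs are new files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths) and stage results. Any stage failure raises an error naming
#'   the stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- sprintf(...)
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line), log_con)
    if (cfg$verbose) message(line)
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logmsg("config hash %s, seed %d", cfg_hash, cfg$seed)

  artifacts <- c(config = cfg_path)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(cfg$input_fasta)) {
    results$qc <- stage("annotate", {
      records <- read_fasta(cfg$input_fasta)
      logmsg("annotate: %d records read", length(records))
      batch <- batch_qc(records, window = cfg$window)
      for (i in seq_len(nrow(batch$table))) {
        fl <- batch$table$flags[i]
        if (nzchar(fl))
          for (f in strsplit(fl, ";", fixed = TRUE)[[1L]])
            logmsg("flag %s %s", batch$table$id[i], f)
      }
      prefix <- file.path(cfg$out_dir, "annotate")
      artifacts <<- c(artifacts, write_qc_table(batch, prefix))
      diag_path <- paste0(prefix, "_diagnoses.txt")
      diags <- vapply(names(batch$annotations), function(id) {
        a <- batch$annotations[[id]]
        if (is.null(a)) sprintf("ITS rDNA (%s) ND bp: annotation failed", id)
        else diagnose(a$annotation, id)
      }, character(1L))
      writeLines(diags, diag_path)
      trimmed <- list()
      for (id in names(batch$annotations)) {
        a <- batch$annotations[[id]]
        if (is.null(a)) next
        regs <- extract_regions(records[[id]], a$annotation)
        if (!is.na(regs$ITS)) trimmed[[id]] <- regs$ITS
        for (rg in c("ITS1", "5.8S", "ITS2"))
          if (!is.na(regs[[rg]]))
            trimmed[[paste(id, rg, sep = "|")]] <- regs[[rg]]
      }
      trim_path <- paste0(prefix, "_trimmed.fasta")
      if (length(trimmed)) write_fasta(unlist(trimmed), trim_path)
      artifacts <<- c(artifacts, diag_path, trim_path)
      logmsg("annotate: %d/%d records trimmed",
             sum(!vapply(batch$annotations, is.null, logical(1L))),
             length(records))
      batch
    })
  }

  if (!is.null(cfg$msa_fasta)) {
    results$distances <- stage("distances", {
      seqs <- read_fasta(cfg$msa_fasta)
      parts <- if (!is.null(cfg$partition_file))
        read_partition_table(cfg$partition_file) else NULL
      if (cfg$method %in% c("ml", "both") && is.null(parts))
        stop("method 'ml' requires a partition file")
      aln <- partitioned_alignment(seqs, parts)
      out <- list()
      if (cfg$method %in% c("p", "both")) {
        out$p <- p_distance_matrix(aln)
        p_path <- file.path(cfg$out_dir, "distances_p.tsv")
        write_distance_matrix(out$p, p_path)
        artifacts <<- c(artifacts, p_path)
      }
      if (cfg$method %in% c("ml", "both")) {
        logmsg("distances: fitting partition models")
        aln <- fit_partition_models(aln)
        out$ml <- ml_distance_matrix(aln)
        ml_path <- file.path(cfg$out_dir, "distances_ml.tsv")
        write_distance_matrix(out$ml, ml_path)
        artifacts <<- c(artifacts, ml_path)
      }
      long <- do.call(distance_long_format, out)
      long_path <- file.path(cfg$out_dir, "distances_long.tsv")
      write_tsv(long, long_path)
      artifacts <<- c(artifacts, long_path)
      logmsg("distances: %d x %d matrix (%s)", length(seqs), length(seqs),
             cfg$method)
      if (!is.null(cfg$group_file)) {
        groups <- read_group_map(cfg$group_file)
        mat <- out$p %||% out$ml
        gs <- group_distance_summary(mat, groups)
        gs_path <- file.path(cfg$out_dir, "group_summary.tsv")
        write_tsv(rbind(
          data.frame(kind = "intra", a = gs$intra$group, b = gs$intra$group,
                     n_pairs = gs$intra$n_pairs,
                     mean_distance = gs$intra$mean_distance),
          data.frame(kind = "inter", a = gs$inter$group_a, b = gs$inter$group_b,
                     n_pairs = gs$inter$n_pairs,
                     mean_distance = gs$inter$mean_distance)), gs_path)
        artifacts <<- c(artifacts, gs_path)
        out$summary <- gs
      }
      out
    })
  }

  if (!is.null(cfg$tree_file) && !is.null(cfg$group_file)) {
    results$taxonomy <- stage("taxonomy", {
      tv <- read_newick(cfg$tree_file)
      groups <- read_group_map(cfg$group_file)
      pmat <- results$distances$p
      out <- list(groups = evaluate_groups(tv, groups, cfg$bp_min, cfg$pp_min))
      if (!is.null(pmat)) {
        rep <- lineage_report(tv, groups, pmat, cfg$bp_min, cfg$pp_min)
        artifacts <<- c(artifacts,
                        write_lineage_report(rep, file.path(cfg$out_dir, "lineage")))
        out$report <- rep
        out$clusters <- delimit_species(pmat, cfg$species_threshold)
        cl_path <- file.path(cfg$out_dir, "species_clusters.tsv")
        write_tsv(out$clusters, cl_path)
        artifacts <<- c(artifacts, cl_path)
      } else {
        mono_path <- file.path(cfg$out_dir, "monophyly.tsv")
        write_tsv(out$groups, mono_path)
        artifacts <<- c(artifacts, mono_path)
      }
      logmsg("taxonomy: %d groups evaluated", nrow(out$groups))
      out
    })
  }

  logmsg("pipeline complete: %d artifacts", length(artifacts))
  invisible(list(status = 0L, artifacts = artifacts, results = results,
                 config_hash = cfg_hash))
}
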
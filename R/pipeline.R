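#' Pipeline configuration
#'
#' Assembles the per-stage parameter objects and file paths driving
#' [run_pipeline()]. Every default matches the pipeline's canonical values
#' (1 Mb windows with 500 kb overlap, 8 assembly rounds, 0.4 kb fragment
#' merging, the 13%/4.5 kb indel rule, and the type-specific intersection
#' windows).
#'
#' @param reference Either a list with `seqs`/`maps` (in-memory) or a FASTA
#'   path.
#' @param sim A [sim_config()] to simulate molecules, or `NULL` when
#'   `rmaps` is given.
#' @param rmaps Optional list of [rmap()] (or a map-TSV path).
#' @param normal_rmaps Optional normal-sample molecules (or path) for CNV
#'   normalization; when `NULL` and `sim` is given, a matched diploid
#'   normal is simulated.
#' @param panels Optional panels for somatic filtering (see
#'   [filter_somatic()]).
#' @param genes Optional gene `GRanges` or BED path.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Master seed; every stage's randomness derives from it.
#' @param n_rounds Assembly rounds.
#' @param window_bp,overlap_bp Assembly window geometry.
#' @param cnv_m Normal midpoints per CNV interval.
#' @param aln_params,asm_params,thresholds,rules Stage parameter objects.
#' @export
pipeline_config <- function(reference, sim = NULL, rmaps = NULL,
                            normal_rmaps = NULL, panels = list(),
                            genes = NULL, out_dir = NULL, seed = 1L,
                            n_rounds = 8L, window_bp = 1e6, overlap_bp = 5e5,
                            cnv_m = 10L,
                            aln_params = alignment_params(),
                            asm_params = assembly_params(),
                            thresholds = call_thresholds(),
                            rules = intersection_rules()) {
  if (is.null(sim) && is.null(rmaps))
    stop("either a simulation config or an rmap collection is required")
  structure(list(reference = reference, sim = sim, rmaps = rmaps,
                 normal_rmaps = normal_rmaps, panels = panels, genes = genes,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_rounds = as.integer(n_rounds), window_bp = window_bp,
                 overlap_bp = overlap_bp, cnv_m = as.integer(cnv_m),
                 aln_params = aln_params, asm_params = asm_params,
                 thresholds = thresholds, rules = rules),
            class = "pipeline_config")
}

#' Run the full optical-map analysis pipeline
#'
#' simulate (optional) → align → iterative assembly → structural-alteration
#' calling → copy-number analysis (whole sample and per slice) → somatic
#' filtering / gene annotation. Returns a run report with per-class OSA
#' counts, the fold coverage of aligned molecule mass over the reference,
#' the copy-number segment table, and truth-comparison metrics when the
#' molecules carry simulation truth.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- config$reference
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference path does not exist: ",
                                      reference)
    seqs <- read_fasta(reference)
    reference <- list(seqs = seqs, maps = digest_genome(seqs))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  truth <- NULL; variant_truth <- NULL
  if (!is.null(config$sim)) {
    simres <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_tumor(reference, cfg)
    })
    rmaps <- simres$rmaps
    truth <- simres$molecule_truth
    variant_truth <- simres$variant_truth
  } else {
    rmaps <- config$rmaps
    if (is.character(rmaps)) rmaps <- read_maps(rmaps)
  }
  asm <- stage("assemble", iterate_assembly(
    rmaps, reference$maps, n_rounds = config$n_rounds,
    aln_params = config$aln_params, asm_params = config$asm_params,
    window_bp = config$window_bp, overlap_bp = config$overlap_bp))
  tab <- asm$alignment$table
  aligned_mass_kb <- sum(vapply(rmaps, function(r) sum(r$fragments),
                                numeric(1))[tab$status == "aligned"])
  fold_coverage <- aligned_mass_kb * 1000 / reference$maps$total_length_bp

  svs <- stage("call-sv", call_genome(
    asm, reference$maps, thresholds = config$thresholds,
    error_params = pipeline_error_params(config),
    aln_params = config$aln_params))

  # CNV: normal midpoints from a matched diploid normal
  normal <- config$normal_rmaps
  if (is.null(normal) && !is.null(config$sim)) {
    ncfg <- config$sim
    ncfg$seed <- config$seed + 104729L
    ncfg$subclones <- list(list(label = "normal", fraction = 1,
                                copy_profile = NULL, variant_set = list()))
    normal <- stage("simulate-normal",
                    simulate_rmaps(list(normal = list(maps = reference$maps)),
                                   ncfg)$rmaps)
  } else if (is.character(normal)) normal <- read_maps(normal)
  cnv <- NULL; slices <- NULL
  if (!is.null(normal)) {
    nm <- stage("align-normal",
                midpoints(align_batch(normal, reference$maps,
                                      config$aln_params)$table))
    cnv <- stage("call-cnv", tryCatch(
      call_cnv(tab, nm, reference$maps$chrom_lengths_bp, m = config$cnv_m),
      error = function(e) { warning(conditionMessage(e)); NULL }))
    if (length(unique(tab$source_label[tab$status == "aligned"])) > 1L)
      slices <- stage("call-cnv-slices", per_slice_cnv(
        tab, nm, reference$maps$chrom_lengths_bp, m = config$cnv_m))
  }

  calls <- svs$calls
  somatic <- NULL
  if (length(config$panels))
    somatic <- stage("filter-somatic",
                     filter_somatic(calls, config$panels, config$rules))
  if (!is.null(config$genes)) {
    genes <- config$genes
    if (is.character(genes)) genes <- read_bed(genes)
    calls <- stage("annotate", annotate_genes(calls, genes))
  }

  report <- structure(list(
    n_molecules = length(rmaps),
    alignment_status = c(table(tab$status)),
    aligned_per_round = asm$aligned_per_round,
    fold_coverage = fold_coverage,
    per_class = svs$per_class,
    calls = calls,
    cnv_segments = if (!is.null(cnv)) cnv$segments,
    slice_discordance = if (!is.null(slices)) slices$discordance,
    somatic = somatic,
    truth = truth, variant_truth = variant_truth,
    seed = config$seed), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, asm, cnv, config)
  report
}

pipeline_error_params <- function(config) {
  if (!is.null(config$sim))
    list(p_d = config$sim$digest_efficiency,
         false_cut_rate = config$sim$false_cut_rate,
         sizing_cv = config$sim$sizing_cv)
  else list(p_d = 0.8, false_cut_rate = 5,
            sizing_cv = config$aln_params$sizing_cv)
}

write_report <- function(report, asm, cnv, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_alignment_table(asm$alignment$table, p("alignments.tsv"))
  cons <- Filter(function(cm) attr(cm, "status") == "assembled",
                 asm$consensus)
  if (length(cons)) write_consensus_maps(cons, p("consensus.maps.tsv"))
  if (nrow(report$calls)) write_osa(report$calls, p("osa"))
  if (!is.null(cnv)) write_cnv(cnv, p("cnv"))
  summary <- report[c("n_molecules", "fold_coverage", "per_class",
                      "aligned_per_round", "seed")]
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}

#' Write consensus maps in the map TSV dialect with support annotations
#'
#' @param consensus_list Named list of consensus maps.
#' @param path Output path.
#' @export
write_consensus_maps <- function(consensus_list, path) {
  lines <- MAP_TSV_HEADER
  for (cm in consensus_list) {
    sup <- attr(cm, "support")
    if (!is.null(sup))
      lines <- c(lines, sprintf("#support=%s %s", cm$map_id,
                                paste(sprintf("%d/%d", sup$concordant,
                                              sup$spanning), collapse = ",")))
    lines <- c(lines, paste(cm$map_id, cm$chrom %||% ".",
                            length(cm$fragments),
                            paste(sprintf("%.3f", cm$fragments),
                                  collapse = ","),
                            cm$origin, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== rmapforge pipeline report ==\n")
  cat(sprintf("molecules: %d; fold coverage (aligned mass / genome): %.2f\n",
              x$n_molecules, x$fold_coverage))
  cat("alignment:", paste(names(x$alignment_status), x$alignment_status,
                          collapse = ", ", sep = "="), "\n")
  cat("aligned per assembly round:", paste(x$aligned_per_round,
                                           collapse = " "), "\n")
  cat("OSA calls:", paste(names(x$per_class), x$per_class, collapse = ", ",
                          sep = "="), "\n")
  if (!is.null(x$cnv_segments)) {
    cat("copy-number segments:\n")
    print(x$cnv_segments, row.names = FALSE)
  }
  if (!is.null(x$slice_discordance))
    cat(sprintf("slice-discordant intervals: %d\n",
                nrow(x$slice_discordance)))
  if (!is.null(x$somatic))
    cat(sprintf("somatic candidates: %d of %d calls\n",
                nrow(x$somatic$candidates),
                nrow(x$somatic$candidates) + nrow(x$somatic$removed)))
  invisible(x)
}
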
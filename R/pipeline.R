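#' Default pipeline run configuration
#'
#' All knobs of the end-to-end pipeline in one validated list. Defaults
#' describe the full-scale replicate-well design (188 wells, 50,000 cells
#' per well, 130 nt reads, 0.1% per-base error, 10x coverage); analyses at
#' desk scale override `richness`, `cells_per_well` and `n_wells`.
#'
#' @param ... Named overrides of the defaults.
#' @return A `"run_config"` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_wells = 188L,
    cells_per_well = 50000L,
    read_length = 130L,
    error_rate = 0.001,
    coverage = 10,
    amplification_cv = 0.3,
    richness = 10000L,
    cell_type = "naive-like",
    mixing_shape = NULL,     # NULL = cell-type preset
    mixing_scale = 1,
    shm_rate = NULL,
    contamination = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is_count(cfg$n_wells) || !is_count(cfg$cells_per_well) ||
      !is_count(cfg$read_length) || !is_count(cfg$richness))
    stop("n_wells, cells_per_well, read_length and richness must be ",
         "positive integers", call. = FALSE)
  stop_if_not_scalar_prob(cfg$error_rate, "error_rate", allow_one = FALSE)
  if (cfg$coverage < 1) stop("coverage must be >= 1", call. = FALSE)
  if (cfg$amplification_cv < 0)
    stop("amplification_cv must be nonnegative", call. = FALSE)
  if (!cfg$cell_type %in% c("naive-like", "memory-like"))
    stop("cell_type must be naive-like or memory-like", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Simulate a replicate-well experiment to files
#'
#' Runs the synthetic generator under `config` and writes the well read
#' table (TSV), the ground-truth sidecar (JSON) and the germline reference
#' (FASTA) into `outdir`. Deterministic under `config$seed`.
#'
#' @param config A `"run_config"` (see [default_run_config()]).
#' @param outdir Output directory (created if needed).
#' @param reference Optional germline reference; defaults to the bundled
#'   synthetic one.
#' @return Invisibly, named paths of the written files.
#' @export
run_simulate <- function(config = default_run_config(), outdir,
                         reference = synthetic_germline_reference()) {
  config <- validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_well_experiment(
    reference, config$richness, config$cell_type,
    n_wells = config$n_wells, cells_per_well = config$cells_per_well,
    coverage = config$coverage, error_rate = config$error_rate,
    amplification_cv = config$amplification_cv,
    read_length = config$read_length,
    mixing_shape = config$mixing_shape,
    mixing_scale = config$mixing_scale,
    shm_rate = config$shm_rate, contamination = config$contamination,
    seed = config$seed
  )
  paths <- c(reads = file.path(outdir, "reads.tsv"),
             truth = file.path(outdir, "truth.json"),
             reference = file.path(outdir, "germline.fasta"))
  write_well_reads(truth$reads, paths[["reads"]])
  write_truth_json(truth, paths[["truth"]])
  write_germline_fasta(reference, paths[["reference"]])
  invisible(paths)
}

#' Run the analysis pipeline on a well read table
#'
#' Orchestrates collapse, occupancy, diversity fitting, annotation and the
#' descriptive statistics, writing every stage's output to `outdir`:
#' `clones.tsv`, `spectrum.tsv`, `diversity.json`, `annotation.tsv`,
#' `mutations.tsv`, `v_usage.tsv`, `cdr3_lengths.tsv`,
#' `shm_by_occupancy.tsv` and `run_log.txt`. Stage failures abort with the
#' stage name.
#'
#' @param reads_path Well read table TSV (see [write_well_reads()]).
#' @param reference_path Germline reference FASTA.
#' @param outdir Output directory.
#' @param fit_diversity_model Set `FALSE` to skip the likelihood fit (for
#'   very small runs).
#' @return Invisibly, a list with the in-memory stage results
#'   (`clones`, `spectrum`, `fit`, `annotation`, `descriptives`).
#' @export
run_analyze <- function(reads_path, reference_path, outdir,
                        fit_diversity_model = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  reads <- stage("read-input", read_well_reads(reads_path))
  reference <- stage("read-reference", read_germline_fasta(reference_path))
  clones <- stage("collapse", collapse_errors(reads))
  write_clone_table(clones, file.path(outdir, "clones.tsv"))
  spectrum <- stage("spectrum", occupancy_spectrum(clones))
  write_occupancy_spectrum(spectrum, file.path(outdir, "spectrum.tsv"))
  fit <- NULL
  if (fit_diversity_model) {
    fit <- stage("diversity", fit_diversity(spectrum))
    write_diversity_json(fit, file.path(outdir, "diversity.json"))
  }
  ann <- stage("annotation", annotate_clones(clones, reference))
  write_airr_tsv(ann, file.path(outdir, "annotation.tsv"),
                 file.path(outdir, "mutations.tsv"))
  desc <- stage("descriptives", {
    usage <- v_usage(ann$clones, reference)
    cdr3 <- cdr3_length_distribution(ann$clones)
    shm_occ <- shm_by_occupancy(ann$clones)
    write_tsv_plain(usage$gene, file.path(outdir, "v_usage.tsv"))
    write_tsv_plain(cdr3$histogram, file.path(outdir, "cdr3_lengths.tsv"))
    write_tsv_plain(as.data.frame(shm_occ),
                    file.path(outdir, "shm_by_occupancy.tsv"))
    list(v_usage = usage, cdr3 = cdr3, shm_by_occupancy = shm_occ)
  })
  writeLines(c(
    sprintf("repwell %s", as.character(utils::packageVersion("repwell"))),
    sprintf("R %s", R.version.string),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("reads %s", reads_path),
    sprintf("reference %s", reference_path),
    sprintf("n_wells %d", attr(reads, "n_wells")),
    sprintf("clones %d", nrow(clones)),
    if (!is.null(fit)) sprintf("richness %.0f clonality %.4f",
                               fit$richness, fit$clonality) else
      "diversity skipped"
  ), file.path(outdir, "run_log.txt"))
  invisible(list(clones = clones, spectrum = spectrum, fit = fit,
                 annotation = ann, descriptives = desc))
}
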
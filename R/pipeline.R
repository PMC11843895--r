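#' Build and validate a pipeline configuration
#'
#' One object carries every knob of the end-to-end run:
#' PQS scan -> read simulation (or a supplied call table) -> pileup ->
#' accuracy track -> differential strand report. The validated
#' configuration is echoed into the run manifest of every output
#' directory.
#'
#' @param amplicon_path FASTA path of the amplicon (default: the packaged
#'   752-nt promoter amplicon).
#' @param out_dir Output directory (created if missing).
#' @param numbering_offset Reported number of the first CpG site.
#' @param g4_window,g4_threshold G4Hunter window and score cutoff.
#' @param call_threshold Modification-call confidence cutoff.
#' @param region Either `"pqs"` (label sites by PQS-interval overlap) or a
#'   length-2 vector of reported site numbers bounding the primary PQS
#'   region (default `c(47, 72)`).
#' @param preset Simulation preset name (see [preset_truth()]); ignored
#'   when `calls_path` is given.
#' @param calls_path Optional per-read call TSV to analyze instead of
#'   simulating.
#' @param n_reads Reads per strand for the simulator.
#' @param seed Integer seed for the simulator.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(amplicon_path = system.file(
                              "extdata", "mgmt752.fa",
                              package = "quadmeth"),
                            out_dir = "quadmeth_run",
                            numbering_offset = 3L,
                            g4_window = 25L, g4_threshold = 1.2,
                            call_threshold = 0.65,
                            region = c(47L, 72L),
                            preset = "dnmt3a", calls_path = NULL,
                            n_reads = 500L, seed = 1L) {
  cfg <- list(amplicon_path = amplicon_path, out_dir = out_dir,
              numbering_offset = as.integer(numbering_offset),
              g4_window = as.integer(g4_window),
              g4_threshold = g4_threshold,
              call_threshold = call_threshold, region = region,
              preset = preset, calls_path = calls_path,
              n_reads = as.integer(n_reads), seed = as.integer(seed))
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param path JSON file with any subset of the configuration fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  if (!file.exists(cfg$amplicon_path))
    stop("amplicon file not found: ", cfg$amplicon_path, call. = FALSE)
  if (!is.null(cfg$calls_path) && !file.exists(cfg$calls_path))
    stop("call table not found: ", cfg$calls_path, call. = FALSE)
  if (cfg$g4_threshold <= 0) stop("g4_threshold must be > 0",
                                  call. = FALSE)
  if (cfg$call_threshold <= 1/3 || cfg$call_threshold > 1)
    stop("call_threshold must be in (1/3, 1]", call. = FALSE)
  region_ok <- identical(cfg$region, "pqs") ||
    (is.numeric(cfg$region) && length(cfg$region) == 2L &&
       cfg$region[1] <= cfg$region[2])
  if (!region_ok)
    stop("region must be 'pqs' or a length-2 site-number range",
         call. = FALSE)
  if (cfg$n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: load amplicon -> CpG index -> G4Hunter track and PQS
#' intervals -> simulate reads (or read a call table) -> pileup ->
#' accuracy track -> differential strand report. All artifacts are written
#' into `cfg$out_dir`:
#' `pqs.bed`, `g4hunter.bedgraph`, `calls.tsv`, `pileup.bedmethyl.tsv`,
#' `accuracy.tsv`, `report.tsv`, `report.txt` and `manifest.json` (full
#' configuration echo, its MD5 hash, seed and package version). A rerun
#' with an identical configuration reproduces the outputs byte-identically.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage logging to stderr.
#' @return Invisibly, a named list of output paths plus the in-memory
#'   `report`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_config(cfg)
  t0 <- Sys.time()
  log_stage <- function(...) if (!quiet)
    message(sprintf("[quadmeth %6.2fs] ",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            ...)
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  amp <- stage("load amplicon",
               load_fasta(cfg$amplicon_path,
                          numbering_offset = cfg$numbering_offset))
  idx <- stage("index CpG sites", find_cpg_sites(amp))
  track <- stage("G4Hunter scan", g4hunter_scores(amp, cfg$g4_window))
  intervals <- stage("call PQS", call_pqs(track, cfg$g4_threshold))
  pqs_labels <- stage("label CpG sites", pqs_cpg_overlap(intervals, idx))
  calls <- if (!is.null(cfg$calls_path)) {
    stage("read call table", read_call_table(cfg$calls_path))
  } else {
    stage(sprintf("simulate reads (preset '%s', %d/strand, seed %d)",
                  cfg$preset, cfg$n_reads, cfg$seed), {
      pre <- preset_truth(cfg$preset)
      simulate_reads(amp, idx, pqs_labels, pre$truth, pre$noise,
                     n_reads_per_strand = cfg$n_reads, seed = cfg$seed)
    })
  }
  pu <- stage("pileup", pileup(calls, idx, threshold = cfg$call_threshold))
  acc <- stage("accuracy track", accuracy_track(calls, idx))
  report <- stage("differential report", {
    if (identical(cfg$region, "pqs")) {
      differential_report(pu, site_labels = pqs_labels,
                          site_positions = idx$positions)
    } else {
      differential_report(pu, cpg_index = idx,
                          region_sites = cfg$region)
    }
  })
  paths <- list(
    pqs_bed = file.path(cfg$out_dir, "pqs.bed"),
    bedgraph = file.path(cfg$out_dir, "g4hunter.bedgraph"),
    calls = file.path(cfg$out_dir, "calls.tsv"),
    bedmethyl = file.path(cfg$out_dir, "pileup.bedmethyl.tsv"),
    accuracy = file.path(cfg$out_dir, "accuracy.tsv"),
    report_tsv = file.path(cfg$out_dir, "report.tsv"),
    report_txt = file.path(cfg$out_dir, "report.txt"),
    manifest = file.path(cfg$out_dir, "manifest.json"))
  stage("write artifacts", {
    write_bed(intervals, paths$pqs_bed, chrom = amp$id)
    write_bedgraph(track, paths$bedgraph)
    write_call_table(calls, paths$calls)
    write_bedmethyl(pu, paths$bedmethyl, chrom = amp$id)
    data.table::fwrite(acc, paths$accuracy, sep = "\t", quote = FALSE)
    write_report_tsv(report, paths$report_tsv)
    writeLines(utils::capture.output(print(report)), paths$report_txt)
  })
  stage("write manifest", {
    cfg_plain <- unclass(cfg)
    cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(
      package = "quadmeth",
      version = as.character(utils::packageVersion("quadmeth")),
      config = cfg_plain,
      config_md5 = unname(tools::md5sum(tmp)),
      seed = cfg$seed)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  })
  log_stage("done")
  invisible(c(paths, list(report = report)))
}
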
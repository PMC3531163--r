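## Subcommand front-end: simulate, refine, orf-audit, evaluate, report.
## run_pipeline() is the programmatic entry point; inst/scripts/gmrefine is
## a thin Rscript wrapper around it.

.parse_args <- function(argv) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[[i + 1L]], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- c(opts[[key]], argv[[i + 1L]])
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(opts = opts, positional = positional)
}

.manifest <- function(outdir, seed, inputs, counts) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    tool = "gmrefine",
    version = as.character(utils::packageVersion("gmrefine")),
    seed = seed,
    input_digests = digests,
    event_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (write a synthetic benchmark to `--outdir`),
#' `refine` (`--gtf --fasta --coverage sample:strand:path ... --junctions
#' --out-gtf --out-events`), `orf-audit` (`--gtf --fasta --events --out`),
#' `evaluate` (`--gtf --fasta --out`), and `report` (`--gtf --events
#' --coverage ... --junctions --out`, emitting the summary accounting and,
#' when the events came from a simulated benchmark with a ledger
#' (`--ledger`), the planted-error recovery rate). Returns an exit status
#' instead of quitting so it can be driven programmatically; the Rscript
#' wrapper turns it into the process exit code.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status: 0 success, 1 stage failure, 2 usage error.
#' @export
run_pipeline <- function(argv) {
  if (!length(argv)) {
    message("usage: gmrefine <simulate|refine|orf-audit|evaluate|report> ...")
    return(2L)
  }
  cmd <- argv[[1L]]
  parsed <- .parse_args(argv[-1L])
  opts <- parsed$opts
  need <- function(keys) {
    miss <- setdiff(keys, names(opts))
    if (length(miss)) {
      message("missing required option(s): ",
              paste0("--", miss, collapse = " "))
      TRUE
    } else FALSE
  }
  run <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message(cmd, " failed: ", conditionMessage(e))
      1L
    })
  }
  seed <- as.integer(opts$seed %||% 1L)

  if (cmd == "simulate") {
    if (need("outdir")) return(2L)
    return(run(.cmd_simulate(opts$outdir, seed)))
  }
  if (cmd == "refine") {
    if (need(c("gtf", "fasta", "coverage", "junctions", "out-gtf",
               "out-events"))) return(2L)
    return(run(.cmd_refine(opts)))
  }
  if (cmd == "orf-audit") {
    if (need(c("gtf", "events", "out"))) return(2L)
    return(run(.cmd_orf_audit(opts)))
  }
  if (cmd == "evaluate") {
    if (need(c("gtf", "fasta", "out"))) return(2L)
    return(run(.cmd_evaluate(opts)))
  }
  if (cmd == "report") {
    if (need(c("gtf", "events", "coverage", "junctions", "out")))
      return(2L)
    return(run(.cmd_report(opts)))
  }
  message("unknown subcommand: ", cmd)
  2L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cmd_simulate <- function(outdir, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(seed = seed)
  ds <- simulate_dataset(cfg)
  write_fasta(ds$genome, file.path(outdir, "genome.fa"))
  write_gtf(ds$truth, file.path(outdir, "truth.gtf"))
  write_gtf(ds$models, file.path(outdir, "annotation.gtf"))
  for (tr in ds$evidence$coverage)
    write_bedgraph(tr$depth, file.path(outdir,
      sprintf("coverage_%s_%s.bedgraph", tr$sample_id,
              if (tr$strand == "+") "plus" else "minus")))
  write_junction_tsv(ds$evidence$junctions,
                     file.path(outdir, "junctions.tsv"))
  write_bedgraph(ds$conservation, file.path(outdir, "conservation.bedgraph"))
  utils::write.table(ds$ledger, file.path(outdir, "plant_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("simulate: %d transcripts, %d plants",
                  length(ds$truth), nrow(ds$ledger)))
  .manifest(outdir, seed, character(0),
            list(transcripts = length(ds$truth), plants = nrow(ds$ledger)))
}

.parse_coverage_args <- function(specs, chrom_lengths) {
  lapply(specs, function(sp) {
    parts <- strsplit(sp, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("coverage spec must be sample:strand:path, got ", sp)
    load_bedgraph(parts[3L], parts[1L], parts[2L], chrom_lengths)
  })
}

.cmd_refine <- function(opts) {
  genome <- read_fasta(opts$fasta)
  models <- read_gtf(opts$gtf)
  coverage <- .parse_coverage_args(opts$coverage, chrom_lengths(genome))
  junctions <- read_junction_tsv(opts$junctions)
  config <- refinement_config()
  res <- refine(models, list(coverage = coverage, junctions = junctions,
                             genome = genome), config)
  write_gtf(res$models, opts[["out-gtf"]])
  write_events_tsv(res$events, opts[["out-events"]])
  counts <- as.list(table(res$events$event_type))
  message("refine: ", nrow(res$events), " event(s)")
  .manifest(dirname(opts[["out-events"]]),
            as.integer(opts$seed %||% 1L),
            c(opts$fasta, opts$gtf, opts$junctions), counts)
}

.cmd_orf_audit <- function(opts) {
  models <- read_gtf(opts$gtf)
  events <- read_events_tsv(opts$events)
  audit <- orf_audit(models, events)
  utils::write.table(audit, opts$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("orf-audit: ", sum(audit$frameshift), " frameshift event(s)")
}

.cmd_evaluate <- function(opts) {
  genome <- read_fasta(opts$fasta)
  models <- read_gtf(opts$gtf)
  pfm <- splice_pfm(models, genome)
  hex <- hexamer_end_profile(models, genome)
  out <- list(
    donor_ic = pfm$donor$ic, acceptor_ic = pfm$acceptor$ic,
    donor_n = pfm$donor$n, acceptor_n = pfm$acceptor$n,
    polya_peak_frequency = max(hex$profile$frequency),
    polya_control_peak_frequency = max(hex$control$frequency))
  jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("evaluate: ", pfm$donor$n, " donor site(s)")
}

.cmd_report <- function(opts) {
  models <- read_gtf(opts$gtf)
  events <- read_events_tsv(opts$events)
  chroms <- NULL
  if (!is.null(opts$fasta)) {
    chroms <- chrom_lengths(read_fasta(opts$fasta))
  } else {
    # infer chromosome extents from the models plus slack
    sp <- model_spans(models)
    chroms <- tapply(sp$end + 10000L, sp$chrom, max)
  }
  coverage <- .parse_coverage_args(opts$coverage, chroms)
  junctions <- read_junction_tsv(opts$junctions)
  rep <- summary_report(models, list(coverage = coverage,
                                     junctions = junctions), events)
  out <- list(coverage_table = rep$coverage_table,
              revision_table = rep$revision_table,
              n_new_transcripts = rep$n_new_transcripts)
  if (!is.null(opts$ledger)) {
    ledger <- utils::read.delim(opts$ledger, stringsAsFactors = FALSE)
    revised <- if (!is.null(opts[["revised-gtf"]]))
      read_gtf(opts[["revised-gtf"]], provenance = "revised")
    else gene_model_set(list(), provenance = "revised")
    res <- structure(list(events = events, models = revised),
                     class = "gm_refinement")
    rec <- recovery_report(ledger, res)
    out$recovery_rate_percent <- summary_percentage(
      sum(rec$table$recovered[rec$table$satisfiable]),
      max(sum(rec$table$satisfiable), 1L))
    out$decoys_reported <- rec$decoys_reported
    out$off_ledger_events <- rec$off_ledger_events
  }
  jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("report: ", rep$revision_table$events[5L], " event(s) total")
}
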
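# End-to-end orchestration: simulate -> call -> remodel -> classify ->
# profile -> motifs, with plain-file stage handoffs so any stage is
# independently re-runnable, plus a thin command-line front end.

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (YAML-style scalars only); `#` starts a
#' comment. Values are auto-typed to numeric where possible.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Split multi-replicate tracks into per-replicate single-column tracks
#'
#' Used to call nucleosomes on each replicate alone, which supplies the
#' N-per-group observations for the 150-bp-block t-tests.
#'
#' @param tracks named list of `probe_track`.
#' @return list (one element per replicate) of per-chromosome track lists.
#' @export
split_replicate_tracks <- function(tracks) {
  n_rep <- attr(tracks[[1]], "replicate_count")
  lapply(seq_len(n_rep), function(r)
    lapply(tracks, function(tr)
      probe_track(tr$chrom[1], tr$position,
                  probe_values(tr)[, r, drop = FALSE])))
}

#' Run the full pipeline on a simulated dataset
#'
#' Stages, in order: simulate, nucleosome calling (stringency sweep plus
#' the working level), remodeling partition, expression classification,
#' TSS profiles per class, motif statistics on the truth promoter classes.
#' All stage outputs are plain files under `out_dir`; the manifest lists
#' every artifact with its md5 checksum, so a rerun with the same config
#' and seed is verifiably bit-identical.
#'
#' @param config a [simulation_config()] (holds the seed).
#' @param out_dir output directory.
#' @param working_level stringency level used for downstream stages
#'   (default -1.0, the level the source analysis settled on).
#' @param levels stringency sweep levels.
#' @return data.frame manifest (`stage`, `path`, `md5`), invisibly the
#'   in-memory stage results as attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir,
                         working_level = -1.0,
                         levels = stringency_levels()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)

  ## simulate
  sim <- simulate_dataset(config)
  for (p in write_dataset(sim, file.path(out_dir, "data")))
    note("simulate", p)

  ## call
  sweep <- stringency_sweep(sim$tracks$control, sim$tracks$treated,
                            levels = levels,
                            probe_pitch = config$probe_pitch)
  p <- file.path(out_dir, "sweep_summary.tsv")
  utils::write.table(sweep$summary, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("call", p)
  reg_c <- call_regions_all(sim$tracks$control, working_level,
                            probe_pitch = config$probe_pitch,
                            condition = "control")
  reg_t <- call_regions_all(sim$tracks$treated, working_level,
                            probe_pitch = config$probe_pitch,
                            condition = "treated")
  for (nm in c("control", "treated")) {
    reg <- if (nm == "control") reg_c else reg_t
    p <- file.path(out_dir, paste0("regions_", nm, ".tsv"))
    write_regions_tsv(reg, p); note("call", p)
    p <- file.path(out_dir, paste0("regions_", nm, ".bed"))
    write_regions_bed(reg, p); note("call", p)
  }

  ## remodel
  part <- compare_conditions(merge_regions(reg_c), merge_regions(reg_t))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                           paste0("chr", seq_len(config$n_chromosomes)))
  remod <- genome_remodeling_summary(part, sizes)
  p <- file.path(out_dir, "remodeling_summary.tsv")
  utils::write.table(cbind(part$totals, remod[, -1]), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("remodel", p)
  for (nm in c("depleted", "enriched", "common")) {
    p <- file.path(out_dir, paste0(nm, ".bed"))
    write_regions_bed(part[[nm]], p); note("remodel", p)
  }

  ## classify
  groups <- classify_genes(sim$expression)
  p <- file.path(out_dir, "gene_classes.tsv")
  utils::write.table(groups, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("classify", p)

  ## profile
  prof_rows <- list()
  for (cl in intersect(c("SI", "SR", "CON", "SIL"), unique(groups$class))) {
    gsel <- sim$genes[sim$genes$gene_id %in%
                        groups$gene_id[groups$class == cl], ]
    if (nrow(gsel) == 0) next
    rp <- remodeling_percent_profile(gsel, reg_c, reg_t)
    rp$class <- cl
    prof_rows[[cl]] <- rp
  }
  p <- file.path(out_dir, "remodeling_profiles.tsv")
  utils::write.table(do.call(rbind, prof_rows), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("profile", p)

  ## motifs
  stats_tab <- region_class_motif_stats(sim$promoters,
                                        sim$promoter_classes,
                                        c("TTGAC", "TGACG/C"))
  p <- file.path(out_dir, "motif_stats.tsv")
  utils::write.table(stats_tab, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("motifs", p)

  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  attr(manifest, "results") <- list(sim = sim, sweep = sweep,
                                    partition = part, summary = remod,
                                    groups = groups,
                                    motif_stats = stats_tab)
  manifest
}

#' Command-line entry point
#'
#' Dispatches `nucdyn <command> [options]` with commands `simulate`,
#' `callnuc`, `remodel`, `classify`, `run-all`, `--version`. Installed as
#' `inst/cli/nucdyn.R`; invoke as
#' `Rscript -e 'nucdyn::nucdyn_cli()' -- <command> ...` or through the
#' script.
#'
#' @param args command-line arguments (default: `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
nucdyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: nucdyn <simulate|callnuc|remodel|classify|run-all>",
        "[--config FILE] [--seed N] [--out DIR]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat("nucdyn", as.character(utils::packageVersion("nucdyn")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- list(seed = 1, out = ".", config = NULL,
              control = NULL, treated = NULL, level = -1.0, expr = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg_args <- list(seed = as.integer(opt$seed))
  if (!is.null(opt$config)) {
    file_cfg <- read_config(opt$config)
    known <- intersect(names(file_cfg), names(formals(simulation_config)))
    cfg_args <- utils::modifyList(cfg_args, file_cfg[known])
  }
  cfg <- do.call(simulation_config, cfg_args)
  status <- 0L
  if (cmd == "simulate") {
    write_dataset(simulate_dataset(cfg), opt$out)
  } else if (cmd == "callnuc") {
    if (is.null(opt$control) || is.null(opt$treated))
      stop("callnuc requires --control and --treated probe-track files")
    tc <- read_probe_track(opt$control)
    tt <- read_probe_track(opt$treated)
    sw <- stringency_sweep(tc, tt)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sw$summary, file.path(opt$out, "sweep_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_tsv(sw$regions, file.path(opt$out, "regions.tsv"))
  } else if (cmd == "remodel") {
    if (is.null(opt$control) || is.null(opt$treated))
      stop("remodel requires --control and --treated region BED files")
    part <- compare_conditions(merge_regions(read_regions_bed(opt$control)),
                               merge_regions(read_regions_bed(opt$treated)))
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(part$totals, file.path(opt$out, "totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("depleted", "enriched", "common"))
      write_regions_bed(part[[nm]], file.path(opt$out, paste0(nm, ".bed")))
  } else if (cmd == "classify") {
    if (is.null(opt$expr)) stop("classify requires --expr")
    groups <- classify_genes(read_expression(opt$expr))
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(groups, file.path(opt$out, "gene_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cmd == "run-all") {
    run_pipeline(cfg, opt$out)
  } else {
    stop("unknown command: ", cmd)
  }
  invisible(status)
}
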
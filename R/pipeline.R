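#' Pipeline run configuration
#'
#' Collects every knob of a simulate -> demux -> usage -> k-mer -> energy
#' run. The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]), and every random stage
#' derives its own seed from `seed`.
#'
#' @param n_minigenes Library size.
#' @param depth Mean Poisson sequencing depth per minigene and condition.
#' @param lambda_wt,lambda_k700e Mutant -1-mismatch tolerance per
#'   condition (WT is 1 by definition; `lambda_k700e = 1` switches the
#'   condition effect off).
#' @param beta_bp,beta_ppt,sa2_bonus,novel_penalty Splice model weights,
#'   see [splice_model_params()].
#' @param seed Master seed.
#' @param sequencing Emit FASTQ and demultiplex (`TRUE`), or analyse the
#'   simulated transcript tables directly (`FALSE`, the default; with
#'   error-free sequencing both routes agree exactly).
#' @param read_len,error_rate Read emission settings when `sequencing`.
#' @param max_mismatch,min_flank Demultiplexer settings.
#' @param min_reads Minimum-representation filter (default 5).
#' @param region Degenerate region for the k-mer contrast (default
#'   `"25A"`, the branch-point-bearing upstream region).
#' @param kmer_k Word length (default 6).
#' @param pseudocount Odds-ratio pseudocount (default 0.5).
#' @param or_threshold Enhancer odds-ratio cutoff (default 1.5).
#' @param out_dir Output directory for artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_minigenes = 2000L, depth = 50,
                       lambda_wt = 1, lambda_k700e = 0.4,
                       beta_bp = 1, beta_ppt = 2, sa2_bonus = -0.5,
                       novel_penalty = -2,
                       seed = 1L, sequencing = FALSE,
                       read_len = 50L, error_rate = 0,
                       max_mismatch = 1L, min_flank = 15L,
                       min_reads = 5L, region = "25A", kmer_k = 6L,
                       pseudocount = 0.5, or_threshold = 1.5,
                       out_dir = tempfile("bpmpra_run_")) {
  cfg <- list(
    n_minigenes = as.integer(n_minigenes), depth = depth,
    lambda_wt = lambda_wt, lambda_k700e = lambda_k700e,
    beta_bp = beta_bp, beta_ppt = beta_ppt, sa2_bonus = sa2_bonus,
    novel_penalty = novel_penalty,
    seed = as.integer(seed), sequencing = isTRUE(sequencing),
    read_len = as.integer(read_len), error_rate = error_rate,
    max_mismatch = as.integer(max_mismatch), min_flank = as.integer(min_flank),
    min_reads = as.integer(min_reads), region = region,
    kmer_k = as.integer(kmer_k), pseudocount = pseudocount,
    or_threshold = or_threshold, out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' Demonstration configuration
#'
#' The packaged desk-scale study: a 20,000-minigene library at mean depth
#' 50 per condition, with the mutant -1-mismatch tolerance at 0.4.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("bpmpra_demo_"), ...) {
  run_config(n_minigenes = 20000L, depth = 50, lambda_k700e = 0.4,
             seed = seed, out_dir = out_dir, ...)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

cfg_model_params <- function(cfg, condition) {
  splice_model_params(
    beta_bp = cfg$beta_bp, beta_ppt = cfg$beta_ppt,
    sa2_bonus = cfg$sa2_bonus, novel_penalty = cfg$novel_penalty,
    lambda_minus1 = if (condition == "K700E") cfg$lambda_k700e else cfg$lambda_wt,
    seed = cfg$seed
  )
}

#' Run the full analysis pipeline
#'
#' Generates the library, simulates both conditions (optionally through
#' FASTQ emission and demultiplexing), applies the minimum-representation
#' filter, and computes usage fractions, the SA1 partition, per-6-mer odds
#' ratios with the condition contrast, the enhancer ranking and motif
#' census, the novel-acceptor context matrix, and the branch point energy
#' comparison between shared and K700E-only SA1 minigenes. All artifacts
#' are written to `cfg$out_dir` together with a manifest (file hashes,
#' seeds, timings) and a rendered markdown report.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`library`,
#'   `tables`, `usage`, `partition`, `kmer`, `enhancers`, `census`,
#'   `energy`, `novel_context`, `report_path`, `manifest`).
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_times <- list()
  tick <- function(name, t) {
    stage_times[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 3)
  }

  say("generating library of %d minigenes", cfg$n_minigenes)
  t <- Sys.time()
  lib <- generate_library(cfg$n_minigenes, scaffold_config(),
                          seed = derive_seed(cfg$seed, 1L))
  write_library(lib, file.path(cfg$out_dir, "library.tsv"))
  tick("library", t)

  tables <- list()
  for (cond in c("WT", "K700E")) {
    say("simulating condition %s", cond)
    t <- Sys.time()
    params <- cfg_model_params(cfg, cond)
    truth <- simulate_transcripts(lib, cond, params, depth = cfg$depth,
                                  seed = derive_seed(cfg$seed,
                                                     if (cond == "WT") 2L else 3L))
    if (cfg$sequencing) {
      fq <- emit_reads(truth, lib, cfg$out_dir, read_len = cfg$read_len,
                       error_rate = cfg$error_rate,
                       seed = derive_seed(cfg$seed,
                                          if (cond == "WT") 4L else 5L),
                       prefix = paste0("reads_", cond))
      dm <- build_transcript_table(fq$r1, fq$r2, lib, condition = cond,
                                   max_mismatch = cfg$max_mismatch,
                                   min_flank = cfg$min_flank)
      tables[[cond]] <- dm$records
      jsonlite::write_json(dm$report,
                           file.path(cfg$out_dir,
                                     paste0("demux_report_", cond, ".json")),
                           auto_unbox = TRUE, digits = NA)
    } else {
      tables[[cond]] <- truth
    }
    write.table(tables[[cond]],
                file.path(cfg$out_dir, paste0("transcripts_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tick(paste0("simulate_", cond), t)
  }

  say("filtering (min %d reads in both conditions)", cfg$min_reads)
  t <- Sys.time()
  filtered <- apply_filters(tables, min_reads = cfg$min_reads,
                            require_both = TRUE)
  usage <- usage_summary(filtered$WT, filtered$K700E)
  part <- partition_sa1(filtered$WT, filtered$K700E)
  # serialize named numeric vectors as JSON objects, not bare arrays
  usage_json <- usage
  for (cond in c("WT", "K700E")) {
    usage_json[[cond]]$transcript_fractions <-
      as.list(usage_json[[cond]]$transcript_fractions)
  }
  jsonlite::write_json(usage_json,
                       file.path(cfg$out_dir, "usage_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  part_json <- unclass(part)
  part_json$counts <- as.list(part_json$counts)
  part_json$percentages <- as.list(part_json$percentages)
  jsonlite::write_json(part_json,
                       file.path(cfg$out_dir, "sa1_partition.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("usage", t)

  say("k-mer odds ratios in region %s", cfg$region)
  t <- Sys.time()
  stats_wt <- kmer_or_stats(lib, filtered$WT, region = cfg$region,
                            condition = "WT", k = cfg$kmer_k,
                            pseudocount = cfg$pseudocount)
  stats_ke <- kmer_or_stats(lib, filtered$K700E, region = cfg$region,
                            condition = "K700E", k = cfg$kmer_k,
                            pseudocount = cfg$pseudocount)
  contrast <- delta_log2(stats_wt, stats_ke)
  write.table(contrast, file.path(cfg$out_dir, "kmer_delta_log2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enh <- top_enhancers(contrast, or_threshold = cfg$or_threshold,
                       by = "delta")
  census <- classification_census()
  jsonlite::write_json(list(census = census,
                            enhancer_share = as.list(enh$class_share),
                            n_enhancers = nrow(enh$table)),
                       file.path(cfg$out_dir, "motif_census.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("kmer", t)

  say("novel acceptor context and branch point energetics")
  t <- Sys.time()
  ctx <- novel_ss_context(rbind(filtered$WT, filtered$K700E), lib)
  write_pfm(ctx$pfm, file.path(cfg$out_dir, "novel_context_pfm.txt"))
  energy <- sa1_energy_comparison(lib, filtered$WT, filtered$K700E)
  if (!is.null(energy)) {
    jsonlite::write_json(unclass(energy),
                         file.path(cfg$out_dir, "energy_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tick("energy", t)

  manifest <- list(
    package = "bpmpra",
    config = unclass(cfg),
    stages = stage_times,
    files = as.list(tools::md5sum(list.files(cfg$out_dir, full.names = TRUE))),
    wall_time_s = round(as.numeric(Sys.time()) - as.numeric(t0), 3)
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- list(library = lib, tables = tables, filtered = filtered,
              usage = usage, partition = part, kmer = contrast,
              enhancers = enh, census = census, energy = energy,
              novel_context = ctx, manifest = manifest)
  res$report_path <- render_report(cfg$out_dir)
  invisible(res)
}

#' Predicted branch point energies behind shared vs K700E-only SA1 use
#'
#' Predicts the best branch point upstream of SA1 (single descriptive
#' energy model, WT mode) for every SA1-utilizing minigene, and compares
#' the energies of minigenes whose SA1 use is shared between conditions
#' against those used exclusively under K700E.
#'
#' @param lib The `bp_library`.
#' @param table_wt,table_k700e Filtered `bp_transcripts` tables.
#' @param params A [duplex_params()] (default: descriptive, lambda = 1).
#' @return An `energy_comparison` (see [compare_energies()]), with extra
#'   fields `delta_g_shared` and `delta_g_k700e_only`, or `NULL` when
#'   either set is empty.
#' @export
sa1_energy_comparison <- function(lib, table_wt, table_k700e,
                                  params = duplex_params()) {
  sa1 <- function(tab) unique(tab$minigene_id[tab$acceptor_class == "SA1"])
  w <- sa1(table_wt); k <- sa1(table_k700e)
  shared <- intersect(w, k)
  k_only <- setdiff(k, w)
  if (!length(shared) || !length(k_only)) return(NULL)
  dg_of <- function(ids) {
    idx <- match(ids, lib$id)
    bp <- bp_scan(lib$full_seq[idx], lib$sa1_pos[idx], params = params,
                  mode = "WT")
    ifelse(is.na(bp$delta_g), 0, bp$delta_g)
  }
  dg_shared <- dg_of(shared)
  dg_k_only <- dg_of(k_only)
  cmp <- compare_energies(dg_shared, dg_k_only,
                          labels = c("shared", "k700e_only"))
  cmp$delta_g_shared <- mean(dg_shared)
  cmp$delta_g_k700e_only <- mean(dg_k_only)
  cmp
}

#' Render the markdown summary report
#'
#' Deterministically renders `report.md` from the artifact files of a
#' [run_pipeline()] output directory; every number in the report is read
#' back from an artifact. Missing artifacts are listed and the remaining
#' sections rendered.
#'
#' @param dir Artifact directory.
#' @return The report path, invisibly.
#' @export
render_report <- function(dir) {
  path <- file.path(dir, "report.md")
  lines <- c("# Minigene branch point utilization report", "")
  missing <- character(0)
  grab <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      missing <<- c(missing, name)
      return(NULL)
    }
    jsonlite::read_json(p, simplifyVector = TRUE)
  }

  usage <- grab("usage_summary.json")
  if (!is.null(usage)) {
    lines <- c(lines, "## Acceptor usage", "",
               "| condition | SA1 | SA2 | NOVEL | minigene SA1 ratio |",
               "|---|---|---|---|---|")
    for (cond in c("WT", "K700E")) {
      u <- usage[[cond]]
      tf <- unlist(u$transcript_fractions)
      lines <- c(lines, sprintf("| %s | %.4f | %.4f | %.4f | %.4f |",
                                cond, tf[["SA1"]], tf[["SA2"]],
                                tf[["NOVEL"]], u$minigene_sa1_ratio))
    }
    fc <- usage$sa1_fold_change
    lines <- c(lines, "",
               sprintf("SA1 transcript-level fold change (K700E/WT): **%.2f**", fc))
    if (is.finite(fc) && abs(log2(fc)) < 0.25) {
      lines <- c(lines, "", "*No condition effect detected (fold change ~ 1).*")
    }
    lines <- c(lines, "")
  }

  part <- grab("sa1_partition.json")
  if (!is.null(part)) {
    pc <- unlist(part$percentages)
    lines <- c(lines, "## SA1-utilizing minigenes", "",
               sprintf("%d minigenes used SA1: %.1f%% shared, %.1f%% K700E-only, %.1f%% WT-only.",
                       part$n_total, pc[["shared"]], pc[["k700e_only"]],
                       pc[["wt_only"]]), "")
  }

  census <- grab("motif_census.json")
  if (!is.null(census)) {
    cs <- census$census
    lines <- c(lines, "## Branch point motif census (all 4096 6-mers)", "",
               "| class | n | % |", "|---|---|---|",
               sprintf("| %s | %d | %.1f |", cs$class, cs$n, cs$pct),
               "", sprintf("Total: %d 6-mers.", sum(cs$n)), "")
    es <- unlist(census$enhancer_share)
    if (!all(is.na(es))) {
      lines <- c(lines,
                 sprintf("Among the %d differential enhancers (OR > threshold, delta_log2 > 0): %s.",
                         census$n_enhancers,
                         paste(sprintf("%s %.1f%%", names(es), es),
                               collapse = ", ")), "")
    }
  }

  delta_path <- file.path(dir, "kmer_delta_log2.tsv")
  if (file.exists(delta_path)) {
    d <- read.delim(delta_path, stringsAsFactors = FALSE)
    d <- d[order(-d$delta_log2), ][1:10, ]
    lines <- c(lines, "## Top 10 6-mers by delta log2 OR (K700E - WT)", "",
               "| kmer | log2 OR WT | log2 OR K700E | delta |",
               "|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %.3f |", d$kmer, d$log2_or_wt,
                       d$log2_or_k700e, d$delta_log2), "")
  } else {
    missing <- c(missing, "kmer_delta_log2.tsv")
  }

  energy <- grab("energy_comparison.json")
  if (!is.null(energy)) {
    lines <- c(lines, "## U2-branch point duplex energies", "",
               sprintf("Mean predicted delta G: shared %.3f kcal/mol vs K700E-only %.3f kcal/mol (Wilcoxon p = %.3g); less stable set: %s.",
                       energy$delta_g_shared, energy$delta_g_k700e_only,
                       energy$p_value, energy$less_stable), "")
  }

  pfm_path <- file.path(dir, "novel_context_pfm.txt")
  if (file.exists(pfm_path)) {
    pfm <- as.matrix(read.table(pfm_path, row.names = 1))
    if (sum(pfm) == 0) {
      lines <- c(lines, "## Novel acceptors", "",
                 "No novel acceptors were observed.", "")
    } else {
      lines <- c(lines, "## Novel acceptors", "",
                 sprintf("Position frequency matrix over %d upstream 20-mers written to `novel_context_pfm.txt`.",
                         sum(pfm[, 1])), "")
    }
  }

  if (length(missing)) {
    lines <- c(lines, "## Missing artifacts", "",
               paste0("- ", missing), "")
  }
  writeLines(lines, path)
  invisible(path)
}
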
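#' Validate a pipeline run configuration
#'
#' Reads a YAML or JSON configuration (or takes a list directly) and
#' validates every field, reporting all problems at once rather than
#' stopping at the first. Recognized fields:
#'
#' * `catalog` (required): path to the signal-catalog TSV
#' * `out_dir` (required): output directory, created if absent
#' * `genotype_counts`, `reported_effects`: optional replication inputs
#' * `ld_table`, `annotations`: optional annotation inputs
#' * `annotate` (logical): request the annotation stage
#' * `suggestive_threshold`, `genome_wide_threshold`, `window_half_width`,
#'   `nos_fail_max`, `hwe_alpha`, `d_min`, `r2_min`, `continuity`,
#'   `keep_population_controls`, `seed`: thresholds and policies, all
#'   defaulting to the protocol values
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A validated `run_config` list; on any problem, an error of class
#'   `drmeta_config_error` whose message enumerates every issue.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(config_error(paste("config file not found:", config)))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop(config_error("config must be a file path or a list"))
  defaults <- list(genotype_counts = NULL, reported_effects = NULL,
                   ld_table = NULL, annotations = NULL, annotate = FALSE,
                   suggestive_threshold = 5e-5, genome_wide_threshold = 1e-7,
                   window_half_width = 100000, nos_fail_max = 6L,
                   hwe_alpha = 0.05, d_min = 0.8, r2_min = 0.8,
                   continuity = "haldane", keep_population_controls = FALSE,
                   seed = 1L)
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]

  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$catalog)) note("missing required field: catalog")
  else if (!file.exists(config$catalog))
    note(paste("catalog file not found:", config$catalog))
  if (is.null(config$out_dir)) note("missing required field: out_dir")
  for (f in c("genotype_counts", "reported_effects", "ld_table", "annotations"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      note(paste0(f, " file not found: ", config[[f]]))
  if (isTRUE(config$annotate) &&
      (is.null(config$ld_table) || is.null(config$annotations)))
    note("annotation requested but ld_table and/or annotations input is missing")
  num_in <- function(f, lo, hi, lo_ok = FALSE) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lo || v > hi || (!lo_ok && v == lo))
      note(sprintf("%s must be %s %s and <= %s (got %s)", f,
                   if (lo_ok) ">=" else ">", format(lo), format(hi),
                   paste(format(v), collapse = ",")))
  }
  num_in("suggestive_threshold", 0, 1)
  num_in("genome_wide_threshold", 0, 1)
  if (is.numeric(config$genome_wide_threshold) &&
      is.numeric(config$suggestive_threshold) &&
      length(config$genome_wide_threshold) == 1L &&
      length(config$suggestive_threshold) == 1L &&
      !is.na(config$genome_wide_threshold) &&
      !is.na(config$suggestive_threshold) &&
      config$genome_wide_threshold >= config$suggestive_threshold)
    note("genome_wide_threshold must be smaller than suggestive_threshold")
  if (!is.numeric(config$window_half_width) || length(config$window_half_width) != 1L ||
      is.na(config$window_half_width) || config$window_half_width < 0)
    note("half_width must be >= 0")
  num_in("hwe_alpha", 0, 1)
  num_in("d_min", 0, 1, lo_ok = TRUE)
  num_in("r2_min", 0, 1, lo_ok = TRUE)
  if (!is.numeric(config$nos_fail_max) || config$nos_fail_max < 0 ||
      config$nos_fail_max > 9)
    note("nos_fail_max must lie in 0..9")
  if (!config$continuity %in% c("haldane", "strict"))
    note("continuity must be 'haldane' or 'strict'")
  if (!is.numeric(config$seed) || length(config$seed) != 1L || is.na(config$seed))
    note("seed must be a single integer")
  if (length(errs) > 0L) stop(config_error(errs))
  config$seed <- as.integer(config$seed)
  class(config) <- c("run_config", "list")
  config
}

config_error <- function(msgs) {
  structure(class = c("drmeta_config_error", "error", "condition"),
            list(message = paste0("invalid configuration:\n",
                                  paste0("  - ", msgs, collapse = "\n")),
                 call = NULL))
}

pipe_log <- function(...) message("[drmeta] ", ...)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full evidence-synthesis pipeline
#'
#' Orchestrates curate -> overlap -> effects -> meta -> annotate and writes
#' deterministic reports to the configured output directory:
#'
#' * `catalog_summary.tsv`, `rejects.tsv` — curated signals and rejected rows
#' * `tier_counts.tsv` — per-phenotype-group counts at each significance tier
#' * `overlap_report.tsv`, `clusters.bed` — cross-study overlap per group
#' * `meta_table.tsv`, `meta_detail.json`, `sensitivity.tsv`,
#'   `funnel_<snp>.csv` — pooled results per SNP (when replication inputs
#'   are provided)
#' * `annotation_report.tsv`, `proxy_counts.tsv` — when annotation inputs
#'   are provided
#' * `manifest.json` — every threshold actually used, package version,
#'   seed, config hash and timestamp (the only non-deterministic field)
#'
#' Any stage failure aborts with the stage name in the error message.
#'
#' @param config A `run_config` from [validate_config()], a list, or a
#'   YAML/JSON path.
#' @return The output directory path, invisibly; stage results are also
#'   returned as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  pipe_log("stage curate: reading ", config$catalog)
  catalog <- stage("curate", read_signal_catalog(config$catalog))
  tier <- significance_tier(config$suggestive_threshold,
                            config$genome_wide_threshold)
  sig_all <- eligible_signals(catalog, config$keep_population_controls)
  stage("curate", {
    write_tsv(catalog$signals, file.path(out, "catalog_summary.tsv"))
    write_tsv(catalog$rejects, file.path(out, "rejects.tsv"))
    groups <- sort(unique(catalog$signals$phenotype_group))
    tiers <- do.call(rbind, lapply(groups, function(g) {
      sg <- catalog$signals[catalog$signals$phenotype_group == g, , drop = FALSE]
      data.frame(phenotype_group = g, n_signals = nrow(sg),
                 n_suggestive = nrow(filter_by_tier(sg, tier, "suggestive")),
                 n_genome_wide = nrow(filter_by_tier(sg, tier, "genome_wide")),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(tiers, file.path(out, "tier_counts.tsv"))
  })

  pipe_log("stage overlap: window +/- ", config$window_half_width, " bp")
  win <- window_spec(config$window_half_width)
  overlap <- stage("overlap", {
    groups <- sort(unique(sig_all$phenotype_group))
    reports <- list(); clusters_all <- list()
    for (g in groups) {
      sg <- sig_all[sig_all$phenotype_group == g, , drop = FALSE]
      cl <- c(find_identical(sg), find_proximal(sg, win))
      reports[[g]] <- overlap_report(cl, g)
      clusters_all <- c(clusters_all, cl)
    }
    rep_all <- if (length(reports) > 0L) do.call(rbind, reports)
               else overlap_report(list(), character(0))
    rownames(rep_all) <- NULL
    write_tsv(rep_all, file.path(out, "overlap_report.tsv"))
    write_clusters_bed(clusters_all, file.path(out, "clusters.bed"))
    rep_all
  })

  meta_results <- list(); sens_rows <- NULL
  have_repl <- !is.null(config$genotype_counts) || !is.null(config$reported_effects)
  if (have_repl) {
    pipe_log("stage effects+meta")
    rule <- quality_rule(config$nos_fail_max, config$hwe_alpha)
    est <- stage("effects", effect_estimates(
      counts = if (is.null(config$genotype_counts)) NULL
               else read_genotype_counts(config$genotype_counts),
      reported = if (is.null(config$reported_effects)) NULL
                 else read_reported_effects(config$reported_effects),
      rule = rule, correction = config$continuity))
    stage("meta", {
      for (snp in names(est)) {
        e <- est[[snp]]
        if (nrow(e) < 2L) {
          pipe_log("  ", snp, ": only ", nrow(e),
                   " replication record(s); skipped (needs >= 2)")
          next
        }
        res <- dersimonian_laird(e)
        meta_results[[snp]] <- res
        if (nrow(e) >= 3L) {
          sens <- leave_one_out(e)
          sens_rows <- rbind(sens_rows, do.call(rbind, lapply(sens, function(s)
            data.frame(snp = snp, omitted_study_id = s$omitted_study_id,
                       or_without = s$result_without$or_random,
                       p_without = s$result_without$p_summary,
                       significance_flipped = s$significance_flipped,
                       stringsAsFactors = FALSE))))
        }
        fd <- funnel_data(e, res)
        utils::write.csv(fd$points, file.path(out, paste0("funnel_", snp, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
      tab <- meta_table(meta_results)
      write_tsv(tab, file.path(out, "meta_table.tsv"))
      if (!is.null(sens_rows))
        write_tsv(sens_rows, file.path(out, "sensitivity.tsv"))
      detail <- lapply(meta_results, function(r)
        list(k = r$k, beta_random = r$beta_random, se_random = r$se_random,
             or = r$or_random, ci = r$ci_random, q = r$q_stat, tau2 = r$tau2,
             i2 = r$i2, p = r$p_summary,
             weights = as.list(stats::setNames(r$weights_random,
                                               r$estimates$study_id)),
             studies = r$estimates$study_id))
      jsonlite::write_json(detail, file.path(out, "meta_detail.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  annotation <- NULL
  if (isTRUE(config$annotate)) {
    pipe_log("stage annotate")
    annotation <- stage("annotate", {
      ld <- read_ld_table(config$ld_table)
      ann <- read_annotation_table(config$annotations)
      idx <- if (length(meta_results) > 0L) names(meta_results)
             else unique(sig_all$rsid)
      res <- annotate_indices(idx, ld, ann, config$d_min, config$r2_min)
      write_tsv(res$report, file.path(out, "annotation_report.tsv"))
      write_tsv(res$proxy_counts, file.path(out, "proxy_counts.tsv"))
      res
    })
  }

  cfg_plain <- unclass(config)
  cfg_file <- file.path(out, "config_used.json")
  jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  manifest <- list(
    package = "drmeta",
    version = as.character(utils::packageVersion("drmeta")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    thresholds = cfg_plain[c("suggestive_threshold", "genome_wide_threshold",
                             "window_half_width", "nos_fail_max", "hwe_alpha",
                             "d_min", "r2_min", "continuity")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log("run complete: ", out)
  res <- invisible(out)
  attr(res, "results") <- list(catalog = catalog, overlap = overlap,
                               meta = meta_results, annotation = annotation)
  res
}
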
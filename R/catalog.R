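#' Significance tiers for GWAS signals
#'
#' Thresholds used to tier reported association p-values. The genome-wide
#' gate defaults to 1e-7 and the suggestive gate to 5e-5; both are strict
#' ("<") comparisons. The conventional 5e-8 genome-wide threshold can be set
#' via `genome_wide`.
#'
#' @param suggestive Suggestive-significance threshold (default `5e-5`).
#' @param genome_wide Genome-wide-significance threshold (default `1e-7`).
#' @return An object of class `significance_tier`.
#' @examples
#' significance_tier()
#' significance_tier(genome_wide = 5e-8)
#' @export
significance_tier <- function(suggestive = 5e-5, genome_wide = 1e-7) {
  stopifnot(is.numeric(suggestive), is.numeric(genome_wide),
            length(suggestive) == 1L, length(genome_wide) == 1L,
            suggestive > 0, genome_wide > 0)
  if (genome_wide >= suggestive)
    stop("genome_wide threshold must be smaller than the suggestive threshold")
  structure(list(suggestive = suggestive, genome_wide = genome_wide),
            class = "significance_tier")
}

#' Column-mapping dialects for signal catalogs
#'
#' A dialect maps the canonical signal fields to the column names of a
#' particular TSV layout. `default_dialect()` matches the column names this
#' package writes; `gwas_catalog_dialect()` matches a GWAS-Catalog
#' association export.
#'
#' @return A named list mapping canonical field names to file column names.
#' @export
default_dialect <- function() {
  list(study_id = "study_id", rsid = "rsid", chrom = "chrom", pos = "pos",
       p_value = "p_value", effect_allele = "effect_allele",
       other_allele = "other_allele", odds_ratio = "odds_ratio",
       ci_lower = "ci_lower", ci_upper = "ci_upper",
       trait = "trait", phenotype_group = "phenotype_group",
       uses_population_controls = "uses_population_controls")
}

#' @rdname default_dialect
#' @export
gwas_catalog_dialect <- function() {
  list(study_id = "STUDY ACCESSION", rsid = "SNPS", chrom = "CHR_ID",
       pos = "CHR_POS", p_value = "P-VALUE", trait = "DISEASE/TRAIT",
       odds_ratio = "OR or BETA", ci_lower = NA, ci_upper = NA,
       effect_allele = NA, other_allele = NA,
       phenotype_group = NA, uses_population_controls = NA)
}

#' Default trait-to-phenotype-group mapping
#'
#' Maps the study trait labels found in published diabetic-retinopathy GWASs
#' to the three separately analyzed phenotype groups: `DR`,
#' `PDR_sight_threatening` (proliferative / severe / sight-threatening
#' retinopathy) and `DME_maculopathy` (macular edema / maculopathy).
#' Matching is case-insensitive on the trait string.
#'
#' @return Named character vector: trait label -> phenotype group.
#' @export
default_trait_map <- function() {
  c("dr" = "DR",
    "diabetic retinopathy" = "DR",
    "dr (dme + pdr)" = "DR",
    "dr (severe npdr + pdr + dme)" = "DR",
    "pdr" = "PDR_sight_threatening",
    "proliferative diabetic retinopathy" = "PDR_sight_threatening",
    "severe dr" = "PDR_sight_threatening",
    "sight-threatening dr" = "PDR_sight_threatening",
    "severe diabetic retinopathy" = "PDR_sight_threatening",
    "dme" = "DME_maculopathy",
    "diabetic macular edema" = "DME_maculopathy",
    "diabetic maculopathy" = "DME_maculopathy",
    "dme and pdr" = "DME_maculopathy")
}

phenotype_groups <- c("DR", "PDR_sight_threatening", "DME_maculopathy")

# "chr10" -> "10", "x" -> "X"; original retained by callers where needed
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
  toupper(x)
}

normalize_rsid <- function(x) tolower(gsub("[[:space:]]", "", as.character(x)))

#' Read and validate a GWAS signal catalog
#'
#' Reads a tab-separated signal table, applies a column-mapping dialect,
#' validates every row and splits the input into accepted signals and a
#' rejects report. Rows are never silently dropped: accepted + rejected
#' always equals the input row count.
#'
#' Validation requires: non-empty `rsid` and `chrom`, integer `pos >= 1`,
#' `p_value` in (0, 1], and, when an odds ratio with confidence limits is
#' present, `ci_lower <= odds_ratio <= ci_upper` with all three positive.
#' Chromosome labels are normalized to an un-prefixed form (`"10"`, `"X"`);
#' the original label is kept in `chrom_input`. Phenotype groups are taken
#' from a `phenotype_group` column when mapped, otherwise derived from the
#' `trait` column via `trait_map`.
#'
#' @param path Path to a TSV file.
#' @param dialect Named list mapping canonical fields to file columns
#'   (see [default_dialect()]). Mandatory fields: `study_id`, `rsid`,
#'   `chrom`, `pos`, `p_value`.
#' @param trait_map Named character vector used to derive phenotype groups
#'   from trait labels (default [default_trait_map()]).
#' @return An object of class `signal_catalog`: a list with data frames
#'   `signals`, `studies` and `rejects` (columns `row`, `rsid`, `reason`).
#' @seealso [filter_by_tier()], [write_signal_catalog()]
#' @export
read_signal_catalog <- function(path, dialect = default_dialect(),
                                trait_map = default_trait_map()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), quote = "")
  mandatory <- c("study_id", "rsid", "chrom", "pos", "p_value")
  for (f in mandatory) {
    col <- dialect[[f]]
    if (is.null(col) || is.na(col) || !(col %in% names(raw)))
      stop("configuration error: mandatory column for '", f,
           "' (mapped to '", if (is.null(col)) "<unmapped>" else col,
           "') not found in ", path)
  }
  pick <- function(f) {
    col <- dialect[[f]]
    if (is.null(col) || is.na(col) || !(col %in% names(raw)))
      rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  n <- nrow(raw)
  parsed <- data.frame(
    study_id = trimws(pick("study_id")),
    rsid = pick("rsid"),
    chrom_input = pick("chrom"),
    pos_raw = pick("pos"),
    p_raw = pick("p_value"),
    effect_allele = toupper(trimws(pick("effect_allele"))),
    other_allele = toupper(trimws(pick("other_allele"))),
    or_raw = pick("odds_ratio"),
    lo_raw = pick("ci_lower"),
    hi_raw = pick("ci_upper"),
    trait = pick("trait"),
    pg_raw = pick("phenotype_group"),
    popctrl_raw = pick("uses_population_controls"),
    stringsAsFactors = FALSE)

  reasons <- character(n)
  num <- function(x) suppressWarnings(as.numeric(x))
  pos <- num(parsed$pos_raw)
  p <- num(parsed$p_raw)
  or_v <- num(parsed$or_raw); lo <- num(parsed$lo_raw); hi <- num(parsed$hi_raw)

  for (i in seq_len(n)) {
    errs <- character(0)
    if (is.na(parsed$study_id[i]) || parsed$study_id[i] == "")
      errs <- c(errs, "missing study_id")
    if (is.na(parsed$rsid[i]) || trimws(parsed$rsid[i]) == "")
      errs <- c(errs, "missing rsid")
    if (is.na(parsed$chrom_input[i]) || trimws(parsed$chrom_input[i]) == "")
      errs <- c(errs, "missing chrom")
    if (is.na(pos[i]) || pos[i] != round(pos[i]) || pos[i] < 1)
      errs <- c(errs, sprintf("unparseable or invalid position '%s' (must be integer >= 1)",
                              parsed$pos_raw[i]))
    if (is.na(p[i]))
      errs <- c(errs, sprintf("unparseable p-value '%s'", parsed$p_raw[i]))
    else if (p[i] <= 0 || p[i] > 1)
      errs <- c(errs, sprintf("p-value %s outside (0, 1]", parsed$p_raw[i]))
    if (!is.na(or_v[i]) && or_v[i] <= 0)
      errs <- c(errs, "odds_ratio must be positive")
    if (!is.na(lo[i]) && !is.na(hi[i]) && !is.na(or_v[i])) {
      if (lo[i] <= 0 || hi[i] <= 0)
        errs <- c(errs, "confidence limits must be positive")
      else if (!(lo[i] <= or_v[i] && or_v[i] <= hi[i]))
        errs <- c(errs, "confidence interval does not bracket odds_ratio")
    }
    reasons[i] <- paste(errs, collapse = "; ")
  }
  ok <- reasons == ""

  pg <- parsed$pg_raw
  derive <- is.na(pg) | !(pg %in% phenotype_groups)
  mapped <- unname(trait_map[tolower(trimws(parsed$trait))])
  pg[derive] <- mapped[derive]
  pg[is.na(pg)] <- "DR"

  signals <- data.frame(
    study_id = parsed$study_id[ok],
    rsid = trimws(parsed$rsid[ok]),
    chrom = normalize_chrom(parsed$chrom_input[ok]),
    chrom_input = parsed$chrom_input[ok],
    pos = as.integer(pos[ok]),
    effect_allele = parsed$effect_allele[ok],
    other_allele = parsed$other_allele[ok],
    p_value = p[ok],
    odds_ratio = or_v[ok],
    ci_lower = lo[ok],
    ci_upper = hi[ok],
    trait = parsed$trait[ok],
    phenotype_group = pg[ok],
    stringsAsFactors = FALSE)

  rejects <- data.frame(row = which(!ok),
                        rsid = parsed$rsid[!ok],
                        reason = reasons[!ok],
                        stringsAsFactors = FALSE)

  popctrl <- tolower(parsed$popctrl_raw) %in% c("true", "t", "1", "yes")
  studies <- unique(data.frame(study_id = parsed$study_id[ok],
                               uses_population_controls = popctrl[ok],
                               stringsAsFactors = FALSE))
  studies <- studies[!is.na(studies$study_id) & studies$study_id != "", ,
                     drop = FALSE]
  rownames(signals) <- rownames(rejects) <- rownames(studies) <- NULL

  structure(list(signals = signals, studies = studies, rejects = rejects),
            class = "signal_catalog")
}

#' @export
print.signal_catalog <- function(x, ...) {
  cat("GWAS signal catalog:", nrow(x$signals), "signals,",
      nrow(x$studies), "studies,", nrow(x$rejects), "rejected rows\n")
  tab <- table(x$signals$phenotype_group)
  for (g in names(tab)) cat("  ", g, ": ", tab[[g]], "\n", sep = "")
  invisible(x)
}

#' Write a signal catalog back to TSV
#'
#' Canonical serialization: writing with the default dialect and re-reading
#' with [read_signal_catalog()] round-trips the signal table exactly.
#'
#' @param signals Signal data frame (as in a `signal_catalog`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signal_catalog <- function(signals, path) {
  out <- signals
  out$chrom <- out$chrom_input
  out$chrom_input <- NULL
  # full-precision p so read -> write -> read is the identity
  num_cols <- c("p_value", "odds_ratio", "ci_lower", "ci_upper")
  for (cc in num_cols) if (cc %in% names(out))
    out[[cc]] <- ifelse(is.na(out[[cc]]), NA, format(out[[cc]], digits = 17,
                                                     scientific = TRUE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Filter signals by significance tier
#'
#' Retains exactly the signals whose p-value falls strictly below the
#' selected threshold; boundary equality is excluded and input order is
#' preserved.
#'
#' @param signals Signal data frame.
#' @param tier A [significance_tier()].
#' @param level `"suggestive"` or `"genome_wide"`.
#' @return The retained subset of `signals`.
#' @examples
#' sig <- data.frame(rsid = c("rs1", "rs2"), p_value = c(3e-15, 1e-7))
#' filter_by_tier(sig, significance_tier(), "genome_wide")  # rs1 only
#' @export
filter_by_tier <- function(signals, tier = significance_tier(),
                           level = c("genome_wide", "suggestive")) {
  level <- match.arg(level)
  stopifnot(inherits(tier, "significance_tier"))
  thr <- if (level == "genome_wide") tier$genome_wide else tier$suggestive
  signals[!is.na(signals$p_value) & signals$p_value < thr, , drop = FALSE]
}

#' Count distinct gene loci among signals
#'
#' @param signals Signal data frame.
#' @param locus_labels Named character vector mapping rsid to a gene-locus
#'   label; every signal rsid must be present.
#' @return Integer number of distinct locus labels.
#' @export
count_distinct_loci <- function(signals, locus_labels) {
  if (nrow(signals) == 0L) return(0L)
  missing <- setdiff(signals$rsid, names(locus_labels))
  if (length(missing) > 0L)
    stop("no locus label for rsid(s): ", paste(missing, collapse = ", "))
  length(unique(unname(locus_labels[signals$rsid])))
}

#' Drop studies that used non-diabetic population controls
#'
#' Studies flagged `uses_population_controls` stay in the catalog but are
#' excluded from overlap search and meta-analysis by default, since their
#' control arms are not diabetic-without-retinopathy comparators.
#'
#' @param catalog A `signal_catalog`.
#' @param keep_population_controls Set `TRUE` to retain them.
#' @return Signal data frame restricted to eligible studies.
#' @export
eligible_signals <- function(catalog, keep_population_controls = FALSE) {
  sig <- catalog$signals
  if (keep_population_controls) return(sig)
  drop_ids <- catalog$studies$study_id[catalog$studies$uses_population_controls]
  sig[!(sig$study_id %in% drop_ids), , drop = FALSE]
}
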
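#' Read a pairwise LD table
#'
#' Expects a PLINK-`.ld`-style tab-separated layout with columns `SNP_A`,
#' `SNP_B`, `R2` and a `DP` column for D-prime (an optional `POP` column
#' carries the reference-population label, kept as an opaque string). Pairs
#' are symmetric: the table is normalized so a lookup works from either
#' side.
#'
#' @param path TSV path.
#' @return Data frame with columns `rsid_a`, `rsid_b`, `d_prime`, `r2`,
#'   `population`, symmetric-normalized (both orientations present).
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("LD table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("SNP_A", "SNP_B", "R2", "DP")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("LD table lacks column(s): ", paste(missing, collapse = ", "))
  pop <- if ("POP" %in% names(raw)) as.character(raw$POP) else NA_character_
  ld <- data.frame(rsid_a = normalize_rsid(raw$SNP_A),
                   rsid_b = normalize_rsid(raw$SNP_B),
                   d_prime = as.numeric(raw$DP), r2 = as.numeric(raw$R2),
                   population = pop, stringsAsFactors = FALSE)
  if (any(ld$d_prime < 0 | ld$d_prime > 1, na.rm = TRUE) ||
      any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE))
    stop("D-prime and r2 must lie in [0, 1]")
  flipped <- ld[, c("rsid_b", "rsid_a", "d_prime", "r2", "population")]
  names(flipped) <- names(ld)
  out <- unique(rbind(ld, flipped))
  rownames(out) <- NULL
  out
}

#' Select LD proxies for an index SNP
#'
#' Returns the rsIDs in high linkage disequilibrium with the index SNP:
#' `d_prime >= d_min` AND `r2 >= r2_min`, both inclusive. The index SNP is
#' never returned as its own proxy. An index absent from the table yields
#' an empty result with a warning.
#'
#' @param index_rsid Index SNP rsID.
#' @param ld Symmetric-normalized LD data frame from [read_ld_table()].
#' @param d_min Minimum D-prime (default 0.8).
#' @param r2_min Minimum r-squared (default 0.8).
#' @return Character vector of proxy rsIDs (sorted, unique).
#' @export
select_proxies <- function(index_rsid, ld, d_min = 0.8, r2_min = 0.8) {
  idx <- normalize_rsid(index_rsid)
  rel <- ld[ld$rsid_a == idx & ld$rsid_b != idx, , drop = FALSE]
  if (nrow(rel) == 0L) {
    warning("index SNP ", index_rsid, " not present in the LD table")
    return(character(0))
  }
  hits <- rel$rsid_b[!is.na(rel$d_prime) & !is.na(rel$r2) &
                     rel$d_prime >= d_min & rel$r2 >= r2_min]
  sort(unique(hits))
}

#' Read a local functional-annotation table
#'
#' Tab-separated, with columns `rsid`, `location_class`, `nearest_gene`,
#' `sift`, `polyphen`, `cadd`, `regulomedb_rank`, `eqtl_gene`, `eqtl_p`;
#' missing scores are the literal string `na`.
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("na", "NA"))
  need <- c("rsid", "location_class", "nearest_gene", "sift", "polyphen",
            "cadd", "regulomedb_rank", "eqtl_gene", "eqtl_p")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  raw$cadd <- suppressWarnings(as.numeric(raw$cadd))
  raw$eqtl_p <- suppressWarnings(as.numeric(raw$eqtl_p))
  raw$regulomedb_rank <- as.character(raw$regulomedb_rank)
  if (any(raw$cadd < 0, na.rm = TRUE)) stop("CADD scores must be >= 0")
  if (any(raw$eqtl_p <= 0 | raw$eqtl_p > 1, na.rm = TRUE))
    stop("eQTL p-values must lie in (0, 1]")
  raw
}

#' Join functional annotations onto SNPs
#'
#' Produces one report row per queried rsID in input order: annotated SNPs
#' carry their table values; rsIDs absent from the table yield all-`NA`
#' rows flagged `unannotated`, so the join is total
#' (`nrow(report) == length(rsids)`).
#'
#' @param rsids Character vector of rsIDs (e.g. an index SNP plus its
#'   [select_proxies()] output).
#' @param table Annotation data frame from [read_annotation_table()].
#' @return Data frame mirroring the annotation columns plus `unannotated`.
#' @export
join_annotations <- function(rsids, table) {
  cols <- c("rsid", "location_class", "nearest_gene", "sift", "polyphen",
            "cadd", "regulomedb_rank", "eqtl_gene", "eqtl_p")
  empty <- data.frame(rsid = character(0), location_class = character(0),
                      nearest_gene = character(0), sift = character(0),
                      polyphen = character(0), cadd = numeric(0),
                      regulomedb_rank = character(0), eqtl_gene = character(0),
                      eqtl_p = numeric(0), unannotated = logical(0),
                      stringsAsFactors = FALSE)
  if (length(rsids) == 0L) return(empty)
  key <- normalize_rsid(table$rsid)
  rows <- lapply(rsids, function(rs) {
    hit <- which(key == normalize_rsid(rs))
    if (length(hit) >= 1L) {
      r <- table[hit[1L], cols]
      r$rsid <- rs
      r$unannotated <- FALSE
      r
    } else {
      data.frame(rsid = rs, location_class = NA_character_,
                 nearest_gene = NA_character_, sift = NA_character_,
                 polyphen = NA_character_, cadd = NA_real_,
                 regulomedb_rank = NA_character_, eqtl_gene = NA_character_,
                 eqtl_p = NA_real_, unannotated = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotation report for index SNPs and their LD proxies
#'
#' For each index SNP, selects its high-LD proxies and joins annotations
#' for the index and proxies together; the per-index proxy count is
#' reported alongside.
#'
#' @param index_rsids Character vector of index SNPs.
#' @param ld LD data frame from [read_ld_table()].
#' @param table Annotation data frame.
#' @param d_min,r2_min LD proxy thresholds (inclusive).
#' @return List with `report` (annotation rows, column `index_rsid` added)
#'   and `proxy_counts` (data frame `index_rsid`, `n_proxies`).
#' @export
annotate_indices <- function(index_rsids, ld, table,
                             d_min = 0.8, r2_min = 0.8) {
  reports <- list()
  counts <- data.frame(index_rsid = character(0), n_proxies = integer(0),
                       stringsAsFactors = FALSE)
  for (idx in index_rsids) {
    proxies <- suppressWarnings(select_proxies(idx, ld, d_min, r2_min))
    rep_i <- join_annotations(c(idx, proxies), table)
    rep_i$index_rsid <- idx
    reports[[idx]] <- rep_i
    counts <- rbind(counts, data.frame(index_rsid = idx,
                                       n_proxies = length(proxies),
                                       stringsAsFactors = FALSE))
  }
  report <- if (length(reports) > 0L) do.call(rbind, reports)
            else join_annotations(character(0), table)
  rownames(report) <- NULL
  list(report = report, proxy_counts = counts)
}
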
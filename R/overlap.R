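#' Proximity window for overlap search
#'
#' @param half_width Half-width of the window in base pairs; two signals on
#'   the same chromosome are proximal when `|pos1 - pos2| <= half_width`
#'   (inclusive). Default 100,000 ("+/- 100 kb").
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(half_width = 100000L) {
  stopifnot(is.numeric(half_width), length(half_width) == 1L, half_width >= 0)
  structure(list(half_width = as.numeric(half_width)), class = "window_spec")
}

# minimal union-find; indices 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

check_one_group <- function(signals) {
  g <- unique(signals$phenotype_group)
  if (length(g) > 1L)
    stop("signals span multiple phenotype groups (", paste(g, collapse = ", "),
         "); overlap search is per-group")
  invisible(g)
}

build_clusters <- function(signals, member_idx_list, kind) {
  keep <- vapply(member_idx_list,
                 function(ix) length(unique(signals$study_id[ix])) >= 2L,
                 logical(1))
  member_idx_list <- member_idx_list[keep]
  if (length(member_idx_list) == 0L) return(list())
  # sort clusters by chrom then min pos for order-invariant output
  key <- vapply(member_idx_list, function(ix)
    sprintf("%s:%012d", signals$chrom[ix][1L], min(signals$pos[ix])), character(1))
  member_idx_list <- member_idx_list[order(key)]
  lapply(seq_along(member_idx_list), function(ci) {
    ix <- member_idx_list[[ci]]
    m <- signals[ix, , drop = FALSE]
    m <- m[order(m$pos, m$rsid, m$study_id), , drop = FALSE]
    rownames(m) <- NULL
    structure(list(cluster_id = ci, kind = kind, members = m,
                   n_studies = length(unique(m$study_id)),
                   chrom = m$chrom[1L], start = min(m$pos), end = max(m$pos)),
              class = "overlap_cluster")
  })
}

#' Find identical signals reported by independent studies
#'
#' Groups signals by rsID (string-equal after lowercasing and whitespace
#' stripping) and returns one cluster per rsID reported by two or more
#' distinct studies within a phenotype group. An rsID repeated within a
#' single study does not constitute independent overlap.
#'
#' @param signals Signal data frame from one phenotype group.
#' @return List of `overlap_cluster` objects (possibly empty).
#' @seealso [find_proximal()], [overlap_report()]
#' @export
find_identical <- function(signals) {
  if (nrow(signals) == 0L) return(list())
  check_one_group(signals)
  groups <- split(seq_len(nrow(signals)), normalize_rsid(signals$rsid))
  build_clusters(signals, unname(groups), "identical")
}

#' Find proximal signals across studies within a window
#'
#' Builds a graph whose edges link pairs of signals from *different* studies
#' on the same chromosome with `|pos1 - pos2| <= half_width`, then reports
#' each connected component involving at least two distinct studies
#' (`mode = "component"`, the default; components can chain beyond one
#' window, and the reported span makes chained extents visible). With
#' `mode = "pairwise"` every qualifying cross-study pair is reported as its
#' own two-member cluster instead.
#'
#' @param signals Signal data frame from one phenotype group, positions on
#'   one declared genome build.
#' @param window A [window_spec()].
#' @param mode `"component"` or `"pairwise"`.
#' @return List of `overlap_cluster` objects.
#' @export
find_proximal <- function(signals, window = window_spec(),
                          mode = c("component", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "window_spec"))
  if (nrow(signals) < 2L) return(list())
  check_one_group(signals)
  w <- window$half_width
  n <- nrow(signals)
  parent <- uf_new(n)
  pairs <- list()
  for (ch in unique(signals$chrom)) {
    idx <- which(signals$chrom == ch)
    if (length(idx) < 2L) next
    idx <- idx[order(signals$pos[idx])]
    pos <- signals$pos[idx]
    stud <- signals$study_id[idx]
    lo <- 1L
    for (j in 2L:length(idx)) {
      while (pos[j] - pos[lo] > w) lo <- lo + 1L
      if (lo < j) for (i in lo:(j - 1L)) {
        if (stud[i] != stud[j]) {  # within-study pairs never link
          if (mode == "component") parent <- uf_union(parent, idx[i], idx[j])
          else pairs[[length(pairs) + 1L]] <- c(idx[i], idx[j])
        }
      }
    }
  }
  if (mode == "pairwise") return(build_clusters(signals, pairs, "proximal"))
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[vapply(comps, length, integer(1)) >= 2L]
  build_clusters(signals, unname(comps), "proximal")
}

#' @export
print.overlap_cluster <- function(x, ...) {
  cat(sprintf("overlap cluster %d [%s] chr%s:%d-%d, %d signals from %d studies\n",
              x$cluster_id, x$kind, x$chrom, x$start, x$end,
              nrow(x$members), x$n_studies))
  invisible(x)
}

#' Tabulate overlap clusters
#'
#' One row per cluster with members, contributing studies and genomic span,
#' sorted by chromosome and position. An empty cluster list yields one
#' explicit "no overlap" row per phenotype group so absence of overlap is a
#' recorded result, not a missing one.
#'
#' @param clusters List of `overlap_cluster` objects.
#' @param phenotype_group Group label(s) used for the explicit no-overlap
#'   rows when `clusters` is empty.
#' @return Data frame report.
#' @export
overlap_report <- function(clusters, phenotype_group = "DR") {
  if (length(clusters) == 0L) {
    return(data.frame(phenotype_group = phenotype_group,
                      cluster_id = NA_integer_, kind = "none",
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_, n_signals = 0L, n_studies = 0L,
                      rsids = "", studies = "",
                      note = "no overlap", stringsAsFactors = FALSE))
  }
  rows <- lapply(clusters, function(cl) {
    data.frame(phenotype_group = cl$members$phenotype_group[1L],
               cluster_id = cl$cluster_id, kind = cl$kind,
               chrom = cl$chrom, start = cl$start, end = cl$end,
               n_signals = nrow(cl$members), n_studies = cl$n_studies,
               rsids = paste(cl$members$rsid, collapse = ","),
               studies = paste(sort(unique(cl$members$study_id)), collapse = ","),
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cluster spans as BED
#'
#' Emits one BED interval per cluster (0-based, half-open) for
#' genome-browser inspection.
#'
#' @param clusters List of `overlap_cluster` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (length(clusters) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(chrom = paste0("chr", cl$chrom), start = cl$start - 1L,
               end = cl$end,
               name = sprintf("%s_cluster_%d", cl$kind, cl$cluster_id),
               stringsAsFactors = FALSE)
  }))
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
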
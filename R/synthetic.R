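#' Specification for a synthetic case-control cohort
#'
#' Defines the generative model for one replication-style allelic
#' case-control study: control genotypes are drawn from Hardy-Weinberg
#' proportions at the control effect-allele frequency; a study-level log
#' odds ratio is drawn as `ln(true_or) + Normal(0, tau^2)`; the case
#' effect-allele frequency follows from the exact allelic-odds-ratio
#' inversion `p_case = OR p / (1 + p (OR - 1))`, and case genotypes are
#' drawn from Hardy-Weinberg proportions at `p_case`. With
#' `hwe_in_controls = FALSE` control genotype probabilities are distorted
#' by a fixed inbreeding-style coefficient `inbreeding_f`.
#'
#' @param true_or True allelic odds ratio (> 0).
#' @param control_maf Control effect-allele frequency in (0, 0.5].
#' @param n_case,n_control Per-arm sample sizes (>= 1).
#' @param k_studies Number of cohorts for [simulate_meta()] (>= 1).
#' @param tau Between-study SD of the log odds ratio (>= 0).
#' @param hwe_in_controls Draw control genotypes from exact HWE
#'   proportions (default `TRUE`).
#' @param inbreeding_f Inbreeding-style distortion of control genotype
#'   probabilities used when `hwe_in_controls = FALSE` (default 0.15).
#' @param jitter_n Jitter per-cohort sample sizes uniformly by +/- 20% in
#'   [simulate_meta()] (default `TRUE`).
#' @param seed Mandatory integer seed; all generators are bit-reproducible
#'   under it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(true_or = 1.38, control_maf = 0.3,
                     n_case = 1000L, n_control = 1000L,
                     k_studies = 5L, tau = 0,
                     hwe_in_controls = TRUE, inbreeding_f = 0.15,
                     jitter_n = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory in the simulation spec")
  stopifnot(true_or > 0, control_maf > 0, control_maf <= 0.5,
            n_case >= 1, n_control >= 1, k_studies >= 1, tau >= 0,
            inbreeding_f >= 0, inbreeding_f < 1)
  structure(list(true_or = true_or, control_maf = control_maf,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 k_studies = as.integer(k_studies), tau = tau,
                 hwe_in_controls = isTRUE(hwe_in_controls),
                 inbreeding_f = inbreeding_f, jitter_n = isTRUE(jitter_n),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# genotype probabilities (EE, EO, OO) at effect-allele frequency p,
# optionally distorted by inbreeding coefficient f
genotype_probs <- function(p, f = 0) {
  q <- 1 - p
  pr <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  pr / sum(pr)
}

# one cohort, NO seeding here: callers own the RNG stream
sim_study_counts <- function(spec, study_id, n_case = spec$n_case,
                             n_control = spec$n_control) {
  log_or <- log(spec$true_or) + stats::rnorm(1L, 0, spec$tau)
  or_i <- exp(log_or)
  p <- spec$control_maf
  p_case <- (or_i * p) / (1 + p * (or_i - 1))
  if (!(p_case > 0 && p_case < 1))
    stop("derived case allele frequency outside (0, 1)")
  f <- if (spec$hwe_in_controls) 0 else spec$inbreeding_f
  co <- as.integer(stats::rmultinom(1L, n_control, genotype_probs(p, f)))
  ca <- as.integer(stats::rmultinom(1L, n_case, genotype_probs(p_case)))
  genotype_counts(study_id, ca, co)
}

#' Simulate one case-control cohort
#'
#' Draws genotype counts for a single study under the model documented in
#' [sim_spec()]. Deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @param study_id Study label (default `"sim_study_1"`).
#' @return A [genotype_counts()] object.
#' @examples
#' simulate_study(sim_spec(true_or = 1.38, control_maf = 0.3, seed = 7))
#' @export
simulate_study <- function(spec, study_id = "sim_study_1") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sim_study_counts(spec, study_id)
}

#' Simulate a set of independent cohorts for meta-analysis
#'
#' Generates `k_studies` independent cohorts sharing `true_or` and `tau`;
#' per-cohort sample sizes are jittered uniformly by +/- 20% unless
#' `jitter_n = FALSE` in the spec. Deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()] with `k_studies >= 2`.
#' @return List of [genotype_counts()] objects, named `sim_study_<i>`.
#' @export
simulate_meta <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$k_studies < 2L) stop("simulate_meta requires k_studies >= 2")
  set.seed(spec$seed)
  lapply(seq_len(spec$k_studies), function(i) {
    if (spec$jitter_n) {
      n_ca <- max(1L, as.integer(round(spec$n_case * stats::runif(1L, 0.8, 1.2))))
      n_co <- max(1L, as.integer(round(spec$n_control * stats::runif(1L, 0.8, 1.2))))
    } else {
      n_ca <- spec$n_case; n_co <- spec$n_control
    }
    sim_study_counts(spec, sprintf("sim_study_%d", i), n_ca, n_co)
  })
}

#' Simulate a signal catalog with planted overlaps
#'
#' Builds a GWAS-catalog-style signal table for exercising the overlap
#' search. Background signals are placed on a coarse position grid whose
#' spacing exceeds twice the window, so they can never cluster by
#' accident; planted clusters (identical rsIDs across studies, or distinct
#' rsIDs within the window across studies) occupy their own grid slots. A
#' ground-truth table of planted clusters is returned alongside.
#'
#' @param n_studies Number of contributing studies (>= 2 when anything is
#'   planted).
#' @param n_signals Number of background signals.
#' @param planted_identical Number of planted identical clusters.
#' @param planted_proximal Number of planted proximal pairs.
#' @param window A [window_spec()]; planted proximal pairs sit at exactly
#'   this distance or closer.
#' @param proximal_distance Distance for planted proximal pairs (default:
#'   the window half-width itself, the inclusive boundary).
#' @param phenotype_group Group label for all signals.
#' @param seed Integer seed.
#' @return List with `signals` (signal data frame) and `truth` (data frame
#'   `cluster`, `kind`, `rsids`).
#' @export
simulate_catalog <- function(n_studies = 4L, n_signals = 50L,
                             planted_identical = 0L, planted_proximal = 0L,
                             window = window_spec(),
                             proximal_distance = window$half_width,
                             phenotype_group = "DR", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  n_planted <- planted_identical + planted_proximal
  if (n_planted > n_signals)
    stop("planted clusters cannot exceed n_signals")
  if (n_planted > 0L && n_studies < 2L)
    stop("planting overlaps requires at least 2 studies")
  set.seed(as.integer(seed))
  studies <- sprintf("SIM%02d", seq_len(n_studies))
  spacing <- as.integer(2 * window$half_width + 1e6)
  n_slots <- n_signals + n_planted
  slot <- sample(seq_len(4L * n_slots), n_slots)
  chrom <- as.character(sample(1:22, n_slots, replace = TRUE))
  base_pos <- 1e6 + (slot - 1L) * spacing  # per-chrom grid; safe even if shared

  rows <- list()
  truth <- data.frame(cluster = integer(0), kind = character(0),
                      rsids = character(0), stringsAsFactors = FALSE)
  mk_row <- function(rsid, chrom, pos, study, p)
    data.frame(study_id = study, rsid = rsid, chrom = chrom, pos = as.integer(pos),
               p_value = p, phenotype_group = phenotype_group,
               stringsAsFactors = FALSE)
  si <- 0L
  next_slot <- 0L
  take_slot <- function() { next_slot <<- next_slot + 1L; next_slot }

  for (i in seq_len(n_signals)) {
    s <- take_slot()
    rows[[length(rows) + 1L]] <-
      mk_row(sprintf("rsbg%06d", i), chrom[s], base_pos[s],
             sample(studies, 1L), 10^stats::runif(1L, -12, -5))
  }
  cl <- 0L
  for (i in seq_len(planted_identical)) {
    s <- take_slot(); cl <- cl + 1L
    rs <- sprintf("rsid%04d", i)
    members <- sample(studies, sample(2:min(3L, n_studies), 1L))
    for (st in members)
      rows[[length(rows) + 1L]] <-
        mk_row(rs, chrom[s], base_pos[s], st, 10^stats::runif(1L, -12, -5))
    truth <- rbind(truth, data.frame(cluster = cl, kind = "identical",
                                     rsids = rs, stringsAsFactors = FALSE))
  }
  for (i in seq_len(planted_proximal)) {
    s <- take_slot(); cl <- cl + 1L
    rs <- c(sprintf("rspxa%04d", i), sprintf("rspxb%04d", i))
    members <- sample(studies, 2L)
    rows[[length(rows) + 1L]] <-
      mk_row(rs[1L], chrom[s], base_pos[s], members[1L],
             10^stats::runif(1L, -12, -5))
    rows[[length(rows) + 1L]] <-
      mk_row(rs[2L], chrom[s], base_pos[s] + proximal_distance, members[2L],
             10^stats::runif(1L, -12, -5))
    truth <- rbind(truth, data.frame(cluster = cl, kind = "proximal",
                                     rsids = paste(rs, collapse = ","),
                                     stringsAsFactors = FALSE))
  }
  signals <- do.call(rbind, rows)
  signals$chrom_input <- signals$chrom
  rownames(signals) <- NULL
  list(signals = signals, truth = truth)
}

#' Write simulated cohorts as a genotype-counts CSV
#'
#' Emits the same CSV layout [read_genotype_counts()] consumes, so
#' synthetic cohorts can exercise the file-based pipeline end to end.
#'
#' @param cohorts List of [genotype_counts()] (e.g. from [simulate_meta()]).
#' @param snp SNP label attached to every cohort.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_counts <- function(cohorts, snp, path) {
  rows <- do.call(rbind, lapply(cohorts, function(g) {
    data.frame(study_id = rep(g$study_id, 2L), snp = snp,
               arm = c("case", "control"),
               n_EE = c(g$case_counts[1L], g$control_counts[1L]),
               n_EO = c(g$case_counts[2L], g$control_counts[2L]),
               n_OO = c(g$case_counts[3L], g$control_counts[3L]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
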
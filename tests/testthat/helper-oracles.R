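# Independent oracles, deliberately coded with different algorithms/styles
# than the package implementation.

# Random-effects pooling, loop-based reference (moment estimator, normal CI).
dl_reference <- function(beta, se) {
  k <- length(beta)
  w <- numeric(k); for (i in 1:k) w[i] <- 1 / (se[i] * se[i])
  sw <- 0; swb <- 0; sw2 <- 0
  for (i in 1:k) { sw <- sw + w[i]; swb <- swb + w[i] * beta[i]; sw2 <- sw2 + w[i]^2 }
  mu_f <- swb / sw
  q <- 0; for (i in 1:k) q <- q + w[i] * (beta[i] - mu_f)^2
  tau2 <- (q - (k - 1)) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  ws <- 1 / (se^2 + tau2)
  mu_r <- sum(ws * beta) / sum(ws)
  se_r <- sqrt(1 / sum(ws))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(beta_random = mu_r, se_random = se_r, tau2 = tau2, q = q, i2 = i2,
       ci = exp(c(mu_r - 1.96 * se_r, mu_r + 1.96 * se_r)))
}

# Brute-force overlap clustering: full O(n^2) adjacency + BFS components.
# Returns a list of sorted row-index vectors (components with >= 2 studies),
# ordered canonically.
overlap_reference <- function(signals, half_width) {
  n <- nrow(signals)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        signals$chrom[i] == signals$chrom[j] &&
        signals$study_id[i] != signals$study_id[j] &&
        abs(signals$pos[i] - signals$pos[j]) <= half_width)
      adj[i, j] <- TRUE
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]; comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (length(comp) >= 2 &&
        length(unique(signals$study_id[comp])) >= 2)
      comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, function(x) x[1], numeric(1)))]
}

# canonical form of package clusters for comparison with the oracle:
# sorted member row indices, looked up by (study_id, rsid, pos)
cluster_indices <- function(clusters, signals) {
  key <- paste(signals$study_id, signals$rsid, signals$pos)
  comps <- lapply(clusters, function(cl)
    sort(match(paste(cl$members$study_id, cl$members$rsid, cl$members$pos), key)))
  comps[order(vapply(comps, function(x) x[1], numeric(1)))]
}

# Exact Hardy-Weinberg p-value by direct enumeration of all genotype
# configurations compatible with the observed allele counts (plain
# factorial formula, no recurrences, no log tricks beyond lgamma).
hwe_enum_reference <- function(counts) {
  n <- sum(counts)
  na <- 2 * counts[1] + counts[2]          # copies of allele A
  nb <- 2 * n - na
  n_rare <- min(na, nb)
  configs <- seq(n_rare %% 2, n_rare, by = 2)  # possible het counts
  pr <- sapply(configs, function(h) {
    rr <- (n_rare - h) / 2
    cc <- n - h - rr
    exp(lgamma(n + 1) - (lgamma(rr + 1) + lgamma(h + 1) + lgamma(cc + 1)) +
          h * log(2) -
          (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1)))
  })
  obs_p <- pr[configs == counts[2]]
  sum(pr[pr <= obs_p + 1e-10])
}

# random effect-estimate table for meta fixtures
random_estimates <- function(k, beta_mu = 0.2, beta_sd = 0.3,
                             se_lo = 0.05, se_hi = 0.5) {
  data.frame(study_id = sprintf("S%02d", seq_len(k)),
             beta = rnorm(k, beta_mu, beta_sd),
             se = runif(k, se_lo, se_hi),
             stringsAsFactors = FALSE)
}

# random signal table for overlap fixtures (collisions allowed on purpose)
random_signals <- function(n, n_studies = 6, n_chrom = 4,
                           max_pos = 5e6, group = "DR") {
  data.frame(study_id = sample(sprintf("S%d", seq_len(n_studies)), n, TRUE),
             rsid = sprintf("rs%06d", sample.int(1e6, n)),
             chrom = as.character(sample.int(n_chrom, n, TRUE)),
             pos = sample.int(max_pos, n, TRUE),
             p_value = 10^runif(n, -12, -5),
             phenotype_group = group,
             stringsAsFactors = FALSE)
}

write_temp_tsv <- function(df, dir = tempdir()) {
  path <- tempfile(fileext = ".tsv", tmpdir = dir)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
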
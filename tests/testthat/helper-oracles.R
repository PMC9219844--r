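# Independent oracles used to check the implementation paths. These are kept
# deliberately naive (brute force / full enumeration) and share no code with
# the package internals they verify.

# Benjamini-Hochberg step-up written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(p[o][js] * m / js)
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Two-sided Fisher p by full hypergeometric enumeration over the table
# support, counting tables whose probability does not exceed the observed
# one (with the conventional relative tolerance for ties).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Brute-force annotation: scan every (compound, adduct) pair, keep matches
# within tol, sort by |ppm| then adduct priority then compound name.
brute_annotate <- function(mz, registry, tol_ppm = 10) {
  comp <- registry$compounds
  add <- registry$adducts
  rows <- list()
  prio_ref <- c("M+H[1+]", "M+Na[1+]", "M+NH3[1+]", "M+K[1+]",
                "M-H2O[1+]", "M-NH3[1+]", "M+2H[2+]", "M+H+Na[2+]")
  for (i in seq_len(nrow(comp))) {
    for (j in seq_len(nrow(add))) {
      theo <- (comp$neutral_mass[i] + add$mass_shift[j]) / add$charge[j]
      if (theo <= 0) next
      ppm <- (mz - theo) / theo * 1e6
      if (abs(ppm) <= tol_ppm)
        rows[[length(rows) + 1L]] <- data.frame(
          compound = comp$name[i], adduct = add$name[j], theoretical_mz = theo,
          ppm_error = ppm, prio = match(add$name[j], prio_ref),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(compound = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$ppm_error), out$prio, out$compound), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("compound", "adduct", "theoretical_mz", "ppm_error", "rank")]
}

# Two-sided permutation p-value for the Welch statistic by random relabeling
# (or exact enumeration when all_splits is supplied).
perm_test_oracle <- function(control, treated, n_draw = 10000, seed = 1,
                             pseudo = 1) {
  x <- log2(c(control, treated) + pseudo)
  n_c <- length(control)
  n <- length(x)
  stat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    abs(mean(b) - mean(a)) / sqrt(stats::var(a) / length(a) +
                                    stats::var(b) / length(b))
  }
  obs <- stat(seq_len(n_c))
  withr::with_seed(seed, {
    draws <- replicate(n_draw, stat(sample.int(n, n_c)))
  })
  mean(draws >= obs - 1e-12)
}

# Exact enumeration over all balanced relabelings (small n only).
perm_test_exact <- function(control, treated, pseudo = 1) {
  x <- log2(c(control, treated) + pseudo)
  n_c <- length(control)
  n <- length(x)
  stat <- function(idx) {
    a <- x[idx]; b <- x[-idx]
    abs(mean(b) - mean(a)) / sqrt(stats::var(a) / length(a) +
                                    stats::var(b) / length(b))
  }
  obs <- stat(seq_len(n_c))
  splits <- utils::combn(n, n_c)
  stats_all <- apply(splits, 2, stat)
  mean(stats_all >= obs - 1e-12)
}

# Minimal hand-built mapping tables for EC-integration unit tests.
toy_maps <- function() {
  structure(list(
    gene2pfam = data.frame(
      gene = c("g1", "g2", "g3"),
      pfam = c("PF00001", "PF00002", "PF00003"), stringsAsFactors = FALSE),
    pfam2ec = data.frame(
      pfam = c("PF00001", "PF00001", "PF00002", "PF00003"),
      ec = c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4"),
      tier = c("gold", "gold", "silver", "gold"), stringsAsFactors = FALSE),
    compound2ec = data.frame(
      compound = c("hypoxanthine", "cpdX"),
      cas = c("68-94-0", ""),
      ec = c("1.17.1.4", "2.2.2.2"), stringsAsFactors = FALSE),
    ec2reaction = data.frame(
      ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "1.17.1.4"),
      reaction = c("R1", "R2", "R2", "R3"), stringsAsFactors = FALSE),
    reaction2pathway = data.frame(
      reaction = c("R1", "R2", "R3"),
      pathway = c("pwA", "pwA", "pwB"), stringsAsFactors = FALSE)),
    class = "mapping_tables")
}

# Small simulated dataset shared across tests (kept cheap).
small_sim <- function(seed = 1, n_compounds = 20, n_genes = 60, ...) {
  cfg <- sim_config(n_compounds = n_compounds, n_genes = n_genes,
                    seed = seed, ...)
  simulate_dataset(cfg, synthetic_registry(n_compounds + 5, seed = seed + 1000))
}

# Consensus feature table averaged to biological samples, plus group map.
averaged_features <- function(ds) {
  rep_map <- stats::setNames(ds$samples$biological, ds$samples$run)
  run_cols <- setdiff(names(ds$features), c("id", "mz", "rt"))
  avg <- average_technical_replicates(ds$features[, run_cols], rep_map)
  grp <- stats::setNames(ds$samples$group, ds$samples$biological)
  list(features = cbind(ds$features[, c("id", "mz", "rt")], as.data.frame(avg)),
       groups = grp[!duplicated(names(grp))])
}
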
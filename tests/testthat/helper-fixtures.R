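# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed explicitly so runs are reproducible.

# Small marker matrix with explicit entries (rows = individuals).
mk_matrix <- function(rows, populations, locus_ids = NULL) {
  ph <- do.call(rbind, rows)
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("OPT-01_%dbp", 100 + 10 * seq_len(ncol(ph)))
  }
  dimnames(ph) <- list(paste0("ind", seq_len(nrow(ph))), locus_ids)
  marker_matrix(ph, populations)
}

# Simulated matrix of a given size, defaulting to moderate differentiation.
sim_matrix <- function(n_pops = 3, n_per_pop = 10, n_rapd = 30, n_issr = 10,
                       fst = 0.3, missing_rate = 0, seed = 1) {
  cfg <- sim_config(n_pops = n_pops, n_per_pop = n_per_pop,
                    loci_per_system = c(RAPD = n_rapd, ISSR = n_issr),
                    fst = fst, missing_rate = missing_rate, seed = seed)
  simulate_dataset(cfg)
}

# Independent brute-force AMOVA oracle: definitional sums with explicit
# double loops, sharing no code with the package implementation.
brute_amova <- function(ph, pops) {
  n <- nrow(ph)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(ph[i, ] != ph[j, ])
    }
  }
  lev <- unique(pops)
  k <- length(lev)
  ssd_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssd_total <- ssd_total + d[i, j]
  ssd_total <- ssd_total / n
  ssd_within <- 0
  for (p in lev) {
    ii <- which(pops == p)
    if (length(ii) < 2) next
    acc <- 0
    for (a in seq_along(ii)) {
      for (b in seq_along(ii)) {
        if (a < b) acc <- acc + d[ii[a], ii[b]]
      }
    }
    ssd_within <- ssd_within + acc / length(ii)
  }
  ssd_among <- ssd_total - ssd_within
  np <- as.numeric(table(factor(pops, levels = lev)))
  msd_among <- ssd_among / (k - 1)
  msd_within <- ssd_within / (n - k)
  n0 <- (n - sum(np^2) / n) / (k - 1)
  var_within <- msd_within
  var_among <- (msd_among - msd_within) / n0
  list(d = d, ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among, msd_among = msd_among, msd_within = msd_within,
       var_among = var_among, var_within = var_within,
       phi = var_among / (var_among + var_within))
}

# Independent mixture log-likelihood of binary data given memberships and
# cluster band frequencies (oracle for the sampler's recorded trace).
mixture_loglik <- function(x, q, f) {
  ll <- 0
  for (i in seq_len(nrow(x))) {
    for (l in seq_len(ncol(x))) {
      if (is.na(x[i, l])) next
      lik <- if (x[i, l] == 1) f[, l] else 1 - f[, l]
      ll <- ll + log(sum(q[i, ] * lik))
    }
  }
  ll
}
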
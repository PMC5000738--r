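test_that("phenotype frequencies count bands over non-missing individuals", {
  m <- mk_matrix(list(c(1L, 1L), c(1L, 1L), c(0L, 1L), c(0L, NA)),
                 rep("P", 4))
  pf <- phenotype_frequencies(m)
  expect_equal(pf$band_freq, c(0.5, 1.0))
  expect_equal(pf$null_freq, c(0.5, 0.0))
  expect_equal(pf$n_scored, c(4L, 3L))
  expect_error(phenotype_frequencies(m, integer(0)), "empty scope")
})

test_that("frequencies on simulated data match a direct per-column recount", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 50, n_rapd = 40, n_issr = 10,
                    missing_rate = 0.05, seed = 21)
  ph <- sim$matrix$phenotypes
  pf <- phenotype_frequencies(sim$matrix)
  for (j in seq_len(ncol(ph))) {
    col <- ph[, j]
    expect_identical(pf$n_scored[j], sum(!is.na(col)))
    expect_equal(pf$band_freq[j], sum(col == 1L, na.rm = TRUE) / sum(!is.na(col)))
  }
})

test_that("allele frequencies are the square root of the null phenotype frequency", {
  af <- estimate_allele_freqs(c(0.25, 0, 0.49, 1))
  expect_equal(af$q_hat, c(0.5, 0, 0.7, 1))
  expect_equal(af$p_hat, c(0.5, 1, 0.3, 0))
  expect_equal(2 * af$p_hat[3] * af$q_hat[3], 0.42)
})

test_that("the Taylor bias correction raises q_hat and needs n", {
  plain <- estimate_allele_freqs(0.25)$q_hat
  corr <- estimate_allele_freqs(0.25, n = 20, correct = TRUE)$q_hat
  expect_gt(corr, plain)
  expect_equal(corr, sqrt(0.25) * (1 + (0.25 * 0.75 / 20) / (8 * 0.25^2)))
  expect_error(estimate_allele_freqs(0.25, correct = TRUE), "sample size")
  # correction vanishes as n grows
  expect_equal(estimate_allele_freqs(0.25, n = 1e8, correct = TRUE)$q_hat,
               plain, tolerance = 1e-6)
})

test_that("the 1 - 3/N usability filter applies per locus at its own n", {
  mk_stats <- function(bf, n) {
    data.frame(locus_id = seq_along(bf), band_freq = bf, n_scored = n)
  }
  expect_identical(nrow(lm_filter(mk_stats(0.6, 10L))), 1L)   # 0.6 < 0.7
  expect_identical(nrow(lm_filter(mk_stats(0.7, 10L))), 0L)   # boundary excluded
  expect_warning(lm_filter(mk_stats(0.2, 3L)), "degenerates")

  sim <- sim_matrix(n_pops = 2, n_per_pop = 12, n_rapd = 60, n_issr = 20,
                    missing_rate = 0.1, seed = 31)
  st <- locus_stats(sim$matrix)
  kept <- lm_filter(st)
  brute <- st$locus_id[st$band_freq < 1 - 3 / st$n_scored]
  expect_identical(kept$locus_id, brute)
  expect_identical(st$locus_id[st$lm_usable], brute)
})

test_that("polymorphism combines the 95% rule with the observed-both-phenotypes rule", {
  st <- function(col, n) locus_stats(mk_matrix(
    lapply(seq_len(n), function(i) col[i]), rep("P", n)))
  # both phenotypes seen: polymorphic regardless of frequency (39/40 bands)
  m40 <- mk_matrix(lapply(c(rep(1L, 39), 0L), function(x) x), rep("P", 40))
  expect_true(locus_stats(m40)$polymorphic)
  # fixed band: monomorphic (q_hat 0, major allele 1)
  mfix <- mk_matrix(lapply(rep(1L, 10), function(x) x), rep("P", 10))
  expect_false(locus_stats(mfix)$polymorphic)
  # fixed null: monomorphic
  mnull <- mk_matrix(lapply(rep(0L, 10), function(x) x), rep("P", 10))
  expect_false(locus_stats(mnull)$polymorphic)
  # intermediate frequency: polymorphic
  mhalf <- mk_matrix(lapply(rep(c(0L, 1L), 5), function(x) x), rep("P", 10))
  expect_true(locus_stats(mhalf)$polymorphic)
})

test_that("percent polymorphism reproduces printed primer-screen percentages", {
  tab <- read.delim(system.file("extdata", "chrysodracon_primer_counts.tsv",
                                package = "bandpop"))
  for (sp in unique(tab$species)) {
    sub <- tab[tab$species == sp & tab$level == "primer", ]
    res <- percent_polymorphism(sub)
    got_primer <- res$pct_polymorphic[res$level == "primer"]
    expect_identical(got_primer, as.numeric(sub$pct_printed))
    printed_sub <- tab[tab$species == sp & tab$level == "subtotal", ]
    got_sub <- res$pct_polymorphic[res$level == "subtotal"]
    expect_identical(got_sub[match(printed_sub$marker_system,
                                   res$marker_system[res$level == "subtotal"])],
                     as.numeric(printed_sub$pct_printed))
    printed_tot <- tab[tab$species == sp & tab$level == "total", ]
    expect_identical(res$pct_polymorphic[res$level == "total"],
                     as.numeric(printed_tot$pct_printed))
  }
  expect_error(percent_polymorphism(data.frame(
    primer = "X", marker_system = "RAPD", n_scored = 5, n_polymorphic = 6)),
    "exceed")
})

test_that("expected heterozygosity follows the closed forms", {
  # all loci fixed (null): mean H is 0
  mnull <- mk_matrix(lapply(1:10, function(i) c(0L, 0L)), rep("P", 10))
  expect_equal(expected_heterozygosity(mnull)$mean, 0)
  # fixed band loci with the filter off also give 0
  mband <- mk_matrix(lapply(1:10, function(i) c(1L, 1L)), rep("P", 10))
  expect_equal(expected_heterozygosity(mband, use_lm_filter = FALSE)$mean, 0)
  # one locus with null frequency 0.25: H = 2 * 0.5 * 0.5 = 0.5
  m <- mk_matrix(lapply(c(rep(1L, 12), rep(0L, 4)), function(x) x),
                 rep("P", 16))
  expect_equal(expected_heterozygosity(m)$mean, 0.5)
})

test_that("mean H over polymorphic loci dominates mean over all loci", {
  # exhaustive over tiny two-locus matrices containing a fixed locus
  for (k in 1:5) {
    col1 <- c(rep(1L, k), rep(0L, 6 - k))   # polymorphic locus
    col2 <- rep(0L, 6)                      # fixed locus
    m <- mk_matrix(lapply(1:6, function(i) c(col1[i], col2[i])), rep("P", 6))
    h_all <- expected_heterozygosity(m, which = "all",
                                     use_lm_filter = FALSE)$mean
    h_poly <- expected_heterozygosity(m, which = "polymorphic",
                                      use_lm_filter = FALSE)$mean
    expect_gte(h_poly, h_all)
  }
})

test_that("h_exp peaks at 0.5 and decreases monotonically toward the boundaries", {
  p <- seq(0, 1, by = 0.01)
  h <- 2 * p * (1 - p)
  expect_equal(h, 1 - (p^2 + (1 - p)^2))
  expect_equal(max(h), 0.5)
  expect_equal(p[which.max(h)], 0.5)
  left <- h[p <= 0.5]
  right <- h[p >= 0.5]
  expect_true(all(diff(left) > 0))
  expect_true(all(diff(right) < 0))
  expect_true(all(h[p %in% c(0, 1)] == 0))
})

test_that("the square-root estimator is consistent on HWE data", {
  set.seed(99)
  q_true <- 0.6
  n <- 500
  q_hat <- replicate(200, {
    geno <- rbinom(n, 2, 1 - q_true)        # amplified-allele copies
    null_freq <- mean(geno == 0)            # null/null homozygotes
    estimate_allele_freqs(null_freq)$q_hat
  })
  expect_lt(abs(mean(q_hat) - q_true), 0.02)
})

test_that("Shannon entropy per locus follows the closed form", {
  mkf <- function(f, n = 40) mk_matrix(
    lapply(c(rep(1L, round(f * n)), rep(0L, n - round(f * n))),
           function(x) x), rep("P", n))
  expect_equal(shannon_index(mkf(0.5))$mean, 1.0)
  expect_equal(shannon_index(mkf(0))$mean, 0)
  expect_equal(shannon_index(mkf(1))$mean, 0)
  expect_equal(shannon_index(mkf(0.25))$mean, 0.811278, tolerance = 1e-6)
})

test_that("diversity summaries are invariant to row and column permutations", {
  sim <- sim_matrix(n_pops = 3, n_per_pop = 8, n_rapd = 25, n_issr = 10,
                    seed = 41)
  m <- sim$matrix
  set.seed(1)
  m2 <- m[sample(nrow(m$phenotypes)), sample(ncol(m$phenotypes))]
  for (f in list(
    function(x) mean(locus_stats(x)$polymorphic),
    function(x) expected_heterozygosity(x)$mean,
    function(x) shannon_index(x)$mean
  )) {
    expect_equal(f(m), f(m2))
  }
})

test_that("pooling fixed-for-alternate-phenotype populations raises %P", {
  # population A fixed for the band, population B fixed for the null
  rows <- c(lapply(1:6, function(i) c(1L, 1L, 0L)),
            lapply(1:6, function(i) c(0L, 0L, 0L)))
  m <- mk_matrix(rows, rep(c("A", "B"), each = 6))
  pct <- function(scope) 100 * mean(locus_stats(m, scope)$polymorphic)
  per_pop <- c(pct(1:6), pct(7:12))
  expect_equal(per_pop, c(0, 0))
  expect_gt(pct(1:12), max(per_pop))
})

test_that("the diversity table matches an independently scripted recomputation", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = c(6, 8), n_rapd = 20, n_issr = 8,
                    seed = 51)
  m <- sim$matrix
  tab <- diversity_table(m)
  expect_identical(nrow(tab), 9L)  # (2 pops + all) x (RAPD, ISSR, combined)

  # direct recomputation of the pooled combined row with plain loops
  ph <- m$phenotypes
  f <- colMeans(ph == 1L)
  q <- sqrt(1 - f)
  h <- 2 * (1 - q) * q
  poly <- (f > 0 & f < 1) | pmax(q, 1 - q) < 0.95
  usable <- f < 1 - 3 / nrow(ph)
  ent <- function(x) if (x %in% c(0, 1)) 0 else -(x * log2(x) + (1 - x) * log2(1 - x))
  row <- tab[tab$scope == "all individuals" & tab$marker_system == "combined", ]
  expect_equal(row$pct_polymorphic, 100 * mean(poly))
  expect_equal(row$h_all, mean(h[usable]))
  expect_equal(row$h_poly, mean(h[usable & poly]))
  expect_equal(row$sdi, mean(vapply(f, ent, numeric(1))))

  # single-population matrix: population rows equal the pooled rows
  one <- m[m$populations == m$populations[1], ]
  t1 <- diversity_table(one)
  pop_rows <- t1[t1$scope != "all individuals", -1]
  all_rows <- t1[t1$scope == "all individuals", -1]
  rownames(pop_rows) <- rownames(all_rows) <- NULL
  expect_equal(pop_rows, all_rows)
})

test_that("per-population %P rarely exceeds the pooled %P on structured data", {
  viol <- 0L
  for (s in 1:20) {
    sim <- sim_matrix(n_pops = 3, n_per_pop = 10, n_rapd = 40, n_issr = 10,
                      fst = 0.3, seed = 100 + s)
    m <- sim$matrix
    pooled <- mean(locus_stats(m)$polymorphic)
    per_pop <- vapply(population_map(m), function(ii) {
      mean(locus_stats(m, ii)$polymorphic)
    }, numeric(1))
    if (any(per_pop > pooled + 1e-12)) viol <- viol + 1L
  }
  expect_lte(viol, 2L)
})
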
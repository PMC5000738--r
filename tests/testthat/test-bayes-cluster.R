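test_that("ln P(D) follows the penalised-mean closed form", {
  expect_equal(ln_prob_data(rep(-3.5, 10)), -3.5)          # zero variance
  expect_equal(ln_prob_data(c(-10, -12)), -12)             # mean -11, var 2
  set.seed(5)
  tr <- rnorm(500, -1000, 4)
  expect_equal(ln_prob_data(tr), mean(tr) - var(tr) / 2)
  expect_error(ln_prob_data(-10), "at least 2")
})

test_that("identical seeds and inputs reproduce identical runs", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 8, n_rapd = 25, n_issr = 5,
                    seed = 151)
  a <- gibbs_fit(sim$matrix, K = 2, burn_in = 50, n_mcmc = 100, seed = 42)
  b <- gibbs_fit(sim$matrix, K = 2, burn_in = 50, n_mcmc = 100, seed = 42)
  expect_identical(a$ln_like_trace, b$ln_like_trace)
  expect_identical(a$q_matrix, b$q_matrix)
  c3 <- gibbs_fit(sim$matrix, K = 2, burn_in = 50, n_mcmc = 100, seed = 43)
  expect_false(identical(a$ln_like_trace, c3$ln_like_trace))
})

test_that("q rows sum to one and frequencies stay inside (0, 1)", {
  sim <- sim_matrix(n_pops = 3, n_per_pop = 6, n_rapd = 20, n_issr = 10,
                    missing_rate = 0.1, seed = 161)
  r <- gibbs_fit(sim$matrix, K = 3, burn_in = 50, n_mcmc = 150, seed = 1)
  expect_equal(unname(rowSums(r$q_matrix)), rep(1, 18), tolerance = 1e-9)
  expect_true(all(r$cluster_freqs > 0 & r$cluster_freqs < 1))
  expect_true(all(is.finite(r$ln_like_trace)))
})

test_that("K = 1 collapses to the single-cluster Beta-Bernoulli model", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 10, n_rapd = 15, n_issr = 5,
                    seed = 171)
  m <- sim$matrix
  r <- gibbs_fit(m, K = 1, burn_in = 200, n_mcmc = 2000, seed = 9)
  expect_equal(unname(r$q_matrix[, 1]), rep(1, 20))

  # oracle: with K = 1 the trace is sum_l log f^x (1-f)^(1-x) with
  # f_l ~ Beta(1 + n1_l, 1 + n0_l); estimate its mean by direct MC
  set.seed(99)
  n1 <- colSums(m$phenotypes == 1L)
  n0 <- colSums(m$phenotypes == 0L)
  draws <- replicate(4000, {
    f <- rbeta(length(n1), 1 + n1, 1 + n0)
    sum(n1 * log(f) + n0 * log(1 - f))
  })
  expect_equal(mean(r$ln_like_trace), mean(draws),
               tolerance = 3 * sd(draws) / sqrt(length(draws)) +
                           3 * sd(r$ln_like_trace) / sqrt(200))

  # with K = 1 population labels cannot matter
  m2 <- m
  m2$populations <- rev(m$populations)
  r2 <- gibbs_fit(m2, K = 1, burn_in = 200, n_mcmc = 2000, seed = 9)
  expect_identical(r2$ln_like_trace, r$ln_like_trace)
})

test_that("duplicate individuals receive near-identical memberships", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 8, n_rapd = 40, n_issr = 10,
                    fst = 0.4, seed = 181)
  ph <- sim$matrix$phenotypes
  ph2 <- rbind(ph, dup = ph[1, ])
  rownames(ph2) <- c(rownames(ph), "dup1")
  m <- marker_matrix(ph2, c(sim$matrix$populations, sim$matrix$populations[1]))
  r <- gibbs_fit(m, K = 2, burn_in = 500, n_mcmc = 2000, seed = 3)
  expect_lt(max(abs(r$q_matrix[1, ] - r$q_matrix[nrow(ph2), ])), 0.05)
})

test_that("the recorded trace is the mixture log-likelihood (label-switching invariant)", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 5, n_rapd = 12, n_issr = 4,
                    missing_rate = 0.05, seed = 191)
  r <- gibbs_fit(sim$matrix, K = 3, burn_in = 10, n_mcmc = 20, seed = 2)
  ll <- mixture_loglik(sim$matrix$phenotypes, r$q_matrix, r$cluster_freqs)
  perm <- c(3, 1, 2)
  ll_perm <- mixture_loglik(sim$matrix$phenotypes,
                            r$q_matrix[, perm], r$cluster_freqs[perm, ])
  expect_equal(ll_perm, ll)
  # posterior means are averages, but the likelihood at the averages should
  # be on the scale of the recorded trace
  expect_lt(abs(ll - mean(r$ln_like_trace)) /
              abs(mean(r$ln_like_trace)), 0.25)
})

test_that("invalid model sizes are rejected", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 3, n_rapd = 8, n_issr = 2,
                    seed = 201)
  expect_error(gibbs_fit(sim$matrix, K = 0), "at least 1")
  expect_error(gibbs_fit(sim$matrix, K = 7), "exceeds")
})

test_that("the default K grid spans 1 to n_pops + 3 and reps are honoured", {
  sim4 <- sim_matrix(n_pops = 4, n_per_pop = 3, n_rapd = 8, n_issr = 2,
                     seed = 211)
  runs <- run_grid(sim4$matrix, reps = 2, burn_in = 2, n_mcmc = 4, seed = 1)
  expect_identical(sort(unique(vapply(runs, `[[`, 1L, "K"))), 1:7)
  expect_length(runs, 14L)

  sim5 <- sim_matrix(n_pops = 5, n_per_pop = 3, n_rapd = 8, n_issr = 2,
                     seed = 221)
  runs5 <- run_grid(sim5$matrix, reps = 2, burn_in = 2, n_mcmc = 4, seed = 1)
  expect_identical(sort(unique(vapply(runs5, `[[`, 1L, "K"))), 1:8)
  expect_length(runs5, 16L)
})

test_that("Evanno delta-K arithmetic matches hand-worked values", {
  fake_runs <- function(means, sds) {
    runs <- list()
    for (i in seq_along(means)) {
      for (v in means[i] + sds[i] * c(-1, 1) / sqrt(2)) {
        runs[[length(runs) + 1L]] <- list(K = i, ln_prob_data = v)
      }
    }
    runs
  }
  # L(K) linear in K: all second differences vanish
  lin <- evanno_delta_k(fake_runs(c(-30, -20, -10, 0), rep(1, 4)))
  expect_equal(lin$table$l_second[2:3], c(0, 0), tolerance = 1e-12)

  # worked example: L = {-100, -50, -45, -44}, sd = 1 -> delta K peaks at 2
  dk <- evanno_delta_k(fake_runs(c(-100, -50, -45, -44), rep(1, 4)))
  expect_equal(dk$table$delta_k[2], 45, tolerance = 1e-9)
  expect_identical(dk$best_k, 2L)

  # zero replicate sd excludes that K from the argmax, with a warning
  expect_warning(
    dk0 <- evanno_delta_k(fake_runs(c(-100, -50, -45, -44), c(1, 0, 1, 1))),
    "undefined")
  expect_identical(dk0$best_k, 3L)

  expect_error(evanno_delta_k(fake_runs(c(-1, -2), c(1, 1))), "consecutive")
})

test_that("two differentiated populations are recovered at K = 2", {
  sim <- sim_matrix(n_pops = 2, n_per_pop = 15, n_rapd = 80, n_issr = 20,
                    fst = 0.4, seed = 231)
  r <- gibbs_fit(sim$matrix, K = 2, burn_in = 300, n_mcmc = 700, seed = 11)
  pops <- sim$matrix$populations
  # majority cluster within each population
  maj <- vapply(unique(pops), function(p) {
    qm <- colMeans(r$q_matrix[pops == p, , drop = FALSE])
    which.max(qm)
  }, integer(1))
  expect_identical(sort(unname(maj)), 1:2)  # populations map to distinct clusters
  mean_member <- mean(vapply(seq_along(pops), function(i) {
    r$q_matrix[i, maj[[pops[i]]]]
  }, numeric(1)))
  expect_gt(mean_member, 0.9)

  # bar-plot records group by population
  bd <- barplot_data(r)
  expect_equal(sum(bd$proportion), nrow(r$q_matrix), tolerance = 1e-9)
  seg <- bd[bd$proportion > 0.5, ]
  consistent <- vapply(unique(pops), function(p) {
    cl <- seg$cluster[seg$population == p]
    max(table(cl)) / sum(pops == p)
  }, numeric(1))
  expect_gt(min(consistent), 0.9)
})

test_that("bar-plot records are complete and ordered by population", {
  sim <- sim_matrix(n_pops = 3, n_per_pop = 4, n_rapd = 10, n_issr = 5,
                    seed = 241)
  r <- gibbs_fit(sim$matrix, K = 1, burn_in = 10, n_mcmc = 20, seed = 1)
  bd <- barplot_data(r)
  expect_identical(nrow(bd), 12L)            # K = 1: one segment per bar
  expect_equal(bd$proportion, rep(1, 12))
  expect_identical(bd$population, rep(c("pop1", "pop2", "pop3"), each = 4))
})
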
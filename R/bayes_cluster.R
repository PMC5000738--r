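# STRUCTURE-style Bayesian admixture clustering for dominant binary data.
# Band phenotypes are modelled as haploid binary alleles (one observation
# per individual per locus), the common pragmatic treatment of RAPD/ISSR
# data; the genotypic recessive-allele model is deliberately out of scope.

#' Fit the Bayesian admixture model by Gibbs sampling
#'
#' Clusters individuals into \code{K} groups with admixture: each individual
#' carries membership proportions \code{q_i} (Dirichlet(alpha) prior, alpha
#' itself updated by a Metropolis step), each cluster carries per-locus band
#' frequencies (Beta(1,1) prior), and each band observation is assigned a
#' cluster of origin per sweep. Missing phenotypes are skipped in all
#' likelihood terms.
#'
#' Defaults are desk-scale (2,000 burn-in / 5,000 recorded sweeps); long
#' protocols (e.g. 100,000/100,000) are available through the arguments.
#'
#' @param m a \code{marker_matrix}.
#' @param K number of clusters, \code{1 <= K <= N}.
#' @param burn_in discarded sweeps.
#' @param n_mcmc recorded sweeps.
#' @param seed optional integer seed; identical seed and input give an
#'   identical run.
#' @param alpha_init,alpha_sd,alpha_max initial value, Metropolis proposal
#'   standard deviation, and upper prior bound of the admixture parameter.
#' @return object of class \code{"cluster_run"}: list with \code{K},
#'   \code{q_matrix} (N x K posterior-mean memberships, rows sum to 1),
#'   \code{cluster_freqs} (K x L posterior-mean band frequencies),
#'   \code{ln_like_trace}, \code{ln_prob_data}, \code{alpha_trace},
#'   \code{burn_in}, \code{n_mcmc}, \code{seed}, \code{populations}.
#' @export
gibbs_fit <- function(m, K, burn_in = 2000, n_mcmc = 5000, seed = NULL,
                      alpha_init = 1.0, alpha_sd = 0.025, alpha_max = 10) {
  stopifnot(inherits(m, "marker_matrix"))
  n <- nrow(m$phenotypes)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K = ", K, " exceeds the number of individuals (", n, ")")
  if (n_mcmc < 1L || burn_in < 0L) stop("need n_mcmc >= 1 and burn_in >= 0")
  x <- m$phenotypes
  x[is.na(x)] <- -1L
  if (!is.null(seed)) set.seed(seed)
  fit <- gibbs_admixture_cpp(x, as.integer(K), as.integer(burn_in),
                             as.integer(n_mcmc), alpha_init, alpha_sd,
                             alpha_max)
  q <- fit$q_mean / rowSums(fit$q_mean)
  dimnames(q) <- list(rownames(m$phenotypes), paste0("cluster", seq_len(K)))
  dimnames(fit$f_mean) <- list(paste0("cluster", seq_len(K)),
                               colnames(m$phenotypes))
  structure(
    list(K = as.integer(K), q_matrix = q, cluster_freqs = fit$f_mean,
         ln_like_trace = fit$ln_like_trace,
         ln_prob_data = ln_prob_data(fit$ln_like_trace),
         alpha_trace = fit$alpha_trace,
         burn_in = as.integer(burn_in), n_mcmc = as.integer(n_mcmc),
         seed = seed, populations = m$populations),
    class = "cluster_run"
  )
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf(
    "Admixture model fit: K = %d, %d individuals, %d loci\n",
    x$K, nrow(x$q_matrix), ncol(x$cluster_freqs)))
  cat(sprintf("Sweeps: %d burn-in + %d recorded; ln P(D) estimate = %.2f\n",
              x$burn_in, x$n_mcmc, x$ln_prob_data))
  hard <- apply(x$q_matrix, 1L, which.max)
  cat("Individuals per modal cluster:\n")
  print(table(factor(hard, levels = seq_len(x$K))))
  invisible(x)
}

#' Model log-evidence estimate from a log-likelihood trace
#'
#' The moment estimator \code{mean(trace) - var(trace)/2}: the penalised
#' mean that STRUCTURE reports as ln P(D), with \code{var} the sample
#' variance of the post-burn-in log-likelihoods.
#'
#' @param trace numeric vector of per-sweep log-likelihoods (length >= 2).
#' @return scalar estimate.
#' @export
ln_prob_data <- function(trace) {
  if (length(trace) < 2L) stop("need at least 2 recorded sweeps to estimate ln P(D)")
  mean(trace) - stats::var(trace) / 2
}

#' Replicate admixture fits over a grid of K
#'
#' Runs \code{reps} independently seeded fits for each K. The default grid
#' is \code{1:(number of populations + 3)}, the usual upper limit for
#' model-size exploration.
#'
#' @param m a \code{marker_matrix}.
#' @param k_values integer vector of K values; default \code{1:(n_pops + 3)}.
#' @param reps replicate runs per K.
#' @param burn_in,n_mcmc sweep counts per run.
#' @param seed integer seed for the whole grid; per-run sub-seeds are drawn
#'   from it.
#' @return list of \code{"cluster_run"} objects, class
#'   \code{"cluster_grid"}.
#' @export
run_grid <- function(m, k_values = NULL, reps = 5, burn_in = 2000,
                     n_mcmc = 5000, seed = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  if (is.null(k_values)) {
    k_values <- seq_len(length(unique(m$populations)) + 3L)
  }
  if (!length(k_values)) stop("k_values must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(reps), K = sort(unique(k_values)))
  subseeds <- sample.int(.Machine$integer.max, nrow(grid))
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    runs[[i]] <- gibbs_fit(m, K = grid$K[i], burn_in = burn_in,
                           n_mcmc = n_mcmc, seed = subseeds[i])
  }
  class(runs) <- "cluster_grid"
  runs
}

#' Evanno delta-K model-size selection
#'
#' Aggregates replicate ln P(D) estimates per K into the second-difference
#' statistic \code{delta_K = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))} and
#' selects the interior K maximising it. K values with zero replicate
#' standard deviation get an undefined delta_K and are excluded from the
#' argmax with a warning.
#'
#' @param runs a \code{"cluster_grid"} (or plain list of
#'   \code{"cluster_run"} objects) covering at least 3 consecutive K values
#'   with at least 2 replicates each.
#' @return object of class \code{"delta_k"}: list with \code{table} (K,
#'   n_reps, mean_lnp, sd_lnp, l_prime, l_second, delta_k) and
#'   \code{best_k}.
#' @export
evanno_delta_k <- function(runs) {
  ks <- vapply(runs, function(r) r$K, integer(1))
  lnp <- vapply(runs, function(r) r$ln_prob_data, numeric(1))
  kk <- sort(unique(ks))
  if (length(kk) < 3L || any(diff(kk) != 1L)) {
    stop("need at least 3 consecutive K values")
  }
  nrep <- vapply(kk, function(k) sum(ks == k), integer(1))
  if (any(nrep < 2L)) stop("need at least 2 replicate runs per K")
  mu <- vapply(kk, function(k) mean(lnp[ks == k]), numeric(1))
  sd_ <- vapply(kk, function(k) stats::sd(lnp[ks == k]), numeric(1))
  nk <- length(kk)
  l_prime <- c(NA, diff(mu))
  l_second <- rep(NA_real_, nk)
  delta <- rep(NA_real_, nk)
  for (i in 2:(nk - 1L)) {
    l_second[i] <- abs(mu[i + 1L] - 2 * mu[i] + mu[i - 1L])
    if (sd_[i] > 0) {
      delta[i] <- l_second[i] / sd_[i]
    } else {
      warning("sd(L(K)) = 0 at K = ", kk[i],
              "; delta_K undefined there", call. = FALSE)
    }
  }
  tab <- data.frame(K = kk, n_reps = nrep, mean_lnp = mu, sd_lnp = sd_,
                    l_prime = l_prime, l_second = l_second, delta_k = delta)
  best <- if (all(is.na(delta))) NA_integer_ else kk[which.max(delta)]
  structure(list(table = tab, best_k = best), class = "delta_k")
}

#' @export
print.delta_k <- function(x, ...) {
  tab <- x$table
  tab$mean_lnp <- round(tab$mean_lnp, 2)
  tab$sd_lnp <- round(tab$sd_lnp, 3)
  tab$l_prime <- round(tab$l_prime, 2)
  tab$l_second <- round(tab$l_second, 2)
  tab$delta_k <- round(tab$delta_k, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Best K by delta-K: %s\n",
              if (is.na(x$best_k)) "undefined" else x$best_k))
  invisible(x)
}

#' Stacked-membership bar-plot records
#'
#' Long-format records for a STRUCTURE-style membership bar plot from a
#' single run: individuals are ordered by population (first-appearance
#' order) and, within a population, by modal cluster then by its membership
#' (descending); each record is one coloured segment of one bar.
#'
#' @param run a \code{"cluster_run"}.
#' @param populations population labels; default those stored in the run.
#' @return data frame with columns \code{position} (bar index), \code{id},
#'   \code{population}, \code{cluster}, \code{proportion}.
#' @export
barplot_data <- function(run, populations = run$populations) {
  stopifnot(inherits(run, "cluster_run"))
  q <- run$q_matrix
  populations <- as.character(populations)
  stopifnot(length(populations) == nrow(q))
  modal <- apply(q, 1L, which.max)
  modal_q <- q[cbind(seq_len(nrow(q)), modal)]
  ord <- order(match(populations, unique(populations)), modal, -modal_q)
  out <- do.call(rbind, lapply(seq_along(ord), function(pos) {
    i <- ord[pos]
    data.frame(position = pos, id = rownames(q)[i],
               population = populations[i],
               cluster = colnames(q), proportion = as.numeric(q[i, ]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot stacked membership bars
#'
#' @param x a \code{"cluster_run"}.
#' @param populations population labels; default those stored in the run.
#' @param ... further arguments to [graphics::barplot()].
#' @export
plot.cluster_run <- function(x, populations = x$populations, ...) {
  bd <- barplot_data(x, populations)
  wide <- matrix(bd$proportion, nrow = x$K,
                 dimnames = list(unique(bd$cluster), NULL))
  graphics::barplot(wide, space = 0, border = NA, col = seq_len(x$K) + 1L,
                    ylab = "membership", ...)
  invisible(x)
}
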
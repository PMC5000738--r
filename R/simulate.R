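# Synthetic dominant-marker datasets with known truth. Population band-allele
# frequencies follow the Balding-Nichols Beta model around an ancestral
# frequency, diploid genotypes are Binomial(2, p), and the band phenotype is
# visible iff at least one amplified allele is carried (standard RAPD/ISSR
# dominance). The default design mirrors a 4-population survey with sample
# sizes (10, 10, 13, 20) scored at 180 RAPD + 49 ISSR loci and strong
# differentiation (F = 0.5).

#' Simulation configuration
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals sampled per population (recycled to
#'   \code{n_pops} when scalar).
#' @param loci_per_system named counts of RAPD-like and ISSR-like loci.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param ancestral_freq_range interval within (0, 1) for the uniform
#'   ancestral band-allele frequency.
#' @param admixture_alpha optional symmetric Dirichlet parameter; when set,
#'   each individual receives admixed membership proportions over the
#'   populations and each locus draws its population of origin from them.
#'   \code{NULL} (default) disables admixture.
#' @param missing_rate fraction of cells masked as missing, uniformly.
#' @param seed optional integer seed.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_pops = 4, n_per_pop = c(10, 10, 13, 20),
                       loci_per_system = c(RAPD = 180, ISSR = 49),
                       fst = 0.5, ancestral_freq_range = c(0.1, 0.9),
                       admixture_alpha = NULL, missing_rate = 0,
                       seed = NULL) {
  n_pops <- as.integer(n_pops)
  if (n_pops < 1L) stop("n_pops must be positive")
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, n_pops)
  n_per_pop <- as.integer(n_per_pop)
  if (length(n_per_pop) != n_pops || any(n_per_pop < 1L)) {
    stop("n_per_pop must give a positive count for each of the ", n_pops,
         " populations")
  }
  if (is.null(names(loci_per_system))) {
    names(loci_per_system) <- c("RAPD", "ISSR")[seq_along(loci_per_system)]
  }
  loci_per_system <- loci_per_system[loci_per_system > 0]
  if (!length(loci_per_system) || !all(names(loci_per_system) %in% c("RAPD", "ISSR"))) {
    stop("loci_per_system must be positive counts named RAPD and/or ISSR")
  }
  if (!(fst > 1e-6 && fst < 1 - 1e-6)) {
    stop("fst must lie strictly inside (0, 1); values this close to the ",
         "boundary make the Beta shape parameters degenerate - use e.g. ",
         "fst = 0.01 for near-panmixia")
  }
  r <- ancestral_freq_range
  if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1) {
    stop("ancestral_freq_range must be an interval strictly inside (0, 1)")
  }
  if (!is.null(admixture_alpha) && admixture_alpha <= 0) {
    stop("admixture_alpha must be positive (or NULL)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  structure(
    list(n_pops = n_pops, n_per_pop = n_per_pop,
         loci_per_system = as.integer(loci_per_system) |>
           stats::setNames(names(loci_per_system)),
         fst = fst, ancestral_freq_range = as.numeric(r),
         admixture_alpha = admixture_alpha,
         missing_rate = missing_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a flat key-value (YAML) file
#'
#' @param path file path; keys are the [sim_config()] arguments.
#' @return a \code{"sim_config"}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$loci_per_system)) {
    vals$loci_per_system <- unlist(vals$loci_per_system)
  }
  do.call(sim_config, vals)
}

# Beta draws around the ancestral frequency (no seeding; callers seed).
bn_freqs <- function(cfg, n_loci) {
  p0 <- stats::runif(n_loci, cfg$ancestral_freq_range[1],
                     cfg$ancestral_freq_range[2])
  ratio <- (1 - cfg$fst) / cfg$fst
  pk <- matrix(NA_real_, cfg$n_pops, n_loci)
  for (k in seq_len(cfg$n_pops)) {
    pk[k, ] <- stats::rbeta(n_loci, p0 * ratio, (1 - p0) * ratio)
  }
  list(ancestral = p0, pop_freqs = pk)
}

synthetic_locus_names <- function(cfg) {
  per_primer <- 16L
  out <- character(0)
  systems <- character(0)
  for (sys in names(cfg$loci_per_system)) {
    nl <- cfg$loci_per_system[[sys]]
    n_primers <- ceiling(nl / per_primer)
    prefix <- if (sys == "ISSR") "ISSR-90" else "OPS-"
    primers <- sprintf("%s%02d", prefix, seq_len(n_primers))
    primer_of <- rep(primers, each = per_primer)[seq_len(nl)]
    sizes <- integer(nl)
    for (p in primers) {
      ii <- which(primer_of == p)
      sizes[ii] <- sort(sample(seq(150L, 2400L, by = 10L), length(ii)))
    }
    out <- c(out, sprintf("%s_%dbp", primer_of, sizes))
    systems <- c(systems, rep(sys, nl))
  }
  list(ids = out, systems = systems)
}

#' Simulate per-population band-allele frequencies
#'
#' Ancestral frequencies are uniform on \code{ancestral_freq_range}; each
#' population's frequency at each locus is an independent
#' \code{Beta(p0 (1-F)/F, (1-p0)(1-F)/F)} draw (the Balding-Nichols model),
#' so \code{E[p_k] = p0} and \code{Var[p_k] = F p0 (1-p0)}.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{ancestral} (length-L vector) and
#'   \code{pop_freqs} (n_pops x L matrix).
#' @export
simulate_allele_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bn_freqs(cfg, sum(cfg$loci_per_system))
}

#' Simulate a dominant-marker dataset with known truth
#'
#' Draws population allele frequencies from the Balding-Nichols model,
#' diploid genotypes as \code{Binomial(2, p)} (with per-locus population of
#' origin drawn from Dirichlet memberships when admixture is enabled), and
#' scores the band phenotype as present iff at least one amplified allele is
#' carried, so the expected band frequency is \code{1 - (1 - p)^2}. Missing
#' cells are masked uniformly at \code{missing_rate}.
#'
#' @param cfg a [sim_config()].
#' @return list of class \code{"sim_dataset"} with \code{matrix} (a
#'   \code{marker_matrix}) and \code{truth} (ancestral and per-population
#'   frequencies, latent diploid genotypes, memberships, populations,
#'   config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- sum(cfg$loci_per_system)
  n <- sum(cfg$n_per_pop)
  freqs <- bn_freqs(cfg, L)
  pop_of <- rep(seq_len(cfg$n_pops), cfg$n_per_pop)
  pop_names <- sprintf("pop%d", seq_len(cfg$n_pops))

  memberships <- matrix(0, n, cfg$n_pops)
  if (is.null(cfg$admixture_alpha)) {
    memberships[cbind(seq_len(n), pop_of)] <- 1
  } else {
    g <- matrix(stats::rgamma(n * cfg$n_pops, shape = cfg$admixture_alpha),
                n, cfg$n_pops)
    memberships <- g / rowSums(g)
  }

  geno <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    origin <- if (is.null(cfg$admixture_alpha)) {
      rep(pop_of[i], L)
    } else {
      sample.int(cfg$n_pops, L, replace = TRUE, prob = memberships[i, ])
    }
    p <- freqs$pop_freqs[cbind(origin, seq_len(L))]
    geno[i, ] <- stats::rbinom(L, 2L, p)
  }
  ph <- matrix(as.integer(geno >= 1L), n, L)
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(n * L) < cfg$missing_rate
    ph[mask] <- NA_integer_
  }
  nm <- synthetic_locus_names(cfg)
  dimnames(ph) <- list(sprintf("ind%03d", seq_len(n)), nm$ids)
  rownames(geno) <- rownames(ph)
  colnames(geno) <- nm$ids
  m <- marker_matrix(ph, populations = pop_names[pop_of])
  structure(
    list(matrix = m,
         truth = list(ancestral = freqs$ancestral,
                      pop_freqs = freqs$pop_freqs,
                      genotypes = geno,
                      memberships = memberships,
                      populations = pop_names[pop_of],
                      config = cfg)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dominant-marker dataset (F =",
      x$truth$config$fst, ")\n")
  print(x$matrix)
  invisible(x)
}

#' Genotype-based F_ST from the simulation truth
#'
#' Weir-Cockerham variance-components estimator on the latent diploid
#' genotypes: per locus the among-population (a), between-individual (b)
#' and within-individual (c) components are formed from sample sizes,
#' allele frequencies and observed heterozygote proportions, and the
#' multi-locus estimate is \code{sum(a) / sum(a + b + c)}. This is the
#' oracle against which the dominant-phenotype Phi-ST is judged.
#'
#' @param truth the \code{truth} element of a [simulate_dataset()] result
#'   (needs \code{genotypes} and \code{populations}).
#' @return scalar F_ST estimate (NA with a warning when every locus is
#'   monomorphic).
#' @export
true_fst <- function(truth) {
  geno <- truth$genotypes
  pops <- factor(truth$populations, levels = unique(truth$populations))
  if (nlevels(pops) < 2L) stop("need at least two populations")
  ni <- as.numeric(table(pops))
  r <- nlevels(pops)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  idx <- split(seq_len(nrow(geno)), pops)
  num <- den <- 0
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]
    pi_ <- vapply(idx, function(ii) mean(g[ii]) / 2, numeric(1))
    hi <- vapply(idx, function(ii) mean(g[ii] == 1L), numeric(1))
    pbar <- sum(ni * pi_) / sum(ni)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) {
    warning("all loci monomorphic; F_ST undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}
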
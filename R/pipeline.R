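# End-to-end orchestration: each stage reads a marker-matrix file (or a
# simulation config), runs the corresponding analyses and writes plain TSV
# reports with a commented provenance header. All randomness in a stage
# flows from its single seed argument.

report_header <- function(stage, input, seed = NULL) {
  c(sprintf("# bandpop %s", as.character(utils::packageVersion("bandpop"))),
    sprintf("# stage: %s", stage),
    sprintf("# input: %s", input),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_input_matrix <- function(input) {
  if (inherits(input, "marker_matrix")) return(input)
  dialect <- if (grepl("\\.tsv$", input)) "tsv" else "csv"
  read_marker_matrix(input, dialect)
}

#' Simulate a dataset and write it to disk
#'
#' @param config a [sim_config()] or the path of a YAML key-value file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written (\code{markers.csv},
#'   \code{truth_freqs.tsv}, \code{truth_genotypes.tsv}).
#' @export
pipeline_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "sim_config")) config else read_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(cfg)
  mpath <- file.path(out_dir, "markers.csv")
  write_marker_matrix(sim$matrix, mpath, "csv")
  fr <- data.frame(locus_id = colnames(sim$matrix$phenotypes),
                   ancestral = sim$truth$ancestral,
                   t(sim$truth$pop_freqs))
  names(fr)[-(1:2)] <- sprintf("pop%d", seq_len(cfg$n_pops))
  hdr <- report_header("simulate", "sim_config", cfg$seed)
  fpath <- file.path(out_dir, "truth_freqs.tsv")
  write_report(fr, fpath, hdr)
  gt <- data.frame(id = rownames(sim$truth$genotypes),
                   population = sim$truth$populations,
                   sim$truth$genotypes, check.names = FALSE)
  gpath <- file.path(out_dir, "truth_genotypes.tsv")
  write_report(gt, gpath, hdr)
  invisible(c(mpath, fpath, gpath))
}

#' Primer and diversity reports
#'
#' Writes \code{primer_polymorphism.tsv} (scored and polymorphic marker
#' counts with percent polymorphism per primer, marker-system subtotals and
#' the grand total, species-wide scope) and \code{diversity.tsv}
#' (per-population and pooled %P, H, H(P), Shannon index split by marker
#' system).
#'
#' @param input a \code{marker_matrix} or marker-matrix file path.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
pipeline_stats <- function(input, out_dir) {
  m <- read_input_matrix(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- if (is.character(input)) basename(input) else "marker_matrix"
  st <- locus_stats(m)
  st$primer <- m$loci$primer[match(st$locus_id, m$loci$locus_id)]
  st$marker_system <- m$loci$marker_system[match(st$locus_id, m$loci$locus_id)]
  counts <- do.call(rbind, lapply(split(st, st$primer), function(s) {
    data.frame(primer = s$primer[1], marker_system = s$marker_system[1],
               n_scored = nrow(s), n_polymorphic = sum(s$polymorphic))
  }))
  counts <- counts[order(match(counts$primer, m$loci$primer)), ]
  pp <- percent_polymorphism(counts)
  p1 <- file.path(out_dir, "primer_polymorphism.tsv")
  write_report(pp, p1, report_header("stats", inp))
  p2 <- file.path(out_dir, "diversity.tsv")
  write_report(as.data.frame(diversity_table(m)), p2,
               report_header("stats", inp))
  invisible(c(p1, p2))
}

#' AMOVA report
#'
#' @param input a \code{marker_matrix} or file path.
#' @param out_dir output directory.
#' @param n_perm permutations for the Phi-ST test.
#' @param seed integer seed for the permutation streams.
#' @return invisibly, the path written (\code{amova.tsv}).
#' @export
pipeline_amova <- function(input, out_dir, n_perm = 999, seed = 1) {
  m <- read_input_matrix(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- if (is.character(input)) basename(input) else "marker_matrix"
  res <- amova_by_markerset(m, n_perm = n_perm, seed = seed)
  path <- file.path(out_dir, "amova.tsv")
  write_report(amova_table(res), path, report_header("amova", inp, seed))
  invisible(path)
}

#' Similarity and ordination reports
#'
#' Writes \code{similarity_populations.tsv} (population-averaged percent
#' similarity, lower triangle), \code{pco_coordinates.tsv} and
#' \code{pco_eigenvalues.tsv}.
#'
#' @param input a \code{marker_matrix} or file path.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
pipeline_similarity <- function(input, out_dir) {
  m <- read_input_matrix(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- if (is.character(input)) basename(input) else "marker_matrix"
  s <- gower_similarity(m)
  tab <- population_similarity_table(s, m$populations)
  hdr <- report_header("similarity", inp)
  p1 <- file.path(out_dir, "similarity_populations.tsv")
  write_report(data.frame(population = rownames(tab), tab,
                          check.names = FALSE), p1, hdr)
  ord <- pco(s, m$populations)
  coords <- data.frame(id = rownames(ord$points),
                       population = m$populations, ord$points,
                       check.names = FALSE)
  p2 <- file.path(out_dir, "pco_coordinates.tsv")
  write_report(coords, p2, hdr)
  eig <- data.frame(axis = seq_along(ord$eig), eigenvalue = ord$eig,
                    pct_variance = c(ord$pct_variance,
                                     rep(NA, length(ord$eig) -
                                           length(ord$pct_variance))))
  p3 <- file.path(out_dir, "pco_eigenvalues.tsv")
  write_report(eig, p3, hdr)
  invisible(c(p1, p2, p3))
}

#' Bayesian clustering reports
#'
#' Runs the admixture model over a K grid with replicates, writes the
#' Evanno table (\code{delta_k.tsv}), the membership matrix of the first
#' replicate at the selected K (\code{qmatrix.tsv}) and its bar-plot records
#' (\code{barplot_data.tsv}).
#'
#' @param input a \code{marker_matrix} or file path.
#' @param out_dir output directory.
#' @param k_values K grid; default \code{1:(n_pops + 3)}.
#' @param reps replicate runs per K.
#' @param burn_in,n_mcmc sweep counts per run.
#' @param seed integer seed for the whole grid.
#' @return invisibly, the paths written.
#' @export
pipeline_cluster <- function(input, out_dir, k_values = NULL, reps = 5,
                             burn_in = 2000, n_mcmc = 5000, seed = 1) {
  m <- read_input_matrix(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- if (is.character(input)) basename(input) else "marker_matrix"
  runs <- run_grid(m, k_values = k_values, reps = reps, burn_in = burn_in,
                   n_mcmc = n_mcmc, seed = seed)
  dk <- evanno_delta_k(runs)
  hdr <- report_header("cluster", inp, seed)
  p1 <- file.path(out_dir, "delta_k.tsv")
  write_report(dk$table, p1, c(hdr, sprintf("# best_k: %s", dk$best_k)))
  ks <- vapply(runs, function(r) r$K, integer(1))
  best_run <- runs[[which(ks == dk$best_k)[1L]]]
  p2 <- file.path(out_dir, "qmatrix.tsv")
  write_report(data.frame(id = rownames(best_run$q_matrix),
                          population = m$populations, best_run$q_matrix,
                          check.names = FALSE), p2,
               c(hdr, sprintf("# K: %d", best_run$K)))
  p3 <- file.path(out_dir, "barplot_data.tsv")
  write_report(barplot_data(best_run, m$populations), p3, hdr)
  invisible(c(p1, p2, p3))
}

#' Run the full analysis battery
#'
#' Simulates (when given a \code{sim_config}) or reads a marker matrix, then
#' runs the diversity, AMOVA, similarity/PCO and clustering stages into one
#' output directory.
#'
#' @param input a \code{marker_matrix}, marker-matrix file path, or
#'   \code{sim_config}.
#' @param out_dir output directory.
#' @param n_perm AMOVA permutations.
#' @param k_values,reps,burn_in,n_mcmc clustering grid settings.
#' @param seed master integer seed; stage seeds are derived from it.
#' @return invisibly, all paths written.
#' @export
run_pipeline <- function(input, out_dir, n_perm = 999, k_values = NULL,
                         reps = 5, burn_in = 2000, n_mcmc = 5000, seed = 1) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 2)
  if (inherits(input, "sim_config")) {
    pipeline_simulate(input, out_dir)
    input <- file.path(out_dir, "markers.csv")
  }
  paths <- c(
    pipeline_stats(input, out_dir),
    pipeline_amova(input, out_dir, n_perm = n_perm, seed = stage_seeds[1]),
    pipeline_similarity(input, out_dir),
    pipeline_cluster(input, out_dir, k_values = k_values, reps = reps,
                     burn_in = burn_in, n_mcmc = n_mcmc,
                     seed = stage_seeds[2])
  )
  invisible(paths)
}
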
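# Analysis of molecular variance on binary band phenotypes. Distances are
# squared Euclidean on 0/1 vectors, i.e. mismatch counts, the standard choice
# for dominant data; the variance partition follows the classical
# among/within two-level AMOVA with Phi-ST = sigma2_a / (sigma2_a + sigma2_w).

#' Pairwise squared distances between band phenotypes
#'
#' \code{d(i, j)} is the number of loci at which two individuals' phenotypes
#' differ, counted over loci scored in both; with missing data the mismatch
#' count is rescaled by \code{L_total / L_shared} so distances stay on a
#' common scale. On complete data this is exactly the squared Euclidean
#' distance between 0/1 rows.
#'
#' @param m a \code{marker_matrix} with at least two individuals.
#' @return symmetric numeric matrix with zero diagonal, dimnames the
#'   individual ids.
#' @export
squared_distance_matrix <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  ph <- m$phenotypes
  if (nrow(ph) < 2L) stop("need at least two individuals")
  L <- ncol(ph)
  obs <- !is.na(ph)
  x <- ph
  x[!obs] <- 0L
  storage.mode(x) <- "double"
  storage.mode(obs) <- "double"
  shared <- tcrossprod(obs)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1L, ]
    stop(sprintf("individuals %s and %s share no scored locus",
                 rownames(ph)[idx[1L]], rownames(ph)[idx[2L]]))
  }
  m11 <- tcrossprod(x)                 # both band present
  m00 <- tcrossprod(obs - x)           # both band absent
  mismatch <- shared - m11 - m00
  d <- mismatch * L / shared
  diag(d) <- 0
  dimnames(d) <- list(rownames(ph), rownames(ph))
  d
}

# SSD partition from a squared-distance matrix and a population index list.
ssd_partition <- function(d, pops) {
  n <- nrow(d)
  ssd_total <- sum(d[upper.tri(d)]) / n
  ssd_within <- sum(vapply(pops, function(ii) {
    if (length(ii) < 2L) return(0)
    dd <- d[ii, ii, drop = FALSE]
    sum(dd[upper.tri(dd)]) / length(ii)
  }, numeric(1)))
  c(total = ssd_total, within = ssd_within, among = ssd_total - ssd_within)
}

phi_from_partition <- function(ssd, pops, n) {
  k <- length(pops)
  df_a <- k - 1L
  df_w <- n - k
  msd_a <- ssd[["among"]] / df_a
  msd_w <- ssd[["within"]] / df_w
  np <- lengths(pops)
  n0 <- (n - sum(np^2) / n) / (k - 1)
  var_w <- msd_w
  var_a <- (msd_a - msd_w) / n0
  tot <- var_a + var_w
  phi_raw <- if (tot > 0) var_a / tot else NA_real_
  list(df_among = df_a, df_within = df_w, msd_among = msd_a, msd_within = msd_w,
       n0 = n0, var_among = var_a, var_within = var_w, phi_raw = phi_raw)
}

#' Two-level AMOVA with permutation test of Phi-ST
#'
#' Partitions the total sum of squared deviations into among- and
#' within-population components using the classical distance-based identity
#' \code{SSD_total = (1/N) sum_{i<j} d(i,j)} and
#' \code{SSD_within = sum_pops (1/N_p) sum_{i<j in pop} d(i,j)}. Variance
#' components follow from the mean squares with coefficient
#' \code{n0 = (N - sum N_p^2 / N) / (k - 1)}, and
#' \code{Phi_ST = sigma2_a / (sigma2_a + sigma2_w)}.
#'
#' Significance is assessed by permuting whole individuals across
#' populations: \code{p = (1 + #\{Phi_perm >= Phi_obs\}) / (1 + n_perm)},
#' so 999 permutations give a minimum attainable p of 0.001. A negative
#' among-population component is reported as computed
#' (\code{var_among}, \code{phi_raw}) with \code{phi_st} truncated at zero.
#'
#' @param d squared-distance matrix from [squared_distance_matrix()], or a
#'   \code{marker_matrix} (distances computed internally).
#' @param populations population labels, one per row of \code{d}; taken from
#'   the marker matrix when \code{d} is one.
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed optional integer seed for the permutation stream.
#' @return object of class \code{"amova"}: a list with the degrees of
#'   freedom, SSD/MSD components, variance components, percentages of total
#'   variance, \code{phi_st}, \code{phi_raw}, \code{p_value} and
#'   \code{n_perm}.
#' @export
amova <- function(d, populations = NULL, n_perm = 999, seed = NULL) {
  if (inherits(d, "marker_matrix")) {
    populations <- d$populations
    d <- squared_distance_matrix(d)
  }
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (is.null(populations) || length(populations) != n) {
    stop("need one population label per individual")
  }
  populations <- as.character(populations)
  pops <- split(seq_len(n), factor(populations, levels = unique(populations)))
  k <- length(pops)
  if (k < 2L) stop("AMOVA needs at least two populations")
  if (n < 2L) stop("AMOVA needs at least two individuals")

  ssd <- ssd_partition(d, pops)
  pf <- phi_from_partition(ssd, pops, n)
  tot <- pf$var_among + pf$var_within
  res <- list(
    n_individuals = n, n_populations = k,
    df_among = pf$df_among, df_within = pf$df_within,
    ssd_among = ssd[["among"]], ssd_within = ssd[["within"]],
    ssd_total = ssd[["total"]],
    msd_among = pf$msd_among, msd_within = pf$msd_within,
    var_among = pf$var_among, var_within = pf$var_within,
    pct_among = if (tot > 0) 100 * pf$var_among / tot else NA_real_,
    pct_within = if (tot > 0) 100 * pf$var_within / tot else NA_real_,
    phi_raw = pf$phi_raw,
    phi_st = if (is.na(pf$phi_raw)) NA_real_ else max(0, pf$phi_raw),
    p_value = NA_real_, n_perm = 0L
  )
  if (n_perm > 0L && !is.na(pf$phi_raw)) {
    res$p_value <- phi_permutation_test(d, populations, n_perm = n_perm,
                                        seed = seed,
                                        observed = pf$phi_raw)
    res$n_perm <- as.integer(n_perm)
  }
  class(res) <- "amova"
  res
}

#' Permutation test of population differentiation
#'
#' Permutes whole-individual population labels uniformly and recomputes
#' Phi-ST for each permutation; the p-value is
#' \code{(1 + #\{Phi_perm >= Phi_obs\}) / (1 + n_perm)}.
#'
#' @param d squared-distance matrix.
#' @param populations population labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @param observed observed Phi-ST; recomputed when NULL.
#' @return the permutation p-value.
#' @export
phi_permutation_test <- function(d, populations, n_perm = 999, seed = NULL,
                                 observed = NULL) {
  stopifnot(n_perm >= 1)
  n <- nrow(d)
  populations <- as.character(populations)
  lev <- unique(populations)
  phi_of <- function(lab) {
    pops <- split(seq_len(n), factor(lab, levels = lev))
    ssd <- ssd_partition(d, pops)
    phi_from_partition(ssd, pops, n)$phi_raw
  }
  if (is.null(observed)) observed <- phi_of(populations)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    ph <- phi_of(sample(populations))
    if (!is.na(ph) && ph >= observed) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' AMOVA per marker system and combined
#'
#' Runs the AMOVA separately on the RAPD loci, the ISSR loci and the
#' combined matrix. A marker system with no loci is omitted with a warning.
#'
#' @param m a \code{marker_matrix}.
#' @param n_perm permutations per analysis.
#' @param seed optional integer seed (one independent stream per analysis).
#' @return named list of \code{"amova"} objects
#'   (\code{RAPD}, \code{ISSR}, \code{combined}), class
#'   \code{"amova_set"}.
#' @export
amova_by_markerset <- function(m, n_perm = 999, seed = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  sets <- list(
    RAPD = which(m$loci$marker_system == "RAPD"),
    ISSR = which(m$loci$marker_system == "ISSR"),
    combined = seq_len(ncol(m$phenotypes))
  )
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, length(sets))
  out <- list()
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    if (!length(sets[[i]])) {
      warning("marker system ", nm, " has no loci; omitted", call. = FALSE)
      next
    }
    out[[nm]] <- amova(m[, sets[[i]]], n_perm = n_perm, seed = subseeds[i])
  }
  class(out) <- "amova_set"
  out
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA: %d individuals in %d populations\n",
              x$n_individuals, x$n_populations))
  tab <- data.frame(
    Source = c("Among populations", "Within populations", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SSD = round(c(x$ssd_among, x$ssd_within, x$ssd_total), 3),
    MSD = c(round(x$msd_among, 3), round(x$msd_within, 3), NA),
    VarComp = c(round(x$var_among, 3), round(x$var_within, 3), NA),
    pctT = c(round(x$pct_among, 1), round(x$pct_within, 1), NA)
  )
  print(tab, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f", x$phi_st))
  if (!is.na(x$phi_raw) && x$phi_raw < 0) {
    cat(sprintf(" (raw estimate %.4f truncated at 0)", x$phi_raw))
  }
  if (x$n_perm > 0L) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.amova_set <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Flatten an AMOVA set to a report table
#'
#' @param x an \code{"amova_set"} (or single \code{"amova"}).
#' @return data frame with one row per (source, analysis).
#' @export
amova_table <- function(x) {
  if (inherits(x, "amova")) x <- structure(list(combined = x), class = "amova_set")
  rows <- lapply(names(x), function(nm) {
    a <- x[[nm]]
    data.frame(
      source = c("Among Pops", "Within Pops"),
      analysis = nm,
      df = c(a$df_among, a$df_within),
      ssd = c(a$ssd_among, a$ssd_within),
      msd = c(a$msd_among, a$msd_within),
      var_comp = c(a$var_among, a$var_within),
      pct_total = c(a$pct_among, a$pct_within),
      p_value = c(a$p_value, a$p_value),
      phi_st = c(a$phi_st, NA_real_),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
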
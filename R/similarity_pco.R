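# Gower similarity and principal coordinates. For symmetric binary
# characters Gower's general coefficient reduces to simple matching (shared
# band absence counts as a match), and d = sqrt(1 - S) is guaranteed
# Euclidean-embeddable, so classical scaling of that distance is exact PCO.

#' Gower (simple-matching) similarity between individuals
#'
#' For symmetric binary band phenotypes Gower's general similarity
#' coefficient is the simple matching proportion:
#' \code{S(i, j) = matches / loci scored in both}. Missing cells are handled
#' by pairwise deletion.
#'
#' @param m a \code{marker_matrix} with at least two individuals.
#' @return symmetric numeric matrix in [0, 1] with unit diagonal.
#' @export
gower_similarity <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  ph <- m$phenotypes
  if (nrow(ph) < 2L) stop("need at least two individuals")
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
  matches <- tcrossprod(x) + tcrossprod(obs - x)
  s <- matches / shared
  diag(s) <- 1
  dimnames(s) <- list(rownames(ph), rownames(ph))
  s
}

#' Population-averaged similarity table
#'
#' Lower-triangular matrix of mean pairwise similarities expressed as
#' percentages: the diagonal is the mean within-population similarity
#' (self-pairs excluded), off-diagonals the mean between-population
#' similarity. Percentages are rounded half-up to integers. A singleton
#' population has no within-population pair, so its diagonal entry is NA.
#'
#' @param s similarity matrix from [gower_similarity()].
#' @param populations population labels, one per row of \code{s}.
#' @return k x k matrix (lower triangle filled) of integer percentages.
#' @export
population_similarity_table <- function(s, populations) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  populations <- as.character(populations)
  stopifnot(length(populations) == nrow(s))
  lev <- unique(populations)
  k <- length(lev)
  out <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (a in seq_len(k)) {
    ii <- which(populations == lev[a])
    if (length(ii) >= 2L) {
      sub <- s[ii, ii, drop = FALSE]
      out[a, a] <- round_half_up(100 * mean(sub[upper.tri(sub)]))
    }
    for (b in seq_len(a - 1L)) {
      jj <- which(populations == lev[b])
      out[a, b] <- round_half_up(100 * mean(s[ii, jj, drop = FALSE]))
    }
  }
  out
}

#' Principal coordinate analysis of a similarity matrix
#'
#' Classical metric scaling of \code{d = sqrt(1 - S)}: Gower double
#' centering of the squared-distance matrix, eigendecomposition, and
#' coordinates scaled by the square roots of the positive eigenvalues.
#' Percent variance per axis uses the positive eigenvalues as denominator;
#' negative eigenvalues (possible only with missing-data pairwise deletion)
#' are reported but carry no axes.
#'
#' @param s similarity matrix (from [gower_similarity()]) or a
#'   \code{marker_matrix}.
#' @param populations optional population labels stored for plotting; taken
#'   from the marker matrix when \code{s} is one.
#' @return object of class \code{"pco"}: list with \code{points} (N x m
#'   coordinates), \code{eig} (all eigenvalues, descending),
#'   \code{pct_variance} (per retained axis), \code{populations}.
#' @export
pco <- function(s, populations = NULL) {
  if (inherits(s, "marker_matrix")) {
    populations <- s$populations
    s <- gower_similarity(s)
  }
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  n <- nrow(s)
  d <- sqrt(pmax(1 - s, 0))
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0L) {
    pts <- matrix(0, n, 0, dimnames = list(rownames(s), NULL))
  } else {
    pts <- pts[, seq_len(min(ncol(pts), sum(pos))), drop = FALSE]
  }
  if (ncol(pts)) colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  pct <- if (any(pos)) 100 * eig[seq_len(ncol(pts))] / sum(eig[pos]) else numeric(0)
  structure(
    list(points = pts, eig = eig, pct_variance = pct,
         populations = populations),
    class = "pco"
  )
}

#' @export
print.pco <- function(x, ...) {
  cat(sprintf("Principal coordinate analysis: %d individuals, %d retained axes\n",
              nrow(x$points), ncol(x$points)))
  na <- min(5L, ncol(x$points))
  if (na > 0L) {
    cat("Percent variance, first axes:",
        paste(sprintf("%.1f%%", x$pct_variance[seq_len(na)]), collapse = ", "),
        "\n")
  }
  if (any(x$eig < -1e-8)) {
    cat(sprintf("Note: %d negative eigenvalues (min %.3g), excluded from axes\n",
                sum(x$eig < -1e-8), min(x$eig)))
  }
  invisible(x)
}

#' Scatter records for a PCO ordination plot
#'
#' @param r a \code{"pco"} object.
#' @param populations population labels; default those stored in \code{r}.
#' @param axes integer pair of axes to extract.
#' @return list with \code{data} (data frame: id, population, x, y) and
#'   \code{labels} (axis labels carrying percent variance).
#' @export
pco_plot_data <- function(r, populations = r$populations, axes = c(1, 2)) {
  stopifnot(inherits(r, "pco"), length(axes) == 2L)
  if (any(axes > ncol(r$points))) {
    stop("requested axes exceed the ", ncol(r$points), " retained axes")
  }
  data <- data.frame(
    id = rownames(r$points),
    population = if (is.null(populations)) NA_character_ else as.character(populations),
    x = r$points[, axes[1L]],
    y = r$points[, axes[2L]],
    stringsAsFactors = FALSE, row.names = NULL
  )
  labels <- sprintf("PCO axis %d (%.1f%%)", axes, r$pct_variance[axes])
  list(data = data, labels = labels)
}

#' Plot a PCO ordination
#'
#' @param x a \code{"pco"} object.
#' @param axes integer pair of axes.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.pco <- function(x, axes = c(1, 2), ...) {
  pd <- pco_plot_data(x, axes = axes)
  grp <- factor(pd$data$population)
  graphics::plot(pd$data$x, pd$data$y, col = as.integer(grp),
                 pch = 19, xlab = pd$labels[1L], ylab = pd$labels[2L], ...)
  if (nlevels(grp) > 1L) {
    graphics::legend("topright", legend = levels(grp),
                     col = seq_len(nlevels(grp)), pch = 19, bty = "n")
  }
  invisible(x)
}
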
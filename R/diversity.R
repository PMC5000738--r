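# Diversity statistics for dominant markers. Band absence is read as the
# null/null homozygote under HWE, so the null-allele frequency is the square
# root of the null-phenotype frequency; everything else follows from p + q = 1.

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-locus phenotype frequencies
#'
#' Counts band-present phenotypes per locus over a set of individuals,
#' ignoring missing cells (locuswise deletion).
#'
#' @param m a \code{marker_matrix}.
#' @param scope integer indices (or logical/character selector) of the
#'   individuals to include; default all.
#' @return data frame with one row per locus: \code{locus_id},
#'   \code{n_scored} (non-missing individuals), \code{band_freq},
#'   \code{null_freq}. Loci scored in no individual get \code{n_scored = 0}
#'   and \code{NA} frequencies; downstream summaries drop them.
#' @export
phenotype_frequencies <- function(m, scope = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  ph <- m$phenotypes
  if (!is.null(scope)) ph <- ph[scope, , drop = FALSE]
  if (nrow(ph) == 0L) stop("empty scope: no individuals selected")
  n <- colSums(!is.na(ph))
  bf <- ifelse(n > 0L, colSums(ph == 1L, na.rm = TRUE) / n, NA_real_)
  data.frame(
    locus_id = colnames(ph), n_scored = as.integer(n),
    band_freq = as.numeric(bf), null_freq = 1 - as.numeric(bf),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Allele frequencies from the null-phenotype frequency
#'
#' Under Hardy-Weinberg equilibrium the band-absent phenotype is the
#' null/null homozygote, observed with frequency q^2, so the null-allele
#' frequency is estimated as \code{q_hat = sqrt(null_freq)} and the amplified
#' (band) allele as \code{p_hat = 1 - q_hat}.
#'
#' The plain square root is biased upward at small sample sizes. Setting
#' \code{correct = TRUE} applies the first-order Taylor bias correction for
#' dominant markers, \code{q_hat * (1 + var(x)/(8 x^2))} with
#' \code{var(x) = x(1 - x)/n} the sampling variance of the null-phenotype
#' frequency \code{x}; it requires \code{n}. The correction is off by
#' default: the uncorrected estimator is what the heterozygosity identities
#' below assume.
#'
#' @param null_freq numeric vector of null-phenotype frequencies in [0, 1].
#' @param n sample sizes (non-missing individuals per locus); only needed
#'   when \code{correct = TRUE}.
#' @param correct logical; apply the Taylor bias correction.
#' @return data frame with columns \code{q_hat} and \code{p_hat}.
#' @examples
#' estimate_allele_freqs(0.25)   # q_hat 0.5, p_hat 0.5
#' @export
estimate_allele_freqs <- function(null_freq, n = NULL, correct = FALSE) {
  stopifnot(all(is.na(null_freq) | (null_freq >= 0 & null_freq <= 1)))
  q <- sqrt(null_freq)
  if (correct) {
    if (is.null(n)) stop("bias correction needs the per-locus sample size n")
    v <- null_freq * (1 - null_freq) / n
    adj <- ifelse(null_freq > 0, 1 + v / (8 * null_freq^2), 1)
    q <- pmin(q * adj, 1)
  }
  data.frame(q_hat = q, p_hat = 1 - q)
}

#' Per-locus statistics table
#'
#' The full per-locus summary used by every diversity report: phenotype and
#' allele frequencies, expected heterozygosity \code{h_exp = 2 p q}, the
#' polymorphism flag and the dominant-marker usability flag.
#'
#' A locus is polymorphic when its major allele frequency is below 0.95 or,
#' practically, when both phenotypes are observed in scope. \code{lm_usable}
#' flags loci whose band-phenotype frequency is strictly below
#' \code{1 - 3/n_scored}; dominant-marker allele-frequency and
#' heterozygosity summaries restrict to these to limit the small-sample bias
#' of the square-root estimator.
#'
#' @inheritParams phenotype_frequencies
#' @param correct logical; passed to [estimate_allele_freqs()].
#' @return data frame, one row per locus with a positive \code{n_scored}.
#' @export
locus_stats <- function(m, scope = NULL, correct = FALSE) {
  pf <- phenotype_frequencies(m, scope)
  pf <- pf[pf$n_scored > 0L, , drop = FALSE]
  af <- estimate_allele_freqs(pf$null_freq, n = pf$n_scored, correct = correct)
  pf$q_hat <- af$q_hat
  pf$p_hat <- af$p_hat
  pf$h_exp <- 2 * pf$p_hat * pf$q_hat
  both_seen <- pf$band_freq > 0 & pf$band_freq < 1
  pf$polymorphic <- pmax(pf$p_hat, pf$q_hat) < 0.95 | both_seen
  pf$lm_usable <- pf$band_freq < 1 - 3 / pf$n_scored
  row.names(pf) <- NULL
  pf
}

#' Dominant-marker usability filter
#'
#' Retains loci whose observed band frequency is strictly below
#' \code{1 - 3/N}, each locus judged at its own non-missing sample size.
#' With fewer than 4 scored individuals the bound is at or below 0.25 and
#' the rule degenerates; the filter still applies it literally but warns.
#'
#' @param stats a [locus_stats()] data frame.
#' @return the retained subset of \code{stats}.
#' @export
lm_filter <- function(stats) {
  stopifnot(all(c("band_freq", "n_scored") %in% names(stats)))
  if (any(stats$n_scored < 4L)) {
    warning("loci with n_scored < 4: the 1 - 3/N bound is <= 0.25 and the filter degenerates",
            call. = FALSE)
  }
  stats[stats$band_freq < 1 - 3 / stats$n_scored, , drop = FALSE]
}

#' Percent polymorphism from per-primer counts
#'
#' Given the number of scored markers and the number of polymorphic markers
#' per primer, reports percent polymorphism per primer, per marker-system
#' subtotal (pooled counts) and the grand total, with percentages rounded
#' half-up to integers.
#'
#' @param counts data frame with columns \code{primer},
#'   \code{marker_system}, \code{n_scored}, \code{n_polymorphic}.
#' @return data frame with columns \code{level} ("primer", "subtotal",
#'   "total"), \code{primer}, \code{marker_system}, \code{n_scored},
#'   \code{n_polymorphic}, \code{pct_polymorphic}.
#' @export
percent_polymorphism <- function(counts) {
  req <- c("primer", "marker_system", "n_scored", "n_polymorphic")
  stopifnot(all(req %in% names(counts)))
  if (any(counts$n_scored <= 0L)) stop("n_scored must be positive")
  if (any(counts$n_polymorphic > counts$n_scored)) {
    stop("n_polymorphic cannot exceed n_scored")
  }
  pct <- function(p, n) round_half_up(100 * p / n)
  rows <- data.frame(
    level = "primer", primer = counts$primer,
    marker_system = counts$marker_system,
    n_scored = counts$n_scored, n_polymorphic = counts$n_polymorphic,
    pct_polymorphic = pct(counts$n_polymorphic, counts$n_scored),
    stringsAsFactors = FALSE
  )
  for (sys in unique(counts$marker_system)) {
    sub <- counts[counts$marker_system == sys, ]
    rows <- rbind(rows, data.frame(
      level = "subtotal", primer = NA_character_, marker_system = sys,
      n_scored = sum(sub$n_scored), n_polymorphic = sum(sub$n_polymorphic),
      pct_polymorphic = pct(sum(sub$n_polymorphic), sum(sub$n_scored))
    ))
  }
  rows <- rbind(rows, data.frame(
    level = "total", primer = NA_character_, marker_system = NA_character_,
    n_scored = sum(counts$n_scored), n_polymorphic = sum(counts$n_polymorphic),
    pct_polymorphic = pct(sum(counts$n_polymorphic), sum(counts$n_scored))
  ))
  rows
}

#' Expected heterozygosity summary
#'
#' Mean expected heterozygosity \code{H = 2 p q = 1 - (p^2 + q^2)} over a
#' locus set: all scored loci or polymorphic loci only, optionally after the
#' dominant-marker \code{1 - 3/N} usability filter (the default, since the
#' square-root allele-frequency estimator is what H is built from).
#'
#' @inheritParams phenotype_frequencies
#' @param which \code{"all"} or \code{"polymorphic"} loci.
#' @param use_lm_filter logical; restrict to [lm_filter()]-usable loci first.
#' @return list with \code{mean} (NA when no locus qualifies) and
#'   \code{per_locus} (data frame of the loci used).
#' @export
expected_heterozygosity <- function(m, scope = NULL,
                                    which = c("all", "polymorphic"),
                                    use_lm_filter = TRUE) {
  which <- match.arg(which)
  st <- locus_stats(m, scope)
  if (use_lm_filter) st <- suppressWarnings(lm_filter(st))
  if (which == "polymorphic") st <- st[st$polymorphic, , drop = FALSE]
  list(mean = if (nrow(st)) mean(st$h_exp) else NA_real_, per_locus = st)
}

#' Shannon diversity index over band phenotypes
#'
#' Per locus, the base-2 entropy of the two phenotype frequencies,
#' \code{-[f log2 f + (1 - f) log2(1 - f)]} with \code{f} the band frequency
#' and the convention \code{0 log2 0 = 0}; the summary is the arithmetic
#' mean over loci. Maximal (1 bit) at \code{f = 0.5}, zero at fixation.
#'
#' @inheritParams phenotype_frequencies
#' @return list with \code{mean} and \code{per_locus} (locus_id, sdi).
#' @export
shannon_index <- function(m, scope = NULL) {
  pf <- phenotype_frequencies(m, scope)
  pf <- pf[pf$n_scored > 0L, , drop = FALSE]
  ent <- function(f) {
    terms <- cbind(f, 1 - f)
    -rowSums(ifelse(terms > 0, terms * log2(terms), 0))
  }
  sdi <- ent(pf$band_freq)
  list(mean = if (length(sdi)) mean(sdi) else NA_real_,
       per_locus = data.frame(locus_id = pf$locus_id, sdi = sdi))
}

#' Diversity table by population and marker system
#'
#' One row per scope (each population plus all individuals pooled) and
#' marker-system slice (RAPD, ISSR, combined): percent polymorphic markers,
#' mean expected heterozygosity over all usable markers (H) and over the
#' polymorphic usable markers (H(P)), and the Shannon index. Pooling all
#' individuals gives the species-level values (H_T); per-population rows are
#' the within-population values (H_S).
#'
#' @param m a \code{marker_matrix}.
#' @return data frame of class \code{"diversity_table"}.
#' @export
diversity_table <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  pm <- population_map(m)
  scopes <- c(pm, list(`all individuals` = seq_along(m$populations)))
  systems <- list(
    RAPD = which(m$loci$marker_system == "RAPD"),
    ISSR = which(m$loci$marker_system == "ISSR"),
    combined = seq_len(ncol(m$phenotypes))
  )
  rows <- list()
  for (sc in names(scopes)) {
    for (sys in names(systems)) {
      jj <- systems[[sys]]
      if (!length(jj)) next
      sub <- m[, jj]
      st <- locus_stats(sub, scopes[[sc]])
      usable <- suppressWarnings(lm_filter(st))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, marker_system = sys,
        n_loci = nrow(st),
        pct_polymorphic = if (nrow(st)) 100 * mean(st$polymorphic) else NA_real_,
        h_all = if (nrow(usable)) mean(usable$h_exp) else NA_real_,
        h_poly = if (any(usable$polymorphic)) {
          mean(usable$h_exp[usable$polymorphic])
        } else NA_real_,
        sdi = shannon_index(sub, scopes[[sc]])$mean,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
print.diversity_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$pct_polymorphic <- round_half_up(y$pct_polymorphic, 1)
  for (cc in c("h_all", "h_poly", "sdi")) y[[cc]] <- round(y[[cc]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
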
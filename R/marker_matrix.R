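#' Construct a dominant-marker matrix
#'
#' The central data container of the package: an individuals-by-loci matrix of
#' binary band phenotypes (1 = band present, 0 = band absent, `NA` = not
#' scored) together with a population label per individual and per-locus
#' metadata (primer, marker system, fragment size).
#'
#' Locus metadata is parsed from locus identifiers following the convention
#' \code{"<PRIMER>_<size>bp"} (e.g. \code{"OPA-02_850bp"},
#' \code{"ISSR-5007_400bp"}). Primers whose name starts with \code{"ISSR"} are
#' classified as ISSR markers, everything else as RAPD. Identifiers that do
#' not follow the convention fall back to marker system RAPD with a warning.
#'
#' @param phenotypes integer/numeric matrix with entries in \{0, 1, NA\};
#'   rows are individuals, columns are loci. Row and column names are used as
#'   individual and locus identifiers (generated when absent).
#' @param populations character vector of population labels, one per row.
#' @param loci optional data frame of locus metadata with columns
#'   \code{locus_id}, \code{primer}, \code{marker_system}, \code{size_bp};
#'   parsed from column names when omitted.
#' @return An object of class \code{"marker_matrix"}: a list with elements
#'   \code{phenotypes} (integer matrix), \code{populations} (character) and
#'   \code{loci} (data frame).
#' @examples
#' x <- matrix(c(1, 1, 0, 0, 1, NA), nrow = 3,
#'             dimnames = list(paste0("ind", 1:3), c("OPA-01_500bp", "OPA-01_900bp")))
#' m <- marker_matrix(x, populations = c("A", "A", "B"))
#' m
#' @export
marker_matrix <- function(phenotypes, populations, loci = NULL) {
  if (!is.matrix(phenotypes)) {
    phenotypes <- as.matrix(phenotypes)
  }
  if (nrow(phenotypes) < 1L || ncol(phenotypes) < 1L) {
    stop("marker matrix must have at least one individual and one locus")
  }
  bad <- !(phenotypes %in% c(0, 1) | is.na(phenotypes))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(phenotypes)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "phenotype entries must be 0, 1 or NA; offending value '%s' at row %d, column %d",
      phenotypes[idx[1L], idx[2L]], idx[1L], idx[2L]
    ))
  }
  storage.mode(phenotypes) <- "integer"
  if (is.null(rownames(phenotypes))) {
    rownames(phenotypes) <- paste0("ind", seq_len(nrow(phenotypes)))
  }
  if (is.null(colnames(phenotypes))) {
    colnames(phenotypes) <- paste0("locus", seq_len(ncol(phenotypes)))
  }
  if (anyDuplicated(rownames(phenotypes))) {
    dup <- unique(rownames(phenotypes)[duplicated(rownames(phenotypes))])
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(phenotypes))) {
    dup <- unique(colnames(phenotypes)[duplicated(colnames(phenotypes))])
    stop("duplicate locus id(s): ", paste(dup, collapse = ", "))
  }
  populations <- as.character(populations)
  if (length(populations) != nrow(phenotypes)) {
    stop("need one population label per individual")
  }
  if (anyNA(populations) || any(!nzchar(populations))) {
    stop("every individual must carry a non-empty population label")
  }
  if (is.null(loci)) {
    loci <- parse_locus_info(colnames(phenotypes))
  } else {
    loci <- as.data.frame(loci, stringsAsFactors = FALSE)
    req <- c("locus_id", "primer", "marker_system", "size_bp")
    if (!all(req %in% names(loci))) {
      stop("locus metadata must have columns: ", paste(req, collapse = ", "))
    }
    loci <- loci[, req]
    if (nrow(loci) != ncol(phenotypes)) {
      stop("locus metadata must have one row per locus")
    }
    if (!all(loci$marker_system %in% c("RAPD", "ISSR"))) {
      stop("marker_system must be 'RAPD' or 'ISSR' for every locus")
    }
    loci$locus_id <- as.character(loci$locus_id)
    if (!identical(loci$locus_id, colnames(phenotypes))) {
      stop("locus metadata ids must match phenotype column names (same order)")
    }
  }
  rownames(loci) <- NULL
  structure(
    list(phenotypes = phenotypes, populations = populations, loci = loci),
    class = "marker_matrix"
  )
}

#' Parse locus metadata from identifier strings
#'
#' @param locus_ids character vector of locus identifiers.
#' @return data frame with columns \code{locus_id}, \code{primer},
#'   \code{marker_system}, \code{size_bp} (NA when unknown).
#' @keywords internal
parse_locus_info <- function(locus_ids) {
  pat <- "^(.+)_([0-9]+)bp$"
  ok <- grepl(pat, locus_ids)
  primer <- ifelse(ok, sub(pat, "\\1", locus_ids), NA_character_)
  size <- ifelse(ok, as.integer(sub(pat, "\\2", locus_ids)), NA_integer_)
  system <- ifelse(!is.na(primer) & startsWith(primer, "ISSR"), "ISSR", "RAPD")
  if (any(!ok)) {
    warning(sprintf(
      "%d locus id(s) do not follow the '<PRIMER>_<size>bp' convention; defaulting to marker system RAPD",
      sum(!ok)
    ), call. = FALSE)
  }
  data.frame(
    locus_id = as.character(locus_ids), primer = primer,
    marker_system = system, size_bp = as.integer(size),
    stringsAsFactors = FALSE
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  np <- length(unique(x$populations))
  cat(sprintf(
    "Dominant-marker matrix: %d individuals x %d loci (%d RAPD, %d ISSR), %d population%s\n",
    nrow(x$phenotypes), ncol(x$phenotypes),
    sum(x$loci$marker_system == "RAPD"), sum(x$loci$marker_system == "ISSR"),
    np, if (np == 1L) "" else "s"
  ))
  nmiss <- sum(is.na(x$phenotypes))
  if (nmiss > 0L) {
    cat(sprintf("Missing cells: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(x$phenotypes)))
  }
  tab <- table(x$populations)
  cat("Individuals per population:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.marker_matrix <- function(object, ...) {
  print(object)
  f <- colMeans(object$phenotypes, na.rm = TRUE)
  cat(sprintf("Band frequency per locus: min %.3f, median %.3f, max %.3f\n",
              min(f), stats::median(f), max(f)))
  invisible(object)
}

#' Subset a marker matrix
#'
#' @param x a \code{marker_matrix}.
#' @param i individual selector (indices, names or logical).
#' @param j locus selector.
#' @param ... ignored.
#' @return a \code{marker_matrix} restricted to the selected rows/columns.
#' @export
`[.marker_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$phenotypes))
  if (missing(j)) j <- seq_len(ncol(x$phenotypes))
  ph <- x$phenotypes[i, j, drop = FALSE]
  jj <- seq_len(ncol(x$phenotypes))
  names(jj) <- colnames(x$phenotypes)
  jidx <- jj[j]
  marker_matrix(ph, x$populations[i], loci = x$loci[jidx, , drop = FALSE])
}

#' Population map of a marker matrix
#'
#' @param m a \code{marker_matrix}.
#' @return named list, one element per population in first-appearance order,
#'   each the integer indices of its individuals.
#' @export
population_map <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  pops <- unique(m$populations)
  out <- lapply(pops, function(p) which(m$populations == p))
  names(out) <- pops
  out
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row \code{id, population, <locus1>, ...} and one row per
#' individual with cells in \{0, 1, NA\}. Column (locus) order from the file
#' is authoritative and never re-sorted: a dominant marker's identity is its
#' primer plus approximate fragment size, so ordering is part of the dataset.
#'
#' @param path file path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return a \code{marker_matrix}.
#' @export
read_marker_matrix <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3L || nrow(df) < 1L) {
    stop("empty or malformed marker file: need id, population and >= 1 locus column")
  }
  if (!identical(tolower(names(df)[1:2]), c("id", "population"))) {
    stop("first two columns must be 'id' and 'population'")
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- as.matrix(df[, -(1:2), drop = FALSE])
  ok <- body %in% c("0", "1", "NA")
  if (!all(ok)) {
    idx <- which(matrix(!ok, nrow(body)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid cell value '%s' at row %d, column %s (must be 0, 1 or NA)",
      body[idx[1L], idx[2L]], idx[1L], colnames(body)[idx[2L]]
    ))
  }
  ph <- matrix(suppressWarnings(as.integer(body)), nrow = nrow(body),
               dimnames = list(ids, colnames(body)))
  marker_matrix(ph, populations = df[[2L]])
}

#' Write a marker matrix to delimited text
#'
#' Inverse of [read_marker_matrix()]: the written file reads back to an equal
#' object, including the missing-data pattern (missing cells are the literal
#' token \code{NA}).
#'
#' @param m a \code{marker_matrix}.
#' @param path output file path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_marker_matrix <- function(m, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(m, "marker_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  body <- m$phenotypes
  chr <- matrix(as.character(body), nrow(body))
  chr[is.na(body)] <- "NA"
  out <- cbind(id = rownames(body), population = m$populations, chr)
  colnames(out) <- c("id", "population", colnames(body))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a marker matrix in STRUCTURE haploid format
#'
#' One row per individual: individual id, integer-coded population (coded by
#' first appearance, so runs are reproducible from the file alone), then one
#' allele code per locus with band present = 1, band absent = 0 and
#' missing = -9. Dominant band phenotypes carry one observation per
#' individual per locus, hence the haploid (one-row) encoding.
#'
#' @param m a \code{marker_matrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_structure <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  pops <- unique(m$populations)
  code <- match(m$populations, pops)
  body <- m$phenotypes
  body[is.na(body)] <- -9L
  lines <- paste(rownames(m$phenotypes), code,
                 apply(body, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Merge two marker sets scored on the same individuals
#'
#' Column-concatenates two matrices (e.g. the RAPD and the ISSR panel) after
#' matching individuals by id; the second matrix is reordered to the first's
#' individual order. Locus sets must be disjoint. Marker systems are weighted
#' equally: combined analyses simply see the union of columns.
#'
#' @param a,b \code{marker_matrix} objects over the same individuals.
#' @return a \code{marker_matrix} with \code{ncol(a) + ncol(b)} loci.
#' @export
merge_marker_sets <- function(a, b) {
  stopifnot(inherits(a, "marker_matrix"), inherits(b, "marker_matrix"))
  ia <- rownames(a$phenotypes)
  ib <- rownames(b$phenotypes)
  if (!setequal(ia, ib)) {
    stop("individual sets differ; only in first: [",
         paste(setdiff(ia, ib), collapse = ", "), "], only in second: [",
         paste(setdiff(ib, ia), collapse = ", "), "]")
  }
  if (length(common <- intersect(colnames(a$phenotypes), colnames(b$phenotypes)))) {
    stop("locus ids must be disjoint; shared: ", paste(common, collapse = ", "))
  }
  ord <- match(ia, ib)
  if (!identical(a$populations, b$populations[ord])) {
    stop("population labels disagree between the two marker sets")
  }
  ph <- cbind(a$phenotypes, b$phenotypes[ord, , drop = FALSE])
  marker_matrix(ph, a$populations, loci = rbind(a$loci, b$loci))
}
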
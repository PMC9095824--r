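#' Population-by-haplogroup frequency table
#'
#' @param values Numeric matrix; rows = populations, columns =
#'   haplogroups, entries = frequencies in `[0, 1]`. Row sums may fall
#'   short of 1 (the remainder is haplogroups not listed) but must not
#'   exceed it.
#' @return The matrix with class `frequency_table`.
#' @export
frequency_table <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0 | values > 1)) {
    bad <- rownames(values)[apply(values < 0 | values > 1, 1, any)]
    stop("frequencies outside [0, 1] in population(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rs <- rowSums(values)
  if (any(rs > 1 + 1e-9)) {
    bad <- rownames(values)[rs > 1 + 1e-9]
    stop("row sums exceed 1 for population(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(values, class = c("frequency_table", "matrix"))
}

#' Read a long-format reference frequency CSV
#'
#' Expects columns `population,haplogroup,frequency`.
#'
#' @param path CSV path.
#' @return A `frequency_table` (populations in file order, haplogroup
#'   columns sorted).
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "haplogroup", "frequency") %in% names(df)))
  pops <- unique(df$population)
  haps <- sort(unique(df$haplogroup))
  m <- matrix(0, nrow = length(pops), ncol = length(haps),
              dimnames = list(pops, haps))
  m[cbind(match(df$population, pops), match(df$haplogroup, haps))] <-
    df$frequency
  frequency_table(m)
}

#' Packaged synthetic reference frequency table
#'
#' A synthetic stand-in for published state-wise haplogroup frequencies
#' of 14 South Asian populations, generated by
#' [simulate_reference_frequencies()] from the packaged west-Eurasian
#' cline at a fixed seed. Population codes follow the usual regional
#' shorthand (Pak, Pun, Raj, Guj, Mah, Up, Bih, Jhk, WB, Mp, Cg, Odi,
#' Ap, Ker). Replace with real published frequencies for real analyses.
#'
#' @return A `frequency_table` of 14 populations.
#' @export
default_reference_frequencies <- function() {
  read_frequency_csv(system.file("extdata",
                                 "synthetic_reference_frequencies.csv",
                                 package = "paleoprov", mustWork = TRUE))
}

#' Append a cohort to a reference frequency table
#'
#' Takes the union of haplogroup columns (absent entries are 0) and
#' appends the cohort as one additional population row. Column order is
#' deterministic (sorted labels).
#'
#' @param reference A `frequency_table` (or matrix) of reference
#'   populations.
#' @param cohort_frequencies Named numeric vector of cohort haplogroup
#'   fractions, e.g. `call_cohort()$frequencies`.
#' @param cohort_id Row label for the cohort (default `"Aj"`).
#' @return A `frequency_table` with `nrow(reference) + 1` rows.
#' @export
build_frequency_matrix <- function(reference, cohort_frequencies,
                                   cohort_id = "Aj") {
  haps <- sort(union(colnames(reference), names(cohort_frequencies)))
  m <- matrix(0, nrow = nrow(reference) + 1L, ncol = length(haps),
              dimnames = list(c(rownames(reference), cohort_id), haps))
  m[seq_len(nrow(reference)), colnames(reference)] <- unclass(reference)
  m[cohort_id, names(cohort_frequencies)] <- cohort_frequencies
  frequency_table(m)
}

#' PCA of haplogroup frequencies
#'
#' Principal component analysis of the column-mean-centered frequency
#' matrix via singular value decomposition. Frequencies share a scale, so
#' columns are centered but not rescaled. Sign convention: within each
#' component the largest-magnitude loading is positive, making output
#' reproducible across platforms.
#'
#' @param table A `frequency_table` (populations x haplogroups).
#' @param n_components Number of components to keep (default
#'   `min(nrow - 1, ncol)`).
#' @return An object of class `pca_result`: list with `coordinates`
#'   (populations x components), `eigenvalues` (non-increasing; variances
#'   with denominator `nrow - 1`), `loadings` (haplogroups x components,
#'   orthonormal columns) and `explained_fraction`.
#' @export
pca_frequencies <- function(table, n_components = NULL) {
  x <- unclass(table)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 populations", call. = FALSE)
  maxc <- min(n - 1L, ncol(x))
  if (is.null(n_components)) n_components <- maxc
  if (n_components > maxc || n_components < 1) {
    stop("n_components must be in [1, ", maxc, "]", call. = FALSE)
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 0, nv = maxc)
  eig <- sv$d[seq_len(maxc)]^2 / (n - 1)
  total_var <- sum(apply(xc, 2, function(col) sum(col^2))) / (n - 1)
  load <- sv$v
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  coords <- xc %*% load
  comp_names <- paste0("PC", seq_len(maxc))
  dimnames(load) <- list(colnames(x), comp_names)
  dimnames(coords) <- list(rownames(x), comp_names)
  keep <- seq_len(n_components)
  structure(list(
    coordinates = coords[, keep, drop = FALSE],
    eigenvalues = eig[keep],
    loadings = load[, keep, drop = FALSE],
    explained_fraction = if (total_var > 0) eig[keep] / total_var
                         else rep(0, n_components)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$coordinates), "populations,",
      length(x$eigenvalues), "components\n")
  cat("explained:", paste0(sprintf("%.1f%%", 100 * x$explained_fraction),
                           collapse = " "), "\n")
  invisible(x)
}

#' Nearest reference populations in PC space
#'
#' Euclidean distance in the leading components (default PC1--PC2) from
#' one focal row to every other row, ascending.
#'
#' @param pca A `pca_result`.
#' @param focal Row label of the focal population (e.g. the cohort).
#' @param n_components Components used for the distance (default 2).
#' @return Named numeric vector of distances, nearest first.
#' @export
nearest_populations <- function(pca, focal, n_components = 2) {
  co <- pca$coordinates[, seq_len(min(n_components, ncol(pca$coordinates))),
                        drop = FALSE]
  if (!focal %in% rownames(co)) {
    stop("'", focal, "' is not a row of the PCA", call. = FALSE)
  }
  d <- sqrt(rowSums((co - matrix(co[focal, ], nrow(co), ncol(co),
                                 byrow = TRUE))^2))
  sort(d[names(d) != focal])
}
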
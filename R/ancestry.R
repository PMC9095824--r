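REGIONS <- c("SouthAsian", "WestEurasian", "EastEurasian", "Unclassified")

#' Region map: haplogroup-to-ancestry rules
#'
#' @param rules Data frame with character columns `pattern` (haplogroup
#'   label or label prefix) and `region` (one of `SouthAsian`,
#'   `WestEurasian`, `EastEurasian`, `Unclassified`).
#' @return The validated data frame with class `region_map`.
#' @export
region_map <- function(rules) {
  stopifnot(is.data.frame(rules), all(c("pattern", "region") %in% names(rules)))
  bad <- setdiff(unique(rules$region), REGIONS)
  if (length(bad) > 0) {
    stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  class(rules) <- c("region_map", "data.frame")
  rules
}

#' @describeIn region_map Read a `pattern,region` CSV.
#' @param path CSV file path.
#' @export
read_region_map <- function(path) {
  region_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

expand_numeric_range <- function(prefix, from, to) paste0(prefix, from:to)

#' Default regional-ancestry rules for South Asian mtDNA haplogroups
#'
#' Encodes the standard regional affiliations: South Asian (M2--M6, M18,
#' M25, M30--M67, N5, R5--R8, R30--R32, U2a, U2b), West Eurasian (HV, H,
#' J, K, R0, R1, R2, U1--U5, U7, U8, U9, W, X) and East Eurasian (the
#' macro-clades A through G, M7--M12, R22, N9). Numeric ranges expand to
#' explicit labels; lettered sub-clades inherit by prefix. The
#' East-Eurasian "A--G" set is alphabetic (the seven macro-clade letters),
#' not a numeric range. Sub-clade carve-outs (U2a/U2b are South Asian
#' although U2 falls in the West Eurasian U1--U5 block) are honoured by
#' the longest-pattern rule of [assign_region()].
#'
#' @return A `region_map`.
#' @export
default_region_map <- function() {
  sa <- c(expand_numeric_range("M", 2, 6), "M18", "M25",
          expand_numeric_range("M", 30, 67), "N5",
          expand_numeric_range("R", 5, 8),
          expand_numeric_range("R", 30, 32), "U2a", "U2b")
  we <- c("HV", "H", "J", "K", "R0", "R1", "R2",
          expand_numeric_range("U", 1, 5), "U7", "U8", "U9", "W", "X")
  ee <- c(LETTERS[1:7], expand_numeric_range("M", 7, 12), "R22", "N9")
  region_map(data.frame(
    pattern = c(sa, we, ee),
    region = rep(c("SouthAsian", "WestEurasian", "EastEurasian"),
                 c(length(sa), length(we), length(ee))),
    stringsAsFactors = FALSE))
}

# does rule pattern match a haplogroup label? exact, or prefix ending at a
# letter/digit class boundary (so "M37" matches "M37e" but "M3" does not
# match "M39")
pattern_matches <- function(pattern, label) {
  if (pattern == label) return(TRUE)
  if (!startsWith(label, pattern)) return(FALSE)
  last <- substr(pattern, nchar(pattern), nchar(pattern))
  nxt <- substr(label, nchar(pattern) + 1, nchar(pattern) + 1)
  grepl("[0-9]", last) != grepl("[0-9]", nxt)
}

#' Assign a haplogroup to a regional ancestry
#'
#' Walks the haplogroup's ancestor path (self first) and collects every
#' rule whose pattern matches a path label. The most specific rule wins:
#' longest pattern first, then the match closest to the queried label.
#' With no match the region is `Unclassified`.
#'
#' @param label Haplogroup label present in `tree`.
#' @param map A `region_map` (default [default_region_map()]).
#' @param tree A `haplo_tree`.
#' @return Region name (character scalar).
#' @export
assign_region <- function(label, map = default_region_map(), tree) {
  path <- rev(ancestor_path(tree, label)) # self, parent, ..., root
  best_region <- "Unclassified"
  best_len <- -1L
  best_depth <- -1L
  for (i in seq_along(path)) {
    lab <- path[i]
    depth <- length(path) - i # deeper labels matched earlier
    for (r in seq_len(nrow(map))) {
      pat <- map$pattern[r]
      if (!pattern_matches(pat, lab)) next
      len <- nchar(pat)
      if (len > best_len || (len == best_len && depth > best_depth)) {
        best_region <- map$region[r]
        best_len <- len
        best_depth <- depth
      }
    }
  }
  best_region
}

#' Regional ancestry proportions of a cohort
#'
#' @param calls A `cohort_calls`, a list of `haplogroup_call`, or a
#'   character vector of haplogroup labels.
#' @param map A `region_map`.
#' @param tree A `haplo_tree`.
#' @param cohort_id Label for the cohort (default `"cohort"`).
#' @return An object of class `ancestry_proportions`: list with
#'   `cohort_id`, `counts` and `fractions` (both named over the four
#'   regions; fractions sum to 1).
#' @export
ancestry_proportions <- function(calls, map = default_region_map(), tree,
                                 cohort_id = "cohort") {
  labels <- call_labels(calls)
  if (length(labels) == 0) stop("empty cohort", call. = FALSE)
  regions <- vapply(labels, assign_region, character(1), map = map,
                    tree = tree)
  counts <- stats::setNames(integer(length(REGIONS)), REGIONS)
  tab <- table(regions)
  counts[names(tab)] <- as.integer(tab)
  structure(list(cohort_id = cohort_id, counts = counts,
                 fractions = counts / sum(counts)),
            class = "ancestry_proportions")
}

call_labels <- function(calls) {
  if (inherits(calls, "cohort_calls")) calls <- calls$calls
  if (is.character(calls)) return(calls)
  vapply(calls, `[[`, character(1), "best")
}

#' @export
print.ancestry_proportions <- function(x, ...) {
  cat("Ancestry proportions for", x$cohort_id, "(n =", sum(x$counts), ")\n")
  for (r in names(x$fractions)) {
    cat(sprintf("  %-13s %3d  %.3f\n", r, x$counts[r], x$fractions[r]))
  }
  invisible(x)
}

#' Compare one ancestry component between two cohorts
#'
#' Fisher's exact test on the 2x2 table (focus region vs all other
#' regions, cohort A vs cohort B). The two-tailed p-value is the sum of
#' the probabilities of all tables with the observed margins that are no
#' more probable than the observed table.
#'
#' @param countsA,countsB Named integer vectors of region counts (as in
#'   `ancestry_proportions()$counts`).
#' @param focus Region name to compare (e.g. `"WestEurasian"`).
#' @return Two-tailed p-value in `(0, 1]`.
#' @export
compare_ancestry <- function(countsA, countsB, focus) {
  nA <- sum(countsA)
  nB <- sum(countsB)
  if (nA == 0 || nB == 0) stop("both cohorts must be non-empty", call. = FALSE)
  fA <- sum(countsA[focus], na.rm = TRUE)
  fB <- sum(countsB[focus], na.rm = TRUE)
  tab <- matrix(c(fA, nA - fA, fB, nB - fB), nrow = 2, byrow = TRUE,
                dimnames = list(cohort = c("A", "B"),
                                region = c(focus, "other")))
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}
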
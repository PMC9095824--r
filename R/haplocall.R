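#' Sample genotypes at panel positions
#'
#' @param sample_id Character scalar.
#' @param calls Named character vector: names are panel positions, values
#'   are bases `A/C/G/T` or `NA` for a failed (MISSING) call.
#' @return An object of class `sample_genotypes`.
#' @export
sample_genotypes <- function(sample_id, calls) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  vals <- unname(calls)
  ok <- is.na(vals) | vals %in% BASES
  if (!all(ok)) {
    stop("invalid allele call(s) for sample ", sample_id, ": ",
         paste(unique(vals[!ok]), collapse = ", "), call. = FALSE)
  }
  structure(list(sample_id = sample_id, calls = calls),
            class = "sample_genotypes")
}

# expected base at each panel position for one haplogroup, plus the rCRS
# base; positions absent from the profile are reference
panel_profile <- function(profile, panel_pos, ref) {
  key <- as.character(panel_pos)
  exp <- ref[key]
  hit <- intersect(names(profile$states), key)
  exp[hit] <- profile$states[hit]
  exp
}

# cache of per-haplogroup expected panel states; recomputed per (tree, panel)
build_profile_cache <- function(tree, panel) {
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)
  missing_ref <- key[is.na(ref[key])]
  if (length(missing_ref) > 0) {
    stop("no reference allele derivable from the tree for panel position(s) ",
         paste(utils::head(missing_ref, 5), collapse = ", "),
         "; supply an rCRS FASTA", call. = FALSE)
  }
  labels <- names(tree$nodes)
  profiles <- lapply(labels, function(lab) {
    panel_profile(expected_profile(tree, lab), panel$position, ref)
  })
  names(profiles) <- labels
  list(ref = ref[key], profiles = profiles,
       depth = vapply(tree$nodes, `[[`, integer(1), "depth"))
}

#' Score a sample against one haplogroup
#'
#' Kulczynski similarity between the sample's observed derived calls and
#' the haplogroup's expected derived states, over panel positions with a
#' successful call: the mean of recall (`n_matched / n_expected`) and
#' precision (`n_matched / n_observed_derived`), with the convention
#' `0/0 = 1` in either ratio. Positions with a MISSING call are excluded
#' from every count: an assay dropout is not evidence for the reference
#' state.
#'
#' @param sample A `sample_genotypes`.
#' @param label Haplogroup label in `tree`.
#' @param tree A `haplo_tree`.
#' @param panel A `panel_definition`.
#' @return Numeric score in `[0, 1]`, with attributes `n_expected`,
#'   `n_matched`, `n_observed_derived`.
#' @export
score_haplogroup <- function(sample, label, tree, panel) {
  cache <- build_profile_cache(tree, panel)
  if (is.null(cache$profiles[[label]])) {
    stop("unknown haplogroup label '", label, "'", call. = FALSE)
  }
  score_against_profile(sample, cache$profiles[[label]], cache$ref)
}

score_against_profile <- function(sample, expected, ref) {
  key <- names(ref)
  obs <- sample$calls[key]
  eval_mask <- !is.na(obs)
  if (!any(eval_mask)) {
    stop("sample '", sample$sample_id,
         "' has no evaluable panel positions (all calls MISSING)",
         call. = FALSE)
  }
  exp_derived <- expected != ref & eval_mask
  obs_derived <- obs != ref & eval_mask
  matched <- exp_derived & obs_derived & obs == expected
  n_exp <- sum(exp_derived)
  n_obs <- sum(obs_derived)
  n_match <- sum(matched)
  recall <- if (n_exp == 0) 1 else n_match / n_exp
  precision <- if (n_obs == 0) 1 else n_match / n_obs
  structure(0.5 * (recall + precision),
            n_expected = n_exp, n_matched = n_match,
            n_observed_derived = n_obs)
}

#' Call the best haplogroup for a sample
#'
#' Scores the sample against every haplogroup in the tree and returns the
#' argmax. Ties are broken towards the deeper (more derived) node, then
#' lexicographically, so output is deterministic.
#'
#' @inheritParams score_haplogroup
#' @param k Number of ranked alternatives to report (default 5).
#' @param cache Optional precomputed profile cache (internal reuse).
#' @return An object of class `haplogroup_call`: list with `sample_id`,
#'   `best`, `score`, `n_expected`, `n_matched`, `n_observed_derived` and
#'   `alternatives` (data frame `label`, `score`).
#' @export
call_haplogroup <- function(sample, tree, panel, k = 5, cache = NULL) {
  if (is.null(cache)) cache <- build_profile_cache(tree, panel)
  labels <- names(cache$profiles)
  scores <- numeric(length(labels))
  stats <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- score_against_profile(sample, cache$profiles[[labels[i]]], cache$ref)
    scores[i] <- as.numeric(s)
    stats[[i]] <- attributes(s)
  }
  ord <- order(-scores, -cache$depth[labels], labels, method = "radix")
  best_i <- ord[1]
  alt <- utils::head(ord[-1], k)
  structure(list(
    sample_id = sample$sample_id,
    best = labels[best_i],
    score = scores[best_i],
    n_expected = stats[[best_i]]$n_expected,
    n_matched = stats[[best_i]]$n_matched,
    n_observed_derived = stats[[best_i]]$n_observed_derived,
    alternatives = data.frame(label = labels[alt], score = scores[alt],
                              stringsAsFactors = FALSE)
  ), class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("%s -> %s (score %.3f; %d/%d expected variants matched)\n",
              x$sample_id, x$best, x$score, x$n_matched, x$n_expected))
  invisible(x)
}

#' Call haplogroups for a cohort and tabulate frequencies
#'
#' @param samples List of `sample_genotypes`.
#' @param tree A `haplo_tree`.
#' @param panel A `panel_definition`.
#' @param k Alternatives per call (see [call_haplogroup()]).
#' @param macros Macrohaplogroup set passed to [macro_of()].
#' @return A list of class `cohort_calls` with elements `calls` (list of
#'   `haplogroup_call`), `frequencies` (named numeric, haplogroup fractions
#'   over called labels, summing to 1) and `macro_frequencies` (fractions
#'   by macrohaplogroup).
#' @export
call_cohort <- function(samples, tree, panel, k = 5,
                        macros = c(paste0("L", 0:6), "M", "N", "R")) {
  if (length(samples) == 0) stop("empty cohort", call. = FALSE)
  cache <- build_profile_cache(tree, panel)
  calls <- lapply(samples, call_haplogroup, tree = tree, panel = panel,
                  k = k, cache = cache)
  labels <- vapply(calls, `[[`, character(1), "best")
  freq <- table(labels) / length(labels)
  macro <- vapply(labels, macro_of, character(1), tree = tree, macros = macros)
  mfreq <- table(macro) / length(macro)
  structure(list(calls = calls,
                 frequencies = c(freq)[sort(names(freq))],
                 macro_frequencies = c(mfreq)[sort(names(mfreq))]),
            class = "cohort_calls")
}

#' Convert cohort calls to a data frame
#'
#' @param x A `cohort_calls` or list of `haplogroup_call`.
#' @param ... Unused.
#' @return Data frame with one row per sample: `sample_id`, `haplogroup`,
#'   `score`, `n_expected`, `n_matched`, `n_observed_derived`.
#' @export
as.data.frame.cohort_calls <- function(x, ...) {
  calls_to_df(x$calls)
}

calls_to_df <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(sample_id = cl$sample_id, haplogroup = cl$best,
               score = cl$score, n_expected = cl$n_expected,
               n_matched = cl$n_matched,
               n_observed_derived = cl$n_observed_derived,
               stringsAsFactors = FALSE)
  }))
}

#' Read genotype calls from long-format CSV
#'
#' Expects columns `sample_id,position,allele`; a MISSING call is an empty
#' allele field or `"N"`. Positions outside the panel are dropped.
#'
#' @param path CSV path.
#' @param panel A `panel_definition`.
#' @return List of `sample_genotypes`, one per distinct sample, with every
#'   panel position present (`NA` where unreported or MISSING).
#' @export
read_genotypes_csv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele = "character"))
  stopifnot(all(c("sample_id", "position", "allele") %in% names(df)))
  df$allele[df$allele %in% c("", "N", "n")] <- NA_character_
  df$allele <- toupper(df$allele)
  df <- df[df$position %in% panel$position, , drop = FALSE]
  key <- as.character(panel$position)
  lapply(split(df, df$sample_id), function(d) {
    calls <- stats::setNames(rep(NA_character_, length(key)), key)
    calls[as.character(d$position)] <- d$allele
    sample_genotypes(d$sample_id[1], calls)
  })
}

#' Read genotype calls from a VCF file
#'
#' Requires the `vcfR` package. Diploid genotypes are collapsed to haploid
#' by majority allele; at ploidy 2 a heterozygous call has no majority and
#' becomes MISSING. Sites outside the panel and non-SNP alleles are
#' ignored.
#'
#' @param path VCF path (plain or bgzipped).
#' @param panel A `panel_definition`.
#' @return List of `sample_genotypes`.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  pos <- as.integer(vcfR::getPOS(v))
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- pos %in% panel$position & nchar(ref) == 1
  key <- as.character(panel$position)
  lapply(colnames(gt), function(sm) {
    calls <- stats::setNames(rep(NA_character_, length(key)), key)
    for (i in which(keep)) {
      g <- gt[i, sm]
      if (is.na(g)) next
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0) next
      tab <- table(idx)
      if (sum(tab == max(tab)) > 1) {
        next # heterozygous: no majority allele
      }
      ai <- as.integer(names(tab)[which.max(tab)])
      alleles <- c(ref[i], strsplit(alt[i], ",")[[1]])
      base <- alleles[ai + 1]
      if (!is.na(base) && nchar(base) == 1 && base %in% BASES) {
        calls[as.character(pos[i])] <- base
      }
    }
    sample_genotypes(sm, calls)
  })
}

#' Write haplogroup calls to CSV
#'
#' @param cohort A `cohort_calls`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
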
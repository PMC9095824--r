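#' Run the full provenance pipeline from a config file
#'
#' Orchestrates the genetic track (haplogroup calling, ancestry
#' aggregation and comparison, frequency PCA) and/or the isotope track
#' (drinking-water back-calculation, locality and diet classification),
#' depending on which inputs the config names, and writes flat CSV/JSON
#' artifacts plus a report. Runs with any subset of inputs: an
#' isotope-only config produces only the isotope sections.
#'
#' Config keys (YAML, all paths relative to the config file):
#' \describe{
#'   \item{cohort_id}{Cohort label (default `"cohort"`).}
#'   \item{tree, panel}{Haplogroup tree / panel files (defaults: packaged).}
#'   \item{genotypes / genotypes_vcf}{Sample genotype CSV or VCF.}
#'   \item{simulate_genotypes}{Alternative to `genotypes`: list with
#'     `scenario` (`"Gangetic"`/`"Punjab"`), `n_samples`, `missing_rate`,
#'     `error_rate` — generates the cohort with [default_cohort_spec()].}
#'   \item{reference_frequencies}{Long-format frequency CSV (default:
#'     packaged synthetic table).}
#'   \item{region_map}{`pattern,region` CSV (default: built-in rules).}
#'   \item{reference_n}{Assumed per-population sample size used to turn
#'     reference frequencies into counts for Fisher comparisons
#'     (default 100).}
#'   \item{focus_region}{Region compared across cohorts (default
#'     `"WestEurasian"`).}
#'   \item{n_components}{PCA components kept (default 2).}
#'   \item{isotopes}{Isotope CSV, or `simulate_isotopes` (list with
#'     `region`, `n`).}
#'   \item{water_references, local_region, tolerance}{Locality
#'     classification config (defaults: packaged ranges, `"Punjab"`,
#'     0.5 permil).}
#'   \item{c3_enamel_endmember, c4_enamel_endmember}{Diet endmembers.}
#'   \item{seed}{Simulation seed (overridden by the `seed` argument).}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param seed Optional integer overriding the config seed.
#' @param out_dir Output directory for artifacts (default: no files
#'   written, report returned only).
#' @return An object of class `provenance_report` (invisibly if
#'   `out_dir` is given): list with `meta`, `genetics`, `isotope` and
#'   `verdict` sections.
#' @export
run_provenance <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    cfg <- yaml::read_yaml(config)
    base_dir <- dirname(normalizePath(config))
  } else {
    cfg <- config
    cfg_path <- NULL
    base_dir <- getwd()
  }
  seed <- if (!is.null(seed)) as.integer(seed)
          else as.integer(cfg$seed %||% 1L)
  cohort_id <- cfg$cohort_id %||% "cohort"
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  need <- function(key) {
    p <- resolve(cfg[[key]])
    if (!is.null(cfg[[key]]) && !file.exists(p)) {
      stop("config key '", key, "': file not found: ", cfg[[key]],
           call. = FALSE)
    }
    p
  }

  meta <- list(tool = "paleoprov",
               version = as.character(utils::packageVersion("paleoprov")),
               config_hash = config_hash(cfg), seed = seed,
               cohort_id = cohort_id)

  report <- list(meta = meta)

  # ---- genetic track ----
  has_genotypes <- !is.null(cfg$genotypes) || !is.null(cfg$genotypes_vcf) ||
    !is.null(cfg$simulate_genotypes)
  if (has_genotypes) {
    tree <- if (is.null(cfg$tree)) default_haplotree()
            else read_haplotree(need("tree"))
    panel <- if (is.null(cfg$panel)) default_panel()
             else read_panel(need("panel"))
    rmap <- if (is.null(cfg$region_map)) default_region_map()
            else read_region_map(need("region_map"))
    samples <- if (!is.null(cfg$genotypes)) {
      read_genotypes_csv(need("genotypes"), panel)
    } else if (!is.null(cfg$genotypes_vcf)) {
      read_genotypes_vcf(need("genotypes_vcf"), panel)
    } else {
      sg <- cfg$simulate_genotypes
      spec <- default_cohort_spec(
        scenario = sg$scenario %||% "Gangetic",
        n_samples = sg$n_samples %||% 50,
        missing_rate = sg$missing_rate %||% 0.05,
        error_rate = sg$error_rate %||% 0.01, seed = seed)
      simulate_cohort_genotypes(spec, tree, panel)$samples
    }
    cohort <- call_cohort(samples, tree, panel)
    anc <- ancestry_proportions(cohort, rmap, tree, cohort_id = cohort_id)

    reference <- if (is.null(cfg$reference_frequencies)) {
      default_reference_frequencies()
    } else {
      read_frequency_csv(need("reference_frequencies"))
    }
    freq_matrix <- build_frequency_matrix(reference, cohort$frequencies,
                                          cohort_id = cohort_id)
    n_comp <- cfg$n_components %||% 2
    pca <- pca_frequencies(freq_matrix, n_components = n_comp)
    nearest <- nearest_populations(pca, cohort_id)

    # Fisher comparisons against each reference population; reference
    # frequencies are converted to counts at an assumed sample size
    ref_n <- cfg$reference_n %||% 100
    focus <- cfg$focus_region %||% "WestEurasian"
    comparisons <- reference_comparisons(anc$counts, reference, rmap, tree,
                                         ref_n, focus)

    report$genetics <- list(
      calls = as.data.frame(cohort),
      haplogroup_frequencies = as.list(cohort$frequencies),
      macro_frequencies = as.list(cohort$macro_frequencies),
      ancestry = list(counts = as.list(anc$counts),
                      fractions = as.list(anc$fractions)),
      comparisons = comparisons,
      pca = list(coordinates = pca$coordinates,
                 eigenvalues = pca$eigenvalues,
                 explained_fraction = pca$explained_fraction),
      nearest_populations = as.list(nearest)
    )
  }

  # ---- isotope track ----
  has_isotopes <- !is.null(cfg$isotopes) || !is.null(cfg$simulate_isotopes)
  if (has_isotopes) {
    refs <- if (is.null(cfg$water_references)) default_water_references()
            else read_water_references(need("water_references"))
    local_region <- cfg$local_region %||% "Punjab"
    records <- if (!is.null(cfg$isotopes)) {
      read_isotopes_csv(need("isotopes"))
    } else {
      si <- cfg$simulate_isotopes
      simulate_isotope_cohort(default_isotope_spec(seed = seed),
                              si$region %||% "GangeticPlain",
                              si$n %||% 50)
    }
    iso <- analyze_isotopes(
      records, refs, local_region,
      tolerance = cfg$tolerance %||% 0.5,
      c3_enamel_endmember = cfg$c3_enamel_endmember %||% C3_ENAMEL_DEFAULT,
      c4_enamel_endmember = cfg$c4_enamel_endmember %||% C4_ENAMEL_DEFAULT)
    report$isotope <- list(local_region = local_region, results = iso)
  }

  report$verdict <- build_verdict(report)
  class(report) <- "provenance_report"
  if (!is.null(out_dir)) {
    write_report_artifacts(report, out_dir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

reference_comparisons <- function(cohort_counts, reference, rmap, tree,
                                  ref_n, focus) {
  out <- list()
  haps <- colnames(reference)
  regions <- vapply(haps, function(h) {
    if (h %in% names(tree$nodes)) assign_region(h, rmap, tree)
    else "Unclassified"
  }, character(1))
  for (pop in rownames(reference)) {
    counts <- stats::setNames(numeric(length(REGIONS)), REGIONS)
    fr <- tapply(unclass(reference)[pop, ], regions, sum)
    counts[names(fr)] <- fr
    counts["Unclassified"] <- counts["Unclassified"] +
      max(0, 1 - sum(unclass(reference)[pop, ]))
    pop_counts <- round(counts * ref_n)
    out[[pop]] <- list(
      focus = focus,
      focus_fraction = unname(counts[focus]),
      p_value = compare_ancestry(cohort_counts, pop_counts, focus))
  }
  out
}

build_verdict <- function(report) {
  v <- list()
  if (!is.null(report$genetics)) {
    fr <- unlist(report$genetics$ancestry$fractions)
    v$majority_ancestry <- names(fr)[which.max(fr)]
    v$nearest_reference_populations <-
      utils::head(names(report$genetics$nearest_populations), 3)
  }
  if (!is.null(report$isotope)) {
    res <- report$isotope$results
    v$fraction_non_local <- mean(!res$local_flag)
    v$diet_classes <- as.list(table(res$diet_class) / nrow(res))
  }
  v
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# paleoprov %s | config %s | seed %d",
                 report$meta$version, report$meta$config_hash,
                 report$meta$seed)
  write_csv_with_header <- function(df, file) {
    con <- file(file.path(out_dir, file), "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  g <- report$genetics
  if (!is.null(g)) {
    write_csv_with_header(g$calls, "calls.csv")
    write_csv_with_header(
      data.frame(haplogroup = names(g$haplogroup_frequencies),
                 frequency = unlist(g$haplogroup_frequencies)),
      "haplogroup_frequencies.csv")
    write_csv_with_header(
      data.frame(region = names(g$ancestry$fractions),
                 count = unlist(g$ancestry$counts),
                 fraction = unlist(g$ancestry$fractions)),
      "ancestry.csv")
    write_csv_with_header(
      data.frame(population = names(g$comparisons),
                 focus_fraction = vapply(g$comparisons, `[[`, numeric(1),
                                         "focus_fraction"),
                 p_value = vapply(g$comparisons, `[[`, numeric(1),
                                  "p_value")),
      "ancestry_comparisons.csv")
    co <- as.data.frame(g$pca$coordinates)
    co <- cbind(population = rownames(co), co)
    write_csv_with_header(co, "pca_coordinates.csv")
    write_csv_with_header(
      data.frame(component = seq_along(g$pca$eigenvalues),
                 eigenvalue = g$pca$eigenvalues,
                 explained_fraction = g$pca$explained_fraction),
      "pca_eigenvalues.csv")
  }
  if (!is.null(report$isotope)) {
    write_csv_with_header(report$isotope$results, "isotope_results.csv")
  }
  jsonlite::write_json(unclass_report(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(hdr, utils::capture.output(print(report)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

unclass_report <- function(report) {
  r <- unclass(report)
  if (!is.null(r$genetics)) {
    r$genetics$pca$coordinates <-
      cbind(data.frame(population = rownames(r$genetics$pca$coordinates)),
            as.data.frame(r$genetics$pca$coordinates))
  }
  r
}

#' @export
print.provenance_report <- function(x, ...) {
  cat("== paleoprov provenance report:", x$meta$cohort_id, "==\n")
  cat("seed", x$meta$seed, "| config", x$meta$config_hash, "\n")
  if (!is.null(x$genetics)) {
    cat("\n-- Genetics --\n")
    fr <- unlist(x$genetics$haplogroup_frequencies)
    top <- sort(fr, decreasing = TRUE)
    cat("top haplogroups:",
        paste(sprintf("%s (%.2f)", names(utils::head(top, 4)),
                      utils::head(top, 4)), collapse = ", "), "\n")
    mf <- unlist(x$genetics$macro_frequencies)
    cat("macro frequencies:",
        paste(sprintf("%s %.2f", names(mf), mf), collapse = ", "), "\n")
    af <- unlist(x$genetics$ancestry$fractions)
    cat("ancestry:",
        paste(sprintf("%s %.2f", names(af), af), collapse = ", "), "\n")
    cat("nearest reference populations:",
        paste(utils::head(names(x$genetics$nearest_populations), 3),
              collapse = ", "), "\n")
  }
  if (!is.null(x$isotope)) {
    cat("\n-- Isotopes --\n")
    res <- x$isotope$results
    cat(sprintf("n = %d; non-local fraction vs %s: %.2f\n", nrow(res),
                x$isotope$local_region, mean(!res$local_flag)))
    dc <- table(res$diet_class)
    cat("diet:", paste(sprintf("%s %d", names(dc), dc), collapse = ", "),
        "\n")
  }
  if (length(x$verdict)) {
    cat("\n-- Verdict --\n")
    if (!is.null(x$verdict$majority_ancestry)) {
      cat("majority ancestry:", x$verdict$majority_ancestry, "\n")
    }
    if (!is.null(x$verdict$fraction_non_local)) {
      cat(sprintf("fraction non-local: %.2f\n",
                  x$verdict$fraction_non_local))
    }
  }
  invisible(x)
}
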
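# Run code under a local RNG seed, restoring the caller's RNG state.
# All simulators draw through this; nothing touches global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Cohort simulation specification
#'
#' @param n_samples Number of samples.
#' @param haplogroup_distribution Named numeric vector of sampling
#'   probabilities over haplogroup labels (must sum to 1).
#' @param missing_rate Per-call dropout probability in `[0, 1)`.
#' @param error_rate Per-call genotyping-error probability in `[0, 1)`;
#'   an erroneous call is a uniform draw among the three other bases.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples, haplogroup_distribution,
                        missing_rate = 0, error_rate = 0, seed = 1L) {
  p <- haplogroup_distribution
  if (abs(sum(p) - 1) > 1e-9) {
    stop("haplogroup_distribution must sum to 1", call. = FALSE)
  }
  stopifnot(n_samples >= 1, missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  structure(list(n_samples = as.integer(n_samples),
                 haplogroup_distribution = p,
                 missing_rate = missing_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate panel genotypes for a cohort
#'
#' Each sample draws a generating haplogroup, takes that haplogroup's
#' expected states at the panel positions (reference elsewhere), then
#' each call is independently set MISSING with `missing_rate` and flipped
#' to a uniformly random other base with `error_rate`. Reproducible given
#' the spec's seed; the caller's RNG state is untouched.
#'
#' @param spec A [cohort_spec()].
#' @param tree A `haplo_tree`.
#' @param panel A `panel_definition`.
#' @return List with `samples` (list of `sample_genotypes`) and `truth`
#'   (data frame `sample_id`, `haplogroup`).
#' @export
simulate_cohort_genotypes <- function(spec, tree, panel) {
  labs <- names(spec$haplogroup_distribution)
  unknown <- setdiff(labs, names(tree$nodes))
  if (length(unknown) > 0) {
    stop("haplogroup(s) absent from tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cache <- build_profile_cache(tree, panel)
  npos <- nrow(panel)
  with_seed(spec$seed, {
    haps <- sample(labs, spec$n_samples, replace = TRUE,
                   prob = spec$haplogroup_distribution)
    ids <- sprintf("S%03d", seq_len(spec$n_samples))
    samples <- vector("list", spec$n_samples)
    for (i in seq_len(spec$n_samples)) {
      calls <- cache$profiles[[haps[i]]]
      if (spec$error_rate > 0) {
        err <- stats::runif(npos) < spec$error_rate
        for (j in which(err)) {
          calls[j] <- sample(setdiff(BASES, calls[j]), 1)
        }
      }
      if (spec$missing_rate > 0) {
        calls[stats::runif(npos) < spec$missing_rate] <- NA_character_
      }
      samples[[i]] <- sample_genotypes(ids[i], calls)
    }
    list(samples = samples,
         truth = data.frame(sample_id = ids, haplogroup = haps,
                            stringsAsFactors = FALSE))
  })
}

#' West-Eurasian cline specification for reference populations
#'
#' @param populations Data frame with columns `population` and
#'   `coordinate` (1-D geographic coordinate; by convention 0 = far
#'   north-west, 1 = far east/south).
#' @param west_eurasian_endpoints Length-2 numeric: the West-Eurasian
#'   ancestry fraction at coordinate 0 and at coordinate 1; intermediate
#'   populations interpolate linearly, so the fraction is monotone along
#'   the coordinate.
#' @param pools Named list of haplogroup-label pools, one per ancestry
#'   component; must contain `WestEurasian` and at least one other pool.
#' @param east_eurasian_fraction Constant minor East-Eurasian fraction
#'   (default 0.05; 0 if no `EastEurasian` pool is given).
#' @param concentration Dirichlet concentration tying each population's
#'   within-pool haplogroup composition to a shared base composition
#'   (default 50). Published state-wise frequency tables are spatially
#'   autocorrelated: neighbouring populations share composition and
#'   differ mainly in their ancestry-component fractions; large values
#'   reproduce that, small values give independent compositions.
#' @param seed Integer seed.
#' @return A `cline_spec` list.
#' @export
cline_spec <- function(populations, west_eurasian_endpoints, pools,
                       east_eurasian_fraction = 0.05, concentration = 50,
                       seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("population", "coordinate") %in% names(populations)),
            nrow(populations) >= 2,
            length(west_eurasian_endpoints) == 2,
            all(west_eurasian_endpoints >= 0 & west_eurasian_endpoints <= 1),
            "WestEurasian" %in% names(pools))
  if (any(vapply(pools, length, integer(1)) == 0)) {
    stop("empty haplogroup pool(s)", call. = FALSE)
  }
  if (!"EastEurasian" %in% names(pools)) east_eurasian_fraction <- 0
  stopifnot(concentration > 0)
  structure(list(populations = populations,
                 west_eurasian_endpoints = west_eurasian_endpoints,
                 pools = pools,
                 east_eurasian_fraction = east_eurasian_fraction,
                 concentration = concentration,
                 seed = as.integer(seed)),
            class = "cline_spec")
}

#' Simulate a reference frequency table along a west-Eurasian cline
#'
#' Each population's West-Eurasian fraction is the linear interpolation
#' of the endpoint fractions at its coordinate; that mass is spread over
#' the West-Eurasian haplogroup pool, a small constant East-Eurasian
#' mass over its pool, and the remainder over the South-Asian pool.
#' Within each pool a shared base composition is drawn once
#' (Dirichlet(1)) and each population perturbs it
#' (Dirichlet(concentration x base)), so populations differ mainly in
#' their ancestry fractions, as published tables do. Rows sum to 1
#' exactly.
#'
#' @param spec A [cline_spec()].
#' @return A `frequency_table` (populations x pooled haplogroups).
#' @export
simulate_reference_frequencies <- function(spec) {
  pops <- spec$populations
  w <- spec$west_eurasian_endpoints[1] +
    pops$coordinate * diff(spec$west_eurasian_endpoints)
  haps <- sort(unique(unlist(spec$pools)))
  m <- matrix(0, nrow = nrow(pops), ncol = length(haps),
              dimnames = list(pops$population, haps))
  with_seed(spec$seed, {
    base <- lapply(spec$pools, function(pool) {
      g <- stats::rgamma(length(pool), 1)
      g / sum(g)
    })
    for (i in seq_len(nrow(pops))) {
      frac <- c(WestEurasian = w[i],
                EastEurasian = spec$east_eurasian_fraction)
      frac <- frac[names(frac) %in% names(spec$pools)]
      rest_pools <- setdiff(names(spec$pools), names(frac))
      rest <- (1 - sum(frac)) / length(rest_pools)
      frac <- c(frac, stats::setNames(rep(rest, length(rest_pools)),
                                      rest_pools))
      for (pool in names(spec$pools)) {
        g <- stats::rgamma(length(spec$pools[[pool]]),
                           spec$concentration * base[[pool]])
        m[i, spec$pools[[pool]]] <- m[i, spec$pools[[pool]]] +
          frac[pool] * g / sum(g)
      }
    }
  })
  frequency_table(m)
}

#' Isotope cohort specification
#'
#' @param regions Named list; each element a list with `water_mean`,
#'   `water_sd` (drinking-water d18O, permil VSMOW) and `diet_shape1`,
#'   `diet_shape2` (Beta parameters of the C4 dietary fraction), or a
#'   `diet_fixed` constant fraction instead of the Beta parameters.
#' @param carbonate_noise_sd Analytical noise SD on carbonate d18O
#'   (permil; default 0.2).
#' @param d13C_noise_sd Analytical noise SD on d13C (permil; default
#'   0.3).
#' @param c3_enamel_endmember,c4_enamel_endmember Diet endmembers used by
#'   the forward d13C model.
#' @param seed Integer seed.
#' @return An `isotope_spec` list.
#' @export
isotope_spec <- function(regions, carbonate_noise_sd = 0.2,
                         d13C_noise_sd = 0.3,
                         c3_enamel_endmember = C3_ENAMEL_DEFAULT,
                         c4_enamel_endmember = C4_ENAMEL_DEFAULT,
                         seed = 1L) {
  stopifnot(length(regions) >= 1, !is.null(names(regions)),
            carbonate_noise_sd >= 0, d13C_noise_sd >= 0)
  for (r in regions) stopifnot(r$water_sd >= 0)
  structure(list(regions = regions, carbonate_noise_sd = carbonate_noise_sd,
                 d13C_noise_sd = d13C_noise_sd,
                 c3_enamel_endmember = c3_enamel_endmember,
                 c4_enamel_endmember = c4_enamel_endmember,
                 seed = as.integer(seed)),
            class = "isotope_spec")
}

#' Simulate isotope measurements for one region
#'
#' Drinking-water values are drawn from the region's Gaussian, pushed
#' through the forward carbonate calibration, and perturbed with
#' analytical noise; d13C comes from Beta-distributed C4 fractions
#' through the forward mixing model plus noise.
#'
#' @param spec An [isotope_spec()].
#' @param region Region name in `spec$regions`.
#' @param n Number of samples.
#' @return An `isotope_records` data frame (`sample_id`,
#'   `d18O_carbonate_vsmow`, `d13C_vpdb`) with the generating water
#'   values and C4 fractions attached as columns `true_d18O_water` and
#'   `true_fraction_C4`.
#' @export
simulate_isotope_cohort <- function(spec, region, n) {
  rg <- spec$regions[[region]]
  if (is.null(rg)) {
    stop("unknown region '", region, "' in isotope spec", call. = FALSE)
  }
  with_seed(spec$seed, {
    water <- stats::rnorm(n, rg$water_mean, rg$water_sd)
    carb <- drinking_water_to_carbonate(water) +
      stats::rnorm(n, 0, spec$carbonate_noise_sd)
    f4 <- if (!is.null(rg$diet_fixed)) rep(rg$diet_fixed, n)
          else stats::rbeta(n, rg$diet_shape1, rg$diet_shape2)
    d13c <- spec$c3_enamel_endmember +
      f4 * (spec$c4_enamel_endmember - spec$c3_enamel_endmember) +
      stats::rnorm(n, 0, spec$d13C_noise_sd)
    df <- data.frame(sample_id = sprintf("I%03d", seq_len(n)),
                     d18O_carbonate_vsmow = carb, d13C_vpdb = d13c,
                     true_d18O_water = water, true_fraction_C4 = f4,
                     stringsAsFactors = FALSE)
    class(df) <- c("isotope_records", "data.frame")
    df
  })
}

# ---- packaged default study conditions ------------------------------------

#' Default haplogroup pools by ancestry component
#'
#' Label pools over the packaged tree, split by the regions the default
#' region map assigns them to.
#'
#' @return Named list of character vectors.
#' @export
default_haplogroup_pools <- function() {
  list(
    WestEurasian = c("HV0e", "H", "J", "K", "W", "X", "R0", "R1", "R2",
                     "U1", "U3", "U4", "U5", "U7", "U9"),
    SouthAsian = c("M2", "M3", "M4", "M5", "M6", "M18", "M25", "M30",
                   "M33", "M35", "M37", "M39", "M40", "M65", "M67", "N5",
                   "R5", "R6", "R7", "R8", "R30", "R31", "R32", "U2a",
                   "U2b"),
    EastEurasian = c("A", "B", "C", "D", "E", "F", "G", "M7", "M8", "M9",
                     "M10", "M11", "M12", "R22", "N9")
  )
}

#' Default west-Eurasian cline across 14 reference populations
#'
#' The 14 South Asian reference populations placed on a 1-D north-west to
#' east/south coordinate, with the West-Eurasian ancestry fraction
#' declining linearly from 0.45 (upper Indus) to 0.05 (far east/south) —
#' the clinal structure reported for the subcontinent.
#'
#' @param seed Integer seed (default 1).
#' @return A `cline_spec`.
#' @export
default_cline_spec <- function(seed = 1L) {
  pops <- data.frame(
    population = c("Pak", "Pun", "Raj", "Guj", "Mah", "Mp", "Up", "Cg",
                   "Jhk", "Bih", "WB", "Odi", "Ap", "Ker"),
    coordinate = c(0.00, 0.05, 0.20, 0.30, 0.45, 0.50, 0.60, 0.65,
                   0.70, 0.75, 0.80, 0.85, 0.90, 1.00),
    stringsAsFactors = FALSE)
  cline_spec(pops, west_eurasian_endpoints = c(0.45, 0.05),
             pools = default_haplogroup_pools(),
             east_eurasian_fraction = 0.05, seed = seed)
}

#' Default cohort composition by provenance scenario
#'
#' `"Gangetic"` mirrors the kind of composition reported for the study
#' cohort (M39-rich, R32 present, minor West-Eurasian lineages);
#' `"Punjab"` is a north-western population with a high West-Eurasian
#' fraction.
#'
#' @param scenario `"Gangetic"` or `"Punjab"`.
#' @param n_samples Cohort size (default 50, the study's cohort size).
#' @param missing_rate,error_rate,seed Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(scenario = c("Gangetic", "Punjab"),
                                n_samples = 50, missing_rate = 0.05,
                                error_rate = 0.01, seed = 1L) {
  scenario <- match.arg(scenario)
  p <- if (scenario == "Gangetic") {
    c(M39 = 0.24, R32 = 0.14, M2 = 0.08, M3 = 0.08, M5 = 0.06, M6 = 0.06,
      M30 = 0.06, M33 = 0.05, M35 = 0.04, M65 = 0.04, R5 = 0.04,
      R30 = 0.03, HV0e = 0.06, U3 = 0.02, U7 = 0.02, N5 = 0.04,
      U2a = 0.04)
  } else {
    c(HV0e = 0.10, H = 0.10, J = 0.06, K = 0.05, U1 = 0.05, U3 = 0.04,
      U4 = 0.04, U5 = 0.05, U7 = 0.05, W = 0.04, R0 = 0.04, R1 = 0.03,
      M3 = 0.08, M5 = 0.07, M30 = 0.06, M39 = 0.05, R5 = 0.05,
      U2b = 0.04)
  }
  cohort_spec(n_samples, p / sum(p), missing_rate, error_rate, seed)
}

#' Default regional isotope parameters
#'
#' Gaussian drinking-water d18O per provenance region (permil VSMOW) and
#' Beta-distributed C4 dietary fractions, chosen to sit inside the
#' packaged example water-reference ranges: Punjab/upper Indus mean -7.5
#' (SD 0.6), Gangetic plain mean -4.5 (SD 0.9), eastern coastal belt
#' mean -2.5 (SD 0.6). Diet skews C3-to-mixed everywhere (Beta(2, 4),
#' mean 1/3).
#'
#' @param seed Integer seed.
#' @return An `isotope_spec`.
#' @export
default_isotope_spec <- function(seed = 1L) {
  isotope_spec(list(
    Punjab = list(water_mean = -7.5, water_sd = 0.6,
                  diet_shape1 = 2, diet_shape2 = 4),
    GangeticPlain = list(water_mean = -4.5, water_sd = 0.9,
                         diet_shape1 = 2, diet_shape2 = 4),
    Coastal = list(water_mean = -2.5, water_sd = 0.6,
                   diet_shape1 = 2, diet_shape2 = 4)
  ), seed = seed)
}
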
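# Shared fixtures and independent oracles, built in code.

# Small hand-built tree: rCRS -> {M -> M39 -> M39a, R -> R32} with a
# back-mutation on M39a reverting the M variant at 489.
fixture_tree_text <- function() {
  c("rCRS",
    "\tM\tT489C C10400T",
    "\t\tM39\tC12361T",
    "\t\t\tM39a\tC489T! A5301G",
    "\tR\tT12705C",
    "\t\tR32\tA9852G T16311C")
}

fixture_tree <- function() parse_haplotree(fixture_tree_text())

fixture_panel <- function(tree = fixture_tree()) {
  pos <- sort(as.integer(names(reference_alleles(tree))))
  panel_definition(data.frame(position = pos,
                              pool = rep_len(1:4, length(pos))))
}

# genotype vector exactly matching a haplogroup's expected panel states
profile_calls <- function(tree, panel, label) {
  prof <- expected_profile(tree, label)
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)
  calls <- ref[key]
  hit <- intersect(names(prof$states), key)
  calls[hit] <- prof$states[hit]
  calls
}

# Independent brute-force haplogroup caller: recomputes each node's
# expected states by its own path walk and scores with explicit loops.
oracle_call <- function(sample, tree, panel) {
  ref <- reference_alleles(tree)
  key <- as.character(panel$position)
  best <- NULL
  best_score <- -1
  for (label in names(tree$nodes)) {
    # walk root -> label applying variants sequentially
    path <- character(0)
    lab <- label
    repeat {
      path <- c(lab, path)
      lab <- tree$nodes[[lab]]$parent
      if (is.na(lab)) break
    }
    exp <- ref[key]
    for (pl in path) {
      v <- tree$nodes[[pl]]$variants
      for (k in seq_len(nrow(v))) {
        p <- as.character(v$position[k])
        if (p %in% key) exp[p] <- v$derived[k]
      }
    }
    ne <- 0; no <- 0; nm <- 0
    for (p in key) {
      obs <- sample$calls[[p]]
      if (is.na(obs)) next
      e_der <- exp[[p]] != ref[[p]]
      o_der <- obs != ref[[p]]
      if (e_der) ne <- ne + 1
      if (o_der) no <- no + 1
      if (e_der && o_der && obs == exp[[p]]) nm <- nm + 1
    }
    rec <- if (ne == 0) 1 else nm / ne
    pre <- if (no == 0) 1 else nm / no
    sc <- (rec + pre) / 2
    depth <- tree$nodes[[label]]$depth
    if (is.null(best)) {
      best <- list(label = label, score = sc, depth = depth)
      best_score <- sc
    } else {
      better <- sc > best_score + 1e-12 ||
        (abs(sc - best_score) <= 1e-12 &&
           (depth > best$depth ||
              (depth == best$depth && label < best$label)))
      if (better) {
        best <- list(label = label, score = sc, depth = depth)
        best_score <- sc
      }
    }
  }
  best
}

# Independent two-tailed Fisher p: enumerate the hypergeometric
# distribution over all 2x2 tables with the observed margins and sum the
# probabilities <= the observed table's probability.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  p_obs <- stats::dhyper(a, m, n, k)
  xs <- max(0, k - n):min(k, m)
  ps <- stats::dhyper(xs, m, n, k)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}
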
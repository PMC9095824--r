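test_that("frequency matrices union cohort columns and validate rows", {
  ref <- frequency_table(matrix(c(0.5, 0.5, 0.3, 0.7, 0.1, 0.8),
                                nrow = 3, byrow = TRUE,
                                dimnames = list(c("P1", "P2", "P3"),
                                                c("M39", "R32"))))
  ft <- build_frequency_matrix(ref, c(M39 = 0.4, HV0e = 0.6),
                               cohort_id = "Aj")
  expect_equal(nrow(ft), 4L)
  expect_equal(colnames(ft), c("HV0e", "M39", "R32")) # sorted union
  # haplogroup absent from the reference is a zero-filled column
  expect_equal(unname(unclass(ft)[c("P1", "P2", "P3"), "HV0e"]),
               rep(0, 3))
  expect_equal(unname(unclass(ft)["Aj", ]), c(0.6, 0.4, 0))

  # packaged 14-population table + cohort row = 15 populations
  full <- build_frequency_matrix(default_reference_frequencies(),
                                 c(M39 = 0.24, R32 = 0.14, HV0e = 0.06,
                                   M2 = 0.56))
  expect_equal(nrow(full), 15L)
  expect_true("Aj" %in% rownames(full))

  expect_error(frequency_table(matrix(c(0.5, 0.7), 1, 2,
                                      dimnames = list("P1",
                                                      c("a", "b")))),
               "exceed 1.*P1")
  expect_error(frequency_table(matrix(c(-0.1, 0.5), 1, 2,
                                      dimnames = list("P1",
                                                      c("a", "b")))),
               "outside")
})

test_that("two-point PCA has one axis with mirror-image coordinates", {
  ft <- frequency_table(matrix(c(0.2, 0.8, 0.8, 0.2), 2, byrow = TRUE,
                               dimnames = list(c("P1", "P2"),
                                               c("h1", "h2"))))
  p <- pca_frequencies(ft, 1)
  expect_length(p$eigenvalues, 1L)
  expect_gt(p$eigenvalues[1], 0)
  expect_equal(p$coordinates["P1", 1], -p$coordinates["P2", 1])
  expect_equal(p$explained_fraction, 1.0)
})

test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    k <- sample(4:10, 1)
    m <- matrix(stats::runif(n * k, 0, 1 / k), n, k,
                dimnames = list(paste0("P", 1:n), paste0("h", 1:k)))
    ft <- frequency_table(m)
    p <- pca_frequencies(ft)
    # oracle: eigenvalues of the sample covariance matrix
    ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[seq_along(p$eigenvalues)]
    expect_equal(p$eigenvalues, ev, tolerance = 1e-8)
    # eigenvalues non-increasing, variance conserved
    expect_true(all(diff(p$eigenvalues) <= 1e-12))
    expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(m))),
                 tolerance = 1e-8)
    expect_lte(sum(p$explained_fraction), 1 + 1e-9)
    # loadings orthonormal
    gram <- crossprod(p$loadings)
    expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCA output is reproducible and row-order invariant", {
  set.seed(3)
  m <- matrix(stats::runif(40, 0, 0.12), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("h", 1:5)))
  ft <- frequency_table(m)
  p1 <- pca_frequencies(ft, 2)
  p2 <- pca_frequencies(ft, 2)
  expect_identical(p1$coordinates, p2$coordinates)

  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  p3 <- pca_frequencies(frequency_table(m[perm, ]), 2)
  expect_equal(p3$coordinates[rownames(p1$coordinates), ],
               p1$coordinates, tolerance = 1e-8)

  # duplicated population rows get coincident coordinates
  m2 <- rbind(m, P9 = m["P1", ])
  p4 <- pca_frequencies(frequency_table(m2), 2)
  expect_equal(p4$coordinates["P9", ], p4$coordinates["P1", ],
               tolerance = 1e-10)

  # degenerate inputs
  const <- frequency_table(matrix(0.25, 3, 4,
                                  dimnames = list(paste0("P", 1:3),
                                                  paste0("h", 1:4))))
  pc <- pca_frequencies(const)
  expect_equal(pc$eigenvalues, rep(0, length(pc$eigenvalues)))
  expect_equal(max(abs(pc$coordinates)), 0)
  expect_error(pca_frequencies(ft, 99), "n_components")
  expect_error(pca_frequencies(frequency_table(m[1, , drop = FALSE])),
               "at least 2")
})

test_that("a Gangetic-parameter cohort projects nearest the eastern cline", {
  tree <- default_haplotree()
  panel <- default_panel()
  reference <- simulate_reference_frequencies(default_cline_spec(seed = 5))
  sim <- simulate_cohort_genotypes(default_cohort_spec("Gangetic",
                                                       seed = 5),
                                   tree, panel)
  cc <- call_cohort(sim$samples, tree, panel)
  ft <- build_frequency_matrix(reference, cc$frequencies)
  d <- nearest_populations(pca_frequencies(ft, 2), "Aj")
  gangetic <- mean(d[c("Up", "Bih", "Jhk", "WB")])
  punjab <- mean(d[c("Pak", "Pun")])
  expect_lt(gangetic, punjab)
})
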
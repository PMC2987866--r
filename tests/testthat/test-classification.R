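test_that("cva reduces to Euclidean geometry under identity pooled covariance", {
  # two groups of 4 points whose pooled within-group covariance is exactly I
  a <- sqrt(1.5)
  muA <- c(0, 0); muB <- c(3, 1)
  dev <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  X <- rbind(sweep(dev, 2, muA, "+"), sweep(dev, 2, muB, "+"))
  rownames(X) <- paste0("s", 1:8); colnames(X) <- c("v1", "v2")
  sv <- fake_shape_variables(X)
  model <- fit_cva(sv, rep(c("A", "B"), each = 4))
  expect_equal(model$pooled_within_covariance, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mahalanobis_distance(model, muA, "B"), sqrt(sum((muA - muB)^2)),
               tolerance = 1e-10)
  expect_equal(mahalanobis_distance(model, muA, "A"), 0, tolerance = 1e-12)
  # identity covariance, one unit from the mean along one axis
  expect_equal(mahalanobis_distance(model, muA + c(1, 0), "A"), 1,
               tolerance = 1e-10)
  # g = 2 gives exactly one discriminant axis
  expect_equal(ncol(model$discriminant_axes), 1L)
})

test_that("Mahalanobis distances are invariant under invertible linear maps", {
  set.seed(171)
  X <- matrix(rnorm(40 * 5), 40, 5)
  labels <- rep(c("A", "B"), each = 20)
  X[labels == "B", ] <- X[labels == "B", ] + 1
  d0 <- {
    m <- fit_cva(fake_shape_variables(X), labels)
    outer(1:40, c("A", "B"), Vectorize(function(i, g)
      mahalanobis_distance(m, X[i, ], g)))
  }
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(25), 5, 5) + diag(5)  # generic invertible map
    XA <- X %*% A
    m2 <- fit_cva(fake_shape_variables(XA), labels)
    d2 <- outer(1:40, c("A", "B"), Vectorize(function(i, g)
      mahalanobis_distance(m2, XA[i, ], g)))
    expect_equal(d2, d0, tolerance = 1e-8)
  }
})

test_that("mahalanobis_distance matches the explicit-inverse oracle", {
  set.seed(181)
  X <- matrix(rnorm(30 * 6), 30, 6)
  labels <- rep(c("A", "B", "C"), each = 10)
  model <- fit_cva(fake_shape_variables(X), labels)
  for (g in c("A", "B", "C")) for (i in c(1, 15, 30)) {
    expect_equal(mahalanobis_distance(model, X[i, ], g),
                 mahal_inverse_oracle(model$pooled_within_covariance,
                                      X[i, ], model$group_means[g, ]),
                 tolerance = 1e-10)
  }
})

test_that("cva assignments agree with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  d <- make_two_species(25, 0.05, 0.015, seed = 191)
  pw <- partial_warps(gpa(d))
  labels <- species_labels(d)
  model <- fit_cva(pw, labels, retain = 6)
  mine <- vapply(seq_len(nrow(pw$scores)), function(i) {
    dists <- vapply(model$group_labels, function(g)
      mahalanobis_distance(model, pw$scores[i, ], g), numeric(1))
    model$group_labels[which.min(dists)]
  }, character(1))
  # project onto the same retained axes for lda (equal group sizes, so the
  # posterior rule coincides with nearest Mahalanobis distance)
  Z <- sweep(pw$scores, 2, model$pc_center) %*% model$pc_rotation
  ld <- MASS::lda(Z, grouping = labels)
  theirs <- as.character(predict(ld, Z)$class)
  expect_equal(mine, theirs)
})

test_that("procrustes classification is exact on its own references", {
  d <- make_two_species(15, 0.1, 0.01, seed = 201)
  for (rule in c("nearest_consensus", "nearest_individual")) {
    rep <- procrustes_classify(d, d, rule = rule)
    expect_equal(tail(rep$error_table$misassigned, 1), 0L,
                 ignore_attr = TRUE)
  }
  # distances to every species are reported, and percentages re-derive
  rep <- procrustes_classify(d, d)
  expect_true(all(c("d_species_01", "d_species_02") %in% names(rep$records)))
  et <- rep$error_table
  expect_equal(et$percent, 100 * et$misassigned / et$total)
})

test_that("well-separated species classify without error under both methods", {
  # mean separation 20x the within-species scatter
  refs <- make_two_species(30, 0.2, 0.01, seed = 211)
  unk <- simulate_specimens(
    simulate_species_means(make_template(11, "wing"), 2, 0.2, seed = 211),
    20, 0.01, seed = 213)
  repp <- procrustes_classify(refs, unk)
  expect_equal(tail(repp$error_table$misassigned, 1), 0L, ignore_attr = TRUE)
  repm <- classify_one_by_one(refs, unk)
  expect_equal(tail(repm$error_table$misassigned, 1), 0L, ignore_attr = TRUE)
  expect_equal(tail(repm$error_table$total, 1), 40L, ignore_attr = TRUE)
})

test_that("equidistant unknowns tie-break to the first species label, flagged", {
  # two single-specimen species and an unknown exactly midway between them
  tpl <- preshape(make_template(11, "wing")$coords)
  dir <- morphid:::.random_tangent(tpl)
  va <- as.vector(tpl) + 0.05 * dir; va <- va / sqrt(sum(va^2))
  vb <- as.vector(tpl) - 0.05 * dir; vb <- vb / sqrt(sum(vb^2))
  refs <- landmark_dataset(list(
    landmark_config(matrix(va, 11, 2), "ra", species = "spB"),
    landmark_config(matrix(vb, 11, 2), "rb", species = "spA")))
  unk <- landmark_dataset(list(landmark_config(tpl, "mid")))
  rep <- suppressWarnings(procrustes_classify(refs, unk))
  expect_true(rep$records$tie)
  expect_equal(rep$records$assigned, "spA")  # lexicographically first
})

test_that("the one-by-one protocol is independent of the unknown set", {
  refs <- make_two_species(10, 0.06, 0.012, seed = 221)
  unk <- simulate_specimens(
    simulate_species_means(make_template(11, "wing"), 2, 0.06, seed = 221),
    3, 0.012, seed = 223)
  r_all <- classify_one_by_one(refs, unk)
  # permuting the unknowns leaves every record identical
  perm <- c(4, 1, 6, 2, 5, 3)
  r_perm <- classify_one_by_one(refs, subset_dataset(unk, perm))
  expect_identical(r_perm$records[order(perm), ]$assigned, r_all$records$assigned)
  expect_equal(r_perm$records[order(perm), ]$d_species_01,
               r_all$records$d_species_01, tolerance = 0)
  # classifying a single unknown gives the same record as in the batch
  r_one <- classify_one_by_one(refs, subset_dataset(unk, 2))
  expect_identical(r_one$records$assigned, r_all$records$assigned[2])
  expect_identical(r_one$records$d_species_02, r_all$records$d_species_02[2])
})

test_that("the discriminant model never sees unknown specimens", {
  refs <- make_two_species(10, 0.06, 0.012, seed = 231)
  unk <- simulate_specimens(
    simulate_species_means(make_template(11, "wing"), 2, 0.06, seed = 231),
    2, 0.012, seed = 233)
  r1 <- classify_one_by_one(refs, unk)
  # perturbing unknown 2 leaves unknown 1's distances and assignment
  # bit-identical (each unknown has its own reference-only model)
  unk2 <- unk
  unk2$configurations[[2]]$coords <- unk2$configurations[[2]]$coords +
    matrix(rnorm(22, sd = 0.05), 11, 2)
  r2 <- classify_one_by_one(refs, unk2)
  expect_identical(r2$records[1, ], r1$records[1, ])
  # and fit_cva itself is a pure function of the reference rows
  pw <- partial_warps(gpa(refs))
  m1 <- fit_cva(pw, species_labels(refs))
  m2 <- fit_cva(pw, species_labels(refs))
  expect_identical(m1$discriminant_axes, m2$discriminant_axes)
})

test_that("leave-one-out is error-free when every specimen has a duplicate", {
  base <- make_two_species(8, 0.1, 0.015, seed = 241)
  twin <- base
  twin$configurations <- lapply(twin$configurations, function(cfg) {
    cfg$replicate_id <- "2"; cfg
  })
  dup <- bind_datasets(base, twin)
  for (method in c("procrustes", "mahalanobis")) {
    loo <- loo_errors(dup, method,
                      rule = "nearest_individual")
    expect_equal(tail(loo$error_table$misassigned, 1), 0L, ignore_attr = TRUE)
    expect_equal(loo$metadata$validation, "leave-one-out")
  }
})

test_that("LOO error on overlapping species matches the planted-overlap oracle", {
  # small version of the planted-overlap design: per-dimension noise sigma,
  # means one noise-SD apart
  sigma <- 0.02
  refs <- make_two_species(20, sigma, sigma, seed = 251)
  sep <- attr(refs, "mean_distance")
  loo <- loo_errors(refs, "mahalanobis")
  observed <- tail(loo$error_table$misassigned, 1)
  orc <- overlap_error_oracle(sep, sigma, 18, n_draws = 1e5, seed = 252)
  n <- 40
  # generous envelope at this small n: oracle p +/- 3 binomial SDs
  half <- 3 * sqrt(orc$error * (1 - orc$error) / n)
  expect_gte(observed / n, orc$error - half)
  expect_lte(observed / n, orc$error + half)
})

test_that("Procrustes and Mahalanobis assignments agree on isotropic data", {
  refs <- make_two_species(22, 0.06, 0.015, seed = 261)
  unk <- simulate_specimens(
    simulate_species_means(make_template(11, "wing"), 2, 0.06, seed = 261),
    15, 0.015, seed = 263)
  ap <- procrustes_classify(refs, unk)$records$assigned
  am <- classify_one_by_one(refs, unk)$records$assigned
  expect_gt(mean(ap == am), 0.95)
})

test_that("singleton species are excluded from LOO with a warning", {
  d <- make_two_species(6, 0.1, 0.01, seed = 271)
  lone <- d$configurations[[1]]
  lone$specimen_id <- "lone"; lone$species <- "species_99"
  d3 <- landmark_dataset(c(d$configurations, list(lone)))
  expect_warning(loo <- loo_errors(d3, "procrustes"), "singleton")
  expect_false("species_99" %in% loo$error_table$species)
})

test_that("classification reports serialize to JSON and text", {
  d <- make_two_species(6, 0.1, 0.01, seed = 281)
  rep <- procrustes_classify(d, d)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, fj)
  write_report(rep, ft)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$method, "procrustes")
  expect_equal(nrow(parsed$records), 12)
  expect_true(any(grepl("Total errors", readLines(ft))))
})
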
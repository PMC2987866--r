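test_that("centroid size matches closed forms and a direct sum-of-squares oracle", {
  sq <- landmark_config(cbind(c(1, 1, -1, -1), c(1, -1, -1, 1)), "sq")
  expect_equal(centroid_size(sq), 2 * sqrt(2), tolerance = 1e-12)
  th <- 2 * pi * (0:2) / 3
  tri <- landmark_config(cbind(cos(th), sin(th)), "tri")
  expect_equal(centroid_size(tri), sqrt(3), tolerance = 1e-12)

  for (s in 1:5) {
    cfg <- rand_config(11, s)
    m <- cfg$coords
    ctr <- c(mean(m[, 1]), mean(m[, 2]))
    ss <- 0
    for (i in 1:11) ss <- ss + sum((m[i, ] - ctr)^2)  # loop-computed oracle
    expect_equal(centroid_size(cfg), sqrt(ss), tolerance = 1e-12)
  }
  # scaling equivariance and translation invariance
  cfg <- rand_config(8, 99)
  expect_equal(centroid_size(similarity_transform(cfg, 0, 3.7, c(0, 0))),
               3.7 * centroid_size(cfg), tolerance = 1e-12)
  expect_equal(centroid_size(similarity_transform(cfg, 0, 1, c(100, -40))),
               centroid_size(cfg), tolerance = 1e-10)
  # degenerate configuration returns 0 with a warning, not an error
  degen <- landmark_dataset(list(landmark_config(matrix(2, 3, 2), "d")),
                            validate = FALSE)$configurations[[1]]
  expect_warning(cs0 <- centroid_size(degen), "degenerate")
  expect_equal(cs0, 0)
})

test_that("preshape centers, normalizes, is idempotent and similarity-stable", {
  for (s in 1:5) {
    cfg <- rand_config(7, s + 20)
    p <- preshape(cfg)
    expect_equal(colMeans(p$coords), c(x = 0, y = 0), tolerance = 1e-12)
    expect_equal(centroid_size(p), 1, tolerance = 1e-12)
    expect_equal(preshape(p)$coords, p$coords, tolerance = 1e-12)
    # translation + scaling (no rotation) leaves the preshape unchanged
    t_cfg <- similarity_transform(cfg, 0, 2.5, c(10, -3))
    expect_equal(preshape(t_cfg)$coords, p$coords, tolerance = 1e-12)
  }
})

test_that("opa recovers exact similarity transforms and excludes reflections", {
  cfg <- rand_config(11, 31)
  moved <- similarity_transform(cfg, pi / 6, 1, c(5, -2))
  fit <- opa(cfg, moved)
  expect_lt(fit$distance, 1e-10)
  expect_equal(abs(fit$angle), pi / 6, tolerance = 1e-8)
  expect_equal(fit$aligned$coords, cfg$coords, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(fit$rotation), diag(2), tolerance = 1e-10)

  # scaling recovery
  moved2 <- similarity_transform(cfg, -0.8, 3.2, c(1, 1))
  fit2 <- opa(cfg, moved2, allow_scaling = TRUE)
  expect_equal(fit2$scale, 1 / 3.2, tolerance = 1e-8)
  expect_equal(fit2$aligned$coords, cfg$coords, tolerance = 1e-7)

  # a mirror image cannot be fitted by rotation alone
  mirror <- cfg; mirror$coords[, 1] <- -mirror$coords[, 1]
  expect_gt(opa(cfg, mirror)$distance, 0.05)

  expect_error(opa(cfg, rand_config(9, 1)), "mismatch")
})

test_that("opa matches the exhaustive rotation grid search", {
  for (s in 1:10) {
    a <- rand_config(11, 1000 + s)
    b <- rand_config(11, 2000 + s)
    orc <- opa_grid_oracle(a, b)
    expect_equal(opa(a, b)$distance, orc$distance, tolerance = 1e-6)
  }
})

test_that("gpa collapses replicated shapes, is order-invariant and monotone", {
  # n copies of one configuration under random similarity transforms
  base <- rand_config(8, 55)
  set.seed(56)
  cfgs <- lapply(1:6, function(i) {
    out <- similarity_transform(base, runif(1, 0, 2 * pi), exp(runif(1, -1, 1)),
                                runif(2, -5, 5))
    out$specimen_id <- paste0("c", i)
    out
  })
  fit <- gpa(landmark_dataset(cfgs))
  for (i in 1:6)
    expect_lt(procrustes_distance(fit$aligned[, , i], fit$consensus), 1e-8)
  expect_equal(colMeans(fit$consensus), c(x = 0, y = 0), tolerance = 1e-10)
  expect_equal(.cs_test(fit$consensus), 1, tolerance = 1e-10)

  d <- make_two_species(10, 0.05, 0.01, seed = 60)
  fit1 <- gpa(d)
  # objective trace never increases
  expect_true(all(diff(fit1$objective_trace) <= 1e-12))
  # every aligned specimen keeps unit centroid size (unit-CS convention)
  for (i in seq_len(dim(fit1$aligned)[3]))
    expect_equal(.cs_test(fit1$aligned[, , i]), 1, tolerance = 1e-10)
  # permuting input order: identical consensus and per-key aligned shapes
  perm <- sample(seq_len(n_specimens(d)))
  fit2 <- gpa(subset_dataset(d, perm))
  expect_equal(fit2$consensus, fit1$consensus, tolerance = 1e-10)
  expect_equal(fit2$aligned[, , fit1$keys], fit1$aligned[, , fit1$keys],
               tolerance = 1e-8)
})

test_that("gpa results are invariant to similarity transforms of any input specimen", {
  d <- make_two_species(8, 0.05, 0.01, seed = 71)
  fit1 <- gpa(d)
  d2 <- d
  # transform a middle specimen and the one the fit is initialized from
  for (i in c(1L, 5L)) {
    cfg <- d2$configurations[[i]]
    d2$configurations[[i]] <- similarity_transform(cfg, 1.1, 0.4, c(8, 8))
  }
  fit2 <- gpa(d2)
  expect_equal(tail(fit2$objective_trace, 1), tail(fit1$objective_trace, 1),
               tolerance = 1e-8)
  expect_lt(procrustes_distance(fit2$consensus, fit1$consensus), 1e-8)
  D1 <- distance_matrix(d); D2 <- distance_matrix(d2)
  expect_equal(unclass(D2), unclass(D1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("gpa consensus converges to the true mean shape", {
  tpl <- make_template(11, "wing")
  d <- simulate_specimens(list(tpl), 200, 0.01, seed = 81)
  fit <- gpa(d)
  expect_true(fit$converged)
  expect_lt(procrustes_distance(fit$consensus, tpl$coords), 0.005)
})

test_that("tangent coordinates vanish at the consensus and span 2k - 4 dimensions", {
  d <- make_two_species(10, 0.05, 0.01, seed = 91)
  fit <- gpa(d)
  TT <- tangent_coordinates(fit)
  k <- landmark_count(d)
  sv <- svd(TT)$d
  expect_lt(sv[2 * k - 3], 1e-10)          # rank <= 2k - 4
  expect_gt(sv[2 * k - 4] / sv[1], 1e-8)   # and generically equal to it
  # the consensus itself projects to zero
  cvec <- as.vector(fit$consensus)
  expect_equal(as.vector(cvec - sum(cvec * cvec) * cvec), rep(0, 2 * k),
               tolerance = 1e-12)
  # identical shapes give identical rows
  two <- landmark_dataset(list(
    landmark_config(fit$consensus + 0.01, "a"),
    similarity_transform(landmark_config(fit$consensus + 0.01, "b"), 0.3, 2, c(1, 1))))
  T2 <- tangent_coordinates(gpa(two))
  expect_equal(T2[1, ], T2[2, ], tolerance = 1e-10)
})

test_that("tangent distances approximate Procrustes distances at small dispersion", {
  d <- make_two_species(10, 0.02, 0.005, seed = 95)
  fit <- gpa(d)
  TT <- tangent_coordinates(fit)
  D <- distance_matrix(d, "partial")
  ut <- upper.tri(D)
  expect_lt(max(abs(as.matrix(dist(TT))[ut] - D[ut]) / D[ut]), 0.01)
})

test_that("procrustes_distance is a similarity-invariant shape metric", {
  set.seed(101)
  for (s in 1:8) {
    a <- rand_config(9, 300 + s); b <- rand_config(9, 400 + s)
    expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-12)
    # partial = 2 sin(geodesic / 2), full = sin(geodesic)
    g <- procrustes_distance(a, b, "geodesic")
    expect_equal(procrustes_distance(a, b, "partial"), 2 * sin(g / 2),
                 tolerance = 1e-10)
    expect_equal(procrustes_distance(a, b, "full"), sin(g), tolerance = 1e-10)
    # invariance to similarity transforms of either argument
    bt <- similarity_transform(b, runif(1, 0, 2 * pi), exp(runif(1, -1, 1)),
                               runif(2, -10, 10))
    expect_lt(abs(procrustes_distance(a, bt) - procrustes_distance(a, b)), 1e-8)
  }
  # triangle inequality for the geodesic variant
  for (s in 1:10) {
    a <- rand_config(7, 500 + s); b <- rand_config(7, 600 + s)
    c_ <- rand_config(7, 700 + s)
    expect_lte(procrustes_distance(a, c_, "geodesic"),
               procrustes_distance(a, b, "geodesic") +
                 procrustes_distance(b, c_, "geodesic") + 1e-10)
  }
})

test_that("distance_matrix agrees with element-wise calls and exports cleanly", {
  d <- make_two_species(4, 0.05, 0.01, seed = 111)
  D <- distance_matrix(d)
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_equal(diag(D), rep(0, 8), ignore_attr = TRUE)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(D[i, j],
                 procrustes_distance(d$configurations[[i]], d$configurations[[j]]),
                 tolerance = 1e-12)
  # identical shapes give an all-zero matrix
  one <- d$configurations[[1]]
  trip <- landmark_dataset(lapply(1:3, function(i) {
    x <- one; x$specimen_id <- paste0("t", i); x
  }))
  expect_equal(max(distance_matrix(trip)), 0, tolerance = 1e-12)
  # round-trip of the CSV export
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(D, f, "csv")
  back <- read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(D), tolerance = 1e-9,
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(D, f2, "phylip")
  expect_equal(readLines(f2)[1], "8")
})
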
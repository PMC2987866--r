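# stylized 11-landmark wing template (unit CS after standardization):
# 9 outline points following a wing margin plus 2 interior vein landmarks;
# deliberately non-symmetric and non-collinear
.WING11 <- cbind(
  x = c(0.00, 0.18, 0.42, 0.70, 0.92, 0.80, 0.55, 0.30, 0.12, 0.35, 0.60),
  y = c(0.05, 0.12, 0.16, 0.12, 0.02, -0.06, -0.10, -0.09, -0.05, 0.03, 0.02))

#' Template mean shapes for simulations
#'
#' `polygon`: regular k-gon; `wing`: a fixed stylized 11-point insect wing
#' (outline plus interior vein landmarks), resampled along its outline for
#' other k.  Both are centered and scaled to unit centroid size.
#'
#' @param k landmark count (>= 3 for `polygon`, >= 4 for `wing`).
#' @param kind `"polygon"` or `"wing"`.
#' @return a [landmark_config()] at unit centroid size.
#' @export
make_template <- function(k, kind = c("polygon", "wing")) {
  kind <- match.arg(kind)
  if (kind == "polygon") {
    if (k < 3L) .stopf("polygon template needs k >= 3")
    th <- 2 * pi * (seq_len(k) - 1L) / k
    m <- cbind(cos(th), sin(th))
  } else {
    if (k < 4L) .stopf("wing template needs k >= 4")
    if (k == 11L) m <- .WING11
    else {
      # resample the closed outline polyline at k slightly irregular arc
      # positions (irregularity avoids accidental symmetry/collinearity)
      P <- rbind(.WING11[1:9, ], .WING11[1, ])
      seg <- sqrt(rowSums(diff(P)^2))
      cum <- c(0, cumsum(seg)); tot <- cum[length(cum)]
      u <- (seq_len(k) - 1L) / k + 0.013 * sin(7 * seq_len(k))
      u <- (u %% 1) * tot
      m <- t(vapply(u, function(s) {
        j <- findInterval(s, cum, rightmost.closed = TRUE)
        w <- (s - cum[j]) / seg[j]
        (1 - w) * P[j, ] + w * P[j + 1L, ]
      }, numeric(2)))
    }
  }
  landmark_config(preshape(m), sprintf("template_%s_k%d", kind, k))
}

# orthonormal basis of the tangent space at a unit preshape (2k x (2k-4)):
# complement of translations, the preshape itself and its rotation
.tangent_complement <- function(C) {
  k <- nrow(C)
  cx <- C[, 1]; cy <- C[, 2]; one <- rep(1, k) / sqrt(k); zer <- numeric(k)
  Pm <- cbind(c(one, zer), c(zer, one), c(cx, cy), c(-cy, cx))
  Pm
}

# random unit tangent direction at preshape C
.random_tangent <- function(C) {
  Pm <- .tangent_complement(C)
  z <- rnorm(2L * nrow(C))
  z <- z - Pm %*% solve(crossprod(Pm), crossprod(Pm, z))
  as.vector(z / sqrt(sum(z^2)))
}

#' Simulate species mean shapes around a template
#'
#' Each species mean is the template displaced along a random tangent-space
#' direction, rescaled so that its partial Procrustes distance from the
#' template equals `separation` exactly.  The pairwise distances between
#' the generated means are recorded as ground truth.
#'
#' @param template a [landmark_config()] (any size; its preshape is used).
#' @param n_species number of species.
#' @param separation partial Procrustes distance of each mean from the
#'   template (>= 0).
#' @param seed mandatory integer seed.
#' @return list of [landmark_config()] means (named `species_01`, ...)
#'   with attribute `"truth"`: a list holding `separation` and the pairwise
#'   distance matrix between the means.
#' @export
simulate_species_means <- function(template, n_species, separation, seed) {
  if (separation < 0) .stopf("separation must be >= 0")
  set.seed(seed)
  C <- preshape(.coords(template))
  cvec <- .vec2(C)
  # tangent displacement delta giving exact partial distance s after
  # renormalization: cos(rho) = 1/sqrt(1+delta^2), s = 2 sin(rho/2)
  delta <- if (separation == 0) 0 else tan(2 * asin(separation / 2))
  means <- lapply(seq_len(n_species), function(i) {
    v <- if (delta == 0) cvec else {
      t_dir <- .random_tangent(C)
      w <- cvec + delta * t_dir
      w / sqrt(sum(w^2))
    }
    landmark_config(.unvec2(v), sprintf("species_%02d", i),
                    species = sprintf("species_%02d", i))
  })
  D <- matrix(0, n_species, n_species)
  if (n_species > 1L) for (i in seq_len(n_species - 1L))
    for (j in seq.int(i + 1L, n_species)) {
      D[i, j] <- D[j, i] <- procrustes_distance(means[[i]], means[[j]])
    }
  attr(means, "truth") <- list(separation = separation, pairwise_distances = D)
  means
}

#' Simulate specimens around species means
#'
#' Each specimen is its species mean plus i.i.d. Gaussian coordinate noise
#' of SD `sigma_shape` (in units of the unit-CS mean), then pushed through
#' a random similarity transform — rotation uniform on the circle,
#' log-scale uniform in [-0.2, 0.2], translation uniform in [-1, 1]^2 — to
#' emulate arbitrary digitizing frames.  True species labels are attached.
#'
#' @param means list of species mean configurations (e.g. from
#'   [simulate_species_means()]).
#' @param n_per_species specimens per species.
#' @param sigma_shape within-species coordinate SD (>= 0).
#' @param seed mandatory integer seed.
#' @return a species-labelled [landmark_dataset()] with attribute
#'   `"truth"` (species of every specimen).
#' @export
simulate_specimens <- function(means, n_per_species, sigma_shape, seed) {
  if (sigma_shape < 0) .stopf("sigma_shape must be >= 0")
  set.seed(seed)
  cfgs <- list()
  for (s in seq_along(means)) {
    M <- preshape(.coords(means[[s]]))
    k <- nrow(M)
    spname <- if (!is.null(means[[s]]$species) && !is.na(means[[s]]$species))
      means[[s]]$species else sprintf("species_%02d", s)
    for (i in seq_len(n_per_species)) {
      m <- M + matrix(rnorm(2L * k, sd = sigma_shape), k, 2L)
      th <- runif(1, 0, 2 * pi)
      sc <- exp(runif(1, -0.2, 0.2))
      tr <- runif(2, -1, 1)
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
      m <- sc * m %*% R + rep(tr, each = k)
      cfgs[[length(cfgs) + 1L]] <-
        landmark_config(m, sprintf("%s_%03d", spname, i), species = spname)
    }
  }
  d <- landmark_dataset(cfgs, provenance = sprintf("simulated (seed %d)", seed))
  attr(d, "truth") <- data.frame(specimen_id = specimen_ids(d),
                                 species = species_labels(d),
                                 stringsAsFactors = FALSE)
  d
}

# draw one persistent per-landmark offset field for a user (k x 2)
.user_offsets <- function(k, delta_persistent, seed) {
  set.seed(seed)
  matrix(rnorm(2L * k, sd = delta_persistent), k, 2L)
}

#' Apply a user's digitization error model
#'
#' Models the "user effect": a user who re-digitizes landmarks introduces
#' (a) a persistent per-landmark offset — the same small displacement of
#' e.g. landmark 3 on every specimen, drawn once per user from an isotropic
#' Gaussian with SD `delta_persistent` — plus (b) fresh i.i.d. pointing
#' noise with SD `sigma_point` at each digitization.  Both are expressed
#' relative to unit centroid size and scaled by each specimen's CS, since
#' pointing error grows with the rendered size of the structure.
#'
#' The persistent offset is expressed in the digitizing (image) frame —
#' the frame in which the user actually points: parallax, display and
#' motor habits bias the cursor the same way in screen coordinates however
#' the specimen happens to be oriented on the photograph.  Because
#' specimens are mounted and photographed in arbitrary orientations, a
#' screen-frame bias projects onto a different anatomical displacement for
#' every specimen.  This is precisely what makes a second user harmful in
#' practice: the bias does not cancel between specimens, so it inflates
#' pairwise-distance scatter and among-specimen variance as well as
#' depressing pooled two-user repeatability.  (A bias anchored purely to
#' the anatomy would shift all shapes equally and largely cancel from
#' pairwise comparisons.)
#'
#' With `n_replicates > 1` each specimen is digitized that many times by
#' the user (same persistent offset, fresh pointing noise), with
#' `replicate_id` set accordingly.
#'
#' @param dataset a [landmark_dataset()].
#' @param user_id label recorded on the outputs.
#' @param delta_persistent SD of the persistent per-landmark offset (>= 0).
#' @param sigma_point SD of the per-digitization pointing noise (>= 0).
#' @param seed mandatory integer seed; the persistent offsets depend only
#'   on `seed` (and k), so two calls with the same seed share them.
#' @param n_replicates digitizations per specimen (default 1).
#' @return a [landmark_dataset()] with `user_id` (and `replicate_id`) set.
#' @export
apply_user_effect <- function(dataset, user_id, delta_persistent, sigma_point,
                              seed, n_replicates = 1L) {
  if (delta_persistent < 0 || sigma_point < 0)
    .stopf("error magnitudes must be >= 0")
  k <- landmark_count(dataset)
  O <- .user_offsets(k, delta_persistent, seed)
  set.seed(.derive_seed(seed, 1L))
  cfgs <- list()
  for (i in seq_along(dataset$configurations)) {
    cfg <- dataset$configurations[[i]]
    cs <- .cs(cfg$coords)
    for (r in seq_len(n_replicates)) {
      new <- cfg
      new$coords <- cfg$coords + cs * O +
        matrix(rnorm(2L * k, sd = cs * sigma_point), k, 2L)
      new$user_id <- as.character(user_id)
      if (n_replicates > 1L || !is.na(cfg$replicate_id))
        new$replicate_id <- as.character(r)
      cfgs[[length(cfgs) + 1L]] <- new
    }
  }
  out <- landmark_dataset(cfgs, provenance = dataset$provenance)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Replicate digitizations with pointing noise
#'
#' Duplicates every specimen `n_replicates` times with independent pointing
#' noise (SD `sigma_point`, scaled by the specimen's centroid size) and
#' attaches replicate ids — the input design for [repeatability_anova()].
#' Averaging the replicates is the classical way to shrink measurement
#' error: the within-specimen variance of the replicate mean drops by
#' about 1/n_replicates.
#'
#' @param dataset a [landmark_dataset()].
#' @param n_replicates >= 2 digitizations per specimen.
#' @param sigma_point pointing-noise SD (>= 0).
#' @param seed mandatory integer seed.
#' @return a [landmark_dataset()] with `replicate_id` set.
#' @export
simulate_replicates <- function(dataset, n_replicates, sigma_point, seed) {
  if (n_replicates < 2L) .stopf("n_replicates must be >= 2")
  if (sigma_point < 0) .stopf("sigma_point must be >= 0")
  set.seed(seed)
  k <- landmark_count(dataset)
  cfgs <- list()
  for (cfg in dataset$configurations) {
    cs <- .cs(cfg$coords)
    for (r in seq_len(n_replicates)) {
      new <- cfg
      new$coords <- cfg$coords + matrix(rnorm(2L * k, sd = cs * sigma_point), k, 2L)
      new$replicate_id <- as.character(r)
      cfgs[[length(cfgs) + 1L]] <- new
    }
  }
  out <- landmark_dataset(cfgs, provenance = dataset$provenance)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Simulate a full study scenario
#'
#' Wires the generator stages together from a single scenario description:
#' template -> species means -> specimens -> per-user digitizations with
#' replicates.  Every stage is seeded deterministically from the scenario
#' seed, so the same scenario reproduces byte-identical datasets.
#'
#' @param scenario named list (or path to a YAML/JSON file) with fields
#'   `k`, `template` ("polygon"/"wing"), `n_species`, `separation`,
#'   `sigma_shape`, `n_per_species`, `n_replicates`, `seed`, and `users`: a
#'   list of lists with `user_id`, `delta_persistent`, `sigma_point`.  With
#'   no `users` entry the specimens are returned undigitized (no error
#'   model).
#' @return list with `dataset` (all users' digitizations bound together)
#'   and `truth` (data frame of specimen species plus the scenario and the
#'   planted pairwise mean distances).
#' @export
simulate_scenario <- function(scenario) {
  if (is.character(scenario) && length(scenario) == 1L) {
    scenario <- if (grepl("\\.json$", scenario, ignore.case = TRUE))
      jsonlite::read_json(scenario, simplifyVector = TRUE)
    else yaml::read_yaml(scenario)
  }
  need <- c("k", "n_species", "separation", "sigma_shape",
            "n_per_species", "seed")
  miss <- setdiff(need, names(scenario))
  if (length(miss)) .stopf("scenario is missing: %s", paste(miss, collapse = ", "))
  seed <- as.integer(scenario$seed)
  tpl <- make_template(scenario$k, scenario$template %||% "wing")
  means <- simulate_species_means(tpl, scenario$n_species, scenario$separation,
                                  seed = .derive_seed(seed, 101L))
  base <- simulate_specimens(means, scenario$n_per_species, scenario$sigma_shape,
                             seed = .derive_seed(seed, 202L))
  users <- scenario$users
  if (is.null(users) || length(users) == 0L) {
    dataset <- base
  } else {
    if (!is.null(names(users[[1]])) == FALSE) .stopf("users must be a list of lists")
    parts <- lapply(seq_along(users), function(j) {
      u <- users[[j]]
      apply_user_effect(base, u$user_id %||% sprintf("user%d", j),
                        u$delta_persistent %||% 0, u$sigma_point %||% 0,
                        seed = .derive_seed(seed, 300L + j),
                        n_replicates = scenario$n_replicates %||% 1L)
    })
    dataset <- do.call(bind_datasets, parts)
  }
  truth <- attr(base, "truth")
  truth_tab <- merge(
    data.frame(specimen_id = specimen_ids(dataset),
               user = user_ids(dataset), replicate = replicate_ids(dataset),
               stringsAsFactors = FALSE),
    truth, by = "specimen_id", sort = FALSE)
  list(dataset = dataset,
       truth = list(specimens = truth_tab,
                    mean_pairwise_distances = attr(means, "truth")$pairwise_distances,
                    scenario = scenario))
}

#' Monte-Carlo misclassification oracle for a planted two-class overlap
#'
#' Independent reference value for classification tests on synthetic data:
#' draws points from the two planted tangent-space distributions — isotropic
#' Gaussians with per-dimension SD `sigma` whose means are `separation`
#' apart in a `dim`-dimensional space — classifies each draw by the true
#' rule (nearest class mean, which is the Bayes rule for equal isotropic
#' classes), and reports the misclassification rate with its 95% binomial
#' confidence interval.
#'
#' @param separation distance between the two class means.
#' @param sigma per-dimension SD of the class distributions.
#' @param dim dimensionality of the planted space (e.g. 2k - 4).
#' @param n_draws Monte-Carlo sample size (default 1e5).
#' @param seed integer seed.
#' @return list with `error`, `ci` (length-2), `n_draws`.
#' @export
overlap_error_oracle <- function(separation, sigma, dim, n_draws = 1e5, seed = 1L) {
  set.seed(seed)
  n1 <- floor(n_draws / 2); n2 <- n_draws - n1
  m2 <- c(separation, numeric(dim - 1L))
  X1 <- matrix(rnorm(n1 * dim, sd = sigma), n1, dim)
  X2 <- sweep(matrix(rnorm(n2 * dim, sd = sigma), n2, dim), 2L, m2, "+")
  err1 <- rowSums(sweep(X1, 2L, m2)^2) < rowSums(X1^2)
  err2 <- rowSums(X2^2) < rowSums(sweep(X2, 2L, m2)^2)
  e <- (sum(err1) + sum(err2)) / n_draws
  half <- 1.96 * sqrt(e * (1 - e) / n_draws)
  list(error = e, ci = c(max(0, e - half), min(1, e + half)), n_draws = n_draws)
}
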
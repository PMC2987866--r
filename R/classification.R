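# tie tolerance for nearest-distance assignment (relative)
.TIE_TOL <- 1e-9

# nearest-group assignment with deterministic lexicographic tie-break
.assign_nearest <- function(d) {
  # d: named nonnegative distances, names sorted lexicographically by caller
  dmin <- min(d)
  cand <- names(d)[d <= dmin * (1 + .TIE_TOL) + .Machine$double.xmin]
  list(assigned = sort(cand)[1], tie = length(cand) > 1L)
}

#' Fit a canonical variate (discriminant) model on reference shape variables
#'
#' Canonical variate analysis standardizes the within-group variance: with
#' pooled within-group covariance W and group means, the Mahalanobis
#' distance between any two points equals the Euclidean distance between
#' their images in the whitened space, and up to g - 1 discriminant axes
#' separate the g groups.  The model is fitted from the rows of
#' `shape_vars` exclusively — unknown (supplementary) specimens are never
#' part of the fit.
#'
#' Partial-warp input is first reduced to relative-warp axes to control the
#' rank of W: by default the smallest number of axes explaining 95% of the
#' variance, capped at n - g - 1.
#'
#' @param shape_vars a `shape_variables` (partial or relative warps) whose
#'   rows are the reference specimens.
#' @param labels species label for every score row (length n, no NA).
#' @param retain passed to [relative_warps()] (count or variance fraction);
#'   default `0.95` with the n - g - 1 cap.
#' @param ridge nonnegative regularization: `ridge * trace(W)/m` is added
#'   to the diagonal of W (default 0, i.e. plain CVA).
#' @return an object of class `cva_model`: group labels and means, pooled
#'   within-group covariance, discriminant axes (columns, scaled to unit
#'   within-group variance), the projection from the input score space, the
#'   consensus signature the scores were computed under, per-group 95th
#'   percentile of member-to-mean Mahalanobis distances (outlier
#'   thresholds), and training keys.
#' @export
fit_cva <- function(shape_vars, labels, retain = NULL, ridge = 0) {
  if (!inherits(shape_vars, "shape_variables")) .stopf("shape_vars must be shape_variables")
  labels <- as.character(labels)
  n <- nrow(shape_vars$scores)
  if (length(labels) != n) .stopf("labels must cover all %d score rows", n)
  if (anyNA(labels)) .stopf("labels must be non-missing for every reference row")
  groups <- sort(unique(labels))
  g <- length(groups)
  if (g < 2L) .stopf("need at least 2 species among the references")
  # rank control: reduce partial warps to retained relative-warp axes
  if (shape_vars$kind == "partial_warps") {
    cap <- max(1L, n - g - 1L)
    rw <- relative_warps(shape_vars, retain = retain %||% 0.95)
    if (ncol(rw$scores) > cap) {
      rw$scores <- rw$scores[, seq_len(cap), drop = FALSE]
      rw$basis <- rw$basis[seq_len(cap), , drop = FALSE]
      rw$score_center <- rw$score_center[seq_len(cap)]
      rw$eigenvalues <- rw$eigenvalues[seq_len(cap)]
    }
    pc_rotation <- .rw_rotation(shape_vars, rw)
    pc_center <- colMeans(shape_vars$scores)
    X <- rw$scores
  } else {
    m0 <- ncol(shape_vars$scores)
    r <- if (is.null(retain)) m0
    else if (length(retain) == 1L && retain > 0 && retain < 1) {
      ev <- shape_vars$eigenvalues
      which(cumsum(ev) / sum(ev) >= retain)[1]
    } else min(as.integer(retain), m0)
    pc_rotation <- diag(1, m0)[, seq_len(r), drop = FALSE]
    pc_center <- numeric(m0)
    X <- shape_vars$scores[, seq_len(r), drop = FALSE]
  }
  m <- ncol(X)
  means <- rowsum(X, labels) / as.vector(table(labels)[groups])
  W <- matrix(0, m, m)
  for (grp in groups) {
    Xi <- X[labels == grp, , drop = FALSE]
    Xi <- sweep(Xi, 2L, means[grp, ])
    W <- W + crossprod(Xi)
  }
  if (n - g < m && ridge == 0)
    .stopf(paste("pooled within-group covariance is singular (n - g = %d < %d",
                 "retained dimensions); lower `retain` or set `ridge` > 0"),
           n - g, m)
  W <- W / (n - g)
  if (ridge > 0) W <- W + diag(ridge * sum(diag(W)) / m, m)
  ch <- tryCatch(chol(W), error = function(e)
    .stopf(paste("pooled within-group covariance is singular;",
                 "lower `retain` or set `ridge` > 0")))
  # discriminant axes: whiten, eigen-decompose the between-group scatter
  Tinv <- backsolve(ch, diag(1, m))
  mu <- colMeans(X)
  ng <- as.vector(table(labels)[groups])
  Bm <- crossprod(sweep(means, 2L, mu) * sqrt(ng)) / max(1L, g - 1L)
  Bw <- t(Tinv) %*% Bm %*% Tinv
  egB <- eigen((Bw + t(Bw)) / 2, symmetric = TRUE)
  naxes <- min(g - 1L, m)
  axes <- Tinv %*% egB$vectors[, seq_len(naxes), drop = FALSE]
  model <- structure(list(
    group_labels = groups, group_means = means,
    pooled_within_covariance = W, chol_W = ch,
    discriminant_axes = axes, axis_eigenvalues = egB$values[seq_len(naxes)],
    pc_rotation = pc_rotation, pc_center = pc_center,
    input_kind = shape_vars$kind, input_dim = ncol(shape_vars$scores),
    retained = m, ridge = ridge,
    consensus_signature = shape_vars$consensus_signature,
    training_keys = shape_vars$keys, n_per_group = ng
  ), class = "cva_model")
  # per-group outlier thresholds: 95th percentile of members' distances to
  # their own group mean
  thr <- vapply(groups, function(grp) {
    di <- vapply(which(labels == grp), function(i)
      .mahal(model, X[i, ], grp, retained = TRUE), numeric(1))
    as.numeric(quantile(di, 0.95, type = 7))
  }, numeric(1))
  model$outlier_thresholds <- thr
  model
}

# rotation from full pw score space to retained rw space; recovered from the
# bases (rw$basis = t(V) %*% pw$basis, and pw basis rows are orthonormal)
.rw_rotation <- function(pw, rw) {
  t(rw$basis %*% t(pw$basis))
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("<cva_model> %d groups (%s), %d retained variable(s), %d axis/axes%s\n",
              length(x$group_labels), paste(x$group_labels, collapse = ", "),
              x$retained, ncol(x$discriminant_axes),
              if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else ""))
  invisible(x)
}

# Mahalanobis distance in retained space (retained = TRUE: z already there)
.mahal <- function(model, x, group, retained = FALSE) {
  z <- if (retained) x else as.vector((x - model$pc_center) %*% model$pc_rotation)
  d <- z - model$group_means[group, ]
  sqrt(sum(backsolve(model$chol_W, d, transpose = TRUE)^2))
}

#' Mahalanobis distance from a score row to a group mean
#'
#' sqrt((x - mu_g)' W^-1 (x - mu_g)) with W the model's pooled within-group
#' covariance; computed by triangular solve, no cached inverse.
#'
#' @param model a `cva_model`.
#' @param score_row numeric vector in the score space the model was fitted
#'   from (e.g. a row of the same `shape_variables` object).
#' @param group one of `model$group_labels`.
#' @return nonnegative scalar; 0 iff `score_row` projects onto the group
#'   mean.
#' @export
mahalanobis_distance <- function(model, score_row, group) {
  if (!group %in% model$group_labels)
    .stopf("unknown group '%s'", group)
  if (length(score_row) != model$input_dim)
    .stopf("score_row has length %d, model input space has %d",
           length(score_row), model$input_dim)
  .mahal(model, as.numeric(score_row), group)
}

# distances of one input-space row to every group
.mahal_all <- function(model, x) {
  vapply(model$group_labels, function(g) .mahal(model, as.numeric(x), g), numeric(1))
}

# ---- classification reports -------------------------------------------------

.build_error_table <- function(records) {
  rec <- records[!is.na(records$true), , drop = FALSE]
  if (nrow(rec) == 0L) return(NULL)
  sp <- sort(unique(rec$true))
  rows <- lapply(sp, function(s) {
    sub <- rec[rec$true == s, , drop = FALSE]
    mis <- sum(sub$assigned != sub$true)
    data.frame(species = s, misassigned = mis, total = nrow(sub),
               percent = 100 * mis / nrow(sub),
               label = sprintf("%d/%d (%.0f%%)", mis, nrow(sub), 100 * mis / nrow(sub)),
               stringsAsFactors = FALSE)
  })
  tot_mis <- sum(rec$assigned != rec$true)
  rows[[length(rows) + 1L]] <- data.frame(
    species = "Total errors", misassigned = tot_mis, total = nrow(rec),
    percent = 100 * tot_mis / nrow(rec),
    label = sprintf("%d/%d (%.0f%%)", tot_mis, nrow(rec), 100 * tot_mis / nrow(rec)),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

.classification_report <- function(records, method, metadata = list()) {
  structure(list(records = records,
                 error_table = .build_error_table(records),
                 method = method, metadata = metadata),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> method = %s%s, %d specimen(s)\n",
              x$method,
              if (!is.null(x$metadata$validation))
                paste0(" (", x$metadata$validation, ")") else "",
              nrow(x$records)))
  if (!is.null(x$error_table)) {
    cat("Assignation errors:\n")
    for (i in seq_len(nrow(x$error_table)))
      cat(sprintf("  %-24s %s\n", x$error_table$species[i], x$error_table$label[i]))
  } else {
    tb <- table(x$records$assigned)
    cat("Assignments:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  nt <- sum(x$records$tie); no <- sum(x$records$outlier)
  if (nt) cat(sprintf("  %d tied assignment(s) broken lexicographically\n", nt))
  if (no) cat(sprintf("  %d assignment(s) flagged as outliers\n", no))
  invisible(x)
}

#' Write a classification report
#'
#' @param report a `classification_report`.
#' @param path output path; `.json` gets the full machine-readable report,
#'   anything else a human-readable text table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(method = report$method, metadata = report$metadata,
                              records = report$records,
                              error_table = report$error_table),
                         path, digits = NA, auto_unbox = TRUE, na = "null")
  } else {
    con <- textConnection("out", "w", local = TRUE)
    sink(con); print(report); sink()
    close(con)
    writeLines(out, path)
  }
  invisible(path)
}

# ---- Procrustes classification ----------------------------------------------

#' Classify unknowns by Procrustes distance to reference species
#'
#' For each species a consensus is estimated by GPA over its reference
#' specimens; every unknown is then assigned to the species minimizing
#' either the Procrustes distance to the species consensus
#' (`nearest_consensus`, the default) or the distance to the closest
#' individual reference specimen (`nearest_individual`).  Both distance
#' sets are reported.  An assignment is flagged as an outlier when the
#' unknown's distance to the winning consensus exceeds the 95th percentile
#' of that species' own member-to-consensus distances: a shortest distance
#' may still be an important one, so statistical discrimination does not by
#' itself establish biological identification.
#'
#' @param references species-labelled [landmark_dataset()] (>= 2 species).
#' @param unknowns dataset of specimens to classify (species labels, if
#'   present, are treated as the truth for the error table).
#' @param rule `"nearest_consensus"` or `"nearest_individual"`.
#' @param variant Procrustes distance variant (default `"partial"`).
#' @return a `classification_report`; `records` has one row per unknown
#'   with the distance to every species consensus (`d_<species>`), the
#'   distance to the nearest individual reference (`nearest_ref_dist`,
#'   with `nearest_ref_species`), tie and outlier flags.
#' @export
procrustes_classify <- function(references, unknowns,
                                rule = c("nearest_consensus", "nearest_individual"),
                                variant = "partial") {
  rule <- match.arg(rule)
  sp <- species_labels(references)
  if (anyNA(sp)) .stopf("all reference specimens must carry a species label")
  groups <- sort(unique(sp))
  if (length(groups) < 2L) .stopf("need at least 2 reference species")
  if (landmark_count(references) != landmark_count(unknowns))
    .stopf("landmark count mismatch between references (%d) and unknowns (%d)",
           landmark_count(references), landmark_count(unknowns))
  cons <- list(); members <- list(); thr <- numeric(0)
  for (g in groups) {
    sub <- subset_dataset(references, sp == g)
    if (n_specimens(sub) >= 2L) {
      fit <- gpa(sub)
      cons[[g]] <- fit$consensus
    } else {
      .warnf("species '%s' has a single reference specimen; its consensus is that specimen", g)
      cons[[g]] <- preshape(sub$configurations[[1]]$coords)
    }
    members[[g]] <- lapply(sub$configurations, function(c) preshape(c$coords))
    di <- vapply(members[[g]], function(p)
      procrustes_distance(p, cons[[g]], variant = variant), numeric(1))
    thr[g] <- as.numeric(quantile(di, 0.95, type = 7))
  }
  recs <- lapply(seq_len(n_specimens(unknowns)), function(i) {
    u <- unknowns$configurations[[i]]
    up <- preshape(u$coords)
    d_cons <- vapply(groups, function(g)
      procrustes_distance(up, cons[[g]], variant = variant), numeric(1))
    d_ind <- vapply(groups, function(g)
      min(vapply(members[[g]], function(p)
        procrustes_distance(up, p, variant = variant), numeric(1))), numeric(1))
    d_used <- if (rule == "nearest_consensus") d_cons else d_ind
    asg <- .assign_nearest(d_used)
    rec <- data.frame(specimen_id = u$specimen_id, key = .config_key(u),
                      method = "procrustes", rule = rule,
                      assigned = asg$assigned, tie = asg$tie,
                      outlier = d_cons[asg$assigned] > thr[asg$assigned],
                      true = u$species,
                      nearest_ref_dist = min(d_ind),
                      nearest_ref_species = groups[which.min(d_ind)],
                      converged = TRUE,
                      stringsAsFactors = FALSE)
    for (g in groups) rec[[paste0("d_", g)]] <- d_cons[[g]]
    rec
  })
  .classification_report(do.call(rbind, recs), "procrustes",
                         list(rule = rule, variant = variant))
}

# ---- one-by-one Mahalanobis classification ----------------------------------

#' One-by-one Mahalanobis classification of unknown specimens
#'
#' The supplementary-specimen protocol for discriminant classification:
#' each unknown is processed independently — (i) GPA over the references
#' plus that single unknown, (ii) partial warps for all n + 1 specimens
#' relative to that joint consensus, (iii) a canonical variate model fitted
#' on the reference rows exclusively, (iv) the unknown projected and
#' assigned to the species with the smallest Mahalanobis distance.
#' Processing all unknowns against one joint consensus is deliberately not
#' offered here: a batch of external specimens would shift the consensus,
#' degrade the reference discrimination, and make every score depend on the
#' composition of the unknown set.  One consequence of the protocol is that
#' each unknown's assignment is invariant to the order and composition of
#' the other unknowns.
#'
#' @inheritParams procrustes_classify
#' @param retain,ridge passed to [fit_cva()].
#' @param include_uniform passed to [partial_warps()].
#' @return a `classification_report` with per-species Mahalanobis distances
#'   (`d_<species>`), tie/outlier flags and a `converged` flag per specimen
#'   (FALSE when the joint GPA failed to converge; the specimen is still
#'   classified).
#' @export
classify_one_by_one <- function(references, unknowns, retain = NULL, ridge = 0,
                                include_uniform = TRUE) {
  sp <- species_labels(references)
  if (anyNA(sp)) .stopf("all reference specimens must carry a species label")
  groups <- sort(unique(sp))
  if (length(groups) < 2L) .stopf("need at least 2 reference species")
  if (landmark_count(references) != landmark_count(unknowns))
    .stopf("landmark count mismatch between references (%d) and unknowns (%d)",
           landmark_count(references), landmark_count(unknowns))
  nref <- n_specimens(references)
  recs <- lapply(seq_len(n_specimens(unknowns)), function(i) {
    u <- unknowns$configurations[[i]]
    # the unknown enters the joint GPA as its own supplementary digitization;
    # tag it so its key cannot collide with a reference it duplicates
    u_tag <- u
    u_tag$replicate_id <- paste0(ifelse(is.na(u$replicate_id), "", u$replicate_id),
                                 "@unknown")
    comb <- landmark_dataset(c(references$configurations, list(u_tag)),
                             provenance = references$provenance, validate = FALSE)
    fit <- withCallingHandlers(gpa(comb),
                               warning = function(w) invokeRestart("muffleWarning"))
    pw <- partial_warps(fit, include_uniform = include_uniform)
    model <- fit_cva(pw[seq_len(nref)], sp, retain = retain, ridge = ridge)
    d <- .mahal_all(model, pw$scores[nref + 1L, ])
    asg <- .assign_nearest(d)
    rec <- data.frame(specimen_id = u$specimen_id, key = .config_key(u),
                      method = "mahalanobis", rule = "one_by_one",
                      assigned = asg$assigned, tie = asg$tie,
                      outlier = d[asg$assigned] >
                        model$outlier_thresholds[asg$assigned],
                      true = u$species,
                      nearest_ref_dist = NA_real_,
                      nearest_ref_species = NA_character_,
                      converged = fit$converged,
                      stringsAsFactors = FALSE)
    for (g in groups) rec[[paste0("d_", g)]] <- d[[g]]
    rec
  })
  .classification_report(do.call(rbind, recs), "mahalanobis",
                         list(protocol = "one_by_one", ridge = ridge,
                              include_uniform = include_uniform))
}

# ---- leave-one-out error tables ---------------------------------------------

#' Leave-one-out assignation-error table
#'
#' Each reference specimen is removed in turn, treated as the single
#' unknown via the chosen protocol ([procrustes_classify()] or
#' [classify_one_by_one()]), and scored against its true species.  The
#' result is a per-species "misassigned/total (percent)" table plus a total
#' row.  The validation design is recorded in the report metadata as
#' `"leave-one-out"`.
#'
#' @param references species-labelled [landmark_dataset()], >= 2 specimens
#'   per species (singleton species are excluded with a warning).
#' @param method `"procrustes"` or `"mahalanobis"`.
#' @param rule,variant passed to [procrustes_classify()].
#' @param retain,ridge,include_uniform passed to [classify_one_by_one()].
#' @return a `classification_report`.
#' @export
loo_errors <- function(references, method = c("procrustes", "mahalanobis"),
                       rule = "nearest_consensus", variant = "partial",
                       retain = NULL, ridge = 0, include_uniform = TRUE) {
  method <- match.arg(method)
  sp <- species_labels(references)
  if (anyNA(sp)) .stopf("all reference specimens must carry a species label")
  counts <- table(sp)
  single <- names(counts)[counts < 2L]
  if (length(single)) {
    .warnf("excluding singleton species from leave-one-out: %s",
           paste(single, collapse = ", "))
    references <- subset_dataset(references, !sp %in% single)
    sp <- species_labels(references)
  }
  if (length(unique(sp)) < 2L) .stopf("need at least 2 species with >= 2 specimens")
  n <- n_specimens(references)
  recs <- lapply(seq_len(n), function(i) {
    refs_i <- subset_dataset(references, -i)
    unk <- subset_dataset(references, i)
    rep_i <- suppressWarnings(
      if (method == "procrustes")
        procrustes_classify(refs_i, unk, rule = rule, variant = variant)
      else
        classify_one_by_one(refs_i, unk, retain = retain, ridge = ridge,
                            include_uniform = include_uniform))
    rep_i$records
  })
  common <- Reduce(intersect, lapply(recs, names))
  recs <- lapply(recs, function(r) r[, common, drop = FALSE])
  .classification_report(do.call(rbind, recs), method,
                         list(validation = "leave-one-out", rule = rule))
}
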
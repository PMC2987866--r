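# vectorized one-way ANOVA repeatability over the columns of X, with
# individuals as groups; handles unbalanced designs via the ANOVA
# coefficient n0 = (N - sum(n_i^2)/N) / (a - 1)
.anova_R <- function(X, individual) {
  ind <- factor(individual)
  a <- nlevels(ind); N <- nrow(X)
  n_i <- as.vector(table(ind))
  if (a < 2L) .stopf("repeatability needs at least 2 individuals")
  if (any(n_i < 2L))
    .stopf("every individual needs >= 2 replicate digitizations (found one with %d)",
           min(n_i))
  G <- rowsum(X, ind) / n_i
  grand <- colMeans(X)
  ss_among <- colSums(n_i * sweep(G, 2L, grand)^2)
  ss_total <- colSums(sweep(X, 2L, grand)^2)
  ss_within <- pmax(0, ss_total - ss_among)
  ms_among <- ss_among / (a - 1L)
  ms_within <- ss_within / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1L)
  s2_among <- (ms_among - ms_within) / n0
  denom <- s2_among + ms_within
  R <- ifelse(denom > 0, s2_among / denom, ifelse(ms_within == 0 & ms_among > 0, 1, 0))
  R <- pmin(1, pmax(0, R))
  # columns with no variance at all carry no repeatability information
  R[ss_total <= .Machine$double.eps * N] <- NA_real_
  list(R = R, n0 = n0, a = a)
}

#' ANOVA-based repeatability of landmark digitization
#'
#' Quantifies measurement error by partitioning the variance of each shape
#' variable into among-individual and within-individual (replicate)
#' components with a one-way ANOVA: s2_among = (MS_among - MS_within) / r
#' (r = replicates per individual, or the n0 coefficient when replication
#' is unbalanced) and R = s2_among / (s2_among + MS_within), truncated to
#' [0, 1].  R near 1 means re-digitization barely perturbs the variable;
#' low R means measurement error swamps true among-individual differences.
#'
#' All digitizations enter a single joint GPA; variables are either the
#' partial-warp scores (default — the same space the classification works
#' in) or the 2k aligned preshape coordinates.
#'
#' @param dataset a [landmark_dataset()] in which each individual
#'   (identified by `specimen_id`) appears with >= 2 replicate
#'   digitizations (distinguished by `replicate_id` and/or `user_id`).
#' @param variable_kind `"partial_warps"` or `"coordinates"`.
#' @param design label stored on the result (`"one_user"` or
#'   `"two_users"`); informational only.
#' @return an object of class `repeatability_result`: `per_variable_R`
#'   (data frame variable/R), `mean_R`, `sd_R` (across variables),
#'   `design`, `n_individuals`, `n_replicates` (the n0 coefficient),
#'   `variable_kind`.
#' @export
repeatability_anova <- function(dataset,
                                variable_kind = c("partial_warps", "coordinates"),
                                design = "one_user") {
  variable_kind <- match.arg(variable_kind)
  fit <- gpa(dataset)
  X <- if (variable_kind == "partial_warps") {
    partial_warps(fit)$scores
  } else {
    n <- dim(fit$aligned)[3]; k <- nrow(fit$consensus)
    M <- t(vapply(seq_len(n), function(i) .vec2(fit$aligned[, , i]),
                  numeric(2L * k)))
    colnames(M) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
    rownames(M) <- fit$keys
    M
  }
  res <- .anova_R(X, specimen_ids(dataset))
  keep <- !is.na(res$R)
  structure(list(
    per_variable_R = data.frame(variable = colnames(X)[keep], R = res$R[keep],
                                stringsAsFactors = FALSE),
    mean_R = mean(res$R[keep]), sd_R = sd(res$R[keep]),
    design = design, n_individuals = res$a, n_replicates = res$n0,
    variable_kind = variable_kind
  ), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability_result> %s, %d individuals x %.3g replicates (%s)\n",
              x$design, x$n_individuals, x$n_replicates, x$variable_kind))
  cat(sprintf("  mean repeatability R: %.4f ± %.4f (%d variables)\n",
              x$mean_R, x$sd_R, nrow(x$per_variable_R)))
  invisible(x)
}

#' Compare one-user and two-user repeatability (the user effect)
#'
#' Splits a dataset digitized by two users into (a) each user's own
#' replicate series, giving the one-user repeatability, and (b) the pooled
#' digitizations of both users treated as replicates of the same
#' individuals, giving the two-user repeatability.  Persistent per-landmark
#' pointing differences between users inflate the within-individual
#' variance of the pooled design, so a systematic drop of the two-user R
#' below the one-user R is the signature of a user effect.
#'
#' @param dataset a [landmark_dataset()] whose configurations carry exactly
#'   two distinct `user_id` values; each specimen must be digitized by both
#'   users (others are dropped with a warning).  The per-user one-user R
#'   requires >= 2 replicates per specimen within that user (otherwise that
#'   component is `NULL`).
#' @param variable_kind passed to [repeatability_anova()].
#' @return an object of class `user_comparison`: `one_user` (named list of
#'   `repeatability_result`, one per user), `two_users`
#'   (`repeatability_result` for the pooled design), and `difference`
#'   (mean one-user mean_R minus two-user mean_R; positive under a user
#'   effect).
#' @export
compare_users <- function(dataset, variable_kind = "partial_warps") {
  us <- user_ids(dataset)
  users <- sort(unique(us[!is.na(us)]))
  if (length(users) != 2L)
    .stopf("compare_users needs exactly 2 users, found %d", length(users))
  ids <- specimen_ids(dataset)
  by_user <- lapply(users, function(u) unique(ids[us == u]))
  common <- intersect(by_user[[1]], by_user[[2]])
  dropped <- setdiff(unique(ids), common)
  if (length(dropped)) {
    .warnf("dropping %d specimen(s) not digitized by both users: %s",
           length(dropped), paste(head(dropped, 5), collapse = ", "))
  }
  keep <- ids %in% common & !is.na(us)
  dataset <- subset_dataset(dataset, keep)
  us <- user_ids(dataset); ids <- specimen_ids(dataset)
  one_user <- stats::setNames(lapply(users, function(u) {
    sub <- subset_dataset(dataset, us == u)
    reps <- table(specimen_ids(sub))
    if (any(reps < 2L)) return(NULL)
    r <- repeatability_anova(sub, variable_kind = variable_kind, design = "one_user")
    r
  }), users)
  two_users <- repeatability_anova(dataset, variable_kind = variable_kind,
                                   design = "two_users")
  ou_means <- vapply(one_user, function(r) if (is.null(r)) NA_real_ else r$mean_R,
                     numeric(1))
  structure(list(one_user = one_user, two_users = two_users,
                 difference = mean(ou_means, na.rm = TRUE) - two_users$mean_R),
            class = "user_comparison")
}

#' @export
print.user_comparison <- function(x, ...) {
  for (u in names(x$one_user)) {
    r <- x$one_user[[u]]
    if (is.null(r)) cat(sprintf("  one user (%s): not estimable (single replicate)\n", u))
    else cat(sprintf("  one user (%s): R = %.4f ± %.4f\n", u, r$mean_R, r$sd_R))
  }
  cat(sprintf("  two users:     R = %.4f ± %.4f\n",
              x$two_users$mean_R, x$two_users$sd_R))
  if (is.finite(x$difference))
    cat(sprintf("  one-user minus two-user mean R: %+.4f\n", x$difference))
  invisible(x)
}

#' Pairwise-distance scatter between two digitization sessions
#'
#' The measurement-error amplification diagnostic: the same specimens are
#' digitized in two sessions (same or different users), all pairwise
#' Procrustes distances are computed within each session, and matched by
#' specimen pair.  If the sessions agreed perfectly every pair would fall
#' on the identity line; scatter around it visualizes how digitization
#' error propagates into the distances on which classification is based.
#'
#' @param session1,session2 datasets covering the same specimens (matched
#'   by `specimen_id`, which must be unique within each session).
#' @param variant Procrustes distance variant.
#' @return an object of class `session_scatter`: `pair_ids`,
#'   `distances_session1`, `distances_session2`, `correlation`, and
#'   `rms_deviation_from_identity` (root mean square perpendicular
#'   deviation from the identity line; 0 iff the sessions give identical
#'   distances).
#' @export
session_scatter <- function(session1, session2, variant = "partial") {
  id1 <- specimen_ids(session1); id2 <- specimen_ids(session2)
  if (anyDuplicated(id1) || anyDuplicated(id2))
    .stopf("specimen ids must be unique within each session")
  un1 <- setdiff(id1, id2); un2 <- setdiff(id2, id1)
  if (length(un1) || length(un2))
    .stopf("sessions do not cover the same specimens; unmatched: %s",
           paste(c(un1, un2), collapse = ", "))
  session2 <- subset_dataset(session2, match(id1, id2))
  D1 <- distance_matrix(session1, variant = variant)
  D2 <- distance_matrix(session2, variant = variant)
  ut <- upper.tri(D1)
  pairs <- which(ut, arr.ind = TRUE)
  d1 <- D1[ut]; d2 <- D2[ut]
  corr <- if (sd(d1) == 0 || sd(d2) == 0) {
    if (all(d1 == d2)) 1 else NA_real_
  } else cor(d1, d2)
  structure(list(
    pair_ids = paste(id1[pairs[, 1]], id1[pairs[, 2]], sep = "|"),
    distances_session1 = d1, distances_session2 = d2,
    correlation = corr,
    rms_deviation_from_identity = sqrt(mean((d1 - d2)^2) / 2)
  ), class = "session_scatter")
}

#' @export
print.session_scatter <- function(x, ...) {
  cat(sprintf("<session_scatter> %d specimen pairs\n", length(x$pair_ids)))
  cat(sprintf("  correlation: %.4f, RMS deviation from identity: %.6g\n",
              x$correlation, x$rms_deviation_from_identity))
  invisible(x)
}

#' @export
#' @importFrom graphics abline plot.default
plot.session_scatter <- function(x, ...) {
  plot.default(x$distances_session1, x$distances_session2,
       xlab = "pairwise Procrustes distance, session 1",
       ylab = "pairwise Procrustes distance, session 2", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Export matched session distances
#'
#' @param scatter a `session_scatter`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_scatter <- function(scatter, path) {
  write.csv(data.frame(pair = scatter$pair_ids,
                       session1 = scatter$distances_session1,
                       session2 = scatter$distances_session2),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
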
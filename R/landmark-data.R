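#' Create a single landmark configuration
#'
#' A configuration is the ordered set of 2-D landmarks digitized on one
#' specimen, together with the metadata the downstream repeatability and
#' classification stages need.  Landmark order is positional: landmark i is
#' assumed operationally homologous across all specimens of a dataset.
#'
#' @param coords numeric k x 2 matrix of landmark coordinates (pixel units;
#'   x rightward, y upward, origin arbitrary).  k >= 3, all values finite.
#' @param specimen_id character scalar identifying the specimen (or, for
#'   replicated digitizations, the individual being re-digitized).
#' @param scale_factor optional positive scalar, length units per pixel.
#' @param species optional species label; labelled configurations form the
#'   reference partition of a dataset.
#' @param user_id,replicate_id optional digitization labels used by the
#'   repeatability and user-effect analyses.
#' @param extra named list of free-form metadata (sex, locality, date, ...).
#' @return An object of class `landmark_config`.
#' @examples
#' tri <- landmark_config(cbind(c(0, 1, 0), c(0, 0, 1)), "t1")
#' centroid_size(tri)
#' @export
landmark_config <- function(coords, specimen_id,
                            scale_factor = NULL,
                            species = NA_character_,
                            user_id = NA_character_,
                            replicate_id = NA_character_,
                            extra = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) .stopf("coords must have 2 columns, got %d", ncol(coords))
  if (nrow(coords) < 3L) .stopf("a configuration needs k >= 3 landmarks, got %d", nrow(coords))
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) .stopf("non-finite coordinate in specimen '%s'", specimen_id)
  if (!is.null(scale_factor)) {
    scale_factor <- as.numeric(scale_factor)
    if (!is.finite(scale_factor) || scale_factor <= 0)
      .stopf("scale_factor must be a positive number (specimen '%s')", specimen_id)
  }
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(
    specimen_id = as.character(specimen_id),
    coords = coords,
    scale_factor = scale_factor,
    species = as.character(species),
    user_id = as.character(user_id),
    replicate_id = as.character(replicate_id),
    extra = extra
  ), class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> '%s': %d landmarks, CS = %.6g%s%s\n",
              x$specimen_id, nrow(x$coords), centroid_size(x),
              if (!is.na(x$species)) paste0(", species = ", x$species) else "",
              if (!is.na(x$user_id)) paste0(", user = ", x$user_id) else ""))
  invisible(x)
}

# unique digitization key: one physical specimen may be digitized several
# times (users/replicates); the triple must be unique within a dataset
.config_key <- function(cfg) {
  paste(cfg$specimen_id,
        ifelse(is.na(cfg$user_id), "", cfg$user_id),
        ifelse(is.na(cfg$replicate_id), "", cfg$replicate_id),
        sep = "|")
}

#' Assemble landmark configurations into a dataset
#'
#' All configurations of a dataset must share the landmark count and order.
#' Digitizations are identified by the triple (specimen_id, user_id,
#' replicate_id), which must be unique; the same specimen_id may appear
#' several times when it was digitized repeatedly.
#'
#' @param configurations list of [landmark_config()] objects.
#' @param provenance free-text record of where the data came from.
#' @param validate run [validate_dataset()] and fail on violations
#'   (default TRUE).  Set to FALSE to build a deliberately invalid dataset
#'   for inspection.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(configurations, provenance = "", validate = TRUE) {
  if (!is.list(configurations) || length(configurations) == 0L)
    .stopf("configurations must be a non-empty list")
  ok <- vapply(configurations, inherits, logical(1), "landmark_config")
  if (!all(ok)) .stopf("element %d is not a landmark_config", which(!ok)[1])
  d <- structure(list(
    configurations = configurations,
    landmark_count = nrow(configurations[[1]]$coords),
    provenance = provenance
  ), class = "landmark_dataset")
  if (validate) {
    rep <- validate_dataset(d)
    if (nrow(rep$violations) > 0L)
      .stopf("invalid dataset: %s", paste(rep$violations$message, collapse = "; "))
  }
  d
}

#' @export
print.landmark_dataset <- function(x, ...) {
  sp <- species_labels(x)
  cat(sprintf("<landmark_dataset> %d configurations, k = %d landmarks\n",
              n_specimens(x), landmark_count(x)))
  if (any(!is.na(sp))) {
    tb <- table(sp[!is.na(sp)])
    cat("  species:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  us <- unique(user_ids(x)); us <- us[!is.na(us)]
  if (length(us)) cat("  users:", paste(us, collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Dataset accessors
#'
#' @param dataset a `landmark_dataset`.
#' @return `n_specimens()`: number of configurations; `landmark_count()`:
#'   k; `specimen_ids()`, `species_labels()`, `user_ids()`,
#'   `replicate_ids()`: per-configuration character vectors;
#'   `specimen_keys()`: unique digitization keys; `coords_array()`:
#'   a k x 2 x n array of raw coordinates.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
n_specimens <- function(dataset) length(dataset$configurations)

#' @rdname dataset-accessors
#' @export
landmark_count <- function(dataset) dataset$landmark_count

#' @rdname dataset-accessors
#' @export
specimen_ids <- function(dataset)
  vapply(dataset$configurations, function(c) c$specimen_id, character(1))

#' @rdname dataset-accessors
#' @export
specimen_keys <- function(dataset)
  vapply(dataset$configurations, .config_key, character(1))

#' @rdname dataset-accessors
#' @export
species_labels <- function(dataset)
  vapply(dataset$configurations, function(c) c$species, character(1))

#' @rdname dataset-accessors
#' @export
user_ids <- function(dataset)
  vapply(dataset$configurations, function(c) c$user_id, character(1))

#' @rdname dataset-accessors
#' @export
replicate_ids <- function(dataset)
  vapply(dataset$configurations, function(c) c$replicate_id, character(1))

#' @rdname dataset-accessors
#' @export
coords_array <- function(dataset) {
  k <- landmark_count(dataset); n <- n_specimens(dataset)
  a <- array(NA_real_, c(k, 2L, n),
             dimnames = list(NULL, c("x", "y"), specimen_keys(dataset)))
  for (i in seq_len(n)) a[, , i] <- dataset$configurations[[i]]$coords
  a
}

#' Subset or combine landmark datasets
#'
#' @param dataset a `landmark_dataset`.
#' @param i integer or logical index over configurations.
#' @return a `landmark_dataset`.
#' @export
subset_dataset <- function(dataset, i) {
  landmark_dataset(dataset$configurations[i], provenance = dataset$provenance)
}

#' @rdname subset_dataset
#' @param ... datasets to concatenate (same k).
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  landmark_dataset(do.call(c, lapply(ds, function(d) d$configurations)),
                   provenance = paste(unique(vapply(ds, function(d) d$provenance,
                                                    character(1))), collapse = " + "))
}

#' Attach metadata columns to a dataset
#'
#' Joins a data frame of per-specimen metadata (columns among `specimen_id`,
#' `species`, `user`, `replicate`, `scale`) onto the matching configurations.
#'
#' @param dataset a `landmark_dataset`.
#' @param meta data frame with a `specimen_id` column.
#' @return the updated dataset.
#' @export
attach_metadata <- function(dataset, meta) {
  if (!"specimen_id" %in% names(meta)) .stopf("meta needs a 'specimen_id' column")
  idx <- match(specimen_ids(dataset), as.character(meta$specimen_id))
  cfgs <- dataset$configurations
  for (i in seq_along(cfgs)) {
    j <- idx[i]
    if (is.na(j)) next
    if ("species" %in% names(meta)) cfgs[[i]]$species <- as.character(meta$species[j])
    if ("user" %in% names(meta)) cfgs[[i]]$user_id <- as.character(meta$user[j])
    if ("replicate" %in% names(meta)) cfgs[[i]]$replicate_id <- as.character(meta$replicate[j])
    if ("scale" %in% names(meta) && is.finite(meta$scale[j]))
      cfgs[[i]]$scale_factor <- as.numeric(meta$scale[j])
  }
  landmark_dataset(cfgs, provenance = dataset$provenance)
}

#' Validate a landmark dataset
#'
#' Checks the dataset invariants (non-empty, uniform landmark count, finite
#' coordinates, unique digitization keys, no configuration collapsed to
#' fewer than 3 distinct points) and returns a report rather than erroring.
#' Missing scale factors produce warnings, not violations: shape analysis is
#' scale-free, but centroid sizes digitized on different devices are only
#' comparable once pixels are converted to length units.
#'
#' @param dataset a `landmark_dataset` (possibly built with
#'   `validate = FALSE`).
#' @return An object of class `validation_report`: a list with data frames
#'   `violations` and `warnings`, each with columns `kind`, `specimen`,
#'   `message`.  An empty `violations` table means the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  viol <- list(); warns <- list()
  add_v <- function(kind, specimen, msg)
    viol[[length(viol) + 1L]] <<- data.frame(kind = kind, specimen = specimen,
                                             message = msg, stringsAsFactors = FALSE)
  add_w <- function(kind, specimen, msg)
    warns[[length(warns) + 1L]] <<- data.frame(kind = kind, specimen = specimen,
                                               message = msg, stringsAsFactors = FALSE)
  cfgs <- dataset$configurations
  if (length(cfgs) == 0L) {
    add_v("empty", NA_character_, "dataset has no configurations")
  } else {
    ks <- vapply(cfgs, function(c) nrow(c$coords), integer(1))
    if (length(unique(ks)) > 1L)
      add_v("landmark-count", NA_character_,
            sprintf("mixed landmark counts: %s", paste(unique(ks), collapse = ", ")))
    keys <- vapply(cfgs, .config_key, character(1))
    dup <- keys[duplicated(keys)]
    for (d in unique(dup))
      add_v("duplicate-key", d, sprintf("duplicated digitization key '%s'", d))
    for (cfg in cfgs) {
      if (!all(is.finite(cfg$coords)))
        add_v("non-finite", cfg$specimen_id,
              sprintf("non-finite coordinate in '%s'", cfg$specimen_id))
      else if (nrow(unique(cfg$coords)) < 3L)
        add_v("degenerate-configuration", cfg$specimen_id,
              sprintf("'%s' has fewer than 3 distinct landmark positions", cfg$specimen_id))
      if (is.null(cfg$scale_factor))
        add_w("missing-scale", cfg$specimen_id,
              sprintf("'%s' has no pixel-to-length scale factor", cfg$specimen_id))
    }
  }
  empty <- data.frame(kind = character(), specimen = character(),
                      message = character(), stringsAsFactors = FALSE)
  structure(list(
    violations = if (length(viol)) do.call(rbind, viol) else empty,
    warnings = if (length(warns)) do.call(rbind, warns) else empty
  ), class = "validation_report")
}

#' @rdname validate_dataset
#' @param report a `validation_report`.
#' @export
is_valid <- function(report) nrow(report$violations) == 0L

#' @export
print.validation_report <- function(x, ...) {
  if (is_valid(x)) cat("valid dataset (no violations)\n")
  else {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s\n", x$violations$kind[i], x$violations$message[i]))
  }
  if (nrow(x$warnings) > 0L)
    cat(sprintf("%d warning(s), e.g.: %s\n", nrow(x$warnings), x$warnings$message[1]))
  invisible(x)
}

# split a labelled dataset into its reference (species-labelled) and
# unknown partitions
reference_partition <- function(dataset) {
  sp <- species_labels(dataset)
  list(references = if (any(!is.na(sp))) subset_dataset(dataset, !is.na(sp)) else NULL,
       unknowns = if (any(is.na(sp))) subset_dataset(dataset, is.na(sp)) else NULL)
}
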
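#' Read landmark coordinates from a plain table
#'
#' Two dialects are supported.  `wide`: one specimen per row with 2k
#' coordinate columns named `x1, y1, ..., xk, yk` (case-insensitive) plus
#' optional metadata columns `specimen_id` (or `id`), `species`, `user`,
#' `replicate`, `scale`.  `long`: one landmark per row with columns
#' `specimen_id`, `landmark`, `x`, `y` plus the same metadata columns
#' (constant within a specimen).
#'
#' @param path path to a delimited text file.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field separator; defaults to tab for `.tsv` files, comma
#'   otherwise.
#' @return a [landmark_dataset()].
#' @seealso [write_table()]
#' @export
read_table <- function(path, dialect = c("wide", "long"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  if (dialect == "wide") .table_wide(df) else .table_long(df)
}

.meta_col <- function(df, names_) {
  hit <- intersect(names_, tolower(names(df)))
  if (length(hit) == 0L) return(NULL)
  df[[which(tolower(names(df)) == hit[1])[1]]]
}

.table_wide <- function(df) {
  cn <- tolower(names(df))
  xcols <- grep("^x[0-9]+$", cn); ycols <- grep("^y[0-9]+$", cn)
  if (length(xcols) == 0L) .stopf("no coordinate columns (x1, y1, ...) found")
  if (length(xcols) != length(ycols))
    .stopf("unpaired coordinate columns: %d x vs %d y", length(xcols), length(ycols))
  xi <- as.integer(sub("^x", "", cn[xcols])); yi <- as.integer(sub("^y", "", cn[ycols]))
  if (!setequal(xi, yi))
    .stopf("x and y column indices do not match")
  k <- length(xcols)
  xcols <- xcols[order(xi)]; ycols <- ycols[order(yi)]
  ids <- .meta_col(df, c("specimen_id", "id", "specimen"))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
  species <- .meta_col(df, c("species", "group"))
  user <- .meta_col(df, c("user", "user_id"))
  repl <- .meta_col(df, c("replicate", "replicate_id", "session"))
  scale <- .meta_col(df, c("scale", "scale_factor"))
  cfgs <- lapply(seq_len(nrow(df)), function(i) {
    coords <- cbind(as.numeric(df[i, xcols]), as.numeric(df[i, ycols]))
    if (any(is.na(coords))) .stopf("non-numeric coordinate in row %d", i)
    landmark_config(coords, as.character(ids[i]),
                    scale_factor = if (!is.null(scale) && is.finite(as.numeric(scale[i])))
                      as.numeric(scale[i]) else NULL,
                    species = if (!is.null(species)) as.character(species[i]) else NA_character_,
                    user_id = if (!is.null(user)) as.character(user[i]) else NA_character_,
                    replicate_id = if (!is.null(repl)) as.character(repl[i]) else NA_character_)
  })
  landmark_dataset(cfgs)
}

.table_long <- function(df) {
  cn <- tolower(names(df))
  need <- c("specimen_id", "landmark", "x", "y")
  alt <- list(specimen_id = c("specimen_id", "id", "specimen"),
              landmark = c("landmark", "lm", "point"),
              x = "x", y = "y")
  cols <- lapply(alt, function(a) {
    j <- which(cn %in% a)
    if (length(j) == 0L) NA_integer_ else j[1]
  })
  miss <- need[vapply(cols, is.na, logical(1))]
  if (length(miss)) .stopf("long table missing column(s): %s", paste(miss, collapse = ", "))
  sid <- as.character(df[[cols$specimen_id]])
  lm <- as.integer(df[[cols$landmark]])
  species <- .meta_col(df, c("species", "group"))
  user <- .meta_col(df, c("user", "user_id"))
  repl <- .meta_col(df, c("replicate", "replicate_id", "session"))
  scale <- .meta_col(df, c("scale", "scale_factor"))
  # a digitization is identified by (specimen, user, replicate); the same
  # specimen may legitimately recur across users/replicates
  digit <- paste(sid,
                 if (is.null(user)) "" else as.character(user),
                 if (is.null(repl)) "" else as.character(repl), sep = "\r")
  key <- paste(digit, lm)
  if (anyDuplicated(key))
    .stopf("duplicated (specimen, landmark) pair: %s",
           gsub("\r", "/", key[duplicated(key)][1]))
  uid <- unique(digit)
  cfgs <- lapply(uid, function(s) {
    rows <- which(digit == s)
    rows <- rows[order(lm[rows])]
    coords <- cbind(as.numeric(df[[cols$x]][rows]), as.numeric(df[[cols$y]][rows]))
    if (any(is.na(coords)))
      .stopf("non-numeric coordinate for specimen '%s'", gsub("\r.*", "", s))
    r1 <- rows[1]
    landmark_config(coords, sid[r1],
                    scale_factor = if (!is.null(scale) && is.finite(as.numeric(scale[r1])))
                      as.numeric(scale[r1]) else NULL,
                    species = if (!is.null(species)) as.character(species[r1]) else NA_character_,
                    user_id = if (!is.null(user)) as.character(user[r1]) else NA_character_,
                    replicate_id = if (!is.null(repl)) as.character(repl[r1]) else NA_character_)
  })
  landmark_dataset(cfgs)
}

#' Write a dataset as a coordinate table
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path.
#' @param dialect `"wide"` or `"long"` (see [read_table()]).
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_table <- function(dataset, path, dialect = c("wide", "long"), sep = ",") {
  dialect <- match.arg(dialect)
  k <- landmark_count(dataset)
  meta <- data.frame(specimen_id = specimen_ids(dataset),
                     species = species_labels(dataset),
                     user = user_ids(dataset),
                     replicate = replicate_ids(dataset),
                     scale = vapply(dataset$configurations,
                                    function(c) c$scale_factor %||% NA_real_, numeric(1)),
                     stringsAsFactors = FALSE)
  if (dialect == "wide") {
    a <- coords_array(dataset)
    cm <- matrix(NA_real_, n_specimens(dataset), 2L * k)
    for (j in seq_len(k)) { cm[, 2L * j - 1L] <- a[j, 1, ]; cm[, 2L * j] <- a[j, 2, ] }
    colnames(cm) <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
    df <- cbind(meta, as.data.frame(cm))
  } else {
    rows <- lapply(seq_len(n_specimens(dataset)), function(i) {
      cfg <- dataset$configurations[[i]]
      data.frame(specimen_id = cfg$specimen_id, landmark = seq_len(k),
                 x = cfg$coords[, 1], y = cfg$coords[, 2],
                 species = cfg$species, user = cfg$user_id,
                 replicate = cfg$replicate_id,
                 scale = cfg$scale_factor %||% NA_real_,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  # drop all-NA metadata columns to keep files minimal
  keep <- vapply(df, function(col) !all(is.na(col)), logical(1))
  df <- df[, keep, drop = FALSE]
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @importFrom utils write.table
NULL
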
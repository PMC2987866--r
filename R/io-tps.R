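#' Read a TPS landmark file
#'
#' TPS is the community-standard plain-text format for 2-D landmark data:
#' each record starts with an `LM=<k>` line followed by k coordinate lines,
#' optionally followed by `ID=`, `IMAGE=` and `SCALE=` lines.  The parser is
#' liberal about dialects seen in the wild: keywords are case-insensitive,
#' Windows and Unix line endings are accepted, and coordinates may be
#' separated by whitespace or commas.  Coordinates are kept at full printed
#' precision and record order is preserved.
#'
#' The specimen id is taken from `ID=`, falling back to the `IMAGE=`
#' basename, and finally to the running record index.
#'
#' @param path path to a TPS file.
#' @return a [landmark_dataset()].
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  cfgs <- list()
  i <- 1L; nrec <- 0L
  nline <- length(lines)
  while (i <= nline) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    m <- regmatches(line, regexec("^[Ll][Mm]\\s*=\\s*([0-9]+)\\s*$", line))[[1]]
    if (length(m) == 0L)
      .stopf("line %d: expected an LM= record header, got '%s'", i, line)
    k <- as.integer(m[2])
    nrec <- nrec + 1L
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      while (i <= nline && !nzchar(trimws(lines[i]))) i <- i + 1L
      if (i > nline || grepl("^[A-Za-z]+\\s*=", trimws(lines[i])))
        .stopf("record %d: LM=%d announced but only %d coordinate line(s) found",
               nrec, k, j - 1L)
      parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
      if (length(parts) != 2L)
        .stopf("line %d: expected 'x y', got '%s'", i, lines[i])
      xy <- suppressWarnings(as.numeric(parts))
      if (any(is.na(xy)))
        .stopf("line %d: non-numeric coordinate '%s'", i, lines[i])
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NULL; scale <- NULL
    repeat {
      if (i > nline) break
      line <- trimws(lines[i])
      if (!nzchar(line)) { i <- i + 1L; next }
      if (grepl("^[Ll][Mm]\\s*=", line)) break
      kv <- regmatches(line, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
      if (length(kv) == 0L)
        .stopf("line %d: unexpected content '%s' (extra coordinate line?)", i, line)
      key <- toupper(kv[2]); val <- trimws(kv[3])
      if (key == "ID") id <- val
      else if (key == "IMAGE") image <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale)) .stopf("line %d: non-numeric SCALE '%s'", i, val)
      }
      # other keys (CURVES, COMMENT, ...) are tolerated and ignored
      i <- i + 1L
    }
    if (is.null(id))
      id <- if (!is.null(image)) sub("\\.[^.]*$", "", basename(image)) else as.character(nrec)
    cfgs[[nrec]] <- landmark_config(coords, id, scale_factor = scale,
                                    extra = if (!is.null(image)) list(image = image) else list())
  }
  if (length(cfgs) == 0L) .stopf("no TPS records found in %s", path)
  ks <- vapply(cfgs, function(c) nrow(c$coords), integer(1))
  if (length(unique(ks)) > 1L)
    .stopf("mixed landmark counts across records: %s", paste(unique(ks), collapse = ", "))
  landmark_dataset(cfgs, provenance = path)
}

#' Write a dataset as a TPS file
#'
#' Coordinates are written with 17 significant digits so that
#' `read_tps(write_tps(d))` round-trips them exactly; `SCALE=` lines are
#' emitted only for configurations that carry a scale factor.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path (UTF-8 text).
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  out <- character(0)
  for (cfg in dataset$configurations) {
    out <- c(out, sprintf("LM=%d", nrow(cfg$coords)),
             sprintf("%.17g %.17g", cfg$coords[, 1], cfg$coords[, 2]),
             sprintf("ID=%s", cfg$specimen_id))
    if (!is.null(cfg$extra$image)) out <- c(out, sprintf("IMAGE=%s", cfg$extra$image))
    if (!is.null(cfg$scale_factor)) out <- c(out, sprintf("SCALE=%.17g", cfg$scale_factor))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}
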
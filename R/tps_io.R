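#' Write landmark configurations to a TPS file
#'
#' Standard TPS landmark records: an `LM=k` (2D) or `LM3=k` (3D) header, one
#' whitespace-separated coordinate row per landmark, then an `ID=` provenance
#' line. Coordinates are written with six decimals so that
#' write -> read -> write is bit-identical.
#'
#' @param configs a [landmarks()] object or list of them.
#' @param path output file path.
#' @param digits coordinate decimals (default 6, the conventional precision;
#'   pipeline intermediates use more to keep stages numerically equivalent).
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, digits = 6L) {
  if (inherits(configs, "landmarks")) configs <- list(configs)
  fmt <- paste0("%.", digits, "f")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cf in configs) {
    d <- ncol(cf$coords)
    key <- if (d == 3L) "LM3" else "LM"
    writeLines(sprintf("%s=%d", key, nrow(cf$coords)), con)
    writeLines(apply(cf$coords, 1L,
                     function(r) paste(sprintf(fmt, r), collapse = " ")),
               con)
    writeLines(sprintf("ID=%s", cf$label), con)
  }
  invisible(path)
}

#' Read landmark configurations from a TPS file
#'
#' Parses `LM=`/`LM3=` records with an optional `ID=` line; other `KEY=`
#' lines (IMAGE, SCALE, ...) are ignored.
#'
#' @param path TPS file path.
#' @return list of [landmarks()] objects.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^(LM3?)=([0-9]+)$", ln))[[1L]]
    if (length(m) == 0L) { i <- i + 1L; next }
    k <- as.integer(m[3L])
    coords <- matrix(NA_real_, k, if (m[2L] == "LM3") 3L else 2L)
    for (j in seq_len(k)) {
      vals <- as.numeric(strsplit(trimws(lines[i + j]), "[[:space:]]+")[[1L]])
      if (length(vals) != ncol(coords))
        stop("malformed coordinate row in TPS file at line ", i + j)
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    label <- ""
    while (i <= length(lines) && grepl("^[A-Z0-9]+=", trimws(lines[i])) &&
           !grepl("^LM3?=", trimws(lines[i]))) {
      ln2 <- trimws(lines[i])
      if (startsWith(ln2, "ID=")) label <- sub("^ID=", "", ln2)
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- landmarks(coords, label = label)
  }
  out
}
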
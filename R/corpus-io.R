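#' Write posts as JSON Lines
#'
#' One JSON object per line, UTF-8, ISO-8601 UTC timestamps.
#'
#' @param posts Posts tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(posts, path) {
  out <- posts
  out$timestamp <- format(posts$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(out), con, verbose = FALSE,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' Read a JSON Lines post corpus
#'
#' @param path JSONL file with one post object per line.
#' @return Posts tibble with parsed UTC timestamps.
#' @export
read_corpus <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  out <- tibble::as_tibble(df)
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ")
  if (!"retweeted_user_id" %in% names(out)) out$retweeted_user_id <- NA_character_
  out
}

#' Validate a JSONL corpus file
#'
#' Checks each line parses as JSON and carries the required fields
#' (`post_id`, `user_id`, `timestamp`, `text`). A nonzero malformed count
#' raises a warning; more than 10% malformed is an error.
#'
#' @param path JSONL file.
#' @param max_malformed_frac Hard-error threshold (default 0.1).
#' @return Tibble: `n_lines`, `n_malformed`, `malformed_frac`; attribute
#'   `malformed_lines` lists the offending line numbers.
#' @export
validate_corpus <- function(path, max_malformed_frac = 0.1) {
  if (!file.exists(path)) abort(paste0("cannot read corpus file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("post_id", "user_id", "timestamp", "text")
  bad <- vapply(lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    is.null(obj) || !all(required %in% names(obj)) ||
      any(vapply(obj[required], function(v) is.null(v) || all(is.na(v)),
                 logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  n <- length(lines)
  frac <- if (n == 0) 0 else mean(bad)
  if (frac > max_malformed_frac) {
    abort(sprintf("corpus malformed beyond threshold: %d of %d lines (%.1f%%)",
                  sum(bad), n, 100 * frac))
  }
  if (any(bad)) {
    warn(sprintf("%d of %d corpus lines malformed", sum(bad), n))
  }
  out <- tibble::tibble(n_lines = n, n_malformed = sum(bad),
                        malformed_frac = frac)
  attr(out, "malformed_lines") <- which(bad)
  out
}
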
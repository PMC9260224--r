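# Internal helpers shared across modules.

# Path to a file bundled under inst/extdata.
ci_extdata <- function(file) {
  path <- system.file("extdata", file, package = "campaignimpact")
  if (!nzchar(path)) abort(paste0("bundled file not found: ", file))
  path
}

#' Default bundled resources
#'
#' Paths to the plain-text resources shipped with the package: a small
#' synthetic stand-in lexicon in the LIWC `.dic` dialect (the proprietary
#' LIWC 2015 dictionary is not redistributable), gendered first-name lists,
#' the campaign keyword set, a default diet/health baseline term list, and a
#' compact stopword list.
#'
#' @return A named list of file paths.
#' @export
#' @examples
#' default_resources()$lexicon
default_resources <- function() {
  list(
    lexicon        = ci_extdata("synthetic_liwc_standin.dic"),
    names          = ci_extdata("names_gendered.tsv"),
    campaign_terms = ci_extdata("campaign_keywords.txt"),
    baseline_terms = ci_extdata("baseline_health_terms.txt"),
    stopwords      = ci_extdata("stopwords.txt")
  )
}

#' Default word lists
#'
#' Reads the bundled campaign keywords, baseline diet/health terms, or
#' stopwords as a character vector (one term per line, `#` comments and blank
#' lines dropped).
#'
#' @param which One of `"campaign"`, `"baseline"`, `"stopwords"`.
#' @return Character vector of terms.
#' @export
default_terms <- function(which = c("campaign", "baseline", "stopwords")) {
  which <- match.arg(which)
  file <- switch(which,
    campaign  = default_resources()$campaign_terms,
    baseline  = default_resources()$baseline_terms,
    stopwords = default_resources()$stopwords
  )
  read_term_list(file)
}

#' Read a plain-text term list
#'
#' One term per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_term_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

# Validate a scalar probability.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a probability in [0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be an integer >= ", min))
  }
  invisible(as.integer(x))
}

# Run `code` under a temporary RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise run as-is.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

as_utc_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x, tz = "UTC"))
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out)) && !all(is.na(x))) abort("unparseable date input")
  out
}
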
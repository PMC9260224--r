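#' Load a gendered first-name dictionary
#'
#' Reads a two-column UTF-8 file with one `name<TAB>gender` entry per line
#' (`gender` is `female` or `male`). A name may legitimately appear under
#' both genders; the ambiguity is resolved at lookup time, not at load time.
#' Honorific rules (`mr`, `mrs`, ...) are built in.
#'
#' @param path Path to a name list; defaults to the compact open list
#'   bundled with the package (the large compiled name resources the field
#'   uses are not redistributable).
#' @return An object of class `name_dictionary`: sets `female` and `male`
#'   plus the honorific map.
#' @export
load_name_dictionary <- function(path = default_resources()$names) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  name <- stringr::str_to_lower(trimws(parts[, 1]))
  gender <- stringr::str_to_lower(trimws(parts[, 2]))
  if (any(!gender %in% c("female", "male"))) {
    abort("name list genders must be 'female' or 'male'")
  }
  structure(
    list(
      female = unique(name[gender == "female"]),
      male = unique(name[gender == "male"]),
      honorifics = c(
        mrs = "female", ms = "female", miss = "female", madam = "female",
        mr = "male", mister = "male", sir = "male"
      )
    ),
    class = "name_dictionary"
  )
}

#' @export
print.name_dictionary <- function(x, ...) {
  cat("<name_dictionary>", length(x$female), "female,", length(x$male),
      "male names;", length(x$honorifics), "honorifics\n")
  invisible(x)
}

#' Normalize a display name into lowercase tokens
#'
#' Unicode-aware: splits camel-case boundaries, strips emoji, punctuation and
#' digits, splits on whitespace and lowercases. Total function: empty or
#' `NA` input gives an empty token vector.
#'
#' @param display_name Character vector of display names.
#' @return List of character vectors (one per input).
#' @export
#' @examples
#' normalize_name("Dr.JohnSmith_99 \U0001F389")[[1]]
normalize_name <- function(display_name) {
  x <- as.character(display_name)
  x[is.na(x)] <- ""
  s <- stringr::str_replace_all(x, "(?<=\\p{Ll})(?=\\p{Lu})", " ")
  s <- stringr::str_replace_all(s, "[^\\p{L}]+", " ")
  s <- stringr::str_to_lower(stringr::str_squish(s))
  stringr::str_split(s, " ") |>
    purrr::map(~ .x[nzchar(.x)])
}

# Label one normalized token vector.
infer_gender_tokens <- function(tokens, dict) {
  hon <- dict$honorifics[tokens]
  hon <- hon[!is.na(hon)]
  if (length(hon) > 0) {
    return(list(label = unname(hon[[1]]), evidence = "honorific"))
  }
  for (tok in tokens) {
    f <- tok %in% dict$female
    m <- tok %in% dict$male
    if (f && m) next   # ambiguous token carries no label
    if (f) return(list(label = "female", evidence = "name_match"))
    if (m) return(list(label = "male", evidence = "name_match"))
  }
  list(label = "unknown", evidence = "none")
}

#' Infer gender labels from display names
#'
#' Three-class labelling (`female`/`male`/`unknown`) with the precedence: (1)
#' the first honorific token found wins (an honorific is explicit
#' self-description); (2) otherwise tokens are scanned left to right and the
#' first token found in exactly one of the two name sets labels the user — a
#' token present in both sets is ambiguous and contributes nothing; (3)
#' otherwise `unknown`. Display names lead with given names, which is why
#' first position wins. The three-class scheme cannot represent non-binary
#' identities and can mislabel them; results are aggregate tendencies, not
#' individual facts.
#'
#' @param display_name Character vector.
#' @param dict A [load_name_dictionary()] object.
#' @return Tibble: `display_name`, `label`, `evidence` (`honorific`,
#'   `name_match` or `none`).
#' @export
#' @examples
#' d <- load_name_dictionary()
#' infer_gender(c("Brigitte Lanteri", "Mr. Ashley X", "zxqvw42"), d)
infer_gender <- function(display_name, dict) {
  stopifnot(inherits(dict, "name_dictionary"))
  toks <- normalize_name(display_name)
  res <- purrr::map(toks, infer_gender_tokens, dict = dict)
  tibble::tibble(
    display_name = as.character(display_name),
    label = purrr::map_chr(res, "label"),
    evidence = purrr::map_chr(res, "evidence")
  )
}

#' Label every account in a corpus
#'
#' Applies [infer_gender()] to each distinct user's display name.
#'
#' @param posts Posts tibble with `user_id` and `display_name`.
#' @param dict A [load_name_dictionary()] object.
#' @return Tibble: `user_id`, `display_name`, `label`, `evidence`.
#' @export
infer_user_genders <- function(posts, dict) {
  users <- posts |>
    dplyr::distinct(.data$user_id, .data$display_name) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  dplyr::bind_cols(users["user_id"],
                   infer_gender(users$display_name, dict))
}

#' Gender shares
#'
#' Proportions of female/male/unknown over the supplied unit (tweets or
#' users, whichever the rows of `x` represent). `pct` is the share as a
#' percentage rounded to one decimal, the reporting convention.
#'
#' @param x Either a data frame with a `label` column, or a named numeric
#'   vector of counts (names among `female`, `male`, `unknown`).
#' @return Tibble: `label`, `n`, `share`, `pct`. Shares sum to 1.
#' @export
#' @examples
#' gender_shares(c(female = 8363, male = 3416, unknown = 7653))
gender_shares <- function(x) {
  lv <- c("female", "male", "unknown")
  if (is.data.frame(x)) {
    if (nrow(x) == 0) abort("empty input: no labels to summarize")
    if (!"label" %in% names(x)) abort("`x` must have a `label` column")
    counts <- table(factor(x$label, levels = lv))
    n <- as.numeric(counts)
  } else if (is.numeric(x)) {
    if (length(x) == 0 || sum(x) == 0) abort("empty input: no labels to summarize")
    if (is.null(names(x)) || any(!names(x) %in% lv)) {
      abort("counts must be named with female/male/unknown")
    }
    n <- as.numeric(x[match(lv, names(x))])
    n[is.na(n)] <- 0
  } else {
    abort("`x` must be a data frame or a named count vector")
  }
  share <- n / sum(n)
  tibble::tibble(label = lv, n = n, share = share,
                 pct = round(100 * share, 1))
}
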
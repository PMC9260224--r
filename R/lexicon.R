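#' Construct a category lexicon
#'
#' A lexicon maps category names to sets of entries, where an entry is either
#' a literal token or a prefix pattern written with a single trailing `*`
#' (the LIWC wildcard convention). Category names must be unique and entries
#' nonempty.
#'
#' @param entries Named list: category name -> character vector of entries.
#' @return An object of class `liwc_lexicon` with components `categories`
#'   (character vector) and `entries` (tibble with columns `category`,
#'   `entry`, `is_prefix`, `stem`).
#' @export
#' @examples
#' lex <- liwc_lexicon(list(Female = c("women", "she", "her"),
#'                          Anxiety = c("worr*", "nervous")))
#' score_day(c("trans", "women", "are", "women"), lex)
liwc_lexicon <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(!nzchar(names(entries)))) {
    abort("`entries` must be a named list of character vectors")
  }
  if (anyDuplicated(names(entries))) abort("category names must be unique")
  tbl <- purrr::imap_dfr(entries, function(words, cat) {
    words <- unique(as.character(words))
    if (any(!nzchar(words)) || any(words == "*")) {
      abort(paste0("empty pattern in category '", cat, "'"))
    }
    tibble::tibble(category = cat, entry = stringr::str_to_lower(words))
  })
  tbl$is_prefix <- stringr::str_ends(tbl$entry, stringr::fixed("*"))
  tbl$stem <- ifelse(tbl$is_prefix, stringr::str_sub(tbl$entry, 1, -2), tbl$entry)
  if (any(tbl$is_prefix & !nzchar(tbl$stem))) abort("bare '*' is not a valid entry")
  structure(
    list(categories = names(entries), entries = tbl),
    class = "liwc_lexicon"
  )
}

#' @export
print.liwc_lexicon <- function(x, ...) {
  cat("<liwc_lexicon>", length(x$categories), "categories,",
      nrow(x$entries), "entries\n")
  cat(" ", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Read a lexicon in the LIWC `.dic` dialect
#'
#' The dialect is: a header block delimited by lines consisting of `%`,
#' holding `id<TAB>name` category definitions, followed by `word<TAB>id...`
#' entry lines (a word may list several category ids). `*` is allowed only as
#' a trailing wildcard, giving a prefix pattern.
#'
#' @param path Path to a `.dic` file. Defaults to the bundled synthetic
#'   stand-in lexicon.
#' @param keep Optional character vector of category names to retain (the
#'   reporting convention drops composite parent categories; which categories
#'   to keep is configuration, not inference).
#' @return A [liwc_lexicon()] object.
#' @export
read_liwc_dic <- function(path = default_resources()$lexicon, keep = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2) abort("not a LIWC .dic file: missing '%' header delimiters")
  header <- lines[(pct[1] + 1):(pct[2] - 1)]
  body <- if (pct[2] < length(lines)) lines[(pct[2] + 1):length(lines)] else character()

  hparts <- stringr::str_split_fixed(trimws(header), "\\s+", 2)
  ids <- hparts[, 1]
  cats <- trimws(hparts[, 2])
  if (any(!nzchar(cats))) abort("malformed .dic header line")
  id_to_cat <- setNames(cats, ids)

  entries <- setNames(vector("list", length(cats)), cats)
  bparts <- stringr::str_split(trimws(body), "\\s+")
  for (p in bparts) {
    word <- p[[1]]
    for (id in p[-1]) {
      cat <- id_to_cat[id]
      if (is.na(cat)) abort(paste0("entry '", word, "' references unknown category id ", id))
      entries[[cat]] <- c(entries[[cat]], word)
    }
  }
  if (!is.null(keep)) {
    missing <- setdiff(keep, cats)
    if (length(missing)) abort(paste0("unknown categories: ", paste(missing, collapse = ", ")))
    entries <- entries[keep]
  }
  entries <- entries[!vapply(entries, is.null, logical(1))]
  liwc_lexicon(entries)
}

#' Write a lexicon in the LIWC `.dic` dialect
#'
#' @param lexicon A [liwc_lexicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_liwc_dic <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  ids <- seq_along(lexicon$categories)
  header <- paste0(ids, "\t", lexicon$categories)
  id_of <- setNames(ids, lexicon$categories)
  body <- lexicon$entries |>
    dplyr::group_by(.data$entry) |>
    dplyr::summarise(ids = paste(sort(id_of[.data$category]), collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$entry)
  writeLines(c("%", header, "%", paste0(body$entry, "\t", body$ids)), path,
             useBytes = TRUE)
  invisible(path)
}

# For a vocabulary of distinct tokens, return a tibble (token, category) of
# all lexicon hits. Literals match exactly; prefix entries match by prefix.
lexicon_hits <- function(vocab, lexicon) {
  ent <- lexicon$entries
  lit <- ent[!ent$is_prefix, c("stem", "category")]
  hits_lit <- tibble::tibble(token = vocab) |>
    dplyr::inner_join(lit, by = c(token = "stem"))
  pre <- ent[ent$is_prefix, c("stem", "category")]
  hits_pre <- purrr::pmap_dfr(pre, function(stem, category) {
    m <- vocab[startsWith(vocab, stem)]
    tibble::tibble(token = m, category = rep(category, length(m)))
  })
  dplyr::distinct(dplyr::bind_rows(hits_lit, hits_pre))
}

#' Score one token stream against a lexicon
#'
#' For each category, the rate is the number of tokens matching any of its
#' entries divided by the total token count. A token may count toward several
#' categories. An empty token stream yields `NA` rates (missing, not zero):
#' silence carries no information about category usage.
#'
#' @param tokens Character vector of (lowercased) tokens.
#' @param lexicon A [liwc_lexicon()].
#' @return Named numeric vector of rates in `[0, 1]`, one per category.
#' @export
score_day <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  rates <- setNames(rep(NA_real_, length(lexicon$categories)), lexicon$categories)
  n <- length(tokens)
  if (n == 0) return(rates)
  hits <- lexicon_hits(unique(tokens), lexicon)
  tok_tbl <- tibble::tibble(token = tokens) |>
    dplyr::count(.data$token, name = "mult") |>
    dplyr::inner_join(hits, by = "token") |>
    dplyr::count(.data$category, wt = .data$mult, name = "n_match")
  rates[] <- 0
  rates[tok_tbl$category] <- tok_tbl$n_match / n
  rates
}

#' Score a corpus into per-user per-day category rate vectors
#'
#' Tokenizes every post, pools all tokens a user produced on each day of
#' their observation window, and computes the category rate vector for that
#' user-day (matching tokens / total tokens). Days on which a user posted
#' nothing contribute no row (missing, not zero).
#'
#' @param posts Posts tibble (see [simulate_corpus()] for the schema).
#' @param assignments Cohort assignments from [build_cohorts()]; only
#'   eligible users are scored.
#' @param lexicon A [liwc_lexicon()].
#' @param days_before,days_after Window lengths in days; relative days kept
#'   are `[-days_before, days_after)`.
#' @param exclude_post_ids Post ids to drop before scoring (by default the
#'   cohort builder's recorded day-0 campaign engagement posts, so the
#'   intervention content does not mechanically inflate the measured change).
#' @param include_retweets Score retweeted text as the retweeter's own
#'   language (default `TRUE`).
#' @return Long tibble: `user_id`, `relative_day`, `token_count`,
#'   `category`, `rate`.
#' @export
score_corpus <- function(posts, assignments, lexicon,
                         days_before = 15, days_after = 15,
                         exclude_post_ids = NULL, include_retweets = TRUE) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  keep <- assignments[assignments$eligible, c("user_id", "day0")]
  dat <- posts |>
    dplyr::inner_join(keep, by = "user_id") |>
    dplyr::mutate(relative_day = as.integer(as_utc_date(.data$timestamp) - .data$day0)) |>
    dplyr::filter(.data$relative_day >= -days_before,
                  .data$relative_day < days_after)
  if (!is.null(exclude_post_ids)) {
    dat <- dat[!dat$post_id %in% exclude_post_ids, ]
  }
  if (!include_retweets) dat <- dat[!dat$is_retweet, ]
  if (nrow(dat) == 0) {
    return(tibble::tibble(user_id = character(), relative_day = integer(),
                          token_count = integer(), category = character(),
                          rate = double()))
  }

  toks <- tokenize(dat$text)
  lens <- lengths(toks)
  long <- tibble::tibble(
    user_id = rep(dat$user_id, lens),
    relative_day = rep(dat$relative_day, lens),
    token = unlist(toks, use.names = FALSE)
  )
  totals <- long |>
    dplyr::count(.data$user_id, .data$relative_day, name = "token_count")
  hits <- lexicon_hits(unique(long$token), lexicon)
  matched <- long |>
    dplyr::inner_join(hits, by = "token", relationship = "many-to-many") |>
    dplyr::count(.data$user_id, .data$relative_day, .data$category,
                 name = "n_match")
  totals |>
    tidyr::crossing(category = lexicon$categories) |>
    dplyr::left_join(matched, by = c("user_id", "relative_day", "category")) |>
    dplyr::mutate(rate = dplyr::coalesce(.data$n_match, 0L) / .data$token_count) |>
    dplyr::select("user_id", "relative_day", "token_count", "category", "rate")
}

#' Build a cohort-level daily rate series for one category and group
#'
#' The series value on each relative day is the mean over contributing users
#' of that user's category rate for the day, so every user weighs equally
#' regardless of activity. Users with no posts on a day are skipped, not
#' zero-filled. A day with zero contributing users is linearly interpolated
#' from its nearest observed neighbours and flagged.
#'
#' @param day_vectors Output of [score_corpus()].
#' @param assignments Cohort assignments ([build_cohorts()]).
#' @param category Category name.
#' @param role `"target"` or `"baseline"`.
#' @param gender `"all"` (default) or a gender label; requires
#'   `gender_labels`.
#' @param gender_labels Optional tibble `user_id`, `label` from
#'   [infer_user_genders()].
#' @param days_before,days_after Window lengths.
#' @return Tibble: `relative_day`, `value`, `n_users`, `interpolated`.
#' @export
build_series <- function(day_vectors, assignments, category, role,
                         gender = "all", gender_labels = NULL,
                         days_before = 15, days_after = 15) {
  users <- assignments$user_id[assignments$role == role & assignments$eligible]
  if (!identical(gender, "all")) {
    if (is.null(gender_labels)) abort("`gender_labels` required for gender-stratified series")
    users <- intersect(users, gender_labels$user_id[gender_labels$label == gender])
  }
  dv <- day_vectors[day_vectors$category == category &
                      day_vectors$user_id %in% users, ]
  days <- seq.int(-days_before, days_after - 1L)
  agg <- dv |>
    dplyr::group_by(.data$relative_day) |>
    dplyr::summarise(value = mean(.data$rate), n_users = dplyr::n(),
                     .groups = "drop")
  out <- tibble::tibble(relative_day = days) |>
    dplyr::left_join(agg, by = "relative_day") |>
    dplyr::mutate(n_users = dplyr::coalesce(.data$n_users, 0L),
                  interpolated = is.na(.data$value))
  if (all(out$interpolated)) {
    abort(paste0("no contributing users for category '", category,
                 "', role '", role, "', gender '", gender, "'"))
  }
  if (any(out$interpolated)) {
    obs <- !out$interpolated
    out$value <- approx(x = out$relative_day[obs], y = out$value[obs],
                        xout = out$relative_day, rule = 2)$y
  }
  out
}

#' Build rate series for every category and group
#'
#' Convenience wrapper producing the long series table the impact estimator
#' consumes: one row per category x group x role x relative day.
#'
#' @inheritParams build_series
#' @param groups Character vector of groups; `"all"` plus any gender labels.
#' @return Long tibble: `category`, `group`, `role`, `relative_day`,
#'   `value`, `n_users`, `interpolated`.
#' @export
build_category_series <- function(day_vectors, assignments,
                                  gender_labels = NULL,
                                  groups = "all",
                                  days_before = 15, days_after = 15) {
  cats <- unique(day_vectors$category)
  grid <- tidyr::expand_grid(category = cats, group = groups,
                             role = c("target", "baseline"))
  purrr::pmap_dfr(grid, function(category, group, role) {
    s <- build_series(day_vectors, assignments, category, role,
                      gender = group, gender_labels = gender_labels,
                      days_before = days_before, days_after = days_after)
    dplyr::bind_cols(tibble::tibble(category = category, group = group,
                                    role = role)[rep(1, nrow(s)), ], s)
  })
}
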
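#' Filter posts matching a lexicon category
#'
#' Returns the posts whose token stream contains at least one entry of the
#' named category, under the same matching rules as the scorer (literals
#' exactly, trailing-`*` entries by prefix).
#'
#' @param posts Posts tibble.
#' @param lexicon A [liwc_lexicon()].
#' @param category Category name; unknown names are an error.
#' @return The matching subset of `posts`.
#' @export
filter_category_tweets <- function(posts, lexicon, category) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  if (!category %in% lexicon$categories) {
    abort(paste0("unknown category: '", category, "'"))
  }
  sub <- liwc_lexicon(setNames(
    list(lexicon$entries$entry[lexicon$entries$category == category]),
    category))
  toks <- tokenize(posts$text)
  vocab <- unique(unlist(toks, use.names = FALSE))
  hit_tokens <- lexicon_hits(vocab, sub)$token
  keep <- vapply(toks, function(tk) any(tk %in% hit_tokens), logical(1))
  posts[keep, , drop = FALSE]
}

#' Gendered odds-ratio word ranking
#'
#' For every word, counts the tweets of each group containing it (binary
#' per-tweet usage) and computes the Haldane–Anscombe smoothed odds ratio
#' `((a+1/2)/(b+1/2)) / ((c+1/2)/(d+1/2))`, where `a` of the `a+b` group-1
#' tweets and `c` of the `c+d` group-2 tweets contain the word. Words with
#' OR above 1 lean toward group 1, below 1 toward group 2. Ties are broken
#' by total frequency, then lexicographically. Stopwords are excluded by
#' default since the contrast targets content words.
#'
#' @param posts_g1,posts_g2 Posts tibbles for the two groups (nonempty).
#' @param top_k Number of words per leaning (default 30).
#' @param stopwords Character vector to exclude; `NULL` disables.
#' @return Tibble: `word`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_raw`, `direction` (`"g1"`/`"g2"`), `rank`. At most `top_k`
#'   rows per direction. Empty (with a warning) if no vocabulary remains.
#' @export
odds_ratio_ranking <- function(posts_g1, posts_g2, top_k = 30,
                               stopwords = default_terms("stopwords")) {
  if (nrow(posts_g1) == 0 || nrow(posts_g2) == 0) {
    abort("both groups must contain at least one post")
  }
  n1 <- nrow(posts_g1)
  n2 <- nrow(posts_g2)
  per_tweet_words <- function(posts) {
    toks <- tokenize(posts$text)
    purrr::map(toks, unique) |> unlist(use.names = FALSE)
  }
  w1 <- per_tweet_words(posts_g1)
  w2 <- per_tweet_words(posts_g2)
  counts <- dplyr::full_join(
    tibble::tibble(word = w1) |> dplyr::count(.data$word, name = "a"),
    tibble::tibble(word = w2) |> dplyr::count(.data$word, name = "c"),
    by = "word"
  ) |>
    dplyr::mutate(a = dplyr::coalesce(.data$a, 0L),
                  c = dplyr::coalesce(.data$c, 0L))
  if (!is.null(stopwords)) {
    counts <- counts[!counts$word %in% stopwords, , drop = FALSE]
  }
  if (nrow(counts) == 0) {
    warn("empty vocabulary after filtering")
    return(tibble::tibble(word = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), odds_ratio = double(),
                          odds_ratio_raw = double(), direction = character(),
                          rank = integer()))
  }
  counts <- counts |>
    dplyr::mutate(
      b = n1 - .data$a, d = n2 - .data$c,
      odds_ratio = ((.data$a + 0.5) / (.data$b + 0.5)) /
        ((.data$c + 0.5) / (.data$d + 0.5)),
      odds_ratio_raw = (.data$a / .data$b) / (.data$c / .data$d),
      total = .data$a + .data$c
    )
  g1 <- counts |>
    dplyr::arrange(dplyr::desc(.data$odds_ratio), dplyr::desc(.data$total),
                   .data$word) |>
    head(top_k) |>
    dplyr::mutate(direction = "g1", rank = dplyr::row_number())
  g2 <- counts |>
    dplyr::arrange(.data$odds_ratio, dplyr::desc(.data$total), .data$word) |>
    head(top_k) |>
    dplyr::mutate(direction = "g2", rank = dplyr::row_number())
  dplyr::bind_rows(g1, g2) |>
    dplyr::select("word", "a", "b", "c", "d", "odds_ratio",
                  "odds_ratio_raw", "direction", "rank")
}

#' Two-proportion z test of keyword prevalence change
#'
#' Splits the posts at `split_day`, computes per-period proportions of posts
#' matching any keyword (trailing-`*` prefix wildcards allowed), and tests
#' the change with the pooled-variance two-proportion z statistic
#' (two-sided normal p-value). Positive `z` means the post-period
#' proportion is larger.
#'
#' @param posts Posts tibble.
#' @param keywords Character vector of terms, e.g. `c("covid*",
#'   "coronavirus")`.
#' @param split_day Date; period 1 is strictly before it, period 2 from it
#'   onward. Both periods must be nonempty.
#' @return One-row tibble: `n_pre`, `n_post`, `prop_pre`, `prop_post`, `z`,
#'   `p_value`.
#' @export
prevalence_z_test <- function(posts, keywords, split_day) {
  split_day <- as_utc_date(split_day)
  kw <- normalize_terms(keywords)
  is_prefix <- stringr::str_ends(kw, stringr::fixed("*"))
  literals <- kw[!is_prefix]
  stems <- stringr::str_sub(kw[is_prefix], 1, -2)
  toks <- tokenize(posts$text)
  hit <- vapply(toks, function(tk) {
    any(tk %in% literals) ||
      (length(stems) > 0 && any(vapply(stems, function(s) any(startsWith(tk, s)),
                                       logical(1))))
  }, logical(1))
  date <- as_utc_date(posts$timestamp)
  pre <- date < split_day
  n1 <- sum(pre); n2 <- sum(!pre)
  if (n1 == 0 || n2 == 0) abort("both periods must contain at least one post")
  x1 <- sum(hit[pre]); x2 <- sum(hit[!pre])
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p2 - p1) / se
  tibble::tibble(n_pre = n1, n_post = n2, prop_pre = p1, prop_post = p2,
                 z = z, p_value = 2 * pnorm(-abs(z)))
}
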
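#' Tokenize post text
#'
#' Lowercases, removes URLs, optionally removes user mentions, strips the
#' leading `#` from hashtags (keeping the hashtag body), and splits on
#' non-word characters. Internal apostrophes are kept, so contractions stay
#' whole (`don't`).
#'
#' Mentions are removed by default because a handle is an address rather than
#' the author's own vocabulary; keyword matching against campaign terms keeps
#' them (with `@` stripped) since retweeting `@SomeCampaign` counts as
#' engagement with that term.
#'
#' @param text Character vector of raw post texts.
#' @param drop_mentions Drop `@user` mentions entirely (`TRUE`, the default)
#'   or keep them as tokens with the `@` stripped.
#' @return A list of character vectors, one per input string (empty vector
#'   for empty input).
#' @export
#' @examples
#' tokenize("RT @user: Check https://t.co/x #ComeAsYouAre!")[[1]]
tokenize <- function(text, drop_mentions = TRUE) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  s <- stringr::str_to_lower(text)
  s <- stringr::str_remove_all(s, "https?://\\S+|www\\.\\S+")
  if (drop_mentions) {
    s <- stringr::str_remove_all(s, "@\\w+")
  } else {
    s <- stringr::str_replace_all(s, "@(\\w)", "\\1")
  }
  s <- stringr::str_replace_all(s, "#(\\w)", "\\1")
  stringr::str_extract_all(s, "[\\p{L}\\p{N}_]+(?:'[\\p{L}\\p{N}_]+)*")
}

# Normalize a keyword set for matching: lowercase, strip leading '#'/'@'.
normalize_terms <- function(terms) {
  terms <- stringr::str_to_lower(trimws(terms))
  unique(stringr::str_remove(terms, "^[#@]+"))
}

#' Match posts against a keyword set
#'
#' Case-insensitive whole-token matching after stripping leading `#`/`@` from
#' both the keywords and the post tokens. Substring matching is deliberately
#' not performed, so a keyword like `neda` does not fire inside unrelated
#' words.
#'
#' @param text Character vector of post texts.
#' @param terms Character vector of keywords (may carry leading `#` or `@`).
#' @return Logical vector, one element per post.
#' @export
matches_terms <- function(text, terms) {
  if (length(terms) == 0) abort("`terms` must be nonempty")
  toks <- tokenize(text, drop_mentions = FALSE)
  match_token_list(toks, terms)
}

# Vectorized any-token-in-set matching over a list of token vectors.
match_token_list <- function(toks, terms) {
  terms <- normalize_terms(terms)
  lens <- lengths(toks)
  idx <- rep.int(seq_along(toks), lens)
  hit_tok <- unlist(toks, use.names = FALSE) %in% terms
  out <- logical(length(toks))
  out[idx[hit_tok]] <- TRUE
  out
}
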
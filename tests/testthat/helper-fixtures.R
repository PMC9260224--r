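# Shared fixtures: compact post builders and a tiny lexicon, all built in
# code at test time.

base_day <- as.Date("2019-02-25")

# Build a posts tibble from parallel vectors; `day` is an offset from
# base_day (or a Date). Post ids are globally unique across calls.
.post_counter <- local({n <- 0L; function(k) {n <<- n + k; n - k + seq_len(k)}})
mk_posts <- function(user_id, day, text, is_retweet = FALSE,
                     retweeted_user_id = NA_character_, retweet_count = 0L,
                     like_count = 0L, follower_count = 100L,
                     display_name = "Test User", hour = 12) {
  n <- max(lengths(list(user_id, day, text)))
  day <- if (inherits(day, "Date")) day else base_day + day
  tibble::tibble(
    post_id = sprintf("t%06d", .post_counter(n)),
    user_id = rep_len(user_id, n),
    timestamp = as.POSIXct(rep_len(day, n), tz = "UTC") +
      rep_len(hour, n) * 3600,
    text = rep_len(text, n),
    is_retweet = rep_len(is_retweet, n),
    retweeted_user_id = rep_len(retweeted_user_id, n),
    retweet_count = rep_len(retweet_count, n),
    like_count = rep_len(like_count, n),
    follower_count = rep_len(follower_count, n),
    display_name = rep_len(display_name, n)
  )
}

tiny_lexicon <- function() {
  liwc_lexicon(list(
    Female = c("women", "she", "her"),
    Anxiety = c("worr*", "nervous", "panic"),
    Risk = c("risk*", "danger*", "beware")
  ))
}

# Small-but-realistic generator config for pipeline tests.
quick_config <- function(n_target_users = 40, n_baseline_users = 80,
                         posts_per_user_day = 1.2, ...) {
  corpus_config(n_target_users = n_target_users,
                n_baseline_users = n_baseline_users,
                posts_per_user_day = posts_per_user_day, ...)
}
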
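#' Detect a user's day 0
#'
#' Day 0 is the calendar date (UTC) of the chronologically first post that
#' matches any campaign keyword — by retweeting campaign content or posting a
#' related tweet. Matching is case-insensitive whole-token matching after
#' stripping leading `#`/`@` (see [matches_terms()]).
#'
#' @param posts Posts tibble for one user (any order).
#' @param campaign_terms Nonempty character vector of campaign keywords.
#' @return A `Date`, or `NA` if no post matches (including empty input).
#' @export
detect_day0 <- function(posts, campaign_terms) {
  if (length(campaign_terms) == 0) abort("`campaign_terms` must be nonempty")
  if (nrow(posts) == 0) return(as.Date(NA))
  hit <- matches_terms(posts$text, campaign_terms)
  if (!any(hit)) return(as.Date(NA))
  as_utc_date(min(posts$timestamp[hit]))
}

#' Partition a user's posts around day 0
#'
#' Pre-window is the half-open interval `[day0 - days_before, day0)` and the
#' post-window is `[day0, day0 + days_after)`, both in UTC calendar days; day
#' 0 belongs to the post period because the engagement marks the start of
#' exposure. Posts outside both windows are discarded. Posts listed in
#' `exclude_post_ids` (typically the day-0 campaign engagement itself) are
#' dropped from the post window.
#'
#' @param posts Posts tibble for one user.
#' @param day0 A `Date`.
#' @param days_before,days_after Nonnegative window lengths in days.
#' @param exclude_post_ids Optional post ids to drop from the post window.
#' @return List with tibbles `pre` and `post`.
#' @export
partition_window <- function(posts, day0, days_before = 15, days_after = 15,
                             exclude_post_ids = NULL) {
  if (days_before < 0 || days_after < 0) abort("window lengths must be nonnegative")
  day0 <- as_utc_date(day0)
  d <- as_utc_date(posts$timestamp)
  pre <- posts[d >= day0 - days_before & d < day0, , drop = FALSE]
  post <- posts[d >= day0 & d < day0 + days_after, , drop = FALSE]
  if (!is.null(exclude_post_ids)) {
    post <- post[!post$post_id %in% exclude_post_ids, , drop = FALSE]
  }
  list(pre = pre, post = post)
}

#' Assemble target and baseline cohorts
#'
#' Any user with at least one campaign-keyword match is a target user, with a
#' per-user day 0 from [detect_day0()]. Users matching at least one baseline
#' diet/health term and no campaign term form the baseline cohort and all
#' share `campaign_start` as day 0, so their observation span mirrors the
#' target users'. Users matching neither term set are excluded. A user is
#' eligible when both windows hold at least `min_posts` posts.
#'
#' When `exclude_campaign_day0_post` is `TRUE` (default) each target user's
#' first campaign-matching post is excluded from the post window before
#' counting and is recorded in the `excluded_post_id` column so downstream
#' scoring can drop it too; the engagement content itself is not the user's
#' continued self-expression.
#'
#' @param posts Posts tibble (all users).
#' @param campaign_terms,baseline_terms Keyword vectors.
#' @param campaign_start First day of the campaign (anything `as.Date`
#'   accepts).
#' @param days_before,days_after Window lengths in days.
#' @param min_posts Eligibility threshold per window (default 3).
#' @param exclude_campaign_day0_post See Details.
#' @return Tibble: `user_id`, `role`, `day0`, `eligible`, `n_pre`,
#'   `n_post`, `excluded_post_id`.
#' @export
build_cohorts <- function(posts, campaign_terms, baseline_terms,
                          campaign_start, days_before = 15, days_after = 15,
                          min_posts = 3, exclude_campaign_day0_post = TRUE) {
  campaign_start <- as_utc_date(campaign_start)
  if (is.na(campaign_start)) abort("`campaign_start` is not a parseable date")
  min_posts <- check_count(min_posts, "min_posts", min = 0)

  toks <- tokenize(posts$text, drop_mentions = FALSE)
  camp_hit <- match_token_list(toks, campaign_terms)
  base_hit <- match_token_list(toks, baseline_terms)
  date <- as_utc_date(posts$timestamp)

  per_user <- tibble::tibble(
    user_id = posts$user_id, post_id = posts$post_id,
    timestamp = posts$timestamp, date = date,
    camp = camp_hit, base = base_hit
  )

  targets <- per_user |>
    dplyr::filter(.data$camp) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::slice_min(.data$timestamp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$user_id, role = "target",
                     day0 = .data$date,
                     excluded_post_id = if (exclude_campaign_day0_post)
                       .data$post_id else NA_character_)

  baselines <- per_user |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(any_base = any(.data$base), any_camp = any(.data$camp),
                     .groups = "drop") |>
    dplyr::filter(.data$any_base, !.data$any_camp) |>
    dplyr::transmute(.data$user_id, role = "baseline",
                     day0 = campaign_start,
                     excluded_post_id = NA_character_)

  assign <- dplyr::bind_rows(targets, baselines)
  if (nrow(assign) == 0) {
    return(tibble::tibble(user_id = character(), role = character(),
                          day0 = as.Date(character()), eligible = logical(),
                          n_pre = integer(), n_post = integer(),
                          excluded_post_id = character()))
  }

  counts <- per_user |>
    dplyr::inner_join(assign, by = "user_id") |>
    dplyr::mutate(
      in_pre = .data$date >= .data$day0 - days_before & .data$date < .data$day0,
      in_post = .data$date >= .data$day0 &
        .data$date < .data$day0 + days_after &
        (is.na(.data$excluded_post_id) | .data$post_id != .data$excluded_post_id)
    ) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n_pre = sum(.data$in_pre), n_post = sum(.data$in_post),
                     .groups = "drop")

  assign |>
    dplyr::left_join(counts, by = "user_id") |>
    dplyr::mutate(n_pre = as.integer(dplyr::coalesce(.data$n_pre, 0L)),
                  n_post = as.integer(dplyr::coalesce(.data$n_post, 0L)),
                  eligible = .data$n_pre >= min_posts & .data$n_post >= min_posts) |>
    dplyr::select("user_id", "role", "day0", "eligible", "n_pre", "n_post",
                  "excluded_post_id") |>
    dplyr::arrange(.data$role, .data$user_id)
}
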
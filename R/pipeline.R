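#' Study configuration
#'
#' Bundles every knob of the end-to-end analysis: keyword sets, window
#' lengths, the activity filter, the impact-model configuration, the groups
#' analysed, and the seed propagated to every stochastic stage.
#'
#' @param campaign_terms,baseline_terms Keyword vectors (default: bundled
#'   lists).
#' @param campaign_start First campaign day (baseline users' shared day 0).
#' @param days_before,days_after Window lengths in days.
#' @param min_posts Per-window eligibility threshold.
#' @param exclude_campaign_day0_post Drop the day-0 engagement post from the
#'   post-period language (default `TRUE`).
#' @param include_retweets Score retweeted text as the retweeter's own
#'   language (default `TRUE`).
#' @param lexicon A [liwc_lexicon()] (default: bundled stand-in).
#' @param name_dictionary A [load_name_dictionary()] object.
#' @param groups Groups analysed; `"all"` plus gender labels.
#' @param impact An [impact_config()].
#' @param contrast_categories Categories for the gendered odds-ratio
#'   contrast; `NULL` picks the categories significant at `alpha` for the
#'   `"all"` group.
#' @param top_k Words per leaning in the contrast.
#' @param seed Integer seed for the stochastic stages.
#' @return List of class `study_config`.
#' @export
study_config <- function(campaign_terms = default_terms("campaign"),
                         baseline_terms = default_terms("baseline"),
                         campaign_start = as.Date("2019-02-25"),
                         days_before = 15, days_after = 15, min_posts = 3,
                         exclude_campaign_day0_post = TRUE,
                         include_retweets = TRUE,
                         lexicon = read_liwc_dic(),
                         name_dictionary = load_name_dictionary(),
                         groups = c("all", "female", "male", "unknown"),
                         impact = impact_config(),
                         contrast_categories = NULL,
                         top_k = 30,
                         seed = 1) {
  impact$seed <- impact$seed %||% as.integer(seed)
  structure(
    list(campaign_terms = campaign_terms, baseline_terms = baseline_terms,
         campaign_start = as_utc_date(campaign_start),
         days_before = check_count(days_before, "days_before", 1),
         days_after = check_count(days_after, "days_after", 1),
         min_posts = check_count(min_posts, "min_posts", 0),
         exclude_campaign_day0_post = exclude_campaign_day0_post,
         include_retweets = include_retweets,
         lexicon = lexicon, name_dictionary = name_dictionary,
         groups = groups, impact = impact,
         contrast_categories = contrast_categories, top_k = top_k,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full campaign-impact study
#'
#' Executes the stages in dependency order: cohort construction, gender
#' inference, lexicon scoring into daily series, counterfactual impact
#' estimation per category and group, reach statistics with community
#' detection, and the gendered odds-ratio contrast on post-period tweets of
#' the target cohort. Identical seed and inputs give an identical report.
#'
#' @param posts Posts tibble (e.g. from [read_corpus()] or
#'   [simulate_corpus()]).
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, per-stage CSV/JSON
#'   artifacts and the consolidated `report.json` are written there.
#' @return List of class `study_report`: `cohorts`, `gender_labels`,
#'   `gender_shares`, `series`, `impact`, `reach` (summary, network,
#'   communities), `contrast`, and `report` (the plain-list summary that
#'   `report.json` serializes).
#' @export
run_study <- function(posts, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  cohorts <- stage("cohorts", build_cohorts(
    posts, config$campaign_terms, config$baseline_terms,
    config$campaign_start, config$days_before, config$days_after,
    config$min_posts, config$exclude_campaign_day0_post
  ))

  genders <- stage("gender", infer_user_genders(posts, config$name_dictionary))
  eligible_ids <- cohorts$user_id[cohorts$eligible]
  shares <- stage("gender", gender_shares(
    genders[genders$user_id %in% eligible_ids, ]
  ))

  day_vectors <- stage("score", score_corpus(
    posts, cohorts, config$lexicon,
    days_before = config$days_before, days_after = config$days_after,
    exclude_post_ids = stats::na.omit(cohorts$excluded_post_id),
    include_retweets = config$include_retweets
  ))
  series <- stage("score", build_category_series(
    day_vectors, cohorts, gender_labels = genders, groups = config$groups,
    days_before = config$days_before, days_after = config$days_after
  ))

  impact <- stage("impact", run_impact(series, config$impact))

  network <- stage("reach", build_retweet_network(posts))
  communities <- if (nrow(network) > 0) {
    stage("reach", detect_communities(network))
  } else {
    tibble::tibble(user_id = character(), community = integer())
  }
  reach <- stage("reach", reach_summary(posts))

  contrast_cats <- config$contrast_categories %||%
    unique(impact$category[impact$group == "all" &
                             impact$significance != "none"])
  target_ids <- cohorts$user_id[cohorts$role == "target" & cohorts$eligible]
  post_period <- posts |>
    dplyr::inner_join(cohorts[cohorts$eligible,
                              c("user_id", "day0", "excluded_post_id")],
                      by = "user_id") |>
    dplyr::filter(.data$user_id %in% target_ids,
                  as_utc_date(.data$timestamp) >= .data$day0,
                  as_utc_date(.data$timestamp) < .data$day0 + config$days_after,
                  is.na(.data$excluded_post_id) |
                    .data$post_id != .data$excluded_post_id)
  fem_ids <- genders$user_id[genders$label == "female"]
  mal_ids <- genders$user_id[genders$label == "male"]
  contrast <- purrr::map_dfr(contrast_cats, function(cat) {
    matched <- filter_category_tweets(post_period, config$lexicon, cat)
    g1 <- matched[matched$user_id %in% fem_ids, ]
    g2 <- matched[matched$user_id %in% mal_ids, ]
    if (nrow(g1) == 0 || nrow(g2) == 0) return(NULL)
    dplyr::mutate(odds_ratio_ranking(g1, g2, top_k = config$top_k),
                  category = cat, .before = 1)
  })

  report <- list(
    n_posts = nrow(posts),
    cohort_sizes = as.list(table(cohorts$role[cohorts$eligible])),
    gender_shares = setNames(as.list(shares$pct), shares$label),
    reach = as.list(reach),
    n_communities = dplyr::n_distinct(communities$community),
    impact = impact |>
      dplyr::select("category", "group", "relative_effect", "ci_lower",
                    "ci_upper", "p_value", "significance"),
    top_words = if (nrow(contrast %||% tibble::tibble()) > 0) {
      contrast |>
        dplyr::group_by(.data$category, .data$direction) |>
        dplyr::slice_head(n = 5) |>
        dplyr::summarise(words = paste(.data$word, collapse = " "),
                         .groups = "drop")
    } else NULL,
    seed = config$seed
  )

  out <- structure(
    list(cohorts = cohorts, gender_labels = genders, gender_shares = shares,
         series = series, impact = impact,
         reach = list(summary = reach, network = network,
                      communities = communities),
         contrast = contrast, report = report),
    class = "study_report"
  )

  if (!is.null(out_dir)) write_study_artifacts(out, out_dir)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cs <- x$report$cohort_sizes
  cat("<study_report>\n")
  cat("  eligible users:", paste(names(cs), unlist(cs), collapse = ", "), "\n")
  cat("  gender shares (%):",
      paste(names(x$report$gender_shares), unlist(x$report$gender_shares),
            collapse = ", "), "\n")
  cat("  impact rows:", nrow(x$impact), "\n")
  invisible(x)
}

write_study_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cohorts, file.path(out_dir, "cohorts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$gender_labels, file.path(out_dir, "genders.csv"),
                   row.names = FALSE)
  utils::write.csv(result$series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)
  utils::write.csv(
    dplyr::select(result$impact, -"result"),
    file.path(out_dir, "impact.csv"), row.names = FALSE
  )
  utils::write.csv(result$reach$network, file.path(out_dir, "network.csv"),
                   row.names = FALSE)
  if (!is.null(result$contrast) && nrow(result$contrast) > 0) {
    utils::write.csv(result$contrast, file.path(out_dir, "contrast.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Serialize a study report to a JSON string
#'
#' The consolidated report in its stable serialized form (used for the
#' reproducibility guarantee: same seed and inputs, same bytes).
#'
#' @param result A `study_report`.
#' @return A JSON string.
#' @export
report_json <- function(result) {
  as.character(jsonlite::toJSON(result$report, auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE))
}
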
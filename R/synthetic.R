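# Synthetic corpus generation with known ground truth. The generator emulates
# the statistical structure the downstream pipeline assumes: two cohorts that
# share a common trend, a multiplicative category lift switched on for target
# users from day 0, gendered display names, and a planted retweet community
# structure. Token streams are bags of lexicon and filler words, not natural
# language.

# word pools ---------------------------------------------------------------

surname_pool <- c(
  "smith", "johnson", "brown", "miller", "wilson", "moore", "clark", "hall",
  "allen", "young", "king", "wright", "green", "baker", "adams", "nelson",
  "hill", "campbell", "mitchell", "carter", "phillips", "evans", "turner",
  "parker", "collins", "edwards", "stewart", "morris", "rogers", "reed"
)

handle_pool <- c(
  "pixel", "nova", "echo", "drift", "lunar", "comet", "ember", "frost",
  "quartz", "zephyr", "onyx", "cinder", "vortex", "sprocket", "glimmer"
)

filler_pool <- c(
  "today", "tomorrow", "maybe", "always", "never", "thing", "things",
  "moment", "while", "because", "little", "really", "actually", "pretty",
  "everyone", "someone", "anyone", "nothing", "something", "everything",
  "week", "month", "year", "night", "morning", "afternoon", "world", "city",
  "place", "school", "music", "movie", "game", "story", "idea", "point",
  "question", "answer", "reason", "start", "end", "part", "side", "line",
  "word", "words", "again", "still", "almost", "quite"
)

#' Synthetic-corpus generator configuration
#'
#' Defines the study conditions the generator emulates: cohort sizes, the
#' 31-day observation window (15 days before and after day 0 plus day 0
#' itself), per-user Poisson posting rates, category token probabilities with
#' an optional multiplicative lift applied to target users from day 0
#' onward, the gender mix of display names, and a planted community
#' structure.
#'
#' @param n_target_users,n_baseline_users Cohort sizes.
#' @param days_before,days_after Window lengths in days.
#' @param posts_per_user_day Mean of the per-user-day Poisson post count.
#' @param tokens_per_post Integer range `c(min, max)`; each post draws its
#'   token count uniformly from it.
#' @param category_base_rates Named probabilities: chance that any given
#'   token belongs to the category.
#' @param injected_lifts Named multiplicative lifts; the effective rate for
#'   target users from day 0 on is `base * (1 + lift)` and must stay within
#'   `[0, 1]` (violations are a configuration error naming the category).
#' @param gender_mix Proportions `c(female, male, unknown)`; must sum to 1.
#' @param n_communities Number of planted retweet communities (>= 1).
#' @param campaign_start First day of the campaign week; target users' day 0
#'   is jittered uniformly over the 7 campaign days, mirroring staggered
#'   first engagement.
#' @param eligible_prob Probability a user's post counts are topped up to at
#'   least 3 per window, so both retained and filtered users exist.
#' @param ambiguous_name_frac Fraction of gendered users given a first name
#'   present in both name lists, exercising the ambiguity rule.
#' @param lexicon Lexicon whose literal entries supply the category word
#'   pools (defaults to the bundled stand-in).
#' @param seed Integer seed; a fixed seed makes [simulate_corpus()]
#'   byte-identical across calls.
#' @return A validated list of class `corpus_config`.
#' @export
corpus_config <- function(n_target_users = 500,
                          n_baseline_users = 1000,
                          days_before = 15,
                          days_after = 15,
                          posts_per_user_day = 1.5,
                          tokens_per_post = c(8, 20),
                          category_base_rates = c(
                            Female = 0.05, Anxiety = 0.02, Risk = 0.02,
                            Money = 0.02, Body = 0.03, Health = 0.03,
                            Ingest = 0.02, Friend = 0.02, Posemo = 0.05
                          ),
                          injected_lifts = c(),
                          gender_mix = c(female = 0.40, male = 0.18,
                                         unknown = 0.42),
                          n_communities = 4,
                          campaign_start = as.Date("2019-02-25"),
                          eligible_prob = 0.9,
                          ambiguous_name_frac = 0.05,
                          lexicon = read_liwc_dic(),
                          seed = 1) {
  n_target_users <- check_count(n_target_users, "n_target_users", 1)
  n_baseline_users <- check_count(n_baseline_users, "n_baseline_users", 1)
  days_before <- check_count(days_before, "days_before", 1)
  days_after <- check_count(days_after, "days_after", 1)
  if (posts_per_user_day <= 0) abort("`posts_per_user_day` must be positive")
  if (length(tokens_per_post) != 2 || any(tokens_per_post < 1) ||
      tokens_per_post[1] > tokens_per_post[2]) {
    abort("`tokens_per_post` must be an increasing positive integer range")
  }
  if (is.null(names(category_base_rates)) || any(!nzchar(names(category_base_rates)))) {
    abort("`category_base_rates` must be named")
  }
  for (cat in names(category_base_rates)) {
    check_prob(category_base_rates[[cat]], paste0("category_base_rates$", cat))
  }
  injected_lifts <- unlist(injected_lifts) %||% numeric()
  if (length(injected_lifts)) {
    bad <- setdiff(names(injected_lifts), names(category_base_rates))
    if (length(bad)) {
      abort(paste0("injected lift for unknown category: ",
                   paste(bad, collapse = ", ")))
    }
    for (cat in names(injected_lifts)) {
      lift <- injected_lifts[[cat]]
      eff <- category_base_rates[[cat]] * (1 + lift)
      if (lift < -1 || eff > 1) {
        abort(paste0("invalid configuration for category '", cat,
                     "': base_rate * (1 + lift) = ", signif(eff, 4),
                     " is outside [0, 1]"))
      }
    }
  }
  if (abs(sum(gender_mix) - 1) > 1e-9) {
    abort("`gender_mix` proportions must sum to 1")
  }
  n_communities <- check_count(n_communities, "n_communities", 1)
  if (n_communities > n_target_users + n_baseline_users) {
    abort("`n_communities` exceeds the number of users")
  }
  check_prob(eligible_prob, "eligible_prob")
  check_prob(ambiguous_name_frac, "ambiguous_name_frac")
  missing_cat <- setdiff(names(category_base_rates), lexicon$categories)
  if (length(missing_cat)) {
    abort(paste0("categories absent from lexicon: ",
                 paste(missing_cat, collapse = ", ")))
  }
  structure(
    list(n_target_users = n_target_users,
         n_baseline_users = n_baseline_users,
         days_before = days_before, days_after = days_after,
         posts_per_user_day = posts_per_user_day,
         tokens_per_post = as.integer(tokens_per_post),
         category_base_rates = category_base_rates,
         injected_lifts = injected_lifts,
         gender_mix = gender_mix, n_communities = n_communities,
         campaign_start = as_utc_date(campaign_start),
         eligible_prob = eligible_prob,
         ambiguous_name_frac = ambiguous_name_frac,
         lexicon = lexicon, seed = as.integer(seed)),
    class = "corpus_config"
  )
}

# Literal entries of each configured category that match no other category,
# so an injected lift cannot spill into a different category's rate.
category_word_pools <- function(config) {
  lex <- config$lexicon
  cats <- names(config$category_base_rates)
  literals <- lex$entries[!lex$entries$is_prefix, ]
  hits <- lexicon_hits(unique(literals$stem), lex)
  n_cats <- table(hits$token)
  clean <- names(n_cats)[n_cats == 1]
  pools <- purrr::map(cats, function(cat) {
    intersect(literals$stem[literals$category == cat], clean)
  })
  names(pools) <- cats
  empty <- cats[lengths(pools) == 0]
  if (length(empty)) {
    abort(paste0("no unambiguous literal words for categories: ",
                 paste(empty, collapse = ", ")))
  }
  pools
}

sample_display_names <- function(gender, ambiguous, dict) {
  both <- intersect(dict$female, dict$male)
  fem_only <- setdiff(dict$female, both)
  mal_only <- setdiff(dict$male, both)
  n <- length(gender)
  first <- character(n)
  idx_f <- gender == "female"
  idx_m <- gender == "male"
  first[idx_f] <- sample(fem_only, sum(idx_f), replace = TRUE)
  first[idx_m] <- sample(mal_only, sum(idx_m), replace = TRUE)
  amb <- ambiguous & (idx_f | idx_m)
  first[amb] <- sample(both, sum(amb), replace = TRUE)
  last <- sample(surname_pool, n, replace = TRUE)
  name <- stringr::str_to_title(paste(first, last))
  idx_u <- gender == "unknown"
  name[idx_u] <- paste0(sample(handle_pool, sum(idx_u), replace = TRUE), "_",
                        sample(handle_pool, sum(idx_u), replace = TRUE),
                        sample(10:99, sum(idx_u), replace = TRUE))
  name
}

#' Generate a synthetic post corpus with ground truth
#'
#' Draws per-user-day Poisson post counts over the observation window; each
#' token of each post belongs to category `c` independently with probability
#' `base_rate[c] * (1 + lift[c])` for target users from day 0 onward and
#' `base_rate[c]` otherwise, with the remaining tokens drawn from a neutral
#' filler pool. Every target user emits exactly one campaign engagement post
#' on their (jittered) day 0; every baseline user emits one post carrying a
#' baseline health keyword and never matches a campaign term. Deterministic
#' for a fixed seed.
#'
#' @param config A [corpus_config()].
#' @return List with `posts` (tibble; one row per post with ids, UTC
#'   timestamp, text, retweet fields, engagement counts, follower count and
#'   display name) and `truth` (list: `users` tibble with per-user role,
#'   gender, community, day 0; `lifts`; the `config`).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  withr::with_seed(config$seed, simulate_corpus_impl(config))
}

simulate_corpus_impl <- function(config) {
  n_t <- config$n_target_users
  n_b <- config$n_baseline_users
  n_users <- n_t + n_b
  dict <- load_name_dictionary()

  users <- tibble::tibble(
    user_id = sprintf("u%05d", seq_len(n_users)),
    role = rep(c("target", "baseline"), c(n_t, n_b)),
    gender = sample(names(config$gender_mix), n_users, replace = TRUE,
                    prob = config$gender_mix),
    community = sample.int(config$n_communities, n_users, replace = TRUE),
    follower_count = round(rlnorm(n_users, meanlog = 5.5, sdlog = 1.5))
  )
  users$day0 <- config$campaign_start +
    ifelse(users$role == "target", sample(0:6, n_users, replace = TRUE), 0L)
  ambiguous <- runif(n_users) < config$ambiguous_name_frac
  users$display_name <- sample_display_names(users$gender, ambiguous, dict)

  days <- seq.int(-config$days_before, config$days_after - 1L)
  n_days <- length(days)
  ud <- tidyr::expand_grid(uidx = seq_len(n_users), relative_day = days)
  ud$n_posts <- rpois(nrow(ud), config$posts_per_user_day)

  # top up guaranteed users to >= 3 posts per window
  guaranteed <- runif(n_users) < config$eligible_prob
  ud$window <- ifelse(ud$relative_day < 0, "pre", "post")
  win_sum <- ud |>
    dplyr::group_by(.data$uidx, .data$window) |>
    dplyr::summarise(n = sum(.data$n_posts), .groups = "drop") |>
    dplyr::filter(.data$n < 3, guaranteed[.data$uidx])
  if (nrow(win_sum) > 0) {
    for (i in seq_len(nrow(win_sum))) {
      rows <- which(ud$uidx == win_sum$uidx[i] & ud$window == win_sum$window[i])
      add <- sample(rows, 3 - win_sum$n[i], replace = TRUE)
      for (r in add) ud$n_posts[r] <- ud$n_posts[r] + 1L
    }
  }

  posts <- ud[rep.int(seq_len(nrow(ud)), ud$n_posts),
              c("uidx", "relative_day")]
  n_posts <- nrow(posts)
  tmin <- config$tokens_per_post[1]
  tmax <- config$tokens_per_post[2]
  tok_n <- sample(seq.int(tmin, tmax), n_posts, replace = TRUE)

  pools <- category_word_pools(config)
  cats <- names(config$category_base_rates)
  lifted <- users$role[posts$uidx] == "target" & posts$relative_day >= 0

  rows_all <- integer(0)
  words_all <- character(0)
  cat_counts <- matrix(0L, n_posts, length(cats))
  for (j in seq_along(cats)) {
    p <- config$category_base_rates[[cats[j]]]
    lift <- config$injected_lifts[cats[j]]
    lift <- if (is.na(lift)) 0 else lift
    p_eff <- ifelse(lifted, p * (1 + lift), p)
    k <- rbinom(n_posts, tok_n, p_eff)
    cat_counts[, j] <- k
    tot <- sum(k)
    if (tot > 0) {
      rows_all <- c(rows_all, rep.int(seq_len(n_posts), k))
      words_all <- c(words_all, sample(pools[[j]], tot, replace = TRUE))
    }
  }
  filler_n <- pmax(tok_n - rowSums(cat_counts), 0L)
  tot_f <- sum(filler_n)
  rows_all <- c(rows_all, rep.int(seq_len(n_posts), filler_n))
  words_all <- c(words_all, sample(filler_pool, tot_f, replace = TRUE))
  text <- vapply(split(words_all, factor(rows_all, levels = seq_len(n_posts))),
                 paste, character(1), collapse = " ")

  posts <- tibble::tibble(
    uidx = posts$uidx, relative_day = posts$relative_day,
    text = unname(text), is_retweet = FALSE,
    retweeted_user_id = NA_character_
  )

  # one campaign engagement post per target user on their day 0: half of
  # them retweets of the campaign account, half original related tweets
  camp_terms <- stringr::str_to_lower(default_terms("campaign"))
  t_idx <- seq_len(n_t)
  as_rt <- runif(n_t) < 0.5
  camp_posts <- tibble::tibble(
    uidx = t_idx, relative_day = 0L,
    text = paste("rt", sample(camp_terms, n_t, replace = TRUE),
                 "awareness week"),
    is_retweet = as_rt,
    retweeted_user_id = ifelse(as_rt, "campaign_org", NA_character_)
  )

  # one baseline-keyword post per baseline user, on a random window day
  base_words <- c("fitness", "gym", "workout")
  b_idx <- n_t + seq_len(n_b)
  base_posts <- tibble::tibble(
    uidx = b_idx,
    relative_day = sample(days, n_b, replace = TRUE),
    text = paste(sample(base_words, n_b, replace = TRUE), "plan for the",
                 sample(c("week", "month"), n_b, replace = TRUE)),
    is_retweet = FALSE, retweeted_user_id = NA_character_
  )

  posts <- dplyr::bind_rows(posts, camp_posts, base_posts)
  n_all <- nrow(posts)
  date <- users$day0[posts$uidx] + posts$relative_day
  secs <- sample.int(86400L, n_all, replace = TRUE) - 1L
  posts <- tibble::tibble(
    post_id = sprintf("p%07d", seq_len(n_all)),
    user_id = users$user_id[posts$uidx],
    timestamp = as.POSIXct(date, tz = "UTC") + secs,
    text = posts$text,
    is_retweet = posts$is_retweet,
    retweeted_user_id = posts$retweeted_user_id,
    retweet_count = rnbinom(n_all, size = 0.5, mu = 5),
    like_count = rnbinom(n_all, size = 0.5, mu = 12),
    follower_count = users$follower_count[posts$uidx],
    display_name = users$display_name[posts$uidx]
  ) |>
    dplyr::arrange(.data$timestamp, .data$post_id)

  lifts <- setNames(rep(0, length(cats)), cats)
  lifts[names(config$injected_lifts)] <- config$injected_lifts
  list(
    posts = posts,
    truth = list(
      users = users[, c("user_id", "role", "gender", "community", "day0",
                        "display_name", "follower_count")],
      lifts = tibble::tibble(category = cats, lift = unname(lifts)),
      config = config
    )
  )
}

#' Generate a planted-partition retweet graph
#'
#' Planted-partition (stochastic block model) fixture: nodes are the
#' corpus's users, intra-community edges appear with probability `intra_p`
#' and inter-community edges with `inter_p`; each edge gets a random
#' direction (retweeter to author) and a count weight of at least 1.
#'
#' @param corpus Output of [simulate_corpus()] (or its `truth`).
#' @param intra_p,inter_p Edge probabilities within / between communities.
#' @param seed Optional seed.
#' @return Edge tibble `retweeter`, `author`, `weight` with attribute
#'   `communities` (tibble `user_id`, `community` of the planted labels).
#' @export
simulate_retweet_graph <- function(corpus, intra_p = 0.3, inter_p = 0.005,
                                   seed = NULL) {
  truth <- corpus$truth %||% corpus
  users <- truth$users
  with_optional_seed(seed, {
    ord <- order(users$community)
    users <- users[ord, ]
    sizes <- as.integer(table(factor(users$community,
                                     levels = sort(unique(users$community)))))
    k <- length(sizes)
    pref <- matrix(inter_p, k, k)
    diag(pref) <- intra_p
    g <- igraph::sample_sbm(nrow(users), pref.matrix = pref,
                            block.sizes = sizes)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) {
      edges <- tibble::tibble(retweeter = character(), author = character(),
                              weight = integer())
    } else {
      flip <- runif(nrow(el)) < 0.5
      from <- ifelse(flip, el[, 2], el[, 1])
      to <- ifelse(flip, el[, 1], el[, 2])
      edges <- tibble::tibble(
        retweeter = users$user_id[from],
        author = users$user_id[to],
        weight = 1L + rpois(nrow(el), 0.5)
      )
    }
    attr(edges, "communities") <- tibble::tibble(user_id = users$user_id,
                                                 community = users$community)
    edges
  })
}

#' Materialize a retweet edge list as posts
#'
#' Expands each weighted edge into that many retweet posts, so the network
#' builder can be validated against a known edge list.
#'
#' @param edges Edge tibble (`retweeter`, `author`, `weight`).
#' @param date Timestamp date given to every generated post.
#' @return Minimal posts tibble.
#' @export
graph_as_posts <- function(edges, date = as.Date("2019-02-25")) {
  long <- edges[rep.int(seq_len(nrow(edges)), edges$weight), ]
  n <- nrow(long)
  tibble::tibble(
    post_id = sprintf("rt%06d", seq_len(n)),
    user_id = long$retweeter,
    timestamp = as.POSIXct(date, tz = "UTC"),
    text = "rt",
    is_retweet = TRUE,
    retweeted_user_id = long$author,
    retweet_count = 0L, like_count = 0L, follower_count = 0L,
    display_name = ""
  )
}
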
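#' Welch two-sample t test
#'
#' Independent-samples t statistic with the Welch approximation to the
#' degrees of freedom and a two-sided p-value. Thin tidy wrapper over
#' [stats::t.test()].
#'
#' @param a,b Numeric samples, each of size >= 2, with nonzero variance in
#'   at least one.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    abort("both samples have zero variance: t statistic undefined")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic for the first sample with midrank tie handling;
#' p-value from the normal approximation with tie-corrected variance and
#' continuity correction ([stats::wilcox.test()]).
#'
#' @param a,b Nonempty numeric samples.
#' @return One-row tibble: `U` (for sample `a`), `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("samples must be nonempty")
  ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  tibble::tibble(U = unname(ht$statistic), p_value = ht$p.value)
}

#' Build the retweet network
#'
#' One directed weighted edge per (retweeter, author) pair — an edge
#' signifies at least one observed retweet, its weight the retweet count.
#' Retweets with a missing source are skipped with a warning; self-loops are
#' dropped. Users who neither retweet nor are retweeted do not appear.
#'
#' @param posts Posts tibble with `is_retweet` and `retweeted_user_id`.
#' @return Tibble of class `retweet_network`: `retweeter`, `author`,
#'   `weight`.
#' @export
build_retweet_network <- function(posts) {
  rts <- posts[posts$is_retweet, , drop = FALSE]
  missing_src <- is.na(rts$retweeted_user_id) | !nzchar(rts$retweeted_user_id)
  if (any(missing_src)) {
    warn(paste0(sum(missing_src), " retweet(s) with missing source skipped"))
    rts <- rts[!missing_src, , drop = FALSE]
  }
  rts <- rts[rts$user_id != rts$retweeted_user_id, , drop = FALSE]
  edges <- rts |>
    dplyr::count(retweeter = .data$user_id, author = .data$retweeted_user_id,
                 name = "weight") |>
    dplyr::arrange(.data$retweeter, .data$author)
  class(edges) <- c("retweet_network", class(edges))
  edges
}

retweet_network_graph <- function(network, directed = TRUE) {
  igraph::graph_from_data_frame(
    as.data.frame(network[, c("retweeter", "author", "weight")]),
    directed = directed
  )
}

#' Detect communities with short random walks (Walktrap)
#'
#' Runs the Walktrap agglomeration on the symmetrized, weight-aggregated
#' retweet network — random-walk community theory assumes an undirected
#' graph — cutting the merge tree at maximum modularity. Walk length
#' defaults to 4, the algorithm's classical default. Communities are
#' relabelled in decreasing size order (community 1 is the largest).
#'
#' @param network A `retweet_network` edge tibble (or any tibble with
#'   `retweeter`, `author`, `weight`).
#' @param walk_length Random-walk length in steps.
#' @return Tibble: `user_id`, `community`; attribute `modularity` holds the
#'   modularity of the returned partition.
#' @export
detect_communities <- function(network, walk_length = 4) {
  if (nrow(network) == 0) abort("empty network")
  g <- retweet_network_graph(network, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
  if (igraph::vcount(g) == 1) {
    out <- tibble::tibble(user_id = igraph::V(g)$name, community = 1L)
    attr(out, "modularity") <- 0
    return(out)
  }
  cl <- igraph::cluster_walktrap(g, steps = walk_length,
                                 weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- tibble::tibble(user_id = names(memb),
                        community = unname(relabel[as.character(memb)]))
  attr(out, "modularity") <- igraph::modularity(g, memb,
                                                weights = igraph::E(g)$weight)
  out
}

#' Sizes of the largest communities
#'
#' @param communities Output of [detect_communities()].
#' @param k Number of communities to keep (default 5).
#' @return Tibble: `community`, `n_users`, largest first.
#' @export
top_communities <- function(communities, k = 5) {
  communities |>
    dplyr::count(.data$community, name = "n_users") |>
    dplyr::arrange(dplyr::desc(.data$n_users)) |>
    head(k)
}

#' Summarize campaign reach
#'
#' Computes the follower sum over the distinct participating accounts (a
#' hypothetical maximum audience: follower overlap between accounts cannot
#' be excluded), mean/median retweet and like counts of campaign-originating
#' content, and mean/median follower counts of the retweeting accounts.
#'
#' @param posts Posts tibble.
#' @param campaign_account_ids Optional account ids whose posts count as the
#'   campaign's own content; by default all non-retweet posts do.
#' @return One-row tibble of reach statistics.
#' @export
reach_summary <- function(posts, campaign_account_ids = NULL) {
  users <- posts |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(follower_count = .data$follower_count[1], .groups = "drop")
  content <- if (is.null(campaign_account_ids)) {
    posts[!posts$is_retweet, , drop = FALSE]
  } else {
    posts[posts$user_id %in% campaign_account_ids & !posts$is_retweet, ,
          drop = FALSE]
  }
  retweeters <- posts |>
    dplyr::filter(.data$is_retweet) |>
    dplyr::distinct(.data$user_id) |>
    dplyr::inner_join(users, by = "user_id")
  tibble::tibble(
    n_users = nrow(users),
    total_followers = sum(users$follower_count),
    n_content_posts = nrow(content),
    mean_retweets = mean(content$retweet_count),
    median_retweets = median(content$retweet_count),
    mean_likes = mean(content$like_count),
    median_likes = median(content$like_count),
    n_retweeters = nrow(retweeters),
    mean_followers_of_retweeters = mean(retweeters$follower_count),
    median_followers_of_retweeters = median(retweeters$follower_count)
  )
}

#' Accounts ranked by follower count
#'
#' The shape of the "top accounts by reach" table: distinct retweeting
#' accounts, largest audiences first.
#'
#' @param posts Posts tibble.
#' @param k Number of accounts (default 20).
#' @param retweeting_only Rank only accounts that retweeted (default
#'   `TRUE`).
#' @return Tibble: `user_id`, `display_name`, `follower_count`.
#' @export
top_accounts <- function(posts, k = 20, retweeting_only = TRUE) {
  pool <- if (retweeting_only) posts[posts$is_retweet, , drop = FALSE] else posts
  pool |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(display_name = .data$display_name[1],
                     follower_count = .data$follower_count[1],
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$follower_count)) |>
    head(k)
}
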
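test_that("invalid generator configurations fail loudly, naming the category", {
  expect_error(corpus_config(category_base_rates = c(Risk = 1.2)),
               "probability")
  expect_error(corpus_config(category_base_rates = c(Risk = 0.6),
                             injected_lifts = c(Risk = 0.9)),
               "Risk")
  expect_error(corpus_config(injected_lifts = c(NoSuch = 0.1)), "NoSuch")
  expect_error(corpus_config(gender_mix = c(female = 0.5, male = 0.5,
                                            unknown = 0.1)),
               "sum to 1")
  expect_error(corpus_config(n_target_users = 2, n_baseline_users = 2,
                             n_communities = 10),
               "exceeds")
})

test_that("a fixed seed reproduces the corpus byte for byte", {
  cfg <- quick_config(seed = 7)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  expect_identical(a$posts, b$posts)
  expect_identical(a$truth$users, b$truth$users)
  fa <- withr::local_tempfile(fileext = ".jsonl")
  fb <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(a$posts, fa)
  write_corpus(b$posts, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("generated corpora satisfy their structural guarantees", {
  sim <- simulate_corpus(quick_config(seed = 3))
  users <- sim$truth$users
  expect_equal(anyDuplicated(users$user_id), 0L)
  expect_setequal(unique(sim$posts$user_id), users$user_id)
  expect_true(all(nchar(trimws(sim$posts$text)) > 0))     # >= 1 token

  camp <- default_terms("campaign")
  hit <- matches_terms(sim$posts$text, camp)
  d <- as.Date(sim$posts$timestamp, tz = "UTC")
  # target users: a campaign post exactly on their day 0
  tu <- users[users$role == "target", ]
  for (i in seq_len(nrow(tu))) {
    sel <- sim$posts$user_id == tu$user_id[i] & hit
    expect_true(any(sel) && min(d[sel]) == tu$day0[i])
  }
  # baseline users: no campaign matches, >= 1 baseline keyword
  bu <- users$user_id[users$role == "baseline"]
  expect_false(any(hit[sim$posts$user_id %in% bu]))
  bhit <- matches_terms(sim$posts$text, default_terms("baseline"))
  expect_setequal(bu, intersect(bu, unique(sim$posts$user_id[bhit])))
})

test_that("empirical category rates honour base rate and injected lift", {
  # independent token accounting: split on spaces, count Risk-entry tokens
  risk_rate <- function(posts, users_keep, period) {
    lex <- read_liwc_dic()
    ent <- lex$entries[lex$entries$category == "Risk", ]
    sel <- posts$user_id %in% users_keep
    d <- as.Date(posts$timestamp, tz = "UTC")
    day0 <- as.Date("2019-02-25")
    camp <- matches_terms(posts$text, default_terms("campaign"))
    sel <- sel & !camp
    rel <- as.integer(d - day0)
    sel <- sel & if (period == "pre") rel < -6 else rel >= 7
    toks <- unlist(strsplit(posts$text[sel], " ", fixed = TRUE))
    is_risk <- toks %in% ent$stem[!ent$is_prefix]
    for (s in ent$stem[ent$is_prefix]) is_risk <- is_risk | startsWith(toks, s)
    mean(is_risk)
  }
  # (relative days are computed against the campaign start; restricting to
  # rel < -6 / rel >= +7 keeps each side strictly pre/post for every jittered
  # target day 0 in 0..6)
  cfg <- corpus_config(n_target_users = 500, n_baseline_users = 50,
                       tokens_per_post = c(20, 20),
                       category_base_rates = c(Risk = 0.02),
                       injected_lifts = c(Risk = 0.30), seed = 17)
  sim <- simulate_corpus(cfg)
  tu <- sim$truth$users$user_id[sim$truth$users$role == "target"]
  ratio <- risk_rate(sim$posts, tu, "post") / risk_rate(sim$posts, tu, "pre")
  expect_lt(abs(ratio - 1.30), 0.03)

  # no injected lift: post/pre ratio is 1 within Monte-Carlo error
  cfg0 <- corpus_config(n_target_users = 500, n_baseline_users = 50,
                        tokens_per_post = c(20, 20),
                        category_base_rates = c(Risk = 0.02), seed = 18)
  sim0 <- simulate_corpus(cfg0)
  tu0 <- sim0$truth$users$user_id[sim0$truth$users$role == "target"]
  ratio0 <- risk_rate(sim0$posts, tu0, "post") / risk_rate(sim0$posts, tu0, "pre")
  expect_lt(abs(ratio0 - 1), 0.03)
})

test_that("the planted retweet graph realizes its communities", {
  sim <- simulate_corpus(quick_config(seed = 9, n_communities = 2))
  edges <- simulate_retweet_graph(sim, intra_p = 0.4, inter_p = 0, seed = 9)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[, c("retweeter", "author")]), directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  planted <- attr(edges, "communities")
  memb <- comp$membership[planted$user_id[planted$user_id %in% names(comp$membership)]]
  tab <- table(memb, planted$community[planted$user_id %in% names(comp$membership)])
  expect_true(all(rowSums(tab > 0) == 1))  # components align with blocks
})

test_that("an edge list materialized as posts is recovered exactly", {
  sim <- simulate_corpus(quick_config(seed = 4))
  edges <- simulate_retweet_graph(sim, intra_p = 0.2, inter_p = 0.01, seed = 4)
  net <- build_retweet_network(graph_as_posts(edges))
  expect_equal(
    dplyr::arrange(as.data.frame(net), retweeter, author),
    dplyr::arrange(as.data.frame(edges[, c("retweeter", "author", "weight")]),
                   retweeter, author),
    ignore_attr = TRUE
  )
})
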
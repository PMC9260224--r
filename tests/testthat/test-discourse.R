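test_that("category filtering returns exactly the matching tweets", {
  lex <- tiny_lexicon()
  expect_equal(nrow(filter_category_tweets(mk_posts("u", 0, "she said hi"),
                                           lex, "Female")), 1)
  expect_equal(nrow(filter_category_tweets(mk_posts("u", 0, "plain talk"),
                                           lex, "Female")), 0)
  texts <- c("she is here", "worried sick", "nothing much", "women unite",
             "her idea", "hello world", "plain", "more words", "filler",
             "the her story")
  ten <- mk_posts("u", rep(0, 10), texts)
  got <- filter_category_tweets(ten, lex, "Female")
  expect_setequal(got$text, texts[c(1, 4, 5, 10)])
  expect_error(filter_category_tweets(ten, lex, "NoSuch"), "unknown category")
})

test_that("smoothed odds ratios match direct arithmetic", {
  # 20 of 120 group-1 tweets use the word; 5 of 105 group-2 tweets do
  g1 <- mk_posts("f", rep(0, 120),
                 c(rep("she spoke about abortion rights", 20),
                   rep("she spoke plainly", 100)))
  g2 <- mk_posts("m", rep(0, 105),
                 c(rep("he spoke about abortion too", 5),
                   rep("he spoke plainly", 100)))
  or <- odds_ratio_ranking(g1, g2, top_k = 50, stopwords = NULL)
  row <- or[or$word == "abortion" & or$direction == "g1", ]
  expect_equal(row$a, 20); expect_equal(row$b, 100)
  expect_equal(row$c, 5); expect_equal(row$d, 100)
  expect_equal(row$odds_ratio_raw, (20 / 100) / (5 / 100), tolerance = 1e-12)
  expect_equal(row$odds_ratio, (20.5 / 100.5) / (5.5 / 100.5),
               tolerance = 1e-12)

  # with equal-sized groups, a word used in every tweet of both has OR 1
  e1 <- mk_posts("f", rep(0, 30), "common ground here")
  e2 <- mk_posts("m", rep(0, 30), "common ground there")
  ore <- odds_ratio_ranking(e1, e2, stopwords = NULL)
  expect_equal(ore$odds_ratio[ore$word == "common"][1], 1)
  expect_equal(ore$odds_ratio[ore$word == "ground"][1], 1)

  # swapping the groups maps every OR to its reciprocal
  rev <- odds_ratio_ranking(g2, g1, top_k = 50, stopwords = NULL)
  j <- dplyr::inner_join(or[or$direction == "g1", c("word", "odds_ratio")],
                         rev[rev$direction == "g2", c("word", "odds_ratio")],
                         by = "word")
  expect_true(nrow(j) > 0)
  expect_equal(j$odds_ratio.x, 1 / j$odds_ratio.y, tolerance = 1e-12)

  # duplicating every tweet leaves the unsmoothed OR exactly invariant
  or2 <- odds_ratio_ranking(dplyr::bind_rows(g1, g1),
                            dplyr::bind_rows(g2, g2),
                            top_k = 50, stopwords = NULL)
  jj <- dplyr::inner_join(or[or$direction == "g1", ],
                          or2[or2$direction == "g1", ], by = "word")
  expect_equal(jj$odds_ratio_raw.x, jj$odds_ratio_raw.y, tolerance = 1e-12)

  expect_error(odds_ratio_ranking(g1[0, ], g2), "at least one post")
})

test_that("OR is finite and positive even with zero cells", {
  g1 <- mk_posts("f", rep(0, 4), c("unique word here", rep("common talk", 3)))
  g2 <- mk_posts("m", rep(0, 4), rep("common talk", 4))
  or <- odds_ratio_ranking(g1, g2, stopwords = NULL)
  u <- or[or$word == "unique", ][1, ]
  expect_true(is.finite(u$odds_ratio) && u$odds_ratio > 0)
})

test_that("prevalence z test matches the pooled-variance closed form", {
  posts <- dplyr::bind_rows(
    mk_posts("u", rep(-5, 100), c(rep("covid19 news", 10), rep("plain", 90))),
    mk_posts("u", rep(5, 100), c(rep("coronavirus update", 30), rep("plain", 70)))
  )
  z <- prevalence_z_test(posts, c("covid*", "coronavirus", "covid-19"),
                         base_day)
  expect_equal(z$prop_pre, 0.1)
  expect_equal(z$prop_post, 0.3)
  expect_equal(z$z, (0.3 - 0.1) / sqrt(0.2 * 0.8 * (1 / 100 + 1 / 100)),
               tolerance = 1e-10)
  # independent route: z^2 equals the uncorrected chi-squared statistic
  pt <- prop.test(c(10, 30), c(100, 100), correct = FALSE)
  expect_equal(z$z^2, unname(pt$statistic), tolerance = 1e-10)

  # identical proportions: z = 0, p = 1
  flat <- dplyr::bind_rows(
    mk_posts("u", rep(-5, 50), c(rep("covid", 5), rep("plain", 45))),
    mk_posts("u", rep(5, 50), c(rep("covid", 5), rep("plain", 45)))
  )
  z0 <- prevalence_z_test(flat, "covid*", base_day)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1)

  # reversing the periods negates z
  rev_posts <- posts
  rev_posts$timestamp <- as.POSIXct(base_day, tz = "UTC") -
    (as.numeric(posts$timestamp) - as.numeric(as.POSIXct(base_day, tz = "UTC")))
  zr <- prevalence_z_test(rev_posts, c("covid*", "coronavirus"), base_day)
  expect_equal(zr$z, -z$z, tolerance = 1e-10)

  expect_error(prevalence_z_test(posts[1:100, ], "covid*", base_day),
               "both periods")
})
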
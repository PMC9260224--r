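test_that("the bundled .dic stand-in parses and round-trips", {
  lex <- read_liwc_dic()
  expect_s3_class(lex, "liwc_lexicon")
  expect_length(lex$categories, 9)
  expect_true(all(c("Female", "Anxiety", "Risk", "Posemo") %in% lex$categories))
  tmp <- withr::local_tempfile(fileext = ".dic")
  write_liwc_dic(lex, tmp)
  lex2 <- read_liwc_dic(tmp)
  expect_setequal(lex2$categories, lex$categories)
  expect_identical(
    dplyr::arrange(lex2$entries, category, entry),
    dplyr::arrange(lex$entries, category, entry)
  )
  expect_error(read_liwc_dic(keep = "NoSuchCategory"), "unknown categories")
})

test_that("malformed .dic input is rejected", {
  tmp <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("1\tFemale", "women\t1"), tmp)   # missing % delimiters
  expect_error(read_liwc_dic(tmp), "delimiters")
  writeLines(c("%", "1\tFemale", "%", "women\t9"), tmp)
  expect_error(read_liwc_dic(tmp), "unknown category id")
})

test_that("score_day counts literals exactly and wildcards by prefix", {
  lex <- tiny_lexicon()
  r <- score_day(c("trans", "women", "are", "women"), lex)
  expect_equal(r[["Female"]], 0.5)
  expect_equal(score_day(c("worried", "worry"), lex)[["Anxiety"]], 1)
  # a category with no patterns scores 0 on everything
  lex0 <- liwc_lexicon(list(Female = "she", Empty = character(0)))
  expect_equal(score_day(c("a", "b"), lex0)[["Empty"]], 0)
  # zero tokens: missing, not zero
  expect_true(all(is.na(score_day(character(0), lex))))
})

test_that("score_day is permutation- and multiplicity-scale-invariant", {
  lex <- tiny_lexicon()
  set.seed(31)
  vocab <- c("women", "she", "worried", "risky", "plain", "words", "beware")
  for (i in 1:20) {
    toks <- sample(vocab, sample(3:12, 1), replace = TRUE)
    expect_identical(score_day(sample(toks), lex), score_day(toks, lex))
    expect_equal(score_day(rep(toks, 2), lex), score_day(toks, lex))
  }
})

test_that("score_corpus pools tokens per user-day and skips empty days", {
  lex <- tiny_lexicon()
  posts <- mk_posts(
    user_id = c("u1", "u1", "u2"),
    day = c(-3, -3, -3),
    text = c("women rock", "plain words here", "she worried today danger ahead")
  )
  assign <- tibble::tibble(user_id = c("u1", "u2"), role = "target",
                           day0 = base_day, eligible = TRUE)
  dv <- score_corpus(posts, assign, lex)
  u1 <- dv[dv$user_id == "u1" & dv$category == "Female", ]
  expect_equal(u1$rate, 1 / 5)        # "women" of 5 pooled tokens
  expect_equal(u1$token_count, 5L)
  u2r <- dv[dv$user_id == "u2" & dv$category == "Risk", ]
  expect_equal(u2r$rate, 1 / 5)       # "danger" of 5
  expect_false(any(dv$relative_day != -3))  # no zero-filled days
})

test_that("series values average users equally and interpolate empty days", {
  lex <- tiny_lexicon()
  posts <- dplyr::bind_rows(
    mk_posts("u1", -3, "women are great"),
    mk_posts("u2", -3, "she is here women women women women women hi hi hi"),
    mk_posts(c("u1", "u2"), c(-5, -5), "plain filler text")
  )
  assign <- tibble::tibble(user_id = c("u1", "u2"), role = "target",
                           day0 = base_day, eligible = TRUE)
  dv <- score_corpus(posts, assign, lex)
  s <- build_series(dv, assign, "Female", "target")
  # day -3: u1 has 1 of 3 tokens, u2 has 6 of 11 ("she" + 5x "women")
  expect_equal(s$value[s$relative_day == -3], mean(c(1 / 3, 6 / 11)))
  expect_equal(s$n_users[s$relative_day == -3], 2L)
  expect_true(s$interpolated[s$relative_day == 0])
  expect_false(any(is.na(s$value)))
  # single-user group equals that user's own daily rates
  a1 <- assign[1, ]
  s1 <- build_series(dv[dv$user_id == "u1", ], a1, "Female", "target")
  expect_equal(s1$value[s1$relative_day == -3], 1 / 3)
})

test_that("the all-users series is the user-weighted mean of gender strata", {
  cfg <- quick_config(seed = 21, ambiguous_name_frac = 0)
  sim <- simulate_corpus(cfg)
  co <- build_cohorts(sim$posts, default_terms("campaign"),
                      default_terms("baseline"), base_day)
  # use the generator's true genders so that every user is labeled
  labels <- tibble::tibble(user_id = sim$truth$users$user_id,
                           label = sim$truth$users$gender)
  lex <- read_liwc_dic(keep = c("Female", "Risk"))
  dv <- score_corpus(sim$posts, co, lex,
                     exclude_post_ids = stats::na.omit(co$excluded_post_id))
  ser <- build_category_series(dv, co, gender_labels = labels,
                               groups = c("all", "female", "male", "unknown"))
  one <- ser[ser$category == "Female" & ser$role == "target", ]
  wide <- tidyr::pivot_wider(one, id_cols = "relative_day",
                             names_from = "group",
                             values_from = c("value", "n_users"))
  recomposed <- with(wide, (value_female * n_users_female +
                              value_male * n_users_male +
                              value_unknown * n_users_unknown) /
                       (n_users_female + n_users_male + n_users_unknown))
  expect_equal(recomposed, wide$value_all, tolerance = 1e-12)
})
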
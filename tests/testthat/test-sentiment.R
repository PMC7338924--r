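test_that("health-keyword neutralization replaces whole keywords only", {
  expect_equal(neutralize_keywords("this headache is awful", "headache"),
               "this X is awful")
  expect_equal(neutralize_keywords("no health words", c("headache")),
               "no health words")
  # multi-word keyword replaced as one unit
  expect_equal(neutralize_keywords("sore throat and cough",
                                   c("sore throat", "cough")), "X and X")
  # idempotent, case-insensitive, boundary-respecting
  t1 <- neutralize_keywords("Headaches vs headache", "headache")
  expect_equal(t1, "Headaches vs X")
  expect_equal(neutralize_keywords(t1, "headache"), t1)
})

test_that("compound scores follow the s/sqrt(s^2+15) normalization", {
  expect_equal(score_sentiment("nothing in lexicon", c(love = 2)), 0)
  expect_equal(score_sentiment("I enjoy this", c(enjoy = 2)), 2 / sqrt(19))
  # offsetting valences cancel
  expect_equal(score_sentiment("love hate", c(love = 2, hate = -2)), 0)
  # negation flip within the 3-token window
  expect_lt(score_sentiment("this is not good", c(good = 1.9)), 0)
  expect_gt(score_sentiment("this is good", c(good = 1.9)), 0)
  # beyond the window no flip occurs
  expect_gt(score_sentiment("not that it was at all good",
                            c(good = 1.9)), 0)
  # empty text
  expect_equal(score_sentiment("", c(good = 1)), 0)
})

test_that("scores are bounded, odd in the valence sum", {
  lex <- c(aa = 4, bb = -3.5, cc = 1.2)
  texts <- c("aa aa bb", "bb bb bb cc", "aa cc", "aa bb cc aa")
  s_pos <- score_sentiment(texts, lex)
  s_neg <- score_sentiment(texts, -lex)
  expect_true(all(abs(s_pos) < 1))
  expect_equal(s_neg, -s_pos)
})

test_that("neutralizing a post whose only hits are health keywords zeroes it", {
  tx <- fixture_taxonomies()
  lex <- vapelens_lexicon()
  texts <- c("cough cough headache", "my anxiety and insomnia",
             "lung cancer runs in the family")
  kws <- neutralizable_keywords(tx$health, lex)
  neut <- neutralize_keywords(texts, kws)
  expect_equal(score_sentiment(neut, lex), rep(0, 3))
  # and twice neutralizing changes nothing
  expect_equal(neutralize_keywords(neut, kws), neut)
})

test_that("propensity thresholds partition [-1, 1] with closed polar bounds", {
  expect_equal(classify_propensity(0.05), "positive")
  expect_equal(classify_propensity(0.049), "neutral")
  expect_equal(classify_propensity(-0.05), "negative")
  expect_equal(classify_propensity(-0.049), "neutral")
  expect_error(classify_propensity(1.2), "must lie")
  grid <- seq(-1, 1, by = 0.001)
  cls <- classify_propensity(grid)
  expect_true(all(cls %in% c("positive", "neutral", "negative")))
  expect_equal(cls[grid >= 0.05], rep("positive", sum(grid >= 0.05)))
  expect_equal(cls[grid <= -0.05], rep("negative", sum(grid <= -0.05)))
})

test_that("pooled z-test matches the closed form and the chi-square identity", {
  eq <- two_proportion_z_test(30, 100, 15, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  zt <- two_proportion_z_test(60, 100, 40, 100)
  expect_equal(zt$z, 2.828427, tolerance = 1e-6)
  expect_equal(zt$p_value, 0.004677735, tolerance = 1e-6)

  # z^2 equals the 1-df chi-square statistic without continuity correction
  for (case in list(c(60, 100, 40, 100), c(5, 40, 9, 35),
                    c(120, 300, 80, 260))) {
    zt <- two_proportion_z_test(case[1], case[2], case[3], case[4])
    chi <- suppressWarnings(stats::chisq.test(
      rbind(c(case[1], case[2] - case[1]), c(case[3], case[4] - case[3])),
      correct = FALSE))
    expect_equal(zt$z^2, unname(chi$statistic), tolerance = 1e-9)
    expect_equal(zt$p_value, chi$p.value, tolerance = 1e-9)
  }
  expect_true(two_proportion_z_test(0, 10, 0, 10)$degenerate)
  expect_true(two_proportion_z_test(10, 10, 10, 10)$degenerate)
})

test_that("bonferroni adjustment scales and caps, matching p.adjust", {
  expect_equal(bonferroni_adjust(0.01, m = 1), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  p <- c(0.001, 0.04, 0.3, 0.9)
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  # explicit multiplicity for a fixed family size
  expect_equal(bonferroni_adjust(0.01, m = 9), 0.09)
})

test_that("category summaries recover a planted sentiment mix", {
  tx <- fixture_taxonomies()
  mix <- default_sentiment_mix()
  for (h in names(mix)) mix[[h]] <- c(positive = .2, neutral = .1,
                                      negative = .7)
  cfg <- sim_config(n_users = 400, posts_per_user_mean = 5,
                    sentiment_mix = mix, seed = 21)
  posts <- generate_corpus(cfg)
  hm <- match_corpus(posts, tx$health)
  sm <- summarize_sentiment(posts, hm, tx$health)
  expect_true(all(abs(sm$p_pos + sm$p_neu + sm$p_neg - 1) < 1e-9))
  expect_true(all(sm$p_adj >= sm$p_raw - 1e-12))
  expect_true(all(sm$p_adj <= 1))
  # planted 70% negative recovered within binomial error (3 sd)
  big <- sm[sm$n >= 200, ]
  expect_true(all(abs(big$p_neg - 0.7) < 3 * sqrt(.7 * .3 / big$n) + 0.02))
  # all-identical scores degenerate to a flagged comparison
  ps <- make_posts(rep("vaping has been really great for me lately", 10))
  asn <- data.frame(post_id = ps$post_id, category = "Respiratory")
  one <- summarize_sentiment(ps, asn, tx$health)
  expect_equal(one$p_pos, 1)
  expect_equal(one$p_neg, 0)
  expect_gt(one$mean_score, 0.4)
})
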
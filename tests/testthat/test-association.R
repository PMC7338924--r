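test_that("entry extraction keeps single-flavor posts, one row per health keyword", {
  tx <- fixture_taxonomies()
  posts <- make_posts(c(
    "strawberry e-juice gives me cough and headache",   # 2 entries
    "strawberry and menthol e-juice, cough",            # 2 flavor kw -> 0
    "strawberry e-juice is lovely",                     # no health -> 0
    "custard vape, sore throat again",                  # 1 entry
    "plain vape, just a cough"),                        # no flavor -> 0
    users = c("u1", "u1", "u2", "u2", "u3"))
  ent <- extract_entries(posts, tx$health, tx$flavor)
  expect_equal(nrow(ent), 3L)
  e1 <- ent[ent$post_id == "p001", ]
  expect_setequal(e1$health_category, c("Respiratory", "Neurological"))
  expect_equal(unique(e1$flavor_category), "Fruit")
  expect_equal(ent$health_category[ent$post_id == "p004"], "Throat")
  expect_equal(ent$user_id[ent$post_id == "p004"], "u2")
  expect_false("p002" %in% ent$post_id)
  expect_false("p003" %in% ent$post_id)
  expect_false("p005" %in% ent$post_id)
})

test_that("with one entry per user the GEE reduces to cell-means logistic", {
  set.seed(31)
  n <- 800
  ent <- data.frame(user_id = sprintf("u%04d", 1:n),
                    post_id = sprintf("p%04d", 1:n),
                    flavor_category = sample(c("Fruit", "Sweet", "Tobacco"),
                                             n, TRUE),
                    health_category = sample(c("Respiratory", "Throat"),
                                             n, TRUE, prob = c(.3, .7)),
                    stringsAsFactors = FALSE)
  fit <- fit_gee(ent, "Respiratory")
  emp <- tapply(ent$health_category == "Respiratory", ent$flavor_category,
                mean)
  expect_equal(unname(plogis(fit$beta)), as.vector(emp[names(fit$beta)]),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("independence-limit fit matches the logistic-regression oracle", {
  cfg <- sim_config(n_users = 300, user_effect_sd = 1, seed = 8)
  ent <- generate_entries(cfg, entries_per_user = 4)
  fit <- fit_gee(ent, "Respiratory", corstr = "independence")
  oracle <- glm_cellmeans_oracle(ent, "Respiratory")
  expect_equal(fit$beta[names(oracle)], oracle, tolerance = 1e-6)
  expect_equal(fit$alpha_hat, 0)
})

test_that("sandwich equals the robust GLM covariance when clusters are singletons", {
  skip_if_not_installed("sandwich")
  set.seed(12)
  n <- 500
  ent <- data.frame(user_id = sprintf("u%04d", 1:n),
                    post_id = sprintf("p%04d", 1:n),
                    flavor_category = sample(c("Fruit", "Sweet"), n, TRUE),
                    health_category = sample(c("Respiratory", "Throat"),
                                             n, TRUE),
                    stringsAsFactors = FALSE)
  fit <- fit_gee(ent, "Respiratory")
  y <- as.numeric(ent$health_category == "Respiratory")
  f <- factor(ent$flavor_category)
  g <- stats::glm(y ~ f - 1, family = binomial())
  vc <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$robust_cov), unname(vc), tolerance = 1e-6)
})

test_that("coefficients are invariant to permuting entries within users", {
  cfg <- sim_config(n_users = 200, user_effect_sd = 1.5, seed = 14)
  ent <- generate_entries(cfg, entries_per_user = 3)
  fit1 <- fit_gee(ent, "Throat")
  perm <- order(rev(seq_len(nrow(ent))))
  fit2 <- fit_gee(ent[perm, ], "Throat")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$alpha_hat, fit2$alpha_hat, tolerance = 1e-10)
  expect_equal(fit1$robust_cov, fit2$robust_cov, tolerance = 1e-8)
})

test_that("constant-outcome flavor cells are flagged as boundary", {
  ent <- data.frame(user_id = sprintf("u%03d", 1:60),
                    post_id = sprintf("p%03d", 1:60),
                    flavor_category = rep(c("Fruit", "Sweet", "Beverage"),
                                          20),
                    health_category = c(rep(c("Respiratory", "Throat",
                                              "Throat"), 10),
                                        rep(c("Respiratory", "Throat",
                                              "Respiratory"), 10)),
                    stringsAsFactors = FALSE)
  fit <- fit_gee(ent, "Respiratory")
  expect_true(fit$boundary[["Fruit"]])      # all 1
  expect_true(fit$boundary[["Sweet"]])      # all 0
  pr <- estimate_probabilities(fit)
  expect_equal(pr$probability[pr$flavor == "Fruit"], 1)
  expect_equal(pr$probability[pr$flavor == "Sweet"], 0)
  expect_true(is.na(pr$se[pr$flavor == "Fruit"]))
})

test_that("probability estimates invert the logit with delta-method errors", {
  cfg <- sim_config(n_users = 400, user_effect_sd = 0.5, seed = 16)
  ent <- generate_entries(cfg, entries_per_user = 3)
  fit <- fit_gee(ent, "Respiratory")
  pr <- estimate_probabilities(fit)
  expect_equal(pr$probability, unname(plogis(fit$beta[pr$flavor])))
  se_beta <- sqrt(diag(fit$robust_cov))[pr$flavor]
  expect_equal(pr$se, unname(pr$probability * (1 - pr$probability) * se_beta))
  # exhaustive, mutually exclusive health categories: per-flavor rows of the
  # independence-model probability table sum to 1
  fits <- fit_gee_all(ent, min_entries = 1, corstr = "independence")
  hm <- heatmap_table(fits)
  expect_equal(unname(rowSums(hm)), rep(1, nrow(hm)), tolerance = 1e-9)
})

test_that("tukey contrasts reduce to the normal test at k = 2 and are conservative", {
  set.seed(18)
  n <- 400
  ent <- data.frame(user_id = sprintf("u%04d", 1:n),
                    post_id = sprintf("p%04d", 1:n),
                    flavor_category = sample(c("Fruit", "Sweet"), n, TRUE),
                    health_category = sample(c("Respiratory", "Throat"), n,
                                             TRUE, prob = c(.4, .6)),
                    stringsAsFactors = FALSE)
  fit2 <- fit_gee(ent, "Respiratory")
  ct <- pairwise_tukey(fit2)
  expect_equal(nrow(ct), 1L)
  p_unadj <- 2 * pnorm(-abs(ct$z))
  expect_lt(abs(ct$p_adj - p_unadj), 1e-6)

  # k = 6: adjusted >= unadjusted, bounded by the Bonferroni envelope
  cfg <- sim_config(n_users = 500, user_effect_sd = 0.5, seed = 19)
  ent6 <- generate_entries(cfg, entries_per_user = 3)
  fit6 <- fit_gee(ent6, "Respiratory")
  ct6 <- pairwise_tukey(fit6)
  k <- length(fit6$fit_levels)
  expect_equal(nrow(ct6), k * (k - 1) / 2)
  p_unadj6 <- 2 * pnorm(-abs(ct6$z))
  expect_true(all(ct6$p_adj >= p_unadj6 - 1e-12))
  expect_true(all(ct6$p_adj <= pmin(1, p_unadj6 * k * (k - 1) / 2) + 1e-12))
  expect_equal(ct6$significant, ct6$p_adj < 0.05)
  # antisymmetry is a sign flip of the estimate
  expect_equal(ct6$estimate,
               fit6$beta[ct6$flavor_a] - fit6$beta[ct6$flavor_b],
               ignore_attr = TRUE)
})

test_that("heatmap table reports excluded combinations as missing", {
  cfg <- sim_config(n_users = 300, user_effect_sd = 0, seed = 23)
  ent <- generate_entries(cfg, entries_per_user = 3)
  # starve one flavor below the exclusion threshold
  ent2 <- ent[!(ent$flavor_category == "Beverage" &
                  seq_len(nrow(ent)) > 40), ]
  nbev <- sum(ent2$flavor_category == "Beverage")
  fits <- fit_gee_all(ent2, min_entries = nbev + 1L)
  hm <- heatmap_table(fits,
                      flavor_order = sort(unique(ent$flavor_category)))
  expect_true(all(is.na(hm["Beverage", ])))
  expect_true(all(!is.na(hm[rownames(hm) != "Beverage", ])))
  expect_equal(ncol(hm), length(fits))
})
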
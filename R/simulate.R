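# Synthetic-corpus and synthetic-entry generators. They reproduce the
# statistical structure the analysis pipeline assumes -- user-clustered
# posts, configurable flavor-category frequencies, health co-mention
# probabilities conditional on flavor, within-user correlation via
# logit-normal user effects, a monthly volume trend and per-category
# sentiment mixes -- so every stage runs and is testable at desk scale
# without any external download. All draws flow from one seed.

SIM_HEALTH <- c("Respiratory", "Cardiovascular", "Neurological",
                "Psychological", "Digestive", "Throat")
SIM_FLAVORS <- c("Fruit", "Menthol or Mint", "Tobacco", "Sweet",
                 "Beverage", "Mixed")

#' Default planted co-mention matrix
#'
#' `P(health category | flavor category)` for the six flavors and six health
#' categories the generator simulates, scaled by an overall health-mention
#' rate (the row remainder is the no-mention probability). Throat and
#' Respiratory dominate, mirroring the magnitudes reported for
#' flavor-health heatmaps.
#'
#' @param mention_rate Overall probability that a flavor post mentions any
#'   health category.
#' @return Matrix with flavor rows and health-category columns.
#' @export
default_comention_matrix <- function(mention_rate = 0.6) {
  cond <- rbind(
    Fruit             = c(.25, .08, .08, .09, .06, .44),
    `Menthol or Mint` = c(.30, .05, .06, .07, .05, .47),
    Tobacco           = c(.35, .06, .07, .08, .06, .38),
    Sweet             = c(.28, .05, .07, .08, .09, .43),
    Beverage          = c(.20, .06, .07, .08, .07, .52),
    Mixed             = c(.30, .06, .09, .11, .06, .38))
  colnames(cond) <- SIM_HEALTH
  cond * mention_rate
}

#' Default per-category sentiment mixes
#'
#' Positive-dominant mixes for every simulated health category, a
#' negative-dominant mix for Cancer-style discussions, and a `"none"` mix
#' for posts without a health mention.
#'
#' @return Named list of probability vectors (positive, neutral, negative).
#' @export
default_sentiment_mix <- function() {
  base <- c(positive = .55, neutral = .15, negative = .30)
  mix <- lapply(SIM_HEALTH, function(h) base)
  names(mix) <- SIM_HEALTH
  mix$Cancer <- c(positive = .15, neutral = .10, negative = .75)
  mix$none <- c(positive = .45, neutral = .35, negative = .20)
  mix
}

#' Simulation configuration
#'
#' @param n_users Number of users (clusters).
#' @param posts_per_user_mean Poisson mean of posts (or entries) per user.
#' @param date_range `c(from, to)` months, "YYYY-MM".
#' @param monthly_volume_trend Positive weight per month in the window;
#'   default a linear 1 -> 3 increase (volume grows over the window).
#' @param flavor_distribution Named probability vector over flavor
#'   categories (normalized if needed).
#' @param comention_matrix Matrix of `P(health category | flavor category)`,
#'   rows = flavors, columns = health categories, row sums <= 1; the
#'   remainder of each row is the probability of no health mention.
#' @param user_effect_sd Standard deviation of the per-user random effects
#'   on the logit scale (0 = independent entries within users).
#' @param sentiment_mix Named list: health category (plus `"none"`) ->
#'   probability vector over positive/neutral/negative template text.
#' @param contamination_rate Probability that a post gets a second, distinct
#'   flavor keyword (such posts exercise the one-flavor exclusion rule).
#' @param seed Integer root seed for all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_users = 500L, posts_per_user_mean = 4,
                       date_range = c("2013-01", "2019-04"),
                       monthly_volume_trend = NULL,
                       flavor_distribution = NULL,
                       comention_matrix = default_comention_matrix(),
                       user_effect_sd = 0.5,
                       sentiment_mix = default_sentiment_mix(),
                       contamination_rate = 0, seed = 1L) {
  stopifnot(n_users >= 1L, posts_per_user_mean > 0, user_effect_sd >= 0,
            contamination_rate >= 0, contamination_rate <= 1)
  if (is.null(flavor_distribution)) {
    flavor_distribution <- setNames(
      c(.28, .17, .10, .22, .10, .13), SIM_FLAVORS)
  }
  if (abs(sum(flavor_distribution) - 1) > 1e-8)
    flavor_distribution <- flavor_distribution / sum(flavor_distribution)
  if (any(flavor_distribution < 0)) stop("invalid flavor_distribution")
  if (is.null(rownames(comention_matrix)) ||
      !setequal(rownames(comention_matrix), names(flavor_distribution)))
    stop("comention_matrix rows must match flavor_distribution names")
  if (any(comention_matrix < 0) || any(rowSums(comention_matrix) > 1 + 1e-9))
    stop("comention_matrix rows must be non-negative with sums <= 1")
  months <- month_seq(date_range[1], date_range[2])
  if (is.null(monthly_volume_trend))
    monthly_volume_trend <- seq(1, 3, length.out = length(months))
  if (length(monthly_volume_trend) != length(months) ||
      any(monthly_volume_trend <= 0))
    stop("monthly_volume_trend needs one positive weight per month")
  structure(list(n_users = as.integer(n_users),
                 posts_per_user_mean = posts_per_user_mean,
                 date_range = date_range, months = months,
                 monthly_volume_trend = monthly_volume_trend,
                 flavor_distribution = flavor_distribution,
                 comention_matrix = comention_matrix,
                 user_effect_sd = user_effect_sd,
                 sentiment_mix = sentiment_mix,
                 contamination_rate = contamination_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Calibrated per-category intercepts: find gamma such that the
# population-averaged (marginal) category distribution
#   E_b[ plogis(gamma + b) / sum_h plogis(gamma_h + b_h) ],  b ~ N(0, sd^2 I)
# equals the target conditional row. Users draw independent per-category
# effects b; without calibration the renormalized logit-normal perturbation
# would bias the marginal row, and the GEE estimates marginals. The
# expectation uses a fixed quasi-sample of standard normals, so the result
# is deterministic.
calibrate_offsets <- function(p_cond, sd, n_mc = 20000L, tol = 5e-5,
                              max_iter = 200L) {
  m <- length(p_cond)
  gamma <- qlogis(p_cond)
  if (sd == 0) return(gamma)
  Z <- withr_seed(987654L, matrix(rnorm(n_mc * m), n_mc, m)) * sd
  for (it in seq_len(max_iter)) {
    Q <- plogis(sweep(Z, 2L, gamma, "+"))
    marg <- colMeans(Q / rowSums(Q))
    if (max(abs(marg - p_cond)) < tol) break
    gamma <- gamma + qlogis(p_cond) - qlogis(marg)
  }
  gamma
}

# Sample one category per row of a probability matrix (rows sum to 1).
sample_rows <- function(P) {
  u <- runif(nrow(P))
  cp <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  as.integer(rowSums(u > cp)) + 1L
}

#' Generate user-clustered association entries directly
#'
#' Bypasses text generation: emits entries whose flavor follows the
#' configured flavor distribution and whose health category follows the
#' planted conditional co-mention row (the `comention_matrix` row normalized
#' to sum to 1), perturbed per user by calibrated logit-normal random
#' effects so that the marginal row equals the planted row while entries of
#' one user are positively correlated.
#'
#' @param config A [sim_config()].
#' @param entries_per_user Fixed entries per user; default Poisson
#'   (`posts_per_user_mean`) truncated at >= 1.
#' @param seed Seed override (default `config$seed`).
#' @return Entry data frame: `user_id`, `post_id`, `flavor_category`,
#'   `health_category`.
#' @export
generate_entries <- function(config, entries_per_user = NULL,
                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cm <- config$comention_matrix
  cond <- cm / rowSums(cm)
  flavors <- rownames(cm)
  healths <- colnames(cm)
  gam <- t(vapply(flavors, function(f)
    calibrate_offsets(cond[f, ], config$user_effect_sd), numeric(ncol(cm))))
  withr_seed(seed, {
    n_e <- if (is.null(entries_per_user))
      pmax(1L, rpois(config$n_users, config$posts_per_user_mean))
    else rep(as.integer(entries_per_user), config$n_users)
    user <- rep(seq_len(config$n_users), n_e)
    n <- length(user)
    B <- matrix(rnorm(config$n_users * ncol(cm), 0, config$user_effect_sd),
                config$n_users, ncol(cm))
    fl <- sample(flavors, n, replace = TRUE,
                 prob = config$flavor_distribution[flavors])
    he <- character(n)
    for (f in flavors) {
      idx <- which(fl == f)
      if (length(idx) == 0L) next
      Q <- plogis(sweep(B[user[idx], , drop = FALSE], 2L, gam[f, ], "+"))
      P <- Q / rowSums(Q)
      he[idx] <- healths[sample_rows(P)]
    }
    data.frame(user_id = sprintf("u%06d", user),
               post_id = sprintf("p%07d", seq_len(n)),
               flavor_category = fl, health_category = he,
               stringsAsFactors = FALSE)
  })
}

# Text templates. The flavor sentence always contains an e-cigarette term
# ("e-juice") and the word "flavor", so generated posts pass the corpus
# filter and the tobacco disambiguation rule by construction.
sim_flavor_sentence <- function(kw) {
  sprintf("Picked up a %s flavor e-juice yesterday.", kw)
}
sim_health_sentence <- function(kw, sentiment) {
  switch(sentiment,
    positive = sprintf("It is great and my %s got so much better.", kw),
    neutral = sprintf("I noticed some %s this week.", kw),
    negative = sprintf("It is awful and the %s just got worse.", kw))
}
sim_plain_sentence <- function(sentiment) {
  switch(sentiment,
    positive = "Vaping has been really great for me lately.",
    neutral = "Spent the evening cleaning my vape gear.",
    negative = "To be honest this batch tastes pretty bad.")
}

#' Generate a synthetic post corpus
#'
#' For each user: a Poisson number of posts; for each post a month (drawn
#' from the volume trend), one flavor keyword from the fixture flavor
#' taxonomy (exactly one per post unless contaminated), a health category
#' from the user-perturbed co-mention row (or none, with probability
#' 1 - row sum) with a concrete health keyword, and template text whose
#' sentiment follows the configured per-category mix. Deterministic given
#' the seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (default `config$seed`).
#' @return Post data frame: `post_id`, `user_id`, `created_utc`, `text`,
#'   plus hidden truth columns `.flavor`, `.health` (`NA` when absent) for
#'   validation.
#' @export
generate_corpus <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  flavor_tx <- vapelens_taxonomies()$flavor
  health_tx <- vapelens_taxonomies()$health
  cm <- config$comention_matrix
  cond <- cm / rowSums(cm)
  mention_p <- rowSums(cm)
  flavors <- rownames(cm)
  healths <- colnames(cm)
  gam <- t(vapply(flavors, function(f)
    calibrate_offsets(cond[f, ], config$user_effect_sd), numeric(ncol(cm))))
  first_days <- seq(as.Date(paste0(config$months[1], "-01")),
                    by = "month", length.out = length(config$months) + 1L)
  bounds <- as.POSIXct(format(first_days), tz = "UTC")
  month_start <- bounds[-length(bounds)]
  month_len <- as.numeric(difftime(bounds[-1L], month_start, units = "secs"))
  withr_seed(seed, {
    n_posts <- rpois(config$n_users, config$posts_per_user_mean)
    user <- rep(seq_len(config$n_users), n_posts)
    n <- length(user)
    if (n == 0L) stop("no posts generated; increase posts_per_user_mean")
    B <- matrix(rnorm(config$n_users * ncol(cm), 0, config$user_effect_sd),
                config$n_users, ncol(cm))
    mo <- sample(seq_along(config$months), n, replace = TRUE,
                 prob = config$monthly_volume_trend)
    ts <- as.numeric(month_start[mo]) + floor(runif(n) * month_len[mo])
    fl <- sample(flavors, n, replace = TRUE,
                 prob = config$flavor_distribution[flavors])
    mention <- runif(n) < mention_p[fl]
    he <- rep(NA_character_, n)
    for (f in flavors) {
      idx <- which(fl == f & mention)
      if (length(idx) == 0L) next
      Q <- plogis(sweep(B[user[idx], , drop = FALSE], 2L, gam[f, ], "+"))
      he[idx] <- healths[sample_rows(Q / rowSums(Q))]
    }
    flavor_kw <- vapply(fl, function(f)
      sample(flavor_tx$categories[[f]], 1L), "")
    health_kw <- ifelse(is.na(he), NA_character_,
                        vapply(seq_len(n), function(i) {
                          if (is.na(he[i])) "" else
                            sample(health_tx$categories[[he[i]]], 1L)
                        }, ""))
    senti <- vapply(seq_len(n), function(i) {
      mix <- config$sentiment_mix[[if (is.na(he[i])) "none" else he[i]]]
      if (is.null(mix)) mix <- config$sentiment_mix$none
      sample(names(mix), 1L, prob = mix)
    }, "")
    text <- vapply(seq_len(n), function(i) {
      s1 <- sim_flavor_sentence(flavor_kw[i])
      s2 <- if (is.na(he[i])) sim_plain_sentence(senti[i])
            else sim_health_sentence(health_kw[i], senti[i])
      out <- paste(s1, s2)
      if (config$contamination_rate > 0 &&
          runif(1) < config$contamination_rate) {
        other <- setdiff(unlist(flavor_tx$categories), flavor_kw[i])
        out <- paste(out, sim_flavor_sentence(sample(other, 1L)))
      }
      out
    }, "")
    data.frame(post_id = sprintf("p%07d", seq_len(n)),
               user_id = sprintf("u%06d", user),
               created_utc = as.integer(ts), text = text,
               .flavor = fl, .health = he,
               stringsAsFactors = FALSE)
  })
}

#' Bundled fixture taxonomies
#'
#' Small e-cigarette / health / flavor taxonomies shipped with the package:
#' the published 20-term e-cigarette list, nine health categories and seven
#' flavor categories with a handful of keywords each (a synthetic,
#' desk-scale stand-in for full keyword appendices), including the
#' sentence-scope tobacco disambiguation rule.
#'
#' @return List with elements `ecig`, `health`, `flavor`
#'   (`keyword_taxonomy` objects).
#' @export
vapelens_taxonomies <- function() {
  dir <- system.file("extdata", package = "vapelens", mustWork = TRUE)
  list(ecig = read_taxonomy(file.path(dir, "taxonomy_ecig.csv")),
       health = read_taxonomy(file.path(dir, "taxonomy_health.csv")),
       flavor = read_taxonomy(file.path(dir, "taxonomy_flavor.csv")))
}
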
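test_that("keyword matching finds token-boundary occurrences per sentence", {
  tx <- keyword_taxonomy("ecig", list(ecig = c("vape", "e-juice")))
  m <- match_keywords("I love my vape.", tx, "p1")
  expect_equal(nrow(m), 1L)
  expect_equal(m$keyword, "vape")
  expect_equal(m$category, "ecig")
  expect_equal(m$sentence_index, 0L)

  # token boundaries: no substring hits, hyphenated keyword is literal
  expect_equal(nrow(match_keywords("vapers unite", tx)), 0L)
  expect_equal(match_keywords("Best e-juice ever.", tx)$keyword, "e-juice")
  expect_equal(nrow(match_keywords("ejuice", tx)), 0L)
  # case-insensitive; empty text gives empty record set
  expect_equal(nrow(match_keywords("VAPE on", tx)), 1L)
  expect_equal(nrow(match_keywords("", tx)), 0L)
})

test_that("tobacco disambiguation keeps only flavor-context sentences", {
  fl <- tiny_flavor_taxonomy()
  expect_equal(nrow(match_keywords("Tobacco kills.", fl)), 0L)
  m <- match_keywords("This tobacco flavor e-liquid is smooth.", fl)
  expect_equal(m$keyword, "tobacco")
  # context must be in the same sentence, not merely the same post
  m2 <- match_keywords("I like tobacco. The flavor of mango is better.", fl)
  expect_false("tobacco" %in% m2$keyword)
  expect_true("mango" %in% m2$keyword)
})

test_that("disambiguation survivors verifiably contain a context keyword", {
  fl <- tiny_flavor_taxonomy()
  texts <- c("tobacco flavor is fine", "pure tobacco here",
             "tobacco. flavor elsewhere", "juice with tobacco",
             "mango tobacco e-juice", "no keywords at all")
  posts <- make_posts(texts)
  recs <- match_corpus(posts, fl)
  amb <- recs[recs$keyword == "tobacco", , drop = FALSE]
  rule <- fl$rules[["tobacco"]]
  for (i in seq_len(nrow(amb))) {
    sent <- split_sentences(posts$text[posts$post_id == amb$post_id[i]])[
      amb$sentence_index[i] + 1L]
    expect_true(any(vapply(rule$context, function(ck)
      grepl(paste0("\\b", ck, "\\b"), tolower(sent)), logical(1))))
  }
  expect_false("p002" %in% amb$post_id)  # bare tobacco filtered
})

test_that("longest keyword wins at overlapping positions", {
  tx <- keyword_taxonomy("health",
                         list(Throat = c("sore throat", "throat")),
                         strict = FALSE)
  m <- match_keywords("My sore throat is back.", tx)
  expect_equal(m$keyword, "sore throat")
  # the shorter keyword still matches on its own
  expect_equal(match_keywords("throat feels fine", tx)$keyword, "throat")
})

test_that("match_corpus agrees with per-post matching regardless of order", {
  tx <- fixture_taxonomies()
  texts <- c("I love my vape.", "This tobacco flavor e-juice is smooth.",
             "Tobacco kills.", "strawberry custard drip",
             "sore throat from vaping. menthol helps")
  posts <- make_posts(texts)
  per_post <- do.call(rbind, lapply(seq_len(nrow(posts)), function(i)
    match_keywords(posts$text[i], tx$flavor, posts$post_id[i])))
  bulk <- match_corpus(posts, tx$flavor)
  ord <- function(d) {
    d <- d[order(d$post_id, d$sentence_index, d$keyword), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(bulk), ord(per_post))
  # permuting the stream yields the same records
  perm <- sample(nrow(posts))
  bulk2 <- match_corpus(posts[perm, ], tx$flavor)
  expect_equal(ord(bulk2), ord(bulk))
})

test_that("filter_corpus keeps matching English posts in order", {
  tx <- fixture_taxonomies()
  posts <- make_posts(c("no keywords here", "my new e-juice rocks",
                        "https://example.com/vape",
                        "вейп курю",
                        "best vape ever"))
  out <- filter_corpus(posts, tx$ecig)
  expect_equal(out$post_id, c("p002", "p005"))
  expect_gte(attr(out, "n_dropped_language"), 2L)
  # empty stream passes through
  expect_equal(nrow(filter_corpus(posts[0, ], tx$ecig)), 0L)
  # subset nesting: health/flavor subsets are within the e-cig corpus
  corpus <- filter_corpus(posts, tx$ecig)
  hm <- match_corpus(corpus, tx$health)
  expect_true(all(hm$post_id %in% corpus$post_id))
})

test_that("adding a keyword never decreases a category's post count", {
  base <- keyword_taxonomy("ecig", list(ecig = "vape"))
  wider <- keyword_taxonomy("ecig", list(ecig = c("vape", "juul")))
  posts <- make_posts(c("vape life", "juul pods", "tea time", "vape + juul"))
  n_base <- nrow(filter_corpus(posts, base, language_filter = NULL))
  n_wide <- nrow(filter_corpus(posts, wider, language_filter = NULL))
  expect_gte(n_wide, n_base)
})

test_that("classify_post unions categories and counts distinct keywords", {
  tx <- fixture_taxonomies()
  r1 <- classify_post("This cough and wheezing won't stop", tx$health,
                      tx$flavor)
  expect_equal(r1$health_categories, "Respiratory")
  expect_equal(r1$flavor_categories, character(0))

  r2 <- classify_post("strawberry vape gives me a headache", tx$health,
                      tx$flavor)
  expect_equal(r2$health_categories, "Neurological")
  expect_equal(r2$flavor_categories, "Fruit")

  r3 <- classify_post("menthol and mint help my sore throat", tx$health,
                      tx$flavor)
  expect_equal(r3$health_categories, "Throat")
  expect_equal(r3$flavor_categories, "Menthol or Mint")
  expect_equal(length(r3$flavor_keywords), 2L)
})

test_that("taxonomy validation enforces the category contracts", {
  expect_error(keyword_taxonomy("x", list(a = "dup", b = "dup")),
               "more than one category")
  expect_error(keyword_taxonomy("health", list(Respiratory = "cough")),
               "nine")
  # keywords are normalized to lowercase on construction
  expect_equal(keyword_taxonomy("x", list(a = "UPPER"))$categories$a,
               "upper")
  # strict = FALSE allows ad hoc category sets
  expect_s3_class(keyword_taxonomy("health", list(Respiratory = "cough"),
                                   strict = FALSE), "keyword_taxonomy")
})

test_that("taxonomies load from CSV and YAML with rules intact", {
  tx <- fixture_taxonomies()
  expect_length(tx$health$categories, 9L)
  expect_length(tx$flavor$categories, 7L)
  expect_named(tx$flavor$rules, "tobacco")

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "flavor",
                        categories = lapply(tx$flavor$categories, as.list),
                        rules = list(list(keyword = "tobacco",
                                          context = as.list(
                                            tx$flavor$rules$tobacco$context)))),
                   yml)
  tx2 <- read_taxonomy(yml)
  expect_equal(sort(unlist(tx2$categories)), sort(unlist(tx$flavor$categories)))
  expect_equal(tx2$rules$tobacco$context, tx$flavor$rules$tobacco$context)
})

test_that("precision audit samples deterministically and scores labels", {
  tx <- fixture_taxonomies()
  posts <- make_posts(rep(c("my vape is fine", "cats are fine"), 100))
  a1 <- audit_filter_precision(posts, "vape", tx$ecig, n_sample = 50,
                               seed = 42)
  a2 <- audit_filter_precision(posts, "vape", tx$ecig, n_sample = 50,
                               seed = 42)
  expect_equal(a1$sample$post_id, a2$sample$post_id)
  expect_equal(nrow(a1$sample), 50L)
  # labels -> precision = true positives / sample size
  labs <- rep(c(TRUE, FALSE), c(85, 15))[seq_len(50)]
  a3 <- audit_filter_precision(posts, "vape", tx$ecig, n_sample = 50,
                               seed = 42, labels = labs)
  expect_equal(a3$precision, mean(labs))
  # capped at availability
  a4 <- audit_filter_precision(posts[1:6, ], "vape", tx$ecig, n_sample = 100)
  expect_equal(nrow(a4$sample), 3L)
  expect_warning(audit_filter_precision(posts, "absent", tx$ecig),
                 "not found")
})
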
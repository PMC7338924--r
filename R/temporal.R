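# Monthly mention counting and normalization against total e-cigarette post
# volume, plus the category-share arithmetic used in headline summaries.

# UTC calendar month label ("YYYY-MM") for epoch-second timestamps.
month_of <- function(created_utc) {
  format(as.POSIXct(as.numeric(created_utc), origin = "1970-01-01",
                    tz = "UTC"), "%Y-%m")
}

month_seq <- function(from, to) {
  f <- as.Date(paste0(from, "-01")); t <- as.Date(paste0(to, "-01"))
  format(seq(f, t, by = "month"), "%Y-%m")
}

#' Monthly post counts per category
#'
#' A post mentioning a category in month m increments that category's count
#' for m by one, regardless of how many of the category's keywords it
#' contains. Months inside the window with no posts appear with count 0, so
#' every series covers the window contiguously.
#'
#' @param posts Post data frame with `post_id` and `created_utc`.
#' @param category_assignment Data frame mapping posts to categories
#'   (columns `post_id`, `category`), e.g. the match records from
#'   [match_corpus()]; a post matched several times in one category counts
#'   once.
#' @param window Character vector `c(from, to)` of "YYYY-MM" months; default
#'   the observed range. Posts outside the window are excluded (their number
#'   is returned in attribute `"n_outside_window"` with a warning).
#' @return Data frame: `month`, `category`, `count`.
#' @export
monthly_counts <- function(posts, category_assignment, window = NULL) {
  stopifnot(all(c("post_id", "created_utc") %in% names(posts)),
            all(c("post_id", "category") %in% names(category_assignment)))
  if (any(is.na(posts$created_utc)))
    stop("every post needs a valid created_utc")
  posts$month <- month_of(posts$created_utc)
  if (is.null(window)) window <- range(posts$month)
  months <- month_seq(window[1], window[2])
  outside <- !(posts$month %in% months)
  if (any(outside))
    warning(sum(outside), " post(s) outside the window were excluded")
  posts <- posts[!outside, , drop = FALSE]
  ca <- unique(category_assignment[, c("post_id", "category")])
  ca$month <- posts$month[match(ca$post_id, posts$post_id)]
  ca <- ca[!is.na(ca$month), , drop = FALSE]
  cats <- sort(unique(category_assignment$category))
  grid <- expand.grid(month = months, category = cats,
                      stringsAsFactors = FALSE)
  if (nrow(ca) > 0L) {
    tb <- as.data.frame(table(month = ca$month, category = ca$category),
                        stringsAsFactors = FALSE)
    key <- paste(grid$month, grid$category)
    grid$count <- tb$Freq[match(key, paste(tb$month, tb$category))]
    grid$count[is.na(grid$count)] <- 0L
  } else grid$count <- 0L
  grid <- grid[order(grid$category, grid$month), , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "n_outside_window") <- sum(outside)
  grid
}

#' Total posts per month (the normalization denominator)
#'
#' @param posts Post data frame (typically the full e-cigarette corpus).
#' @param window As in [monthly_counts()].
#' @return Data frame: `month`, `total`.
#' @export
monthly_totals <- function(posts, window = NULL) {
  m <- month_of(posts$created_utc)
  if (is.null(window)) window <- range(m)
  months <- month_seq(window[1], window[2])
  tb <- table(factor(m[m %in% months], levels = months))
  data.frame(month = months, total = as.integer(tb),
             stringsAsFactors = FALSE)
}

#' Normalize category series by total monthly volume
#'
#' proportion = category count / total e-cigarette posts that month. Months
#' with zero total yield `NA` (missing), never 0.
#'
#' @param category_series Output of [monthly_counts()].
#' @param total_series Output of [monthly_totals()], same month axis.
#' @return `category_series` with a `proportion` column added.
#' @export
normalize_series <- function(category_series, total_series) {
  if (!setequal(unique(category_series$month), total_series$month))
    stop("month axes are not aligned")
  tot <- total_series$total[match(category_series$month, total_series$month)]
  category_series$proportion <- ifelse(tot > 0,
                                       category_series$count / tot, NA_real_)
  category_series
}

#' Category shares as printed percentages
#'
#' percentage = 100 * count / denominator, reported to two decimals.
#' `mode = "round"` (default) uses round-half-even; `mode = "truncate"`
#' drops digits beyond the second decimal instead. Published tables mix both
#' conventions (e.g. 0.9775% printed as 0.97%), so both are supported.
#'
#' @param category_counts Named numeric vector of counts per category.
#' @param denominator Common denominator; default `sum(category_counts)`.
#' @param mode `"round"` or `"truncate"`.
#' @return Named numeric vector of percentages, ordered descending.
#' @export
#' @examples
#' category_share(c(Respiratory = 94691, Cancer = 3299), 337482)
category_share <- function(category_counts, denominator = NULL,
                           mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(all(category_counts >= 0))
  if (is.null(denominator)) denominator <- sum(category_counts)
  if (denominator <= 0) stop("denominator must be positive")
  pct <- 100 * category_counts / denominator
  pct <- if (mode == "truncate") floor(pct * 100 + 1e-9) / 100
         else round(pct, 2)
  sort(pct, decreasing = TRUE)
}
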
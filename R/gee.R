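# Binomial-logit GEE with exchangeable (compound-symmetry) working
# correlation, clustered by user, for flavor-health co-mention probabilities.
#
# For the modeled health category, each entry contributes y = 1 if the
# entry's health category equals the target. The design is a cell-means
# (no-intercept) indicator over flavor levels, so the inverse-logit of each
# coefficient is directly the estimated co-mention probability for that
# flavor. Coefficients solve sum_i D_i' V_i^-1 (y_i - mu_i) = 0 by Fisher
# scoring, with V_i = phi A_i^1/2 R(alpha) A_i^1/2 and R exchangeable;
# alpha and phi are re-estimated from Pearson residuals each iteration
# (moment estimators). Inference uses the robust sandwich covariance
# B^-1 M B^-1. The exchangeable R^-1 is applied in closed form
# (R^-1 = (I - c J) / (1 - alpha), c = alpha / (1 + (n_i - 1) alpha)), so no
# per-cluster matrix inversion is needed and fits on 10^4+ entries take
# fractions of a second.

#' Fit a per-health-category co-mention GEE
#'
#' @param entries Data frame of association entries: `user_id`,
#'   `flavor_category`, `health_category` (see [extract_entries()]).
#' @param health_category The modeled category; the binary outcome is the
#'   indicator that an entry belongs to it.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param tol Convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param max_iter Fisher-scoring iteration cap (default 100).
#' @param min_entries Flavor levels with fewer entries are dropped with a
#'   warning (default 1 = keep all non-empty levels).
#' @return Object of class `gee_fit`: `beta` (log-odds per flavor),
#'   `robust_cov`, `alpha_hat`, `phi_hat`, `boundary` (flavors whose outcome
#'   is constant, excluded from the fit), `n_entries`, `n_users`,
#'   `converged`, `n_iter`.
#' @export
fit_gee <- function(entries, health_category,
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100L, min_entries = 1L) {
  corstr <- match.arg(corstr)
  stopifnot(all(c("user_id", "flavor_category", "health_category")
                %in% names(entries)), nrow(entries) > 0L)
  flavor <- as.character(entries$flavor_category)
  n_per <- table(flavor)
  drop_small <- names(n_per)[n_per < min_entries]
  if (length(drop_small) > 0L) {
    warning("dropping flavor level(s) with < ", min_entries, " entries: ",
            paste(drop_small, collapse = ", "))
    keep <- !(flavor %in% drop_small)
    entries <- entries[keep, , drop = FALSE]
    flavor <- flavor[keep]
  }
  levels_f <- sort(unique(flavor))
  if (length(levels_f) < 2L) stop("need at least two flavor levels")
  y <- as.numeric(entries$health_category == health_category)

  # boundary cells: constant outcome within a flavor -> beta diverges; flag
  # and exclude from the scoring iterations
  cell_mean <- vapply(split(y, flavor), mean, numeric(1))
  boundary <- cell_mean %in% c(0, 1)
  names(boundary) <- names(cell_mean)
  fit_levels <- levels_f[!boundary[levels_f]]
  if (length(fit_levels) == 0L) stop("all flavor cells have constant outcome")

  in_fit <- flavor %in% fit_levels
  yf <- y[in_fit]
  ff <- factor(flavor[in_fit], levels = fit_levels)
  cl <- factor(as.character(entries$user_id[in_fit]))
  p <- length(fit_levels)
  X <- vapply(fit_levels, function(l) as.numeric(ff == l),
              numeric(length(yf)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(yf))
  colnames(X) <- fit_levels
  n_i <- as.integer(table(cl))
  N <- length(yf)
  Nstar <- sum(n_i * (n_i - 1)) / 2
  alpha_lo <- if (max(n_i) > 1L) -1 / (max(n_i) - 1) + 1e-6 else 0

  # independence start: cell-means logistic has the closed-form solution
  # beta_f = logit(cell mean)
  beta <- qlogis(cell_mean[fit_levels])
  alpha_hat <- 0; phi_hat <- 1
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    a <- mu * (1 - mu)
    w <- sqrt(a)
    e <- (yf - mu) / w                       # Pearson residuals
    phi_hat <- sum(e^2) / (N - p)
    if (corstr == "exchangeable" && Nstar > p) {
      E <- rowsum(e, cl)
      cross <- sum((E^2 - rowsum(e^2, cl))) / 2
      alpha_hat <- cross / ((Nstar - p) * phi_hat)
      alpha_hat <- min(max(alpha_hat, alpha_lo), 0.999)
    } else alpha_hat <- 0
    c_i <- alpha_hat / (1 + (n_i - 1) * alpha_hat)
    Xw <- X * w
    Swx <- rowsum(Xw, cl)                    # per-cluster sum of w_j x_j
    E <- drop(rowsum(e, cl))
    B <- crossprod(X, X * a) - crossprod(Swx, Swx * c_i)
    G <- rowsum(Xw * e, cl) - (c_i * E) * Swx
    delta <- solve(B, colSums(G))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  # sandwich at the solution (recompute pieces at final beta)
  eta <- drop(X %*% beta); mu <- plogis(eta)
  a <- mu * (1 - mu); w <- sqrt(a); e <- (yf - mu) / w
  c_i <- alpha_hat / (1 + (n_i - 1) * alpha_hat)
  Xw <- X * w
  Swx <- rowsum(Xw, cl)
  E <- drop(rowsum(e, cl))
  B <- crossprod(X, X * a) - crossprod(Swx, Swx * c_i)
  G <- rowsum(Xw * e, cl) - (c_i * E) * Swx
  Binv <- solve(B)
  robust_cov <- Binv %*% crossprod(G) %*% Binv
  robust_cov <- (robust_cov + t(robust_cov)) / 2
  dimnames(robust_cov) <- list(fit_levels, fit_levels)

  beta_full <- setNames(rep(NA_real_, length(levels_f)), levels_f)
  beta_full[fit_levels] <- beta
  beta_full[levels_f[boundary[levels_f]]] <-
    ifelse(cell_mean[levels_f[boundary[levels_f]]] == 1, Inf, -Inf)
  structure(list(health_category = health_category, flavors = levels_f,
                 n_per_flavor = setNames(as.integer(table(flavor)[levels_f]),
                                         levels_f),
                 fit_levels = fit_levels, beta = beta_full,
                 robust_cov = robust_cov, alpha_hat = alpha_hat,
                 phi_hat = phi_hat, boundary = boundary[levels_f],
                 corstr = corstr, n_entries = nrow(entries),
                 n_users = length(unique(entries$user_id)),
                 converged = converged, n_iter = iter),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "<gee_fit '%s': %d entries, %d users, %s, alpha=%.3f, %sconverged (%d it)>\n",
    x$health_category, x$n_entries, x$n_users, x$corstr, x$alpha_hat,
    if (x$converged) "" else "NOT ", x$n_iter))
  print(estimate_probabilities(x))
  invisible(x)
}

#' Co-mention probabilities with robust standard errors
#'
#' probability = inverse-logit(beta_f); delta-method standard error
#' p (1 - p) se(beta_f) on the probability scale. Boundary flavors report
#' probability 0/1 with `NA` standard error.
#'
#' @param fit A `gee_fit`.
#' @return Data frame: `flavor`, `probability`, `se`, `n`, `boundary`.
#' @export
estimate_probabilities <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  se_beta <- setNames(rep(NA_real_, length(fit$flavors)), fit$flavors)
  se_beta[fit$fit_levels] <- sqrt(diag(fit$robust_cov))
  prob <- plogis(fit$beta)
  data.frame(flavor = fit$flavors, probability = unname(prob),
             se = unname(prob * (1 - prob) * se_beta),
             n = unname(fit$n_per_flavor),
             boundary = unname(fit$boundary),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tukey-adjusted pairwise flavor contrasts
#'
#' For every pair of fitted flavor levels, the log-odds difference, its
#' robust standard error, z = estimate / se, and the single-step Tukey
#' adjustment `p_adj = P(Q_(k, Inf) >= |z| sqrt(2))` from the studentized
#' range distribution with infinite degrees of freedom (appropriate for the
#' GEE's asymptotic z statistics). Two-sided, significance at 5%.
#'
#' @param fit A converged `gee_fit` with >= 2 fitted levels.
#' @return Data frame: `health_category`, `flavor_a`, `flavor_b`,
#'   `estimate`, `se`, `z`, `p_adj`, `significant`, `degenerate`.
#' @export
pairwise_tukey <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  lv <- fit$fit_levels
  k <- length(lv)
  if (k < 2L) stop("need at least two fitted flavor levels")
  pairs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    aL <- pairs[1L, j]; bL <- pairs[2L, j]
    est <- fit$beta[aL] - fit$beta[bL]
    v <- fit$robust_cov[aL, aL] + fit$robust_cov[bL, bL] -
      2 * fit$robust_cov[aL, bL]
    se <- sqrt(max(v, 0))
    if (se == 0) {
      return(data.frame(health_category = fit$health_category,
                        flavor_a = aL, flavor_b = bL, estimate = unname(est),
                        se = 0, z = NA_real_, p_adj = 1, significant = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    z <- unname(est / se)
    p_adj <- ptukey(abs(z) * sqrt(2), nmeans = k, df = Inf,
                    lower.tail = FALSE)
    data.frame(health_category = fit$health_category, flavor_a = aL,
               flavor_b = bL, estimate = unname(est), se = se, z = z,
               p_adj = p_adj, significant = p_adj < 0.05, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit one GEE per health category
#'
#' @param entries Association entries.
#' @param health_categories Categories to model (default all present).
#' @param min_entries Flavor levels with fewer entries are excluded from
#'   every model (the small-sample exclusion; default 10).
#' @param ... Passed to [fit_gee()].
#' @return Named list of `gee_fit` objects.
#' @export
fit_gee_all <- function(entries, health_categories = NULL, min_entries = 10L,
                        ...) {
  if (is.null(health_categories))
    health_categories <- sort(unique(as.character(entries$health_category)))
  n_per <- table(as.character(entries$flavor_category))
  keep_fl <- names(n_per)[n_per >= min_entries]
  ents <- entries[entries$flavor_category %in% keep_fl, , drop = FALSE]
  fits <- lapply(health_categories, function(h) fit_gee(ents, h, ...))
  names(fits) <- health_categories
  fits
}

#' Flavor-by-health probability matrix (heatmap table)
#'
#' @param fits Named list of `gee_fit` objects (one per health category),
#'   e.g. from [fit_gee_all()].
#' @param flavor_order,health_order Row/column orders; defaults to the
#'   union observed, sorted.
#' @return Numeric matrix (flavor x health) of estimated co-mention
#'   probabilities, `NA` where a combination was excluded.
#' @export
heatmap_table <- function(fits, flavor_order = NULL, health_order = NULL) {
  if (is.null(health_order)) health_order <- names(fits)
  if (is.null(flavor_order))
    flavor_order <- sort(unique(unlist(lapply(fits, `[[`, "flavors"))))
  m <- matrix(NA_real_, length(flavor_order), length(health_order),
              dimnames = list(flavor_order, health_order))
  for (h in health_order) {
    pr <- estimate_probabilities(fits[[h]])
    m[pr$flavor, h] <- pr$probability
  }
  m
}
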
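#' Fit a two-component Gaussian mixture to CLR values
#'
#' The workhorse behind automated thresholding and gating: a univariate
#' two-component Gaussian mixture fitted by EM, with a deterministic
#' quantile-based initialization plus seeded random restarts, keeping the
#' best-likelihood solution. Components are ordered by mean, so component 1
#' is the negative (background) population and component 2 the positive one.
#'
#' Separation between the components is summarized by Ashman's D,
#' `|mu2 - mu1| / sqrt((s1^2 + s2^2)/2)`; D of about 2 or more indicates
#' clear bimodality.
#'
#' The mixture is homoscedastic (one pooled variance). With free variances
#' the maximum-likelihood fit of a skewed background distribution is often a
#' split of the background itself (a narrow core plus a wide tail
#' component), which masks genuinely separated positive populations; forcing
#' a shared variance makes that solution unattractive while leaving real
#' negative/positive splits intact.
#'
#' @param values Numeric vector of normalized (CLR) values for one antibody
#'   in one concentration arm.
#' @param seed Integer seed for the restart draws (no implicit global RNG
#'   state is used or left behind).
#' @param min_n Minimum number of values required (default 50).
#' @param restarts Number of random restarts in addition to the quantile
#'   initialization (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `mixture_fit` list: `means`, `sds`, `weights` (summing to 1),
#'   `assignment` (1 or 2 per value, by maximum posterior), `separation`
#'   (Ashman's D), `positive_fraction` (weight of the upper component),
#'   `loglik`, and the input `values`.
#' @export
fit_population_model <- function(values, seed = 1L, min_n = 50L,
                                 restarts = 10L, max_iter = 200L, tol = 1e-7) {
  values <- as.numeric(values)
  if (length(values) < min_n) {
    stop("insufficient cells for a population fit: ", length(values),
         " values, need at least ", min_n, call. = FALSE)
  }
  s_all <- stats::sd(values)
  if (!is.finite(s_all) || s_all < 1e-12) {
    # degenerate: all values (numerically) identical
    return(structure(list(
      means = c(values[1], values[1]), sds = c(0, 0), weights = c(1, 0),
      assignment = rep(1L, length(values)), separation = 0,
      positive_fraction = 0, loglik = Inf, values = values
    ), class = "mixture_fit"))
  }

  # three deterministic quantile initializations (balanced split, rare upper
  # population, rare lower population) plus seeded random restarts
  qpairs <- list(c(0.25, 0.75), c(0.50, 0.99), c(0.01, 0.50))
  inits <- lapply(qpairs, function(q) {
    list(mu = stats::quantile(values, q, names = FALSE),
         sd = rep(s_all / 2, 2), w = c(0.5, 0.5))
  })
  rng <- local({
    set.seed(seed)
    lapply(seq_len(restarts), function(i) sort(sample(values, 2L)))
  })
  for (i in seq_len(restarts)) {
    inits[[length(inits) + 1L]] <- list(mu = rng[[i]], sd = rep(s_all / 2, 2),
                                        w = c(0.5, 0.5))
  }

  best <- NULL
  for (init in inits) {
    fit <- em_gmm2(values, init$mu, init$sd, init$w, max_iter, tol,
                   sd_floor = s_all * 1e-3)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$mu)
  mu <- best$mu[ord]; sd_ <- best$sd[ord]; w <- best$w[ord]
  post_upper <- best$post[, ord[2L]]
  assignment <- ifelse(post_upper > 0.5, 2L, 1L)
  # Ashman's D from the per-component *empirical* spreads of the assigned
  # values: the shared fitted variance is a fitting device, and it would
  # hide the widening of a heterogeneous (sub-saturated) positive population
  emp_sd <- sd_
  for (k in 1:2) {
    vals_k <- values[assignment == k]
    if (length(vals_k) >= 2L) emp_sd[k] <- max(stats::sd(vals_k), 1e-12)
  }
  sep <- ashman_d(mu, emp_sd)
  structure(list(
    means = mu, sds = sd_, weights = w,
    assignment = assignment,
    separation = sep,
    positive_fraction = w[2L],
    loglik = best$loglik,
    values = values
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component mixture: means %.3f / %.3f, weights %.3f / %.3f, Ashman D %.2f\n",
    x$means[1], x$means[2], x$weights[1], x$weights[2], x$separation))
  invisible(x)
}

# Minimum-misclassification boundary of a 2-component fit: the point between
# the component means where the weighted component densities cross (found
# numerically; midpoint fallback for degenerate fits or tiny components).
mixture_boundary <- function(fit, min_component = 20L) {
  mu <- fit$means; sd_ <- fit$sds; w <- fit$weights
  mid <- mean(mu)
  if (min(table(factor(fit$assignment, levels = 1:2))) < min_component ||
      any(sd_ < 1e-10) || mu[2] - mu[1] < 1e-10) {
    return(mid)
  }
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sd_[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sd_[2], log = TRUE)
  }
  if (sign(f(mu[1])) == sign(f(mu[2]))) return(mid)
  stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root
}

# Ashman's D for ordered component means/sds; 0 if both variances vanish.
ashman_d <- function(mu, sd_) {
  pooled <- sqrt((sd_[1]^2 + sd_[2]^2) / 2)
  if (pooled < 1e-12) return(0)
  abs(mu[2] - mu[1]) / pooled
}

# Plain EM for a univariate 2-component Gaussian mixture.
em_gmm2 <- function(x, mu, sd_, w, max_iter, tol, sd_floor) {
  n <- length(x)
  sd_ <- pmax(sd_, sd_floor)
  ll_old <- -Inf
  post <- matrix(0.5, n, 2L)
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    post <- cbind(d1 / tot, d2 / tot)
    n1 <- sum(post[, 1L]); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(post[, 1L] * x) / n1, sum(post[, 2L] * x) / n2)
    pooled <- sqrt((sum(post[, 1L] * (x - mu[1])^2) +
                      sum(post[, 2L] * (x - mu[2])^2)) / n)
    sd_ <- pmax(c(pooled, pooled), sd_floor)
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd_, w = w, post = post, loglik = ll)
}
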
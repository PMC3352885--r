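#' Taxonomic productivity curve
#'
#' Pairs each year's number of new descriptions `d_t` with the cumulative
#' total described by the end of the previous year, `C_{t-1}`.  Plotted,
#' this is the discovery-rate-versus-progress curve whose x-intercept the
#' productivity estimator extrapolates.
#'
#' @param series a `description_series` (see [description_series()]).
#' @return a tibble with `year`, `c_prev`, `d`, one row per year from the
#'   second onward.
#' @export
productivity_curve <- function(series) {
  check_series(series)
  if (nrow(series) < 2L) stop("series must span at least 2 years",
                              call. = FALSE)
  n <- nrow(series)
  tibble::tibble(year = series$year[-1L],
                 c_prev = series$cumulative[-n],
                 d = series$count[-1L])
}

check_series <- function(series) {
  if (!all(c("year", "count", "cumulative") %in% names(series))) {
    stop("expected a description series with year/count/cumulative columns",
         call. = FALSE)
  }
  invisible(series)
}

#' Locate the onset of the declining phase of a productivity curve
#'
#' Smooths `d` against `c_prev` with a local-linear (tricube-weighted)
#' regression and finds the last point at which the smoothed slope turns
#' from non-negative to negative and then stays negative through the end
#' of the record.  A record whose smoothed slope never ends negative has
#' no declining phase, hence no finite richness extrapolation, and is an
#' error.
#'
#' @param points a [productivity_curve()] tibble.
#' @param span fraction of points in each local fit (default 0.75).
#' @return the 1-based index into `points` where the declining phase
#'   starts (1 if the record declines throughout).
#' @export
detect_negative_slope_start <- function(points, span = 0.75) {
  stopifnot(all(c("c_prev", "d") %in% names(points)))
  if (nrow(points) < 10L) stop("need at least 10 productivity points",
                               call. = FALSE)
  fit <- stats::loess(d ~ c_prev, data = points, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = points)
  dx <- diff(points$c_prev)
  slope <- diff(sm) / ifelse(dx == 0, NA, dx)  # NA where no species added
  ok <- !is.na(slope)
  if (!any(ok) || slope[max(which(ok))] >= 0) {
    stop("no declining phase: smoothed productivity slope is not negative ",
         "at the end of the record", call. = FALSE)
  }
  neg <- slope < 0
  neg[!ok] <- NA
  # last index after which every defined slope is negative
  later_nonneg <- rev(cumsum(rev(!is.na(neg) & !neg)))
  start <- max(which(later_nonneg == 0 & !is.na(neg) & neg)[1], 1L)
  if (is.na(start)) start <- 1L
  # slope[i] spans points i..i+1; declining phase begins at point `start`
  as.integer(start)
}

#' Estimate total richness from the productivity x-intercept
#'
#' Fits ordinary least squares of yearly descriptions `d_t` on the prior
#' cumulative total `C_{t-1}` over the declining phase of the record, and
#' extrapolates to the cumulative total at which productivity reaches
#' zero.  That x-intercept is read as the total species richness, under
#' the strong assumption that description effort is constant.  The 95%
#' interval is a seeded percentile bootstrap over the (C, d) points.
#'
#' @param series a `description_series`.
#' @param start_year first calendar year of the fitting window, or
#'   `"auto"` to locate the declining phase with
#'   [detect_negative_slope_start()].
#' @param span smoothing span passed to the declining-phase detector.
#' @param n_boot bootstrap replicates for the percentile interval.
#' @param seed integer seed for the bootstrap.
#' @return a `richness_estimate` list: `method`, `estimate`, `lower`,
#'   `upper`, `n_points`, `start_year`, plus `below_observed` when the
#'   extrapolation falls short of the already-described total.
#' @export
estimate_richness_productivity <- function(series, start_year = "auto",
                                           span = 0.75, n_boot = 2000,
                                           seed = 1) {
  pts <- productivity_curve(series)
  if (identical(start_year, "auto")) {
    idx <- detect_negative_slope_start(pts, span = span)
    start_year <- pts$year[idx]
  } else {
    if (start_year > max(pts$year)) {
      stop("start_year is after the end of the series", call. = FALSE)
    }
  }
  win <- pts[pts$year >= start_year, ]
  if (nrow(win) < 3L) stop("fewer than 3 points in the fitting window",
                           call. = FALSE)
  x_intercept <- function(df) {
    cf <- stats::coef(stats::lm(d ~ c_prev, data = df))
    if (is.na(cf[2]) || cf[2] >= 0) return(NA_real_)
    unname(-cf[1] / cf[2])
  }
  est <- x_intercept(win)
  if (is.na(est)) {
    stop("productivity regression slope is not negative; ",
         "no finite richness estimate", call. = FALSE)
  }
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      x_intercept(win[sample.int(nrow(win), replace = TRUE), ])
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  observed <- max(series$cumulative)
  below <- est < observed
  if (below) {
    warning("x-intercept estimate (", round(est, 1),
            ") is below the observed richness (", observed, ")",
            call. = FALSE)
  }
  new_richness_estimate(method = "productivity", estimate = est,
                        lower = ci[1], upper = ci[2],
                        n_points = nrow(win), start_year = start_year,
                        below_observed = below)
}

new_richness_estimate <- function(method, estimate, lower = NA_real_,
                                  upper = NA_real_, ...) {
  structure(c(list(method = method, estimate = estimate, lower = lower,
                   upper = upper), list(...)),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Richness estimate [%s]: %.2f", x$method, x$estimate))
  if (!is.na(x$lower)) cat(sprintf(" (95%%: %.2f-%.2f)", x$lower, x$upper))
  cat("\n")
  for (nm in setdiff(names(x), c("method", "estimate", "lower", "upper"))) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Settings for the NHPP discovery model
#'
#' The discovery record is modelled as a non-homogeneous Poisson process:
#' yearly counts `d_t ~ Poisson(N * (F(t+1) - F(t)))` where `N` is the
#' total (described plus undescribed) richness and `F` is a logistic
#' discovery CDF with midpoint `m` and scale `s_c`.  Priors: `N`
#' log-uniform between the observed count and `n_max_factor` times it;
#' `m` normal centred mid-record with sd `midpoint_prior_sd` years; `s_c`
#' half-normal with scale `scale_prior_sd` years.
#'
#' @param n_max_factor cap on `N` as a multiple of the observed count.
#' @param midpoint_prior_sd prior sd of the discovery midpoint (years).
#' @param scale_prior_sd prior scale of the discovery scale (years).
#' @param chains,iter,burn_in MCMC layout: `chains` adaptive random-walk
#'   Metropolis chains of `burn_in + iter` iterations each.
#' @param upper_mass_frac,upper_tail_frac the model declares "no finite
#'   estimate" when more than `upper_mass_frac` of the posterior mass of
#'   `N` lies in the top `upper_tail_frac` of the prior range measured on
#'   the log scale (the scale on which the prior is flat).  With the
#'   defaults the flag trips exactly when the 97.5% credible bound is not
#'   pulled below the geometric midpoint of the prior range — the record
#'   then carries no asymptote information and `N` is bounded only by the
#'   prior cap.
#' @return a list of class `nhpp_config`.
#' @export
nhpp_config <- function(n_max_factor = 50, midpoint_prior_sd = 100,
                        scale_prior_sd = 50, chains = 3, iter = 3000,
                        burn_in = 1500, upper_mass_frac = 0.025,
                        upper_tail_frac = 0.5) {
  stopifnot(n_max_factor > 1, scale_prior_sd > 0, chains >= 2, iter > 0)
  structure(list(n_max_factor = n_max_factor,
                 midpoint_prior_sd = midpoint_prior_sd,
                 scale_prior_sd = scale_prior_sd, chains = chains,
                 iter = iter, burn_in = burn_in,
                 upper_mass_frac = upper_mass_frac,
                 upper_tail_frac = upper_tail_frac),
            class = "nhpp_config")
}

logistic_increment <- function(years, m, s_c) {
  stats::plogis(years + 1, m, s_c) - stats::plogis(years, m, s_c)
}

#' Fit the NHPP discovery model by MCMC
#'
#' Adaptive random-walk Metropolis on `(log N, m, log s_c)`, multiple
#' overdispersed chains, seeded.  Convergence is checked with the
#' split-chain potential-scale-reduction statistic; values above 1.1 on
#' any parameter abort with diagnostics.  A record still far from its
#' discovery asymptote cannot pin down `N`: the posterior then piles up
#' at the prior cap and the result is flagged `no_finite_estimate`
#' (forecasts of near-term descriptions remain valid).
#'
#' @param series a `description_series` with at least one nonzero count
#'   and at least two years.
#' @param config an [nhpp_config()].
#' @param seed integer seed.
#' @return an `nhpp_posterior`: tibble `draws` (`n`, `midpoint`, `scale`,
#'   `chain`), `rhat`, `no_finite_estimate`, `n_bounds`, `last_year`,
#'   `observed`, and the accepted fraction per chain.
#' @export
fit_nhpp_bayes <- function(series, config = nhpp_config(), seed = 1) {
  check_series(series)
  stopifnot(inherits(config, "nhpp_config"))
  if (nrow(series) < 2L || sum(series$count) == 0) {
    stop("degenerate series: need >= 2 years and a nonzero count",
         call. = FALSE)
  }
  years <- series$year
  d <- series$count
  observed <- sum(d)
  n_lo <- observed
  n_hi <- config$n_max_factor * observed
  m0 <- mean(range(years))                     # prior centre: mid-record
  m_init <- stats::weighted.mean(years, d + 1e-9)  # chain starts near peak
  log_post <- function(p) {
    ln <- p[1]; m <- p[2]; ls <- p[3]
    if (ln < log(n_lo) || ln > log(n_hi)) return(-Inf)
    s_c <- exp(ls)
    mu <- exp(ln) * pmax(logistic_increment(years, m, s_c), 1e-300)
    sum(d * log(mu) - mu) +
      stats::dnorm(m, m0, config$midpoint_prior_sd, log = TRUE) +
      stats::dnorm(s_c, 0, config$scale_prior_sd, log = TRUE) + ls
  }
  span <- diff(range(years)) + 1
  withr::with_seed(seed, {
    chains <- lapply(seq_len(config$chains), function(ch) {
      init <- c(stats::runif(1, log(n_lo), log(n_hi)),
                m_init + stats::rnorm(1, 0, span / 10),
                log(stats::runif(1, span / 20, span / 4)))
      run_rwm(log_post, init, config$iter, config$burn_in)
    })
  })
  draws <- do.call(rbind, lapply(seq_along(chains), function(i) {
    x <- chains[[i]]$draws
    tibble::tibble(n = exp(x[, 1]), midpoint = x[, 2], scale = exp(x[, 3]),
                   chain = i)
  }))
  rhat <- c(n = split_rhat(lapply(chains, function(c) c$draws[, 1])),
            midpoint = split_rhat(lapply(chains, function(c) c$draws[, 2])),
            scale = split_rhat(lapply(chains, function(c) c$draws[, 3])))
  if (any(rhat > 1.1)) {
    stop("NHPP chains did not converge (split R-hat: ",
         paste(names(rhat), round(rhat, 3), sep = "=", collapse = ", "),
         "); increase iterations", call. = FALSE)
  }
  tail_lo <- exp(log(n_hi) - config$upper_tail_frac *
                   (log(n_hi) - log(n_lo)))
  no_finite <- mean(draws$n > tail_lo) > config$upper_mass_frac
  structure(list(draws = draws, rhat = rhat,
                 no_finite_estimate = no_finite,
                 n_bounds = c(n_lo, n_hi), last_year = max(years),
                 observed = observed,
                 acceptance = vapply(chains, function(c) c$acceptance,
                                     numeric(1))),
            class = "nhpp_posterior")
}

# Adaptive random-walk Metropolis with joint normal proposals.  Two layers
# of burn-in adaptation: the global step scale is tuned toward ~23%
# acceptance, and the proposal shape is re-estimated from the chain's own
# history so that ridge-shaped posteriors (e.g. the N-midpoint ridge of a
# pre-asymptote record) are traversed along their long axis.
run_rwm <- function(log_post, init, iter, burn_in) {
  d <- length(init)
  p <- init
  lp <- log_post(p)
  if (!is.finite(lp)) stop("non-finite posterior at initial values",
                           call. = FALSE)
  scale <- 0.3
  chol_prop <- diag(c(0.5, 10, 0.3))
  total <- iter + burn_in
  hist_mat <- matrix(NA_real_, total, d)
  out <- matrix(NA_real_, iter, d)
  acc <- 0L
  acc_window <- 0L
  for (i in seq_len(total)) {
    prop <- p + scale * drop(stats::rnorm(d) %*% chol_prop)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      p <- prop
      lp <- lp_prop
      acc_window <- acc_window + 1L
      if (i > burn_in) acc <- acc + 1L
    }
    hist_mat[i, ] <- p
    if (i <= burn_in && i %% 50L == 0L) {
      scale <- scale * exp(0.7 * (acc_window / 50 - 0.234))
      acc_window <- 0L
      if (i >= 400L && i %% 200L == 0L) {
        emp <- stats::cov(hist_mat[seq(i %/% 2, i), , drop = FALSE])
        ch <- tryCatch(chol(emp + diag(1e-8, d)), error = function(e) NULL)
        if (!is.null(ch)) {
          chol_prop <- ch * (2.38 / sqrt(d)) / scale
        }
      }
    }
    if (i > burn_in) out[i - burn_in, ] <- p
  }
  list(draws = out, acceptance = acc / iter)
}

# Split-chain potential scale reduction (each chain halved).
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq_len(n) + n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.nhpp_posterior <- function(x, ...) {
  q <- stats::quantile(x$draws$n, c(0.025, 0.5, 0.975))
  cat("<nhpp_posterior> ", nrow(x$draws), " draws in ",
      length(unique(x$draws$chain)), " chains\n", sep = "")
  cat(sprintf("  N median %.0f (95%%: %.0f-%.0f)%s\n", q[2], q[1], q[3],
              if (x$no_finite_estimate) "  [no finite estimate]" else ""))
  cat("  split R-hat:",
      paste(names(x$rhat), round(x$rhat, 3), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Posterior-predictive forecast of future descriptions
#'
#' Simulates, for every posterior draw, the Poisson number of new species
#' described in each year after the end of the record up to the furthest
#' horizon, and accumulates per draw.  Because each horizon's total is the
#' running sum of the same simulated years, forecasts are monotone in the
#' horizon draw by draw.  Valid even when the posterior carries the
#' `no_finite_estimate` flag: near-term rates are constrained by the
#' recent record even when the asymptote is not.
#'
#' @param posterior an [fit_nhpp_bayes()] result.
#' @param horizon_year one or more calendar years beyond the record.
#' @param seed integer seed for the predictive simulation.
#' @return a list of `richness_estimate`s (one per horizon), each the
#'   posterior-predictive median and 2.5/97.5 percentiles of additional
#'   species described by that horizon; a single object if one horizon.
#' @export
forecast_descriptions <- function(posterior, horizon_year, seed = 1) {
  stopifnot(inherits(posterior, "nhpp_posterior"))
  if (any(horizon_year <= posterior$last_year)) {
    stop("horizon_year must be after the last observed year (",
         posterior$last_year, ")", call. = FALSE)
  }
  horizon_year <- sort(as.integer(horizon_year))
  years <- seq.int(posterior$last_year + 1L, max(horizon_year))
  dr <- posterior$draws
  totals <- withr::with_seed(seed, {
    acc <- matrix(0, nrow(dr), length(horizon_year))
    run <- numeric(nrow(dr))
    j <- 1L
    for (y in years) {
      mu <- dr$n * pmax(logistic_increment(y, dr$midpoint, dr$scale), 0)
      run <- run + stats::rpois(nrow(dr), mu)
      while (j <= length(horizon_year) && horizon_year[j] == y) {
        acc[, j] <- run
        j <- j + 1L
      }
    }
    acc
  })
  ests <- lapply(seq_along(horizon_year), function(j) {
    q <- stats::quantile(totals[, j], c(0.025, 0.5, 0.975), names = FALSE)
    new_richness_estimate(method = "nhpp_forecast", estimate = q[2],
                          lower = q[1], upper = q[3],
                          horizon_year = horizon_year[j],
                          no_finite_estimate = posterior$no_finite_estimate)
  })
  if (length(ests) == 1L) ests[[1]] else ests
}

#' Ratio extrapolation from a well-described reference fauna
#'
#' Multiplies the global-to-regional richness ratio of a reference taxon
#' whose inventory is considered essentially complete (e.g. birds or
#' mammals) by the regional richness of the focal taxon.  The implicit
#' assumption — that the focal taxon's global/regional ratio matches the
#' reference taxon's — is strong, and no interval is attached.
#'
#' @param ref_global,ref_region global and regional species counts of the
#'   reference taxon.
#' @param target_region regional species count of the focal taxon.
#' @return a `richness_estimate` with the point estimate and the
#'   reference `ratio` (also rounded to 2 decimals as `ratio_2dp`, the
#'   conventional reporting precision).
#' @export
extrapolate_from_reference <- function(ref_global, ref_region,
                                       target_region) {
  if (any(c(ref_global, ref_region, target_region) <= 0)) {
    stop("all counts must be positive", call. = FALSE)
  }
  ratio <- ref_global / ref_region
  new_richness_estimate(method = "reference_ratio",
                        estimate = ratio * target_region,
                        ratio = ratio, ratio_2dp = round(ratio, 2))
}
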
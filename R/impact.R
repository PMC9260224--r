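#' Impact-model configuration
#'
#' @param n_sim Number of simulated counterfactual trajectories (>= 100).
#' @param interval_level Credible/predictive interval level in (0, 1).
#' @param alpha Family-wise significance level.
#' @param bonferroni Apply Bonferroni correction across categories when
#'   flagging significance tiers.
#' @param n_starts Deterministic multi-starts for the likelihood optimizer.
#' @param seed Optional integer seed for the predictive draws.
#' @return A list of class `impact_config`.
#' @export
impact_config <- function(n_sim = 1000, interval_level = 0.95, alpha = 0.05,
                          bonferroni = TRUE, n_starts = 5, seed = NULL) {
  n_sim <- check_count(n_sim, "n_sim", min = 100)
  check_prob(alpha, "alpha")
  if (interval_level <= 0 || interval_level >= 1) {
    abort("`interval_level` must lie strictly in (0, 1)")
  }
  structure(list(n_sim = n_sim, interval_level = interval_level,
                 alpha = alpha, bonferroni = bonferroni,
                 n_starts = n_starts, seed = seed),
            class = "impact_config")
}

# Kalman filter for y_t = mu_t + beta * x_t + eps_t, mu_{t+1} = mu_t + eta_t,
# with the static regression coefficient carried in the state vector
# alpha_t = (mu_t, beta) under a (numerically) diffuse initialization, so the
# terminal filtered covariance reflects the joint estimation uncertainty of
# the level and the coefficient. The prediction-error-decomposition
# log-likelihood conditions out the first `n_diffuse` innovations, which only
# serve to initialize the diffuse states.
kalman_local_level <- function(y, x, sigma_obs, sigma_lvl, n_diffuse = 2,
                               kappa = NULL) {
  so2 <- sigma_obs^2 + 1e-14
  sl2 <- sigma_lvl^2
  n <- length(y)
  kappa <- kappa %||% max(1e6 * var(y), 1)
  a1 <- 0; a2 <- 0                      # (level, beta)
  P11 <- kappa; P12 <- 0; P22 <- kappa  # 2x2 covariance, unrolled
  ll <- 0
  pred <- numeric(n)
  for (t in seq_len(n)) {
    P11 <- P11 + sl2
    xt <- x[t]
    pred[t] <- a1 + a2 * xt
    v <- y[t] - pred[t]
    pz1 <- P11 + P12 * xt
    pz2 <- P12 + P22 * xt
    Fv <- pz1 + pz2 * xt + so2
    if (!is.finite(Fv) || Fv <= 0) {   # numerical breakdown: reject point
      ll <- -Inf
      break
    }
    if (t > n_diffuse) {
      ll <- ll - 0.5 * (log(2 * pi) + log(Fv) + v * v / Fv)
    }
    k1 <- pz1 / Fv; k2 <- pz2 / Fv
    a1 <- a1 + k1 * v; a2 <- a2 + k2 * v
    P11 <- max(P11 - k1 * pz1, 0); P12 <- P12 - k1 * pz2
    P22 <- max(P22 - k2 * pz2, 0)
  }
  list(loglik = ll, a_T = c(a1, a2),
       P_T = matrix(c(P11, P12, P12, P22), 2, 2), fitted = pred)
}

#' Construct an impact model fit object directly
#'
#' Mostly useful for closed-form checks and for propagating externally known
#' parameters; [fit_pre_period()] is the estimation route. Parameters set
#' here are treated as exact (no estimation uncertainty) unless `P_mat` /
#' `df_resid` are supplied.
#'
#' @param sigma_obs,sigma_lvl Observation / level innovation SDs (>= 0).
#' @param beta Control-covariate coefficient.
#' @param mu0 Initial level.
#' @param m_T,P_T Terminal filtered level mean and variance.
#' @param P_mat Optional 2x2 terminal covariance of `(level, beta)`;
#'   defaults to `diag(c(P_T, 0))`.
#' @param df_resid Optional residual degrees of freedom; when finite, the
#'   predictive draws integrate over the observation-variance uncertainty.
#' @param loglik Log-likelihood (optional).
#' @param n Pre-period length (optional).
#' @return Object of class `impact_fit`.
#' @export
impact_fit <- function(sigma_obs, sigma_lvl, beta, mu0,
                       m_T = mu0, P_T = 0, P_mat = NULL,
                       df_resid = NA_real_, loglik = NA_real_,
                       n = NA_integer_) {
  structure(
    list(estimable = TRUE, sigma_obs = sigma_obs, sigma_lvl = sigma_lvl,
         beta = beta, mu0 = mu0, m_T = m_T, P_T = P_T,
         P_mat = P_mat %||% diag(c(P_T, 0)), df_resid = df_resid,
         loglik = loglik, n = n, fitted = NULL, reason = NULL),
    class = "impact_fit"
  )
}

#' Fit the pre-period structural time-series model
#'
#' Fits a local-level model with one control covariate,
#' `y_t = mu_t + beta x_t + eps_t`, `mu_{t+1} = mu_t + eta_t`, with
#' `eps ~ N(0, sigma_obs^2)` and `eta ~ N(0, sigma_lvl^2)`, to the pre-period
#' target series `y` using the control series `x` as the covariate. The
#' level and the static coefficient are carried in the state vector under a
#' diffuse initialization, so for given variances the Kalman filter delivers
#' their maximum-likelihood estimates together with their joint filtered
#' covariance; the two innovation variances are estimated by maximizing the
#' prediction-error-decomposition (profile) likelihood on the log scale from
#' `n_starts` deterministic multi-starts, ties broken by highest likelihood
#' then smallest `sigma_lvl`. A single control covariate is the
#' one-regressor limit of the multi-covariate structural models used for
#' this kind of intervention analysis.
#'
#' A constant target series is not estimable; the fit is returned flagged
#' with `estimable = FALSE` and a reason, and downstream steps skip it.
#'
#' @param y,x Numeric pre-period series of equal length >= 5.
#' @param n_starts Number of deterministic optimizer starts.
#' @return Object of class `impact_fit` with elements `sigma_obs`,
#'   `sigma_lvl`, `beta`, `mu0`, terminal filtered state (`m_T`, and the
#'   2x2 `(level, beta)` covariance `P_mat`), residual degrees of freedom
#'   `df_resid`, `loglik` and one-step-ahead `fitted` values.
#' @export
fit_pre_period <- function(y, x, n_starts = 5) {
  if (length(y) != length(x)) abort("`y` and `x` must have equal length")
  if (length(y) < 5) abort("pre-period series must have length >= 5")
  if (any(!is.finite(y)) || any(!is.finite(x))) abort("series must be finite")

  sdy <- sd(y)
  if (sdy == 0) {
    return(structure(list(estimable = FALSE,
                          reason = "constant target series: nothing to fit"),
                     class = "impact_fit"))
  }

  # optimize on series normalized by sd(y): the fit (and everything drawn
  # from it) is then exactly equivariant under a common rescaling of y and x
  ys <- y / sdy
  xs <- x / sdy
  negll <- function(par) {
    k <- kalman_local_level(ys, xs, sigma_obs = exp(par[1]),
                            sigma_lvl = exp(par[2]))
    if (!is.finite(k$loglik)) return(1e10)
    -k$loglik
  }

  # deterministic start grid on the normalized scale
  grid <- list(c(0.5, 0.5), c(0.5, 0.05), c(0.1, 0.5), c(0.1, 0.05), c(1, 0.01))
  grid <- grid[seq_len(min(n_starts, length(grid)))]
  fits <- purrr::map(grid, function(g) {
    optim(log(g), negll, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10))
  })
  lls <- -purrr::map_dbl(fits, "value")
  slvl <- purrr::map_dbl(fits, ~ exp(.x$par[2]))
  best <- order(-lls, slvl)[1]
  par <- fits[[best]]$par

  k <- kalman_local_level(ys, xs, exp(par[1]), exp(par[2]))
  n_cond <- length(y) - 2   # diffuse-conditioned likelihood terms
  structure(
    list(estimable = TRUE,
         sigma_obs = exp(par[1]) * sdy, sigma_lvl = exp(par[2]) * sdy,
         beta = k$a_T[2], mu0 = k$a_T[1] * sdy,
         m_T = k$a_T[1] * sdy, P_T = k$P_T[1, 1] * sdy^2,
         P_mat = k$P_T * matrix(c(sdy^2, sdy, sdy, 1), 2, 2),
         scale = sdy, m_norm = k$a_T, P_norm = k$P_T,
         df_resid = max(length(y) - 3, 3),
         loglik = k$loglik - n_cond * log(sdy),
         n = length(y), fitted = k$fitted * sdy, reason = NULL),
    class = "impact_fit"
  )
}

#' @export
print.impact_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<impact_fit> non-estimable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<impact_fit> n=%d  sigma_obs=%.4g  sigma_lvl=%.4g  beta=%.4g  mu0=%.4g  loglik=%.3f\n",
    x$n, x$sigma_obs, x$sigma_lvl, x$beta, x$mu0, x$loglik))
  invisible(x)
}

#' @export
tidy.impact_fit <- function(x, ...) {
  if (!x$estimable) return(tibble::tibble(term = character(), estimate = double()))
  tibble::tibble(term = c("sigma_obs", "sigma_lvl", "beta", "mu0"),
                 estimate = c(x$sigma_obs, x$sigma_lvl, x$beta, x$mu0))
}

#' @export
glance.impact_fit <- function(x, ...) {
  if (!x$estimable) {
    return(tibble::tibble(estimable = FALSE, logLik = NA_real_, nobs = NA_integer_))
  }
  tibble::tibble(estimable = TRUE, logLik = x$loglik, nobs = x$n,
                 sigma_obs = x$sigma_obs, sigma_lvl = x$sigma_lvl,
                 beta = x$beta)
}

#' Simulate counterfactual post-period trajectories
#'
#' Each draw samples a `(level, beta)` pair from the terminal filtered
#' distribution, propagates the local level with fresh level shocks, adds
#' `beta * x_t`, and adds fresh observation noise — the predictive
#' distribution of the post-period series had the intervention never
#' occurred. When the fit carries residual degrees of freedom, each draw
#' also samples the observation variance from its scaled inverse-chi-square,
#' integrating over its estimation uncertainty; a fit constructed with exact
#' parameters ([impact_fit()] without `df_resid`) uses them as given.
#'
#' @param fit An estimable [impact_fit()].
#' @param x_post Control series over the post period.
#' @param n_sim Number of draws.
#' @param seed Optional seed; a fixed seed gives an identical draw matrix.
#' @return `n_sim x length(x_post)` matrix with attribute
#'   `counterfactual_mean` (per-day mean over draws).
#' @export
predict_counterfactual <- function(fit, x_post, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(fit, "impact_fit"))
  if (!fit$estimable) abort("cannot predict from a non-estimable fit")
  if (any(!is.finite(x_post))) abort("`x_post` must be finite")
  h <- length(x_post)
  # simulate on the fit's normalized scale and rescale, so a common
  # rescaling of target and control maps the draw matrix exactly
  s <- fit$scale %||% 1
  P <- fit$P_norm %||% fit$P_mat %||% diag(c(fit$P_T, 0))
  m <- fit$m_norm %||% c(fit$m_T, fit$beta)
  xn <- x_post / s
  so <- fit$sigma_obs / s
  sl <- fit$sigma_lvl / s
  draws <- with_optional_seed(seed, {
    # joint draw of terminal level and coefficient
    ev <- eigen(P, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    ab <- matrix(rnorm(2 * n_sim), n_sim, 2) %*% rt
    level <- m[1] + ab[, 1]
    beta <- m[2] + ab[, 2]
    sig <- if (is.finite(fit$df_resid %||% NA_real_)) {
      so * sqrt(fit$df_resid / stats::rchisq(n_sim, fit$df_resid))
    } else {
      rep(so, n_sim)
    }
    out <- matrix(0, n_sim, h)
    for (t in seq_len(h)) {
      level <- level + rnorm(n_sim, 0, sl)
      out[, t] <- level + beta * xn[t] + rnorm(n_sim, 0, sig)
    }
    s * out
  })
  attr(draws, "counterfactual_mean") <- colMeans(draws)
  draws
}

#' Summarize the causal effect for one series
#'
#' The relative effect is the cumulative observed-minus-predicted difference
#' over the post period divided by the cumulative counterfactual prediction.
#' Interval endpoints apply the same ratio to the predictive quantiles of the
#' simulated cumulative sums. The p-value is the two-sided tail-area
#' probability: twice the share of draws whose cumulative sum is at least as
#' extreme as the observation on its side, with a +1/+1 correction so it is
#' never exactly zero.
#'
#' @param y_post Observed post-period series.
#' @param trajectories Draw matrix from [predict_counterfactual()].
#' @param config An [impact_config()].
#' @param category,group Labels carried into the output.
#' @return Object of class `impact_result`: `$summary` (one-row tibble) and
#'   `$series` (per-day tibble with observed, predicted, predictive band,
#'   pointwise and cumulative effects).
#' @export
summarize_effect <- function(y_post, trajectories, config = impact_config(),
                             category = NA_character_, group = NA_character_) {
  h <- length(y_post)
  stopifnot(ncol(trajectories) == h)
  cf_mean <- attr(trajectories, "counterfactual_mean") %||% colMeans(trajectories)
  s_obs <- sum(y_post)
  s_cf <- sum(cf_mean)
  if (s_cf <= 0) {
    abort("cumulative counterfactual prediction is nonpositive: empty category")
  }
  rel <- (s_obs - s_cf) / s_cf

  sums <- rowSums(trajectories)
  lvl <- config$interval_level
  qs <- quantile(sums, c((1 - lvl) / 2, (1 + lvl) / 2), names = FALSE)
  ci <- if (qs[1] > 0) {
    c((s_obs - qs[2]) / qs[2], (s_obs - qs[1]) / qs[1])
  } else {
    c(NA_real_, NA_real_)
  }

  n_sim <- nrow(trajectories)
  extreme <- min(sum(sums >= s_obs), sum(sums <= s_obs))
  p <- min(1, 2 * (1 + extreme) / (1 + n_sim))

  pointwise <- y_post - cf_mean
  band <- apply(trajectories, 2, quantile,
                probs = c((1 - lvl) / 2, (1 + lvl) / 2))
  structure(
    list(
      summary = tibble::tibble(
        category = category, group = group,
        relative_effect = rel, ci_lower = ci[1], ci_upper = ci[2],
        p_value = p, n_sim = n_sim
      ),
      series = tibble::tibble(
        day = seq_len(h) - 1L,
        observed = y_post,
        predicted = cf_mean,
        pred_lower = band[1, ],
        pred_upper = band[2, ],
        pointwise = pointwise,
        cumulative = cumsum(pointwise)
      )
    ),
    class = "impact_result"
  )
}

#' @export
print.impact_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<impact_result> %s / %s: relative effect %+.1f%% [%+.1f%%, %+.1f%%], p = %.4g\n",
    s$category, s$group, 100 * s$relative_effect,
    100 * s$ci_lower, 100 * s$ci_upper, s$p_value))
  invisible(x)
}

#' @export
tidy.impact_result <- function(x, ...) x$series

#' @export
glance.impact_result <- function(x, ...) x$summary

#' Estimate the impact for one category series
#'
#' Data-frame-first wrapper: takes a series table with columns
#' `relative_day`, `target` and `control`, splits it at day 0 (pre period =
#' negative days, post period = day 0 onward), fits the pre-period model,
#' simulates the counterfactual and summarizes the effect.
#'
#' @param data Tibble with `relative_day`, `target`, `control`.
#' @param config An [impact_config()].
#' @param category,group Labels carried through.
#' @return An `impact_result`, or a non-estimable `impact_fit` if the
#'   pre-period cannot be fitted.
#' @export
estimate_impact <- function(data, config = impact_config(),
                            category = NA_character_, group = NA_character_) {
  stopifnot(all(c("relative_day", "target", "control") %in% names(data)))
  data <- dplyr::arrange(data, .data$relative_day)
  pre <- data[data$relative_day < 0, ]
  post <- data[data$relative_day >= 0, ]
  fit <- fit_pre_period(pre$target, pre$control, n_starts = config$n_starts)
  if (!fit$estimable) return(fit)
  tr <- predict_counterfactual(fit, post$control, n_sim = config$n_sim,
                               seed = config$seed)
  res <- summarize_effect(post$target, tr, config,
                          category = category, group = group)
  res$fit <- fit
  res
}

#' Run the impact analysis across all categories and groups
#'
#' Applies [estimate_impact()] to every category x group pair of a long
#' series table, then flags each result at the `none` / `0.05` /
#' `bonferroni` tier. The Bonferroni-corrected per-test level is
#' `alpha / n_categories` within each group. Results are sorted by
#' decreasing relative effect. Non-estimable categories are skipped with a
#' message.
#'
#' @param series Long tibble from [build_category_series()]: columns
#'   `category`, `group`, `role`, `relative_day`, `value`.
#' @param config An [impact_config()]. When `config$seed` is set, each
#'   category x group pair receives a deterministic seed derived from it, so
#'   results do not depend on evaluation order.
#' @return Tibble: `category`, `group`, `relative_effect`, `ci_lower`,
#'   `ci_upper`, `p_value`, `significance`, and a `result` list-column of
#'   `impact_result` objects.
#' @export
run_impact <- function(series, config = impact_config()) {
  wide <- series |>
    dplyr::select("category", "group", "role", "relative_day", "value") |>
    tidyr::pivot_wider(names_from = "role", values_from = "value") |>
    dplyr::rename(control = "baseline")
  pairs <- dplyr::distinct(wide, .data$category, .data$group) |>
    dplyr::arrange(.data$category, .data$group)

  results <- purrr::pmap(pairs, function(category, group) {
    dat <- wide[wide$category == category & wide$group == group, ]
    cfg <- config
    if (!is.null(config$seed)) {
      idx <- which(pairs$category == category & pairs$group == group)
      cfg$seed <- (config$seed + 104729L * idx) %% .Machine$integer.max
    }
    res <- tryCatch(
      estimate_impact(dat, cfg, category = category, group = group),
      error = function(e) {
        inform(paste0("skipping ", category, "/", group, ": ", conditionMessage(e)))
        NULL
      })
    if (inherits(res, "impact_fit")) {
      inform(paste0("skipping ", category, "/", group, ": ", res$reason))
      res <- NULL
    }
    res
  })

  keep <- !purrr::map_lgl(results, is.null)
  results <- results[keep]
  if (length(results) == 0) {
    return(tibble::tibble(category = character(), group = character(),
                          relative_effect = double(), ci_lower = double(),
                          ci_upper = double(), p_value = double(),
                          significance = character(), result = list()))
  }
  out <- purrr::map_dfr(results, ~ .x$summary)
  out$result <- results

  out |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      corrected_level = bonferroni_level(config$alpha, dplyr::n_distinct(.data$category)),
      significance = dplyr::case_when(
        config$bonferroni & .data$p_value < .data$corrected_level ~ "bonferroni",
        .data$p_value < config$alpha ~ "0.05",
        TRUE ~ "none"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$relative_effect)) |>
    dplyr::select("category", "group", "relative_effect", "ci_lower",
                  "ci_upper", "p_value", "corrected_level", "significance",
                  "result")
}

#' Bonferroni-corrected per-test level
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_level(0.05, 51)
bonferroni_level <- function(alpha, n_tests) {
  check_prob(alpha, "alpha")
  n_tests <- check_count(n_tests, "n_tests", min = 1)
  alpha / n_tests
}

#' Plot an impact result
#'
#' Three stacked panels in the style standard for intervention analysis:
#' observed vs. counterfactual series with its predictive band, the
#' pointwise (observed minus predicted) effect, and the cumulative effect.
#'
#' @param object An `impact_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impact_result <- function(object, ...) {
  s <- object$series
  panels <- dplyr::bind_rows(
    tibble::tibble(day = s$day, panel = "original", observed = s$observed,
                   line = s$predicted, lower = s$pred_lower,
                   upper = s$pred_upper),
    tibble::tibble(day = s$day, panel = "pointwise", observed = NA_real_,
                   line = s$pointwise, lower = NA_real_, upper = NA_real_),
    tibble::tibble(day = s$day, panel = "cumulative", observed = NA_real_,
                   line = s$cumulative, lower = NA_real_, upper = NA_real_)
  ) |>
    dplyr::mutate(panel = factor(.data$panel,
                                 levels = c("original", "pointwise", "cumulative")))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50", linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "days since engagement (day 0)", y = NULL,
      title = paste0(object$summary$category, " / ", object$summary$group),
      subtitle = sprintf("relative effect %+.1f%% [%+.1f%%, %+.1f%%], p = %.3g",
                         100 * object$summary$relative_effect,
                         100 * object$summary$ci_lower,
                         100 * object$summary$ci_upper,
                         object$summary$p_value)
    ) +
    ggplot2::theme_minimal()
}
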
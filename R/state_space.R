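# Hierarchical state-space smoother for a panel of positive status ratios.
#
# Model (on the log-ratio scale):
#   x_t = x_{t-1} + eta_t,          eta_t ~ N(0, sigma_proc^2)   shared trend
#   a_s ~ N(0, sigma_stock^2)                                    stock offsets
#   y_{s,t} = x_t + a_s + eps_{s,t}, eps ~ N(0, sigma_obs^2)     observations
#
# The offsets are static, so the model is handled exactly by a Kalman filter
# over the augmented state (x_t, a_1, ..., a_S): the random walk receives
# process noise, the offsets none. Observations in a year are absorbed in one
# block update, which keeps the per-year cost at a single Cholesky of the
# n_t x n_t innovation covariance. The marginal likelihood from the
# prediction-error decomposition is exact, which is what the brute-force
# multivariate-normal oracle in the tests checks.

# --- filtering / smoothing core ---------------------------------------------

# obs: list over years, each NULL or list(idx = stock indices, y = log values)
# Returns loglik, and filtered/predicted moments when smooth = TRUE.
ss_kfilter <- function(obs, n_stock_states, sp2, ss2, so2, x0_var, smooth = FALSE) {
  d <- 1L + n_stock_states
  T_len <- length(obs)
  m <- rep(0, d)
  P <- diag(c(x0_var, rep(ss2, n_stock_states)), nrow = d)
  ll <- 0
  if (smooth) {
    m_pred <- matrix(NA_real_, d, T_len); P_pred <- array(NA_real_, c(d, d, T_len))
    m_filt <- matrix(NA_real_, d, T_len); P_filt <- array(NA_real_, c(d, d, T_len))
  }
  for (t in seq_len(T_len)) {
    if (t > 1L) P[1L, 1L] <- P[1L, 1L] + sp2
    if (smooth) { m_pred[, t] <- m; P_pred[, , t] <- P }
    ob <- obs[[t]]
    if (!is.null(ob) && length(ob$idx) > 0L) {
      nt <- length(ob$idx)
      has_off <- ob$idx > 0L             # idx 0 = observation of x_t alone
      idx <- 1L + ob$idx
      # H rows are e_1 (+ e_idx for offset-bearing observations)
      HP <- matrix(P[1L, ], nrow = nt, ncol = d, byrow = TRUE)
      if (any(has_off)) {
        HP[has_off, ] <- HP[has_off, ] + P[idx[has_off], , drop = FALSE]
      }
      S <- matrix(HP[, 1L], nrow = nt, ncol = nt)      # HP %*% t(H), e_1 part
      if (any(has_off)) {
        S[, has_off] <- S[, has_off] + HP[, idx[has_off], drop = FALSE]
      }
      diag(S) <- diag(S) + so2
      pred_y <- m[1L] + ifelse(has_off, m[idx], 0)
      v <- ob$y - pred_y
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(list(loglik = -Inf))  # numerically indefinite
      z <- backsolve(ch, v, transpose = TRUE)
      ll <- ll - 0.5 * (nt * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
      K <- t(HP) %*% chol2inv(ch)                      # d x nt
      m <- m + drop(K %*% v)
      P <- P - K %*% HP
      P <- (P + t(P)) / 2
    }
    if (smooth) { m_filt[, t] <- m; P_filt[, , t] <- P }
  }
  if (!smooth) return(list(loglik = ll))
  list(loglik = ll, m_pred = m_pred, P_pred = P_pred,
       m_filt = m_filt, P_filt = P_filt)
}

# Rauch-Tung-Striebel smoother over the augmented state (transition = identity
# apart from process noise on the first component).
ss_ksmooth <- function(kf) {
  d <- nrow(kf$m_filt); T_len <- ncol(kf$m_filt)
  m_s <- kf$m_filt; P_s <- kf$P_filt
  if (T_len > 1L) {
    for (t in (T_len - 1L):1L) {
      G <- kf$P_filt[, , t] %*% solve(kf$P_pred[, , t + 1L])
      m_s[, t] <- kf$m_filt[, t] + drop(G %*% (m_s[, t + 1L] - kf$m_pred[, t + 1L]))
      P_s[, , t] <- kf$P_filt[, , t] +
        G %*% (P_s[, , t + 1L] - kf$P_pred[, , t + 1L]) %*% t(G)
      P_s[, , t] <- (P_s[, , t] + t(P_s[, , t])) / 2
    }
  }
  list(mean = m_s, var = P_s)
}

# Shared data preparation: log-scale observations indexed by year.
ss_prepare <- function(data, window = NULL) {
  stopifnot(is.data.frame(data),
            all(c("stock_id", "year", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  nonpos <- data$value <= 0
  if (any(nonpos)) {
    warning(sprintf("dropping %d non-positive ratio values before log transform",
                    sum(nonpos)), call. = FALSE)
    data <- data[!nonpos, , drop = FALSE]
  }
  if (is.null(window)) window <- range(data$year)
  years <- seq(window[1], window[2])
  data <- data[data$year >= window[1] & data$year <= window[2], , drop = FALSE]
  if (nrow(data) == 0L) stop("no observations within the window", call. = FALSE)
  stocks <- sort(unique(data$stock_id))
  sidx <- match(data$stock_id, stocks)
  tidx <- match(data$year, years)
  obs <- vector("list", length(years))
  logy <- log(data$value)
  mu0 <- mean(logy)   # prior centre of the initial state; see fit_ss() docs
  logy <- logy - mu0
  for (k in which(tabulate(tidx, length(years)) > 0L)) {
    sel <- tidx == k
    obs[[k]] <- list(idx = sidx[sel], y = logy[sel])
  }
  list(obs = obs, years = years, stocks = stocks, mu0 = mu0,
       n_obs_year = vapply(obs, function(o) if (is.null(o)) 0L else length(o$idx),
                           integer(1)))
}

#' Marginal log-likelihood of the hierarchical state-space model
#'
#' Evaluates, by Kalman filtering with block year updates, the exact marginal
#' likelihood of the panel of log ratios under the shared random-walk model
#' with static stock offsets (offsets and latent states integrated out).
#' Intended both as the objective maximised by [fit_ss()] and as a direct
#' check against brute-force multivariate-normal computation on small
#' instances.
#'
#' @param data data frame with columns `stock_id`, `year`, `value`
#'   (ratio scale, positive; logs are taken internally)
#' @param sigma_proc,sigma_stock,sigma_obs standard deviations of the
#'   process innovations, stock offsets, and observation errors (log scale)
#' @param window integer length-2 year range of the latent trajectory
#'   (default: data range)
#' @param x0_var prior variance of the initial latent state (log scale); the
#'   prior mean is the grand mean of the log observations, so the default
#'   variance of 10 is effectively diffuse for status ratios while keeping
#'   the filter well conditioned
#' @return log-likelihood (scalar)
#' @export
ss_marginal_loglik <- function(data, sigma_proc, sigma_stock, sigma_obs,
                               window = NULL, x0_var = 10) {
  prep <- ss_prepare(data, window)
  if (sigma_stock == 0) {
    obs <- lapply(prep$obs, function(o) {
      if (is.null(o)) NULL else list(idx = rep(0L, length(o$y)), y = o$y)
    })
    n_states <- 0L
  } else {
    obs <- prep$obs
    n_states <- length(prep$stocks)
  }
  ss_kfilter(obs, n_states, sigma_proc^2, sigma_stock^2, sigma_obs^2,
             x0_var, smooth = FALSE)$loglik
}

#' Fit the hierarchical state-space smoother
#'
#' Maximises the marginal likelihood over (sigma_proc, sigma_stock,
#' sigma_obs) — bounded quasi-Newton (L-BFGS-B) on log standard deviations
#' from three fixed starting points — then runs the Kalman smoother at the
#' optimum. The smoothed shared trajectory E\[x_t | all data\] and its
#' variance are defined for every year of the window, including years with
#' no observations (bridged by the random walk).
#'
#' @inheritParams ss_marginal_loglik
#' @param sigma_stock `NULL` to estimate the offset SD (the default), or a
#'   fixed non-negative value; `0` collapses the model to a univariate
#'   random-walk-plus-noise smoother on the pooled observations
#' @param starts optional matrix of starting values (rows; columns are log
#'   SDs of the estimated parameters)
#' @param control passed to [stats::optim()] (L-BFGS-B)
#' @return object of class `ss_fit`: list with `theta` (named SDs),
#'   `loglik`, `convergence` diagnostics, `smoothed` (tibble `year`,
#'   `mean_log`, `var_log`, `n_obs`), `offsets` (posterior stock-offset
#'   means), `stocks`, `window`, `x0_var`
#' @export
#' @examples
#' d <- data.frame(stock_id = rep(c("a", "b"), each = 8),
#'                 year = rep(2001:2008, 2),
#'                 value = exp(rnorm(16, 0, 0.1)))
#' fit <- fit_ss(d)
#' fit$theta
fit_ss <- function(data, window = NULL, sigma_stock = NULL, x0_var = 10,
                   starts = NULL, control = list()) {
  prep <- ss_prepare(data, window)
  n_stocks_data <- length(prep$stocks)
  n_years_obs <- sum(prep$n_obs_year > 0L)
  fixed_stock <- !is.null(sigma_stock)
  if (!fixed_stock && n_stocks_data < 2L) {
    stop("need >= 2 stocks to estimate the stock-offset SD; pass `sigma_stock` to fix it",
         call. = FALSE)
  }
  if (n_years_obs < 3L) stop("need observations in >= 3 years", call. = FALSE)

  drop_offsets <- fixed_stock && sigma_stock == 0
  if (drop_offsets) {
    obs <- lapply(prep$obs, function(o) {
      if (is.null(o)) NULL else list(idx = rep(0L, length(o$y)), y = o$y)
    })
    n_states <- 0L
  } else {
    obs <- prep$obs
    n_states <- n_stocks_data
  }

  nll <- function(logsd) {
    sds <- exp(logsd)
    ss <- if (fixed_stock) sigma_stock else sds[2]
    so <- sds[length(sds)]
    val <- -ss_kfilter(obs, n_states, sds[1]^2, ss^2, so^2, x0_var)$loglik
    if (!is.finite(val)) 1e10 else val  # penalty where chol breaks down
  }

  if (is.null(starts)) {
    starts <- if (fixed_stock) {
      rbind(log(c(0.05, 0.20)), log(c(0.20, 0.50)), log(c(0.01, 0.08)))
    } else {
      rbind(log(c(0.05, 0.30, 0.20)),
            log(c(0.20, 0.10, 0.50)),
            log(c(0.02, 0.60, 0.08)))
    }
  }
  lower <- rep(log(1e-4), ncol(starts))
  upper <- rep(log(10), ncol(starts))
  ctrl <- utils::modifyList(list(factr = 4.5e7, maxit = 200), control)

  best <- NULL
  msgs <- character(0)
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B",
            lower = lower, upper = upper, control = ctrl),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e), par = starts[i, ])
    )
    msgs <- c(msgs, sprintf("start %d: value=%.6g convergence=%d", i,
                            opt$value, opt$convergence))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) {
    stop(paste(c("state-space fit failed from every start:", msgs),
               collapse = "\n  "), call. = FALSE)
  }
  converged <- best$convergence == 0L
  if (!converged) {
    warning("state-space optimiser did not report convergence; returning best-so-far fit",
            call. = FALSE)
  }

  sds <- exp(best$par)
  theta <- c(
    sigma_proc = sds[1],
    sigma_stock = if (fixed_stock) sigma_stock else sds[2],
    sigma_obs = sds[length(sds)]
  )
  at_lower <- exp(best$par) <= exp(lower) * (1 + 1e-8)
  if (any(at_lower)) {
    warning("variance estimate(s) at the lower bound (near-degenerate input?)",
            call. = FALSE)
  }

  kf <- ss_kfilter(obs, n_states, theta[["sigma_proc"]]^2,
                   theta[["sigma_stock"]]^2, theta[["sigma_obs"]]^2,
                   x0_var, smooth = TRUE)
  sm <- ss_ksmooth(kf)
  smoothed <- tibble::tibble(
    year = prep$years,
    mean_log = sm$mean[1L, ] + prep$mu0,
    var_log = pmax(sm$var[1L, 1L, ], 0),
    n_obs = prep$n_obs_year
  )
  offsets <- if (n_states > 0L) {
    stats::setNames(sm$mean[-1L, ncol(sm$mean)], prep$stocks)
  } else {
    stats::setNames(rep(0, n_stocks_data), prep$stocks)
  }

  structure(list(
    theta = theta, loglik = -best$value,
    convergence = list(converged = converged, code = best$convergence,
                       restarts = nrow(starts), log = msgs),
    smoothed = smoothed, offsets = offsets, stocks = prep$stocks,
    window = range(prep$years), x0_var = x0_var
  ), class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> %d stocks, years %d-%d, loglik %.3f\n",
              length(x$stocks), x$window[1], x$window[2], x$loglik))
  cat(sprintf("  sigma_proc=%.4g sigma_stock=%.4g sigma_obs=%.4g%s\n",
              x$theta[["sigma_proc"]], x$theta[["sigma_stock"]],
              x$theta[["sigma_obs"]],
              if (x$convergence$converged) "" else " (not converged)"))
  invisible(x)
}

#' Smoothed global trajectory on the ratio scale
#'
#' Back-transforms the smoothed log-scale trajectory of a fitted model to
#' the ratio scale: estimate `exp(m + v/2)` (lognormal mean correction) with
#' delta-method standard error `exp(m + v/2) * sqrt(v)`. The returned years
#' are exactly the fitted window, including years with no observations.
#'
#' @param model an `ss_fit` from [fit_ss()]
#' @return tibble with columns `year`, `estimate`, `se`, `n_stocks`
#' @export
ss_smoother_trajectory <- function(model) {
  if (!inherits(model, "ss_fit")) stop("`model` must be a fitted `ss_fit`", call. = FALSE)
  m <- model$smoothed$mean_log
  v <- model$smoothed$var_log
  est <- exp(m + v / 2)
  tibble::tibble(year = model$smoothed$year,
                 estimate = est,
                 se = est * sqrt(v),
                 n_stocks = model$smoothed$n_obs)
}

#' Export a fitted state-space model summary as JSON
#' @param model an `ss_fit`
#' @param path output path
#' @return invisibly, `path`
#' @export
ss_export_json <- function(model, path) {
  stopifnot(inherits(model, "ss_fit"))
  jsonlite::write_json(list(
    theta = as.list(model$theta),
    loglik = model$loglik,
    convergence = model$convergence[c("converged", "code", "restarts")],
    window = model$window,
    smoothed = model$smoothed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
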
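#' Build right-censored survival records from tracks and aggregate calls
#'
#' Converts death-annotated tracks into one survival record per analyzable
#' neuron: a death at interval `k` becomes an observed event at
#' `k * interval_hours`; a censored track contributes
#' `n_timepoints * interval_hours` with no event. Tracks lacking a
#' timepoint-1 ROI or (when calls are supplied) without a usable CV are
#' excluded and logged with a reason, never silently dropped.
#'
#' @param deaths Per-track table from [call_death()].
#' @param calls Optional per-track classification from
#'   [classify_neurons()]; adds the `aggregated` covariate.
#' @param group Group label for these tracks (scalar) or one label per row
#'   of `deaths`.
#' @param n_timepoints Total number of imaging timepoints.
#' @param interval_hours Hours between timepoints (default 24).
#' @return List with `records` (data frame: `track_id`, `group`, `time`
#'   in hours, `event` logical, and `aggregated` when calls are given) and
#'   `exclusions` (data frame: `track_id`, `reason`).
#' @export
build_records <- function(deaths, calls = NULL, group,
                          n_timepoints, interval_hours = 24) {
  stopifnot(is.data.frame(deaths), n_timepoints >= 1, interval_hours > 0)
  group <- rep_len(as.character(group), nrow(deaths))
  excl <- list()
  keep <- rep(TRUE, nrow(deaths))
  agg <- rep(NA, nrow(deaths))
  if (!is.null(calls)) {
    m <- match(deaths$track_id, calls$track_id)
    agg <- calls$aggregated[m]
  }
  for (k in seq_len(nrow(deaths))) {
    if (!isTRUE(deaths$has_t1[k])) {
      keep[k] <- FALSE
      excl[[length(excl) + 1L]] <- data.frame(
        track_id = deaths$track_id[k], reason = "no timepoint-1 ROI")
    } else if (!is.null(calls) && is.na(agg[k])) {
      keep[k] <- FALSE
      excl[[length(excl) + 1L]] <- data.frame(
        track_id = deaths$track_id[k], reason = "no usable CV")
    }
  }
  d <- deaths[keep, ]
  records <- data.frame(
    track_id = d$track_id,
    group = group[keep],
    time = ifelse(is.na(d$death_interval),
                  n_timepoints * interval_hours,
                  d$death_interval * interval_hours),
    event = !is.na(d$death_interval))
  if (!is.null(calls)) records$aggregated <- agg[keep]
  rownames(records) <- NULL
  list(records = records,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(track_id = integer(0), reason = character(0)))
}

#' Kaplan-Meier estimate of survival and cumulative risk of death
#'
#' Product-limit estimator over the distinct event times, with the
#' cumulative risk of death reported as `1 - S(t)`.
#'
#' @param time Numeric vector of death/censoring times (hours).
#' @param event Logical vector: `TRUE` if the death was observed.
#' @return Object of class `km_estimate`: data frame `table` with one row
#'   per distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `cumrisk`), plus `n`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(is.numeric(time), length(time) >= 1L,
            length(event) == length(time), all(time >= 0))
  event <- as.logical(event)
  ts <- sort(unique(time))
  n <- length(time)
  surv <- 1
  rows <- vector("list", length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    n_risk <- sum(time >= t)
    n_event <- sum(time == t & event)
    n_censor <- sum(time == t & !event)
    if (n_event > 0L) surv <- surv * (1 - n_event / n_risk)
    rows[[k]] <- data.frame(time = t, n_risk = n_risk, n_event = n_event,
                            n_censor = n_censor, surv = surv,
                            cumrisk = 1 - surv)
  }
  structure(list(table = do.call(rbind, rows), n = n),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate, n =", x$n, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Log partial likelihood, score and observed information of the Cox model,
# with Efron or Breslow handling of tied event times. Ties are pervasive in
# this assay because deaths land on the 24 h imaging grid. Returns the three
# quantities at once for the Newton-Raphson loop.
cox_derivatives <- function(beta, time, event, X, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event]))) {
    risk <- time >= t
    dead <- time == t & event
    dj <- sum(dead)
    s0r <- sum(w[risk])
    s1r <- colSums(X[risk, , drop = FALSE] * w[risk])
    s2r <- crossprod(X[risk, , drop = FALSE] * sqrt(w[risk]))
    if (ties == "efron" && dj > 1L) {
      s0d <- sum(w[dead])
      s1d <- colSums(X[dead, , drop = FALSE] * w[dead])
      s2d <- crossprod(X[dead, , drop = FALSE] * sqrt(w[dead]))
    } else {
      s0d <- 0; s1d <- numeric(p); s2d <- matrix(0, p, p)
    }
    loglik <- loglik + sum(eta[dead])
    score <- score + colSums(X[dead, , drop = FALSE])
    for (l in seq_len(dj) - 1L) {
      f <- l / dj
      phi <- s0r - f * s0d
      psi <- s1r - f * s1d
      xi <- s2r - f * s2d
      loglik <- loglik - log(phi)
      score <- score - psi / phi
      info <- info + xi / phi - tcrossprod(psi / phi)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox log partial likelihood with the Efron correction for
#' tied event times (the default of the standard R survival machinery, and
#' material here because deaths are observed on a 24 h grid) by
#' Newton-Raphson from `beta = 0`. Convergence is declared when the
#' maximal absolute score falls below `tol_score` or the step norm below
#' `tol_step`; the covariance estimate is the inverse observed information
#' at the optimum. A covariate that perfectly separates events drives the
#' likelihood monotone; this is detected and raised as a non-convergence
#' error rather than returning a divergent estimate.
#'
#' @param time Numeric event/censoring times.
#' @param event Logical event indicator (`TRUE` = death observed).
#' @param X Numeric covariate matrix (one column per covariate; column
#'   names become coefficient names).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol_score,tol_step Convergence tolerances.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return Object of class `cox_fit`: coefficients `coef`, covariance
#'   `var`, standard errors `se`, hazard ratios `hr` with 95% normal-theory
#'   confidence limits `hr_lower`/`hr_upper`, log partial likelihoods
#'   `loglik` (at the optimum) and `loglik_null` (at 0), per-coefficient
#'   Wald `z` and `p`, the likelihood-ratio statistic against the null
#'   model, iteration count and tie method.
#' @export
cox_ph <- function(time, event, X, ties = c("efron", "breslow"),
                   tol_score = 1e-8, tol_step = 1e-10, max_iter = 30L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  event <- as.logical(event)
  stopifnot(length(time) == nrow(X), length(event) == nrow(X))
  if (!any(event)) stop("cannot fit a Cox model with no observed events")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(X)$rank < ncol(X)) stop("covariates are collinear")
  p <- ncol(X)
  beta <- numeric(p)
  d0 <- cox_derivatives(beta, time, event, X, ties)
  loglik_null <- d0$loglik
  d <- d0
  converged <- FALSE
  iter <- 0L
  repeat {
    if (max(abs(d$score)) < tol_score) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(d$info, d$score), error = function(e)
      stop("information matrix is singular (monotone likelihood or ",
           "collinear covariates): fit flagged as non-convergent"))
    # step-halve if the partial likelihood would decrease
    for (h in 0:5) {
      cand <- beta + step / 2^h
      dc <- cox_derivatives(cand, time, event, X, ties)
      if (dc$loglik >= d$loglik - 1e-12) break
    }
    if (sqrt(sum((cand - beta)^2)) < tol_step) {
      beta <- cand; d <- dc; converged <- TRUE; break
    }
    beta <- cand
    d <- dc
    if (max(abs(beta)) > 20) {
      stop("coefficient diverging (|beta| > 20): a covariate appears to ",
           "perfectly separate events (monotone likelihood)")
    }
  }
  if (!converged) {
    stop("Newton-Raphson failed to converge in ", max_iter, " iterations")
  }
  var <- solve(d$info)
  se <- sqrt(diag(var))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  zq <- qnorm(0.975)
  structure(list(coef = beta, var = var, se = se,
                 hr = exp(beta),
                 hr_lower = exp(beta - zq * se),
                 hr_upper = exp(beta + zq * se),
                 loglik = d$loglik, loglik_null = loglik_null,
                 wald_z = z, wald_p = 2 * pnorm(-abs(z)),
                 lr_stat = 2 * (d$loglik - loglik_null),
                 lr_df = p,
                 lr_p = pchisq(2 * (d$loglik - loglik_null), p,
                               lower.tail = FALSE),
                 n = length(time), n_event = sum(event),
                 iter = iter, converged = converged, ties = ties,
                 terms = colnames(X)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  tab <- data.frame(coef = x$coef, se = x$se, HR = x$hr,
                    lower95 = x$hr_lower, upper95 = x$hr_upper,
                    z = x$wald_z, p = signif(x$wald_p, 3))
  print(tab)
  cat(sprintf("Likelihood ratio test: %.3f on %d df, p = %.3g\n",
              x$lr_stat, x$lr_df, x$lr_p))
  invisible(x)
}

#' Fit a Cox model to survival records
#'
#' Builds the covariate matrix from a record table: factor-like covariates
#' (such as `group`) are expanded into 0/1 indicators against an explicit
#' reference level; logical covariates (such as `aggregated`) enter as a
#' single 0/1 column. Aggregate status is treated as a static baseline
#' covariate; see the package vignette for the immortal-time caveat.
#'
#' @param records Record data frame from [build_records()] (columns
#'   `time`, `event`, plus the covariates).
#' @param covariates Character vector of record columns to include.
#' @param reference Named character vector of reference levels for
#'   factor-like covariates; defaults to the first level encountered.
#' @param ... Passed to [cox_ph()].
#' @return A `cox_fit` (see [cox_ph()]).
#' @export
cox_fit <- function(records, covariates = "group", reference = NULL, ...) {
  stopifnot(all(c("time", "event") %in% names(records)),
            all(covariates %in% names(records)))
  cols <- list()
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.logical(v)) {
      cols[[cv]] <- as.numeric(v)
    } else if (is.numeric(v)) {
      cols[[cv]] <- v
    } else {
      v <- as.character(v)
      lev <- unique(v)
      ref <- if (!is.null(reference) && cv %in% names(reference)) {
        reference[[cv]]
      } else {
        lev[1]
      }
      if (!ref %in% lev) stop("unknown reference level '", ref,
                              "' for covariate ", cv)
      for (l in setdiff(lev, ref)) {
        cols[[paste0(cv, "=", l)]] <- as.numeric(v == l)
      }
    }
  }
  if (length(cols) == 0L) stop("no covariate columns produced")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  cox_ph(records$time, records$event, X, ...)
}

#' Wald tests of a Cox fit
#'
#' Two-sided normal-theory test of each coefficient: `z = coef / se`,
#' `p = 2 * pnorm(-|z|)`.
#'
#' @param fit A `cox_fit`.
#' @return Data frame with `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  data.frame(term = fit$terms, estimate = unname(fit$coef),
             se = unname(fit$se), z = unname(fit$wald_z),
             p = unname(fit$wald_p), row.names = NULL)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' The statistic is twice the difference in log partial likelihood,
#' referred to a chi-square distribution on the difference in the number
#' of coefficients. If `fit_null` is omitted, the full fit is tested
#' against the empty (beta = 0) model. The null model's terms must be a
#' subset of the full model's terms and both fits must use the same data.
#'
#' @param fit_full,fit_null `cox_fit` objects.
#' @return List with `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_null = NULL) {
  stopifnot(inherits(fit_full, "cox_fit"))
  if (is.null(fit_null)) {
    return(list(statistic = fit_full$lr_stat, df = fit_full$lr_df,
                p = fit_full$lr_p))
  }
  stopifnot(inherits(fit_null, "cox_fit"))
  if (!all(fit_null$terms %in% fit_full$terms)) {
    stop("models are not nested: null terms are not a subset of full terms")
  }
  if (fit_null$n != fit_full$n || fit_null$n_event != fit_full$n_event) {
    stop("models are not fitted to the same data")
  }
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  df <- length(fit_full$terms) - length(fit_null$terms)
  p <- if (df == 0L) {
    if (abs(stat) < 1e-8) 1 else 0
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}
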
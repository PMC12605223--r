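# Survival mathematics: Weibull evaluation, medians, proportional-hazard
# transforms, per-cycle transition probabilities, and maximum-likelihood
# fitting of five parametric families with AIC/BIC selection.

#' Weibull survival function
#'
#' Evaluates `S(t) = exp(-scale * t^shape)` at times `t` (months).
#'
#' @param p A [weibull_params()] object.
#' @param t Numeric vector of non-negative times in months.
#' @return Survival probabilities in `[0, 1]`.
#' @export
weibull_survival <- function(p, t) {
  if (any(t < 0)) stop("domain error: t must be >= 0", call. = FALSE)
  exp(-p$scale * t^p$shape)
}

#' Weibull median survival time
#'
#' Closed form `(log(2) / scale)^(1/shape)`, in months.
#'
#' @param p A [weibull_params()] object.
#' @return Median survival time in months.
#' @export
weibull_median <- function(p) (log(2) / p$scale)^(1 / p$shape)

# Mean of the cumulative-hazard Weibull: scale^(-1/shape) * gamma(1 + 1/shape)
weibull_mean <- function(p) p$scale^(-1 / p$shape) * gamma(1 + 1 / p$shape)

#' Apply a proportional hazard ratio to a Weibull law
#'
#' Under proportional hazards a Weibull keeps its shape and multiplies its
#' scale: the transformed curve satisfies `S'(t) = S(t)^hr` pointwise.
#'
#' @param p A [weibull_params()] object.
#' @param hr Positive hazard ratio.
#' @return A [weibull_params()] with `scale * hr` and unchanged shape.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (!is.numeric(hr) || hr <= 0)
    stop("domain error: hr must be positive", call. = FALSE)
  weibull_params(p$scale * hr, p$shape)
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the state during cycle `k` conditional on being
#' in it at the start: `1 - S(k u) / S((k-1) u)` for cycle length `u`
#' months. If the conditioning survival has been exhausted numerically the
#' transition is treated as certain.
#'
#' @param p A [weibull_params()] object.
#' @param k Cycle index (>= 1); vectorised.
#' @param u Cycle length in months (> 0).
#' @return Transition probabilities in `[0, 1]`.
#' @export
cycle_transition_prob <- function(p, k, u) {
  if (any(k < 1)) stop("domain error: k must be >= 1", call. = FALSE)
  if (u <= 0) stop("domain error: u must be > 0", call. = FALSE)
  s_prev <- weibull_survival(p, (k - 1) * u)
  s_now <- weibull_survival(p, k * u)
  out <- ifelse(s_prev == 0, 1, 1 - s_now / s_prev)
  pmin(pmax(out, 0), 1)
}

# ---- five-family parametric toolkit ----------------------------------------
#
# Parameterizations (t in months):
#   exponential:  S = exp(-rate t)
#   weibull:      S = exp(-scale t^shape)               (cumulative-hazard form)
#   lognormal:    S = 1 - Phi((log t - meanlog)/sdlog)
#   loglogistic:  S = 1 / (1 + (t/alpha)^beta)
#   gompertz:     S = exp(-(b/c)(exp(c t) - 1)), c may be negative

surv_families <- function() c("exponential", "weibull", "lognormal",
                              "loglogistic", "gompertz")

#' Parametric survival curve
#'
#' Container for one fitted or specified curve from the five-family menu.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`.
#' @param params Named numeric vector of family parameters.
#' @return An object of class `survival_curve` with an `$sf(t)` evaluator.
#' @export
survival_curve <- function(family, params) {
  family <- match.arg(family, surv_families())
  params <- check_family_params(family, params)
  obj <- list(family = family, params = params)
  obj$sf <- function(t) eval_survival(family, params, t)
  structure(obj, class = "survival_curve")
}

check_family_params <- function(family, params) {
  want <- switch(family,
    exponential = "rate", weibull = c("scale", "shape"),
    lognormal = c("meanlog", "sdlog"), loglogistic = c("alpha", "beta"),
    gompertz = c("b", "c"))
  if (is.null(names(params)) && length(params) == length(want))
    names(params) <- want
  if (!all(want %in% names(params)))
    stop(sprintf("family '%s' needs parameters %s", family,
                 paste(want, collapse = ", ")), call. = FALSE)
  params <- params[want]
  pos <- setdiff(want, "c")   # gompertz c may be negative
  if (any(params[pos] <= 0))
    stop("range error: family parameters must be positive", call. = FALSE)
  params
}

eval_survival <- function(family, p, t) {
  if (any(t < 0)) stop("domain error: t must be >= 0", call. = FALSE)
  switch(family,
    exponential = exp(-p[["rate"]] * t),
    weibull = exp(-p[["scale"]] * t^p[["shape"]]),
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                              lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p[["alpha"]])^p[["beta"]]),
    gompertz = {
      b <- p[["b"]]; cc <- p[["c"]]
      if (abs(cc) < 1e-12) exp(-b * t) else exp(-(b / cc) * (exp(cc * t) - 1))
    })
}

eval_log_density <- function(family, p, t) {
  # log f = log h + log S; hazards in closed form per family
  logS <- log(pmax(eval_survival(family, p, t), 1e-300))
  logh <- switch(family,
    exponential = log(p[["rate"]]) + 0 * t,
    weibull = log(p[["scale"]]) + log(p[["shape"]]) +
      (p[["shape"]] - 1) * log(t),
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE) -
      logS,
    loglogistic = {
      a <- p[["alpha"]]; b <- p[["beta"]]
      log(b) - log(a) + (b - 1) * (log(t) - log(a)) -
        log1p((t / a)^b)
    },
    gompertz = log(p[["b"]]) + p[["c"]] * t)
  logh + logS
}

n_free_params <- function(family) if (family == "exponential") 1L else 2L

# map between the natural parameter space and an unconstrained one
to_unconstrained <- function(family, p) {
  switch(family,
    gompertz = c(log(p[["b"]]), p[["c"]]),
    lognormal = c(p[["meanlog"]], log(p[["sdlog"]])),
    log(p))
}
from_unconstrained <- function(family, x) {
  want <- names(check_family_params(family,
    switch(family, exponential = c(rate = 1),
           weibull = c(scale = 1, shape = 1),
           lognormal = c(meanlog = 1, sdlog = 1),
           loglogistic = c(alpha = 1, beta = 1),
           gompertz = c(b = 1, c = 0.1))))
  p <- if (family == "gompertz") c(exp(x[1L]), max(min(x[2L], 1), -1)) else
    exp(x)
  names(p) <- want
  if (family == "lognormal") p[["meanlog"]] <- x[1L]  # meanlog unconstrained
  p
}

#' Fit one parametric family to pseudo individual-patient data
#'
#' Maximum-likelihood estimation under right censoring, optimised on a
#' transformed (unconstrained) parameter scale from three starting points
#' to guard against local optima.
#'
#' @param ipd A [pseudo_ipd()] object or a `data.frame` with columns
#'   `time` (months, > 0) and `event` (1 = event, 0 = censored).
#' @param family One of the five supported families.
#' @return An object of class `fit_result`: `curve` ([survival_curve()]),
#'   `loglik`, `aic`, `bic`, `n_obs`, `converged`.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  d <- as.data.frame(ipd)
  if (nrow(d) < 10L) stop("need >= 10 observations", call. = FALSE)
  if (sum(d$event) < 1L) stop("need >= 1 event", call. = FALSE)
  t <- d$time; ev <- d$event
  nll <- function(x) {
    p <- from_unconstrained(family, x)
    ll <- sum(ev * eval_log_density(family, p, t) +
                (1 - ev) * log(pmax(eval_survival(family, p, t), 1e-300)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- fit_starts(family, t, ev)
  best <- NULL
  for (s in starts) {
    x0 <- to_unconstrained(family, s)
    opt <- tryCatch(
      if (length(x0) == 1L) {
        stats::optim(x0, nll, method = "Brent", lower = -25, upper = 10)
      } else {
        stats::optim(x0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) {
    return(structure(list(curve = NULL, loglik = NA_real_, aic = NA_real_,
                          bic = NA_real_, n_obs = nrow(d), converged = FALSE,
                          family = family,
                          diagnostics = "all optimisation starts failed"),
                     class = "fit_result"))
  }
  p <- from_unconstrained(family, best$par)
  k <- n_free_params(family)
  ll <- -best$value
  structure(list(curve = survival_curve(family, p), loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(nrow(d)) - 2 * ll,
                 n_obs = nrow(d), converged = best$convergence == 0,
                 family = family, diagnostics = NULL),
            class = "fit_result")
}

# moment-flavoured starting values, jittered for the multi-start
fit_starts <- function(family, t, ev) {
  tbar <- mean(t[ev == 1]); if (!is.finite(tbar) || tbar <= 0) tbar <- mean(t)
  base <- switch(family,
    exponential = c(rate = 1 / tbar),
    weibull = c(scale = log(2) / stats::median(t)^1, shape = 1),
    lognormal = c(meanlog = mean(log(t)), sdlog = stats::sd(log(t))),
    loglogistic = c(alpha = stats::median(t), beta = 1.5),
    gompertz = c(b = 1 / tbar, c = 0.01))
  mult <- list(1, 0.5, 2)
  lapply(mult, function(m) {
    s <- base
    idx <- names(s) != "c" & names(s) != "meanlog"
    s[idx] <- s[idx] * m
    s
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): loglik %.2f, AIC %.2f, BIC %.2f%s\n",
              x$family, x$n_obs, x$loglik, x$aic, x$bic,
              if (isTRUE(x$converged)) "" else "  [not converged]"))
  if (!is.null(x$curve))
    cat("  params:", paste(sprintf("%s = %.6g", names(x$curve$params),
                                   x$curve$params), collapse = ", "), "\n")
  invisible(x)
}

#' Fit all five families and select the best by information criteria
#'
#' Fits every family, ranks by AIC (ties broken by BIC, then by fewer
#' parameters) and returns the winner with the full ranking attached.
#'
#' @inheritParams fit_parametric
#' @param families Candidate families; defaults to all five.
#' @return The winning `fit_result`, with attribute `ranking`: a
#'   `data.frame` (family, loglik, aic, bic, converged) sorted best-first.
#' @export
select_best_family <- function(ipd, families = surv_families()) {
  fits <- lapply(families, function(f)
    tryCatch(fit_parametric(ipd, f), error = function(e)
      structure(list(curve = NULL, loglik = NA_real_, aic = NA_real_,
                     bic = NA_real_, n_obs = NA_integer_, converged = FALSE,
                     family = f, diagnostics = conditionMessage(e)),
                class = "fit_result")))
  ok <- vapply(fits, function(f) is.finite(f$aic), logical(1L))
  if (!any(ok)) {
    msgs <- vapply(fits, function(f) paste0(f$family, ": ",
                                            f$diagnostics %||% "failed"),
                   character(1L))
    stop("all parametric fits failed\n", paste(msgs, collapse = "\n"),
         call. = FALSE)
  }
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1L), "family"),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic"),
    n_params = vapply(fits, function(f) n_free_params(f$family), integer(1L)),
    converged = vapply(fits, `[[`, logical(1L), "converged"))
  ord <- order(tab$aic, tab$bic, tab$n_params)
  best <- fits[[ord[1L]]]
  attr(best, "ranking") <- tab[ord, , drop = FALSE]
  best
}

#' Export a model-selection table to CSV
#'
#' @param fit A `fit_result` from [select_best_family()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path) {
  tab <- attr(fit, "ranking")
  if (is.null(tab)) stop("fit has no ranking table", call. = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
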
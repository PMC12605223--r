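# Synthetic pseudo individual-patient data: Weibull event/censoring
# generation, Kaplan-Meier estimation, emulated curve digitization and
# Guyot-style interval reconstruction of patient-level records.

#' Pseudo individual-patient data container
#'
#' @param time Positive event/censoring times in months.
#' @param event 1 = event, 0 = censored.
#' @param arm_label,endpoint_label Optional provenance labels.
#' @param seed Seed the records were generated under, if any.
#' @return An object of class `pseudo_ipd` (a `data.frame`).
#' @export
pseudo_ipd <- function(time, event, arm_label = NA_character_,
                       endpoint_label = NA_character_, seed = NA_integer_) {
  if (any(time <= 0)) stop("range error: times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("range error: event flags must be 0/1", call. = FALSE)
  out <- data.frame(time = time, event = event)
  class(out) <- c("pseudo_ipd", "data.frame")
  attr(out, "arm_label") <- arm_label
  attr(out, "endpoint_label") <- endpoint_label
  attr(out, "seed") <- seed
  out
}

#' Generate pseudo individual-patient survival data
#'
#' Event times are drawn from the Weibull law by inverse-CDF
#' (`T = (-log(U)/scale)^(1/shape)`); each subject is additionally exposed,
#' with probability `censor_rate`, to an independent uniform censoring time
#' on `[0, max_followup_months]`, and everyone is administratively censored
#' at `max_followup_months`.
#'
#' @param p A [weibull_params()] object.
#' @param n Number of subjects (>= 1).
#' @param censor_rate Probability of carrying a random censoring time, in
#'   `[0, 1)`.
#' @param max_followup_months Administrative censoring horizon (may be
#'   `Inf`).
#' @param seed RNG seed; identical seeds give identical records.
#' @param arm_label,endpoint_label Provenance labels.
#' @return A [pseudo_ipd()].
#' @export
generate_ipd <- function(p, n, censor_rate = 0, max_followup_months = Inf,
                         seed = 1L, arm_label = NA_character_,
                         endpoint_label = NA_character_) {
  stopifnot(n >= 1L, censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  tev <- (-log(stats::runif(n)) / p$scale)^(1 / p$shape)
  cens <- rep(Inf, n)
  has_c <- stats::runif(n) < censor_rate
  if (any(has_c) && is.finite(max_followup_months))
    cens[has_c] <- stats::runif(sum(has_c), 0, max_followup_months)
  tobs <- pmin(tev, cens, max_followup_months)
  event <- as.integer(tev <= pmin(cens, max_followup_months))
  tobs <- pmax(tobs, .Machine$double.eps)
  pseudo_ipd(tobs, event, arm_label, endpoint_label, seed)
}

#' Kaplan-Meier estimate of a pseudo-IPD sample
#'
#' Product-limit step function via [survival::survfit()], returned as an
#' ordered `(t, s)` curve with optional numbers-at-risk at landmark times.
#'
#' @param ipd A [pseudo_ipd()].
#' @param landmarks Optional numeric vector of landmark times (months) at
#'   which to tabulate numbers at risk.
#' @return An object of class `digitized_curve`: `data.frame` with columns
#'   `t`, `s` (starting at `(0, 1)`); attribute `risk_table` is a
#'   `data.frame(time, n_risk)` when `landmarks` is given.
#' @export
km_estimate <- function(ipd, landmarks = NULL) {
  d <- as.data.frame(ipd)
  if (sum(d$event) < 1L) stop("need >= 1 event for a KM estimate",
                              call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  out <- data.frame(t = c(0, fit$time), s = c(1, fit$surv))
  class(out) <- c("digitized_curve", "data.frame")
  if (!is.null(landmarks)) {
    sm <- summary(fit, times = landmarks, extend = TRUE)
    attr(out, "risk_table") <- data.frame(time = sm$time, n_risk = sm$n.risk)
  }
  out
}

#' Emulate digitization of a survival curve
#'
#' Resamples a step curve on a uniform time grid and perturbs the survival
#' axis with Gaussian measurement noise, then clamps to `[0, 1]` and
#' restores monotonicity by a running minimum -- mimicking manual
#' extraction of published Kaplan-Meier figures.
#'
#' @param curve A `digitized_curve` (or `data.frame` with `t`, `s`).
#' @param grid_points Number of uniform grid points (default 100).
#' @param jitter_sd Standard deviation of the survival-axis noise
#'   (>= 0; 0 reproduces the step function exactly on the grid).
#' @param seed RNG seed.
#' @return A `digitized_curve` on the uniform grid; any `risk_table`
#'   attribute of the input is carried over.
#' @export
digitize_emulate <- function(curve, grid_points = 100L, jitter_sd = 0,
                             seed = 1L) {
  stopifnot(jitter_sd >= 0)
  grid <- seq(0, max(curve$t), length.out = grid_points)
  s <- stats::approx(curve$t, curve$s, xout = grid, method = "constant",
                     f = 0, rule = 2)$y
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, jitter_sd)
  }
  s[1L] <- 1
  s <- cummin(pmin(pmax(s, 0), 1))
  out <- data.frame(t = grid, s = s)
  class(out) <- c("digitized_curve", "data.frame")
  attr(out, "risk_table") <- attr(curve, "risk_table")
  out
}

#' Reconstruct pseudo-IPD from a digitized curve and a risk table
#'
#' Interval accounting in the style of Guyot et al.: within each landmark
#' interval the number censored is chosen (iteratively) so that the
#' implied risk set matches the published number at risk at the next
#' landmark; events at each digitized step are then read off the
#' product-limit drops, and one pseudo-record is emitted per inferred
#' patient. Inconsistent counts (negative inferred events) are repaired by
#' truncation with a warning.
#'
#' @param curve A `digitized_curve` with non-increasing `s`.
#' @param risk_table `data.frame(time, n_risk)` covering the curve's time
#'   span; defaults to the curve's own `risk_table` attribute.
#' @return A [pseudo_ipd()] of inferred event/censoring records.
#' @export
ipd_reconstruct <- function(curve, risk_table = attr(curve, "risk_table")) {
  if (is.null(risk_table))
    stop("missing key: risk_table (none supplied, none attached to curve)",
         call. = FALSE)
  if (is.unsorted(-curve$s)) {
    if (any(diff(curve$s) > 1e-9))
      stop("range error: curve survival must be non-increasing",
           call. = FALSE)
    curve$s <- cummin(curve$s)
  }
  tt <- curve$t; ss <- curve$s
  lt <- risk_table$time; ln <- risk_table$n_risk
  n_int <- length(lt)
  # index of the first digitized point at/after each landmark
  lower <- vapply(lt, function(x) which(tt >= x - 1e-9)[1L], integer(1L))
  upper <- c(lower[-1L] - 1L, length(tt))

  times <- numeric(0); events <- integer(0)
  n_now <- ln[1L]
  km_prev <- 1
  s_prev <- 1
  carry <- 0
  repaired <- FALSE
  for (i in seq_len(n_int)) {
    if (is.na(lower[i]) || lower[i] > upper[i]) next
    idx <- lower[i]:upper[i]
    target <- if (i < n_int) ln[i + 1L] else 0L
    # choose the interval censor count so the risk set hits the target
    nc <- max(0L, n_now - target -
                round(n_now * (1 - ss[upper[i]] / max(s_prev, 1e-12))))
    for (iter in 1:25) {
      res <- walk_interval(tt, ss, idx, n_now, nc, km_prev, s_prev, carry)
      gap <- res$n_end - target
      if (gap == 0L || i == n_int) break
      nc <- max(0L, nc + gap)
      if (nc > n_now) { nc <- n_now; break }
    }
    res <- walk_interval(tt, ss, idx, n_now, nc, km_prev, s_prev, carry)
    repaired <- repaired || res$repaired
    times <- c(times, res$times); events <- c(events, res$events)
    n_now <- res$n_end
    km_prev <- res$km_end
    carry <- res$carry
    s_prev <- ss[upper[i]]
    if (n_now <= 0L) break
  }
  # anyone still at risk after the last landmark interval: administratively
  # censored at the end of follow-up
  if (n_now > 0L) {
    times <- c(times, rep(max(tt), n_now))
    events <- c(events, rep(0L, n_now))
  }
  if (repaired)
    warning("inconsistent counts repaired by truncation during reconstruction")
  keep <- times > 0
  pseudo_ipd(pmax(times[keep], .Machine$double.eps), events[keep])
}

# process one landmark interval: events from KM drops, nc censorings spread
# evenly across the interval's digitized steps. A drop observed at point k
# covers events that happened since the previous digitized point, so event
# times are placed at the midpoint of that gap; fractional events are
# carried forward rather than rounded per step to conserve totals.
walk_interval <- function(tt, ss, idx, n_start, nc, km_prev, s_prev,
                          carry_in = 0) {
  J <- length(idx)
  cens_per_step <- if (J > 0L && nc > 0L) {
    base <- nc %/% J
    extra <- nc %% J
    base + as.integer(seq_len(J) <= extra)
  } else rep(0L, J)
  n <- n_start
  km <- km_prev
  carry <- carry_in
  times <- numeric(0); events <- integer(0)
  repaired <- FALSE
  for (j in seq_len(J)) {
    k <- idx[j]
    d_exact <- if (km > 0 && n > 0) n * (1 - ss[k] / km) else 0
    if (d_exact < 0) {
      # discretisation slack of up to one event is expected; anything
      # larger marks a genuinely inconsistent curve
      if (d_exact < -1) repaired <- TRUE
      d_exact <- 0
    }
    d <- floor(d_exact + carry + 1e-9)
    carry <- carry + d_exact - d
    d <- min(d, n)
    if (d > 0) {
      t_prev <- if (k > 1L) tt[k - 1L] else 0
      t_ev <- if (tt[k] > t_prev) (t_prev + tt[k]) / 2 else tt[k]
      times <- c(times, rep(t_ev, d)); events <- c(events, rep(1L, d))
      km <- km * (1 - d / n)
      n <- n - d
    }
    cj <- min(cens_per_step[j], n)
    if (cj > 0) {
      ct <- if (j < J) (tt[k] + tt[idx[j + 1L]]) / 2 else tt[k]
      times <- c(times, rep(max(ct, 1e-9), cj))
      events <- c(events, rep(0L, cj))
      n <- n - cj
    }
  }
  list(times = times, events = events, n_end = n, km_end = km,
       carry = carry, repaired = repaired)
}

#' Write pseudo-IPD or a digitized curve to CSV
#'
#' @param x A `pseudo_ipd` or `digitized_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ipd_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Default synthetic cohort sizes
#'
#' Arm sizes mirroring the trial: back-computed from the published
#' subsequent-therapy counts (42 of 29.4% treated, 57 of 78.1% placebo).
#'
#' @return Named integer vector with elements `osimertinib` and `placebo`.
#' @export
default_cohort_sizes <- function() {
  c(osimertinib = round(42 / 0.294), placebo = round(57 / 0.781))
}
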
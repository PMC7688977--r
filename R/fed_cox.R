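# Federated Cox proportional hazards with Breslow's method for ties.
#
# The Breslow partial log-likelihood over a global grid of distinct event
# times t_1 < ... < t_K decomposes into per-site, per-event-time sums:
#   d_k   events at t_k,          s_k   covariate sum over those events,
#   S0_k  sum_{i: t_i >= t_k} w_i,            w_i = exp(beta' z_i),
#   S1_k  sum z_i w_i,            S2_k  sum z_i z_i' w_i,
# all additive across sites. The server iterates Newton-Raphson on the
# summed statistics:
#   ll(b) = sum_k [ b's_k - d_k log S0_k ]
#   U(b)  = sum_k [ s_k - d_k S1_k/S0_k ]
#   I(b)  = sum_k d_k [ S2_k/S0_k - (S1_k/S0_k)(S1_k/S0_k)' ]
# Only these aggregates ever cross the site boundary.

#' Build the federation-wide grid of distinct event times
#'
#' One round-trip asking each site for its distinct event times (one-decimal
#' years); the grid is their sorted union. Sharing the global grid is needed
#' by the decomposed algorithm and is documented as a (mild) privacy
#' consideration.
#'
#' @param fed A `federation`.
#' @return Object of class `event_grid`: list with `times` (numeric, sorted,
#'   unique) and `K`.
#' @export
build_event_grid <- function(fed) {
  res <- fed_submit(fed, "event_times")
  tg <- sort(unique(unlist(lapply(res, `[[`, "aggregate"))))
  if (length(tg) == 0)
    stopf("no events anywhere in the federation: model not estimable")
  structure(list(times = tg / 10, K = length(tg), deci = as.integer(tg)),
            class = "event_grid")
}

#' Per-site Breslow aggregates at a coefficient vector
#'
#' Computes, for every grid time (including times where this site had no
#' event or even nobody at risk, which contribute zeros), the site's event
#' count `d`, event covariate sum `s`, and risk-set sums `S0`, `S1`, `S2`
#' at the current `beta`. These are the only quantities a site ever
#' returns during model fitting; their dimensions depend only on the model
#' size `p` and grid size `K`.
#'
#' @param time,event Follow-up (one-decimal years) and 0/1 event indicator.
#' @param X Design matrix (rows aligned with `time`).
#' @param grid Integer deci-year grid (from [build_event_grid()]`$deci`) or
#'   numeric times.
#' @param beta Coefficient vector, length `ncol(X)`.
#' @return Object of class `cox_aggregates`: list `d` (K), `s` (K x p),
#'   `S0` (K), `S1` (K x p), `S2` (K x p x p), plus `p`, `K`.
#' @export
cox_local_aggregates <- function(time, event, X, grid, beta) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(beta) != p) stopf("beta has length %d, expected %d", length(beta), p)
  g <- if (inherits(grid, "event_grid")) grid$deci else
    if (is.double(grid)) deci(grid) else as.integer(grid)
  K <- length(g)
  n <- nrow(X)
  lp <- drop(X %*% beta)
  w <- exp(lp)
  if (any(!is.finite(w)))
    stopf("non-finite exp(linear predictor); max |lp| = %.3g", max(abs(lp)))
  ti <- deci(time)

  d <- integer(K)
  s <- matrix(0, K, p)
  evi <- which(event == 1)
  if (length(evi)) {
    gi <- match(ti[evi], g)
    if (anyNA(gi))
      stopf("site has an event time absent from the shared grid")
    d <- tabulate(gi, nbins = K)
    sm <- rowsum(X[evi, , drop = FALSE] * 1, group = gi)
    s[as.integer(rownames(sm)), ] <- sm
  }

  S0 <- numeric(K); S1 <- matrix(0, K, p); S2 <- array(0, c(K, p, p))
  if (n > 0) {
    ord <- order(ti)
    tis <- ti[ord]; Xs <- X[ord, , drop = FALSE]; ws <- w[ord]
    # suffix sums: entry i holds the sum over rows i..n (times >= tis[i])
    sfx <- function(m) {
      m <- apply(m[n:1, , drop = FALSE], 2, cumsum)
      matrix(m, ncol = ncol(m))[n:1, , drop = FALSE]
    }
    cw <- rev(cumsum(rev(ws)))
    C1 <- sfx(Xs * ws)
    pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    C2 <- sfx(Xs[, pr[, 1], drop = FALSE] * Xs[, pr[, 2], drop = FALSE] * ws)
    # first row with time >= g_k (integer times: count of times <= g_k - 1)
    idx <- findInterval(g - 1L, tis) + 1L
    inset <- idx <= n
    S0[inset] <- cw[idx[inset]]
    S1[inset, ] <- C1[idx[inset], , drop = FALSE]
    P2 <- matrix(0, K, nrow(pr))
    P2[inset, ] <- C2[idx[inset], , drop = FALSE]
    for (m in seq_len(nrow(pr))) {
      i <- pr[m, 1]; j <- pr[m, 2]
      S2[, i, j] <- P2[, m]
      S2[, j, i] <- P2[, m]
    }
  }
  structure(list(d = d, s = s, S0 = S0, S1 = S1, S2 = S2, p = p, K = K),
            class = "cox_aggregates")
}

#' Sum per-site aggregates element-wise
#'
#' Breslow sums are additive across sites; the server combines them with a
#' plain element-wise sum.
#'
#' @param aggs List of `cox_aggregates` from different sites (same grid and
#'   model).
#' @return A single `cox_aggregates`.
#' @export
sum_aggregates <- function(aggs) {
  stopifnot(length(aggs) >= 1)
  out <- aggs[[1]]
  for (a in aggs[-1]) {
    stopifnot(a$p == out$p, a$K == out$K)
    out$d <- out$d + a$d; out$s <- out$s + a$s
    out$S0 <- out$S0 + a$S0; out$S1 <- out$S1 + a$S1; out$S2 <- out$S2 + a$S2
  }
  out
}

#' Breslow partial log-likelihood from summed aggregates
#'
#' `ll(beta) = sum_k [ beta' s_k - d_k log S0_k ]`.
#'
#' @param agg Summed `cox_aggregates` evaluated at `beta`.
#' @param beta Coefficient vector the aggregates were computed at.
#' @return Scalar log partial likelihood.
#' @export
partial_loglik <- function(agg, beta) {
  ev <- agg$d > 0
  if (any(ev & agg$S0 <= 0))
    stopf("impossible state: events at a grid time with an empty risk set")
  drop(crossprod(colSums(agg$s), beta)) - sum(agg$d[ev] * log(agg$S0[ev]))
}

#' One Newton-Raphson update from summed aggregates
#'
#' Computes the Breslow-tie score `U`, observed information `I` and the
#' update `beta + solve(I, U)`.
#'
#' @param agg Summed `cox_aggregates` evaluated at `beta`.
#' @param beta Current coefficient vector.
#' @return List `beta` (updated), `gradient`, `information`.
#' @export
newton_step <- function(agg, beta) {
  ev <- which(agg$d > 0)
  if (any(agg$S0[ev] <= 0))
    stopf("impossible state: events at a grid time with an empty risk set")
  p <- agg$p
  r <- agg$S1[ev, , drop = FALSE] / agg$S0[ev]
  dk <- agg$d[ev]
  U <- colSums(agg$s[ev, , drop = FALSE]) - colSums(dk * r)
  w2 <- dk / agg$S0[ev]
  A <- apply(agg$S2[ev, , , drop = FALSE] * w2, c(2, 3), sum)
  I <- A - crossprod(r * sqrt(dk))
  I <- (I + t(I)) / 2
  ch <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(ch)) {
    qi <- qr(I)
    bad <- if (qi$rank < p) qi$pivot[(qi$rank + 1L):p] else seq_len(p)
    stopf("singular information matrix; near-collinear column(s): %s",
          paste(colnames(agg$s)[bad] %||% bad, collapse = ", "))
  }
  step <- backsolve(ch, forwardsolve(t(ch), U))
  list(beta = beta + step, gradient = U, information = I)
}

#' Control parameters for the federated Cox fit
#'
#' @param tol Convergence tolerance (default `1e-8`).
#' @param criterion `"hr_sum"` stops when the absolute change in
#'   `sum(exp(beta))` between iterations is below `tol` (the stopping rule
#'   on the sums of successive hazard-ratio estimates); `"max_delta"` stops
#'   on `max |beta_new - beta_old| < tol`. The two agree at a stationary
#'   point.
#' @param max_iter Maximum Newton iterations (default 50).
#' @param center Centre design columns at their federated means before
#'   iterating (one extra column-sums round); estimates, information and
#'   likelihood are invariant to this, it only improves conditioning.
#' @param error_on_nonconvergence Error (default) or return a fit flagged
#'   `converged = FALSE` after `max_iter`.
#' @return List of control values.
#' @export
fed_cox_control <- function(tol = 1e-8, criterion = c("hr_sum", "max_delta"),
                            max_iter = 50L, center = TRUE,
                            error_on_nonconvergence = TRUE) {
  list(tol = tol, criterion = match.arg(criterion),
       max_iter = as.integer(max_iter), center = center,
       error_on_nonconvergence = error_on_nonconvergence)
}

#' Fit a Cox proportional-hazards model across a federation
#'
#' Server-side Newton-Raphson from `beta = 0` on per-site Breslow
#' aggregates: each iteration sends the current coefficients to every node,
#' sums the returned per-event-time statistics, and applies one Newton
#' update, until the stopping rule (see [fed_cox_control()]) is met. The
#' covariance is the inverse observed information at the final estimate,
#' recomputed in a final aggregate round.
#'
#' @param fed A `federation` of cohort tables.
#' @param spec A `fedsurv_spec`.
#' @param control See [fed_cox_control()].
#' @return Object of class `fed_cox_fit`: coefficients, covariance,
#'   log-likelihood at the estimate and at zero, iteration trace, event grid
#'   and column labels.
#' @examples
#' cfg <- sim_config(n = c(NL = 150, TW = 250), seed = 1)
#' fed <- federation(generate_cohorts(cfg))
#' fit <- fit_federated_cox(fed, univariable_specs("sex")$sex)
#' hazard_ratios(fit)
#' @export
fit_federated_cox <- function(fed, spec, control = fed_cox_control()) {
  stopifnot(inherits(fed, "federation"), inherits(spec, "fedsurv_spec"))
  labels <- spec_columns(spec)
  p <- length(labels)

  center <- NULL
  n_total <- NA_real_
  cs <- fed_submit(fed, "design_column_sums", payload = list(spec = spec))
  n_total <- sum(vapply(cs, function(r) r$aggregate$n, 0))
  if (isTRUE(control$center)) {
    center <- Reduce(`+`, lapply(cs, function(r) r$aggregate$colsum)) / n_total
  }

  grid <- build_event_grid(fed)
  ask <- function(beta) {
    res <- fed_submit(fed, "cox_aggregates",
                      payload = list(spec = spec, beta = beta,
                                     grid = grid$deci, center = center))
    agg <- sum_aggregates(lapply(res, `[[`, "aggregate"))
    colnames(agg$s) <- labels
    agg
  }

  beta <- numeric(p)
  ll0 <- NA_real_
  trace <- list()
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    agg <- ask(beta)
    ll <- partial_loglik(agg, beta)
    if (iter == 1L) ll0 <- ll
    st <- newton_step(agg, beta)
    crit <- switch(control$criterion,
                   hr_sum = abs(sum(exp(st$beta)) - sum(exp(beta))),
                   max_delta = max(abs(st$beta - beta)))
    trace[[iter]] <- data.frame(iter = iter, loglik = ll, criterion = crit,
                                max_abs_gradient = max(abs(st$gradient)))
    beta <- st$beta
    if (crit < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  trace <- do.call(rbind, trace)
  if (!converged && isTRUE(control$error_on_nonconvergence)) {
    cond <- simpleError(sprintf(
      "federated Cox did not converge in %d iterations (last criterion %.3g)",
      control$max_iter, trace$criterion[nrow(trace)]))
    cond$trace <- trace
    stop(cond)
  }

  # exact likelihood, score and information at the final estimate
  agg <- ask(beta)
  st <- newton_step(agg, beta)
  ll <- partial_loglik(agg, beta)
  V <- chol2inv(chol(st$information))
  dimnames(V) <- list(labels, labels)
  names(beta) <- labels

  structure(list(coefficients = beta, var = V, loglik = ll,
                 loglik_null = ll0, iterations = iter, converged = converged,
                 trace = trace, labels = labels, spec = spec,
                 grid = grid, n = n_total, nevent = sum(agg$d),
                 gradient = st$gradient, means = center,
                 sites = names(fed$nodes)),
            class = "fed_cox_fit")
}

#' @export
coef.fed_cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.fed_cox_fit <- function(object, ...) object$var

#' @export
logLik.fed_cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.fed_cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Federated Cox model (Breslow ties): %d sites, n = %d, %d events\n",
    length(x$sites), as.integer(x$n), as.integer(x$nevent)))
  cat(sprintf("  %d coefficients, %d Newton iterations, %s\n",
              length(x$coefficients), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  se <- sqrt(diag(x$var))
  z <- x$coefficients / se
  tab <- data.frame(coef = x$coefficients, HR = exp(x$coefficients),
                    se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, digits))
  cat(sprintf("Log partial likelihood: %.4f (null %.4f)\n",
              x$loglik, x$loglik_null))
  invisible(x)
}

#' Hazard-ratio table with Wald confidence intervals
#'
#' `HR = exp(beta)` with `exp(beta -/+ z * SE)` limits. Reference levels are
#' included as rows with `HR = 1` and no interval, mirroring the layout of
#' published per-factor tables.
#'
#' @param fit A converged `fed_cox_fit`.
#' @param level Confidence level (default 0.95).
#' @param reference_rows Include reference-level rows.
#' @return Data frame `(variable, level, reference, coef, se, hr, lo, hi)`;
#'   interaction columns appear as their own rows with `variable` set to the
#'   interaction label.
#' @export
hazard_ratios <- function(fit, level = 0.95, reference_rows = TRUE) {
  stopifnot(inherits(fit, "fed_cox_fit"))
  if (!fit$converged)
    stopf("refusing to tabulate hazard ratios from a non-converged fit")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$var))
  rows <- list()
  add <- function(variable, lvl, ref, b, s) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = lvl, reference = ref,
      coef = b, se = s, hr = exp(b),
      lo = if (ref) NA_real_ else exp(b - z * s),
      hi = if (ref) NA_real_ else exp(b + z * s),
      stringsAsFactors = FALSE)
  }
  for (b in fit$spec$blocks) {
    for (lvl in b$levels) {
      if (lvl == b$ref) add(b$variable, lvl, TRUE, 0, 0)
      else {
        lab <- paste0(b$variable, "=", lvl)
        add(b$variable, lvl, FALSE, fit$coefficients[[lab]], se[[lab]])
      }
    }
  }
  for (ia in fit$spec$interactions) {
    a <- block_dummy_labels(fit$spec$blocks[[ia[1]]])
    bb <- block_dummy_labels(fit$spec$blocks[[ia[2]]])
    for (la in a) for (lb in bb) {
      lab <- paste(la, lb, sep = ":")
      add(paste(ia, collapse = ":"), lab, FALSE,
          fit$coefficients[[lab]], se[[lab]])
    }
  }
  out <- do.call(rbind, rows)
  if (!reference_rows) out <- out[!out$reference, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format a hazard-ratio table the way the published tables print it
#'
#' Two-decimal hazard ratios with `lo-hi` intervals; reference rows render
#' as `1.00` with an em-dash interval.
#'
#' @param tab Result of [hazard_ratios()].
#' @return Data frame of character columns `(variable, level, HR, CI)`.
#' @export
format_hr_table <- function(tab) {
  data.frame(
    variable = tab$variable, level = tab$level,
    HR = sprintf("%.2f", tab$hr),
    CI = ifelse(tab$reference, "–",
                sprintf("%.2f–%.2f", tab$lo, tab$hi)),
    stringsAsFactors = FALSE)
}
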
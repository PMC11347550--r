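#' Published clinical Cox coefficients for advanced HCC
#'
#' The seven-covariate clinical risk score reported with the model:
#' `0.3747*Differentiation + 0.1593*NASH|NAFLD - 0.1801*Surgery +
#' 0.6732*PVTT - 0.8235*EBRT + 0.6482*TAE|TACE - 0.4497*RFA|MWA`.
#' Differentiation enters as a single ordinal code (0 = high, 1 = moderate,
#' 2 = low, 3 = undifferentiated); the six remaining covariates are 0/1.
#'
#' @return named numeric vector of the seven log-hazard coefficients.
#' @export
hcc_clinical_coefficients <- function() {
  c(differentiation = 0.3747, nash_nafld = 0.1593, surgery = -0.1801,
    pvtt = 0.6732, ebrt = -0.8235, tae_tace = 0.6482, rfa_mwa = -0.4497)
}

#' Published bivariate fusion coefficients
#'
#' The late-fusion bivariate Cox model combining the radiological and
#' clinical scores: `9.8834 * Radiology_score + 0.5300 * Clinical_score`.
#'
#' @return named numeric vector `c(radiology, clinical)`.
#' @export
hcc_fusion_coefficients <- function() {
  c(radiology = 9.8834, clinical = 0.5300)
}

#' Fit a Cox proportional hazards model by Newton-Raphson (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood with Newton iterations (with
#' step-halving) until the gradient's max-norm falls below `tol`. Constant
#' covariates are dropped with a warning; non-convergence or diverging
#' coefficients (separation) raise an error. The Breslow baseline cumulative
#' hazard, covariate ranges (for nomogram scaling) and the observed-time
#' support are stored with the fit.
#'
#' @param X numeric covariate matrix (columns named).
#' @param times,events survival times and 0/1 event indicators.
#' @param tol convergence tolerance on the score vector's max-norm.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `cox_fit` with `coefficients`, `se`, `var`,
#'   `loglik` (`c(null, final)`), `baseline_cumhaz` (data frame
#'   time/cumhaz), `x_range`, `n`, `n_events`, `max_time`, `dropped`.
#' @export
fit_cox <- function(X, times, events, tol = 1e-8, max_iter = 30L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(times) != n || length(events) != n)
    stop("invalid input: X, times, events must agree in length")
  if (sum(events) < 1) stop("invalid input: at least one event required")
  keep <- apply(X, 2, function(col) sd(col) > 0)
  if (!any(keep)) stop("degenerate design: all covariates are constant")
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping constant covariates: ", paste(dropped, collapse = ", "))
  X_orig <- X[, keep, drop = FALSE]
  if (n < ncol(X_orig) + 1) stop("invalid input: need n >= p + 1")
  ctr <- colMeans(X_orig)
  Xc <- sweep(X_orig, 2, ctr) # centering leaves the partial likelihood shape unchanged

  ord <- order(times)
  Xs <- Xc[ord, , drop = FALSE]
  ts <- times[ord]; es <- events[ord]
  p <- ncol(Xs)
  first_tie <- match(ts, ts) # index of the first member of each tie group
  ev <- es == 1

  pl_parts <- function(beta, need_hess = TRUE) {
    eta <- drop(Xs %*% beta)
    w <- exp(eta)
    S <- rev(cumsum(rev(w)))[first_tie]
    WX <- Xs * w
    Sx <- apply(WX, 2, function(col) rev(cumsum(rev(col))))[first_tie, , drop = FALSE]
    xbar <- Sx / S
    loglik <- sum(eta[ev]) - sum(log(S[ev]))
    U <- colSums(Xs[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
    out <- list(loglik = loglik, U = U, S = S)
    if (need_hess) {
      XXf <- Xs[, rep(seq_len(p), p), drop = FALSE] *
        Xs[, rep(seq_len(p), each = p), drop = FALSE]
      Sxx <- apply(XXf * w, 2, function(col) rev(cumsum(rev(col))))[first_tie, , drop = FALSE]
      A <- colSums(Sxx[ev, , drop = FALSE] / S[ev])
      B <- crossprod(xbar[ev, , drop = FALSE]) # sum over events of xbar xbar'
      I <- matrix(A, p, p) - B
      out$I <- I
    }
    out
  }

  beta <- numeric(p)
  cur <- pl_parts(beta)
  loglik0 <- cur$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      stop("fit_cox: singular information matrix (separation or collinearity)"))
    half <- 1
    repeat {
      cand <- beta + half * step
      nxt <- pl_parts(cand)
      if (nxt$loglik >= cur$loglik - 1e-12 || half < 1e-4) break
      half <- half / 2
    }
    beta <- beta + half * step
    cur <- nxt
    if (any(abs(beta) > 50))
      stop("fit_cox: coefficients diverging (likely separation)")
  }
  if (!converged && max(abs(cur$U)) >= tol)
    stop("fit_cox: Newton iterations failed to converge")

  V <- solve(cur$I)
  # Breslow baseline cumulative hazard on the original (uncentered) scale
  eta_orig <- drop(X_orig[ord, , drop = FALSE] %*% beta)
  w_orig <- exp(eta_orig)
  S_orig <- rev(cumsum(rev(w_orig)))[first_tie]
  ev_times <- unique(ts[ev])
  haz <- vapply(ev_times, function(u) {
    sum(es[ts == u]) / S_orig[match(u, ts)]
  }, 0)
  baseline <- data.frame(time = ev_times, cumhaz = cumsum(haz))

  names(beta) <- colnames(X_orig)
  structure(list(coefficients = beta, var = V,
                 se = sqrt(diag(V)),
                 loglik = c(loglik0, cur$loglik),
                 baseline_cumhaz = baseline,
                 x_range = apply(X_orig, 2, range),
                 n = n, n_events = sum(events), max_time = max(times),
                 dropped = dropped),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d, loglik %.3f -> %.3f\n",
              x$n, x$n_events, x$loglik[1], x$loglik[2]))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = x$se, check.names = FALSE))
  invisible(x)
}

cox_coefs <- function(fit) {
  if (inherits(fit, "cox_fit")) fit$coefficients
  else if (is.numeric(fit) && !is.null(names(fit))) fit
  else stop("expected a cox_fit or a named coefficient vector")
}

#' Clinical risk score (linear predictor) for one patient
#'
#' `score = beta' x`, no intercept. Works with a fitted [fit_cox()] model or
#' directly with the published coefficient vector
#' ([hcc_clinical_coefficients()]).
#'
#' @param record one clinical record: named list, one-row data frame, or
#'   named numeric vector carrying every fitted covariate.
#' @param fit a `cox_fit` or named coefficient vector.
#' @return a `risk_score` with variant `"cln"`.
#' @export
clinical_score <- function(record, fit) {
  cf <- cox_coefs(fit)
  rec <- if (is.data.frame(record)) as.list(record) else as.list(record)
  miss <- setdiff(names(cf), names(rec))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  x <- vapply(names(cf), function(nm) as.numeric(rec[[nm]]), 0)
  risk_score(rec$patient_id %||% NA_character_, sum(cf * x), "cln")
}

#' Clinical risk scores for a cohort table
#'
#' @param records data frame of clinical records.
#' @param fit a `cox_fit` or named coefficient vector.
#' @return data frame with `patient_id`, `score`, `variant = "cln"`.
#' @export
clinical_scores <- function(records, fit) {
  cf <- cox_coefs(fit)
  miss <- setdiff(names(cf), names(records))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  sc <- as.numeric(as.matrix(records[, names(cf), drop = FALSE]) %*% cf)
  data.frame(patient_id = records$patient_id %||% seq_len(nrow(records)),
             score = sc, variant = "cln")
}

#' Fit the bivariate fusion Cox model on training scores
#'
#' @param rad,clin numeric vectors of radiological and clinical scores.
#' @param times,events training survival outcomes.
#' @return a `cox_fit` with covariates `radiology` and `clinical`.
#' @export
fit_fusion <- function(rad, clin, times, events) {
  fit_cox(cbind(radiology = as.numeric(rad), clinical = as.numeric(clin)),
          times, events)
}

#' Fuse radiological and clinical scores with bivariate Cox coefficients
#'
#' `score = beta_rad * rad + beta_clin * clin`. The fusion coefficients are
#' fitted on the training split only ([fit_fusion()]) and then frozen, or
#' taken from the published values ([hcc_fusion_coefficients()]).
#'
#' @param rad radiological score(s): `risk_score` or numeric vector.
#' @param clin clinical score(s): `risk_score` or numeric vector.
#' @param fusion_fit a two-covariate `cox_fit` or a named length-2
#'   coefficient vector ordered (radiology, clinical).
#' @return a `risk_score` (variant `radcln_d`/`radcln_s` following the
#'   radiological input's variant) when both inputs are `risk_score`s,
#'   otherwise a numeric vector.
#' @export
fuse <- function(rad, clin, fusion_fit) {
  cf <- cox_coefs(fusion_fit)
  if (length(cf) != 2L)
    stop("fusion fit must have exactly two covariates (radiology, clinical)")
  objs <- inherits(rad, "risk_score")
  rv <- if (objs) rad$score else as.numeric(rad)
  cv <- if (inherits(clin, "risk_score")) clin$score else as.numeric(clin)
  sc <- cf[[1]] * rv + cf[[2]] * cv
  if (!objs) return(unname(sc))
  variant <- switch(rad$variant, rad_d = "radcln_d", rad_s = "radcln_s", "fused")
  risk_score(rad$patient_id, sc, variant)
}
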
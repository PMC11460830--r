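#' Weighted logistic regression with explicit variance modes
#'
#' Maximum-likelihood (optionally case-weighted) logistic fit by
#' iteratively reweighted least squares, the shared core behind every
#' estimation strategy in the package.  Variance is either model-based
#' (inverse observed information at unit dispersion) or a robust sandwich,
#' optionally with cluster-summed scores.  Perfect separation is reported
#' as an error naming the offending term; a ridge fallback (small L2
#' penalty, excluding the intercept) can be requested instead but is off
#' by default.
#'
#' @param x numeric design matrix (include the intercept column yourself
#'   or use the formula interface of the `estimate_*` functions).
#' @param y binary outcome (0/1 or logical).
#' @param weights optional positive case weights; `NULL` means 1.
#' @param variance `"model"` or `"robust"`.
#' @param cluster optional grouping vector for cluster-robust variance.
#' @param on_separation `"error"` (default) or `"ridge"`.
#' @param ridge_lambda penalty used when `on_separation = "ridge"`.
#' @param epsilon IRLS convergence tolerance on the relative deviance
#'   change.
#' @param maxit maximum IRLS iterations.
#' @param method label stored on the result.
#' @param exposure_terms optional character vector of coefficient names to
#'   tabulate as odds ratios in the result.
#' @return an object of class `ehr_fit`; see [odds_ratio()].
#' @export
fit_logistic <- function(x, y, weights = NULL,
                         variance = c("model", "robust"),
                         cluster = NULL,
                         on_separation = c("error", "ridge"),
                         ridge_lambda = 1e-4,
                         epsilon = 1e-10, maxit = 100,
                         method = "custom", exposure_terms = NULL) {
  variance <- match.arg(variance)
  on_separation <- match.arg(on_separation)
  x <- as.matrix(x)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)", call. = FALSE)
  if (length(y) != nrow(x)) stop("outcome length does not match design matrix")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0) || anyNA(weights))
    stop("case weights must be positive and non-missing", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("perfect separation: outcome has no variation", call. = FALSE)
  if (qr(x)$rank < ncol(x))
    stop("design matrix is rank deficient; drop aliased terms", call. = FALSE)

  # point estimates are invariant to the weight scale; fitting at mean 1
  # keeps IRLS numerically stable for survey-magnitude weights
  wn <- weights / mean(weights)
  fit <- suppressWarnings(stats::glm.fit(
    x, y, weights = wn, family = stats::quasibinomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  beta <- fit$coefficients
  converged <- isTRUE(fit$converged)

  sep_term <- separation_term(beta, fit$fitted.values, y)
  if (!is.null(sep_term)) {
    if (on_separation == "error")
      stop("perfect separation detected for term '", sep_term, "'",
           call. = FALSE)
    beta <- ridge_logistic(x, y, wn, ridge_lambda, epsilon, maxit)
    fit$fitted.values <- as.vector(stats::plogis(x %*% beta))
    converged <- TRUE
  }

  p <- fit$fitted.values
  w_irls <- weights * p * (1 - p)
  info <- crossprod(x * w_irls, x)
  bread <- solve(info)
  vcov_model <- bread
  if (variance == "robust") {
    u <- x * (weights * (y - p))          # score contributions
    if (!is.null(cluster)) u <- rowsum(u, group = cluster)
    vc <- bread %*% crossprod(u) %*% bread
  } else {
    vc <- vcov_model
  }
  dimnames(vc) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)

  new_ehr_fit(coefficients = beta, vcov = vc, method = method,
              n = length(y), sum_weights = sum(weights),
              converged = converged, variance = variance,
              exposure_terms = exposure_terms,
              deviance = fit$deviance)
}

# flags the coefficient drifting to +-infinity when fitted probabilities
# have collapsed onto the outcome
separation_term <- function(beta, p, y) {
  eps <- 1e-8
  degenerate <- all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)
  big <- abs(beta) > 12
  if (any(big) && (degenerate || any(abs(beta) > 15)))
    names(beta)[which.max(abs(beta))]
  else NULL
}

ridge_logistic <- function(x, y, w, lambda, epsilon, maxit) {
  pen <- rep(lambda, ncol(x))
  pen[colnames(x) %in% c("(Intercept)", "Intercept")] <- 0
  beta <- rep(0, ncol(x))
  dev_old <- Inf
  for (i in seq_len(maxit)) {
    eta <- as.vector(x %*% beta)
    p <- stats::plogis(eta)
    wi <- w * p * (1 - p)
    z <- eta + (y - p) / pmax(p * (1 - p), 1e-10)
    beta <- solve(crossprod(x * wi, x) + diag(pen, ncol(x)),
                  crossprod(x * wi, z))
    dev <- -2 * sum(w * stats::dbinom(y, 1, stats::plogis(as.vector(x %*% beta)),
                                      log = TRUE))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon) break
    dev_old <- dev
  }
  beta <- as.vector(beta)
  names(beta) <- colnames(x)
  beta
}

new_ehr_fit <- function(coefficients, vcov, method, n, sum_weights,
                        converged, variance, exposure_terms = NULL,
                        deviance = NA_real_, extra = list()) {
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(0.975)
  terms <- if (is.null(exposure_terms)) names(coefficients) else exposure_terms
  terms <- intersect(terms, names(coefficients))
  or_table <- data.frame(
    term = terms,
    logor = unname(coefficients[terms]),
    se_logor = unname(se[terms]),
    or = exp(unname(coefficients[terms])),
    lower = exp(unname(coefficients[terms]) - z * unname(se[terms])),
    upper = exp(unname(coefficients[terms]) + z * unname(se[terms])),
    stringsAsFactors = FALSE)
  structure(c(list(coefficients = coefficients, vcov = vcov,
                   or_table = or_table, method = method, n = n,
                   sum_weights = sum_weights, converged = converged,
                   variance = variance, deviance = deviance),
              extra),
            class = "ehr_fit")
}

#' Extract odds ratios with 95% confidence intervals
#'
#' Wald intervals on the log-odds scale: `exp(logOR +/- 1.96 * SE)`.
#'
#' @param fit an `ehr_fit`.
#' @param term optional coefficient name(s); default: the fit's exposure
#'   terms.
#' @return data frame with columns `term`, `logor`, `se_logor`, `or`,
#'   `lower`, `upper`.
#' @export
odds_ratio <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "ehr_fit"))
  if (is.null(term)) return(fit$or_table)
  missing_terms <- setdiff(term, names(fit$coefficients))
  if (length(missing_terms))
    stop("term(s) not in fit: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  se <- sqrt(diag(fit$vcov))[term]
  z <- stats::qnorm(0.975)
  b <- fit$coefficients[term]
  data.frame(term = term, logor = unname(b), se_logor = unname(se),
             or = exp(unname(b)),
             lower = exp(unname(b) - z * unname(se)),
             upper = exp(unname(b) + z * unname(se)),
             stringsAsFactors = FALSE)
}

#' @export
print.ehr_fit <- function(x, digits = 3, ...) {
  cat("<ehr_fit>", x$method, "| n =", x$n,
      "| sum(w) =", format(x$sum_weights, digits = 6),
      "| variance:", x$variance,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  ot <- x$or_table
  if (nrow(ot)) {
    ot[-1] <- lapply(ot[-1], round, digits)
    print(ot, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ehr_fit <- function(object, ...) object$coefficients

#' @export
vcov.ehr_fit <- function(object, ...) object$vcov

#' Serialize fit results to JSON
#'
#' @param fits an `ehr_fit` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  if (inherits(fits, "ehr_fit")) fits <- list(fits)
  payload <- lapply(fits, function(f) {
    list(method = f$method, n = f$n, sum_weights = f$sum_weights,
         converged = f$converged, variance = f$variance,
         coefficients = as.list(f$coefficients),
         or_table = f$or_table,
         vcov = unclass(as.data.frame(f$vcov)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
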
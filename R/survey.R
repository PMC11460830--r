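#' Construct a complex survey design
#'
#' Bundles respondent data with analysis weights, stratum ids and primary
#' sampling unit (PSU) ids for design-based estimation.  Every PSU must
#' belong to exactly one stratum; absent strata/PSU columns default to a
#' single stratum with each row its own PSU (i.e. independent sampling).
#'
#' @param data respondent-level data frame.
#' @param weights column name or numeric vector of positive analysis
#'   weights.
#' @param strata optional column name or vector of stratum ids.
#' @param psu optional column name or vector of PSU ids.
#' @return object of class `survey_design`.
#' @export
survey_design <- function(data, weights, strata = NULL, psu = NULL) {
  pick <- function(v, default, what) {
    if (is.null(v)) return(default)
    if (is.character(v) && length(v) == 1) {
      if (!v %in% names(data))
        stop(what, " column not found: '", v, "'", call. = FALSE)
      return(data[[v]])
    }
    v
  }
  w <- pick(weights, NULL, "weights")
  if (is.null(w)) stop("weights column not found", call. = FALSE)
  w <- as.numeric(w)
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
    stop("analysis weights must be positive and finite", call. = FALSE)
  strata <- pick(strata, rep(1L, nrow(data)), "stratum")
  psu <- pick(psu, seq_len(nrow(data)), "PSU")
  # PSU ids are interpreted within stratum (public-use files reuse codes
  # like 1/2 across strata); the effective PSU identity is the pair, so
  # each PSU belongs to exactly one stratum by construction.
  structure(list(data = data, weights = w,
                 strata = as.character(strata), psu = as.character(psu)),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design>", nrow(x$data), "respondents,",
      length(unique(x$strata)), "strata,",
      length(unique(paste(x$strata, x$psu))), "PSUs\n")
  invisible(x)
}

#' Design-based (survey-weighted) logistic regression
#'
#' Weighted pseudo-maximum-likelihood logistic fit with design-based
#' variance: Taylor linearization under the with-replacement
#' approximation, i.e. a sandwich whose meat sums weighted score
#' contributions to PSU totals, centers them within stratum, and scales by
#' `n_h / (n_h - 1)`.  A delete-one-PSU jackknife (JKn) is available for
#' cross-checking.  Point estimates depend on the weights only through
#' their relative values.
#'
#' @param design a [survey_design()].
#' @param formula model formula evaluated in the design's data.
#' @param exposure_terms coefficient names to tabulate as odds ratios
#'   (default: all non-intercept terms).
#' @param variance `"linearized"` (default) or `"jackknife"`.
#' @param single_psu how to treat strata with a single PSU:
#'   `"center"` (default; the lone PSU is centered at the stratum mean and
#'   contributes nothing, with a warning) or `"error"`.
#' @return an `ehr_fit` labelled `"survey"`.
#' @export
fit_survey_logistic <- function(design, formula, exposure_terms = NULL,
                                variance = c("linearized", "jackknife"),
                                single_psu = c("center", "error")) {
  stopifnot(inherits(design, "survey_design"))
  variance <- match.arg(variance)
  single_psu <- match.arg(single_psu)

  mf <- stats::model.frame(formula, design$data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  x <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)", call. = FALSE)
  w <- design$weights[keep]
  strata <- design$strata[keep]
  psu <- design$psu[keep]

  core <- fit_logistic(x, y, weights = w, variance = "model",
                       method = "survey")
  beta <- core$coefficients
  p <- as.vector(stats::plogis(x %*% beta))
  bread <- solve(crossprod(x * (w * p * (1 - p)), x))

  if (variance == "linearized") {
    vc <- taylor_meat(x, y, p, w, strata, psu, single_psu)
    vc <- bread %*% vc %*% bread
  } else {
    vc <- jackknife_vcov(x, y, w, strata, psu, beta)
  }
  dimnames(vc) <- list(colnames(x), colnames(x))

  if (is.null(exposure_terms))
    exposure_terms <- setdiff(colnames(x), "(Intercept)")
  fit <- new_ehr_fit(coefficients = beta, vcov = vc, method = "survey",
                     n = length(y), sum_weights = sum(w),
                     converged = core$converged,
                     variance = paste0("design-", variance),
                     exposure_terms = exposure_terms)
  fit$formula <- deparse(formula)
  fit
}

taylor_meat <- function(x, y, p, w, strata, psu, single_psu) {
  u <- x * (w * (y - p))
  z <- rowsum(u, group = paste(strata, psu, sep = "\r"))
  z_str <- sub("\r.*$", "", rownames(z))
  meat <- matrix(0, ncol(x), ncol(x))
  singletons <- character()
  for (h in unique(z_str)) {
    zh <- z[z_str == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2) { singletons <- c(singletons, h); next }
    zc <- sweep(zh, 2, colMeans(zh))
    meat <- meat + nh / (nh - 1) * crossprod(zc)
  }
  if (length(singletons)) {
    if (single_psu == "error")
      stop("stratum with a single PSU: ",
           paste(singletons, collapse = ", "), call. = FALSE)
    warning("stratum with a single PSU centered at its own mean ",
            "(zero variance contribution): ",
            paste(singletons, collapse = ", "))
  }
  meat
}

jackknife_vcov <- function(x, y, w, strata, psu, beta_full) {
  key <- paste(strata, psu, sep = "\r")
  psus <- unique(key)
  psu_str <- sub("\r.*$", "", psus)
  vc <- matrix(0, length(beta_full), length(beta_full))
  for (h in unique(psu_str)) {
    hp <- psus[psu_str == h]
    nh <- length(hp)
    if (nh < 2) next
    for (j in hp) {
      wj <- w
      wj[key == j] <- 0
      wj[key != j & strata == h] <- w[key != j & strata == h] * nh / (nh - 1)
      use <- wj > 0
      wju <- wj[use] / mean(wj[use])
      fit <- suppressWarnings(stats::glm.fit(
        x[use, , drop = FALSE], y[use], weights = wju,
        family = stats::quasibinomial(), start = beta_full))
      d <- fit$coefficients - beta_full
      vc <- vc + (nh - 1) / nh * tcrossprod(d)
    }
  }
  vc
}
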
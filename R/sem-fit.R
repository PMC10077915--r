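#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations among candidate covariates; of every pair
#' with |r| strictly greater than the threshold, the lower-priority member
#' is dropped. |r| equal to the threshold is retained. Dropping proceeds in
#' priority order, and correlations are not re-estimated after drops (the
#' screen is on the original pairwise matrix).
#'
#' @param covariates Data frame of numeric covariates (sites in rows).
#' @param threshold Absolute-correlation threshold; pairs must exceed it
#'   strictly to trigger a drop. Default 0.7.
#' @param priority Character vector ordering the covariates from most to
#'   least preferred; defaults to column order. Covariates not listed rank
#'   after all listed ones.
#' @return A list: `retained` (character), `dropped` (character), and
#'   `report`, a tibble of all pairs with `r`, `violates`, and which member
#'   (if any) was dropped for that pair.
#' @export
collinearity_screen <- function(covariates, threshold = 0.7, priority = NULL) {
  covariates <- as.data.frame(covariates)
  vars <- names(covariates)
  if (length(vars) < 2) stop_beeniche("need at least 2 covariates to screen")
  if (nrow(covariates) < 3) stop_beeniche("need at least 3 sites to screen")
  sds <- vapply(covariates, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop_beeniche(sprintf("constant covariate(s): %s",
                          paste(vars[sds == 0], collapse = ", ")))
  }
  pr <- priority %||% vars
  rank_of <- function(v) {
    i <- match(v, pr)
    ifelse(is.na(i), length(pr) + match(v, vars), i)
  }
  cm <- stats::cor(covariates)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  report <- tibble::tibble(
    var1 = vars[pairs[, "row"]],
    var2 = vars[pairs[, "col"]],
    r = cm[pairs],
    violates = abs(cm[pairs]) > threshold,
    dropped = NA_character_
  )
  dropped <- character(0)
  viol <- which(report$violates)
  viol <- viol[order(pmax(rank_of(report$var1[viol]), rank_of(report$var2[viol])))]
  for (k in viol) {
    a <- report$var1[k]; b <- report$var2[k]
    if (a %in% dropped || b %in% dropped) next
    loser <- if (rank_of(a) > rank_of(b)) a else b
    dropped <- c(dropped, loser)
    report$dropped[k] <- loser
  }
  list(retained = setdiff(vars, dropped), dropped = dropped, report = report)
}

#' Fit one linear sub-model of a piecewise SEM
#'
#' Ordinary least squares of the (offset-adjusted) response on the
#' predictors with an intercept. A declared offset enters the response with
#' coefficient fixed at 1: the model is fitted to `response - offset`, and
#' R-squared is reported on that adjusted response.
#'
#' @param data Data frame of site-level variables.
#' @param response,predictors Variable names.
#' @param offset Optional offset variable name.
#' @return A list: `paths` (tibble of per-predictor estimate, se, t, p),
#'   `intercept`, `r2`, `residuals`, `sigma`, `n`, `k_params` (coefficients
#'   plus the error variance), and the fitted `lm`.
#' @export
fit_submodel <- function(data, response, predictors, offset = NULL) {
  need <- c(response, predictors, offset)
  assert_cols(data, need, "site table")
  if (any(!stats::complete.cases(data[, need]))) {
    stop_beeniche(sprintf("missing values in sub-model variables for response '%s'",
                          response))
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1) {
    stop_beeniche(sprintf("sub-model '%s': need n > p + 1 (n=%d, p=%d)",
                          response, n, length(predictors)))
  }
  yadj <- data[[response]] - (if (is.null(offset)) 0 else data[[offset]])
  df_fit <- data.frame(.y = yadj, data[, predictors, drop = FALSE],
                       check.names = FALSE)
  fit <- stats::lm(
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", predictors), collapse = " + "))),
    data = df_fit
  )
  cf <- coef(fit)
  if (any(is.na(cf))) {
    aliased <- gsub("`", "", names(cf)[is.na(cf)])
    stop_beeniche(sprintf("rank-deficient design for '%s': aliased column(s): %s",
                          response, paste(aliased, collapse = ", ")))
  }
  sm <- suppressWarnings(summary(fit)) # silence lm's perfect-fit note
  ct <- sm$coefficients
  rows <- gsub("`", "", rownames(ct))
  keep <- rows != "(Intercept)"
  list(
    response = response,
    offset = offset,
    paths = tibble::tibble(
      response = response,
      predictor = rows[keep],
      estimate = ct[keep, "Estimate"],
      se = ct[keep, "Std. Error"],
      t = ct[keep, "t value"],
      p = ct[keep, "Pr(>|t|)"]
    ),
    intercept = unname(cf["(Intercept)"]),
    r2 = sm$r.squared,
    residuals = stats::residuals(fit),
    sigma = sm$sigma,
    n = n,
    k_params = length(cf) + 1, # coefficients + error variance
    lm = fit
  )
}

#' Standardize path coefficients
#'
#' Converts raw slopes to standardized path coefficients,
#' `b_std = b_raw * sd(x) / sd(y)`, using sample standard deviations over
#' sites; the response sd is taken on the offset-adjusted response when the
#' sub-model declares an offset (that being the modeled quantity). Standard
#' errors are scaled by the same factor. Standardized coefficients are
#' invariant to affine changes of units of either variable.
#'
#' @param submodel_fit A fit from [fit_submodel()].
#' @param data The site table the model was fitted to.
#' @return The `paths` tibble with columns `std_estimate` and `std_se`
#'   added.
#' @export
standardize_paths <- function(submodel_fit, data) {
  yadj <- data[[submodel_fit$response]] -
    (if (is.null(submodel_fit$offset)) 0 else data[[submodel_fit$offset]])
  sdy <- stats::sd(yadj)
  paths <- submodel_fit$paths
  sdx <- vapply(paths$predictor, function(v) stats::sd(data[[v]]), numeric(1))
  if (sdy == 0 || any(sdx == 0)) {
    stop_beeniche("zero-variance variable: standardized coefficients undefined")
  }
  paths$std_estimate <- unname(paths$estimate * sdx / sdy)
  paths$std_se <- unname(paths$se * sdx / sdy)
  paths
}

#' Test one d-separation claim
#'
#' The claim that `x` and `y` are independent given a conditioning set is
#' tested by regressing `y` on `x` plus the conditioning set with the same
#' linear-model machinery as the sub-models (offset-aware: if the fitted
#' model declares an offset for response `y`, it is applied), and returning
#' the two-sided t-test p-value of `x`'s coefficient.
#'
#' @param data Site table.
#' @param claim A claim from [basis_set()] (list with `x`, `y`, `cond`).
#' @param model Optional `sem_model`, used only to look up an offset
#'   declared for `y`.
#' @return The p-value.
#' @export
dsep_test <- function(data, claim, model = NULL) {
  offset <- NULL
  if (!is.null(model)) {
    for (sm in model$submodels) {
      if (sm$response == claim$y) offset <- sm$offset
    }
  }
  fit <- fit_submodel(data, claim$y, c(claim$x, claim$cond), offset = offset)
  fit$paths$p[fit$paths$predictor == claim$x]
}

#' Fisher's C statistic
#'
#' Combines the basis-set p-values into the goodness-of-fit statistic
#' `C = -2 * sum(log(p_i))`, chi-square distributed with `2k` degrees of
#' freedom when all claims hold. A large model p-value means no evidence of
#' missing paths. An empty basis set gives C = 0, df = 0, p = 1.
#'
#' @param pvalues Numeric vector of claim p-values, each in (0, 1]. A p of
#'   exactly 0 is rejected: it would send C to infinity, and signals an
#'   underflowed test whose claim should be examined directly.
#' @return A list: `fisher_c`, `k`, `df`, `p_model`.
#' @export
fishers_c <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(list(fisher_c = 0, k = 0L, df = 0L, p_model = 1))
  }
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_beeniche("all p-values must lie in (0, 1]; p = 0 is a numerical floor")
  }
  k <- length(pvalues)
  C <- -2 * sum(log(pvalues))
  list(fisher_c = C, k = k, df = 2L * k,
       p_model = stats::pchisq(C, df = 2 * k, lower.tail = FALSE))
}

#' Information criteria for a piecewise SEM
#'
#' The Fisher's-C-based convention: `AIC = C + 2K`,
#' `AICc = C + 2K * n / (n - K - 1)`, `BIC = C + K * log(n)`, with `K` the
#' total number of estimated parameters across sub-models (slopes,
#' intercepts and error variances) and `n` the number of sites.
#'
#' @param fisher_c Fisher's C value.
#' @param K Total estimated parameters.
#' @param n Number of sites.
#' @return A list: `aic`, `aicc`, `bic`, `K`, `n`.
#' @export
information_criteria <- function(fisher_c, K, n) {
  if (n <= K + 1) {
    stop_beeniche(sprintf("AICc undefined: need n > K + 1 (n=%d, K=%d)", n, K))
  }
  list(
    aic = fisher_c + 2 * K,
    aicc = fisher_c + 2 * K * n / (n - K - 1),
    bic = fisher_c + K * log(n),
    K = K, n = n
  )
}

#' Fit a piecewise structural equation model
#'
#' Fits every sub-model by OLS (offset-aware), standardizes the path
#' coefficients, tests the d-separation basis set, combines the claim
#' p-values into Fisher's C with its chi-square model test, computes
#' information criteria, and (when coordinates are supplied) Moran's I
#' spatial autocorrelation diagnostics for each response and its residuals.
#'
#' @param data Site table with one complete row per site.
#' @param model A `sem_model`.
#' @param coords Optional two-column matrix/data frame of site coordinates
#'   (meters) for Moran's I diagnostics.
#' @param moran_scheme Weighting scheme passed to [morans_i()].
#' @param alpha Significance level used for display stars.
#' @return An object of class `sem_fit`.
#' @export
fit_sem <- function(data, model, coords = NULL,
                    moran_scheme = "inverse_distance_row", alpha = 0.05) {
  fits <- lapply(model$submodels, function(sm) {
    fit_submodel(data, sm$response, sm$predictors, offset = sm$offset)
  })
  paths <- dplyr::bind_rows(lapply(fits, standardize_paths, data = data))
  r2 <- tibble::tibble(
    response = vapply(fits, `[[`, character(1), "response"),
    r2 = vapply(fits, `[[`, numeric(1), "r2")
  )
  claims <- basis_set(model)
  dsep <- tibble::tibble(
    x = vapply(claims, `[[`, character(1), "x"),
    y = vapply(claims, `[[`, character(1), "y"),
    conditioning = vapply(claims, function(cl) paste(cl$cond, collapse = ", "),
                          character(1)),
    p = vapply(claims, function(cl) dsep_test(data, cl, model), numeric(1))
  )
  gof <- fishers_c(dsep$p)
  K <- sum(vapply(fits, `[[`, numeric(1), "k_params"))
  ic <- information_criteria(gof$fisher_c, K, nrow(data))
  moran <- NULL
  if (!is.null(coords)) {
    moran <- dplyr::bind_rows(lapply(fits, function(f) {
      dplyr::bind_rows(
        moran_row(data[[f$response]], coords, moran_scheme, f$response, "response"),
        moran_row(f$residuals, coords, moran_scheme, f$response, "residuals")
      )
    }))
  }
  structure(
    list(paths = paths, r2 = r2, dsep = dsep,
         fisher_c = gof$fisher_c, df = gof$df, p_model = gof$p_model,
         aic = ic$aic, aicc = ic$aicc, bic = ic$bic, K = K, n = nrow(data),
         moran = moran, model = model, alpha = alpha,
         submodel_fits = fits),
    class = "sem_fit"
  )
}

moran_row <- function(values, coords, scheme, response, kind) {
  res <- tryCatch(morans_i(values, coords, scheme = scheme),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(tibble::tibble(response = response, kind = kind,
                          observed = NA_real_, expected = NA_real_,
                          sd = NA_real_, p = NA_real_, scheme = scheme))
  }
  tibble::tibble(response = response, kind = kind,
                 observed = res$observed, expected = res$expected,
                 sd = res$sd, p = res$p_value, scheme = scheme)
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Tabulate a fitted SEM in path-table layout
#'
#' One row per path: response, sub-model R-squared, predictor, standardized
#' estimate with its standard error, p-value and significance stars
#' (* p < 0.05, ** p < 0.01).
#'
#' @param fit A `sem_fit`.
#' @return A tibble.
#' @export
sem_path_table <- function(fit) {
  dplyr::left_join(fit$paths, fit$r2, by = "response") |>
    dplyr::mutate(stars = signif_stars(.data$p)) |>
    dplyr::select("response", "r2", "predictor",
                  "std_estimate", "std_se", "estimate", "se", "p", "stars")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %d sub-models over %d sites\n",
              length(x$model$submodels), x$n))
  cat(sprintf("  Fisher's C = %.2f, df = %d, p = %.3f | AICc = %.2f, BIC = %.2f (K = %d)\n",
              x$fisher_c, x$df, x$p_model, x$aicc, x$bic, x$K))
  tab <- sem_path_table(x)
  for (resp in unique(tab$response)) {
    sub <- tab[tab$response == resp, ]
    cat(sprintf("  %s (R2 = %.2f)\n", resp, sub$r2[1]))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-24s %6.3f ± %.3f %s\n", sub$predictor[i],
                  sub$std_estimate[i], sub$std_se[i], sub$stars[i]))
    }
  }
  invisible(x)
}
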
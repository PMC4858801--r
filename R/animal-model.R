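#' Fit a REML animal model for autosomal crossover count
#'
#' Partitions the phenotypic variance of a per-gamete trait (typically the
#' autosomal crossover count, ACC) into an additive genetic component with
#' covariance proportional to a relationship matrix, an optional permanent
#' environment component (individual identity, capturing repeated measures),
#' further optional individual-level random effects, and residual. Fixed
#' effects (e.g. sex and genomic inbreeding) must be constant within
#' individual. Heritability is the additive variance divided by the sum of
#' all estimated variance components.
#'
#' @param y Response per gamete.
#' @param id Focal individual of each gamete.
#' @param fixed Optional `data.frame` of fixed covariates (one row per
#'   gamete, constant within individual); an intercept is always included.
#' @param relationship Additive relationship matrix (GRM or pedigree NRM)
#'   with ids in dimnames, or `NULL` to omit the additive term.
#' @param pe Include a permanent-environment (individual identity) random
#'   effect (default `TRUE`; only identifiable with repeated measures).
#' @param extra_random Named list of further individual-level covariance
#'   matrices (or `"identity"`).
#' @param ... Passed to [reml_fit()].
#' @return Object of class `acc_reml`: variance components with standard
#'   errors, `h2`/`h2_se`, `e2`, fixed-effect estimates with Wald tests,
#'   restricted log-likelihood and convergence/boundary flags.
#' @export
fit_animal_model <- function(y, id, fixed = NULL, relationship = NULL,
                             pe = TRUE, extra_random = list(), ...) {
  W <- if (is.null(fixed)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(fixed))
  }
  Klist <- list()
  if (!is.null(relationship)) Klist$additive <- relationship
  if (pe) {
    if (max(table(id)) < 2)
      warnf("permanent-environment effect requested without repeated measures")
    Klist$pe <- "identity"
  }
  Klist <- c(Klist, extra_random)
  fit <- reml_fit(y, id, W, Klist, ...)

  sig <- fit$sigma
  V_P <- sum(sig)
  h2 <- if ("additive" %in% names(sig)) sig[["additive"]] / V_P else NA_real_
  # delta method for a ratio of summed components
  h2_se <- NA_real_
  if (!is.na(h2) && all(is.finite(fit$vcov_sigma))) {
    gr <- rep(-sig[["additive"]] / V_P^2, length(sig))
    gr[match("additive", names(sig))] <- (V_P - sig[["additive"]]) / V_P^2
    h2_se <- sqrt(max(0, drop(t(gr) %*% fit$vcov_sigma %*% gr)))
  }
  se_sigma <- sqrt(pmax(0, diag(fit$vcov_sigma)))

  wald <- NULL
  if (ncol(W) > 1) {
    z <- fit$beta / sqrt(diag(fit$vcov_beta))
    wald <- data.frame(term = names(fit$beta), estimate = fit$beta,
                       se = sqrt(diag(fit$vcov_beta)), z = z,
                       p = 2 * pnorm(-abs(z)), row.names = NULL)
  }
  structure(list(
    components = data.frame(component = names(sig), variance = unname(sig),
                            se = unname(se_sigma),
                            boundary = unname(fit$boundary)),
    V_P = V_P, h2 = unname(h2), h2_se = h2_se,
    e2 = unname(sig[["residual"]] / V_P),
    beta = fit$beta, vcov_beta = fit$vcov_beta, wald = wald,
    logLik = fit$logLik, converged = fit$converged,
    n_obs = fit$n_obs, n_ind = fit$n_ind,
    fit = fit), class = "acc_reml")
}

#' @export
print.acc_reml <- function(x, ...) {
  cat(sprintf("Animal model: %d observations, %d individuals, logL = %.3f\n",
              x$n_obs, x$n_ind, x$logLik))
  print(x$components, row.names = FALSE)
  if (!is.na(x$h2))
    cat(sprintf("h2 = %.4f (SE %.4f), V_P = %.3f\n", x$h2, x$h2_se, x$V_P))
  invisible(x)
}

#' Likelihood-ratio test between nested REML models
#'
#' @param full,reduced Fitted models ([fit_animal_model()] or anything with
#'   a `logLik` element), `reduced` nested in `full`.
#' @param df Difference in number of parameters (default 1).
#' @param boundary If `TRUE`, p-values use the 50:50 mixture of chi-square
#'   0 and `df` appropriate when the tested variance sits on the boundary;
#'   default is the plain chi-square.
#' @return `data.frame` with `chi2`, `df`, `p`.
#' @export
lrt_random_effect <- function(full, reduced, df = 1, boundary = FALSE) {
  lf <- if (is.list(full)) full$logLik else full
  lr <- if (is.list(reduced)) reduced$logLik else reduced
  chi2 <- 2 * (lf - lr)
  if (chi2 < -1e-4)
    stopf("full model log-likelihood below reduced (%.4g): convergence failure", chi2)
  chi2 <- max(0, chi2)
  p <- pchisq(chi2, df, lower.tail = FALSE)
  if (boundary) p <- p / 2
  data.frame(chi2 = chi2, df = df, p = p)
}
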
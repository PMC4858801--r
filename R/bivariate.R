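#' Bivariate REML of male and female crossover counts
#'
#' Treats ACC in the two sexes as two traits measured on disjoint sets of
#' individuals and estimates sex-specific additive genetic variances, the
#' cross-sex additive genetic correlation `r_A` (the cross-trait covariance
#' is `r_A * sqrt(V_Am * V_Af)` scaled by the relationship matrix), optional
#' sex-specific permanent-environment variances, and sex-specific
#' residuals. Constrained fits (`r_A = 0`, `r_A = 0.999`, equal additive
#' variances) support likelihood-ratio tests of the correlation and of
#' sex differences in additive variance.
#'
#' @param y Response per gamete.
#' @param id Focal individual per gamete.
#' @param sex Sex of the focal individual per gamete (`"M"`/`"F"`).
#' @param relationship Additive relationship matrix covering all ids.
#' @param constraint One of `"free"`, `"rA0"`, `"rA0.999"`, `"equalVA"`.
#' @param pe Include sex-specific permanent-environment effects.
#' @return Object of class `acc_bivariate`: estimates (`V_A_m`, `V_A_f`,
#'   `r_A` with SE, residuals), log-likelihood, boundary flags.
#' @export
fit_bivariate_acc <- function(y, id, sex, relationship,
                              constraint = c("free", "rA0", "rA0.999", "equalVA"),
                              pe = TRUE) {
  constraint <- match.arg(constraint)
  keep <- complete.cases(y, id, sex)
  y <- y[keep]; id <- as.character(id)[keep]; sex <- as.character(sex)[keep]
  f <- factor(id)
  lv <- levels(f)
  q <- length(lv)
  ni <- as.numeric(table(f))
  M <- as.numeric(rowsum(y, f) / ni)
  sex_ind <- tapply(sex, f, function(s) {
    u <- unique(s)
    if (length(u) > 1) stopf("individual with gametes in both sexes")
    u
  })[lv]
  is_m <- sex_ind == "M"
  SSW_m <- sum((y[sex == "M"] - M[match(id[sex == "M"], lv)])^2)
  SSW_f <- sum((y[sex == "F"] - M[match(id[sex == "F"], lv)])^2)
  Nw_m <- sum(sex == "M") - sum(is_m)
  Nw_f <- sum(sex == "F") - sum(!is_m)
  A <- .align_K(relationship, lv, "additive")
  W <- cbind(M_intercept = as.numeric(is_m), F_intercept = as.numeric(!is_m))

  # parameters: VAm, VAf, rA, [VPEm, VPEf], VEm, VEf (constraint-dependent)
  unpack <- function(par) {
    i <- 1
    VAm <- par[i]; i <- i + 1
    VAf <- if (constraint == "equalVA") VAm else { v <- par[i]; i <- i + 1; v }
    rA <- switch(constraint, rA0 = 0, rA0.999 = 0.999, { v <- par[i]; i <- i + 1; v })
    if (pe) { VPEm <- par[i]; VPEf <- par[i + 1]; i <- i + 2 } else VPEm <- VPEf <- 0
    list(VAm = VAm, VAf = VAf, rA = rA, VPEm = VPEm, VPEf = VPEf,
         VEm = par[i], VEf = par[i + 1])
  }
  scale_vec <- function(p) ifelse(is_m, sqrt(p$VAm), sqrt(p$VAf))
  nll <- function(par) {
    p <- unpack(par)
    if (p$VAm < 0 || p$VAf < 0 || abs(p$rA) > 0.999 ||
        p$VPEm < 0 || p$VPEf < 0 || p$VEm <= 0 || p$VEf <= 0) return(1e10)
    s <- scale_vec(p)
    corr <- outer(is_m, is_m, function(a, b) ifelse(a == b, 1, p$rA))
    Sigma <- A * tcrossprod(s) * corr
    diag(Sigma) <- diag(Sigma) +
      ifelse(is_m, p$VPEm + p$VEm / ni, p$VPEf + p$VEf / ni)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Wt <- backsolve(R, W, transpose = TRUE)
    Mt <- backsolve(R, M, transpose = TRUE)
    XtX <- crossprod(Wt)
    b <- solve(XtX, crossprod(Wt, Mt))
    r <- Mt - Wt %*% b
    0.5 * (Nw_m * log(p$VEm) + SSW_m / p$VEm +
           Nw_f * log(p$VEf) + SSW_f / p$VEf +
           2 * sum(log(diag(R))) +
           as.numeric(determinant(XtX, TRUE)$modulus) + sum(r^2))
  }

  vy <- var(M)
  start <- numeric(0)
  start <- c(start, vy / 4)                                  # VAm
  if (constraint != "equalVA") start <- c(start, vy / 4)     # VAf
  if (!constraint %in% c("rA0", "rA0.999")) start <- c(start, 0.5)  # rA
  if (pe) start <- c(start, vy / 8, vy / 8)
  start <- c(start, vy / 2, vy / 2)
  lower <- rep(0, length(start))
  upper <- rep(Inf, length(start))
  if (!constraint %in% c("rA0", "rA0.999")) {
    ri <- 1 + (constraint != "equalVA") + 1
    lower[ri] <- -0.999; upper[ri] <- 0.999
  }
  lower[(length(start) - 1):length(start)] <- vy * 1e-8

  opt <- nlminb(start, nll, lower = lower, upper = upper,
                control = list(rel.tol = 1e-10, iter.max = 1000, eval.max = 2000))
  p <- unpack(opt$par)
  H <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  rA_se <- NA_real_
  if (!is.null(vc) && !constraint %in% c("rA0", "rA0.999")) {
    ri <- 1 + (constraint != "equalVA") + 1
    rA_se <- sqrt(max(0, vc[ri, ri]))
  }
  va_boundary <- p$VAm < vy * 1e-6 || p$VAf < vy * 1e-6
  if (va_boundary && constraint == "free")
    warnf("additive variance at zero boundary in one sex; r_A is not identifiable")
  structure(list(
    estimates = list(V_A_m = p$VAm, V_A_f = p$VAf, r_A = p$rA, r_A_se = rA_se,
                     V_PE_m = p$VPEm, V_PE_f = p$VPEf,
                     V_E_m = p$VEm, V_E_f = p$VEf),
    constraint = constraint, logLik = -opt$objective,
    converged = opt$convergence == 0, boundary_VA = va_boundary,
    n_male = sum(sex == "M"), n_female = sum(sex == "F")),
    class = "acc_bivariate")
}

#' Cross-sex genetic-correlation tests
#'
#' Fits the unconstrained bivariate model plus the three constrained
#' versions and reports likelihood-ratio tests of `r_A = 0`, `r_A = 0.999`
#' and equal additive variances (1 df each).
#'
#' @inheritParams fit_bivariate_acc
#' @return List with the four fits and a `tests` data.frame.
#' @export
bivariate_acc_tests <- function(y, id, sex, relationship, pe = TRUE) {
  free <- fit_bivariate_acc(y, id, sex, relationship, "free", pe)
  r0 <- fit_bivariate_acc(y, id, sex, relationship, "rA0", pe)
  r1 <- fit_bivariate_acc(y, id, sex, relationship, "rA0.999", pe)
  eq <- fit_bivariate_acc(y, id, sex, relationship, "equalVA", pe)
  tests <- rbind(
    cbind(test = "rA=0", lrt_random_effect(free, r0)),
    cbind(test = "rA=0.999", lrt_random_effect(free, r1)),
    cbind(test = "equal_VA", lrt_random_effect(free, eq)))
  list(free = free, rA0 = r0, rA0.999 = r1, equalVA = eq, tests = tests)
}
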
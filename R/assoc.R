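#' Carrier-phenotype association from a 2x2 table
#'
#' Builds the carrier x case table, estimates the odds ratio
#' `OR = (a*d)/(b*c)` (with the Haldane-Anscombe 0.5 correction applied to
#' every cell iff any cell is zero), a 95% Woolf (log-OR Wald) confidence
#' interval, and a p-value: Pearson chi-square when every expected cell
#' count exceeds 5 (the test's validity condition), otherwise Fisher's
#' exact test. The test actually used is recorded.
#'
#' @param n_carrier_case,n_carrier_ctrl,n_noncarrier_case,n_noncarrier_ctrl
#'   the four cell counts (a, b, c, d).
#' @param locus_id optional label carried into the result.
#' @param m_tests Bonferroni family size applied to `p_adjusted`.
#' @return list of class `assoc_result`: `table`, `or_hat`, `ci95`,
#'   `p_raw`, `p_adjusted`, `test`, `m_tests`.
#' @examples
#' assoc_2x2(22, 5, 210, 150)   # crude OR ~ 3.14
#' @export
assoc_2x2 <- function(n_carrier_case, n_carrier_ctrl, n_noncarrier_case,
                      n_noncarrier_ctrl, locus_id = NA_character_,
                      m_tests = 1L) {
  cells <- c(n_carrier_case, n_carrier_ctrl, n_noncarrier_case,
             n_noncarrier_ctrl)
  stopifnot(all(cells >= 0))
  tab <- matrix(cells, nrow = 2, byrow = TRUE,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the 2x2 table")
  }
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  or_hat <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  ci95 <- exp(log(or_hat) + c(-1, 1) * stats::qnorm(0.975) * se)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected > 5)) {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chi2"
  } else {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  }
  p <- min(1, max(0, p))   # fisher.test can exceed 1 by rounding
  structure(list(locus_id = locus_id, table = tab, or_hat = or_hat,
                 ci95 = ci95, p_raw = p,
                 p_adjusted = bonferroni_adjust(p, m_tests),
                 test = test, m_tests = as.integer(m_tests)),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%sOR = %.2f (95%% CI %.2f-%.2f), %s p = %.3g",
              if (!is.na(x$locus_id)) paste0(x$locus_id, ": ") else "",
              x$or_hat, x$ci95[1], x$ci95[2], x$test, x$p_raw))
  if (x$m_tests > 1) cat(sprintf(", Bonferroni (m=%d) p = %.3g", x$m_tests,
                                 x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' Expected carrier cases under the cohort prevalence
#'
#' The number of carriers expected to be cases if carrier status were
#' unrelated to the phenotype: `n_carriers * prevalence`.
#'
#' @param n_carriers number of carriers.
#' @param prevalence phenotype prevalence in the cohort, in \[0, 1\].
#' @return list with `expected` (exact) and `expected_rounded`.
#' @examples
#' expected_carrier_cases(27, 0.60)   # 16.2 -> 16
#' @export
expected_carrier_cases <- function(n_carriers, prevalence) {
  stopifnot(prevalence >= 0, prevalence <= 1, n_carriers >= 0)
  e <- n_carriers * prevalence
  list(expected = e, expected_rounded = as.integer(round(e)))
}

#' Minimum carrier frequency detectable with given power
#'
#' Smallest carrier frequency f at which a two-sided Wald test on the log
#' odds ratio reaches the target power for an effect of size `or_target`,
#' in a cohort of `n` individuals with the given case fraction. The
#' carrier/noncarrier case rates are chosen so the overall case fraction is
#' preserved; expected cell counts under the alternative give the variance
#' of the log-OR estimate, and the critical value uses the variance under
#' the null at the same margins (the standard case-control sample-size
#' formulation). Solved by bisection to 1e-4.
#'
#' @param n cohort size.
#' @param case_fraction overall phenotype prevalence.
#' @param or_target effect size to detect (> 1).
#' @param power target power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @return minimum detectable carrier frequency (fraction).
#' @export
min_detectable_frequency <- function(n, case_fraction, or_target,
                                     power = 0.8, alpha = 0.05) {
  stopifnot(or_target > 1, power > 0, power < 1)
  # power rises with f from 0 and falls again as noncarriers vanish, so
  # locate the attainable range on a coarse grid before bisecting the
  # rising flank
  grid <- seq(1e-4, 1 - 1e-4, length.out = 400)
  pw <- vapply(grid, assoc_power, numeric(1), n = n,
               case_fraction = case_fraction, or = or_target, alpha = alpha)
  hit <- which(pw >= power)
  if (length(hit) == 0) {
    stop("target power unattainable at any carrier frequency <= 1")
  }
  hi <- grid[hit[1]]
  lo <- if (hit[1] > 1) grid[hit[1] - 1] else 1e-4
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (assoc_power(mid, n, case_fraction, or_target, alpha) >= power) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}

# Wald power for the carrier association test at carrier frequency f.
assoc_power <- function(f, n, case_fraction, or, alpha = 0.05) {
  g <- function(p0) {
    o0 <- p0 / (1 - p0)
    p1 <- or * o0 / (1 + or * o0)
    f * p1 + (1 - f) * p0 - case_fraction
  }
  p0 <- stats::uniroot(g, c(1e-9, 1 - 1e-9))$root
  o0 <- p0 / (1 - p0)
  p1 <- or * o0 / (1 + or * o0)
  a <- n * f * p1; b <- n * f * (1 - p1)
  c_ <- n * (1 - f) * p0; d <- n * (1 - f) * (1 - p0)
  v_alt <- 1 / a + 1 / b + 1 / c_ + 1 / d
  a0 <- n * f * case_fraction; b0 <- n * f * (1 - case_fraction)
  c0 <- n * (1 - f) * case_fraction; d0 <- n * (1 - f) * (1 - case_fraction)
  v_null <- 1 / a0 + 1 / b0 + 1 / c0 + 1 / d0
  z <- stats::qnorm(1 - alpha / 2)
  lo <- log(or)
  stats::pnorm((lo - z * sqrt(v_null)) / sqrt(v_alt)) +
    stats::pnorm((-lo - z * sqrt(v_null)) / sqrt(v_alt))
}

#' Kinship-aware carrier association
#'
#' Logistic regression of a binary phenotype on carrier status with age and
#' sex as covariates, adjusted for relatedness by including the leading
#' eigenvectors of the kinship matrix (diagonal removed) as additional
#' fixed effects — as many as needed to capture 80% of the off-diagonal
#' kinship variance, at most `max_vectors`. This is a fixed-effect
#' approximation to a full logistic mixed model with a kinship random
#' effect. On (quasi-)separation the fit falls back to Firth-penalized
#' logistic regression, flagged in the result.
#'
#' @param phenotype logical/0-1 outcome per sample.
#' @param carrier logical/0-1 carrier status per sample (must vary).
#' @param age,sex covariates (`sex` coded `"M"`/`"F"` or 0/1).
#' @param kin a [king_kinship()] matrix aligned with the samples.
#' @param max_vectors cap on the number of kinship eigenvectors (default 10).
#' @param m_tests Bonferroni family size.
#' @param locus_id optional label.
#' @return an `assoc_result` with `test` `"kinship_adjusted"` (or
#'   `"kinship_adjusted_firth"`), plus `n_eigenvectors` and `coef`.
#' @export
kinship_adjusted_assoc <- function(phenotype, carrier, age, sex, kin,
                                   max_vectors = 10L, m_tests = 1L,
                                   locus_id = NA_character_) {
  y <- as.integer(as.logical(phenotype))
  x <- as.integer(as.logical(carrier))
  if (length(unique(x)) < 2) stop("carrier indicator has no variation")
  if (anyNA(y) || anyNA(x) || anyNA(age)) stop("incomplete inputs")
  sexn <- if (is.numeric(sex)) sex else as.integer(sex == "M")
  K <- as.matrix(kin)
  diag(K) <- 0
  ev <- eigen(K, symmetric = TRUE)
  lam2 <- ev$values^2
  X_extra <- NULL
  n_vec <- 0L
  if (sum(lam2) > 1e-12) {
    ord <- order(lam2, decreasing = TRUE)
    cum <- cumsum(lam2[ord]) / sum(lam2)
    n_vec <- min(max_vectors, which(cum >= 0.8)[1])
    X_extra <- ev$vectors[, ord[seq_len(n_vec)], drop = FALSE]
    colnames(X_extra) <- paste0("kinPC", seq_len(n_vec))
  }
  df <- data.frame(y = y, carrier = x, age = as.numeric(age), sex = sexn)
  if (!is.null(X_extra)) df <- cbind(df, X_extra)
  fml <- stats::as.formula(paste("y ~", paste(setdiff(names(df), "y"),
                                              collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) ||
    abs(stats::coef(fit)["carrier"]) > 15
  test <- "kinship_adjusted"
  if (sep) {
    X <- stats::model.matrix(fml, df)
    fit_coef <- firth_logistic(X, y)
    beta <- fit_coef$coef["carrier"]
    se <- fit_coef$se["carrier"]
    test <- "kinship_adjusted_firth"
    coefs <- fit_coef$coef
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm["carrier", "Estimate"]
    se <- sm["carrier", "Std. Error"]
    coefs <- stats::coef(fit)
  }
  or_hat <- exp(beta)
  ci95 <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(locus_id = locus_id, table = NULL, or_hat = or_hat,
                 ci95 = ci95, p_raw = p,
                 p_adjusted = bonferroni_adjust(p, m_tests), test = test,
                 m_tests = as.integer(m_tests), n_eigenvectors = n_vec,
                 coef = coefs),
            class = "assoc_result")
}

# Firth-penalized logistic regression via modified IRLS (Jeffreys prior);
# used only as the separation fallback.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XW <- X * w
    I <- crossprod(X, XW)
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(Iinv %*% U)
    delta <- pmin(pmax(delta, -5), 5)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  I <- crossprod(X, X * (p * (1 - p)))
  se <- sqrt(diag(solve(I)))
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se)
}
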
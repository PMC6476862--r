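#' Univariate Gaussian mixture fit by EM
#'
#' Fits a k-component normal mixture to the onset distribution by
#' expectation-maximization with multiple random restarts, keeping the best
#' log-likelihood. Component standard deviations are floored at 1% of the
#' sample standard deviation to prevent degenerate spikes on single
#' observations. The log-likelihood is asserted nondecreasing at every
#' iteration. Components are reported sorted by mean (label-swap
#' identifiability convention). `k = 1` is the closed-form MLE, no EM.
#'
#' @param y numeric vector (n >= 2k).
#' @param k number of components (>= 1).
#' @param n_starts random restarts (default 20).
#' @param seed integer seed (per-start substreams).
#' @param max_iter,tol EM stopping rule.
#' @return list of class `mixture_fit`: `k`, `weights`, `means`, `sds`,
#'   `loglik`, `bic`, `responsibilities`, `converged`, `n_iter`, `seed`.
#' @export
fit_mixture <- function(y, k, n_starts = 20L, seed = 1L, max_iter = 1000L,
                        tol = 1e-8) {
  n <- length(y)
  if (k < 1) stop("k must be >= 1")
  if (n < 2 * k) stop("need n >= 2k observations")
  if (k == 1) {
    mu <- mean(y); s <- sqrt(mean((y - mu)^2))
    ll <- sum(dnorm(y, mu, s, log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, sds = s,
                          loglik = ll, bic = -2 * ll + 2 * log(n),
                          responsibilities = matrix(1, n, 1),
                          converged = TRUE, n_iter = 0L, seed = seed),
                     class = "mixture_fit"))
  }
  sd_floor <- 0.01 * sd(y)
  best <- NULL
  for (s0 in seq_len(n_starts)) {
    res <- with_seed(substream(seed, 300L + s0), {
      mu <- sample(y, k)
      sig <- rep(sd(y), k)
      w <- rep(1 / k, k)
      ll_old <- -Inf
      converged <- FALSE
      R <- NULL
      for (it in seq_len(max_iter)) {
        logd <- vapply(seq_len(k), function(j)
          log(w[j]) + dnorm(y, mu[j], sig[j], log = TRUE), numeric(n))
        mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
        lse <- mx + log(rowSums(exp(logd - mx)))
        ll <- sum(lse)
        if (ll < ll_old - 1e-6) stop("EM log-likelihood decreased; internal error")
        R <- exp(logd - lse)
        if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
        ll_old <- ll
        nk <- colSums(R)
        w <- nk / n
        mu <- colSums(R * y) / nk
        sig <- sqrt(colSums(R * (outer(y, mu, "-"))^2) / nk)
        sig <- pmax(sig, sd_floor)
      }
      list(ll = ll, w = w, mu = mu, sig = sig, R = R, converged = converged,
           n_iter = it)
    })
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  ord <- order(best$mu)
  structure(list(k = as.integer(k), weights = best$w[ord],
                 means = best$mu[ord], sds = best$sig[ord],
                 loglik = best$ll,
                 bic = -2 * best$ll + (3 * k - 1) * log(n),
                 responsibilities = best$R[, ord, drop = FALSE],
                 converged = best$converged, n_iter = best$n_iter,
                 seed = seed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: k=%d, loglik=%.2f, BIC=%.2f%s\n", x$k, x$loglik,
              x$bic, if (x$converged) "" else " (not converged)"))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Choose the mixture component count by BIC
#'
#' Fits [fit_mixture()] for each candidate `k` and returns all fits plus
#' the BIC-selected one. The raw log-likelihoods are reported alongside:
#' they increase mechanically with k and cannot select it on their own,
#' which is why an explicitly penalized criterion is used.
#'
#' @param y numeric vector.
#' @param ks candidate component counts (default 1:3).
#' @inheritParams fit_mixture
#' @return list: `fits` (by k), `bic` (named), `best_k`, `best`.
#' @export
select_mixture <- function(y, ks = 1:3, n_starts = 20L, seed = 1L) {
  fits <- lapply(ks, function(k) fit_mixture(y, k, n_starts, seed))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  names(bic) <- names(fits) <- paste0("k", ks)
  best <- which.min(bic)
  list(fits = fits, bic = bic, best_k = ks[best], best = fits[[best]])
}

#' Early/late onset dichotomization
#'
#' Labels onset ages below the cutoff "early" and at or above it "late"
#' (the boundary value is late, matching an inclusive >= convention),
#' summarizes both groups and, when both are non-empty with variation,
#' compares them with a pooled-variance two-sample t test.
#'
#' @param adaoo onset ages (years).
#' @param cutoff dichotomization age (default 48).
#' @return list: `labels` (factor early/late), `summary` (per-group n,
#'   mean, sd), `test` (t, df, p, mean difference CI) or NULL if a group is
#'   empty.
#' @export
dichotomize_onset <- function(adaoo, cutoff = 48) {
  labels <- factor(ifelse(adaoo < cutoff, "early", "late"),
                   levels = c("early", "late"))
  smry <- do.call(rbind, lapply(levels(labels), function(l) {
    v <- adaoo[labels == l]
    data.frame(group = l, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
  test <- NULL
  if (all(smry$n >= 2)) {
    tt <- t.test(adaoo[labels == "late"], adaoo[labels == "early"],
                 var.equal = TRUE)
    test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, diff = unname(diff(rev(tt$estimate))),
                 ci = as.numeric(tt$conf.int))
  }
  list(labels = labels, summary = smry, test = test, cutoff = cutoff)
}

#' Descriptive group comparisons of the onset distribution
#'
#' The comparisons reported alongside the association analysis: onset by
#' sex or by a carrier flag (two-sample t, pooled variance by default so
#' the degrees of freedom follow the n1 + n2 - 2 accounting; Welch by
#' flag), onset across education groups (one-way ANOVA F), and onset on
#' years of education (simple linear regression slope, R-squared, p).
#'
#' @param phenotypes `phenotype_table`.
#' @param design one of `"sex"`, `"edu_group"`, `"edu_years"`, `"carrier"`.
#' @param carrier logical vector (required for `design = "carrier"`).
#' @param var_equal pooled (TRUE, default) or Welch t test.
#' @return one-row data.frame: test, statistic, df, p, effect columns
#'   (mean difference + CI, or F, or slope + R2).
#' @export
group_tests <- function(phenotypes, design = c("sex", "edu_group",
                                               "edu_years", "carrier"),
                        carrier = NULL, var_equal = TRUE) {
  design <- match.arg(design)
  y <- phenotypes$adaoo
  if (design %in% c("sex", "carrier")) {
    g <- if (design == "sex") phenotypes$sex else {
      if (is.null(carrier)) stop("carrier flag required")
      factor(ifelse(carrier, "carrier", "non-carrier"))
    }
    if (nlevels(droplevels(g)) < 2 || min(table(g)) < 2)
      stop("two-sample test needs >= 2 observations per group")
    if (all(tapply(y, g, sd) == 0))
      return(data.frame(test = "two-sample t", statistic = 0,
                        df = length(y) - 2, p = 1, estimate = 0,
                        ci_low = 0, ci_high = 0, note = "degenerate variance"))
    tt <- t.test(y ~ g, var.equal = var_equal)
    # estimate on the same scale as conf.int: first group minus second
    data.frame(test = "two-sample t", statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               estimate = unname(diff(rev(tt$estimate))),
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               note = NA_character_)
  } else if (design == "edu_group") {
    g <- droplevels(factor(phenotypes$edu_group, ordered = FALSE))
    if (nlevels(g) < 2 || min(table(g)) < 2)
      stop("ANOVA needs >= 2 observations per group")
    av <- anova(aov(y ~ g))
    data.frame(test = "one-way ANOVA", statistic = av$`F value`[1],
               df = av$Df[1], p = av$`Pr(>F)`[1],
               estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               note = sprintf("df2 = %d", av$Df[2]))
  } else {
    x <- phenotypes$edu_years
    if (length(y) < 3) stop("regression needs >= 3 points")
    if (sd(x) == 0) stop("regression predictor is constant")
    fit <- summary(lm(y ~ x))
    data.frame(test = "linear regression",
               statistic = fit$coefficients["x", "t value"],
               df = fit$df[2], p = fit$coefficients["x", "Pr(>|t|)"],
               estimate = fit$coefficients["x", "Estimate"],
               ci_low = NA_real_, ci_high = NA_real_,
               note = sprintf("R2 = %.4f", fit$r.squared))
  }
}
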
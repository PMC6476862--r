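#' Eigendecomposition of a kinship matrix
#'
#' Precomputes the spectral decomposition used by the single-ratio profiling
#' in [reml_fit()]. Doing this once per scan (rather than once per marker)
#' is what keeps the per-marker cost linear.
#'
#' @param K a `kinship_matrix` (PSD).
#' @return list with rotation `U` (eigenvectors) and eigenvalues `s`.
#' @export
eigen_kinship <- function(K) {
  ev <- eigen(unclass(K), symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1)) {
    stop("kinship matrix is not positive semidefinite")
  }
  list(U = ev$vectors, s = pmax(ev$values, 0))
}

# Profiled (restricted) log-likelihood machinery for the one-random-effect
# model y ~ N(X b, sigma_e2 (lambda K + I)), lambda = sigma_g2 / sigma_e2.
# After rotation by U', the covariance is diagonal with weights
# d_i = lambda s_i + 1, and each evaluation is a weighted least squares.
.profile_eval <- function(loglam, ystar, Xstar, s, method) {
  lam <- exp(loglam)
  d <- lam * s + 1
  w <- 1 / sqrt(d)
  Xw <- Xstar * w
  yw <- ystar * w
  qr_ <- qr(Xw)
  beta <- qr.coef(qr_, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  n <- length(yw); p <- qr_$rank
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    R <- qr.R(qr_)
    ldXX <- 2 * sum(log(abs(diag(R))))
    ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(d)) + ldXX)
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * sigma2) + 1) + sum(log(d)))
  }
  list(ll = ll, beta = beta, sigma2 = sigma2, lam = lam, qr = qr_, d = d)
}

#' Fit a kinship linear mixed model by REML (or ML)
#'
#' Fits y = X b + u + e with u ~ N(0, sigma_g2 K), e ~ N(0, sigma_e2 I), by
#' profiling the restricted likelihood over the single variance ratio
#' lambda = sigma_g2 / sigma_e2 after a spectral decomposition of K
#' (EMMA-style). Coefficients and standard errors are generalized least
#' squares at the optimum; p-values are Wald t-tests with n - rank(X)
#' degrees of freedom. With both variance components supplied the ratio is
#' fixed and the fit is the exact GLS solution at those components.
#'
#' @param y numeric response (years).
#' @param X fixed-effect design matrix (full column rank; include the
#'   intercept).
#' @param K `kinship_matrix` aligned to `y` rows, or NULL with `eigen_K`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param eigen_K optional precomputed [eigen_kinship()] result.
#' @param sigma_g2,sigma_e2 optionally fix the variance components.
#' @param interval search interval for log(lambda).
#' @return list of class `lmem_fit`: `beta`, `se_beta`, `p_values`,
#'   `sigma_g2`, `sigma_e2`, `pseudo_h2`, `loglik`, `method`, `n_used`,
#'   `df_residual`.
#' @export
reml_fit <- function(y, X, K = NULL, method = c("REML", "ML"), eigen_K = NULL,
                     sigma_g2 = NULL, sigma_e2 = NULL,
                     interval = c(-12, 12)) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y are not aligned")
  if (is.null(eigen_K)) {
    if (is.null(K)) stop("supply K or eigen_K")
    if (nrow(K) != n) stop("kinship matrix and y are not aligned")
    eigen_K <- eigen_kinship(K)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  ystar <- drop(crossprod(eigen_K$U, y))
  Xstar <- crossprod(eigen_K$U, X)
  fixed <- !is.null(sigma_g2) && !is.null(sigma_e2)
  if (fixed) {
    if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
    loglam <- log(max(sigma_g2, 1e-300) / sigma_e2)
    best <- .profile_eval(loglam, ystar, Xstar, eigen_K$s, method)
    best$sigma2 <- sigma_e2  # respect the supplied scale
  } else {
    opt <- optimize(function(l) .profile_eval(l, ystar, Xstar, eigen_K$s, method)$ll,
                    interval = interval, maximum = TRUE, tol = 1e-8)
    best <- .profile_eval(opt$maximum, ystar, Xstar, eigen_K$s, method)
    # boundary check: sigma_g2 = 0 (plain OLS split) can beat an interior optimum
    b0 <- .profile_eval(interval[1], ystar, Xstar, eigen_K$s, method)
    if (b0$ll > best$ll) best <- b0
    if (best$lam <= exp(interval[1]) * 1.01) best$lam <- 0
  }
  p <- ncol(X)
  R <- qr.R(best$qr)
  XtVinvX_inv <- chol2inv(R[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(best$sigma2 * diag(XtVinvX_inv))
  beta <- best$beta
  names(beta) <- names(se) <- colnames(X)
  tval <- beta / se
  pv <- 2 * pt(-abs(tval), df = n - p)
  sg2 <- best$lam * best$sigma2
  structure(list(beta = beta, se_beta = se, t_values = tval, p_values = pv,
                 sigma_g2 = if (fixed) sigma_g2 else sg2,
                 sigma_e2 = best$sigma2,
                 pseudo_h2 = if (fixed) sigma_g2 / (sigma_g2 + sigma_e2)
                             else sg2 / (sg2 + best$sigma2),
                 loglik = best$ll, method = method,
                 n_used = n, df_residual = n - p),
            class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat(sprintf("lmem_fit (%s): n=%d, sigma_g2=%.3f, sigma_e2=%.3f, pseudo-h2=%.3f\n",
              x$method, x$n_used, x$sigma_g2, x$sigma_e2, x$pseudo_h2))
  print(data.frame(beta = x$beta, se = x$se_beta, p = x$p_values))
  invisible(x)
}

# Build the covariate design from a phenotype table.
covariate_design <- function(phenotypes, covariates = c("sex", "edu_years")) {
  X <- matrix(1, nrow(phenotypes), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (cv == "sex") {
      X <- cbind(X, sexmale = as.numeric(phenotypes$sex == "male"))
    } else if (cv == "edu_years") {
      X <- cbind(X, edu_years = phenotypes$edu_years)
    } else if (cv == "edu_group") {
      mm <- model.matrix(~ edu_group, droplevels(
        data.frame(edu_group = factor(phenotypes$edu_group, ordered = FALSE))))
      X <- cbind(X, mm[, -1, drop = FALSE])
    } else stop("unknown covariate: ", cv)
  }
  X
}

#' Single-locus kinship-corrected association scan
#'
#' For each marker: applies the genetic coding, drops samples missing at
#' that marker only, and fits the mixed model
#' adaoo ~ covariates + marker with the kinship random effect. Markers whose
#' coded genotype is constant in the analyzed subsample are reported with NA
#' statistics and a reason rather than failing the scan. Benjamini-Hochberg
#' adjusted p-values are attached; an extreme-value adjusted column is added
#' when `n_perm > 0` (see [evt_adjust()]).
#'
#' @param genotypes QC-passed `genotype_matrix`.
#' @param phenotypes `phenotype_table`.
#' @param K `kinship_matrix`.
#' @param coding genetic coding for all markers.
#' @param orientation `"minor"` (default) or `"major"` allele reference.
#' @param covariates character vector, any of `"sex"`, `"edu_years"`,
#'   `"edu_group"`.
#' @param n_perm permutations for the extreme-value correction (0 = skip).
#' @param seed seed for the permutation stream.
#' @return data.frame of class `scan_result`, one row per marker: marker
#'   metadata, `ma_freq`, `call_rate`, `coding`, `n_used`, `beta`, `se`,
#'   `p`, `p_fdr` (and `p_evt`), `reason` for NA rows.
#' @export
single_locus_scan <- function(genotypes, phenotypes, K,
                              coding = c("dominant", "additive", "recessive"),
                              orientation = "minor",
                              covariates = c("sex", "edu_years"),
                              n_perm = 0L, seed = 1L) {
  coding <- match.arg(coding)
  al <- align_samples(genotypes, phenotypes, K)
  if (!ncol(al$genotypes$dosage)) stop("no markers passed QC; nothing to scan")
  y <- al$phenotypes$adaoo
  X0 <- covariate_design(al$phenotypes, covariates)
  eigen_full <- eigen_kinship(al$K)
  fr <- estimate_frequencies(al$genotypes)
  m <- ncol(al$genotypes$dosage)
  res <- data.frame(id = al$genotypes$markers$id,
                    chrom = al$genotypes$markers$chrom,
                    pos = al$genotypes$markers$pos,
                    gene = al$genotypes$markers$gene,
                    ref_alt = paste0(al$genotypes$markers$ref, "/",
                                     al$genotypes$markers$alt),
                    ma_freq = fr$maf, call_rate = fr$call_rate,
                    coding = coding, n_used = NA_integer_,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    d <- al$genotypes$dosage[, j]
    keep <- !is.na(d)
    g <- code_genotype(d[keep], coding, orientation)
    res$n_used[j] <- sum(keep)
    if (length(unique(g)) < 2) {
      res$reason[j] <- "coded genotype constant in analyzed subsample"
      next
    }
    X <- cbind(X0[keep, , drop = FALSE], marker = g)
    fit <- if (all(keep)) {
      reml_fit(y, X, eigen_K = eigen_full)
    } else {
      reml_fit(y[keep], X, kinship_matrix(unclass(al$K)[keep, keep, drop = FALSE]))
    }
    res$beta[j] <- fit$beta["marker"]
    res$se[j] <- fit$se_beta["marker"]
    res$p[j] <- fit$p_values["marker"]
  }
  res$p_fdr <- fdr_adjust(res$p)
  if (n_perm > 0) {
    ev <- evt_adjust(al$genotypes, al$phenotypes, al$K, coding = coding,
                     orientation = orientation, covariates = covariates,
                     n_perm = n_perm, seed = seed)
    res$p_evt <- pmax(ev$p_evt, res$p)
    attr(res, "evt") <- ev[c("gev_converged", "fallback")]
  }
  class(res) <- c("scan_result", "data.frame")
  attr(res, "covariates") <- covariates
  attr(res, "orientation") <- orientation
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1, monotone in rank. NA entries are
#' preserved and excluded from the ranking.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted vector of the same length.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# ---- extreme-value multiple-testing correction ----

# Negative log-likelihood of the generalized extreme value distribution.
.gev_nll <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
  z <- (x - mu) / sigma
  if (abs(xi) < 1e-8) {
    sum(log(sigma) + z + exp(-z))
  } else {
    t <- 1 + xi * z
    if (any(t <= 0)) return(1e10)
    sum(log(sigma) + (1 + 1 / xi) * log(t) + t^(-1 / xi))
  }
}

# Upper-tail probability of a fitted GEV.
.gev_sf <- function(q, mu, sigma, xi) {
  z <- (q - mu) / sigma
  if (abs(xi) < 1e-8) return(1 - exp(-exp(-z)))
  t <- 1 + xi * z
  if (t <= 0) return(if (xi > 0) 1 else 0)
  1 - exp(-t^(-1 / xi))
}

#' Extreme-value multiple-testing correction
#'
#' Family-wise adjusted p-values from the permutation distribution of the
#' scan's maximum statistic. The phenotype is whitened under the
#' covariates-only mixed model, residuals are permuted, and the maximum
#' absolute marker t-statistic is recorded per permutation; a generalized
#' extreme-value distribution is fitted to the maxima by maximum likelihood
#' and each observed statistic's adjusted p is its fitted upper-tail
#' probability. When the GEV fit fails to converge the empirical add-one
#' permutation p is used and the output is flagged.
#'
#' @param genotypes `genotype_matrix` (missing dosages mean-imputed here).
#' @param phenotypes `phenotype_table`.
#' @param K `kinship_matrix`.
#' @param coding,orientation,covariates as in [single_locus_scan()].
#' @param n_perm number of permutations (>= 200).
#' @param seed integer seed.
#' @return list: `p_evt` (per marker), `stat_obs`, `maxima`,
#'   `gev_converged`, `fallback`, fitted GEV parameters.
#' @export
evt_adjust <- function(genotypes, phenotypes, K, coding = "dominant",
                       orientation = "minor",
                       covariates = c("sex", "edu_years"),
                       n_perm = 1000L, seed = 1L) {
  if (n_perm < 200) stop("n_perm must be >= 200")
  al <- align_samples(genotypes, phenotypes, K)
  y <- al$phenotypes$adaoo
  X0 <- covariate_design(al$phenotypes, covariates)
  ek <- eigen_kinship(al$K)
  null_fit <- reml_fit(y, X0, eigen_K = ek)
  lam <- if (null_fit$sigma_e2 > 0) null_fit$sigma_g2 / null_fit$sigma_e2 else 0
  w <- 1 / sqrt(lam * ek$s + 1)
  yt <- drop(crossprod(ek$U, y)) * w
  Xt <- crossprod(ek$U, X0) * w
  G <- apply(al$genotypes$dosage, 2, function(d) {
    g <- code_genotype(d, coding, orientation)
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  Gt <- crossprod(ek$U, G) * w
  qx <- qr(Xt)
  ry <- qr.resid(qx, yt)
  RG <- qr.resid(qx, Gt)
  gnorm <- colSums(RG^2)
  ok <- gnorm > 1e-10
  n <- length(y); p0 <- ncol(Xt)
  tstat <- function(r) {
    b <- as.vector(crossprod(RG, r)) / gnorm
    rss <- sum(r^2) - b^2 * gnorm
    abs(b) / sqrt(rss / (n - p0 - 1) / gnorm)
  }
  stat_obs <- tstat(ry)
  stat_obs[!ok] <- NA
  maxima <- with_seed(substream(seed, 71L), {
    vapply(seq_len(n_perm), function(b) {
      max(tstat(sample(ry))[ok], na.rm = TRUE)
    }, numeric(1))
  })
  emp <- vapply(stat_obs, function(s) {
    if (is.na(s)) NA_real_ else (1 + sum(maxima >= s)) / (n_perm + 1)
  }, numeric(1))
  start <- c(mean(maxima), log(sd(maxima) * sqrt(6) / pi), 0.05)
  fit <- tryCatch(optim(start, .gev_nll, x = maxima, method = "Nelder-Mead",
                        control = list(maxit = 2000)),
                  error = function(e) NULL)
  converged <- !is.null(fit) && fit$convergence == 0 && is.finite(fit$value)
  if (converged) {
    mu <- fit$par[1]; sigma <- exp(fit$par[2]); xi <- fit$par[3]
    p_evt <- vapply(stat_obs, function(s) {
      if (is.na(s)) NA_real_ else .gev_sf(s, mu, sigma, xi)
    }, numeric(1))
    pars <- c(mu = mu, sigma = sigma, xi = xi)
  } else {
    warning("GEV fit did not converge; falling back to empirical permutation p")
    p_evt <- emp
    pars <- c(mu = NA, sigma = NA, xi = NA)
  }
  list(p_evt = pmin(pmax(p_evt, 0), 1), p_empirical = emp,
       stat_obs = stat_obs, maxima = maxima,
       gev_converged = converged, fallback = !converged, gev_par = pars)
}

#' Stepwise multi-locus mixed-model selection
#'
#' Forward/backward selection of markers into a joint kinship mixed model
#' for the onset trait, with up to `max_steps` forward additions. Each step
#' adds the candidate that most improves the selection criterion (extended
#' BIC on the maximum-likelihood fit, eBIC = -2 logLik + k log n +
#' 2 gamma log C(m, k)) if any improves it, then removes any included
#' marker whose exclusion improves the criterion. Candidates collinear with
#' the current design are skipped (of two duplicated markers only the
#' earlier one can enter). Missing coded dosages are mean-imputed for the
#' joint model. The final model is refitted by REML for coefficients and
#' standard errors, and per-marker variance explained is computed
#' sequentially in selection order (see [pve()]).
#'
#' @param genotypes QC-passed `genotype_matrix`.
#' @param phenotypes `phenotype_table`.
#' @param K `kinship_matrix`.
#' @param coding,orientation,covariates as in [single_locus_scan()].
#' @param max_steps maximum forward additions (default 10).
#' @param criterion `"ebic"` (default) or `"bic"` (gamma = 0).
#' @param gamma eBIC genome-size penalty weight in [0, 1].
#' @return list of class `multilocus_model`: `selected` data.frame (marker,
#'   order, beta, se, p, pve), `total_pve`, `sigma_g2`, `sigma_e2`,
#'   `pseudo_h2`, `trace` (one row per attempted move), `criterion`,
#'   `n_used`, `coding`.
#' @export
multilocus_select <- function(genotypes, phenotypes, K,
                              coding = c("dominant", "additive", "recessive"),
                              orientation = "minor",
                              covariates = c("sex", "edu_years"),
                              max_steps = 10L, criterion = c("ebic", "bic"),
                              gamma = 0.5) {
  coding <- match.arg(coding)
  criterion <- match.arg(criterion)
  if (criterion == "bic") gamma <- 0
  al <- align_samples(genotypes, phenotypes, K)
  if (!ncol(al$genotypes$dosage)) stop("no markers passed QC; nothing to select from")
  y <- al$phenotypes$adaoo
  n <- length(y)
  X0 <- covariate_design(al$phenotypes, covariates)
  ek <- eigen_kinship(al$K)
  G <- apply(al$genotypes$dosage, 2, function(d) {
    g <- code_genotype(d, coding, orientation)
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  colnames(G) <- al$genotypes$markers$id
  m <- ncol(G)
  usable <- which(apply(G, 2, function(g) length(unique(g)) > 1))
  crit_of <- function(sel) {
    X <- cbind(X0, G[, sel, drop = FALSE])
    if (qr(X)$rank < ncol(X)) return(list(crit = Inf, fit = NULL))
    fit <- reml_fit(y, X, eigen_K = ek, method = "ML")
    k <- length(sel)
    list(crit = -2 * fit$loglik + k * log(n) + 2 * gamma * lchoose(m, k),
         fit = fit)
  }
  sel <- integer(0)
  cur <- crit_of(sel)
  trace <- list()
  steps <- 0L
  repeat {
    if (steps >= max_steps) break
    # forward: best admissible addition
    cand <- setdiff(usable, sel)
    best_j <- NA_integer_; best <- cur
    for (j in cand) {
      trial <- crit_of(c(sel, j))
      if (trial$crit < best$crit - 1e-8) { best <- trial; best_j <- j }
    }
    if (is.na(best_j)) break
    sel <- c(sel, best_j)
    cur <- best
    steps <- steps + 1L
    trace[[length(trace) + 1]] <- data.frame(
      step = steps, action = "add", marker = colnames(G)[best_j],
      criterion = cur$crit, stringsAsFactors = FALSE)
    # backward: drop anything that no longer earns its place
    repeat {
      best_drop <- NA_integer_; bestd <- cur
      for (j in sel) {
        trial <- crit_of(setdiff(sel, j))
        if (trial$crit < bestd$crit - 1e-8) { bestd <- trial; best_drop <- j }
      }
      if (is.na(best_drop)) break
      sel <- setdiff(sel, best_drop)
      cur <- bestd
      trace[[length(trace) + 1]] <- data.frame(
        step = steps, action = "drop", marker = colnames(G)[best_drop],
        criterion = cur$crit, stringsAsFactors = FALSE)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(), marker = character(),
               criterion = numeric())
  if (length(sel)) {
    X <- cbind(X0, G[, sel, drop = FALSE])
    fit <- reml_fit(y, X, eigen_K = ek, method = "REML")
    idx <- ncol(X0) + seq_along(sel)
    pv <- pve_sequential(y, X0, G[, sel, drop = FALSE])
    selected <- data.frame(
      marker = colnames(G)[sel], order = seq_along(sel), coding = coding,
      beta = unname(fit$beta[idx]), se = unname(fit$se_beta[idx]),
      p = unname(fit$p_values[idx]), pve = pv$per_marker,
      stringsAsFactors = FALSE)
    total_pve <- pv$total
  } else {
    fit <- reml_fit(y, X0, eigen_K = ek, method = "REML")
    selected <- data.frame(marker = character(), order = integer(),
                           coding = character(), beta = numeric(),
                           se = numeric(), p = numeric(), pve = numeric())
    total_pve <- 0
  }
  structure(list(selected = selected, total_pve = total_pve,
                 sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 pseudo_h2 = fit$pseudo_h2, trace = trace,
                 criterion = list(name = criterion, gamma = gamma,
                                  value = cur$crit),
                 n_used = n, coding = coding, covariates = covariates,
                 fit = fit),
            class = "multilocus_model")
}

#' @export
print.multilocus_model <- function(x, ...) {
  cat(sprintf("multilocus_model (%s, %s): %d markers, total PVE %.3f, pseudo-h2 %.3f\n",
              x$coding, x$criterion$name, nrow(x$selected), x$total_pve,
              x$pseudo_h2))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

# Sequential variance-explained accounting: covariates first, then markers
# in selection order; shared variance is credited to earlier terms.
pve_sequential <- function(y, X0, Gsel) {
  ss_tot <- sum((y - mean(y))^2)
  rss <- numeric(ncol(Gsel) + 1)
  X <- X0
  rss0 <- sum(qr.resid(qr(X), y)^2)
  rss[1] <- rss0
  for (j in seq_len(ncol(Gsel))) {
    X <- cbind(X, Gsel[, j])
    rss[j + 1] <- sum(qr.resid(qr(X), y)^2)
  }
  per <- pmax(-diff(rss), 0) / ss_tot
  list(per_marker = per, total = sum(per))
}

#' Proportion of onset variance explained by a fitted multi-locus model
#'
#' Per-marker PVE is computed sequentially in selection order on the
#' covariate-adjusted phenotype, so variance shared between markers is
#' credited to the earlier-selected one; the total is the R-squared-type
#' gain of the joint genetic terms over the covariates-only model. All
#' components are nonnegative and the total is at most 1.
#'
#' @param model a `multilocus_model`.
#' @param genotypes,phenotypes the inputs the model was fitted on.
#' @return list: `per_marker` (named, selection order), `total`.
#' @export
pve <- function(model, genotypes, phenotypes) {
  stopifnot(inherits(model, "multilocus_model"))
  if (!nrow(model$selected)) return(list(per_marker = numeric(0), total = 0))
  al <- align_samples(genotypes, phenotypes)
  y <- al$phenotypes$adaoo
  X0 <- covariate_design(al$phenotypes, model$covariates)
  G <- vapply(model$selected$marker, function(id) {
    d <- al$genotypes$dosage[, id]
    g <- code_genotype(d, model$coding)
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  }, numeric(length(y)))
  pv <- pve_sequential(y, X0, G)
  list(per_marker = setNames(pv$per_marker, model$selected$marker),
       total = pv$total)
}

#' Covariate-specificity (heterogeneity) test for a marker effect
#'
#' Likelihood-ratio test for whether a marker's effect on onset differs by
#' sex or education group: the mixed model with marker-by-group interaction
#' terms is compared to the model with the marker main effect only (both by
#' ML, same kinship). Group levels with no coded-genotype variation (e.g. no
#' minor-allele carriers) are excluded, reducing the degrees of freedom;
#' the df actually used is reported.
#'
#' @param marker marker id.
#' @param grouping `"sex"` or `"edu_group"`.
#' @param genotypes,phenotypes,K aligned inputs.
#' @param coding,orientation,covariates as elsewhere.
#' @return data.frame: marker, grouping, chi2, df, p, n_groups_used, note.
#' @export
heterogeneity_test <- function(marker, grouping = c("sex", "edu_group"),
                               genotypes, phenotypes, K,
                               coding = "dominant", orientation = "minor",
                               covariates = c("sex", "edu_years")) {
  grouping <- match.arg(grouping)
  al <- align_samples(genotypes, phenotypes, K)
  d <- al$genotypes$dosage[, marker]
  keep <- !is.na(d)
  g <- code_genotype(d[keep], coding, orientation)
  grp <- droplevels(factor(al$phenotypes[[grouping]][keep], ordered = FALSE))
  y <- al$phenotypes$adaoo[keep]
  # keep only group levels in which the coded marker varies
  ok_lvl <- vapply(levels(grp), function(l) length(unique(g[grp == l])) > 1,
                   logical(1))
  note <- NA_character_
  if (!all(ok_lvl)) {
    note <- sprintf("levels without carrier variation excluded: %s",
                    paste(levels(grp)[!ok_lvl], collapse = ", "))
    sub <- grp %in% levels(grp)[ok_lvl]
    y <- y[sub]; g <- g[sub]; grp <- droplevels(grp[sub])
    keep[keep] <- sub
  }
  if (nlevels(grp) < 2) {
    return(data.frame(marker = marker, grouping = grouping, chi2 = NA_real_,
                      df = NA_integer_, p = NA_real_,
                      n_groups_used = nlevels(grp),
                      note = "fewer than 2 usable groups",
                      stringsAsFactors = FALSE))
  }
  Ksub <- kinship_matrix(unclass(al$K)[keep, keep, drop = FALSE])
  X0 <- covariate_design(al$phenotypes[keep, , drop = FALSE], covariates)
  Gm <- model.matrix(~ grp)[, -1, drop = FALSE]
  # avoid duplicating a sex covariate column when grouping == "sex"
  X_base <- cbind(X0, Gm[, setdiff(colnames(Gm), colnames(X0)), drop = FALSE])
  X_base <- X_base[, !duplicated(lapply(seq_len(ncol(X_base)),
                                        function(i) X_base[, i])), drop = FALSE]
  Xr <- cbind(X_base, marker = g)
  inter <- model.matrix(~ 0 + grp)[, -1, drop = FALSE] * g
  colnames(inter) <- paste0("marker:", levels(grp)[-1])
  Xf <- cbind(Xr, inter)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    est <- qf$rank - qr(Xr)$rank
    if (est < 1) {
      return(data.frame(marker = marker, grouping = grouping, chi2 = NA_real_,
                        df = NA_integer_, p = NA_real_,
                        n_groups_used = nlevels(grp),
                        note = "interaction inestimable (empty cells)",
                        stringsAsFactors = FALSE))
    }
    Xf <- Xf[, qf$pivot[seq_len(qf$rank)], drop = FALSE]
  }
  ek <- eigen_kinship(Ksub)
  f_full <- reml_fit(y, Xf, eigen_K = ek, method = "ML")
  f_red <- reml_fit(y, Xr, eigen_K = ek, method = "ML")
  df <- ncol(Xf) - ncol(Xr)
  chi2 <- max(0, 2 * (f_full$loglik - f_red$loglik))
  data.frame(marker = marker, grouping = grouping, chi2 = chi2, df = df,
             p = pchisq(chi2, df, lower.tail = FALSE),
             n_groups_used = nlevels(grp), note = note,
             stringsAsFactors = FALSE)
}
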
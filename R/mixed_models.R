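# Multilevel linear models with diagonal random-effect covariance and AR(1)
# residual correlation within participant-day, fitted by profiled (restricted)
# maximum likelihood.
#
# Model: y = X beta + sum_k Z_k b_k + e, with b_k ~ N(0, sigma_k^2 I) for
# k in {participant intercept, per-predictor participant slopes,
# participant x weekday, participant x hour, optionally participant x
# movement-decile}, and e an AR(1) process within each participant-day
# (record order; unequal gaps are ignored).
#
# Estimation: variance ratios lambda_k = sigma_k^2 / sigma^2 on the log
# scale and phi through atanh are optimized with a quasi-Newton method;
# beta and sigma^2 are profiled out in closed form. The marginal covariance
# is handled by whitening each AR(1) block and applying the Woodbury
# identity, so one likelihood evaluation costs O(q^3) per participant after
# a single O(n) pass that caches lagged cross-products.

#' Specification of a heart-rate mixed model
#'
#' @param model Fixed-effect family: `"acoustic"` (SPL + SML + SNR),
#'   `"soundscape"` (class offsets, Quiet reference), `"interaction"`
#'   (acoustics by collapsed class Quiet/Speech/Noisy), `"movement"`
#'   (windowed movement speed), or `"intercept"` (null).
#' @param response `"hr"` or `"log_hr"`.
#' @param predictor_scaling `"standardized"` (pooled z-scores; coefficients
#'   in bpm per 1 s.d.) or `"raw_db"` (original dB scale, as used for the
#'   log-response refit).
#' @param random_slopes Give continuous predictors participant-level random
#'   slopes (default TRUE for models with continuous predictors).
#' @param random_weekday,random_hour Include nested random intercepts for
#'   participant-weekday and participant-hour (defaults TRUE).
#' @param movement_decile_re Add a participant-by-movement-decile random
#'   intercept (movement-adjusted models).
#' @param ar1 Model within-participant-day AR(1) residual correlation.
#' @param method `"ML"` (default, so likelihood-ratio tests against nested
#'   models are valid) or `"REML"`.
#' @return A classed spec list.
#' @export
model_spec <- function(model = c("acoustic", "soundscape", "interaction",
                                 "movement", "intercept"),
                       response = c("hr", "log_hr"),
                       predictor_scaling = c("standardized", "raw_db"),
                       random_slopes = NULL,
                       random_weekday = TRUE, random_hour = TRUE,
                       movement_decile_re = FALSE,
                       ar1 = TRUE,
                       method = c("ML", "REML")) {
  model <- match.arg(model)
  response <- match.arg(response)
  predictor_scaling <- match.arg(predictor_scaling)
  method <- match.arg(method)
  if (is.null(random_slopes))
    random_slopes <- model %in% c("acoustic", "interaction")
  structure(list(model = model, response = response,
                 predictor_scaling = predictor_scaling,
                 random_slopes = random_slopes,
                 random_weekday = random_weekday,
                 random_hour = random_hour,
                 movement_decile_re = movement_decile_re,
                 ar1 = ar1, method = method),
            class = "model_spec")
}

ACOUSTIC_VARS <- c("spl", "sml", "snr")

#' Build the design for a mixed-model fit
#'
#' Encodes the fixed design (continuous predictors pooled-centered and
#' scaled when standardized; soundscape dummy-coded with Quiet reference;
#' the interaction model collapses Speech-in-Noise and Noise into a single
#' Noisy class), the random-effect column blocks, and the AR(1) block
#' structure (participant-day in record order).
#'
#' @param records Aligned data records (see [align_records()]); the
#'   interaction/soundscape models need `soundscape`, the movement model a
#'   `movement` column.
#' @param spec A [model_spec()].
#' @return A classed design list used by [fit_lme_ar1()].
#' @export
build_design <- function(records, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  ts <- parse_timestamps(records$timestamp)
  o <- order(records$participant_id, ts)
  records <- records[o, , drop = FALSE]
  ts <- ts[o]
  n <- nrow(records)
  if (!n) stop("no records", call. = FALSE)

  y <- switch(spec$response, hr = records$hr, log_hr = log(records$hr))
  if (any(!is.finite(y))) stop("non-finite response", call. = FALSE)

  scaling <- NULL
  zmat <- NULL
  needs_acoustics <- spec$model %in% c("acoustic", "interaction") ||
    (spec$random_slopes && all(ACOUSTIC_VARS %in% names(records)))
  if (needs_acoustics) {
    for (v in ACOUSTIC_VARS)
      if (!v %in% names(records)) stop("missing field: ", v, call. = FALSE)
    raw <- as.matrix(records[, ACOUSTIC_VARS])
    sds <- apply(raw, 2, stats::sd)
    if (any(sds == 0)) stop("constant predictor: ",
                            paste(ACOUSTIC_VARS[sds == 0], collapse = ", "),
                            call. = FALSE)
    if (spec$predictor_scaling == "standardized") {
      mus <- colMeans(raw)
      zmat <- sweep(sweep(raw, 2, mus), 2, sds, "/")
      scaling <- list(mean = mus, sd = sds)
    } else {
      zmat <- raw
    }
  }

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$model == "acoustic") {
    X <- cbind(X, zmat)
  } else if (spec$model == "soundscape") {
    cls <- soundscape_factor(records$soundscape)
    if (any(is.na(cls))) stop("missing field: soundscape", call. = FALSE)
    mm <- stats::model.matrix(~cls)[, -1, drop = FALSE]
    colnames(mm) <- levels(cls)[-1]
    X <- cbind(X, mm)
  } else if (spec$model == "interaction") {
    cls3 <- factor(ifelse(records$soundscape == "Quiet", "Quiet",
                          ifelse(records$soundscape == "Speech", "Speech",
                                 "Noisy")),
                   levels = c("Quiet", "Speech", "Noisy"))
    mm <- stats::model.matrix(~cls3)[, -1, drop = FALSE]
    colnames(mm) <- levels(cls3)[-1]
    inter <- do.call(cbind, lapply(ACOUSTIC_VARS, function(v) {
      out <- mm * zmat[, v]
      colnames(out) <- paste0(colnames(mm), ":", v)
      out
    }))
    X <- cbind(X, mm, zmat, inter)
  } else if (spec$model == "movement") {
    if (!"movement" %in% names(records))
      stop("missing field: movement", call. = FALSE)
    X <- cbind(X, movement = records$movement)
  }

  # random-effect columns (per participant, shared layout)
  Zcols <- list(participant = matrix(1, n, 1,
                                     dimnames = list(NULL, "re_intercept")))
  vgroup <- "participant"
  if (spec$random_slopes && !is.null(zmat)) {
    Zcols$slopes <- zmat
    colnames(Zcols$slopes) <- paste0("re_slope_", ACOUSTIC_VARS)
    vgroup <- c(vgroup, paste0("slope_", ACOUSTIC_VARS))
  }
  indicator <- function(x, prefix) {
    lv <- sort(unique(x))
    m <- vapply(lv, function(l) as.numeric(x == l), numeric(length(x)))
    colnames(m) <- paste0(prefix, lv)
    m
  }
  if (spec$random_weekday) {
    mmw <- indicator(records$weekday, "wd")
    vgroup <- c(vgroup, rep("weekday", ncol(mmw)))
    Zcols$weekday <- mmw
  }
  if (spec$random_hour) {
    mmh <- indicator(records$hour, "hr")
    vgroup <- c(vgroup, rep("hour", ncol(mmh)))
    Zcols$hour <- mmh
  }
  if (spec$movement_decile_re) {
    if (!"movement_decile" %in% names(records))
      stop("missing field: movement_decile", call. = FALSE)
    mmd <- indicator(records$movement_decile, "md")
    vgroup <- c(vgroup, rep("movement_decile", ncol(mmd)))
    Zcols$movdec <- mmd
  }
  Z <- do.call(cbind, Zcols)

  participant <- records$participant_id
  day <- format(ts, "%Y-%m-%d")
  block <- paste(participant, day)
  first_of_block <- c(TRUE, block[-1] != block[-n])

  structure(list(y = y, X = X, Z = Z, vgroup = vgroup,
                 participant = participant, block = block,
                 first_of_block = first_of_block,
                 records = records, spec = spec, scaling = scaling,
                 n = n, p = ncol(X)),
            class = "lme_design")
}

# Cache per-participant lagged cross-products of U = [y X Z] so the profiled
# likelihood is O(q^3) per participant at any phi:
#   crossprod(W U) = C0f + (C0n - phi (C1n + C1n') + phi^2 C2n) / (1 - phi^2)
# where W is the AR(1) whitening transform and f/n index first/non-first
# rows of each AR(1) block.
design_cache <- function(design) {
  U <- cbind(design$y, design$X, design$Z)
  pids <- unique(design$participant)
  cache <- vector("list", length(pids))
  names(cache) <- pids
  for (pid in pids) {
    idx <- which(design$participant == pid)
    Ui <- U[idx, , drop = FALSE]
    f <- design$first_of_block[idx]
    nf <- which(!f)
    Unf <- Ui[nf, , drop = FALSE]
    Ulag <- Ui[nf - 1L, , drop = FALSE]
    cache[[pid]] <- list(
      C0f = crossprod(Ui[f, , drop = FALSE]),
      C0n = crossprod(Unf),
      C1n = crossprod(Ulag, Unf),
      C2n = crossprod(Ulag),
      n_nonfirst = length(nf), n = length(idx)
    )
  }
  cache
}

# Profiled log-likelihood (and GLS quantities) at variance ratios lambda
# (named by variance group) and AR parameter phi.
profiled_ll <- function(design, cache, lambda, phi, method = "ML") {
  p <- design$p
  k <- 1 + p + ncol(design$Z)
  iy <- 1; ix <- 2:(p + 1); iz <- (p + 2):k
  lam <- lambda[design$vgroup]
  A <- matrix(0, p, p); b <- numeric(p); cc <- 0; ld <- 0
  for (ci in cache) {
    S <- ci$C0f + (ci$C0n - phi * (ci$C1n + t(ci$C1n)) + phi^2 * ci$C2n) /
      (1 - phi^2)
    M <- S[iz, iz, drop = FALSE]
    diag(M) <- diag(M) + 1 / lam
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Szx <- S[iz, ix, drop = FALSE]
    Szy <- S[iz, iy]
    W1 <- backsolve(ch, forwardsolve(t(ch), cbind(Szx, Szy)))
    A <- A + S[ix, ix] - crossprod(Szx, W1[, 1:p, drop = FALSE])
    b <- b + S[ix, iy] - crossprod(Szx, W1[, p + 1])
    cc <- cc + S[iy, iy] - sum(Szy * W1[, p + 1])
    # logdet Vtilde_i = logdet R + logdet M + logdet G
    ld <- ld + ci$n_nonfirst * log(1 - phi^2) +
      2 * sum(log(diag(ch))) + sum(log(lam))
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(NULL)
  beta <- backsolve(chA, forwardsolve(t(chA), b))
  rss <- max(cc - sum(b * beta), 1e-300)
  n <- design$n
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + ld + n)
  } else {
    sigma2 <- rss / (n - p)
    ld_xvx <- 2 * sum(log(diag(chA)))
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + ld + ld_xvx + (n - p))
  }
  list(ll = ll, beta = as.numeric(beta), sigma2 = sigma2, A = A)
}

#' Fit the AR(1) multilevel model
#'
#' Maximizes the profiled (restricted) marginal likelihood over the
#' random-effect variance ratios (log scale) and the AR(1) parameter
#' (atanh scale) with `nlminb` from a fixed deterministic start (each
#' variance at 20 percent of the residual variance, phi = 0); on failure
#' two perturbed restarts are tried. Fixed effects and the residual
#' variance are profiled out by generalized least squares.
#'
#' @param design A [build_design()] result.
#' @param method `"ML"` or `"REML"`; defaults to the spec's choice.
#' @param control Optional list: `rel.tol` (default 1e-10), `iter.max`.
#' @return An object of class `lme_ar1_fit`: coefficients with SEs and 95
#'   percent Wald confidence intervals, variance components (bpm^2), AR(1)
#'   phi, log-likelihood, parameter count, convergence report, and random
#'   effect predictions (BLUPs).
#' @export
fit_lme_ar1 <- function(design, method = NULL, control = list()) {
  stopifnot(inherits(design, "lme_design"))
  spec <- design$spec
  method <- method %||% spec$method
  cache <- design_cache(design)
  groups <- unique(design$vgroup)
  n_lam <- length(groups)
  use_ar1 <- isTRUE(spec$ar1)

  obj <- function(par) {
    lambda <- exp(par[seq_len(n_lam)])
    names(lambda) <- groups
    phi <- if (use_ar1) tanh(par[n_lam + 1]) else 0
    res <- profiled_ll(design, cache, lambda, phi, method)
    if (is.null(res) || !is.finite(res$ll)) return(1e10)
    -res$ll
  }

  starts <- list(c(rep(log(0.2), n_lam), if (use_ar1) 0),
                 c(rep(log(0.05), n_lam), if (use_ar1) 0.3),
                 c(rep(log(0.5), n_lam), if (use_ar1) -0.2))
  lower <- c(rep(-23, n_lam), if (use_ar1) -5)
  upper <- c(rep(12, n_lam), if (use_ar1) 5)
  best <- NULL
  conv <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, obj, lower = lower, upper = upper,
                         control = list(rel.tol = control$rel.tol %||% 1e-10,
                                        iter.max = control$iter.max %||% 500))
    if (is.null(best) || opt$objective < best$objective - 1e-8) {
      best <- opt
      conv <- opt$convergence
    }
    if (conv == 0 && is.finite(best$objective)) break
  }
  if (!is.finite(best$objective))
    stop("mixed-model fit failed to produce a finite likelihood",
         call. = FALSE)

  lambda <- exp(best$par[seq_len(n_lam)])
  names(lambda) <- groups
  phi <- if (use_ar1) tanh(best$par[n_lam + 1]) else 0
  final <- profiled_ll(design, cache, lambda, phi, method)
  beta <- final$beta
  names(beta) <- colnames(design$X)
  vc_beta <- final$sigma2 * chol2inv(chol(final$A))
  dimnames(vc_beta) <- list(names(beta), names(beta))
  se <- stats::setNames(sqrt(diag(vc_beta)), names(beta))
  varcomp <- lambda * final$sigma2

  # BLUPs: per participant b = (Ginv + Z*'Z*)^-1 Z*'(y* - X* beta)
  blups <- blup_pass(design, lambda, phi, beta)

  n_param <- design$p + n_lam + (if (use_ar1) 1 else 0) + 1

  structure(list(
    beta = beta, se = se, vcov = vc_beta,
    ci = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
    varcomp = varcomp, sigma2 = final$sigma2, phi = phi,
    loglik = final$ll, n_obs = design$n, n_param = n_param,
    method = method, lambda = lambda, spec = spec,
    scaling = design$scaling, vgroup_levels = groups,
    blups = blups, design = design,
    convergence = list(code = conv, message = best$message,
                       objective = best$objective)
  ), class = "lme_ar1_fit")
}

# One dense pass over the data computing whitened matrices and BLUPs.
blup_pass <- function(design, lambda, phi, beta) {
  lam <- lambda[design$vgroup]
  s <- sqrt(1 - phi^2)
  out <- list()
  for (pid in unique(design$participant)) {
    idx <- which(design$participant == pid)
    f <- design$first_of_block[idx]
    wh <- function(Mx) {
      Mx <- as.matrix(Mx)
      lag <- rbind(0, Mx[-nrow(Mx), , drop = FALSE])
      w <- (Mx - phi * lag) / s
      w[f, ] <- Mx[f, , drop = FALSE]
      w
    }
    Zw <- wh(design$Z[idx, , drop = FALSE])
    rw <- wh(design$y[idx] - design$X[idx, , drop = FALSE] %*% beta)
    M <- crossprod(Zw)
    diag(M) <- diag(M) + 1 / lam
    out[[pid]] <- as.numeric(solve(M, crossprod(Zw, rw)))
    names(out[[pid]]) <- colnames(design$Z)
  }
  out
}

#' @export
print.lme_ar1_fit <- function(x, ...) {
  cat("Multilevel model with AR(1) residuals (", x$method, ")\n", sep = "")
  cat("  observations:", x$n_obs, " log-likelihood:",
      format(x$loglik, digits = 8), "\n")
  cat("  phi:", round(x$phi, 3), " residual SD:",
      round(sqrt(x$sigma2), 3), "\n\nFixed effects (95% CI):\n")
  tab <- data.frame(beta = round(x$beta, 4), se = round(x$se, 4),
                    lower = round(x$ci[, 1], 4),
                    upper = round(x$ci[, 2], 4))
  print(tab)
  cat("\nRandom-effect SDs:\n")
  print(round(sqrt(x$varcomp), 4))
  invisible(x)
}

#' Likelihood-ratio test of nested mixed models
#'
#' `chi2 = 2 (ll_full - ll_null)`, degrees of freedom equal to the
#' difference in total parameter count (fixed coefficients plus variance
#' and correlation parameters), p-value from the chi-square upper tail.
#' Both fits must use maximum likelihood.
#'
#' @param fit_full,fit_null Fits from [fit_lme_ar1()] on the same records.
#' @return List `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_null) {
  if (fit_full$method != "ML" || fit_null$method != "ML")
    stop("likelihood-ratio tests on fixed effects require ML fits",
         call. = FALSE)
  if (fit_full$n_obs != fit_null$n_obs)
    stop("fits must use the same records", call. = FALSE)
  chi2 <- 2 * (fit_full$loglik - fit_null$loglik)
  df <- fit_full$n_param - fit_null$n_param
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = max(df, 1), lower.tail = FALSE))
}

#' Generalized variance inflation factors
#'
#' Fox-Monette determinant-ratio GVIF on the correlation matrix of the
#' non-intercept design columns: for each term block,
#' `det(R11) det(R22) / det(R)`. For a one-column term this is the
#' classical VIF.
#'
#' @param X Fixed-effect design matrix (intercept column ignored).
#' @param terms Named list mapping each term to its column names (or
#'   indices); defaults to one term per column.
#' @return Named numeric vector of GVIFs.
#' @export
gvif <- function(X, terms = NULL) {
  cols <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- cols
  X <- X[, !(cols %in% "(Intercept)"), drop = FALSE]
  if (ncol(X) < 2) stop("need at least two non-intercept columns",
                        call. = FALSE)
  R <- stats::cor(X)
  detR <- det(R)
  if (detR < .Machine$double.eps)
    stop("singular correlation matrix among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  if (is.null(terms))
    terms <- stats::setNames(as.list(colnames(X)), colnames(X))
  vapply(terms, function(cl) {
    i <- if (is.character(cl)) match(cl, colnames(X)) else cl
    det(R[i, i, drop = FALSE]) * det(R[-i, -i, drop = FALSE]) / detR
  }, numeric(1))
}

#' Partial and full variance explained for multilevel fits
#'
#' Proportional reduction in prediction error across grouping levels:
#' level one is the observation-level residual sum-of-squares after
#' removing fixed effects and predicted random effects; levels two and
#' three are the sums of squared predicted random-effect values at the
#' weekday and hour levels. The partial statistic compares the full model
#' with an intercept-only null sharing its random structure; the full-model
#' statistic replaces the denominator with the total sum-of-squares of the
#' observations.
#'
#' @param fit_full Fit of the model of interest.
#' @param fit_null Intercept-only fit on the same records sharing the
#'   nested intercept structure (participant, weekday, hour); the null
#'   carries no random slopes, which would otherwise absorb the common
#'   fixed slopes into their predictions.
#' @return List with the level-wise sums of squares of both models
#'   (`sigma2_*`, `tau2_*`, `gamma2_*`), `RP2` and `RF2`.
#' @export
partial_r2 <- function(fit_full, fit_null) {
  strip_slopes <- function(v) setdiff(v, grep("^slope_", v, value = TRUE))
  if (!identical(strip_slopes(fit_full$vgroup_levels),
                 strip_slopes(fit_null$vgroup_levels)))
    stop("full and null fits must share the nested random structure",
         call. = FALSE)
  if (fit_full$n_obs != fit_null$n_obs)
    stop("fits must use the same records", call. = FALSE)
  ss <- function(fit) {
    d <- fit$design
    fitted_re <- numeric(d$n)
    tau2 <- 0; gamma2 <- 0
    for (pid in names(fit$blups)) {
      idx <- which(d$participant == pid)
      bb <- fit$blups[[pid]]
      fitted_re[idx] <- as.numeric(d$Z[idx, , drop = FALSE] %*% bb)
      tau2 <- tau2 + sum(bb[d$vgroup == "weekday"]^2)
      gamma2 <- gamma2 + sum(bb[d$vgroup == "hour"]^2)
    }
    resid <- d$y - as.numeric(d$X %*% fit$beta) - fitted_re
    list(sigma2 = sum(resid^2), tau2 = tau2, gamma2 = gamma2)
  }
  f <- ss(fit_full); nl <- ss(fit_null)
  num <- f$sigma2 + f$tau2 + f$gamma2
  den <- nl$sigma2 + nl$tau2 + nl$gamma2
  y <- fit_full$design$y
  tss <- sum((y - mean(y))^2)
  list(sigma2_full = f$sigma2, tau2_full = f$tau2, gamma2_full = f$gamma2,
       sigma2_null = nl$sigma2, tau2_null = nl$tau2, gamma2_null = nl$gamma2,
       RP2 = 1 - num / den, RF2 = 1 - num / tss)
}

#' Back-transform a log-scale coefficient to percent change
#'
#' `(exp(beta) - 1) * 100`: percent change in heart rate per unit (1 dB)
#' of the predictor when the model response is log heart rate.
#'
#' @param beta Coefficient(s) on the natural-log scale.
#' @return Percent change(s).
#' @export
percent_change <- function(beta) (exp(beta) - 1) * 100

#' Slope contrasts of the interaction model vs the Quiet class
#'
#' With Quiet as the reference level, each `class:predictor` interaction
#' coefficient is the difference between that class's slope and the Quiet
#' slope; returned with its Wald standard error and two-sided p-value.
#'
#' @param fit An interaction-model fit.
#' @return Tibble `predictor`, `class`, `estimate`, `se`, `p`.
#' @export
interaction_contrasts <- function(fit) {
  nm <- names(fit$beta)
  idx <- grep(":", nm)
  if (!length(idx)) stop("fit has no interaction terms", call. = FALSE)
  est <- fit$beta[idx]
  se <- fit$se[idx]
  parts <- strsplit(nm[idx], ":", fixed = TRUE)
  tibble::tibble(
    predictor = vapply(parts, `[`, "", 2),
    class = vapply(parts, `[`, "", 1),
    estimate = unname(est), se = unname(se),
    p = 2 * stats::pnorm(-abs(est / se))
  )
}
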
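# Descriptive computations: class-conditional CDFs across participants,
# hourly quartiles and soundscape occupancy, marginal-mean decile
# regressions of standardized HR on standardized acoustics, and the
# repeated-measures ANOVA of HR by soundscape.

#' Class-conditional percentile curves across participants
#'
#' Per participant and soundscape class, computes percentiles 1-99 of an
#' acoustic variable; reports the across-participant median per percentile
#' with a bootstrap 95 percent confidence interval (resampling
#' participants).
#'
#' @param sound_logs Sound logs with `participant_id`, `soundscape` and the
#'   variable column.
#' @param variable One of `"spl"`, `"sml"`, `"snr"`.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap.
#' @return Tibble `soundscape`, `percentile`, `median`, `lower`, `upper`,
#'   `n_participants`. Classes observed for fewer than 2 participants are
#'   omitted with a warning; with exactly 2 the CI is flagged degenerate.
#' @export
class_cdfs <- function(sound_logs, variable = "spl", n_boot = 200, seed = 1) {
  stopifnot(variable %in% names(sound_logs))
  probs <- (1:99) / 100
  out <- list()
  for (cl in intersect(SOUNDSCAPES, unique(sound_logs$soundscape))) {
    sel <- sound_logs$soundscape == cl
    per_part <- tapply(sound_logs[[variable]][sel],
                       sound_logs$participant_id[sel],
                       quantile_li, probs = probs)
    npart <- length(per_part)
    if (npart < 2) {
      warning("class ", cl, " observed for fewer than 2 participants; omitted")
      next
    }
    mat <- do.call(rbind, per_part) # participants x percentiles
    med <- apply(mat, 2, stats::median)
    set.seed(substream_seed(seed, paste0("cdf", cl)))
    boot <- replicate(n_boot, {
      apply(mat[sample.int(npart, npart, replace = TRUE), , drop = FALSE],
            2, stats::median)
    })
    ci <- apply(boot, 1, quantile_li, probs = c(0.025, 0.975))
    out[[cl]] <- tibble::tibble(soundscape = cl, percentile = 1:99,
                                median = med, lower = ci[1, ],
                                upper = ci[2, ], n_participants = npart)
  }
  dplyr::bind_rows(out)
}

#' Hourly quartiles and soundscape occupancy
#'
#' Per hour of day: the grand median across participants of each
#' participant's within-hour quartiles of the acoustic variables, and the
#' mean percentage occupancy of each soundscape class (each participant's
#' within-hour class shares, averaged across participants; rows sum to
#' 100).
#'
#' @param sound_logs Sound logs (daytime-filtered or not).
#' @return List `quartiles` (tibble `hour`, `variable`, `q25`, `q50`,
#'   `q75`) and `occupancy` (tibble `hour`, one column per class, percent).
#' @export
hourly_summaries <- function(sound_logs) {
  ts <- parse_timestamps(sound_logs$timestamp)
  hour <- as.integer(format(ts, "%H"))
  qs <- list()
  for (v in intersect(c("spl", "sml", "snr"), names(sound_logs))) {
    per <- stats::aggregate(
      sound_logs[[v]],
      by = list(hour = hour, pid = sound_logs$participant_id),
      FUN = function(x) quantile_li(x, c(0.25, 0.5, 0.75)))
    qmat <- per$x
    med <- stats::aggregate(qmat, by = list(hour = per$hour),
                            FUN = stats::median)
    qs[[v]] <- tibble::tibble(hour = med$hour, variable = v,
                              q25 = med$V1, q50 = med$V2, q75 = med$V3)
  }
  cls <- soundscape_factor(sound_logs$soundscape)
  occ_list <- list()
  for (h in sort(unique(hour))) {
    sel <- hour == h
    shares <- tapply(seq_len(sum(sel)), sound_logs$participant_id[sel],
                     function(i) {
                       tab <- table(cls[sel][i])
                       100 * as.numeric(tab) / sum(tab)
                     })
    m <- colMeans(do.call(rbind, shares))
    occ_list[[as.character(h)]] <- c(hour = h, stats::setNames(m, SOUNDSCAPES))
  }
  occupancy <- tibble::as_tibble(do.call(rbind, occ_list))
  list(quartiles = dplyr::bind_rows(qs), occupancy = occupancy)
}

#' Marginal mean heart rate over deciles of an acoustic variable
#'
#' Standardizes each participant's HR and acoustic variable (centring and
#' scaling within participant), optionally restricts to records with SPL
#' below/above a stratification threshold (60 dB by default, matching the
#' overall median level), pools, bins the standardized variable into
#' deciles (pooled linear-interpolation edges, ties to the lower bin), and
#' regresses the 10 bin means of standardized HR on the bin mid-quantile
#' centers by ordinary least squares with an F test on (1, 8) degrees of
#' freedom.
#'
#' @param records Data records with `hr`, the variable, `spl`,
#'   `participant_id`.
#' @param variable `"spl"`, `"sml"` or `"snr"`.
#' @param spl_stratum `"all"`, `"low"` (SPL <= threshold) or `"high"`.
#' @param spl_threshold Stratification threshold in dB (default 60,
#'   a fixed constant; set `re_estimate = TRUE` to use the records' own
#'   median SPL).
#' @param re_estimate Re-estimate the threshold as the pooled median SPL.
#' @return List: `bins` (tibble `bin`, `center`, `mean_hr`, `n`), `slope`,
#'   `intercept`, `F`, `df` (c(1, 8)), `p`, `r2`.
#' @export
marginal_means <- function(records, variable = "spl",
                           spl_stratum = c("all", "low", "high"),
                           spl_threshold = 60, re_estimate = FALSE) {
  spl_stratum <- match.arg(spl_stratum)
  z_by <- function(x, g) stats::ave(x, g, FUN = function(v) {
    (v - mean(v)) / stats::sd(v)
  })
  zhr <- z_by(records$hr, records$participant_id)
  zvar <- z_by(records[[variable]], records$participant_id)
  if (re_estimate) spl_threshold <- stats::median(records$spl)
  keep <- switch(spl_stratum, all = rep(TRUE, nrow(records)),
                 low = records$spl <= spl_threshold,
                 high = records$spl > spl_threshold)
  zhr <- zhr[keep]; zvar <- zvar[keep]
  if (length(unique(zvar)) < 10)
    stop("need at least 10 distinct standardized values", call. = FALSE)
  bin_id <- decile_bin(zvar)
  if (length(unique(bin_id)) < 10) stop("fewer than 10 populated decile bins",
                                        call. = FALSE)
  centers <- quantile_li(zvar, probs = seq(0.05, 0.95, by = 0.1))
  bins <- tibble::tibble(
    bin = 1:10, center = centers,
    mean_hr = as.numeric(tapply(zhr, bin_id, mean)),
    n = as.integer(table(bin_id))
  )
  fit <- stats::lm(mean_hr ~ center, data = bins)
  an <- stats::anova(fit)
  list(bins = bins,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = an$`F value`[1], df = c(1, 8), p = an$`Pr(>F)`[1],
       r2 = summary(fit)$r.squared,
       stratum = spl_stratum, threshold = spl_threshold)
}

#' Repeated-measures ANOVA of heart rate by soundscape
#'
#' One mean HR per participant and class (participants lacking any class
#' are dropped and counted); one-way repeated-measures ANOVA with
#' Greenhouse-Geisser sphericity correction (non-integer degrees of
#' freedom), plus Bonferroni-adjusted paired t-tests for all class pairs.
#'
#' @param records Data records with `participant_id`, `soundscape`, `hr`.
#' @param correction `"greenhouse-geisser"` (default) or `"none"`.
#' @return List `F`, `df1`, `df2`, `p`, `epsilon`, `n_participants`,
#'   `n_dropped`, `cell_means`, and `pairwise` (tibble with raw and
#'   Bonferroni-adjusted p-values).
#' @export
rm_anova_soundscape <- function(records,
                                correction = c("greenhouse-geisser", "none")) {
  correction <- match.arg(correction)
  cls <- droplevels(soundscape_factor(records$soundscape))
  cell <- tapply(records$hr, list(records$participant_id, cls), mean)
  complete <- stats::complete.cases(cell)
  n_dropped <- sum(!complete)
  Y <- cell[complete, , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) stop("need at least 3 participants with all classes",
                  call. = FALSE)
  # two-way (participant x class) decomposition, no replication
  grand <- mean(Y)
  class_means <- colMeans(Y)
  part_means <- rowMeans(Y)
  ss_class <- n * sum((class_means - grand)^2)
  resid <- Y - outer(part_means, rep(1, k)) -
    outer(rep(1, n), class_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- if (ss_err == 0) {
    if (ss_class == 0) 0 else Inf # no within-participant variation at all
  } else (ss_class / df1) / (ss_err / df2)
  eps <- 1
  if (correction == "greenhouse-geisser") {
    S <- stats::cov(Y)
    # epsilon from the double-centered covariance matrix
    Sc <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k,
                                                 byrow = TRUE) + mean(S)
    eps <- if (sum(Sc^2) == 0) 1 # degenerate covariance: no correction
           else sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }
  p <- stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
  pairs <- utils::combn(colnames(Y), 2)
  pw <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(Y[, pr[1]], Y[, pr[2]], paired = TRUE)
    c(estimate = unname(tt$estimate), p = tt$p.value)
  })
  pairwise <- tibble::tibble(
    class1 = pairs[1, ], class2 = pairs[2, ],
    mean_diff = pw["estimate", ], p_raw = pw["p", ],
    p_bonferroni = pmin(pw["p", ] * ncol(pairs), 1)
  )
  list(F = Fval, df1 = eps * df1, df2 = eps * df2, p = p, epsilon = eps,
       n_participants = n, n_dropped = n_dropped,
       cell_means = class_means, pairwise = pairwise)
}
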
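#' Spot-test score symbols, weakest to strongest
#' @export
SPOT_SYMBOLS <- c("-", "+", "++", "+++", "++++")

SPOT_DILUTIONS <- c(0, -2, -4, -6)

#' Score a spot test from its dilution ladder
#'
#' Serial phage dilutions (10^0, 10^-2, 10^-4, 10^-6) are spotted on a
#' bacterial lawn; the score is set by the deepest dilution still showing
#' lysis: 10^0 only gives "+", down to 10^-2 "++", 10^-4 "+++", 10^-6
#' "++++"; no lysis anywhere gives "-". A non-contiguous pattern (lysis at
#' a deep dilution but not a shallower one) is biologically inconsistent;
#' it raises a warning and is scored by the deepest lytic dilution.
#'
#' @param infective logical vector of length 4, one per dilution in the
#'   ladder \code{c(0, -2, -4, -6)}.
#' @return a score symbol (see \code{SPOT_SYMBOLS}).
#' @export
#' @examples
#' score_spot_test(c(TRUE, TRUE, TRUE, TRUE))    # "++++"
#' score_spot_test(c(TRUE, FALSE, FALSE, FALSE)) # "+"
score_spot_test <- function(infective) {
  stopifnot(is.logical(infective), length(infective) == length(SPOT_DILUTIONS))
  if (!any(infective)) return("-")
  deepest <- max(which(infective))
  if (any(!infective[seq_len(deepest)])) {
    warning("non-contiguous spot-test pattern; scored by deepest infective dilution",
            call. = FALSE)
  }
  SPOT_SYMBOLS[deepest + 1L]
}

spot_rank <- function(score) match(score, SPOT_SYMBOLS)

#' Read a spot-test matrix from CSV
#'
#' Expected columns: \code{strain_id}, \code{pathogenic} (logical) and the
#' per-dilution infectivity flags \code{d0}, \code{d2}, \code{d4},
#' \code{d6}. Scores are (re)computed from the flags.
#'
#' @param path CSV path.
#' @return data.frame of spot-test records with a \code{score} column.
#' @export
read_spot_csv <- function(path) {
  if (!file.exists(path)) {
    pk_stop("phagekit_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "pathogenic", "d0", "d2", "d4", "d6")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    pk_stop("phagekit_table_error",
            sprintf("spot CSV lacks columns: %s", paste(miss, collapse = ", ")))
  }
  df$score <- vapply(seq_len(nrow(df)), function(i) {
    score_spot_test(as.logical(unlist(df[i, c("d0", "d2", "d4", "d6")])))
  }, "")
  df
}

#' Count infected strains in a host-range panel
#'
#' A strain counts as infected when its score reaches \code{min_score} on
#' the ordered symbol scale. The default floor of \code{"++"} excludes the
#' \code{"+"} category, which can reflect lysis from without (clearing at
#' high phage density without productive infection) rather than true
#' infection.
#'
#' @param records spot-test records with \code{score} and \code{pathogenic}.
#' @param min_score minimum qualifying symbol (default \code{"++"}).
#' @return named integer vector \code{c(total, pathogenic, non_pathogenic)}.
#' @export
count_infected <- function(records, min_score = "++") {
  stopifnot(min_score %in% SPOT_SYMBOLS)
  if (is.null(records) || nrow(records) == 0) {
    return(c(total = 0L, pathogenic = 0L, non_pathogenic = 0L))
  }
  ok <- spot_rank(records$score) >= spot_rank(min_score)
  path <- as.logical(records$pathogenic)
  c(total = sum(ok),
    pathogenic = sum(ok & path),
    non_pathogenic = sum(ok & !path))
}

#' Construct a one-step growth curve
#'
#' Replicated (time, titer) series at one temperature. Times must be
#' strictly increasing within each replicate and titers positive.
#'
#' @param time_min numeric times in minutes.
#' @param titer_pfu_per_ml positive titers.
#' @param replicate replicate labels (parallel to \code{time_min}).
#' @param temperature_C incubation temperature.
#' @param moi multiplicity of infection used for the assay.
#' @return data.frame of class \code{growth_curve}.
#' @export
growth_curve <- function(time_min, titer_pfu_per_ml, replicate = 1L,
                         temperature_C = NA_real_, moi = NA_real_) {
  df <- data.frame(time_min = time_min,
                   titer_pfu_per_ml = titer_pfu_per_ml,
                   replicate = replicate, stringsAsFactors = FALSE)
  if (any(df$titer_pfu_per_ml <= 0)) {
    pk_stop("phagekit_value_error", "titers must be positive")
  }
  for (r in unique(df$replicate)) {
    tt <- df$time_min[df$replicate == r]
    if (any(diff(tt) <= 0)) {
      pk_stop("phagekit_value_error",
              sprintf("times not strictly increasing in replicate %s", r))
    }
  }
  structure(df, temperature_C = temperature_C, moi = moi,
            class = c("growth_curve", "data.frame"))
}

#' Read one-step growth curves from CSV
#'
#' Expected columns: \code{temperature_C}, \code{replicate},
#' \code{time_min}, \code{titer_pfu_per_ml}. One \code{growth_curve} is
#' returned per temperature.
#'
#' @param path CSV path.
#' @return named list of \code{growth_curve} objects.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) {
    pk_stop("phagekit_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "replicate", "time_min", "titer_pfu_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    pk_stop("phagekit_table_error",
            sprintf("growth CSV lacks columns: %s",
                    paste(miss, collapse = ", ")))
  }
  out <- lapply(split(df, df$temperature_C), function(d) {
    d <- d[order(d$replicate, d$time_min), ]
    growth_curve(d$time_min, d$titer_pfu_per_ml, d$replicate,
                 temperature_C = d$temperature_C[1])
  })
  out[order(as.numeric(names(out)))]
}

#' Write growth curves to CSV
#'
#' @param curves a \code{growth_curve} or list of them.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_growth_csv <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(temperature_C = attr(cv, "temperature_C"),
               replicate = cv$replicate, time_min = cv$time_min,
               titer_pfu_per_ml = cv$titer_pfu_per_ml)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Burst size from endpoint titers
#'
#' New virions per infected cell: the final titer minus the initial titer,
#' divided by the initial titer.
#'
#' @param initial_titer,final_titer titers in PFU/mL; initial must be
#'   positive.
#' @return burst size (dimensionless).
#' @export
#' @examples
#' burst_size(1e6, 1e8)  # 99
burst_size <- function(initial_titer, final_titer) {
  if (any(initial_titer <= 0)) {
    pk_stop("phagekit_value_error", "initial titer must be positive")
  }
  (final_titer - initial_titer) / initial_titer
}

# Four-parameter logistic fit for one replicate. The response is log10
# titer, but the logistic describes the titer itself:
#   titer(t) = A + (B - A) / (1 + exp((t0 - t)/s)),
# fitted as y = log10(titer) by least squares on the log scale (Poisson
# plating noise is roughly homoscedastic there). t0 is then the midpoint
# of the titer rise - the mean lysis time - not the midpoint of the
# log-transformed curve, which sits earlier for large bursts.
fit_logistic_rise <- function(t, y, rise_min_log10 = 0.3) {
  if (diff(range(y)) < rise_min_log10) {
    pk_stop("phagekit_no_rise_error",
            "titer series shows no rise; latent period undefined")
  }
  la0 <- min(y); lb0 <- max(y)
  titer_mid <- (10^la0 + 10^lb0) / 2
  titer <- 10^y
  above <- which(titer >= titer_mid)
  crossing <- function() {
    i <- above[1]
    if (i == 1) return(t[1])
    t[i - 1] + (titer_mid - titer[i - 1]) / (titer[i] - titer[i - 1]) *
      (t[i] - t[i - 1])
  }
  t00 <- if (length(above) > 0) crossing() else stats::median(t)
  s0 <- max(diff(range(t)) / 20, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ log10(10^la + (10^lb - 10^la) / (1 + exp((t0 - t) / s))),
      data = data.frame(t = t, y = y),
      start = list(la = la0, lb = lb0, t0 = t00, s = s0),
      lower = c(la = la0 - 2, lb = la0 - 2, t0 = min(t), s = 1e-3),
      upper = c(la = lb0 + 2, lb = lb0 + 2, t0 = max(t),
                s = diff(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate rises (an exact step) have a flat objective in t0; fall
    # back to the interpolated half-rise crossing
    if (length(above) == 0) {
      pk_stop("phagekit_fit_error",
              "logistic fit failed and no half-rise crossing found")
    }
    return(list(a = la0, b = lb0, t0 = t00, s = NA_real_))
  }
  cf <- stats::coef(fit)
  list(a = cf[["la"]], b = cf[["lb"]], t0 = cf[["t0"]], s = cf[["s"]])
}

#' Estimate burst size and latent period from a one-step growth curve
#'
#' Fits a four-parameter logistic to log10 titer versus time in each
#' replicate. The latent period is the inflection (midpoint) time of the
#' rise - the operational reading of "the middle of the exponential phase".
#' The burst size is computed from the pre- and post-rise titer levels:
#' with \code{burst_method = "plateau"} (default) the initial and final
#' titers are the means of the first and last \code{n_plateau} observed
#' points, with \code{"asymptote"} the fitted logistic asymptotes are used.
#'
#' @param curve a \code{growth_curve}.
#' @param burst_method \code{"plateau"} or \code{"asymptote"}.
#' @param n_plateau observed points averaged per plateau (default 3).
#' @param latent_method \code{"midpoint"} (logistic inflection) or
#'   \code{"onset"} (first departure from the initial plateau, defined as
#'   the time the fit crosses 5\% of the rise).
#' @return list of class \code{burst_estimate}: \code{burst_size},
#'   \code{burst_sd}, \code{latent_min}, \code{latent_sd},
#'   \code{per_replicate} (data.frame), \code{temperature_C}.
#' @export
estimate_growth_parameters <- function(curve,
                                       burst_method = c("plateau", "asymptote"),
                                       n_plateau = 3L,
                                       latent_method = c("midpoint", "onset")) {
  stopifnot(inherits(curve, "growth_curve"))
  burst_method <- match.arg(burst_method)
  latent_method <- match.arg(latent_method)
  reps <- split(curve, curve$replicate)
  per <- lapply(names(reps), function(r) {
    d <- reps[[r]]
    fit <- fit_logistic_rise(d$time_min, log10(d$titer_pfu_per_ml))
    latent <- if (latent_method == "midpoint") {
      fit$t0
    } else {
      # time at which the logistic has risen by 5% of (b - a)
      fit$t0 - fit$s * log(0.95 / 0.05)
    }
    if (burst_method == "plateau") {
      n <- min(n_plateau, nrow(d))
      init <- mean(utils::head(d$titer_pfu_per_ml, n))
      fin <- mean(utils::tail(d$titer_pfu_per_ml, n))
    } else {
      init <- 10^fit$a
      fin <- 10^fit$b
    }
    data.frame(replicate = r, burst = burst_size(init, fin),
               latent_min = latent, initial_titer = init, final_titer = fin,
               midpoint_slope = fit$s, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(
    burst_size = mean(per$burst),
    burst_sd = if (nrow(per) > 1) stats::sd(per$burst) else NA_real_,
    latent_min = mean(per$latent_min),
    latent_sd = if (nrow(per) > 1) stats::sd(per$latent_min) else NA_real_,
    per_replicate = per,
    temperature_C = attr(curve, "temperature_C")
  ), class = "burst_estimate")
}

#' @export
print.burst_estimate <- function(x, ...) {
  cat(sprintf("<burst_estimate> burst %.3g +/- %.2g, latent %.3g +/- %.2g min (%g C, %d replicates)\n",
              x$burst_size, x$burst_sd, x$latent_min, x$latent_sd,
              x$temperature_C, nrow(x$per_replicate)))
  invisible(x)
}

#' Latent period of a one-step growth curve
#'
#' Midpoint-of-rise latent period averaged over replicates; see
#' \code{\link{estimate_growth_parameters}}.
#'
#' @param curve a \code{growth_curve}.
#' @param method \code{"midpoint"} or \code{"onset"}.
#' @return minutes (numeric scalar) with attribute \code{"sd"}.
#' @export
latent_period <- function(curve, method = "midpoint") {
  est <- estimate_growth_parameters(curve, latent_method = method)
  structure(est$latent_min, sd = est$latent_sd)
}

#' Burst size of a one-step growth curve
#'
#' @param curve a \code{growth_curve}.
#' @param method \code{"plateau"} or \code{"asymptote"}.
#' @return burst size (numeric scalar) with attribute \code{"sd"}.
#' @export
burst_from_curve <- function(curve, method = "plateau") {
  est <- estimate_growth_parameters(curve, burst_method = method)
  structure(est$burst_size, sd = est$burst_sd)
}

groups_to_df <- function(groups) {
  if (is.null(names(groups))) {
    names(groups) <- sprintf("group%d", seq_along(groups))
  }
  if (length(groups) < 2) {
    pk_stop("phagekit_value_error", "at least two groups are required")
  }
  if (any(lengths(groups) < 2)) {
    pk_stop("phagekit_value_error", "each group needs at least two values")
  }
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares F test (via \code{stats::aov}).
#' When the between-group sum of squares is exactly zero the statistic is
#' reported as F = 0 with p = 1; a zero within-group sum of squares with
#' non-zero between-group variation is a degenerate design and raises an
#' error.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: \code{f}, \code{p}, \code{df_between}, \code{df_within},
#'   \code{fit} (the underlying \code{aov} object).
#' @export
one_way_anova <- function(groups) {
  df <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  ss_b <- tab["group", "Sum Sq"]
  ss_w <- tab["Residuals", "Sum Sq"]
  if (isTRUE(all.equal(ss_b, 0))) {
    return(list(f = 0, p = 1, df_between = tab["group", "Df"],
                df_within = tab["Residuals", "Df"], fit = fit))
  }
  if (isTRUE(all.equal(ss_w, 0))) {
    pk_stop("phagekit_degenerate_error",
            "zero within-group variance; F statistic undefined")
  }
  list(f = tab["group", "F value"], p = tab["group", "Pr(>F)"],
       df_between = tab["group", "Df"], df_within = tab["Residuals", "Df"],
       fit = fit)
}

#' Tukey honest-significant-difference test
#'
#' Pairwise comparisons after a one-way ANOVA using the studentized range
#' distribution (Tukey-Kramer at unequal group sizes, as implemented by
#' \code{stats::TukeyHSD}). Identical constant groups yield no significant
#' pairs.
#'
#' @param groups list of numeric vectors.
#' @param alpha family-wise significance level (default 0.01).
#' @return data.frame: \code{pair}, \code{diff}, \code{lwr}, \code{upr},
#'   \code{p_adj}, \code{significant}.
#' @export
tukey_hsd <- function(groups, alpha = 0.01) {
  df <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  pairs_mat <- utils::combn(levels(df$group), 2)
  if (isTRUE(all.equal(tab["Residuals", "Sum Sq"], 0)) &&
      isTRUE(all.equal(tab["group", "Sum Sq"], 0))) {
    return(data.frame(
      pair = apply(pairs_mat, 2, function(p) paste(p[2], p[1], sep = "-")),
      diff = 0, lwr = 0, upr = 0, p_adj = 1, significant = FALSE,
      stringsAsFactors = FALSE))
  }
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  data.frame(pair = rownames(th), diff = th[, "diff"], lwr = th[, "lwr"],
             upr = th[, "upr"], p_adj = th[, "p adj"],
             significant = th[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
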
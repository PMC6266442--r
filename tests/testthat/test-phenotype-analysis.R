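test_that("spot scores map the deepest infective dilution to symbols", {
  expect_equal(score_spot_test(c(TRUE, TRUE, TRUE, TRUE)), "++++")
  expect_equal(score_spot_test(c(TRUE, TRUE, TRUE, FALSE)), "+++")
  expect_equal(score_spot_test(c(TRUE, TRUE, FALSE, FALSE)), "++")
  expect_equal(score_spot_test(c(TRUE, FALSE, FALSE, FALSE)), "+")
  expect_equal(score_spot_test(c(FALSE, FALSE, FALSE, FALSE)), "-")
  expect_warning(s <- score_spot_test(c(FALSE, FALSE, TRUE, FALSE)),
                 "non-contiguous")
  expect_equal(s, "+++")
})

test_that("spot scoring is monotone in added infective dilutions", {
  rank_of <- function(sym) match(sym, SPOT_SYMBOLS)
  set.seed(91)
  for (i in 1:20) {
    pat <- runif(4) < 0.5
    extra <- pat
    off <- which(!pat)
    if (length(off) > 0) extra[sample(off, 1)] <- TRUE
    s1 <- suppressWarnings(score_spot_test(pat))
    s2 <- suppressWarnings(score_spot_test(extra))
    expect_gte(rank_of(s2), rank_of(s1))
  }
})

test_that("the transcribed 73-strain panel gives the published infection counts", {
  spots <- fixture_spots()
  expect_equal(nrow(spots), 73)
  counts <- count_infected(spots)
  expect_equal(unname(counts), c(10, 4, 6))
  # counting "+" spots as infections can only increase the totals
  lenient <- count_infected(spots, min_score = "+")
  expect_gt(lenient[["total"]], 10)
  expect_equal(unname(count_infected(spots[0, ])), c(0, 0, 0))
})

test_that("endpoint burst size is (final - initial) / initial", {
  expect_equal(burst_size(1e6, 1e8), 99)
  expect_equal(burst_size(1e6, 1e6), 0)
  expect_error(burst_size(0, 1e8), class = "phagekit_value_error")
})

test_that("a symmetric noiseless rise has its midpoint recovered", {
  spec <- growth_spec(burst = 99, latent_min = 50, lysis_spread_min = 0,
                      noise = FALSE, sampling_times = seq(0, 100, by = 4),
                      seed = 1)
  curve <- simulate_growth_curve(spec)
  expect_equal(as.numeric(latent_period(curve)), 50, tolerance = 1)
  expect_equal(as.numeric(burst_from_curve(curve)), 99, tolerance = 0.5)
  # smooth version fits the full logistic
  spec2 <- growth_spec(burst = 99, latent_min = 50, lysis_spread_min = 5,
                       noise = FALSE, sampling_times = seq(0, 100, by = 4),
                       seed = 1)
  expect_equal(as.numeric(latent_period(simulate_growth_curve(spec2))), 50,
               tolerance = 1)
})

test_that("a flat curve raises a no-rise error", {
  spec <- growth_spec(burst = 0, noise = FALSE, seed = 1)
  curve <- simulate_growth_curve(spec)
  expect_error(latent_period(curve), class = "phagekit_no_rise_error")
})

test_that("growth CSV round-trips and splits by temperature", {
  f <- withr::local_tempfile(fileext = ".csv")
  curves <- lapply(c("20C", "30C"), function(p) {
    simulate_growth_curve(growth_spec_preset(p, seed = 5))
  })
  write_growth_csv(curves, f)
  back <- read_growth_csv(f)
  expect_equal(names(back), c("20", "30"))
  expect_equal(back[["20"]]$titer_pfu_per_ml,
               curves[[1]]$titer_pfu_per_ml)
})

test_that("ANOVA F agrees with a direct sums-of-squares oracle", {
  groups <- list(a = c(4.2, 4.8, 5.1, 4.4), b = c(6.0, 6.3, 5.8, 6.1),
                 c = c(5.1, 5.5, 4.9, 5.2))
  res <- one_way_anova(groups)
  expect_equal(res$f, oracle_anova_f(groups), tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 9)
  expect_lt(res$p, 0.01)
  # identical constant groups: F defined as zero
  same <- list(a = rep(2, 3), b = rep(2, 3))
  expect_equal(one_way_anova(same)$f, 0)
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               class = "phagekit_degenerate_error")
  expect_error(one_way_anova(list(a = 1:3)), class = "phagekit_value_error")
})

test_that("with two groups F equals the square of the pooled t statistic", {
  set.seed(97)
  for (i in 1:5) {
    a <- rnorm(6, 0, 1)
    b <- rnorm(8, 1, 1)
    f <- one_way_anova(list(a = a, b = b))$f
    t <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-10)
  }
})

test_that("Tukey HSD flags large shifts and spares identical groups", {
  same <- list(a = rep(3, 4), b = rep(3, 4), c = rep(3, 4))
  th <- tukey_hsd(same)
  expect_false(any(th$significant))

  set.seed(103)
  base <- rnorm(6)
  shifted <- list(a = base, b = base + rnorm(6, 0, 0.1),
                  c = base + 10 * sd(base))
  th2 <- tukey_hsd(shifted, alpha = 0.01)
  expect_true(th2$significant[th2$pair == "c-a"])
  expect_true(th2$significant[th2$pair == "c-b"])
  expect_false(th2$significant[th2$pair == "b-a"])
})

test_that("Tukey p-values come from the studentized range distribution", {
  set.seed(107)
  groups <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
  th <- tukey_hsd(groups, alpha = 0.05)
  fit <- stats::aov(value ~ group,
                    data = data.frame(value = unlist(groups),
                                      group = rep(names(groups), each = 5)))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- vapply(groups, mean, 0)
  # recompute each adjusted p by hand: q = |diff| / sqrt(MSE / n)
  for (i in seq_len(nrow(th))) {
    gg <- strsplit(th$pair[i], "-")[[1]]
    q <- unname(abs(means[gg[1]] - means[gg[2]])) / sqrt(mse / 5)
    p <- 1 - ptukey(q, nmeans = 3, df = 12)
    expect_equal(th$p_adj[i], p, tolerance = 1e-8)
  }
})

test_that("Tukey significance is monotone in the mean shift", {
  set.seed(109)
  base <- rnorm(6)
  flags <- vapply(c(0.1, 2, 5, 20), function(delta) {
    th <- tukey_hsd(list(a = base, b = base + delta))
    th$significant[1]
  }, TRUE)
  expect_true(all(diff(as.integer(flags)) >= 0))
})
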
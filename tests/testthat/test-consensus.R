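test_that("consensus is the arithmetic mean and rejects degenerate input", {
  expect_equal(consensus(rep(1.3, 26)), 1.3)
  expect_equal(consensus(c(1.0, 1.2, 1.4, 1.0, 1.4)), 1.2)
  expect_error(consensus(1.5), "at least 2")
  expect_error(consensus(c(1, NaN)), "non-finite")
})

test_that("deviations are signed, order-preserving and mean-zero about the mean", {
  v <- c(1.0, 1.2, 1.4, 1.0, 1.4)
  d <- deviations(v, 1.2)
  expect_equal(d, c(-0.2, 0, 0.2, -0.2, 0.2))
  expect_equal(sum(deviations(v, mean(v))), 0, tolerance = 1e-12)
  expect_equal(deviations(rep(2, 5), 2), rep(0, 5))
})

test_that("RMS dispersion is the population root-mean-square", {
  expect_equal(rms_dispersion(c(-0.2, 0, 0.2, -0.2, 0.2)), sqrt(0.16 / 5))
  expect_equal(rms_dispersion(rep(0, 8)), 0)
  expect_equal(rms_dispersion(-0.7), 0.7)
})

test_that("Levene statistic matches the hand-computed case and edge cases", {
  res <- levene_dispersion_test(c(0, 2, 4), c(1, 2, 3), center = "mean")
  expect_equal(res$W, 0.8, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(0.8, 1, 4, lower.tail = FALSE))
  # mean and median centering coincide here (symmetric groups)
  res_med <- levene_dispersion_test(c(0, 2, 4), c(1, 2, 3))
  expect_equal(res_med$W, 0.8, tolerance = 1e-12)

  same <- levene_dispersion_test(c(0, 2, 4), c(0, 2, 4))
  expect_equal(same$W, 0)

  expect_error(levene_dispersion_test(c(1, 5), c(3, 3)),
               "DEGENERATE_DISPERSION")
  expect_error(levene_dispersion_test(c(1), c(2, 3)), "at least 2")
})

test_that("Levene agrees with the independent reference implementation", {
  skip_if_not_installed("car")
  set.seed(99)
  for (i in 1:40) {
    na <- sample(3:30, 1); nb <- sample(3:30, 1)
    a <- rnorm(na, 0, runif(1, 0.5, 3))
    b <- rnorm(nb, runif(1, -1, 1), runif(1, 0.5, 3))
    for (ctr in c("median", "mean")) {
      mine <- levene_dispersion_test(a, b, center = ctr)
      ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(na, nb))),
                             center = if (ctr == "median") stats::median else mean)
      expect_equal(mine$W, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    }
  }
})

test_that("paired bias test matches the closed-form t distribution", {
  base <- c(1, 2, 3)
  res <- bias_test(base + c(0.1, 0.2, 0.0), base)
  expect_equal(res$mean_bias, 0.1, tolerance = 1e-12)
  expect_equal(res$t, sqrt(3), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-sqrt(3), 2), tolerance = 1e-9)
  expect_equal(res$p, 0.2254, tolerance = 1e-4)

  ident <- bias_test(base, base)
  expect_equal(ident$mean_bias, 0)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  degen <- bias_test(base + 0.5, base)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
  expect_equal(degen$mean_bias, 0.5)
})

simulated_table <- function(n_frames = 8, seed = 123, sd_expert = 0.1,
                            bias_ai = 0.05) {
  withr::with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_frames)) {
      fid <- sprintf("F%03d", f)
      ph <- if (f %% 2 == 1) "ED" else "ES"
      for (st in SITE_NAMES) {
        truth <- runif(1, 0.5, 3)
        for (r in 1:13) {
          for (k in 1:2) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              frame_id = fid, phase = ph, site = st,
              rater_id = sprintf("E%02d", r), repeat_index = k,
              value_cm = truth + rnorm(1, 0, sd_expert))
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          frame_id = fid, phase = ph, site = st, rater_id = "AI",
          repeat_index = 1L, value_cm = truth + bias_ai + rnorm(1, 0, sd_expert))
      }
    }
    dplyr::bind_rows(rows)
  })
}

test_that("pooled expert deviations are mean-zero per phase and site", {
  tab <- simulated_table()
  res <- build_summary(tab)
  expect_true(all(abs(res$summary$expert_dev_mean) < 1e-9))
  # per-frame deviations of experts sum to zero as well
  experts_only <- res$records[res$records$role == "expert", ]
  per_frame <- experts_only |>
    dplyr::group_by(frame_id, site) |>
    dplyr::summarise(s = sum(deviation_cm), .groups = "drop")
  expect_true(all(abs(per_frame$s) < 1e-9))
})

test_that("summary recovers structure, dispersion and bias of the panel", {
  tab <- simulated_table(n_frames = 20, sd_expert = 0.1, bias_ai = 0.3)
  res <- build_summary(tab)
  expect_equal(nrow(res$summary), 6)  # 2 phases x 3 sites
  expect_setequal(res$summary$site, SITE_NAMES)
  expect_equal(unique(res$summary$n_expert_labels), 26 * 10)
  expect_equal(unique(res$summary$n_candidate), 10)
  # expert dispersion close to the generating SD (26 labels x 10 frames)
  expect_lt(max(abs(res$summary$expert_dev_sd - 0.1)), 0.03)
  # the large simulated AI bias is detected
  expect_true(all(res$summary$bias_cm > 0.2))
  expect_true(all(res$summary$bias_p < 0.01))
  expect_equal(nrow(res$excluded), 0)
})

test_that("summary is invariant to input row order", {
  tab <- simulated_table(n_frames = 6)
  res1 <- build_summary(tab)
  res2 <- build_summary(tab[withr::with_seed(1, sample(nrow(tab))), ])
  expect_equal(res1$summary, res2$summary)
})

test_that("frames without a candidate value are reported, not silently dropped", {
  tab <- simulated_table(n_frames = 6)
  tab <- tab[!(tab$rater_id == "AI" & tab$frame_id == "F001"), ]
  res <- build_summary(tab)
  expect_true("F001" %in% res$excluded$frame_id)
  expect_equal(unique(res$summary$n_frames[res$summary$phase == "ED"]), 3)
  expect_equal(unique(res$summary$n_candidate[res$summary$phase == "ED"]), 2)
})

test_that("zero-noise panels produce zero dispersion and flagged degenerate tests", {
  tab <- simulated_table(n_frames = 4, sd_expert = 0, bias_ai = 0)
  res <- build_summary(tab)
  expect_true(all(res$summary$expert_dev_sd == 0))
  expect_true(all(res$summary$cand_dev_sd == 0))
  expect_true(all(is.na(res$summary$levene_p)))  # degenerate dispersion
  expect_true(all(res$summary$bias_p == 1))      # candidate equals consensus

  tab2 <- simulated_table(n_frames = 4, sd_expert = 0, bias_ai = 0.2)
  res2 <- build_summary(tab2)
  expect_true(all(res2$summary$bias_degenerate))
  expect_true(all(is.na(res2$summary$bias_p)))
})

test_that("duplicate or conflicting candidate rows are rejected", {
  tab <- simulated_table(n_frames = 3)
  expect_error(build_summary(dplyr::bind_rows(tab, tab[1, ])), "duplicate")
  ai_extra <- tab[tab$rater_id == "AI", ][1, ]
  ai_extra$repeat_index <- 2L
  expect_error(build_summary(dplyr::bind_rows(tab, ai_extra)),
               "more than one value")
})
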
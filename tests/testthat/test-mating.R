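test_that("plate counts convert to densities", {
  expect_equal(plate_density(40, 1e4, 0.01), 4e7)
  expect_equal(plate_density(0, 1, 1.0), 0)
  expect_equal(plate_density(1, 1, 0.5), 2)
  expect_error(plate_density(1, 1, 0), "plated_volume")
})

test_that("transfer efficiency implements gamma = T/(D R t) with censoring", {
  # T = 4e4, D = R = 1e8 cells/ml, t = 4 h -> gamma = 1e-12
  a <- make_assay(colonies_T = 40, dilution_T = 1e3)
  est <- transfer_efficiency(a)
  expect_equal(est$dens_T, 4e4)
  expect_equal(est$dens_D, 1e8)
  expect_equal(est$gamma, 1e-12)
  expect_false(est$censored)

  # zero transconjugants: 0.5 colonies at the lowest dilution screened
  a0 <- make_assay(colonies_T = 0, dilution_T = 1, plated_volume = 0.01,
                   colonies_D = 1e3, dilution_D = 1e3,
                   colonies_R = 1e3, dilution_R = 1e3)
  est0 <- transfer_efficiency(a0)
  expect_equal(est0$dens_D, 1e8)
  expect_equal(est0$gamma, 1.25e-15)
  expect_true(est0$censored)

  # linearity in the transconjugant count
  a2 <- make_assay(colonies_T = 80, dilution_T = 1e3)
  expect_equal(transfer_efficiency(a2)$gamma, 2 * est$gamma)

  expect_error(transfer_efficiency(make_assay(colonies_T = 5, colonies_D = 0)),
               "zero donor or recipient")
})

test_that("censoring threshold rises as detection gets coarser", {
  vols <- c(1, 0.1, 0.01, 0.001)
  gammas <- vapply(vols, function(v) {
    transfer_efficiency(make_assay(colonies_T = 0, dilution_T = 1,
                                   plated_volume = v,
                                   colonies_D = 100, dilution_D = 1e6 * v,
                                   colonies_R = 100, dilution_R = 1e6 * v))$gamma
  }, 0)
  expect_true(all(diff(gammas) > 0))
})

test_that("restriction efficiency pairs arms by replicate and censors", {
  est <- dplyr::bind_rows(
    make_assay(colonies_T = 100, dilution_T = 1e4, plasmid_id = "p",
               rm_system = "none", replicate = 1:2),
    make_assay(colonies_T = 100, dilution_T = 1e2, plasmid_id = "p",
               rm_system = "EcoRV", replicate = 1:2)
  ) |> transfer_efficiency()
  re <- restriction_efficiency(est)
  expect_equal(nrow(re), 2L)
  expect_equal(re$re_fold, c(100, 100))
  expect_equal(re$raw_ratio, c(0.01, 0.01))
  expect_false(any(re$censored))

  # equal arms: no defence, re_fold = 1
  est_eq <- dplyr::bind_rows(
    make_assay(colonies_T = 50, dilution_T = 1e3, plasmid_id = "p",
               rm_system = "none", replicate = 1),
    make_assay(colonies_T = 50, dilution_T = 1e3, plasmid_id = "p",
               rm_system = "EcoRI", replicate = 1)
  ) |> transfer_efficiency()
  expect_equal(restriction_efficiency(est_eq)$re_fold, 1)

  # censored RM+ arm gives a lower bound on the fold, flagged
  est_cens <- dplyr::bind_rows(
    make_assay(colonies_T = 40, dilution_T = 10, plated_volume = 0.01,
               colonies_D = 1e3, dilution_D = 1e3,
               colonies_R = 1e3, dilution_R = 1e3,
               plasmid_id = "p", rm_system = "none", replicate = 1),
    make_assay(colonies_T = 0, dilution_T = 1, plated_volume = 0.01,
               colonies_D = 1e3, dilution_D = 1e3,
               colonies_R = 1e3, dilution_R = 1e3,
               plasmid_id = "p", rm_system = "EcoRV", replicate = 1)
  ) |> transfer_efficiency()
  re_cens <- restriction_efficiency(est_cens)
  expect_equal(re_cens$gamma_minus, 1e-12)
  expect_equal(re_cens$gamma_plus, 1.25e-15)
  expect_equal(re_cens$re_fold, 800)
  expect_true(re_cens$censored)

  # unpaired extras dropped with a warning
  est_odd <- dplyr::bind_rows(
    make_assay(colonies_T = 10, dilution_T = 1e3, plasmid_id = "p",
               rm_system = "none", replicate = 1:3),
    make_assay(colonies_T = 10, dilution_T = 1e3, plasmid_id = "p",
               rm_system = "EcoRI", replicate = 1:2)
  ) |> transfer_efficiency()
  expect_warning(re_odd <- restriction_efficiency(est_odd), "extras dropped")
  expect_equal(nrow(re_odd), 2L)
})

test_that("re_fold is scale-invariant and log-antisymmetric", {
  set.seed(401)
  for (i in 1:20) {
    gp <- 10^stats::runif(1, -16, -11)
    gm <- 10^stats::runif(1, -16, -11)
    cc <- 10^stats::runif(1, -2, 2)
    expect_equal(gm / gp, (cc * gm) / (cc * gp))
    expect_equal(log(gm / gp), -log(gp / gm))
  }
})

test_that("RE summaries report geometric mean, median and censored fraction", {
  re <- tibble::tibble(
    plasmid_id = "p", rm_system = "EcoRI",
    re_fold = c(10, 1000), censored = c(FALSE, TRUE)
  )
  s <- summarize_re(re)
  expect_equal(s$geo_mean_re, 100)
  expect_equal(s$censored_frac, 0.5)
  expect_equal(summarize_re(tibble::tibble(re_fold = 14,
                                           censored = FALSE))$median_re, 14)
  # grouping and censored exclusion
  re2 <- tibble::tibble(
    plasmid_id = c("a", "a", "b"), rm_system = "EcoRI",
    re_fold = c(10, 1000, 5), censored = c(FALSE, TRUE, FALSE)
  )
  by_plasmid <- summarize_re(re2, plasmid_id)
  expect_equal(nrow(by_plasmid), 2L)
  uncens <- summarize_re(re2, include_censored = FALSE)
  expect_equal(uncens$n, 2L)
  expect_equal(uncens$mean_re, 7.5)
})

test_that("the estimator recovers a known gamma with little bias", {
  set.seed(402)
  assays <- simulate_assay(true_gamma = 1e-12, donor_density = 1e8,
                           recipient_density = 1e8, time_h = 4,
                           n_replicates = 400, dilution_series = 10^(0:6),
                           plated_volume = 1)
  est <- transfer_efficiency(assays)
  expect_false(any(est$censored))
  expect_lt(abs(mean(est$gamma) / 1e-12 - 1), 0.05)
})
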
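test_that("generated sequences hit the target GC and planted site counts", {
  rec <- generate_sequence(10000, gc = 0.6, seed = 601)
  expect_equal(rec$length, 10000L)
  expect_lt(abs(rec$gc - 0.6), 0.02)

  ecoRI <- list(name = "EcoRI", recognition = "GAATTC")
  rec5 <- generate_sequence(5000, gc = 0.5, planted = c(GAATTC = 5),
                            seed = 602)
  expect_equal(count_sites(rec5, ecoRI)$n_sites, 5L)

  rec0 <- generate_sequence(5000, gc = 0.5, forbid = "GAATTC", seed = 603)
  expect_equal(count_sites(rec0, ecoRI)$n_sites, 0L)

  # asymmetric motifs are controlled in the duplex sense
  ecoP15 <- list(name = "EcoP15", recognition = "CAGCAG")
  rec3 <- generate_sequence(4000, gc = 0.5, planted = c(CAGCAG = 3),
                            seed = 604)
  expect_equal(count_sites(rec3, ecoP15)$n_sites, 3L)

  expect_error(generate_sequence(10, planted = c(GAATTC = 5)), "too short")
})

test_that("sequence generation is deterministic under a seed", {
  a <- generate_sequence(3000, gc = 0.45, planted = c(GAATTC = 4), seed = 605)
  b <- generate_sequence(3000, gc = 0.45, planted = c(GAATTC = 4), seed = 605)
  expect_identical(a$sequence, b$sequence)
})

test_that("simulated assays are consistent with the true transfer rate", {
  set.seed(606)
  assays <- simulate_assay(true_gamma = 1e-12, donor_density = 1e8,
                           recipient_density = 1e8, n_replicates = 300,
                           p_escape = 1, n_sites = 7,
                           dilution_series = 10^(0:6), plated_volume = 1)
  est <- transfer_efficiency(assays)
  se <- stats::sd(est$gamma) / sqrt(nrow(est))
  expect_lt(abs(mean(est$gamma) - 1e-12), 3 * se)
})

test_that("the per-site escape model yields the constructed fold restriction", {
  set.seed(607)
  minus <- simulate_assay(1e-11, n_replicates = 60, p_escape = 1,
                          rm_system = "none")
  plus <- simulate_assay(1e-11, n_replicates = 60, p_escape = 0.1,
                         n_sites = 2, rm_system = "RM")
  est <- transfer_efficiency(dplyr::bind_rows(
    dplyr::mutate(minus, plasmid_id = "p"),
    dplyr::mutate(plus, plasmid_id = "p")
  ))
  re <- restriction_efficiency(est)
  # 1 / p_escape^n = 100 by construction
  expect_lt(abs(log10(geometric_mean(re$re_fold)) - 2), 0.1)
})

test_that("assays below the detection limit come back censored", {
  set.seed(608)
  assays <- simulate_assay(true_gamma = 1e-16, donor_density = 1e8,
                           recipient_density = 1e8, n_replicates = 100,
                           dilution_series = 10^(0:4), plated_volume = 0.01)
  est <- transfer_efficiency(assays)
  expect_gt(mean(est$censored), 0.9)
})

test_that("a full synthetic study recovers the escape slope", {
  specs <- tibble::tibble(
    id = paste0("p", 1:5),
    length = 3000L,
    gc = 0.5,
    n_sites = c(0L, 2L, 4L, 8L, 16L)
  )
  enz <- tibble::tibble(name = "EcoRI", rm_type = "II",
                        recognition = "GAATTC")
  study <- simulate_study(specs, enz, p_escape = 0.5, true_gamma = 1e-11,
                          n_replicates = 4, seed = 609)
  # planted counts are recovered by the scanner
  expect_equal(study$sites$n_sites, specs$n_sites)

  est <- transfer_efficiency(study$assays)
  re <- restriction_efficiency(est)
  d <- prepare_re_dataset(re, study$sites)
  fit <- fit_re_model(d, log10_re ~ n_sites)
  ci <- stats::confint(fit$model)["n_sites", ]
  expect_true(ci[1] <= log10(2) && log10(2) <= ci[2])
})

test_that("with no restriction the fitted RM effect vanishes", {
  specs <- tibble::tibble(id = paste0("p", 1:4), length = 2000L, gc = 0.5,
                          n_sites = c(1L, 3L, 6L, 9L))
  enz <- tibble::tibble(name = "EcoRI", rm_type = "II",
                        recognition = "GAATTC")
  study <- simulate_study(specs, enz, p_escape = 1, n_replicates = 6,
                          sequences = FALSE, seed = 610)
  est <- transfer_efficiency(study$assays)
  re <- restriction_efficiency(est)
  d <- prepare_re_dataset(re, study$sites)
  fit <- fit_re_model(d, log10_re ~ n_sites)
  # the slope CI includes zero at this (frozen) seed
  ci <- stats::confint(fit$model)["n_sites", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("study simulation writes a deterministic fixture set", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  specs <- tibble::tibble(id = c("p1", "p2"), length = 1500L, gc = 0.5,
                          n_sites = c(1L, 4L))
  enz <- tibble::tibble(name = "EcoRI", rm_type = "II",
                        recognition = "GAATTC")
  a <- simulate_study(specs, enz, seed = 611, outdir = dir_a)
  b <- simulate_study(specs, enz, seed = 611, outdir = dir_b)
  for (f in c("plasmids.fa", "enzymes.tsv", "assays.tsv", "sites.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), info = f)
  }
  # round trip through the package readers
  plasmids <- read_fasta(file.path(dir_a, "plasmids.fa"))
  expect_equal(plasmids$id, c("p1", "p2"))
  expect_identical(plasmids$sequence, a$plasmids$sequence)
  enzymes <- parse_enzyme_table(file.path(dir_a, "enzymes.tsv"))
  expect_equal(enzymes$recognition, "GAATTC")
  assays <- read_assays(file.path(dir_a, "assays.tsv"))
  expect_equal(nrow(assays), nrow(a$assays))
})
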
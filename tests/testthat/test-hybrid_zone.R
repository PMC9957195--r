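test_that("allele frequencies match every printed Table 4 cell", {
  af <- allele_frequencies(table4_genotypes())
  aut <- af[af$linkage == "autosomal", ]
  xlk <- af[af$linkage == "x_linked", ]
  ord <- c("ARU", "GAB", "HER", "POR", "CM", "PAZ", "ESC")
  aut <- aut[match(ord, aut$population), ]
  xlk <- xlk[match(ord, xlk$population), ]

  expect_equal(aut$q_B, q_autosomal_exact)
  expect_equal(xlk$q_B, q_xlinked_exact)
  # printed cells after 2-decimal half-up rounding
  expect_equal(round_half_up(aut$q_B), c(0, 0, 0.07, 0.13, 0.31, 1, 1))
  expect_equal(round_half_up(aut$p_N), c(1, 1, 0.93, 0.88, 0.69, 0, 0))
  expect_equal(round_half_up(xlk$q_B), c(0, 0, 0, 0, 0.40, 1, 0.78))
  expect_equal(round_half_up(xlk$p_N), c(1, 1, 1, 1, 0.60, 0, 0.22))
  # exact conservation on every row
  expect_true(all(af$p_N + af$q_B == 1))
  expect_equal(aut$n_chromosomes, c(26L, 14L, 14L, 24L, 16L, 20L, 28L))
  expect_equal(xlk$n_chromosomes, c(8L, 8L, 8L, 9L, 10L, 9L, 9L))

  zero <- data.frame(population = "Z", marker = "m", linkage = "autosomal",
                     NN = 0L, NB = 0L, BB = 0L, N = NA, B = NA)
  expect_error(allele_frequencies(zero), "zero")
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(0.875), 0.88)
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round_half_up(0.1249), 0.12)
})

test_that("build_cline orders sites and flags unmatched populations", {
  gt <- table4_genotypes(); sites <- table1_sites()
  cl <- build_cline(gt, sites, "CpaTR100-295")
  expect_s3_class(cl, "cline_profile")
  expect_equal(cl$population, c("ARU", "GAB", "HER", "POR", "CM", "PAZ", "ESC"))
  expect_equal(cl$q_B, q_autosomal_exact)

  bad <- gt
  bad$population[1] <- "NOWHERE"
  expect_error(build_cline(bad, sites, "CpaTR100-295"), "NOWHERE")
  expect_error(build_cline(gt, sites, "missing-marker"), "no genotypes")

  single <- build_cline(gt[gt$population == "CM", ], sites[5, ], "CpaTR100-295")
  expect_equal(nrow(single), 1)
})

test_that("cline_center finds the 0.5 crossing and the nearest site", {
  gt <- table4_genotypes(); sites <- table1_sites()
  cc_a <- cline_center(build_cline(gt, sites, "CpaTR100-295"))
  expect_true(cc_a$crossing)
  expect_equal(cc_a$interval, c("CM", "PAZ"))
  expect_equal(cc_a$nearest_site, "CM")  # |0.3125 - 0.5| < |1 - 0.5|
  cc_x <- cline_center(build_cline(gt, sites, "CpaTR104-269"))
  expect_equal(cc_x$nearest_site, "CM")

  # step profile: tie between the step endpoints resolved to the first
  step <- data.frame(population = paste0("S", 1:4), order_index = 1:4,
                     q_B = c(0, 0, 1, 1))
  class(step) <- c("cline_profile", "data.frame")
  cc_s <- cline_center(step)
  expect_equal(cc_s$interval, c("S2", "S3"))
  expect_equal(cc_s$nearest_site, "S2")

  flat <- data.frame(population = paste0("S", 1:3), order_index = 1:3,
                     q_B = c(0, 0.1, 0.2))
  class(flat) <- c("cline_profile", "data.frame")
  expect_false(cline_center(flat)$crossing)

  # noise-free sigmoid planted between sites 3 and 4
  sim <- simulate_transect(center = 3.5, width = 0.5, n_per_site = 20,
                           linkage = "autosomal", seed = 1)
  prof <- data.frame(population = sim$population, order_index = 1:7,
                     q_B = sim$true_q)
  class(prof) <- c("cline_profile", "data.frame")
  cc <- cline_center(prof)
  expect_equal(cc$interval, c("S3", "S4"))
  expect_equal(cc$center_order, 3.5)
})

test_that("paired_mean_difference reproduces the two-marker effect size", {
  pe <- paired_mean_difference(q_autosomal_exact, q_xlinked_exact, seed = 42)
  expect_equal(round(pe$mean_difference, 4), -0.0473)
  expect_lt(pe$ci_low, 0)
  expect_gt(pe$ci_high, 0)  # non-significant difference: CI spans zero
  # reproducible under the same seed
  pe2 <- paired_mean_difference(q_autosomal_exact, q_xlinked_exact, seed = 42)
  expect_identical(pe[c("ci_low", "ci_high")], pe2[c("ci_low", "ci_high")])

  same <- paired_mean_difference(1:5 / 5, 1:5 / 5, seed = 7)
  expect_equal(same$mean_difference, 0)
  expect_lte(same$ci_low, 0)
  expect_gte(same$ci_high, 0)

  deg <- paired_mean_difference(c(0, 0), c(1, 1), seed = 7)
  expect_equal(deg$mean_difference, 1)
  expect_equal(c(deg$ci_low, deg$ci_high), c(1, 1))

  expect_error(paired_mean_difference(1:3, 1:4, seed = 1), "length")
  expect_error(paired_mean_difference(1:3 + 0, 1:3 + 0), "seed")
})

test_that("BCa interval coverage is near nominal on synthetic paired data", {
  # normal paired differences with known mean; moderate n keeps the BCa
  # approximation in its comfort zone
  delta <- 0.3
  set.seed(777)
  seeds <- sample.int(1e6, 1000)
  covered <- vapply(seq_along(seeds), function(i) {
    d <- rnorm(100, delta, 1)
    pe <- paired_mean_difference(numeric(100), d, n_boot = 999L,
                                 seed = seeds[i])
    pe$ci_low <= delta && delta <= pe$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
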
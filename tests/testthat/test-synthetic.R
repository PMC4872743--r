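test_that("single-pathway citrate species land on their diagnostic shifts", {
  gln <- tracer_spec("U13C5_glutamine")

  red <- simulate_citrate_mids(routing_fractions(f_red_gln = 1), gln)
  expect_equal(unname(red[["459"]][6]), 1)           # m+5 in the full molecule
  expect_equal(unname(red[["273"]][6]), 1)           # C5 fragment keeps all 5

  ox <- simulate_citrate_mids(routing_fractions(f_ox_gln = 1), gln)
  expect_equal(unname(ox[["375"]][5]), 1)            # m+4 full
  expect_equal(unname(ox[["273"]][4]), 1)            # m+3 after losing the carboxyl

  fix <- simulate_citrate_mids(routing_fractions(f_unlab = 1, f_fix = 1),
                               tracer_spec("C13_bicarbonate"))
  expect_equal(unname(fix[["459"]][2]), 1)           # m+1 full molecule
  expect_equal(unname(fix[["273"]][1]), 1)           # m+0: C5 lacks the fixed carbon

  glc <- simulate_citrate_mids(routing_fractions(f_ox_glc = 1),
                               tracer_spec("U13C6_glucose"))
  expect_equal(unname(glc[["375"]][3]), 1)           # m+2 from labelled acetyl-CoA
  pc <- simulate_citrate_mids(routing_fractions(f_pc = 1),
                              tracer_spec("U13C6_glucose"))
  expect_equal(unname(pc[["375"]][4]), 1)            # m+3 via carboxylated pyruvate
})

test_that("mixtures are the fraction-weighted sum of pure-pathway MIDs", {
  mix <- simulate_citrate_mids(
    routing_fractions(f_ox_gln = 0.5, f_red_gln = 0.5),
    tracer_spec("U13C5_glutamine"))
  expect_equal(unname(mix[["375"]][5]), 0.5)
  expect_equal(unname(mix[["375"]][6]), 0.5)

  set.seed(41)
  for (i in 1:20) {
    f <- random_simplex(5)
    fr <- routing_fractions(f[1], f[2], f[3], f[4], f[5], f_fix = runif(1))
    for (tn in c("U13C6_glucose", "U13C5_glutamine", "C13_bicarbonate")) {
      mixed <- simulate_citrate_mids(fr, tracer_spec(tn))
      pure <- lapply(c("f_ox_glc", "f_ox_gln", "f_red_gln", "f_pc", "f_unlab"),
                     function(r) {
                       args <- setNames(list(1), r)
                       args$f_fix <- fr$f_fix
                       simulate_citrate_mids(do.call(routing_fractions, args),
                                             tracer_spec(tn))
                     })
      for (mz in names(mixed)) {
        weighted <- Reduce(`+`, Map(function(p, w) w * p[[mz]],
                                    pure, f))
        expect_equal(unname(mixed[[mz]]), unname(weighted), tolerance = 1e-12)
        expect_equal(sum(mixed[[mz]]), 1, tolerance = 1e-9)
        expect_true(all(mixed[[mz]] >= 0))
      }
    }
  }
})

test_that("fragment MIDs equal the 2^6 per-carbon enumeration oracle", {
  set.seed(99)
  for (i in 1:10) {
    f <- random_simplex(5)
    fr <- routing_fractions(f[1], f[2], f[3], f[4], f[5], f_fix = runif(1))
    for (tn in c("U13C6_glucose", "U13C5_glutamine", "C13_bicarbonate")) {
      sim <- simulate_citrate_mids(fr, tracer_spec(tn))
      expect_equal(unname(sim[["273"]]), oracle_citrate_mid(fr, tn, 1:5),
                   tolerance = 1e-12)
      expect_equal(unname(sim[["375"]]), oracle_citrate_mid(fr, tn, 1:6),
                   tolerance = 1e-12)
    }
  }
})

test_that("simulator validates fractions and fragments", {
  expect_error(routing_fractions(0.5, 0.2), "sum to 1")
  expect_error(routing_fractions(-0.1, 1.1), "\\[0, 1\\]")
  expect_error(fragment_lookup(999L), "unknown fragment")
})

test_that("natural-abundance convolution matches the binomial envelope", {
  mid <- c(1)
  expect_equal(unname(convolve_natural_abundance(mid, 1, 0.0107)),
               c(0.9893, 0.0107))
  # identity at p13c = 0
  m <- as_mid(c(0.2, 0.3, 0.5))
  conv0 <- convolve_natural_abundance(m, 8, 0)
  expect_equal(unname(conv0[1:3]), c(0.2, 0.3, 0.5))
  expect_equal(sum(conv0), 1, tolerance = 1e-12)
  # general case still a distribution
  conv <- convolve_natural_abundance(m, 12, 0.0107)
  expect_equal(sum(conv), 1, tolerance = 1e-12)
})

test_that("noise-free intensity tables are exactly the scaled convolution", {
  mids <- list(`375` = as_mid(c(0.25, 0, 0.75, 0, 0, 0, 0)))
  tab <- generate_intensity_table(mids, c(citrate = 1000), p13c = 0,
                                  noise = noise_model(0, 0),
                                  internal_standard_area = 5e5)
  cit <- tab[tab$metabolite == "citrate", ]
  expect_equal(cit$S1[cit$mass_shift == 0], 250)
  expect_equal(cit$S1[cit$mass_shift == 2], 750)
  expect_equal(tab$S1[tab$metabolite == "cinnamic_acid"], 5e5)

  one <- generate_intensity_table(list(`375` = 1), c(citrate = 1000),
                                  p13c = 0, noise = noise_model(0, 0))
  expect_equal(one$S1[one$metabolite == "citrate" & one$mass_shift == 0], 1000)

  expect_error(generate_intensity_table(mids, c(citrate = -5), p13c = 0),
               ">= 0")
})

test_that("noisy tables are reproducible under a fixed seed", {
  mids <- simulate_citrate_mids(routing_fractions(f_red_gln = 0.4,
                                                  f_unlab = 0.6),
                                tracer_spec("U13C5_glutamine"))
  t1 <- generate_intensity_table(mids, c(citrate = 2000),
                                 noise = noise_model(0.1, 5, seed = 11),
                                 n_samples = 3)
  t2 <- generate_intensity_table(mids, c(citrate = 2000),
                                 noise = noise_model(0.1, 5, seed = 11),
                                 n_samples = 3)
  expect_identical(t1, t2)
  t3 <- generate_intensity_table(mids, c(citrate = 2000),
                                 noise = noise_model(0.1, 5, seed = 12),
                                 n_samples = 3)
  expect_false(identical(t1$S1, t3$S1))
})

test_that("expression generator plants consistent truth labels", {
  gen0 <- generate_expression_experiments(50, 0, seed = 2)
  expect_false(any(gen0$truth$regulated))

  g1 <- generate_expression_experiments(100, 10, seed = 3)
  g2 <- generate_expression_experiments(100, 10, seed = 3)
  expect_identical(g1, g2)
  expect_equal(sum(g1$truth$regulated), 10)
  expect_true(all(g1$truth$sign[g1$truth$regulated] %in% c(-1, 1)))

  expect_error(generate_expression_experiments(10, 11), "<=")
})

test_that("selection recovers the planted set at vanishing noise", {
  gen <- generate_expression_experiments(500, 25, log2_effect = 5,
                                         replicate_cv = 1e-4, seed = 8)
  zs <- z_transform(gen$experiments, window = 50)
  sel <- select_consistent_top(zs, q = 0.10)
  planted <- gen$truth$gene[gen$truth$regulated]
  expect_setequal(sel$selected$gene, planted)
})

test_that("binary association generator hits marginals and modes", {
  ind <- generate_binary_association_dataset(20000, 0.4, 0.3,
                                             mode = "independent", seed = 4)
  expect_equal(mean(ind$a), 0.4, tolerance = 0.02)
  expect_equal(mean(ind$b), 0.3, tolerance = 0.02)
  or_ <- pair_test(ind$a, ind$b)$odds_ratio
  expect_equal(or_, 1, tolerance = 0.1)

  excl <- generate_binary_association_dataset(500, 0.4, 0.4,
                                              mode = "exclusive",
                                              strength = 1, seed = 5)
  expect_equal(sum(excl$a & excl$b), 0)

  r1 <- generate_binary_association_dataset(100, 0.5, 0.5,
                                            mode = "cooccurring",
                                            strength = 0.8, seed = 6)
  r2 <- generate_binary_association_dataset(100, 0.5, 0.5,
                                            mode = "cooccurring",
                                            strength = 0.8, seed = 6)
  expect_identical(r1, r2)
  expect_error(generate_binary_association_dataset(10, 0, 0.5), "\\(0, 1\\)")
})
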
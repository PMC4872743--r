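make_table <- function(intensities, mz = 375L, metabolite = "citrate",
                       ist = 1000, samples = "S1") {
  rows <- data.frame(metabolite = metabolite, fragment_mz = mz,
                     mass_shift = seq_along(intensities) - 1L)
  for (s in samples) rows[[s]] <- intensities
  ist_row <- data.frame(metabolite = "cinnamic_acid", fragment_mz = 131L,
                        mass_shift = 0L)
  for (s in samples) ist_row[[s]] <- ist
  rbind(rows, ist_row)
}

test_that("internal-standard normalization is a per-sample ratio", {
  tab <- make_table(c(1500, 500), ist = 1000)
  nq <- normalize_to_internal_standard(tab)
  expect_equal(nq$normalized_quantity, 2.0)

  # scaling one sample's intensities leaves its normalized quantity unchanged
  tab2 <- make_table(c(1500, 500), ist = 1000, samples = c("S1", "S2"))
  tab2$S2 <- tab2$S2 * 10
  nq2 <- normalize_to_internal_standard(tab2)
  expect_equal(nq2$normalized_quantity[nq2$sample == "S1"],
               nq2$normalized_quantity[nq2$sample == "S2"])

  bad <- make_table(c(100, 50), ist = 0)
  expect_error(normalize_to_internal_standard(bad), "sample S1")
  nois <- make_table(c(100, 50))[1:2, ]
  expect_error(normalize_to_internal_standard(nois), "internal-standard")
})

test_that("quantifier fragment is the one retaining most carbons", {
  tab <- rbind(make_table(c(900, 100), mz = 273L)[1:2, ],
               make_table(c(300, 100), mz = 375L))
  nq <- normalize_to_internal_standard(tab, catalogue = citrate_fragments())
  expect_equal(unique(nq$fragment_mz), 375L)
  expect_equal(nq$normalized_quantity, 0.4)
})

test_that("raw MIDs renormalize intensities and ignore row order", {
  tab <- make_table(c(900, 100))
  expect_equal(unname(raw_mid(tab, "citrate", 375L, "S1")), c(0.9, 0.1))

  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(raw_mid(shuffled, "citrate", 375L, "S1"),
               raw_mid(tab, "citrate", 375L, "S1"))

  single <- make_table(500)
  expect_equal(unname(raw_mid(single, "citrate", 375L, "S1")), 1.0)

  zero <- make_table(c(0, 0))
  expect_error(raw_mid(zero, "citrate", 375L, "S1"), "undefined")
})

test_that("technical duplicates average on the intensity scale", {
  tab <- make_table(c(800, 200), samples = c("A1", "A2"))
  tab$A2 <- c(600, 400, 1000)
  avg <- average_technical_duplicates(tab, c(A1 = "A", A2 = "A"))
  expect_equal(avg$A, c(700, 300, 1000))
})

test_that("label incorporation follows the reference-scaling formula", {
  ref <- c(0.95, 0.05)
  # unlabeled identity
  expect_equal(label_incorporation(ref, ref)$incorporation, 0)
  # fully labeled limit
  full <- label_incorporation(c(0, 0, 0, 0, 0, 1), ref)
  expect_equal(full$incorporation, 1)
  # hand-computed worked example: expected m+1 = 0.475*0.05/0.95 = 0.025,
  # excess only at m+2 (0.5), incorporation = 0.5/(0.475+0.5)
  ex <- label_incorporation(c(0.475, 0.025, 0.5), ref)
  expect_equal(ex$incorporation, 0.5 / 0.975, tolerance = 1e-12)
  expect_equal(unname(ex$excess_mid), c(0, 0, 1))
  expect_equal(ex$clipped_mass, 0)

  expect_error(label_incorporation(c(0.5, 0.5), c(0, 1)), "degenerate")
})

test_that("negative excess is clipped and reported as QC", {
  # sample has less m+1 than natural abundance predicts
  res <- label_incorporation(c(0.93, 0.02, 0.05), c(0.95, 0.05))
  pred_m1 <- 0.93 * 0.05 / 0.95
  expect_equal(res$clipped_mass, pred_m1 - 0.02, tolerance = 1e-12)
  expect_equal(res$incorporation, 0.05 / (0.93 + 0.05), tolerance = 1e-12)
})

test_that("incorporation is monotone when mass moves from m+0 upward", {
  ref <- natural_abundance_reference(15)
  set.seed(13)
  for (i in 1:25) {
    s <- random_simplex(6)
    base <- label_incorporation(s, ref)$incorporation
    delta <- runif(1, 0, s[1])
    shift <- sample(2:6, 1)
    s2 <- s
    s2[1] <- s2[1] - delta
    s2[shift] <- s2[shift] + delta
    expect_gte(label_incorporation(s2, ref)$incorporation, base - 1e-12)
  }
})

test_that("forward-model round trip recovers planted incorporation", {
  # with no isotope background the estimator is exact on the grid
  for (g in seq(0, 1, by = 0.1)) {
    fr <- routing_fractions(f_red_gln = g, f_unlab = 1 - g)
    mids <- simulate_citrate_mids(fr, tracer_spec("U13C5_glutamine"))
    tab <- generate_intensity_table(mids["273"], c(citrate = 1e4), p13c = 0,
                                    noise = noise_model(0, 0))
    mid <- raw_mid(tab, "citrate", 273L, "S1")
    ref <- natural_abundance_reference(11, 0)
    got <- label_incorporation(mid, ref)$incorporation
    expect_equal(got, g, tolerance = 1e-6)
  }
})

test_that("labelled quantity is the product of its two factors", {
  fr <- routing_fractions(f_red_gln = 1)
  mids <- simulate_citrate_mids(fr, tracer_spec("U13C5_glutamine"))
  tab <- generate_intensity_table(mids["375"], c(citrate = 2000), p13c = 0,
                                  noise = noise_model(0, 0),
                                  internal_standard_area = 1000)
  lq <- labelled_quantities(tab, tracer = tracer_spec("U13C5_glutamine"),
                            p13c = 0)
  expect_equal(lq$normalized_quantity, 2.0)
  expect_equal(lq$label_incorporation, 1.0)
  expect_equal(lq$labelled_quantity, 2.0)
  expect_true(all(lq$labelled_quantity <= lq$normalized_quantity + 1e-12))
})

test_that("unlabeled control samples report near-zero labelled quantities", {
  fr <- routing_fractions(f_unlab = 1)
  mids <- simulate_citrate_mids(fr, tracer_spec("unlabeled"))
  tab <- generate_intensity_table(mids, c(citrate = 5000), p13c = 0.0107,
                                  noise = noise_model(0, 0))
  lq <- labelled_quantities(tab, tracer = tracer_spec("unlabeled"),
                            p13c = 0.0107)
  expect_true(all(lq$labelled_quantity < 1e-9))
})

test_that("a planted two-condition labelling contrast is recovered", {
  # lactate-style readout: condition B halves the labelled fraction
  lac_frag <- data.frame(metabolite = "lactate", nominal_mz = 219L,
                         metabolite_carbons_retained = 3L,
                         lost_carbon_position = "none",
                         derivatization = "MSTFA", extra_carbons = 4L,
                         stringsAsFactors = FALSE)
  mk <- function(g, seed) {
    mid <- as_mid(c(1 - g, 0, 0, g))        # m+3 labelled lactate
    generate_intensity_table(list(`219` = mid), c(lactate = 3000),
                             fragments = lac_frag, p13c = 0,
                             noise = noise_model(0.02, 0, seed = seed),
                             n_samples = 3)
  }
  refs <- list(`lactate:219` = natural_abundance_reference(7, 0))
  lqA <- labelled_quantities(mk(0.6, 21), refs, tracer_spec("U13C6_glucose"),
                             catalogue = lac_frag, p13c = 0)
  lqB <- labelled_quantities(mk(0.3, 22), refs, tracer_spec("U13C6_glucose"),
                             catalogue = lac_frag, p13c = 0)
  ratio <- mean(lqB$labelled_quantity) / mean(lqA$labelled_quantity)
  expect_equal(ratio, 0.5, tolerance = 0.1)
})
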
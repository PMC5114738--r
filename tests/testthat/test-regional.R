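test_that("segment assignment follows the AHA 16-segment convention", {
  mid <- tiny_phantom("mid")
  seg_mid <- assign_segments(mid)
  myo <- mid$label_map == 2L
  expect_setequal(unique(seg_mid[myo]), 7:12)
  expect_true(all(is.na(seg_mid[!myo])))

  bas <- tiny_phantom("basal")
  expect_setequal(unique(na.omit(as.vector(assign_segments(bas)))), 1:6)

  api <- make_phantom(nx = 120, ny = 120, r_endo = 14, r_epi = 22,
                      slice = "apical")
  seg_api <- assign_segments(api)
  tab <- table(seg_api[api$label_map == 2L])
  expect_setequal(as.integer(names(tab)), 13:16)
  # four 90-degree sectors have near-equal pixel counts
  expect_lt(diff(range(tab)) / mean(tab), 0.1)

  # tie rule: a pixel exactly on the anterior boundary (12 o'clock with the
  # insertion at 0 deg) goes to the lower-numbered sector
  odd <- make_phantom(nx = 49, ny = 49, r_endo = 7, r_epi = 11, slice = "mid")
  seg_odd <- assign_segments(odd)
  expect_equal(seg_odd[25, 25 + 9], 7L)
})

test_that("segment statistics report mean, sample SD and exclusions", {
  labels <- matrix(NA_integer_, 4, 4)
  labels[1, 1:2] <- 7L
  labels[2, 1:3] <- 8L
  vals <- matrix(NA_real_, 4, 4)
  vals[1, 1:2] <- c(1400, 1600)
  vals[2, 1:3] <- c(1500, 1500, 1500)
  map <- structure(list(values = vals,
                        valid_mask = !is.na(vals),
                        diagnostics = list(), sequence_id = "SASHA"),
                   class = "parameter_map")
  st <- segment_stats(map, labels, subject_id = "S01", session = "native")
  expect_equal(st$mean_t1[st$segment_id == 7], 1500)
  expect_equal(st$sd_t1[st$segment_id == 7], stats::sd(c(1400, 1600)))
  expect_equal(round(st$sd_t1[st$segment_id == 7], 2), 141.42)
  expect_equal(st$sd_t1[st$segment_id == 8], 0)
  # dropping valid pixels below the threshold flags exclusion
  map$valid_mask[1, 1:2] <- FALSE
  st2 <- segment_stats(map, labels)
  expect_true(st2$excluded[st2$segment_id == 7])
  expect_false(st2$excluded[st2$segment_id == 8])
})

test_that("gadolinium concentration reproduces the relaxation-rate arithmetic", {
  expect_equal(compute_concentration(1000, 1000), 0)
  # typical 3T inversion-recovery means, myocardium and blood, in umol/L
  expect_equal(1000 * compute_concentration(1182.6, 541.1), 286.4,
               tolerance = 1e-3)
  expect_equal(1000 * compute_concentration(1781.4, 349.1), 658.3,
               tolerance = 1e-3)
  expect_error(compute_concentration(-5, 500), "positive")
})

test_that("ECV formula satisfies its limits and identities", {
  expect_equal(compute_ecv(1200, 600, 1800, 400, hct = 1 - 1e-12), 0,
               tolerance = 1e-9)
  expect_equal(compute_ecv(1200, 600, 1200, 600, hct = 1e-12), 1,
               tolerance = 1e-9)
  # typical post-contrast means with hct 0.40
  expect_equal(compute_ecv(1182.6, 541.1, 1781.4, 349.1, 0.40), 0.261,
               tolerance = 1e-2)
  # invariant to a common rescaling of all four T1 inputs
  expect_equal(compute_ecv(1182.6, 541.1, 1781.4, 349.1, 0.40),
               compute_ecv(2 * 1182.6, 2 * 541.1, 2 * 1781.4, 2 * 349.1, 0.40),
               tolerance = 1e-12)
  # agreement with the concentration route: ECV = (1-hct) c_myo / c_blood
  cm <- compute_concentration(1182.6, 541.1)
  cb <- compute_concentration(1781.4, 349.1)
  expect_equal(compute_ecv(1182.6, 541.1, 1781.4, 349.1, 0.40),
               0.60 * cm / cb, tolerance = 1e-12)
  expect_error(compute_ecv(1200, 600, 1800, 1900, 0.4), "enhancement")
})

test_that("segment labels partition the myocardium exactly once", {
  for (sl in c("basal", "mid", "apical")) {
    ph <- tiny_phantom(sl)
    seg <- assign_segments(ph)
    myo <- ph$label_map == 2L
    expect_true(all(!is.na(seg[myo])))
    expect_true(all(is.na(seg[!myo])))
  }
})

test_that("bullseye summaries average segments without weighting", {
  tab <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(subject_id = sprintf("S%02d", s), sequence_id = "SASHA",
               session = "native", slice = "mid", segment_id = 7:12,
               mean_t1 = 1500 + s * 10 + (7:12), sd_t1 = 40 + s,
               n_pixels = c(100, 10, 100, 10, 100, 10), excluded = FALSE)
  }))
  class(tab) <- c("segment_table", "data.frame")
  be <- bullseye_table(tab)
  expect_equal(nrow(be$segments), 6)
  # global average is the unweighted mean of segment means
  expect_equal(unname(be$global["t1"]), mean(tab$mean_t1))
  expect_equal(unname(be$global["precision"]), mean(tab$sd_t1))
  # single subject, uniform map: all entries identical
  uni <- tab[tab$subject_id == "S01", ]
  uni$mean_t1 <- 1500
  class(uni) <- c("segment_table", "data.frame")
  be2 <- bullseye_table(uni)
  expect_true(all(be2$segments$t1 == 1500))
  # excluded rows are dropped
  tab2 <- tab; tab2$excluded[1] <- TRUE
  expect_equal(nrow(bullseye_table(tab2)$segments), 6)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(be, what = "t1"))
})
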
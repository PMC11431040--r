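test_that("the rescaled-average baseline evaluates to A at N = 0 and grows with q", {
  expect_equal(baseline_at(degradation_baseline(3.5, 0.000001), 0), 3.5)
  expect_equal(baseline_at(degradation_baseline(8.8, 0.00035), 0), 8.8)
  expect_equal(baseline_at(degradation_baseline(1, 1), 3), 8)

  b <- degradation_baseline(2, 0.001)
  v <- baseline_at(b, 0:100)
  expect_true(all(diff(v) > 0))
  expect_equal(baseline_at(degradation_baseline(2, 0), 0:100), rep(2, 101))
  expect_error(baseline_at(b, -1), class = "mprtseq_input_error")
  expect_error(degradation_baseline(0, 0.1))
  expect_error(degradation_baseline(1, -0.1))
})

test_that("baseline tidiers expose A and q", {
  b <- degradation_baseline(3.5, 1e-6, "freeze_thaw")
  td <- generics::tidy(b)
  expect_equal(td$estimate[td$term == "A"], 3.5)
  expect_equal(generics::glance(b)$regime, "freeze_thaw")
})

test_that("high-intensity classification is strict and oracle-equivalent", {
  b <- degradation_baseline(2, 0)
  tie <- toy_profile(rep(2, 20))
  expect_false(any(classify_high_intensity(tie, b)$high))

  one <- toy_profile(c(rep(1, 9), 4, rep(1, 10)))
  m <- classify_high_intensity(one, b)
  expect_equal(which(m$high), 10L)

  bq <- degradation_baseline(1.3, 0.01)
  prof <- toy_profile(withr::with_seed(8, c(runif(200, 0, 3), NA, NA)))
  mask <- classify_high_intensity(prof, bq)
  # element-wise oracle
  for (i in seq_len(202)) {
    expected <- !is.na(prof$reactivity[i]) &&
      prof$reactivity[i] > 1.3 * (1 + 0.01)^i
    expect_identical(mask$high[i], expected)
  }
})

mask_from <- function(high_positions, L) {
  tibble::tibble(position = seq_len(L), high = seq_len(L) %in% high_positions)
}

test_that("hotspot calling intersects conditions and enforces min_high", {
  L <- 2896L
  regions <- reference_hotspot_regions()
  highs <- unlist(purrr::map2(regions$start, regions$end, seq))
  both <- list(freeze_thaw = mask_from(highs, L),
               heat_37C = mask_from(highs, L))
  calls <- find_hotspots(both)
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$start, regions$start)
  expect_equal(calls$end, regions$end)

  # a run present in only one condition is dropped under intersection
  only_one <- list(freeze_thaw = mask_from(highs, L),
                   heat_37C = mask_from(integer(0), L))
  expect_equal(nrow(find_hotspots(only_one)), 0L)
  # ... but kept when any condition suffices
  expect_equal(nrow(find_hotspots(only_one, require_all_conditions = FALSE)),
               4L)

  # highs at {10, 15} with max_gap 3: two singleton runs, both < min_high
  sparse <- list(a = mask_from(c(10L, 15L), 50L),
                 b = mask_from(c(10L, 15L), 50L))
  expect_equal(nrow(find_hotspots(sparse, min_high = 2, max_gap = 3)), 0L)
  expect_equal(nrow(find_hotspots(sparse, min_high = 1, max_gap = 3)), 2L)

  expect_error(find_hotspots(list()), class = "mprtseq_config_error")
})

test_that("run merging matches a brute-force oracle over gap placements", {
  # all two-high placements in a window: merged iff distance <= max_gap
  for (gap in c(1L, 3L)) {
    for (d in 1:6) {
      m <- list(a = mask_from(c(10L, 10L + d), 40L),
                b = mask_from(c(10L, 10L + d), 40L))
      calls <- find_hotspots(m, min_high = 2, max_gap = gap)
      if (d <= gap) {
        expect_equal(nrow(calls), 1L)
        expect_equal(c(calls$start, calls$end), c(10L, 10L + d))
      } else {
        expect_equal(nrow(calls), 0L)  # two singletons, each below min_high
      }
    }
  }
})

test_that("hotspot calls are order-invariant and non-overlapping", {
  L <- 300L
  set.seed(21)
  for (rep in 1:5) {
    ha <- sort(sample(L, 30))
    hb <- sort(sample(L, 30))
    ab <- find_hotspots(list(a = mask_from(ha, L), b = mask_from(hb, L)))
    ba <- find_hotspots(list(b = mask_from(hb, L), a = mask_from(ha, L)))
    expect_equal(as.data.frame(ab), as.data.frame(ba))
    if (nrow(ab) > 1) {
      expect_true(all(ab$start[-1] > ab$end[-nrow(ab)]))
    }
  }
})

test_that("fold change is the window mean over the reference", {
  prof <- toy_profile(rep(3.5 * 15.8, 10))
  expect_equal(fold_change(prof, 1, 10, 3.5), 15.8)
  expect_equal(fold_change(toy_profile(rep(471.1, 5)), 1, 5, 3.5), 134.6,
               tolerance = 1e-10)
  expect_equal(fold_change(toy_profile(rep(510.51, 5)), 1, 5, 23.1), 22.1,
               tolerance = 1e-10)
  expect_equal(fold_change(toy_profile(rep(7, 4)), 2, 3, 7), 1)
  expect_error(fold_change(toy_profile(c(NA_real_, NA_real_)), 1, 2, 1),
               class = "mprtseq_input_error")
})

test_that("composition stats tally bases at high positions", {
  seq <- "CCGAU"
  mask <- tibble::tibble(position = 1:5, high = c(T, T, T, T, F))
  cs <- composition_stats(mask, seq)
  expect_equal(attr(cs, "n_high"), 4L)
  expect_equal(cs$proportion[cs$base == "C"], 0.5)
  expect_equal(cs$proportion[cs$base == "G"], 0.25)
  expect_equal(cs$proportion[cs$base == "A"], 0.25)
  expect_equal(cs$proportion[cs$base == "U"], 0)

  allc <- composition_stats(tibble::tibble(position = 1:3, high = TRUE), "CCC")
  expect_equal(allc$proportion[allc$base == "C"], 1)

  none <- composition_stats(tibble::tibble(position = 1:3, high = FALSE), "ACG")
  expect_equal(attr(none, "n_high"), 0L)
  expect_true(all(is.na(none$proportion)))

  # counting oracle on random masks
  cons <- toy_construct(120)
  bases <- strsplit(cons$sequence, "")[[1]]
  set.seed(9)
  for (rep in 1:3) {
    hi <- sample(c(TRUE, FALSE), 120, replace = TRUE)
    cs <- composition_stats(tibble::tibble(position = 1:120, high = hi),
                            cons$sequence)
    for (b in c("A", "C", "G", "U")) {
      expect_equal(cs$count[cs$base == b], sum(bases[hi] == b))
    }
    expect_equal(sum(cs$proportion), 1)
  }
})

test_that("hotspot exports are well-formed", {
  L <- 2896L
  regions <- reference_hotspot_regions()
  highs <- unlist(purrr::map2(regions$start, regions$end, seq))
  calls <- find_hotspots(list(a = mask_from(highs, L),
                              b = mask_from(highs, L)),
                         construct = reference_construct())
  expect_equal(calls$sequence[1], "GCC")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_hotspots_bed(calls, bed)
  lines <- readr::read_tsv(bed, col_names = FALSE, col_types = "ciicic")
  expect_equal(lines$X2, regions$start - 1L)  # 0-based half-open
  expect_equal(lines$X3, regions$end)

  js <- withr::local_tempfile(fileext = ".json")
  write_hotspots_json(calls, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$calls), 4L)
})
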
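ref_primer <- function(ps, pe = ps + 19L, name = "P") {
  rt_primer_panel(data.frame(name = name, pairing_start = ps,
                             pairing_end = pe))
}

test_that("peaks map to template positions as pairing_start - cdna_length", {
  p554 <- ref_primer(554)
  expect_equal(
    peaks_to_positions(tibble::tibble(cdna_length = 1L, intensity = 5), p554),
    tibble::tibble(position = 553L, intensity = 5))
  expect_equal(
    peaks_to_positions(tibble::tibble(cdna_length = 553L, intensity = 2), p554),
    tibble::tibble(position = 1L, intensity = 2))
  p1036 <- ref_primer(1036, 1053)
  expect_equal(
    peaks_to_positions(tibble::tibble(cdna_length = 482L, intensity = 1),
                       p1036)$position, 554L)
  # same-position intensities are summed
  dup <- tibble::tibble(cdna_length = c(10L, 10L, 11L), intensity = c(1, 2, 4))
  out <- peaks_to_positions(dup, p554)
  expect_equal(out$intensity[out$position == 544L], 3)
  expect_error(
    peaks_to_positions(tibble::tibble(cdna_length = 554L, intensity = 1), p554),
    class = "mprtseq_coordinate_error")
})

test_that("box-plot normalization is scale-invariant with the 2%/8% factor", {
  const <- toy_profile(rep(7, 100))
  expect_equal(normalize_profile(const)$reactivity, rep(1, 100))

  vals <- withr::with_seed(1, rexp(100))
  prof <- toy_profile(vals)
  n1 <- normalize_profile(prof)
  n10 <- normalize_profile(toy_profile(vals * 10))
  expect_equal(n1$reactivity, n10$reactivity)

  # order-statistic oracle: factor = mean of ranks 3..10 from the top
  sorted <- sort(vals, decreasing = TRUE)
  expect_equal(normalization_factors(prof)$factor, mean(sorted[3:10]))
  expect_equal(n1$reactivity, vals / mean(sorted[3:10]))

  # order preserved
  expect_equal(order(n1$reactivity), order(vals))
  expect_error(normalize_profile(toy_profile(rep(0, 50))),
               class = "mprtseq_normalization_error")
  # robust fallbacks for sparse count data
  expect_equal(normalization_factors(toy_profile(rep(0, 50)),
                                     robust = TRUE)$factor, 1)
  sparse <- c(rep(0, 98), 6, 10)  # positives all inside the excluded top 2%
  expect_equal(normalization_factors(toy_profile(sparse),
                                     robust = TRUE)$factor, 8)
  expect_error(normalize_profile(toy_profile(c(1, 2, 3))), "at least 10")
})

test_that("per-section factors are computed and applied independently", {
  vals <- c(rep(2, 50), rep(20, 50))
  prof <- toy_profile(vals, section = rep(c("S1", "S2"), each = 50))
  nf <- normalization_factors(prof)
  expect_equal(sort(nf$factor), c(2, 20))
  normed <- normalize_profile(prof, nf)
  expect_equal(normed$reactivity, rep(1, 100))
})

test_that("control subtraction clamps negatives and propagates missing", {
  tr <- toy_profile(c(5, 2, NA, 3))
  ct <- toy_profile(c(1, 4, 1, NA))
  expect_message(out <- subtract_control(tr, ct), "clamped 1")
  expect_equal(out$reactivity, c(4, 0, NA, NA))
  expect_equal(attr(out, "clamped"), 1L)

  same <- subtract_control(toy_profile(c(1, 2, 3)), toy_profile(c(1, 2, 3)))
  expect_equal(same$reactivity, c(0, 0, 0))
  zero <- subtract_control(toy_profile(c(1, 2, 3)), toy_profile(c(0, 0, 0)))
  expect_equal(zero$reactivity, c(1, 2, 3))
  expect_error(subtract_control(toy_profile(1:3), toy_profile(1:4)),
               class = "mprtseq_input_error")
})

test_that("assembly keeps each primer inside its own section and marks gaps missing", {
  primers <- rt_primer_panel(data.frame(
    name = c("P1", "P2"), pairing_start = c(101, 201),
    pairing_end = c(120, 220)))
  sm <- build_section_map(primers, 260)
  maps <- list(
    P1 = tibble::tibble(position = c(50L, 150L), intensity = c(3, 9)),
    P2 = tibble::tibble(position = c(150L, 180L), intensity = c(4, 6)))
  prof <- assemble_sections(maps, sm, treatment = "t")
  # P1's read at 150 is outside its section (1..100) and discarded;
  # P2 owns 101..200
  expect_equal(prof$reactivity[50], 3)
  expect_equal(prof$reactivity[150], 4)
  expect_equal(prof$reactivity[180], 6)
  expect_equal(prof$section[50], "P1")
  expect_equal(prof$section[150], "P2")
  # unread positions inside sections are zero, positions 3' of last pairing
  # start are missing
  expect_equal(prof$reactivity[60], 0)
  expect_true(all(is.na(prof$reactivity[201:260])))
})

test_that("assembly equals a brute-force ownership oracle", {
  primers <- reference_primers()
  sm <- build_section_map(primers, 2896)
  maps <- withr::with_seed(42, lapply(seq_len(nrow(primers)), function(i) {
    pos <- sort(sample(primers$pairing_start[i] - 1L, 40))
    tibble::tibble(position = pos, intensity = runif(40))
  }))
  names(maps) <- primers$name
  prof <- assemble_sections(maps, sm, treatment = "t")
  # oracle: loop positions, pick the owning section, look up that map
  for (p in seq(1, 2896, by = 7)) {
    own <- section_at(sm, p)
    if (is.na(own)) {
      expect_true(is.na(prof$reactivity[p]))
    } else {
      m <- maps[[own]]
      expected <- sum(m$intensity[m$position == p])
      expect_equal(prof$reactivity[p], expected)
    }
  }
})

test_that("single-primer assembly equals the clipped map", {
  primers <- ref_primer(101, 120, name = "P1")
  sm <- build_section_map(primers, 150)
  m <- tibble::tibble(position = c(10L, 90L, 130L), intensity = c(1, 2, 3))
  prof <- assemble_sections(list(P1 = m), sm, treatment = "t")
  expect_equal(prof$reactivity[c(10, 90)], c(1, 2))
  expect_true(all(is.na(prof$reactivity[101:150])))  # uncovered tail
})

test_that("the stop-coordinate convention is self-inverse over a whole construct", {
  L <- 500L
  primers <- ref_primer(481L, 500L, name = "P1")
  sm <- build_section_map(primers, L)
  # one molecule per break position p: fragments (1, p-1) and (p, L)
  p_all <- 2:480
  frags <- tibble::tibble(
    molecule = rep(seq_along(p_all), each = 2),
    start = as.vector(rbind(1L, p_all)),
    end = as.vector(rbind(p_all - 1L, L)))
  tr <- simulate_rt_traces(frags, primers)
  got <- peaks_to_positions(tr$P1, ref_primer(481L))
  expect_equal(got$position, p_all)
  expect_equal(got$intensity, rep(1, length(p_all)))
})

test_that("mean reactivity ignores missing and validates input", {
  expect_equal(mean_reactivity(toy_profile(c(2, 4, NA, 6))), 4)
  expect_equal(mean_reactivity(toy_profile(rep(0, 5))), 0)
  expect_error(mean_reactivity(toy_profile(c(NA_real_, NA_real_))),
               class = "mprtseq_input_error")
})

test_that("profiles and peak tables round-trip through disk", {
  prof <- toy_profile(c(1.5, 0, NA, 3), treatment = "ft20")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read_profile(tsv)
  expect_equal(back$reactivity, prof$reactivity)
  expect_equal(attr(back, "treatment"), "ft20")

  pk <- tibble::tibble(cdna_length = c(3L, 7L), intensity = c(1.5, 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pk, csv)
  expect_equal(as.data.frame(read_peak_table(csv)), as.data.frame(pk))
})
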
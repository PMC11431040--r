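test_that("cleavage propensity is the product of base, context and hotspot weights", {
  cons <- toy_construct(40)
  uniform <- cleavage_model(base_weights = c(A = 1, C = 1, G = 1, U = 1))
  expect_equal(cleavage_propensity(cons, NULL, uniform), rep(1, 40))

  cmod <- cleavage_model(base_weights = c(A = 1, C = 4, G = 1, U = 1))
  prop <- cleavage_propensity(cons, NULL, cmod)
  bases <- strsplit(cons$sequence, "")[[1]]
  expect_equal(prop, ifelse(bases == "C", 4, 1))

  hot <- cleavage_model(base_weights = c(A = 1, C = 1, G = 1, U = 1),
                        planted_hotspots = data.frame(start = 10, end = 12,
                                                      multiplier = 10))
  ph <- cleavage_propensity(cons, NULL, hot)
  expect_equal(unname(ph[10:12] / ph[20]), rep(10, 3))
  expect_equal(ph[-(10:12)], rep(1, 37))
})

test_that("structure context multiplies in through element labels", {
  cons <- toy_construct(9)
  s <- parse_dotbracket("(((...)))")
  m <- cleavage_model(base_weights = c(A = 1, C = 1, G = 1, U = 1),
                      context_weights = c(stem_5prime = 0.5, stem_3prime = 0.5,
                                          hairpin_loop = 2))
  expect_equal(cleavage_propensity(cons, s, m),
               c(rep(0.5, 3), rep(2, 3), rep(0.5, 3)))
  expect_error(cleavage_propensity(toy_construct(8), s, m), "length")
})

test_that("zero dose yields only full-length molecules", {
  frags <- simulate_fragments(rep(1, 100), stress_dose("freeze_thaw", 0),
                              50, seed = 3)
  expect_equal(nrow(frags), 50L)
  expect_true(all(frags$start == 1L & frags$end == 100L))
})

test_that("a single permitted cut site splits molecules only there", {
  prop <- rep(0, 100); prop[40] <- 1
  high_rate <- cleavage_model(per_event_rate = 50)
  frags <- simulate_fragments(prop, stress_dose("freeze_thaw", 1), 200,
                              model = high_rate, seed = 4)
  cut <- frags[frags$start != 1L | frags$end != 100L, ]
  expect_true(all(cut$start %in% c(1L, 40L)))
  expect_true(all((cut$start == 1L & cut$end == 39L) |
                  (cut$start == 40L & cut$end == 100L)))
  expect_gt(nrow(cut), 0)
  expect_error(
    simulate_fragments(rep(0, 100), stress_dose("freeze_thaw", 1), 10,
                       model = high_rate, seed = 1),
    class = "mprtseq_degenerate_model")
})

test_that("fragment lengths are conserved per molecule", {
  prop <- withr::with_seed(5, runif(300))
  frags <- simulate_fragments(prop, stress_dose("heat_37C", 48), 500,
                              model = cleavage_model(per_event_rate = 0.05),
                              seed = 6)
  lens <- tapply(frags$end - frags$start + 1L, frags$molecule, sum)
  expect_true(all(lens == 300L))
})

test_that("empirical cut-site frequencies track the propensity vector", {
  L <- 100L
  prop <- rep(c(1, 3), length.out = L)
  prop[1] <- 0
  frags <- simulate_fragments(prop, stress_dose("freeze_thaw", 1), 1e5,
                              model = cleavage_model(per_event_rate = 0.1),
                              seed = 11)
  cuts <- frags$start[frags$start > 1L]
  p <- prop / sum(prop)
  obs <- tabulate(cuts, nbins = L) / length(cuts)
  se <- sqrt(p * (1 - p) / length(cuts))
  expect_true(all(abs(obs - p) <= 3 * se + 1e-12))
})

test_that("RT traces follow the stop arithmetic and are deterministic", {
  primers <- rt_primer_panel(data.frame(name = "RT1", pairing_start = 554,
                                        pairing_end = 573))
  # only full-length molecules: one full-extension peak
  full <- simulate_fragments(rep(1, 600), stress_dose("freeze_thaw", 0),
                             20, seed = 1)
  tr <- simulate_rt_traces(full, primers)
  expect_equal(nrow(tr$RT1), 1L)
  expect_equal(tr$RT1$cdna_length, 553L)
  expect_equal(tr$RT1$intensity, 20)

  # one break at 300: cDNA of length 554 - 300 = 254
  broken <- tibble::tibble(molecule = 1L, start = c(1L, 300L),
                           end = c(299L, 600L))
  tr2 <- simulate_rt_traces(broken, primers)
  expect_true(254L %in% tr2$RT1$cdna_length)

  # determinism with noise
  frags <- simulate_fragments(rep(1, 600), stress_dose("freeze_thaw", 10),
                              200, seed = 2)
  a <- simulate_rt_traces(frags, primers, noise_sd = 5, seed = 9)
  b <- simulate_rt_traces(frags, primers, noise_sd = 5, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$RT1$intensity >= 0))
})

test_that("fragments lacking the full pairing site contribute nothing", {
  primers <- rt_primer_panel(data.frame(name = "RT1", pairing_start = 554,
                                        pairing_end = 573))
  # fragment ends inside the pairing site
  part <- tibble::tibble(molecule = 1L, start = 1L, end = 560L)
  tr <- simulate_rt_traces(part, primers)
  expect_equal(nrow(tr$RT1), 0L)
})

test_that("electropherogram mass is placed at fragment lengths", {
  full <- simulate_fragments(rep(1, 2896), stress_dose("freeze_thaw", 0),
                             100, seed = 1)
  eph <- simulate_electropherogram(full, sizing_sd = 25)
  tb <- tibble::as_tibble(eph)
  expect_equal(tb$size_nt[which.max(tb$signal)], 2896, tolerance = 1e-3)

  # 50/50 mass at 1000 and 2500 nt -> two equal-area peaks
  two <- tibble::tibble(molecule = 1:2, start = c(1L, 1L),
                        end = c(1000L, 2500L))
  two <- two[rep(1:2, c(5, 2)), ]  # 5x1000 vs 2x2500: equal nucleotide mass
  attr(two, "template_length") <- 2500L
  eph2 <- simulate_electropherogram(two, sizing_sd = 20)
  tb2 <- tibble::as_tibble(eph2)
  lowpeak <- pracma::trapz(tb2$size_nt[tb2$size_nt < 1750],
                           tb2$signal[tb2$size_nt < 1750])
  highpeak <- pracma::trapz(tb2$size_nt[tb2$size_nt >= 1750],
                            tb2$signal[tb2$size_nt >= 1750])
  expect_equal(lowpeak, highpeak, tolerance = 0.01)

  expect_error(simulate_electropherogram(full[0, ]),
               class = "mprtseq_input_error")
})
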
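test_that("repeat construction tiles the unit from the requested phase", {
  expect_identical(paste(build_repeat(repeat_spec("TC", 21))$bases, collapse = ""),
                   "TCTCTCTCTCTCTCTCTCTCT")
  expect_identical(paste(build_repeat(repeat_spec("TC", 4, phase = 1))$bases,
                         collapse = ""), "CTCT")
  expect_identical(paste(build_repeat(repeat_spec("AT", 6))$bases, collapse = ""),
                   "ATATAT")
  expect_error(repeat_spec("TC", 1), ">= 2")
})

test_that("repeat-unit mutation substitutes every occurrence", {
  expect_identical(mutate_repeat_unit(repeat_spec("TC", 21), "T", "A")$unit, "AC")
  expect_identical(mutate_repeat_unit(repeat_spec("TC", 21), "C", "T")$unit, "TT")
  expect_error(mutate_repeat_unit(repeat_spec("TC", 21), "G", "A"),
               "does not occur")
})

test_that("self-dimer screen agrees with exhaustive enumeration", {
  at8 <- screen_self_complementarity(annotated_strand("ATATATAT"), 4L)
  expect_identical(at8$self_dimer_run, 8L)
  expect_false(at8$passed)
  t8 <- screen_self_complementarity(annotated_strand("TTTTTTTT"), 4L)
  expect_identical(t8$self_dimer_run, 0L)
  expect_true(t8$passed)

  fx <- fixture_sequences()
  s1 <- screen_self_complementarity(fx$SEQ1, 4L)
  expect_identical(s1$self_dimer_run, oracle_self_dimer_run(fx$SEQ1$bases))

  set.seed(21)
  for (rep in 1:30) {
    s <- rand_strand(sample(4:30, 1))
    expect_identical(screen_self_complementarity(s, 4L)$self_dimer_run,
                     oracle_self_dimer_run(s$bases))
  }
})

test_that("hairpin screen matches brute-force stem-loop enumeration", {
  hp <- screen_hairpin(annotated_strand("GGGGAAAACCCC"), 4L, 4L)
  expect_identical(nrow(hp$hairpin_hits), 1L)
  expect_identical(hp$hairpin_hits$stem_len, 4L)
  expect_identical(hp$hairpin_hits$loop_len, 4L)
  expect_true(screen_hairpin(annotated_strand("TTTTTTTTTTTT"), 4L, 3L)$passed)

  fx <- fixture_sequences()
  s2 <- screen_hairpin(fx$SEQ2, 4L, 3L)
  expect_identical(s2$passed,
                   nrow(oracle_hairpin_triples(fx$SEQ2$bases, 4L, 3L)) == 0L)

  set.seed(22)
  for (rep in 1:25) {
    s <- rand_strand(sample(10:30, 1))
    res <- screen_hairpin(s, 4L, 3L)
    tri <- oracle_hairpin_triples(s$bases, 4L, 3L)
    expect_identical(res$passed, nrow(tri) == 0L)
    if (nrow(res$hairpin_hits)) {
      # every reported hit is a valid brute-force triple, and the longest
      # stem lengths agree
      for (r in seq_len(nrow(res$hairpin_hits))) {
        h <- res$hairpin_hits[r, ]
        expect_true(any(tri$i == h$stem_start & tri$j == h$stem_end &
                          tri$k == h$stem_len))
      }
      expect_identical(max(res$hairpin_hits$stem_len), max(tri$k))
    }
  }
})

test_that("GC filter rejects strictly above the threshold", {
  expect_false(gc_filter(annotated_strand("GCGCGCGC"))$passed)
  exact75 <- annotated_strand("GGGCCCAT")  # 6/8 = 75.0%
  expect_identical(gc_content(exact75), 75)
  expect_true(gc_filter(exact75)$passed)
  expect_true(gc_filter(fixture_sequences()$SEQ1)$passed)
})

test_that("rule-based LNA placement is separated and scales with length", {
  s21 <- parse_lna_notation("TCC TCT CTT TCT CTT TCT CTT")
  expect_identical(place_lna(s21)$lna_flags, c(4L, 13L, 19L))
  expect_identical(place_lna(s21, lna_pattern(binding_site = TRUE))$lna_flags,
                   c(4L, 10L, 13L, 19L))
  expect_error(place_lna(s21, lna_pattern(c(1, 2))), "adjacent")
  expect_error(place_lna(s21, lna_pattern(25)), "out of range")

  s10 <- build_repeat(repeat_spec("TC", 10))
  expect_identical(place_lna(s10)$lna_flags, c(2L, 6L, 9L))
  s63 <- build_repeat(repeat_spec("TC", 63))
  expect_identical(place_lna(s63)$lna_flags,
                   c(4L, 13L, 19L, 25L, 34L, 40L, 46L, 55L, 61L))

  for (n in c(8:15, 21L, 42L, 63L)) {
    p <- place_lna(build_repeat(repeat_spec("TC", n)))$lna_flags
    expect_true(all(diff(p) > 1L), label = sprintf("length %d separated", n))
  }
})

test_that("nearest-neighbor Tm matches a hand-evaluated sum and the LNA
           increment behaves additively", {
  # hand evaluation for 5'-AGCT-3' against the unified parameter table
  dh <- -7.8 - 9.8 - 7.8 + 2.3 + 2.3
  ds <- -21.0 - 24.4 - 21.0 + 4.1 + 4.1 + 0.368 * 3 * log(0.15)
  tm_hand <- 1000 * dh / (ds + 1.987 * log(2.5e-7 / 4)) - 273.15
  est <- estimate_tm(make_duplex(annotated_strand("AGCT")))
  expect_equal(est$tm_celsius, tm_hand, tolerance = 1e-12)
  expect_identical(est$n_lna, 0L)
  expect_true(is.na(est$delta_per_lna))

  fx <- fixture_sequences()
  t1 <- estimate_tm(make_duplex(fx$SEQ1))
  t5 <- estimate_tm(make_duplex(fx$SEQ5))
  expect_identical(t1$tm_unmodified_celsius, t5$tm_celsius)
  expect_gte((t1$tm_celsius - t5$tm_celsius) / 3, 2)

  # monotone in LNA count for a fixed sequence
  tms <- vapply(0:3, function(k) {
    s <- annotated_strand(fx$SEQ5$bases, c(4L, 13L, 19L)[seq_len(k)])
    estimate_tm(make_duplex(s))$tm_celsius
  }, 0)
  expect_true(all(diff(tms) > 0))
  expect_error(estimate_tm(make_duplex(fx$SEQ1), lna_increment = 10), "\\[2, 8\\]")
})

test_that("design pipeline emits only screen-passing, count-preserving candidates", {
  cands <- design_pipeline(list(repeats = list(repeat_spec("TC", 21)), seed = 5))
  expect_gte(length(cands), 1L)
  for (cand in cands) {
    expect_true(cand$screen$passed)
    expect_identical(cand$strand$lna_flags, c(4L, 13L, 19L))
    expect_gte(cand$tm$delta_per_lna, 2)
  }

  # unfixable GC content yields an empty candidate list
  none <- design_pipeline(list(repeats = list(repeat_spec("GC", 21)),
                               screens = list(gc_threshold = 0)))
  expect_length(none, 0L)
  expect_error(design_pipeline(list()), "repeat spec")

  # base counts preserved by structure-breaking shuffles; deterministic per seed
  set.seed(31)
  units <- replicate(8, paste(sample(c("A", "C", "G", "T"), 2), collapse = ""))
  for (u in units) {
    cfg <- list(repeats = list(repeat_spec(u, 21)), seed = 17, lna = FALSE)
    cands <- design_pipeline(cfg)
    pre <- base_composition(build_repeat(cfg$repeats[[1]]))$counts
    for (cand in cands)
      expect_identical(base_composition(cand$strand)$counts, pre)
    again <- design_pipeline(cfg)
    expect_identical(design_summary(cands), design_summary(again))
  }
})
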
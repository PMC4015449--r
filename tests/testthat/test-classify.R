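test_that("rule_thresholds validates and carries the published defaults", {
  t <- rule_thresholds()
  expect_equal(t$area_gate, 0.6784)
  expect_equal(t$wrect_lo, 0.9897)
  expect_equal(t$wrect_hi, 1.5597)
  expect_equal(t$hi_min, 0.7507)
  expect_equal(t$wmax_gate, 2.3453)
  expect_equal(t$discard_factor, 1.5)
  expect_error(rule_thresholds(area_gate = 1.2))
  expect_error(rule_thresholds(wrect_lo = 2, wrect_hi = 1))
})

test_that("classify_object reproduces the documented rule outcomes", {
  t <- rule_thresholds()
  cases <- list(
    list(f = feat_row(0.80, Wrect_ratio = 1.20), class = 1L,
         subtype = NA_character_),
    list(f = feat_row(0.80, Wrect_ratio = 0.50), class = 4L,
         subtype = "small_residue"),
    list(f = feat_row(0.80, Wrect_ratio = 2.50), class = 4L,
         subtype = "large_residue"),
    list(f = feat_row(0.40, Hi_ratio = 0.30), class = 4L,
         subtype = "short_residue"),
    list(f = feat_row(0.40, Hi_ratio = 0.90, Wmax_ratio = 3.0), class = 3L,
         subtype = NA_character_),
    list(f = feat_row(0.40, Hi_ratio = 0.90, Wmax_ratio = 1.2), class = 2L,
         subtype = NA_character_))
  for (cs in cases) {
    got <- classify_object(cs$f, t)
    expect_identical(got$value, cs$class)
    expect_identical(got$subtype, cs$subtype)
  }
})

test_that("boundary semantics match the published inequalities", {
  t <- rule_thresholds()
  # area_ratio exactly at the gate goes to the skewed/overlap branch
  at_gate <- classify_object(feat_row(t$area_gate, Hi_ratio = 1,
                                      Wmax_ratio = 1), t)
  expect_identical(at_gate$value, 2L)
  # Wrect_ratio band inclusive on both ends
  expect_identical(classify_object(feat_row(0.8, Wrect_ratio = t$wrect_lo),
                                   t)$value, 1L)
  expect_identical(classify_object(feat_row(0.8, Wrect_ratio = t$wrect_hi),
                                   t)$value, 1L)
  # Hi_ratio exactly at hi_min is NOT residue
  expect_identical(classify_object(feat_row(0.4, Hi_ratio = t$hi_min,
                                            Wmax_ratio = 1), t)$value, 2L)
  # Wmax_ratio exactly at the gate is skewed, above is overlapping
  expect_identical(classify_object(feat_row(0.4, Hi_ratio = 1,
                                            Wmax_ratio = t$wmax_gate),
                                   t)$value, 2L)
  expect_identical(classify_object(feat_row(0.4, Hi_ratio = 1,
                                            Wmax_ratio = t$wmax_gate + 1e-9),
                                   t)$value, 3L)
})

test_that("rule tree is total and agrees with the flat oracle", {
  t <- rule_thresholds()
  set.seed(101)
  f <- random_features(20000)
  got <- classify_spread(f, t)
  expect_identical(nrow(got), 20000L)
  expect_true(all(got$class %in% 1:4))
  expect_identical(got$class,
                   oracle_classify_vec(f$area_ratio, f$Wrect_ratio,
                                       f$Hi_ratio, f$Wmax_ratio, t))
  # scalar spot checks against the scalar oracle
  for (i in sample(20000, 50))
    expect_identical(classify_object(f[i, ], t)$value,
                     oracle_classify(f$area_ratio[i], f$Wrect_ratio[i],
                                     f$Hi_ratio[i], f$Wmax_ratio[i], t))
})

test_that("increasing Wmax_ratio can only move labels 2 -> 3", {
  t <- rule_thresholds()
  set.seed(33)
  for (i in 1:200) {
    f <- random_features(1)
    lab1 <- classify_object(f, t)$value
    f2 <- f; f2$Wmax_ratio <- f$Wmax_ratio + runif(1, 0, 2)
    lab2 <- classify_object(f2, t)$value
    if (lab1 == 3L) expect_identical(lab2, 3L)
    if (lab1 != 2L && lab1 != 3L) expect_identical(lab2, lab1)
  }
})

test_that("classify_spread preserves order and handles empty input", {
  t <- rule_thresholds()
  expect_identical(nrow(classify_spread(.empty <- spreadsel:::.empty_features(),
                                        t)), 0L)
  set.seed(55)
  f <- random_features(50)
  base <- classify_spread(f, t)
  perm <- sample(50)
  expect_identical(classify_spread(f[perm, ], t)$class, base$class[perm])
  expect_error(classify_spread(f[, -5], t), "incomplete")
})

test_that("threshold config files round-trip and reject junk", {
  t <- rule_thresholds(area_gate = 0.5, wmax_gate = 3,
                       gate_feature = "wrect_ratio")
  f <- tempfile(fileext = ".cfg")
  write_thresholds(t, f)
  got <- read_thresholds(f)
  expect_equal(got[names(got) != "gate_feature"],
               t[names(t) != "gate_feature"])
  expect_identical(got$gate_feature, "wrect_ratio")

  writeLines("not_a_key = 1", f)
  expect_error(read_thresholds(f), "unknown config key")
  writeLines("area_gate 0.5", f)
  expect_error(read_thresholds(f), "malformed")
})

test_that("gate_feature switch implements the alternative reading", {
  t_alt <- rule_thresholds(gate_feature = "wrect_ratio")
  # low fill but Wrect_ratio above the gate: alternative reading takes the
  # straight branch
  f <- feat_row(0.40, Wrect_ratio = 1.2, Hi_ratio = 1, Wmax_ratio = 1)
  expect_identical(classify_object(f, rule_thresholds())$value, 2L)
  expect_identical(classify_object(f, t_alt)$value, 1L)
})
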
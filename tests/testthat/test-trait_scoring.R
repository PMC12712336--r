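test_that("trait ratios follow the defining formulas", {
  m <- base_specimen(femur3_length = 1.00, femur3_width = 0.25)
  s <- score_traits(m)
  expect_equal(s[["thin_legs"]], 0.75)
  expect_equal(s[["elong_ceph"]], 1 - 0.6 / 1)
  expect_equal(s[["elong_abd"]], 1 - 0.5 / 1)
  expect_equal(s[["elong_pedicel"]], 0.1 / (1 + 1 + 0.1))
  # all constriction fields absent -> no-constriction convention
  expect_equal(unname(unclass(s)[5:8]), rep(0, 4))
})

test_that("illusion score takes the rounded discrete levels", {
  flags <- c("illusion_abd_band", "illusion_ceph_band", "illusion_eye_dark")
  for (k in 0:3) {
    args <- setNames(as.list(rep(TRUE, k)), flags[seq_len(k)])
    s <- score_traits(do.call(base_specimen, args))
    expect_equal(s[["illusion_coloration"]], c(0, 0.334, 0.667, 1)[k + 1])
  }
})

test_that("no-constriction encoding and clamping behave", {
  # constriction equal to widest point -> ratio 1 -> score 0
  s <- score_traits(base_specimen(ceph_width_at_constriction = 0.6))
  expect_equal(s[["constr_ceph_dors"]], 0)
  # abdomen wider than long would give a negative ratio -> clamped to 0
  s2 <- score_traits(base_specimen(abd_width = 1.4, abd_length = 1))
  expect_equal(s2[["elong_abd"]], 0)
  # property: any positive measurements stay inside [0, 1]
  for (r in 1:25) {
    v <- with_seed(r, runif(13L, 0.05, 3))
    m <- specimen_measurements("p", v[1], v[2], v[3], v[4], v[5], v[6],
                               v[7], v[8], v[9], v[10], v[11], v[12], v[13])
    expect_true(all(unclass(score_traits(m)) >= 0 &
                    unclass(score_traits(m)) <= 1))
  }
})

test_that("measurement errors are reported by field", {
  expect_error(base_specimen(ceph_length = -1), "ceph_length")
  m <- unclass(base_specimen())
  m$abd_length <- NA_real_
  expect_error(score_traits(m), "abd_length")
  m[c(.core_fields)] <- NA_real_
  expect_error(score_traits(m), "unscorable")
})

test_that("overall accuracy is the mean of the nine scores", {
  z <- setNames(rep(0, 9L), trait_names())
  expect_equal(overall_accuracy(z), 0)
  expect_equal(overall_accuracy(z + 0.3), 0.3)
  z[] <- c(0.5, 0.5, 0.5, 0.5, 0.2, 0.2, 0.3, 0, 0)  # sums to 2.7
  expect_equal(overall_accuracy(z), 0.3)
  z[["thin_legs"]] <- NA
  expect_error(overall_accuracy(z), "incomplete")
})

test_that("accuracy categories partition [0,1] at the stated boundaries", {
  expect_equal(as.character(classify_accuracy(0.10)), "nonmimic")
  expect_equal(as.character(classify_accuracy(0.30)), "accurate")
  expect_equal(as.character(classify_accuracy(0.29)), "inaccurate_moderate")
  expect_equal(as.character(classify_accuracy(0.15)), "inaccurate_low")
  # sub-bin boundary applies to the score rounded to 2 decimals
  expect_equal(as.character(classify_accuracy(c(0.194, 0.195))),
               c("inaccurate_low", "inaccurate_moderate"))
  # every x maps to exactly one category
  x <- seq(0, 1, by = 0.001)
  expect_false(anyNA(classify_accuracy(x)))
  expect_error(classify_accuracy(1.2), "\\[0, 1\\]")
  expect_error(classify_accuracy(-0.1), "\\[0, 1\\]")
})

test_that("round-trip: synthesized measurements rescore to the targets", {
  for (r in 1:30) {
    tgt <- rand_targets(r)
    m <- synthesize_measurements(tgt, seed = r)
    got <- unclass(score_traits(m))
    expect_lt(max(abs(got - tgt)), 1e-12)
  }
  # scale noise changes measurements but not scores
  tgt <- rand_targets(99)
  m <- synthesize_measurements(tgt, seed = 99, scale_noise = TRUE)
  expect_false(isTRUE(all.equal(m$ceph_length, 1)))
  expect_lt(max(abs(unclass(score_traits(m)) - tgt)), 1e-12)
})

test_that("cohort summary equals brute-force recomputation", {
  rows <- lapply(1:12, function(r) {
    m <- synthesize_measurements(rand_targets(200 + r), seed = r,
                                 specimen_id = paste0("s", r))
    as.data.frame(unclass(m)[lengths(unclass(m)) == 1L])
  })
  df <- do.call(rbind, rows)
  sc <- score_specimens(df)
  cs <- cohort_summary(sc, "fixture", digits = NULL)
  for (v in c(trait_names(), "overall_accuracy")) {
    x <- sc[[v]]
    expect_equal(unlist(cs$table[v, ], use.names = FALSE),
                 c(min(x), max(x), mean(x), sd(x)))
  }
  expect_equal(sum(cs$category_counts), nrow(sc))
  expect_equal(unname(cs$category_counts),
               unname(c(table(factor(sc$category,
                                     names(cs$category_counts))))))
  # degenerate cohorts
  expect_error(cohort_summary(sc[0, ]), "empty")
  expect_warning(cs1 <- cohort_summary(sc[1, , drop = FALSE]), "single")
  expect_equal(cs1$table["thin_legs", "sd"], 0)
  two <- cohort_summary(rbind(sc[1, ], sc[1, ]))
  expect_equal(two$table[["minimum"]], two$table[["maximum"]])
  expect_equal(two$table[["sd"]], rep(0, 10))
})

test_that("measurement tables read back and score identically", {
  rows <- lapply(1:5, function(r) {
    m <- synthesize_measurements(rand_targets(300 + r), seed = r,
                                 specimen_id = paste0("t", r))
    as.data.frame(unclass(m)[lengths(unclass(m)) == 1L])
  })
  df <- do.call(rbind, rows)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_measurements(path)
  expect_equal(score_specimens(back)$overall_accuracy,
               score_specimens(df)$overall_accuracy)
  # tab-separated with 0/1 flags auto-detects
  df$illusion_abd_band <- as.integer(df$illusion_abd_band)
  path2 <- tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_measurements(path2)$illusion_abd_band,
               as.logical(df$illusion_abd_band))
})
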
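test_that("min-max normalization maps raw columns linearly onto [0, 1]", {
  tab <- fixture_raw_table()
  # replace one feature with the 4-valued column whose image is hand-known
  tab$f1 <- c(1, 2, 4, 5, 1, 2, 4, 5, 3, 1, 5)
  set <- normalize_features(tab)
  all_f1 <- c(set$training[, 1], set$central[1], set$peripherals[, 1])
  expect_equal(sort(unique(all_f1)), c(0, 0.25, 0.5, 0.75, 1))
  # endpoints and midpoint of the 1-5 scale
  expect_equal(unname(set$peripherals[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(set$peripherals[2, ]), c(1, 1, 1, 1))
  expect_equal(set$central, c(0.5, 0.5, 0.5, 0.5))
})

test_that("normalization is idempotent and rejects constant features", {
  tab <- fixture_raw_table()
  set1 <- normalize_features(tab)
  tab2 <- tab
  tab2[, c("f1", "f2", "f3", "f4")] <-
    rbind(set1$training, set1$central, set1$peripherals)
  set2 <- normalize_features(tab2)
  expect_equal(set2$training, set1$training)
  tab$f3 <- 2
  expect_error(normalize_features(tab), "leg_length")
})

test_that("stimulus-set invariants are enforced", {
  tab <- fixture_raw_table()
  expect_error(normalize_features(tab[-1, ]), "8 'train' rows")
  tab_bad <- tab
  tab_bad$f2[tab_bad$id == "central"] <- "x"
  expect_error(normalize_features(tab_bad), "central")
  # central duplicated into training must be rejected
  tab_dup <- tab
  tab_dup[tab_dup$id == "train1", c("f1", "f2", "f3", "f4")] <- 3
  expect_error(normalize_features(tab_dup), "not be members")
})

test_that("euclidean distance and mean successive distance match hand values", {
  expect_equal(euclidean_distance(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)), 2)
  expect_equal(euclidean_distance(c(0, 0.25, 0.5, 1), c(1, 0.25, 0, 0.5)),
               sqrt(1.5))
  expect_error(euclidean_distance(c(0, 1), c(0, 1, 0)), "same number")
  m <- toy3()
  expect_equal(mean_successive_distance(m[c("a", "c", "a"), ]), 2)
  expect_equal(mean_successive_distance(m[c("a", "b"), ]),
               euclidean_distance(m["a", ], m["b", ]))
  expect_error(mean_successive_distance(m[1, , drop = FALSE]), "at least 2")
})

test_that("sequence enumeration is exhaustive, distinct and lexicographic", {
  m <- toy3()
  seqs <- enumerate_sequences(m, n_expected = 3L)
  expect_equal(nrow(seqs$orders), 6L)
  expect_equal(anyDuplicated(seqs$orders), 0L)
  expect_equal(seqs$orders[1, ], c(1L, 2L, 3L))
  expect_equal(seqs$orders[6, ], c(3L, 2L, 1L))
  # mean EDs agree with an independent brute-force recursion
  brute <- brute_perm_eds(m)
  expect_equal(seqs$mean_ed,
               vapply(seq_len(6), function(k)
                 brute$mean_ed[[which(vapply(brute$perms, identical,
                                             logical(1), seqs$orders[k, ]))]],
                 numeric(1)))
  expect_error(enumerate_sequences(m), "expected 8")
  expect_equal(nrow(enumerate_sequences(m[1, , drop = FALSE],
                                        n_expected = 1L)$orders), 1L)
})

test_that("every sequence and its reversal share the same mean distance", {
  set <- fixture_stimuli()
  seqs <- enumerate_sequences(set$training)
  idx <- seq(1, nrow(seqs$orders), by = 997)
  for (k in idx) {
    rev_order <- rev(seqs$orders[k, ])
    expect_equal(mean_successive_distance(set$training[rev_order, ]),
                 seqs$mean_ed[k])
  }
})

test_that("condition orders pick the brute-forced extremes on the toy set", {
  m <- toy3()
  seqs <- enumerate_sequences(m, n_expected = 3L)
  mx <- build_condition_orders(seqs, "max", n_sets = 1L)
  # max mean ED is 1.5, first such order lexicographically is a,c,b
  expect_equal(unname(mx[1, ]), c(1L, 3L, 2L))
  expect_equal(attr(mx, "mean_ed"), 1.5)
  mn <- build_condition_orders(seqs, "min", n_sets = 2L)
  expect_equal(sort(attr(mn, "mean_ed")), c(1, 1))
  expect_setequal(apply(mn, 1, paste, collapse = ""), c("123", "321"))
  expect_error(build_condition_orders(seqs, "max", n_sets = 7L), "exceeds")
})

test_that("distance conditions partition the sorted sequence space", {
  set <- fixture_stimuli()
  seqs <- enumerate_sequences(set$training)
  eds <- lapply(c("max", "med", "min"), function(cond)
    attr(build_condition_orders(seqs, cond, 24L), "mean_ed"))
  expect_true(min(eds[[1]]) >= max(eds[[2]]))
  expect_true(min(eds[[2]]) >= max(eds[[3]]))
  # the med block is centered on the median position of the ascending sort
  asc <- sort(seqs$mean_ed)
  expect_equal(sort(eds[[2]]), asc[20149:20172])
})

test_that("the random condition is seed-reproducible", {
  set <- fixture_stimuli()
  seqs <- enumerate_sequences(set$training)
  r1 <- build_condition_orders(seqs, "random", 24L, seed = 7)
  r2 <- build_condition_orders(seqs, "random", 24L, seed = 7)
  expect_identical(r1, r2)
})

test_that("the fixture set has the canonical structure", {
  set <- fixture_stimuli()
  expect_equal(set$central, rep(0.5, 4))
  expect_equal(unname(set$peripherals), rbind(rep(0, 4), rep(1, 4)))
  expect_equal(euclidean_distance(set$peripherals[1, ], set$peripherals[2, ]),
               2)
  expect_true(all(apply(set$training, 2, min) == 0))
  expect_true(all(apply(set$training, 2, max) == 1))
})

test_that("stimulus CSV round-trips at full precision and validates schema", {
  set <- fixture_stimuli()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stimulus_csv(set, path)
  back <- read_stimulus_csv(path)
  expect_equal(back$training, set$training)
  expect_equal(back$central, set$central)
  expect_equal(back$peripherals, set$peripherals)
  tab <- utils::read.csv(path)
  expect_named(tab, c("id", "role", "f1", "f2", "f3", "f4"))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[-3, ], bad, row.names = FALSE)
  expect_error(read_stimulus_csv(bad), "8 'train' rows")
  utils::write.csv(tab[, -2], bad, row.names = FALSE)
  expect_error(read_stimulus_csv(bad), "missing columns")
})
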
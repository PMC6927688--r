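test_that("features of canonical renders match their geometry", {
  set.seed(61)
  ft_c <- features_of(render_one("closed"))
  expect_gt(ft_c$S5, 0.95)
  expect_equal(ft_c$apex, 7, tolerance = 0.15)  # smoothed, vs local membrane
  expect_equal(ft_c$apex_offset, 2.5, tolerance = 0.5)  # ring radius
  ft_o <- features_of(render_one("open2"))
  expect_gt(ft_o$apex, 7.8)
  expect_lt(ft_o$apex_offset, 1)
  expect_equal(ft_o$n_lobes, 1)
  # flat patch is flagged
  ft_f <- extract_features(matrix(5, 33, 33))
  expect_true(ft_f$flat)
  expect_identical(classify_snapshot(ft_f), "openplus")
})

test_that("features and class are invariant under 72-degree rotation and offsets", {
  img <- render_one("open1")
  ft <- features_of(img)
  rot <- afmgating:::rotate_about(img, 72, c(24, 24), fill = 5)
  ft_r <- features_of(rot)
  expect_equal(ft_r$S5, ft$S5, tolerance = 0.05)
  expect_equal(ft_r$apex, ft$apex, tolerance = 0.1)
  expect_equal(ft_r$n_lobes, ft$n_lobes)
  expect_identical(classify_snapshot(ft_r), classify_snapshot(ft))
  # constant height offset changes nothing (all features are relative)
  ft_off <- features_of(img + 2.2)
  expect_equal(ft_off$S5, ft$S5, tolerance = 1e-9)
  expect_equal(ft_off$apex, ft$apex, tolerance = 1e-9)
  expect_identical(classify_snapshot(ft_off), classify_snapshot(ft))
})

test_that("noiseless canonical renders classify to their own class", {
  set.seed(62)
  for (cl in gating_classes()) {
    got <- classify_snapshot(features_of(render_one(cl)))
    expect_identical(got, cl)
  }
})

test_that("classification is stable under imaging noise", {
  set.seed(63)
  for (cl in c("closed", "open2")) {
    base <- render_one(cl)
    hits <- sum(vapply(1:40, function(i) {
      noisy <- base + matrix(rnorm(48 * 48, 0, 0.15), 48)
      identical(classify_snapshot(features_of(noisy)), cl)
    }, logical(1)))
    expect_gte(hits, 38)
  }
})

test_that("asymmetric low renders fall through to open-plus", {
  set.seed(64)
  # asymmetric but not elevated: the decision list ends at open-plus
  img <- render_one("openplus", offsets = c(-2, 0.3, -1.5, 0.2, -0.8))
  ft <- features_of(img)
  expect_lt(ft$apex, classify_thresholds()$h_thr)
  expect_identical(classify_snapshot(ft), "openplus")
})

test_that("occupancy averages per molecule first, with s.e.m. across molecules", {
  labs <- data.frame(
    molecule_id = rep(1:2, each = 10),
    frame = rep(1:10, 2),
    class = c(rep("closed", 8), rep("open2", 2), rep("closed", 10)))
  class(labs) <- c("class_labels", "data.frame")
  occ <- occupancy(labs, "test")
  closed <- occ[occ$class == "closed", ]
  expect_equal(closed$mean_percent, 90)
  expect_equal(closed$sem_percent, 10)
  expect_equal(sum(occ$mean_percent), 100, tolerance = 1e-9)
  # all closed: 100/0/0/0 with zero s.e.m.
  labs2 <- labs; labs2$class <- "closed"
  occ2 <- occupancy(labs2)
  expect_equal(occ2$mean_percent, c(100, 0, 0, 0))
  expect_true(all(occ2$sem_percent == 0))
  expect_error(occupancy(labs[labs$molecule_id == 1, ]), "2 molecules")
})

test_that("transition matrix rows are conditional percentages with block sums", {
  # constant labels: all mass on the diagonal, no returns to closed
  labs <- data.frame(molecule_id = 1, frame = 1:10, class = "openplus")
  class(labs) <- c("class_labels", "data.frame")
  tm <- transition_matrix(labs)
  expect_equal(tm$percent["openplus", "openplus"], 100)
  expect_equal(return_to_closed_probability(tm), 0)
  # all-closed record: no open-origin pairs, flagged undefined
  labs_c <- labs; labs_c$class <- "closed"
  class(labs_c) <- c("class_labels", "data.frame")
  expect_warning(p_na <- return_to_closed_probability(transition_matrix(labs_c)),
                 "undefined")
  expect_true(is.na(p_na))
  # known jump chain: empirical rows within 3 binomial SE
  set.seed(65)
  pre <- condition_preset("3mM")
  ch <- sample_chain(pre$P, 10001)
  labs2 <- data.frame(molecule_id = 1, frame = seq_along(ch$labels),
                      class = ch$labels)
  class(labs2) <- c("class_labels", "data.frame")
  tm2 <- transition_matrix(labs2)
  for (i in 1:4) {
    n_i <- sum(tm2$counts[i, ])
    for (j in 1:4) {
      p <- pre$P[i, j]
      expect_lt(abs(tm2$percent[i, j] / 100 - p),
                3 * sqrt(p * (1 - p) / n_i) + 1e-9)
    }
  }
  # block sums equal the sums of their four cells
  expect_equal(unname(tm2$block_sums["elevated"]),
               sum(tm2$counts[c("open2", "open1"), c("open2", "open1")]))
  expect_equal(unname(tm2$block_sums["elongated"]),
               sum(tm2$counts[c("open1", "openplus"), c("open1", "openplus")]))
  # molecule order does not matter
  labs3 <- rbind(labs2[5001:10001, ], labs2[1:5000, ])
  labs3$molecule_id <- rep(1:2, c(5001, 5000))
  class(labs3) <- c("class_labels", "data.frame")
  tm3 <- transition_matrix(labs3)
  expect_equal(sum(abs(tm3$counts - tm2$counts)), 1)  # only the cut pair
})

test_that("return-to-closed probability matches a scripted chain", {
  set.seed(66)
  pre <- condition_preset("0mM")
  ch <- sample_chain(pre$P, 20000)
  labs <- data.frame(molecule_id = 1, frame = seq_along(ch$labels),
                     class = ch$labels)
  class(labs) <- c("class_labels", "data.frame")
  p_meas <- return_to_closed_probability(transition_matrix(labs)) / 100
  n_open <- sum(ch$labels[-length(ch$labels)] != "closed")
  expect_lt(abs(p_meas - pre$return_prob),
            3 * sqrt(pre$return_prob * (1 - pre$return_prob) / n_open))
  # degenerate cases
  labs_all_open <- data.frame(molecule_id = 1, frame = 1:4,
                              class = c("open1", "closed", "open2", "closed"))
  class(labs_all_open) <- c("class_labels", "data.frame")
  expect_equal(return_to_closed_probability(transition_matrix(labs_all_open)),
               100)
})

test_that("occupancy t test behaves at the degenerate limits", {
  a <- c(0.9, 0.92, 0.91); b <- c(0.1, 0.12, 0.11)
  res <- occupancy_test(a, b)
  expect_lt(res$p.value, 1e-3)
  expect_equal(occupancy_test(b, a)$p.value, res$p.value)
  expect_equal(occupancy_test(a, a)$p.value, 1)
  expect_warning(p0 <- occupancy_test(c(1, 1), c(0, 0)), "zero variance")
  expect_true(is.na(p0$p.value))
})
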
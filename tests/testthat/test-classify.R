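test_that("the full design yields 12 events with the composite control", {
  ds <- generate_dataset(tiny_scenario())
  events <- build_events(ds$meta)
  expect_length(events, 12)
  envs <- vapply(events, `[[`, character(1), "environment")
  expect_equal(as.integer(table(envs)), c(6L, 6L))
  # restricting to one environment gives 6
  expect_length(build_events(ds$meta[ds$meta$environment == "litter", ]), 6)
  for (ev in events) {
    expect_true(ev$resident_id != ev$invader_id)
    expect_length(intersect(ev$invader_samples, ev$control_samples), 0)
    expect_length(intersect(ev$final_samples, ev$control_samples), 0)
    # composite control: initial + resident-resident + killed samples
    roles <- ds$meta$role[match(ev$control_samples, ds$meta$sample_id)]
    expect_setequal(unique(roles), c("resident_initial",
                                     "final_resident_resident",
                                     "final_killed_resident"))
  }
})

test_that("presence sets follow the any-sample rule", {
  fx <- venn_fixture()
  counts <- rbind(fx$counts,
                  ctrl2 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L),
                  ctrl3 = c(0L, 1L, 0L, 0L, 0L, 0L, 0L))
  ev <- fx$event
  ev$control_samples <- c("ctrl1", "ctrl2", "ctrl3")
  sets <- presence_sets(counts, ev)
  expect_true("nr" %in% sets$R)        # count 1 in one of three controls
  expect_setequal(sets$I, c("ni", "iv", "nb", "cm"))
  expect_setequal(sets$F, c("ud", "rs", "iv", "cm"))
  # an OTU absent everywhere is in no set
  counts2 <- cbind(fx$counts, ghost = 0L)
  sets2 <- presence_sets(counts2, fx$event)
  expect_false("ghost" %in% unlist(sets2))
})

test_that("classification maps the seven Venn regions correctly", {
  # hand-applied region map
  got <- classify_otus(I = c("B", "C"), R = c("A", "B"), F = c("C", "D"))
  expect_equal(got[c("A", "B", "C", "D")],
               c(A = "nonresilient", B = "nonresilient", C = "invader",
                 D = "undetermined"))
  expect_equal(classify_otus("X", "X", "X"), c(X = "common"))
  fx <- venn_fixture()
  sets <- presence_sets(fx$counts, fx$event)
  expect_equal(classify_otus(sets$I, sets$R, sets$F)[names(fx$expected)],
               fx$expected)
})

test_that("classification equals the brute-force membership oracle", {
  set.seed(42)
  pool <- paste0("o", 1:30)
  for (i in 1:200) {
    I <- sample(pool, sample(0:15, 1))
    R <- sample(pool, sample(0:15, 1))
    F <- sample(pool, sample(0:15, 1))
    if (length(union(union(I, R), F)) == 0) next
    got <- classify_otus(I, R, F)
    want <- brute_force_classify(I, R, F)
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("event summaries partition the universe and track abundance", {
  fx <- venn_fixture()
  sets <- presence_sets(fx$counts, fx$event)
  assignment <- classify_otus(sets$I, sets$R, sets$F)
  s <- summarize_event(fx$counts, fx$event, assignment)
  expect_equal(sum(s$percent), 100, tolerance = 1e-6)
  expect_equal(s$n_otus_universe, 7)
  # region sizes: invader 1, noninvasive 1, resilient 1, nonresilient 2,
  # common 1, undetermined 1 (out of 7)
  expect_equal(unname(s$percent[c("invader", "nonresilient")]),
               c(1, 2) / 7 * 100, tolerance = 1e-6)
  # final sample has depth 10: ud 4, rs 2, iv 2, cm 2
  expect_equal(unname(s$relabund[c("common", "resilient", "invader", "undetermined")]),
               c(2, 2, 2, 4) / 10, tolerance = 1e-12)
  expect_equal(sum(s$relabund), 1, tolerance = 1e-6)

  # all-common degenerate case
  m <- matrix(5L, 3, 2, dimnames = list(c("inoc1", "ctrl1", "fin1"),
                                        c("x", "y")))
  a2 <- classify_otus(c("x", "y"), c("x", "y"), c("x", "y"))
  s2 <- summarize_event(m, fx$event, a2)
  expect_equal(unname(s2$percent["common"]), 100)
  expect_equal(unname(s2$relabund["common"]), 1)
})

test_that("rarefaction averaging is consistent and flags flicker", {
  ds <- generate_dataset(tiny_scenario(seed = 6))
  events <- build_events(ds$meta)
  ev <- events[[1]]
  depth <- min(rowSums(ds$otus))
  one <- average_over_rarefactions(ds$otus, ev, depth, n_reps = 1, seed = 9)
  # n_reps = 1 equals the single-pass path with the same derived seed
  rows <- intersect(rownames(ds$otus),
                    c(ev$invader_samples, ev$control_samples, ev$final_samples))
  rar <- rarefy(ds$otus[rows, ], depth,
                seed = invasim:::derive_seed(9, "rarefaction", 1))
  sets <- presence_sets(rar, ev)
  direct <- summarize_event(rar, ev, classify_otus(sets$I, sets$R, sets$F))
  expect_equal(one$percent, direct$percent)
  expect_equal(one$relabund, direct$relabund)
  expect_equal(unname(one$percent_sd), rep(0, 6))

  # depth equal to the (equal) row sums: no stochasticity, sd = 0
  flat <- matrix(c(4L, 6L, 3L, 7L, 5L, 5L), 3, 2, byrow = TRUE,
                 dimnames = list(c("inoc1", "ctrl1", "fin1"), c("x", "y")))
  many <- average_over_rarefactions(flat, venn_fixture()$event, 10,
                                    n_reps = 5, seed = 1)
  expect_equal(unname(many$percent_sd), rep(0, 6))
  expect_equal(unname(many$relabund_sd), rep(0, 4))
  expect_true(all(many$otu$fraction_modal == 1))

  # per-rarefaction partition property: every universe OTU categorised once
  full <- average_over_rarefactions(ds$otus, ev, depth, n_reps = 4, seed = 2)
  expect_equal(sum(full$percent), 100, tolerance = 1e-6)
  expect_true(all(full$otu$n_reps_present >= 1 & full$otu$n_reps_present <= 4))
})

test_that("cross-event aggregation uses sample sd and min/max", {
  ds <- generate_dataset(tiny_scenario(seed = 6))
  res <- classify_events(ds$otus, ds$meta, depth = 500, n_reps = 2, seed = 4)
  agg <- aggregate_events(res)
  expect_equal(nrow(agg), 6)
  expect_equal(sum(agg$percent_mean), 100, tolerance = 1e-6)

  one <- aggregate_events(res[1])
  expect_equal(one$percent_mean, one$percent_min)
  expect_equal(one$percent_mean, one$percent_max)
  expect_equal(one$percent_sd, rep(0, 6))

  # two artificial events with invader percents 10 and 20
  s1 <- res[[1]]; s2 <- res[[2]]
  s1$percent[] <- c(10, 20, 30, 20, 15, 5)
  s2$percent[] <- c(20, 10, 30, 20, 15, 5)
  two <- aggregate_events(list(s1, s2))
  expect_equal(two$percent_mean[1], 15)
  expect_equal(two$percent_sd[1], stats::sd(c(10, 20)))
})

test_that("the G-test matches direct evaluation and its invariants", {
  # identical count columns across depths: G = 0, p = 1
  same <- cbind(d1 = c(30, 50, 20), d2 = c(30, 50, 20))
  g0 <- g_test(same)
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_equal(g0$p_value, 1)

  tab <- rbind(c(10, 20), c(20, 10))
  # independent direct evaluation of 2 * sum O ln(O/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g_direct <- 2 * sum(tab * log(tab / E))
  g1 <- g_test(tab)
  expect_equal(g1$statistic, g_direct, tolerance = 1e-12)
  expect_equal(g1$df, 1)

  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    expect_gte(g_test(m)$statistic, -1e-12)
  }
  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("depth-robustness test consumes rounded mean category counts", {
  ds <- generate_dataset(tiny_scenario(seed = 6))
  res_by_depth <- lapply(c(`400` = 400, `800` = 800), function(dd) {
    classify_events(ds$otus, ds$meta, depth = dd, n_reps = 2, seed = 4)
  })
  g <- depth_robustness_gtest(res_by_depth)
  expect_true(is.finite(g$statistic) && g$statistic >= 0)
  expect_equal(ncol(g$counts), 2)
  expect_true(all(g$counts == round(g$counts)))
  expect_error(depth_robustness_gtest(res_by_depth[1]), ">= 2 depths")
})
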
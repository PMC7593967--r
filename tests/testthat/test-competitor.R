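make_instances <- function(category, n_initial, n_final = rep(0, length(n_initial)),
                           family = "FamA", environment = "litter") {
  data.frame(family = family, environment = environment,
             event_id = paste0("e", seq_along(n_initial)),
             otu_id = paste0("o", seq_along(n_initial)),
             category = category, n_initial = n_initial, n_final = n_final,
             stringsAsFactors = FALSE)
}

test_that("strong and weak scores follow the printed formulas", {
  # two strong instances with final/initial ratios 2 and 3
  inst <- make_instances(c("invader", "resilient"), n_initial = c(0.01, 0.02),
                         n_final = c(0.02, 0.06))
  s <- strong_score(inst)
  expect_equal(s$score, (2 + 3) * 2, tolerance = 1e-12)
  expect_equal(s$k, 2L)
  expect_equal(sqrt(s$score), 3.16227766, tolerance = 1e-6)

  one <- strong_score(make_instances("invader", 0.05, 0.05))
  expect_equal(one$score, 1, tolerance = 1e-12)

  # doubling every final abundance doubles the strong score
  inst2 <- inst; inst2$n_final <- inst$n_final * 2
  expect_equal(strong_score(inst2)$score, 2 * s$score, tolerance = 1e-12)

  w <- weak_score(make_instances(c("noninvasive", "nonresilient"),
                                 n_initial = c(0.01, 0.03)))
  expect_equal(w$score, 0.04 * 2, tolerance = 1e-12)
  # weak score ignores final abundances
  w2 <- weak_score(make_instances(c("noninvasive", "nonresilient"),
                                  n_initial = c(0.01, 0.03),
                                  n_final = c(0.5, 0.9)))
  expect_equal(w2$score, w$score)

  expect_equal(strong_score(make_instances("noninvasive", 0.1))$k, 0L)
  expect_error(strong_score(make_instances("invader", 0, 0.1)),
               "zero initial")
})

test_that("instance collection applies the taxonomy-confidence filter", {
  ds <- generate_dataset(tiny_scenario(seed = 12))
  res <- classify_events(ds$otus, ds$meta, depth = 500, n_reps = 3, seed = 1)
  tax <- ds$taxonomy
  inst <- suppressWarnings(collect_instances(res, tax, min_confidence = 70))
  expect_true(all(inst$category %in% c("invader", "resilient",
                                       "noninvasive", "nonresilient")))
  # strong instances are detected in their initial pool
  expect_true(all(inst$n_initial[inst$category %in% c("invader", "resilient")] > 0))
  # an OTU at 69.9% confidence is excluded, at 70.0% retained
  probe <- inst$otu_id[1]
  tax2 <- tax
  tax2$family_confidence[tax2$otu_id == probe] <- 69.9
  inst2 <- suppressWarnings(collect_instances(res, tax2, min_confidence = 70))
  expect_false(probe %in% inst2$otu_id)
  tax2$family_confidence[tax2$otu_id == probe] <- 70
  inst3 <- suppressWarnings(collect_instances(res, tax2, min_confidence = 70))
  expect_true(probe %in% inst3$otu_id)
  # an OTU can contribute one instance per event (different outcomes allowed)
  per_event <- table(inst$otu_id, inst$event_id)
  expect_true(all(per_event <= 1))
  expect_true(any(rowSums(per_event > 0) > 1))
})

test_that("k-replication scales both scores by m^2", {
  inst <- make_instances(c("invader", "resilient"), c(0.02, 0.05), c(0.08, 0.05))
  base <- strong_score(inst)$score
  for (m in c(2, 5)) {
    rep_inst <- inst[rep(seq_len(nrow(inst)), m), ]
    expect_equal(strong_score(rep_inst)$score, m^2 * base, tolerance = 1e-12)
  }
  winst <- make_instances(c("noninvasive", "nonresilient"), c(0.02, 0.05))
  wbase <- weak_score(winst)$score
  expect_equal(weak_score(winst[rep(1:2, 3), ])$score, 9 * wbase,
               tolerance = 1e-12)
})

test_that("the report applies environment, threshold and depth filters", {
  # bacterial family above threshold in one environment only -> excluded
  sco <- rbind(
    make_instances("invader", 0.001, 0.061, family = "OnlyAgar", environment = "agar"),
    make_instances("invader", 0.01, 0.004, family = "OnlyAgar", environment = "litter"),
    make_instances("invader", 0.001, 0.060, family = "Both", environment = "agar"),
    make_instances("invader", 0.001, 0.080, family = "Both", environment = "litter"))
  scores <- score_competitors(sco)
  rep_b <- competitor_report(list(scores), organism = "bacteria", threshold = 50)
  expect_false("OnlyAgar" %in% rep_b$family)   # 60 agar / 4 litter
  expect_true("Both" %in% rep_b$family)        # 60 and 80 -> mean 70
  both <- rep_b[rep_b$family == "Both", ]
  expect_equal(both$score_mean, 70, tolerance = 1e-9)
  expect_equal(both$score_sqrt, sqrt(70), tolerance = 1e-9)

  # fungi qualify on the litter score alone
  rep_f <- competitor_report(list(scores), organism = "fungi", threshold = 50)
  expect_true("OnlyAgar" %in% rep_f$family == FALSE)
  expect_true("Both" %in% rep_f$family)
  expect_equal(rep_f$score_mean[rep_f$family == "Both"], 80)

  # a family must qualify at every depth
  weaker <- scores; weaker$strong_score <- weaker$strong_score / 10
  rep_d <- competitor_report(list(scores, weaker), organism = "bacteria",
                             threshold = 50)
  expect_false("Both" %in% rep_d$family)
})

test_that("strength classes cover pure, combined and mixed outcomes", {
  expect_equal(classify_strength("resilient"), "resilient")
  expect_equal(classify_strength(c("invader", "resilient")),
               "invader_and_resilient")
  expect_equal(classify_strength(c("noninvasive", "nonresilient"),
                                 strong_qualifies = FALSE,
                                 weak_qualifies = TRUE),
               "nonresilient_and_noninvasive")
  expect_equal(classify_strength("invader", strong_qualifies = TRUE,
                                 weak_qualifies = TRUE), "mixed")

  # a family qualifying both strong and weak is reported mixed on both rows
  sco <- rbind(
    make_instances("invader", 0.001, 0.061, family = "M", environment = "agar"),
    make_instances("invader", 0.001, 0.061, family = "M", environment = "litter"),
    make_instances(c("nonresilient", "nonresilient"), c(30, 30), family = "M",
                   environment = "agar"),
    make_instances(c("nonresilient", "nonresilient"), c(30, 30), family = "M",
                   environment = "litter"))
  rep_m <- competitor_report(list(score_competitors(sco)), threshold = 50)
  expect_setequal(rep_m$type, c("strong", "weak"))
  expect_true(all(rep_m$strength_class == "mixed"))
})
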
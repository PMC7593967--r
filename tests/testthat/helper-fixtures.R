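# Shared fixtures: all built in code at test time.

# Small, fast scenario for tests that only need structure, not realism.
tiny_scenario <- function(seed = 1, n_otus_per_pool = 40, depth_mean = 1200, ...) {
  invasion_scenario(n_otus_per_pool = n_otus_per_pool,
                    depth_mean = depth_mean, seed = seed, ...)
}

# A 3-sample x 7-OTU table covering all seven Venn regions of the
# (inoculum, control, final) presence sets exactly once, with a minimal
# hand-built event. Region plan (otu: groups it is present in):
#   ni = I only, nr = R only, ud = F only, rs = R+F, iv = I+F,
#   nb = I+R, cm = I+R+F
venn_fixture <- function() {
  otus <- c("ni", "nr", "ud", "rs", "iv", "nb", "cm")
  counts <- matrix(0L, nrow = 3, ncol = 7,
                   dimnames = list(c("inoc1", "ctrl1", "fin1"), otus))
  counts["inoc1", c("ni", "iv", "nb", "cm")] <- c(4L, 2L, 2L, 2L)
  counts["ctrl1", c("nr", "rs", "nb", "cm")] <- c(4L, 2L, 2L, 2L)
  counts["fin1", c("ud", "rs", "iv", "cm")] <- c(4L, 2L, 2L, 2L)
  event <- structure(list(event_id = "litter_MC3-MC1", environment = "litter",
                          resident_id = "MC1", invader_id = "MC3",
                          invader_samples = "inoc1",
                          control_samples = "ctrl1",
                          final_samples = "fin1"),
                     class = "invasion_event")
  list(counts = counts, event = event,
       expected = c(ni = "noninvasive", nr = "nonresilient",
                    ud = "undetermined", rs = "resilient", iv = "invader",
                    nb = "nonresilient", cm = "common"))
}

# Independent brute-force oracle for the presence-pattern classifier:
# explicit per-OTU lookup over the membership triple (in I, in R, in F).
brute_force_classify <- function(I, R, F) {
  triple_map <- c("TFF" = "noninvasive", "FTF" = "nonresilient",
                  "FFT" = "undetermined", "TTF" = "nonresilient",
                  "TFT" = "invader", "FTT" = "resilient", "TTT" = "common")
  u <- union(union(I, R), F)
  key <- paste0(ifelse(u %in% I, "T", "F"), ifelse(u %in% R, "T", "F"),
                ifelse(u %in% F, "T", "F"))
  stats::setNames(unname(triple_map[key]), u)
}

# Flatten per-event modal assignments against planted truth labels.
modal_vs_truth <- function(results, truth) {
  assign <- do.call(rbind, lapply(results, function(s) {
    data.frame(event_id = s$event_id, otu_id = s$otu$otu_id,
               modal = s$otu$modal_category, stringsAsFactors = FALSE)
  }))
  merge(truth, assign, by = c("event_id", "otu_id"), all.x = TRUE)
}

mean_undetermined <- function(results) {
  mean(vapply(results, function(s) s$percent[["undetermined"]], numeric(1)))
}
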
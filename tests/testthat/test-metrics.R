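test_that("spike count maps bin events and enforce window bounds", {
  rec <- synthetic_record(data.frame(x = integer(0), y = integer(0),
                                     t = numeric(0)))
  expect_true(all(spike_count_map(rec) == 0))
  rec1 <- synthetic_record(data.frame(x = 3, y = 4, t = 10))
  m <- spike_count_map(rec1, c(5, 15))
  expect_equal(m[4, 5], 1)
  expect_equal(sum(m), 1)
  expect_equal(sum(spike_count_map(rec1, c(20, 30))), 0)
  expect_error(spike_count_map(rec1, c(15, 5)), "window")
  # conservation: full-run column sums equal per-cell event counts
  sp <- block_spikes(2, 2, 3, 3, t = 1, each = 4)
  expect_equal(sum(spike_count_map(synthetic_record(sp))), nrow(sp))
})

test_that("cluster detection finds blobs, discards specks, conserves spikes", {
  rec <- synthetic_record(data.frame(x = integer(0), y = integer(0),
                                     t = numeric(0)))
  expect_equal(nrow(detect_clusters(rec)), 0)
  # one 5x5 blob: a single cluster with its center of gravity at the middle
  blob <- synthetic_record(block_spikes(5, 7, 5, 5))
  rep <- detect_clusters(blob)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$n_cells, 25)
  expect_equal(c(rep$cog_x, rep$cog_y), c(7, 9))
  # a 2-cell speck is below min_size but still counted in the conservation
  both <- synthetic_record(rbind(block_spikes(5, 7, 5, 5),
                                 block_spikes(15, 15, 2, 1)))
  rep2 <- detect_clusters(both, min_size = 3)
  expect_equal(nrow(rep2), 1)
  expect_equal(sum(rep2$n_spikes) + attr(rep2, "discarded_spikes"),
               attr(rep2, "total_spikes"))
  # 8-connectivity joins diagonal neighbours; 4-connectivity splits them
  diag2 <- synthetic_record(data.frame(x = c(3, 4, 5, 6), y = c(3, 4, 5, 6),
                                       t = 1))
  expect_equal(nrow(detect_clusters(diag2, min_size = 1)), 1)
  expect_equal(nrow(detect_clusters(diag2, min_size = 1, connectivity = 4)), 4)
})

test_that("component labelling agrees with an igraph oracle on random maps", {
  skip_if_not_installed("igraph")
  set.seed(31)
  sizes <- list(c(12, 12), c(30, 30), c(100, 100))
  for (g in sizes) {
    for (p in c(0.1, 0.35)) {
      active <- matrix(stats::runif(g[1] * g[2]) < p, g[1], g[2])
      lab <- spikefield:::label_components(active)
      expect_equal(max(lab), igraph_components(active),
                   info = sprintf("%dx%d p=%.2f", g[1], g[2], p))
      # labels partition the active set
      expect_true(all((lab > 0) == active))
    }
  }
})

test_that("rate filter and off-mask rule separate self-maintained clusters", {
  # blob firing fast plus a mask column firing slowly
  fast <- block_spikes(8, 8, 4, 4, t = 60, each = 10)  # 200 Hz in [50, 100]
  slow <- data.frame(x = 2, y = 2:6, t = 70)           # single late spikes
  rec <- synthetic_record(rbind(fast, slow))
  all_cl <- detect_clusters(rec, window = c(50, 100))
  expect_equal(nrow(all_cl), 2)
  fast_only <- detect_clusters(rec, window = c(50, 100), rate_min = 150)
  expect_equal(nrow(fast_only), 1)
  expect_equal(fast_only$cog_x, 9.5)
  # off-mask rule: a component wholly inside the stimulated set is residue
  mask <- expand.grid(x = 8:11, y = 8:11)
  expect_equal(nrow(detect_clusters(rec, window = c(50, 100), rate_min = 150,
                                    off_mask = mask,
                                    require_off_mask = TRUE)), 0)
  expect_equal(nrow(detect_clusters(rec, window = c(50, 100), rate_min = 150,
                                    off_mask = data.frame(x = 8, y = 8),
                                    require_off_mask = TRUE)), 1)
  # without the requirement the mask only feeds the recruitment latency
  both <- detect_clusters(rec, window = c(50, 100), rate_min = 150,
                          off_mask = data.frame(x = 8, y = 8))
  expect_equal(nrow(both), 1)
  expect_false(is.na(both$recruited_at))
})

test_that("relative activity is a spike-count ratio, linear in the record", {
  a <- synthetic_record(block_spikes(5, 5, 3, 3, each = 2))
  expect_equal(relative_activity(a, a), 1)
  empty <- synthetic_record(data.frame(x = integer(0), y = integer(0),
                                       t = numeric(0)))
  expect_equal(relative_activity(empty, a), 0)
  tripled <- synthetic_record(do.call(rbind, replicate(3, a$spikes,
                                                       simplify = FALSE)))
  expect_equal(relative_activity(tripled, a), 3)
  expect_error(relative_activity(a, empty), "no spikes")
})

test_that("deviation from B is signed toward A and flips under mirroring", {
  rep1 <- data.frame(cluster = 1, n_cells = 10, n_spikes = 50,
                     cog_x = 60, cog_y = 51.5)
  d0 <- deviation_from_b(rep1, b_center = c(60, 51.5), a_center = c(30, 51.5))
  expect_equal(d0$deviation_x, 0)
  # cluster displaced toward A (A left of B) => negative
  rep2 <- data.frame(cluster = 1, n_cells = 10, n_spikes = 50,
                     cog_x = 55, cog_y = 51.5)
  dv <- deviation_from_b(rep2, c(60, 51.5), c(30, 51.5))
  expect_equal(dv$deviation_x, -5)
  # reflect stimulus A about B's column: the same response is now
  # displaced away from the new A, so the sign flips exactly
  dvm <- deviation_from_b(rep2, c(60, 51.5), c(90, 51.5))
  expect_equal(dvm$deviation_x, -dv$deviation_x)
  # no clusters -> flagged suppressed
  none <- deviation_from_b(rep1[0, ], c(60, 51.5), c(30, 51.5))
  expect_true(none$suppressed)
  expect_equal(none$n_clusters, 0)
  # two clusters: the one nearest B wins
  rep3 <- data.frame(cluster = 1:2, n_cells = 10, n_spikes = 50,
                     cog_x = c(35, 58), cog_y = 51.5)
  expect_equal(deviation_from_b(rep3, c(60, 51.5), c(30, 51.5))$winner_x, 58)
})

test_that("rise speed differentiates the probe-line maximum potential", {
  ramp <- structure(list(
    trace = list(times = 0:100,
                 v = rbind(seq(-70, -70 + 100, by = 1),   # 1 mV/ms ramp
                           rep(-75, 101))),
    config = sim_config(grid = c(5, 5), duration = 100)),
    class = "field_sim")
  expect_equal(rise_speed(ramp, c(0, 6)), 1000)
  expect_equal(rise_speed(ramp, c(30, 90)), 1000)
  flat <- ramp; flat$trace$v <- matrix(-70, 2, 101)
  expect_equal(rise_speed(flat, c(0, 6)), 0)
  expect_error(rise_speed(ramp, c(90, 150)), "window")
})

test_that("steady firing rate counts only active cluster members", {
  # 10 cells, 20 spikes each inside the last 50 ms of a 100 ms run
  sp <- do.call(rbind, lapply(0:19, function(k)
    data.frame(x = 5:14, y = 5, t = 52 + k * 2)))
  rec <- synthetic_record(sp, duration = 100)
  rep <- detect_clusters(rec)
  expect_equal(rep$steady_rate, 400)
  expect_equal(steady_firing_rate(rec, rep, window = c(50, 100)), 400)
  # a silent member does not dilute the rate
  sp2 <- rbind(sp, data.frame(x = 15, y = 5, t = 10))
  rep2 <- detect_clusters(synthetic_record(sp2, duration = 100))
  expect_equal(rep2$steady_rate, 400)
})

test_that("first-spike latency handles empty and populated records", {
  empty <- synthetic_record(data.frame(x = integer(0), y = integer(0),
                                       t = numeric(0)))
  expect_true(is.na(first_spike_latency(empty)))
  rec <- synthetic_record(data.frame(x = c(1, 2), y = c(1, 2), t = c(7.5, 3.2)))
  expect_equal(first_spike_latency(rec), 3.2)
})
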
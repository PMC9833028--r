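test_that("droplet footprint matches a numerical spherical-cap oracle", {
  for (v in c(0.5, 2, 10, 30, 50)) {
    expect_equal(droplet_footprint_diameter(v, 150),
                 oracle_cap_diameter(v, 150), tolerance = 1e-7)
  }
  # hydrophilic angles use the contact-line width
  expect_equal(droplet_footprint_diameter(10, 80),
               oracle_cap_diameter(10, 80), tolerance = 1e-7)
  # published approximations: 10 uL ~2.5 mm, 30 uL ~3.7 mm at 150 deg
  expect_equal(droplet_footprint_diameter(10, 150), 2.68, tolerance = 0.01)
  expect_equal(droplet_footprint_diameter(30, 150), 3.87, tolerance = 0.01)
  expect_equal(droplet_footprint_diameter(0), 0)
  vols <- seq(0.5, 60, by = 0.5)
  expect_true(all(diff(droplet_footprint_diameter(vols)) > 0))
  expect_error(droplet_footprint_diameter(10, 0), "contact_angle")
  expect_error(droplet_footprint_diameter(10, 190), "contact_angle")
  expect_error(droplet_footprint_diameter(-1), ">= 0")
})

test_that("channel transitions reproduce both published cases", {
  expect_identical(classify_channel_transition(1.3, 2.5), "PASS_DROPLET")
  expect_identical(classify_channel_transition(0.6, 3.7), "EXTRACT_BEADS")
  # any threshold in (0.24, 0.52) reproduces both; 0.35 sits centrally
  for (r in seq(0.25, 0.51, by = 0.02)) {
    expect_identical(classify_channel_transition(1.3, 2.5, r_pass = r),
                     "PASS_DROPLET")
    expect_identical(classify_channel_transition(0.6, 3.7, r_pass = r),
                     "EXTRACT_BEADS")
  }
  # a channel at least as wide as the droplet never constrains it
  expect_identical(classify_channel_transition(4, 4, r_pass = 1),
                   "PASS_DROPLET")
  expect_error(classify_channel_transition(0, 2), "> 0")
})

test_that("merging conserves volume and species and resets homogeneity", {
  layout <- fixture_layout()
  manifest <- data.frame(well = c(9, 8), species = c("stop", "tmb"),
                         volume_ul = c(10, 30))
  state <- chip_state(layout, manifest, initial_beads = 100,
                      beads_well = 9)
  s1 <- apply_step(state, hold_command(magnet_position("B", 9), 20),
                   layout)
  s2 <- apply_step(s1$state,
                   move_command(magnet_position("B", 9),
                                magnet_position("B", 8)),
                   layout, s1$sink)
  u <- s2$state$units[[1]]
  expect_null(u$droplets[["9"]])
  merged <- u$droplets[["8"]]
  expect_equal(merged$volume_ul, 40)
  expect_equal(unname(merged$species["stop"]), 10)
  expect_equal(unname(merged$species["tmb"]), 30)
  expect_equal(merged$homogeneity, 0)
  expect_identical(u$beads$count, 100L)   # pass-through keeps all beads
})

test_that("extraction draws binomial survivors and logs the losses", {
  layout <- fixture_layout()
  manifest <- data.frame(well = c(1, 2), species = c("sample", "wash"),
                         volume_ul = c(30, 30))
  go <- function(p_retain, seed) {
    set.seed(seed)
    state <- chip_state(layout, manifest, initial_beads = 10000,
                        params = engine_params(p_retain = p_retain))
    s1 <- apply_step(state, hold_command(magnet_position("B", 1), 20),
                     layout)
    apply_step(s1$state, move_command(magnet_position("B", 1),
                                      magnet_position("B", 2)),
               layout, s1$sink)
  }
  # p_retain = 1 keeps every bead
  res <- go(1.0, 1)
  expect_identical(res$state$units[[1]]$beads$count, 10000L)
  # survivors near n * p within 3 binomial standard deviations
  res <- go(0.9694, 42)
  n <- 10000; p <- 0.9694
  expect_lt(abs(res$state$units[[1]]$beads$count - n * p),
            3 * sqrt(n * p * (1 - p)))
  # carry-over volume moved with the cluster
  u <- res$state$units[[1]]
  expect_equal(u$droplets[["1"]]$volume_ul, 29.5)
  expect_equal(u$droplets[["2"]]$volume_ul, 30.5)
})

test_that("traversal without a prior clustering hold is rejected", {
  layout <- fixture_layout()
  manifest <- data.frame(well = 1, species = "sample", volume_ul = 30)
  state <- chip_state(layout, manifest, initial_beads = 100)
  expect_error(
    apply_step(state, move_command(magnet_position("B", 1),
                                   magnet_position("B", 2)), layout),
    "not clustered")
  expect_error(
    run_protocol(layout, mdm_protocol("x", list(
      move_command(magnet_position("B", 1), magnet_position("B", 3)))),
      manifest = manifest),
    "no channel|does not validate")
})

test_that("full workflow retention approaches the published ~78%", {
  layout <- fixture_layout()
  proto <- fixture_protocol()
  run <- run_protocol(layout, proto, seed = 11)
  r <- retention_summary(run$log)
  expect_gt(r, 0.74)
  expect_lt(r, 0.82)
  # exactly eight extraction transfers per unit (wells 1 -> ... -> 9)
  ex <- run$log[run$log$kind == "extract_beads" & run$log$unit == 1, ]
  expect_identical(nrow(ex), 8L)
  expect_equal(ex$well_from, 1:8)
  expect_equal(ex$well_to, 2:9)
})

test_that("runs are deterministic given the seed", {
  layout <- fixture_layout()
  proto <- fixture_protocol()
  a <- run_protocol(layout, proto, seed = 123)
  b <- run_protocol(layout, proto, seed = 123)
  expect_identical(a$log, b$log)
  expect_identical(a$state, b$state)
  c <- run_protocol(layout, proto, seed = 124)
  expect_false(identical(a$log, c$log))
})

test_that("volume and bead ledgers balance against the event log", {
  layout <- fixture_layout()
  proto <- fixture_protocol()
  run <- run_protocol(layout, proto, seed = 5)
  init_vol <- sum(run$log$volume_ul[run$log$kind == "init"])
  expect_equal(total_volume(run$state), init_vol, tolerance = 1e-9)
  init_beads <- sum(run$log$beads_moved[run$log$kind == "init"])
  lost <- sum(run$log$beads_lost, na.rm = TRUE)
  final <- sum(vapply(run$state$units, function(u) u$beads$count,
                      integer(1)))
  expect_identical(final + as.integer(lost), as.integer(init_beads))
  # event times never run backwards
  expect_true(all(diff(run$log$time) >= 0))
})

test_that("retention summary handles the degenerate and pass-only cases", {
  layout <- fixture_layout()
  run <- run_protocol(layout, no_extraction_protocol(), seed = 2,
                      beads_well = 9)
  expect_equal(retention_summary(run$log), 1.0)
  empty_log <- run$log[0, ]
  expect_error(retention_summary(empty_log), "undefined")
})

test_that("mean retention over many runs matches p_retain^8", {
  layout <- fixture_layout()
  proto <- fixture_protocol()
  p <- engine_params()$p_retain
  n_runs <- 200
  r <- vapply(seq_len(n_runs), function(s) {
    retention_summary(run_protocol(layout, proto, seed = s)$log)
  }, numeric(1))
  se <- stats::sd(r) / sqrt(n_runs)
  expect_lt(abs(mean(r) - p^8), 3 * se + 1e-12)
})
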
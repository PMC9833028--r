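test_that("motion commands parse per the grammar", {
  cmd <- parse_motion_command("T1 to N5")
  expect_s3_class(cmd, "move_command")
  expect_identical(cmd$start$layer, "T")
  expect_identical(cmd$start$keypoint, 1L)
  expect_identical(cmd$end$layer, "N")
  expect_identical(cmd$end$keypoint, 5L)

  cmd <- parse_motion_command("b3 to b4")   # case-insensitive
  expect_identical(cmd$start$layer, "B")
  expect_identical(cmd$end$keypoint, 4L)

  mix <- parse_motion_command("MIX 4 50")
  expect_s3_class(mix, "mix_command")
  expect_identical(mix$cycles, 50L)

  hold <- parse_motion_command("hold B1 20")
  expect_s3_class(hold, "hold_command")
  expect_equal(hold$duration, 20)

  inc <- parse_motion_command("INCUBATE 1 900 50")
  expect_s3_class(inc, "incubate_command")
  expect_identical(inc$embedded_mix_cycles, 50L)
})

test_that("parse errors name the offending token", {
  expect_error(parse_motion_command("X2 to N5"), "unknown layer X")
  expect_error(parse_motion_command("T0 to N5"), "outside 1..9")
  expect_error(parse_motion_command("T1 to N10"), "outside 1..9")
  expect_error(parse_motion_command("T1 N5"), "unrecognized")
  expect_error(parse_motion_command("MIX 1"), "MIX expects")
  expect_error(parse_motion_command("HOLD B1"), "HOLD expects")
})

test_that("parse and format are mutually inverse on every command type", {
  cmds <- list(
    move_command(magnet_position("T", 1), magnet_position("N", 5)),
    move_command(magnet_position("B", 3), magnet_position("B", 4)),
    move_command(magnet_position("M", 9), magnet_position("T", 2)),
    mix_command(7, 3),
    mix_command(1, 50),
    hold_command(magnet_position("B", 1), 20),
    hold_command(magnet_position("N", 8), 0),
    incubate_command(4, 900, 50),
    incubate_command(2, 60, 0)
  )
  for (cmd in cmds) {
    back <- parse_motion_command(format_command(cmd))
    expect_equal(back, cmd, ignore_attr = FALSE)
  }
})

test_that("builtin ELISA protocol encodes the published workflow", {
  proto <- fixture_protocol()
  incs <- Filter(function(s) s$type == "incubate", proto$steps)
  first <- incs[[1]]
  expect_identical(first$keypoint, 1L)
  expect_equal(first$duration, 900)
  expect_identical(first$embedded_mix_cycles, 50L)
  # washes at wells 2, 3, 5, 6, 7: 1 min with 3 cycles each
  wash_wells <- vapply(
    Filter(function(s) s$duration == 60, incs),
    function(s) s$keypoint, integer(1))
  expect_setequal(wash_wells, c(2L, 3L, 5L, 6L, 7L))
  # 20 s bottom hold right after the first incubation
  holds <- Filter(function(s) s$type == "hold", proto$steps)
  expect_identical(holds[[1]]$position$layer, "B")
  expect_identical(holds[[1]]$position$keypoint, 1L)
  expect_equal(holds[[1]]$duration, 20)
  # reagent manifest per well
  m <- proto$metadata$manifest
  expect_equal(m$volume_ul[m$species == "sample"], 30)
  expect_equal(m$volume_ul[m$species == "stop_solution"], 10)
  expect_equal(sum(m$volume_ul[m$species == "wash_buffer"]), 150)
  expect_equal(m$volume_ul[m$species == "tmb_substrate"], 50)
})

test_that("protocol validation flags bad keypoints and illegal traversals", {
  layout <- fixture_layout()
  expect_identical(validate_protocol(fixture_protocol(), layout),
                   character(0))
  bad <- mdm_protocol("bad", list(
    move_command(magnet_position("B", 1), magnet_position("B", 5))))
  v <- validate_protocol(bad, layout)
  expect_true(any(grepl("no channel", v)))
  lateral_top <- mdm_protocol("bad2", list(
    move_command(magnet_position("T", 1), magnet_position("T", 2))))
  expect_true(any(grepl("not allowed",
                        validate_protocol(lateral_top, layout))))
})

test_that("a protocol with no violations executes without transition errors", {
  layout <- fixture_layout()
  proto <- fixture_protocol()
  expect_identical(validate_protocol(proto, layout), character(0))
  expect_no_error(run_protocol(layout, proto, seed = 1))
})

test_that("duration estimate sums incubation, hold, travel and mixing", {
  layout <- fixture_layout()
  two_inc <- mdm_protocol("inc", list(incubate_command(1, 900, 50),
                                      incubate_command(4, 900, 50)))
  expect_equal(estimate_duration(two_inc, layout), 1800)

  travel <- mdm_protocol("mv", list(
    move_command(magnet_position("B", 1), magnet_position("B", 2))))
  t1 <- estimate_duration(travel, layout, speed = 1)
  t2 <- estimate_duration(travel, layout, speed = 2)
  expect_gt(t1, 0)
  expect_equal(t2, t1 / 2)

  mixes <- mdm_protocol("mx", list(mix_command(1, 3)))
  expect_equal(estimate_duration(mixes, layout), 54)

  # full workflow comes out near the published ~45 min turnaround
  full <- estimate_duration(fixture_protocol(), layout)
  expect_gt(full, 40 * 60)
  expect_lt(full, 50 * 60)
})

test_that("protocol files round trip in both formats", {
  proto <- fixture_protocol()
  json <- withr::local_tempfile(fileext = ".json")
  write_protocol(proto, json)
  back <- read_protocol(json)
  expect_identical(length(back$steps), length(proto$steps))
  for (i in seq_along(proto$steps)) {
    expect_equal(format_command(back$steps[[i]]),
                 format_command(proto$steps[[i]]))
  }
  expect_equal(back$metadata$manifest, proto$metadata$manifest)

  script <- withr::local_tempfile(fileext = ".mdm")
  write_protocol(proto, script)
  back2 <- read_protocol(script)
  expect_identical(length(back2$steps), length(proto$steps))
})
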
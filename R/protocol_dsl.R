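# Magnet motion DSL
#
# The magnet rack moves among 9 keypoints (microwell centers) on 4 discrete
# height layers: T (top, cluster at droplet ceiling), N (neutral, no droplet
# effect), M (mezzanine, partial attraction for stirring), B (bottom,
# cluster at well floor, enables dragging). A protocol is an ordered list of
# move / mix / hold / incubate commands.

LAYER_CODES <- c("T", "N", "M", "B")

#' Magnet position
#'
#' @param layer One of "T", "N", "M", "B" (top, neutral, mezzanine, bottom).
#' @param keypoint Integer 1-9.
#' @return An object of class `magnet_position`.
#' @export
magnet_position <- function(layer, keypoint) {
  layer <- toupper(as.character(layer))
  if (!(layer %in% LAYER_CODES)) stop("unknown layer ", layer)
  keypoint <- as.integer(keypoint)
  if (is.na(keypoint) || keypoint < 1L || keypoint > 9L) {
    stop("keypoint must be in 1..9, got ", keypoint)
  }
  structure(list(layer = layer, keypoint = keypoint),
            class = "magnet_position")
}

#' Motion commands
#'
#' Constructors for the four command types of the magnet motion DSL.
#' `move_command` relocates the magnet between two layer/keypoint stations;
#' `mix_command` runs mixing cycles at a keypoint (1 cycle = 1 reciprocal
#' vertical motion + 1 circular motion at the mezzanine layer);
#' `hold_command` parks the magnet (a bottom-layer hold of at least 1 s
#' clusters the beads); `incubate_command` waits at a keypoint with a number
#' of mixing cycles embedded in the incubation time.
#'
#' @param start,end,position [magnet_position()] objects.
#' @param speed Travel speed in mm/s (> 0).
#' @param keypoint Integer keypoint 1-9.
#' @param cycles Positive integer number of mixing cycles.
#' @param duration Duration in seconds (>= 0).
#' @param embedded_mix_cycles Integer >= 0 mixing cycles performed within
#'   the incubation window (they do not extend it).
#' @return A command object with class `c("<type>_command", "mdm_command")`.
#' @name motion_commands
NULL

#' @rdname motion_commands
#' @export
move_command <- function(start, end, speed = 1) {
  stopifnot(inherits(start, "magnet_position"),
            inherits(end, "magnet_position"))
  if (!(speed > 0)) stop("speed must be > 0")
  structure(list(type = "move", start = start, end = end,
                 speed = as.numeric(speed)),
            class = c("move_command", "mdm_command"))
}

#' @rdname motion_commands
#' @export
mix_command <- function(keypoint, cycles) {
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("cycles must be >= 1")
  structure(list(type = "mix",
                 keypoint = magnet_position("M", keypoint)$keypoint,
                 cycles = cycles),
            class = c("mix_command", "mdm_command"))
}

#' @rdname motion_commands
#' @export
hold_command <- function(position, duration) {
  stopifnot(inherits(position, "magnet_position"))
  duration <- as.numeric(duration)
  if (is.na(duration) || duration < 0) stop("duration must be >= 0")
  structure(list(type = "hold", position = position, duration = duration),
            class = c("hold_command", "mdm_command"))
}

#' @rdname motion_commands
#' @export
incubate_command <- function(keypoint, duration, embedded_mix_cycles = 0) {
  duration <- as.numeric(duration)
  if (is.na(duration) || duration < 0) stop("duration must be >= 0")
  cycles <- as.integer(embedded_mix_cycles)
  if (is.na(cycles) || cycles < 0L) stop("embedded_mix_cycles must be >= 0")
  structure(list(type = "incubate",
                 keypoint = magnet_position("N", keypoint)$keypoint,
                 duration = duration, embedded_mix_cycles = cycles),
            class = c("incubate_command", "mdm_command"))
}

#' @export
print.mdm_command <- function(x, ...) {
  cat(format_command(x), "\n")
  invisible(x)
}

#' Parse one motion command
#'
#' Grammar (case-insensitive, whitespace-tolerant):
#' \preformatted{
#'   <L><k> to <L><k>        e.g. "T1 to N5"   (move)
#'   MIX <k> <cycles>        e.g. "MIX 1 50"
#'   HOLD <L><k> <seconds>   e.g. "HOLD B1 20"
#'   INCUBATE <k> <seconds> [<cycles>]
#' }
#' where L is a layer letter (T/N/M/B) and k a keypoint 1-9.
#'
#' @param text A single command string.
#' @return A command object (see [motion_commands]).
#' @export
parse_motion_command <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) stop("empty command")
  toks <- strsplit(raw, "\\s+")[[1]]
  parse_pos <- function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1]]
    if (length(m) != 3) stop("malformed position token '", tok, "'")
    layer <- toupper(m[2])
    if (!(layer %in% LAYER_CODES)) {
      stop("unknown layer ", layer, " in token '", tok, "'")
    }
    kp <- as.integer(m[3])
    if (kp < 1L || kp > 9L) {
      stop("keypoint ", kp, " outside 1..9 in token '", tok, "'")
    }
    magnet_position(layer, kp)
  }
  parse_int <- function(tok, what, min) {
    n <- suppressWarnings(as.numeric(tok))
    if (is.na(n)) stop("malformed ", what, " token '", tok, "'")
    if (n < min) stop(what, " ", n, " below minimum ", min)
    n
  }
  head <- toupper(toks[1])
  if (head == "MIX") {
    if (length(toks) != 3) stop("MIX expects 2 arguments: MIX <k> <cycles>")
    kp <- parse_int(toks[2], "keypoint", 1)
    if (kp > 9) stop("keypoint ", kp, " outside 1..9")
    mix_command(kp, parse_int(toks[3], "cycles", 1))
  } else if (head == "HOLD") {
    if (length(toks) != 3) {
      stop("HOLD expects 2 arguments: HOLD <pos> <seconds>")
    }
    hold_command(parse_pos(toks[2]), parse_int(toks[3], "duration", 0))
  } else if (head == "INCUBATE") {
    if (!(length(toks) %in% c(3, 4))) {
      stop("INCUBATE expects INCUBATE <k> <seconds> [<cycles>]")
    }
    kp <- parse_int(toks[2], "keypoint", 1)
    if (kp > 9) stop("keypoint ", kp, " outside 1..9")
    cyc <- if (length(toks) == 4) parse_int(toks[4], "cycles", 0) else 0
    incubate_command(kp, parse_int(toks[3], "duration", 0), cyc)
  } else {
    # move form "<pos> to <pos>"
    if (length(toks) != 3 || toupper(toks[2]) != "TO") {
      stop("unrecognized command '", raw, "'")
    }
    move_command(parse_pos(toks[1]), parse_pos(toks[3]))
  }
}

#' Format a command back to DSL text
#'
#' Inverse of [parse_motion_command()]: `parse(format(x))` reproduces `x`.
#'
#' @param cmd A command object.
#' @return A single string.
#' @export
format_command <- function(cmd) {
  switch(cmd$type,
    move = sprintf("%s%d to %s%d", cmd$start$layer, cmd$start$keypoint,
                   cmd$end$layer, cmd$end$keypoint),
    mix = sprintf("MIX %d %d", cmd$keypoint, cmd$cycles),
    hold = sprintf("HOLD %s%d %g", cmd$position$layer,
                   cmd$position$keypoint, cmd$duration),
    incubate = sprintf("INCUBATE %d %g %d", cmd$keypoint, cmd$duration,
                       cmd$embedded_mix_cycles),
    stop("unknown command type ", cmd$type)
  )
}

#' Construct a protocol
#'
#' @param name Protocol name.
#' @param steps List of command objects (non-empty).
#' @param metadata List; conventionally holds `assay` (target description)
#'   and `manifest`, a data frame of the per-well reagent loading with
#'   columns `well`, `species`, `volume_ul`.
#' @return An object of class `mdm_protocol`.
#' @export
mdm_protocol <- function(name, steps, metadata = list()) {
  if (length(steps) == 0) stop("protocol must have at least one step")
  ok <- vapply(steps, inherits, logical(1), what = "mdm_command")
  if (!all(ok)) stop("steps must all be mdm_command objects")
  structure(list(name = as.character(name), steps = steps,
                 metadata = metadata),
            class = "mdm_protocol")
}

#' @export
print.mdm_protocol <- function(x, ...) {
  cat(sprintf("<mdm_protocol> %s: %d steps\n", x$name, length(x$steps)))
  for (s in x$steps) cat("  ", format_command(s), "\n", sep = "")
  invisible(x)
}

# every keypoint a command touches
command_keypoints <- function(cmd) {
  switch(cmd$type,
    move = c(cmd$start$keypoint, cmd$end$keypoint),
    mix = cmd$keypoint,
    hold = cmd$position$keypoint,
    incubate = cmd$keypoint
  )
}

#' Validate a protocol against a layout
#'
#' Checks that every referenced keypoint exists in the layout's keypoint map
#' and that bottom-layer traversals only run between wells joined by a
#' microchannel (the only stations where a bead cluster can be dragged).
#' Moves that change both layer and keypoint are decomposed as a vertical
#' hop at the start keypoint followed by lateral travel in the end layer.
#' Lateral travel in the top or mezzanine layer is flagged: planar motion is
#' only safe in the neutral layer or, along channels, in the bottom layer.
#'
#' @param protocol An [mdm_protocol()].
#' @param layout A [chip_layout()].
#' @return Character vector of violations; empty if the protocol is valid.
#' @export
validate_protocol <- function(protocol, layout) {
  v <- character(0)
  unit <- layout$units[[1]]   # keypoint maps are identical across units
  kps <- as.integer(names(unit$keypoint_map))
  for (i in seq_along(protocol$steps)) {
    cmd <- protocol$steps[[i]]
    tag <- sprintf("step %d (%s)", i, format_command(cmd))
    for (kp in command_keypoints(cmd)) {
      if (!(kp %in% kps)) {
        v <- c(v, sprintf("%s: keypoint %d not in layout keypoint_map",
                          tag, kp))
      }
    }
    if (cmd$type == "move" && cmd$start$keypoint != cmd$end$keypoint) {
      lat_layer <- cmd$end$layer
      if (lat_layer == "B") {
        a <- unit$keypoint_map[[as.character(cmd$start$keypoint)]]
        b <- unit$keypoint_map[[as.character(cmd$end$keypoint)]]
        if (!is.null(a) && !is.null(b) && is.null(unit_channel(unit, a, b))) {
          v <- c(v, sprintf(
            "%s: bottom-layer traversal between wells %d and %d with no channel",
            tag, a, b))
        }
      } else if (lat_layer %in% c("T", "M")) {
        v <- c(v, sprintf(
          "%s: lateral motion in layer %s is not allowed", tag, lat_layer))
      }
    }
  }
  v
}

#' Built-in bead-based ELISA protocol
#'
#' The stock sandwich-ELISA workflow on the built-in chip, one unit's view
#' (all four magnets move synchronously). Sample and capture beads incubate
#' in well 1 (~15 min, 50 embedded mixing cycles), the cluster is attracted
#' by a 20 s bottom hold and extracted through narrow channels across two
#' washes (wells 2-3, 1 min / 3 cycles each), a second ~15 min / 50 cycle
#' incubation with enzyme-labelled detection antibody in well 4, three more
#' washes (wells 5-7), chromogen development in well 8, extraction to the
#' stop-solution droplet in well 9, and a wide-channel return that carries
#' the stop droplet back to merge in well 8 for reading.
#'
#' @param tmb_volume_ul Chromogen load of well 8 in uL. Default 50.
#' @param develop_s Development incubation in well 8, seconds.
#' @return An [mdm_protocol()] whose metadata carries the reagent manifest.
#' @export
builtin_elisa_protocol <- function(tmb_volume_ul = 50, develop_s = 300) {
  p <- function(l, k) magnet_position(l, k)
  steps <- list()
  add <- function(...) steps[[length(steps) + 1L]] <<- ..1
  transfer <- function(from, to) {
    add(hold_command(p("B", from), 20))          # cluster the beads
    add(move_command(p("B", from), p("B", to)))  # traverse the channel
  }
  add(incubate_command(1, 900, embedded_mix_cycles = 50))
  transfer(1, 2)
  add(incubate_command(2, 60, embedded_mix_cycles = 3))
  transfer(2, 3)
  add(incubate_command(3, 60, embedded_mix_cycles = 3))
  transfer(3, 4)
  add(incubate_command(4, 900, embedded_mix_cycles = 50))
  transfer(4, 5)
  add(incubate_command(5, 60, embedded_mix_cycles = 3))
  transfer(5, 6)
  add(incubate_command(6, 60, embedded_mix_cycles = 3))
  transfer(6, 7)
  add(incubate_command(7, 60, embedded_mix_cycles = 3))
  transfer(7, 8)
  add(incubate_command(8, develop_s, embedded_mix_cycles = 3))
  transfer(8, 9)                                 # beads into stop droplet
  transfer(9, 8)                                 # stop droplet passes back
  manifest <- data.frame(
    well = c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8, 9),
    species = c("sample", "capture_beads", "suspension_g_beads",
                "wash_buffer", "wash_buffer", "detection_antibody",
                "wash_buffer", "wash_buffer", "wash_buffer",
                "tmb_substrate", "stop_solution"),
    volume_ul = c(30, 5, 0.5, 30, 30, 30, 30, 30, 30, tmb_volume_ul, 10),
    stringsAsFactors = FALSE
  )
  mdm_protocol("builtin-elisa", steps,
               metadata = list(assay = "bead-based sandwich ELISA",
                               manifest = manifest))
}

#' Estimate wall-clock duration of a protocol
#'
#' Sums hold and incubation durations, magnet travel time (planar distance
#' between keypoint well centers divided by `speed`; vertical hops are not
#' timed because layer heights are not modelled), and standalone mixing time
#' at `mix_cycle_s` per cycle. Mixing cycles embedded in an incubation do
#' not add time: they happen within the stated incubation window.
#'
#' @param protocol An [mdm_protocol()].
#' @param layout A [chip_layout()].
#' @param speed Travel speed, mm/s.
#' @param mix_cycle_s Seconds per standalone mixing cycle (default 18,
#'   calibrated from 3 cycles taking ~54 s).
#' @return Estimated duration in seconds.
#' @export
estimate_duration <- function(protocol, layout, speed = 1,
                              mix_cycle_s = 18) {
  unit <- layout$units[[1]]
  total <- 0
  for (cmd in protocol$steps) {
    total <- total + switch(cmd$type,
      move = {
        a <- unit$keypoint_map[[as.character(cmd$start$keypoint)]]
        b <- unit$keypoint_map[[as.character(cmd$end$keypoint)]]
        ca <- well_center_global(unit, a)
        cb <- well_center_global(unit, b)
        sqrt(sum((ca - cb)^2)) / speed
      },
      mix = cmd$cycles * mix_cycle_s,
      hold = cmd$duration,
      incubate = cmd$duration
    )
  }
  total
}

#' Read / write protocols
#'
#' Two on-disk forms are supported. The script form is line-oriented DSL
#' text, one command per line, `#` comments and blank lines ignored; it
#' carries no manifest. The JSON form (`.json`) stores name, steps and
#' metadata including the reagent manifest.
#'
#' @param path File path; format chosen by extension (`.json` vs. anything
#'   else = script).
#' @param protocol An [mdm_protocol()].
#' @param name Protocol name to use when reading a script file.
#' @return `read_protocol()` returns an [mdm_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @name protocol_io
NULL

#' @rdname protocol_io
#' @export
read_protocol <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    steps <- lapply(doc$steps, function(s) parse_motion_command(s))
    meta <- doc$metadata
    if (!is.null(meta$manifest)) {
      meta$manifest <- do.call(rbind, lapply(meta$manifest, function(r) {
        data.frame(well = r$well, species = r$species,
                   volume_ul = r$volume_ul, stringsAsFactors = FALSE)
      }))
    }
    mdm_protocol(doc$name, steps, metadata = if (is.null(meta)) list() else meta)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("protocol script '", path, "' has no commands")
    mdm_protocol(name, lapply(lines, parse_motion_command))
  }
}

#' @rdname protocol_io
#' @export
write_protocol <- function(protocol, path) {
  steps_txt <- vapply(protocol$steps, format_command, character(1))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    meta <- protocol$metadata
    if (!is.null(meta$manifest)) {
      m <- meta$manifest
      meta$manifest <- lapply(seq_len(nrow(m)), function(i) {
        list(well = m$well[i], species = m$species[i],
             volume_ul = m$volume_ul[i])
      })
    }
    jsonlite::write_json(
      list(name = protocol$name, steps = steps_txt, metadata = meta),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(c(sprintf("# %s", protocol$name), steps_txt), path)
  }
  invisible(path)
}
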
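# Discrete-event droplet/bead engine.
#
# Executes a motion protocol on a chip layout. Only two droplet operations
# matter for the bead-based ELISA workflow: dragging a droplet through a
# wide channel (merging with any occupant of the target well) and pulling
# the bead cluster alone through a narrow channel (extraction, with
# stochastic bead losses and a fixed liquid carry-over). Volumes and bead
# counts are ledgered in an append-only event log so conservation can be
# audited after any run.

#' Engine parameters
#'
#' @param p_retain Per-extraction bead survival probability. The default
#'   `0.78^(1/8)` is calibrated so the built-in protocol's eight extraction
#'   transfers (wells 1 through 9) retain ~78% of beads overall.
#' @param carryover_ul Liquid volume (uL) dragged along with the bead
#'   cluster at each extraction.
#' @param r_pass Channel-width to droplet-diameter ratio above which the
#'   droplet passes through the channel instead of being held back.
#' @param contact_angle Sessile droplet contact angle on the
#'   superhydrophobic coating, degrees.
#' @param speed Magnet travel speed, mm/s.
#' @param mixing [mixing_params()] used for MIX/INCUBATE steps.
#' @return A list of class `engine_params`.
#' @export
engine_params <- function(p_retain = 0.78^(1 / 8), carryover_ul = 0.5,
                          r_pass = 0.35, contact_angle = 150, speed = 1,
                          mixing = mixing_params()) {
  stopifnot(p_retain > 0, p_retain <= 1, carryover_ul >= 0, r_pass > 0,
            speed > 0)
  structure(list(p_retain = p_retain, carryover_ul = carryover_ul,
                 r_pass = r_pass, contact_angle = contact_angle,
                 speed = speed, mixing = mixing),
            class = "engine_params")
}

#' Footprint diameter of a sessile droplet
#'
#' Maximum planar width of a spherical-cap droplet of the given volume at
#' the given contact angle. For angles above 90 degrees the widest section
#' is the sphere's equator (2R); below, the contact line (2R sin theta).
#' The cap volume is `V = (pi R^3 / 3) (1 - cos t)^2 (2 + cos t)`.
#'
#' @param volume_ul Droplet volume in uL (1 uL = 1 mm^3), >= 0.
#' @param contact_angle Contact angle in degrees, in (0, 180].
#' @return Footprint diameter in mm; monotone increasing in volume.
#' @export
droplet_footprint_diameter <- function(volume_ul, contact_angle = 150) {
  if (!(contact_angle > 0 && contact_angle <= 180)) {
    stop("contact_angle must be in (0, 180]")
  }
  if (any(volume_ul < 0)) stop("volume must be >= 0")
  th <- contact_angle * pi / 180
  ct <- cos(th)
  r3 <- 3 * volume_ul / (pi * (1 - ct)^2 * (2 + ct))
  r <- r3^(1 / 3)
  if (contact_angle >= 90) 2 * r else 2 * r * sin(th)
}

#' Classify a channel transition
#'
#' Decides whether a bead-dragged droplet passes through a microchannel or
#' is held back so that only the bead cluster is extracted. The droplet
#' passes iff `channel_width / droplet_diameter >= r_pass`.
#'
#' @param channel_width Channel width, mm (> 0).
#' @param droplet_diameter Droplet footprint diameter, mm (> 0).
#' @param r_pass Pass threshold ratio (default 0.35).
#' @return `"PASS_DROPLET"` or `"EXTRACT_BEADS"`.
#' @export
classify_channel_transition <- function(channel_width, droplet_diameter,
                                        r_pass = 0.35) {
  if (!(channel_width > 0) || !(droplet_diameter > 0)) {
    stop("channel_width and droplet_diameter must be > 0")
  }
  if (channel_width / droplet_diameter >= r_pass) "PASS_DROPLET"
  else "EXTRACT_BEADS"
}

# -- state ------------------------------------------------------------------

new_droplet <- function(volume_ul, species = numeric(0), homogeneity = 1,
                        od = 0) {
  list(volume_ul = volume_ul, species = species,
       homogeneity = homogeneity, od = od)
}

merge_droplets <- function(a, b) {
  vol <- a$volume_ul + b$volume_ul
  sp_names <- union(names(a$species), names(b$species))
  sp <- stats::setNames(numeric(length(sp_names)), sp_names)
  sp[names(a$species)] <- sp[names(a$species)] + a$species
  sp[names(b$species)] <- sp[names(b$species)] + b$species
  od <- if (vol > 0) {
    (a$od * a$volume_ul + b$od * b$volume_ul) / vol
  } else 0
  # a freshly merged droplet is fully unmixed
  new_droplet(vol, sp, homogeneity = 0, od = od)
}

#' Initialize chip state from a reagent manifest
#'
#' Loads every unit identically from the manifest (rows `well`, `species`,
#' `volume_ul`; several rows for the same well form one pre-mixed droplet)
#' and seeds one bead population per unit.
#'
#' @param layout A [chip_layout()].
#' @param manifest Data frame with columns `well`, `species`, `volume_ul`.
#' @param initial_beads Bead count loaded per unit.
#' @param beads_well Well holding the initial bead population.
#' @param params [engine_params()].
#' @return An object of class `chip_state`.
#' @export
chip_state <- function(layout, manifest, initial_beads = 10000,
                       beads_well = 1, params = engine_params()) {
  units <- lapply(layout$units, function(u) {
    droplets <- list()
    for (w in unique(manifest$well)) {
      rows <- manifest[manifest$well == w, , drop = FALSE]
      droplets[[as.character(w)]] <- new_droplet(
        sum(rows$volume_ul),
        stats::setNames(rows$volume_ul, rows$species),
        homogeneity = 1
      )
    }
    list(droplets = droplets,
         beads = list(count = as.integer(initial_beads),
                      well = as.integer(beads_well), clustered = FALSE))
  })
  structure(list(clock = 0,
                 magnet = magnet_position("N", 1),
                 units = units, params = params),
            class = "chip_state")
}

#' @export
print.chip_state <- function(x, ...) {
  cat(sprintf("<chip_state> t = %.1f s, magnet %s%d, %d unit(s)\n",
              x$clock, x$magnet$layer, x$magnet$keypoint, length(x$units)))
  for (i in seq_along(x$units)) {
    u <- x$units[[i]]
    vols <- vapply(u$droplets, function(d) d$volume_ul, numeric(1))
    cat(sprintf("  unit %d: %d droplet(s), %.1f uL total, %d beads @ well %d\n",
                i, length(u$droplets), sum(vols), u$beads$count,
                u$beads$well))
  }
  invisible(x)
}

#' Total liquid volume on chip
#'
#' @param state A [chip_state()].
#' @return Total droplet volume in uL, summed over units.
#' @export
total_volume <- function(state) {
  sum(vapply(state$units, function(u) {
    sum(vapply(u$droplets, function(d) d$volume_ul, numeric(1)))
  }, numeric(1)))
}

# internal: event accumulator (list in an environment, O(1) append)
event_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- vector("list", 64L)
  env$n <- 0L
  env
}

emit <- function(sink, time, unit, kind, well_from = NA, well_to = NA,
                 volume_ul = NA_real_, beads_moved = NA_integer_,
                 beads_lost = NA_integer_, note = "") {
  if (sink$n == length(sink$events)) {
    length(sink$events) <- 2L * sink$n
  }
  sink$n <- sink$n + 1L
  sink$events[[sink$n]] <- list(
    time = time, unit = unit, kind = kind,
    well_from = well_from, well_to = well_to, volume_ul = volume_ul,
    beads_moved = beads_moved, beads_lost = beads_lost, note = note)
}

sink_to_log <- function(sink) {
  ev <- sink$events[seq_len(sink$n)]
  log <- data.frame(
    time = vapply(ev, `[[`, numeric(1), "time"),
    unit = vapply(ev, `[[`, numeric(1), "unit"),
    kind = vapply(ev, `[[`, character(1), "kind"),
    well_from = vapply(ev, function(e) as.numeric(e$well_from), numeric(1)),
    well_to = vapply(ev, function(e) as.numeric(e$well_to), numeric(1)),
    volume_ul = vapply(ev, `[[`, numeric(1), "volume_ul"),
    beads_moved = vapply(ev, function(e) as.numeric(e$beads_moved),
                         numeric(1)),
    beads_lost = vapply(ev, function(e) as.numeric(e$beads_lost),
                        numeric(1)),
    note = vapply(ev, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
  class(log) <- c("mdm_event_log", "data.frame")
  log
}

# -- step execution ---------------------------------------------------------

#' Apply one protocol step to a chip state
#'
#' Executes a single command on every unit (magnets move synchronously).
#' A bottom-layer traversal first requires a clustered bead population
#' (formed by a bottom hold of at least 1 s at the bead keypoint); the
#' channel's width against the droplet footprint then decides whether the
#' whole droplet passes (merging additively with any occupant) or only the
#' beads transfer, with `Binomial(count, p_retain)` survivors and a fixed
#' liquid carry-over. Neutral-layer motion changes nothing but the magnet
#' position and the clock; MIX and INCUBATE advance droplet homogeneity.
#' Binomial draws consume the current R RNG stream in unit order.
#'
#' @param state A [chip_state()].
#' @param cmd A command object (see [motion_commands]).
#' @param layout The [chip_layout()] being executed.
#' @param sink Internal event accumulator; created when NULL.
#' @return A list with the updated `state` and the event `sink`.
#' @export
apply_step <- function(state, cmd, layout, sink = NULL) {
  if (is.null(sink)) sink <- event_sink()
  params <- state$params
  unit0 <- layout$units[[1]]
  km <- unit0$keypoint_map

  if (cmd$type == "move") {
    a_kp <- cmd$start$keypoint
    b_kp <- cmd$end$keypoint
    if (a_kp != b_kp) {
      ca <- well_center_global(unit0, km[[as.character(a_kp)]])
      cb <- well_center_global(unit0, km[[as.character(b_kp)]])
      state$clock <- state$clock + sqrt(sum((ca - cb)^2)) / params$speed
    }
    if (cmd$end$layer == "B" && a_kp != b_kp) {
      a <- km[[as.character(a_kp)]]
      b <- km[[as.character(b_kp)]]
      ch <- unit_channel(unit0, a, b)
      if (is.null(ch)) {
        stop("illegal transition: no channel between wells ", a, " and ", b)
      }
      for (i in seq_along(state$units)) {
        u <- state$units[[i]]
        if (u$beads$count > 0 && u$beads$well == a) {
          if (!u$beads$clustered) {
            stop("beads in unit ", i, " not clustered before traversal ",
                 a, " -> ", b, " (bottom hold >= 1 s required)")
          }
          src <- u$droplets[[as.character(a)]]
          if (is.null(src)) {
            # dry cluster drag: beads move without liquid
            u$beads$well <- b
            emit(sink, state$clock, i, "drag_beads", a, b, 0,
                 u$beads$count, 0L)
          } else {
            dia <- droplet_footprint_diameter(src$volume_ul,
                                              params$contact_angle)
            outcome <- classify_channel_transition(ch$width_mm, dia,
                                                   params$r_pass)
            if (outcome == "PASS_DROPLET") {
              dst <- u$droplets[[as.character(b)]]
              if (is.null(dst)) {
                moved <- src
                emit(sink, state$clock, i, "move_droplet", a, b,
                     src$volume_ul, u$beads$count, 0L)
              } else {
                moved <- merge_droplets(dst, src)
                emit(sink, state$clock, i, "merge", a, b, src$volume_ul,
                     u$beads$count, 0L)
              }
              u$droplets[[as.character(a)]] <- NULL
              u$droplets[[as.character(b)]] <- moved
              u$beads$well <- b
              cap <- unit_well(unit0, b)$volume_ul
              if (moved$volume_ul > cap) {
                emit(sink, state$clock, i, "overflow_warning", NA, b,
                     moved$volume_ul,
                     note = sprintf("well %d capacity %g uL", b, cap))
              }
            } else {
              survivors <- stats::rbinom(1L, u$beads$count, params$p_retain)
              lost <- u$beads$count - survivors
              carry <- min(params$carryover_ul, src$volume_ul)
              frac <- if (src$volume_ul > 0) carry / src$volume_ul else 0
              carry_dr <- new_droplet(carry, src$species * frac,
                                      homogeneity = src$homogeneity,
                                      od = src$od)
              src$volume_ul <- src$volume_ul - carry
              src$species <- src$species * (1 - frac)
              u$droplets[[as.character(a)]] <- src
              dst <- u$droplets[[as.character(b)]]
              u$droplets[[as.character(b)]] <-
                if (is.null(dst)) carry_dr else merge_droplets(dst, carry_dr)
              u$beads$count <- survivors
              u$beads$well <- b
              emit(sink, state$clock, i, "extract_beads", a, b, carry,
                   survivors, lost)
            }
          }
          state$units[[i]] <- u
        }
      }
    }
    if (cmd$end$layer != "B") {
      # leaving the bottom layer releases any cluster
      for (i in seq_along(state$units)) {
        state$units[[i]]$beads$clustered <- FALSE
      }
    }
    state$magnet <- cmd$end
  } else if (cmd$type == "hold") {
    state$clock <- state$clock + cmd$duration
    state$magnet <- cmd$position
    if (cmd$position$layer == "B" && cmd$duration >= 1) {
      well <- km[[as.character(cmd$position$keypoint)]]
      for (i in seq_along(state$units)) {
        if (state$units[[i]]$beads$count > 0 &&
            state$units[[i]]$beads$well == well) {
          state$units[[i]]$beads$clustered <- TRUE
          emit(sink, state$clock, i, "cluster", well, well)
        }
      }
    }
  } else if (cmd$type == "mix") {
    state$clock <- state$clock + cmd$cycles * params$mixing$cycle_s
    state$magnet <- magnet_position("M", cmd$keypoint)
    well <- km[[as.character(cmd$keypoint)]]
    for (i in seq_along(state$units)) {
      d <- state$units[[i]]$droplets[[as.character(well)]]
      if (!is.null(d)) {
        d$homogeneity <- advance_active(d$homogeneity, cmd$cycles,
                                        params$mixing)
        state$units[[i]]$droplets[[as.character(well)]] <- d
        emit(sink, state$clock, i, "mix", well, well,
             note = sprintf("%d cycles, H = %.4f", cmd$cycles,
                            d$homogeneity))
      }
      state$units[[i]]$beads$clustered <- FALSE
    }
  } else if (cmd$type == "incubate") {
    state$clock <- state$clock + cmd$duration
    state$magnet <- magnet_position("N", cmd$keypoint)
    well <- km[[as.character(cmd$keypoint)]]
    for (i in seq_along(state$units)) {
      d <- state$units[[i]]$droplets[[as.character(well)]]
      if (!is.null(d)) {
        h <- advance_active(d$homogeneity, cmd$embedded_mix_cycles,
                            params$mixing)
        d$homogeneity <- advance_passive(h, cmd$duration, params$mixing)
        state$units[[i]]$droplets[[as.character(well)]] <- d
        emit(sink, state$clock, i, "incubate", well, well,
             note = sprintf("%g s, %d cycles, H = %.4f", cmd$duration,
                            cmd$embedded_mix_cycles, d$homogeneity))
      }
      state$units[[i]]$beads$clustered <- FALSE
    }
  } else {
    stop("unknown command type ", cmd$type)
  }
  list(state = state, sink = sink)
}

#' Run a protocol on a layout
#'
#' Validates the protocol, initializes the chip from the reagent manifest,
#' executes every step and returns the final state plus the complete event
#' log. Deterministic for a given seed: all stochastic draws (bead
#' extraction survivors) come from one seeded generator consumed in step
#' and unit order.
#'
#' @param layout A [chip_layout()].
#' @param protocol An [mdm_protocol()].
#' @param manifest Reagent manifest data frame; defaults to the protocol's
#'   `metadata$manifest`.
#' @param seed Integer RNG seed.
#' @param params [engine_params()].
#' @param initial_beads Beads loaded per unit.
#' @param beads_well Well holding the initial bead population.
#' @return A list of class `mdm_run` with elements `state` ([chip_state()])
#'   and `log` (event data frame).
#' @export
run_protocol <- function(layout, protocol, manifest = NULL, seed = 1,
                         params = engine_params(), initial_beads = 10000,
                         beads_well = 1) {
  bad <- validate_protocol(protocol, layout)
  if (length(bad)) {
    stop("protocol does not validate:\n  ", paste(bad, collapse = "\n  "))
  }
  if (is.null(manifest)) manifest <- protocol$metadata$manifest
  if (is.null(manifest)) stop("no reagent manifest supplied")
  set.seed(seed)
  state <- chip_state(layout, manifest, initial_beads = initial_beads,
                      beads_well = beads_well, params = params)
  sink <- event_sink()
  for (i in seq_along(state$units)) {
    u <- state$units[[i]]
    vols <- sum(vapply(u$droplets, function(d) d$volume_ul, numeric(1)))
    emit(sink, 0, i, "init", NA, NA, vols, u$beads$count, 0L)
  }
  for (si in seq_along(protocol$steps)) {
    res <- tryCatch(
      apply_step(state, protocol$steps[[si]], layout, sink),
      error = function(e) {
        stop("step ", si, " (", format_command(protocol$steps[[si]]),
             "): ", conditionMessage(e), call. = FALSE)
      }
    )
    state <- res$state
    sink <- res$sink
  }
  structure(list(state = state, log = sink_to_log(sink)),
            class = "mdm_run")
}

#' @export
print.mdm_run <- function(x, ...) {
  cat(sprintf("<mdm_run> %d events, final clock %.0f s, retention %.3f\n",
              nrow(x$log), x$state$clock, retention_summary(x$log)))
  invisible(x)
}

#' Bead retention of a completed run
#'
#' Fraction of the initially loaded beads still tracked in the final
#' droplet(s): `(initial - total logged losses) / initial`, summed over
#' units.
#'
#' @param log Event log from [run_protocol()] (or an `mdm_run`).
#' @return Retention fraction in [0, 1].
#' @export
retention_summary <- function(log) {
  if (inherits(log, "mdm_run")) log <- log$log
  init <- sum(log$beads_moved[log$kind == "init"], na.rm = TRUE)
  if (!isTRUE(init > 0)) stop("no initial beads logged; retention undefined")
  lost <- sum(log$beads_lost, na.rm = TRUE)
  (init - lost) / init
}
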
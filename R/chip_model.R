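#' Construct a microwell
#'
#' A microwell is a recessed circular feature that pins a droplet at a known
#' location on the chip. Coordinates are in mm, local to the unit, origin at
#' the unit's lower-left corner, y up.
#'
#' @param id Integer well id, 1-9 within a unit.
#' @param center Numeric length-2, (x, y) center in mm.
#' @param diameter_mm Well diameter in mm (> 0).
#' @param volume_ul Nominal reagent capacity in microlitres (> 0).
#' @param observation_window Logical; TRUE if the cover above this well is
#'   left uncoated so the droplet can be imaged through it.
#' @return An object of class `microwell`.
#' @export
microwell <- function(id, center, diameter_mm, volume_ul,
                      observation_window = FALSE) {
  structure(
    list(id = as.integer(id), center = as.numeric(center),
         diameter_mm = as.numeric(diameter_mm),
         volume_ul = as.numeric(volume_ul),
         observation_window = isTRUE(observation_window)),
    class = "microwell"
  )
}

#' Construct a microchannel
#'
#' Microchannels connect neighbouring microwells. A wide channel lets a
#' droplet pass through (dragged by its bead cluster); a narrow channel holds
#' the droplet back so only the bead cluster is extracted.
#'
#' @param wells Integer length-2, ordered pair of connected well ids.
#' @param width_mm Channel width in mm (> 0).
#' @param depth_mm Channel depth in mm (metadata only).
#' @return An object of class `microchannel`.
#' @export
microchannel <- function(wells, width_mm, depth_mm = 0.5) {
  structure(
    list(wells = as.integer(wells), width_mm = as.numeric(width_mm),
         depth_mm = as.numeric(depth_mm)),
    class = "microchannel"
  )
}

#' Construct a chip unit
#'
#' One self-contained reaction lane: a set of microwells joined by
#' microchannels, plus the keypoint map that ties magnet stations 1-9 to
#' well ids. `origin` places the unit on the chip footprint.
#'
#' @param index Unit index (1-based).
#' @param wells List of [microwell()] objects.
#' @param channels List of [microchannel()] objects.
#' @param keypoint_map Named integer vector mapping keypoint ("1".."9") to a
#'   well id; must be a bijection onto the unit's wells.
#' @param origin Numeric length-2, unit origin (x, y) on the chip in mm.
#' @param size Numeric length-2, unit footprint (width, height) in mm.
#' @return An object of class `chip_unit`.
#' @export
chip_unit <- function(index, wells, channels, keypoint_map,
                      origin = c(0, 0), size = c(15, 60)) {
  if (is.null(names(keypoint_map))) {
    names(keypoint_map) <- as.character(seq_along(keypoint_map))
  }
  structure(
    list(index = as.integer(index), wells = wells, channels = channels,
         keypoint_map = stats::setNames(as.integer(keypoint_map),
                                        names(keypoint_map)),
         origin = as.numeric(origin), size = as.numeric(size)),
    class = "chip_unit"
  )
}

#' Construct a chip layout
#'
#' @param units List of [chip_unit()] objects (>= 1).
#' @param footprint Numeric length-2, chip (width, height) in mm.
#' @param schema_version Layout schema version string.
#' @return An object of class `chip_layout`.
#' @export
chip_layout <- function(units, footprint = c(60, 60),
                        schema_version = "1.0") {
  structure(
    list(schema_version = as.character(schema_version),
         footprint = as.numeric(footprint), units = units),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout v%s> %g x %g mm, %d unit(s)\n",
              x$schema_version, x$footprint[1], x$footprint[2],
              length(x$units)))
  for (u in x$units) {
    cat(sprintf("  unit %d: %d wells, %d channels, origin (%g, %g)\n",
                u$index, length(u$wells), length(u$channels),
                u$origin[1], u$origin[2]))
  }
  invisible(x)
}

# Well lookup helpers (unit-local ids)
unit_well <- function(unit, well_id) {
  for (w in unit$wells) if (w$id == well_id) return(w)
  NULL
}

unit_well_ids <- function(unit) {
  vapply(unit$wells, function(w) w$id, integer(1))
}

# channel between two wells (order-free); NULL if absent
unit_channel <- function(unit, a, b) {
  for (ch in unit$channels) {
    if (all(sort(ch$wells) == sort(c(a, b)))) return(ch)
  }
  NULL
}

# well center in chip (global) coordinates, mm
well_center_global <- function(unit, well_id) {
  w <- unit_well(unit, well_id)
  if (is.null(w)) stop("unknown well id ", well_id, " in unit ", unit$index)
  unit$origin + w$center
}

#' Built-in four-unit ELISA chip layout
#'
#' The stock immunodiagnostic chip: a 60 x 60 mm footprint carrying four
#' identical units run in parallel (sample in triplicate plus a negative
#' control). Each unit holds nine microwells joined in a chain by eight
#' microchannels. Wells 1-7 are 6 mm wide (30 uL), well 8 is 7 mm (50 uL)
#' and serves as the uncoated observation window where the developed droplet
#' is imaged, and well 9 is 4 mm (10 uL) for the stop solution. All
#' channels are narrow (0.6 mm, bead extraction) except the 8-9 link
#' (1.3 mm) which must pass the small stop-solution droplet back to well 8.
#' Keypoint i maps to well i.
#'
#' @return A valid [chip_layout()] with 4 units.
#' @export
builtin_elisa_layout <- function() {
  unit_w <- 15
  n_well <- 9
  pitch <- 60 / n_well              # vertical well pitch, mm
  ys <- (seq_len(n_well) - 0.5) * pitch
  make_unit <- function(i) {
    wells <- lapply(seq_len(n_well), function(k) {
      d <- if (k <= 7) 6 else if (k == 8) 7 else 4
      v <- if (k <= 7) 30 else if (k == 8) 50 else 10
      microwell(k, c(unit_w / 2, ys[k]), d, v, observation_window = (k == 8))
    })
    channels <- lapply(seq_len(n_well - 1), function(k) {
      microchannel(c(k, k + 1), width_mm = if (k == 8) 1.3 else 0.6)
    })
    chip_unit(i, wells, channels,
              keypoint_map = stats::setNames(1:9, as.character(1:9)),
              origin = c((i - 1) * unit_w, 0), size = c(unit_w, 60))
  }
  chip_layout(lapply(1:4, make_unit), footprint = c(60, 60))
}

#' Validate a chip layout
#'
#' Checks every structural invariant of the layout model. Violations are
#' returned as data (character messages naming the offending element), not
#' raised as conditions, so a UI or CLI can report all of them at once.
#'
#' @param layout A [chip_layout()].
#' @return Character vector of violations; empty if the layout is valid.
#' @export
validate_layout <- function(layout) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(layout, "chip_layout")) {
    return("not a chip_layout object")
  }
  if (length(layout$units) < 1) add("layout has no units")
  for (u in layout$units) {
    tag <- sprintf("unit %d", u$index)
    ids <- unit_well_ids(u)
    if (anyDuplicated(ids)) {
      add(sprintf("%s: duplicate well ids", tag))
    }
    for (w in u$wells) {
      if (!(w$diameter_mm > 0)) {
        add(sprintf("%s well %d: diameter must be > 0", tag, w$id))
      }
      if (!(w$volume_ul > 0)) {
        add(sprintf("%s well %d: nominal volume must be > 0", tag, w$id))
      }
    }
    for (ch in u$channels) {
      if (ch$wells[1] == ch$wells[2]) {
        add(sprintf("%s: channel %d-%d is a self-loop", tag,
                    ch$wells[1], ch$wells[2]))
      }
      for (wid in ch$wells) {
        if (!(wid %in% ids)) {
          add(sprintf("%s: channel references unknown well %d", tag, wid))
        }
      }
      if (!(ch$width_mm > 0)) {
        add(sprintf("%s: channel %d-%d width must be > 0", tag,
                    ch$wells[1], ch$wells[2]))
      }
    }
    km <- u$keypoint_map
    if (length(km) != length(ids) || anyDuplicated(km) ||
        !setequal(km, ids)) {
      add(sprintf("%s: keypoint_map not a bijection onto wells", tag))
    }
    # channel graph connectivity (wells reachable from the first)
    if (length(ids) > 1 && length(u$channels) > 0) {
      adj <- lapply(ids, function(i) integer(0))
      names(adj) <- as.character(ids)
      ok_edges <- Filter(function(ch) all(ch$wells %in% ids), u$channels)
      for (ch in ok_edges) {
        a <- as.character(ch$wells[1]); b <- as.character(ch$wells[2])
        adj[[a]] <- c(adj[[a]], ch$wells[2])
        adj[[b]] <- c(adj[[b]], ch$wells[1])
      }
      seen <- ids[1]; frontier <- ids[1]
      while (length(frontier)) {
        nxt <- unique(unlist(adj[as.character(frontier)]))
        frontier <- setdiff(nxt, seen)
        seen <- c(seen, frontier)
      }
      if (!setequal(seen, ids)) {
        add(sprintf("%s: channel graph is not connected", tag))
      }
    } else if (length(ids) > 1 && length(u$channels) == 0) {
      add(sprintf("%s: channel graph is not connected", tag))
    }
  }
  # pairwise disjoint unit footprints
  n <- length(layout$units)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- layout$units[[i]]; b <- layout$units[[j]]
      overlap <- a$origin[1] < b$origin[1] + b$size[1] &&
        b$origin[1] < a$origin[1] + a$size[1] &&
        a$origin[2] < b$origin[2] + b$size[2] &&
        b$origin[2] < a$origin[2] + a$size[2]
      if (overlap) {
        add(sprintf("units %d and %d: footprints overlap",
                    a$index, b$index))
      }
    }
  }
  v
}

#' Write a chip layout to JSON
#'
#' @param layout A [chip_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_layout()]
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    schema_version = layout$schema_version,
    footprint = layout$footprint,
    units = lapply(layout$units, function(u) {
      list(
        index = u$index,
        origin = u$origin,
        size = u$size,
        wells = lapply(u$wells, function(w) {
          list(id = w$id, center = w$center, diameter_mm = w$diameter_mm,
               volume_ul = w$volume_ul,
               observation_window = w$observation_window)
        }),
        channels = lapply(u$channels, function(ch) {
          list(wells = ch$wells, width_mm = ch$width_mm,
               depth_mm = ch$depth_mm)
        }),
        keypoint_map = as.list(stats::setNames(u$keypoint_map,
                                               names(u$keypoint_map)))
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a chip layout from JSON
#'
#' The inverse of [write_layout()]; `read_layout(write_layout(x))`
#' reconstructs `x` exactly (integers bit-exact, coordinates to 1e-9 mm).
#' The document is validated after parsing; structural violations are
#' raised as an error listing every problem found.
#'
#' @param path Path to a layout JSON file.
#' @return A validated [chip_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse layout file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$schema_version)) {
    stop("layout file '", path, "' has no schema_version")
  }
  if (!identical(as.character(doc$schema_version), "1.0")) {
    stop("unsupported layout schema_version: ", doc$schema_version)
  }
  units <- lapply(doc$units, function(u) {
    wells <- lapply(u$wells, function(w) {
      microwell(w$id, unlist(w$center), w$diameter_mm, w$volume_ul,
                isTRUE(w$observation_window))
    })
    channels <- lapply(u$channels, function(ch) {
      microchannel(unlist(ch$wells), ch$width_mm,
                   if (is.null(ch$depth_mm)) 0.5 else ch$depth_mm)
    })
    km <- unlist(u$keypoint_map)
    chip_unit(u$index, wells, channels, km,
              origin = unlist(u$origin), size = unlist(u$size))
  })
  layout <- chip_layout(units, footprint = unlist(doc$footprint),
                        schema_version = doc$schema_version)
  bad <- validate_layout(layout)
  if (length(bad)) {
    stop("invalid layout in '", path, "':\n  ",
         paste(bad, collapse = "\n  "))
  }
  layout
}
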
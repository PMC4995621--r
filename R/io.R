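# fixed 6-significant-digit formatting for deterministic exports
fmt_num <- function(x) sprintf("%.6g", x)

#' Read a configuration file
#'
#' A configuration is a JSON document with two optional top-level blocks:
#' `params` (overrides of [sim_params()] by their model names) and
#' `scenario` (a `preset` name plus overrides of the [scenario()] fields).
#' Unknown keys raise an error listing the valid ones; the assembled
#' parameter set is validated against the parameter invariants (for
#' example `HypoxiaLevel < AnoxiaLevel`).
#'
#' @param path JSON file path.
#' @return A list with `params` (a `tumor_params`) and `scenario`
#'   (a `tumor_scenario`).
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(doc), c("params", "scenario"))
  if (length(bad)) {
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         "; valid blocks are: params, scenario", call. = FALSE)
  }
  params <- sim_params(as.list(doc$params))
  scen_args <- as.list(doc$scenario)
  preset <- scen_args$preset
  scen_args$preset <- NULL
  valid <- setdiff(names(formals(scenario)), "params")
  bad <- setdiff(names(scen_args), valid)
  if (length(bad)) {
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: preset, ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(preset)) {
    scen <- do.call(scenario_preset, c(list(preset = preset), scen_args))
    if (!is.null(doc$params)) {
      scen$params <- sim_params(utils::modifyList(
        lapply(unclass(scen$params), identity), as.list(doc$params)))
    }
  } else {
    scen <- do.call(scenario, c(list(params = params), scen_args))
  }
  list(params = scen$params, scenario = scen)
}

#' Write a configuration file
#'
#' Inverse of [read_config()]: writes the parameter set and the scenario
#' fields as a JSON document that reads back to a semantically identical
#' configuration.
#'
#' @param config a list with `params` and `scenario` (as from
#'   [read_config()]), or a `tumor_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "tumor_scenario")) {
    config <- list(params = config$params, scenario = config)
  }
  scen <- config$scenario
  doc <- list(
    params = unclass(config$params),
    scenario = list(name = scen$name, dims = scen$dims,
                    vessel_mode = scen$vessel_mode,
                    n_vessels = scen$n_vessels,
                    n_fibroblasts = scen$n_fibroblasts,
                    fibroblast_shell = scen$fibroblast_shell,
                    angiogenesis = scen$angiogenesis,
                    proliferative = scen$proliferative, tumor = scen$tumor,
                    horizon = scen$horizon, seed = scen$seed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

snapshot_cells_df <- function(snapshot) {
  df <- snapshot$cells
  df$vessel[is.na(df$vessel)] <- -1L
  df
}

#' Write a spatial snapshot
#'
#' Serializes a snapshot either as JSON lines (one object per entity, plus
#' one `meta`, one `field` object per species and one `vessel` object per
#' vessel) or as an XML element stream with the same content model
#' (`<cell>` elements with `id`/`kind`/`state`/`x`/`y`/`z` attributes), the
#' dialect of viewer front-ends this family of models feeds.  Coordinates
#' are 0-based; floats are written with 6 significant digits; key order is
#' fixed, so writes are byte-stable for a given state.
#'
#' @param snapshot a [sim_snapshot()] (or a `tumor_run`, whose final
#'   snapshot is taken).
#' @param path output file.
#' @param format `"json"` or `"xml"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path, format = c("json", "xml")) {
  if (inherits(snapshot, "tumor_run")) snapshot <- snapshot$snapshot
  stopifnot(inherits(snapshot, "tumor_snapshot"))
  format <- match.arg(format)
  cells <- snapshot_cells_df(snapshot)
  vess <- snapshot$vessels
  if (format == "json") {
    con <- file(path, "w")
    on.exit(close(con))
    line <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                    digits = NA), con)
    line(list(type = "meta", tick = snapshot$tick,
              dims = I(snapshot$dims)))
    if (nrow(cells)) {
      for (i in seq_len(nrow(cells))) {
        line(list(type = "cell", id = cells$id[i], kind = cells$kind[i],
                  state = cells$state[i], x = cells$x[i], y = cells$y[i],
                  z = cells$z[i], vessel = cells$vessel[i]))
      }
    }
    for (sp in c("oxygen", "vegf", "fgf", "hgf", "ecm")) {
      line(list(type = "field", species = sp,
                amounts = as.numeric(fmt_num(as.vector(snapshot$fields[[sp]])))))
    }
    for (v in seq_along(vess$members)) {
      line(list(type = "vessel", id = v - 1L,
                parent = ifelse(is.na(vess$parent[v]), -1L, vess$parent[v]),
                members = I(as.integer(vess$members[[v]]))))
    }
  } else {
    root <- xml2::xml_new_root("snapshot",
                               tick = as.character(snapshot$tick),
                               dims = paste(snapshot$dims, collapse = " "))
    if (nrow(cells)) {
      for (i in seq_len(nrow(cells))) {
        xml2::xml_add_child(root, "cell", id = as.character(cells$id[i]),
                            kind = cells$kind[i], state = cells$state[i],
                            x = as.character(cells$x[i]),
                            y = as.character(cells$y[i]),
                            z = as.character(cells$z[i]),
                            vessel = as.character(cells$vessel[i]))
      }
    }
    for (sp in c("oxygen", "vegf", "fgf", "hgf", "ecm")) {
      xml2::xml_add_child(root, "field", species = sp,
                          paste(fmt_num(as.vector(snapshot$fields[[sp]])),
                                collapse = " "))
    }
    for (v in seq_along(vess$members)) {
      xml2::xml_add_child(root, "vessel", id = as.character(v - 1L),
                          parent = as.character(
                            ifelse(is.na(vess$parent[v]), -1L,
                                   vess$parent[v])),
                          paste(as.integer(vess$members[[v]]),
                                collapse = " "))
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Read a snapshot written by [write_snapshot()]
#'
#' Both dialects parse to the same canonical structure, so a JSON and an
#' XML write of one state read back equal.
#'
#' @param path snapshot file.
#' @param format `"json"` or `"xml"`; inferred from the first byte when
#'   missing.
#' @return A list with `tick`, `dims`, `cells` (data frame), `fields`
#'   (named list of 3D arrays) and `vessels` (`members`, `parent`).
#' @export
read_snapshot <- function(path, format = NULL) {
  if (is.null(format)) {
    first <- readChar(path, 1L)
    format <- if (identical(first, "<")) "xml" else "json"
  }
  if (format == "json") {
    lines <- readLines(path)
    objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    meta <- objs[[which(vapply(objs, `[[`, "", "type") == "meta")[1]]]
    dims <- as.integer(meta$dims)
    is_cell <- vapply(objs, `[[`, "", "type") == "cell"
    cells <- if (any(is_cell)) {
      do.call(rbind, lapply(objs[is_cell], function(o) {
        data.frame(id = o$id, kind = o$kind, state = o$state, x = o$x,
                   y = o$y, z = o$z, vessel = o$vessel)
      }))
    } else {
      data.frame(id = integer(0), kind = character(0), state = character(0),
                 x = integer(0), y = integer(0), z = integer(0),
                 vessel = integer(0))
    }
    fields <- list()
    for (o in objs[vapply(objs, `[[`, "", "type") == "field"]) {
      fields[[o$species]] <- array(as.numeric(o$amounts), dim = dims)
    }
    vs <- objs[vapply(objs, `[[`, "", "type") == "vessel"]
    vessels <- list(
      members = lapply(vs, function(o) as.integer(o$members)),
      parent = vapply(vs, function(o) as.integer(o$parent), integer(1)))
  } else {
    root <- xml2::read_xml(path)
    dims <- as.integer(strsplit(xml2::xml_attr(root, "dims"), " ")[[1]])
    meta <- list(tick = as.integer(xml2::xml_attr(root, "tick")))
    cn <- xml2::xml_find_all(root, "cell")
    cells <- if (length(cn)) {
      data.frame(
        id = as.integer(xml2::xml_attr(cn, "id")),
        kind = xml2::xml_attr(cn, "kind"),
        state = xml2::xml_attr(cn, "state"),
        x = as.integer(xml2::xml_attr(cn, "x")),
        y = as.integer(xml2::xml_attr(cn, "y")),
        z = as.integer(xml2::xml_attr(cn, "z")),
        vessel = as.integer(xml2::xml_attr(cn, "vessel")))
    } else {
      data.frame(id = integer(0), kind = character(0), state = character(0),
                 x = integer(0), y = integer(0), z = integer(0),
                 vessel = integer(0))
    }
    fields <- list()
    for (fn in xml2::xml_find_all(root, "field")) {
      fields[[xml2::xml_attr(fn, "species")]] <-
        array(as.numeric(strsplit(xml2::xml_text(fn), " ")[[1]]), dim = dims)
    }
    vn <- xml2::xml_find_all(root, "vessel")
    vessels <- list(
      members = lapply(vn, function(v) {
        txt <- xml2::xml_text(v)
        if (nchar(txt)) as.integer(strsplit(txt, " ")[[1]]) else integer(0)
      }),
      parent = as.integer(xml2::xml_attr(vn, "parent")))
  }
  list(tick = as.integer(meta$tick), dims = dims, cells = cells,
       fields = fields, vessels = vessels)
}

#' Write / read the per-tick time series as CSV
#'
#' One row per tick with a fixed header naming every column of
#' [sim_timeseries()].
#'
#' @param ts a time-series data frame (or a `tumor_run`).
#' @param path CSV path.
#' @return `path` invisibly; `read_timeseries()` returns the data frame.
#' @export
write_timeseries <- function(ts, path) {
  if (inherits(ts, "tumor_run")) ts <- ts$timeseries
  utils::write.csv(ts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the event log as CSV
#'
#' @param events an event-log data frame (or a `tumor_run`).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "tumor_run")) events <- events$events
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
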
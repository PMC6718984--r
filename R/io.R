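#' Write a scratch field to coordinate CSV files
#'
#' Writes two CSVs in the exchange format consumed by [read_scratch_field()]:
#' a cells file (`field_id`, `object_type`, `id`, `x_um`, `y_um`) and a rim
#' file (`field_id`, `vertex_order`, `x_um`, `y_um`, `wound_side`), where the
#' row flagged `wound_side = 1` carries the wound-side reference point rather
#' than a rim vertex.
#'
#' @param field A `scratch_field`.
#' @param cells_path,rim_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_scratch_field <- function(field, cells_path, rim_path) {
  cells <- rbind(
    data.frame(field_id = field$field_id, object_type = "nucleus",
               id = field$nuclei$id, x_um = field$nuclei$x_um, y_um = field$nuclei$y_um),
    data.frame(field_id = field$field_id, object_type = "golgi",
               id = field$golgi$id, x_um = field$golgi$x_um, y_um = field$golgi$y_um)
  )
  utils::write.csv(cells, cells_path, row.names = FALSE)
  rim <- data.frame(field_id = field$field_id,
                    vertex_order = seq_len(nrow(field$rim)),
                    x_um = field$rim[, 1], y_um = field$rim[, 2], wound_side = 0L)
  rim <- rbind(rim, data.frame(field_id = field$field_id, vertex_order = NA,
                               x_um = field$wound_side_point[1],
                               y_um = field$wound_side_point[2], wound_side = 1L))
  utils::write.csv(rim, rim_path, row.names = FALSE)
  invisible(c(cells_path, rim_path))
}

#' Read a scratch field from coordinate CSV files
#'
#' @param cells_path,rim_path Paths written by [write_scratch_field()] or in
#'   the same column layout.
#' @param field_id Field to read when a file holds several (default: first).
#' @return A `scratch_field` list usable by [polarity_analysis()].
#' @export
read_scratch_field <- function(cells_path, rim_path, field_id = NULL) {
  cells <- utils::read.csv(cells_path)
  rim <- utils::read.csv(rim_path)
  if (is.null(field_id)) field_id <- cells$field_id[1]
  cells <- cells[cells$field_id == field_id, ]
  rim <- rim[rim$field_id == field_id, ]
  wsp <- rim[rim$wound_side == 1, ]
  if (nrow(wsp) != 1) stop("rim file must flag exactly one wound_side row per field")
  verts <- rim[rim$wound_side == 0, ]
  verts <- verts[order(verts$vertex_order), ]
  structure(list(
    nuclei = cells[cells$object_type == "nucleus", c("id", "x_um", "y_um")],
    golgi = cells[cells$object_type == "golgi", c("id", "x_um", "y_um")],
    rim = as.matrix(verts[, c("x_um", "y_um")]),
    wound_side_point = c(wsp$x_um, wsp$y_um),
    pixel_size = 1, field_id = field_id
  ), class = "scratch_field")
}

#' Write brain-section point patterns to CSV
#'
#' @param sections List of `section_pattern` objects.
#' @param cells_path,polygons_path Output paths. Cells: `section_id`,
#'   `tumor_id`, `day`, `cell_id`, `x_um`, `y_um`, `population`. Polygons:
#'   `section_id`, `role` (`rim` or `needle`), `vertex_order`, `x_um`, `y_um`.
#' @return Invisibly, the two paths.
#' @export
write_sections <- function(sections, cells_path, polygons_path) {
  if (inherits(sections, "section_pattern")) sections <- list(sections)
  cells <- do.call(rbind, lapply(sections, function(s) {
    data.frame(section_id = s$section_id, tumor_id = s$tumor_id,
               day = s$day_post_injection, cell_id = s$cells$cell_id,
               x_um = s$cells$x_um, y_um = s$cells$y_um,
               population = s$cells$population)
  }))
  polys <- do.call(rbind, lapply(sections, function(s) {
    p <- data.frame(section_id = s$section_id, role = "rim",
                    vertex_order = seq_len(nrow(s$rim_polygon)),
                    x_um = s$rim_polygon[, 1], y_um = s$rim_polygon[, 2])
    if (!identical(s$exclusion_region, s$rim_polygon)) {
      p <- rbind(p, data.frame(section_id = s$section_id, role = "needle",
                               vertex_order = seq_len(nrow(s$exclusion_region)),
                               x_um = s$exclusion_region[, 1],
                               y_um = s$exclusion_region[, 2]))
    }
    p
  }))
  utils::write.csv(cells, cells_path, row.names = FALSE)
  utils::write.csv(polys, polygons_path, row.names = FALSE)
  invisible(c(cells_path, polygons_path))
}

#' Read brain-section point patterns from CSV
#'
#' @param cells_path,polygons_path Paths in the [write_sections()] layout.
#' @return List of `section_pattern` objects, one per section id.
#' @export
read_sections <- function(cells_path, polygons_path) {
  cells <- utils::read.csv(cells_path)
  polys <- utils::read.csv(polygons_path)
  lapply(split(cells, cells$section_id), function(cc) {
    pp <- polys[polys$section_id == cc$section_id[1], ]
    rim <- pp[pp$role == "rim", ]
    rim <- as.matrix(rim[order(rim$vertex_order), c("x_um", "y_um")])
    needle <- pp[pp$role == "needle", ]
    excl <- if (nrow(needle) > 0) {
      as.matrix(needle[order(needle$vertex_order), c("x_um", "y_um")])
    } else rim
    structure(list(section_id = cc$section_id[1], cells = cc,
                   rim_polygon = rim, exclusion_region = excl,
                   day_post_injection = cc$day[1], tumor_id = cc$tumor_id[1]),
              class = "section_pattern")
  })
}

#' Write a reproducibility manifest for an analysis run
#'
#' Records the command, the configuration, MD5 digests of the input files,
#' seeds, the package version and a timestamp as JSON, so a run can be
#' reproduced and audited.
#'
#' @param path Output JSON path.
#' @param command Subcommand or function name that was run.
#' @param config Named list of parameters.
#' @param inputs Character vector of input file paths (digested if present).
#' @param seed Seed(s) used.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, command, config = list(),
                               inputs = character(), seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command, config = config, input_md5 = digests, seed = seed,
    package = "cimquant",
    version = as.character(utils::packageVersion("cimquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Derive a stable per-stage sub-seed from a top-level seed
#'
#' Lets one user-facing seed fan out to independent, reproducible seeds per
#' pipeline stage so stages can be re-run in isolation.
#'
#' @param seed Top-level integer seed.
#' @param stage Stage name.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}
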
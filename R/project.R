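#' JSON-backed project manifest
#'
#' A project is a single directory holding every imported and derived stack
#' (no subfolders) plus a `mesoconn_project.json` manifest recording the
#' pixel width, the bregma origin, and for each file its source stack and
#' the ordered list of manipulations it has gone through. Because every
#' path in the manifest is relative, the whole folder can be copied to
#' another machine and reopened with all state intact.
#'
#' Projects are plain R values: functions that change a project return the
#' updated object (and rewrite the manifest atomically); reassign the
#' result.
#'
#' @param dir project directory; created if missing.
#' @return A `mesoconn_project` object.
#' @export
create_project <- function(dir) {
  if (file.exists(dir) && !dir.exists(dir))
    stop("create_project: ", dir, " exists and is not a directory")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("create_project: cannot create ", dir)
  proj <- structure(list(dir = normalizePath(dir),
                         manifest = list(version = 1L, um_per_px = NULL,
                                         origin = NULL, files = list())),
                    class = "mesoconn_project")
  .save_manifest(proj)
  proj
}

.manifest_path <- function(dir) file.path(dir, "mesoconn_project.json")

# write-temp-then-rename so a crash mid-step cannot corrupt the manifest
.save_manifest <- function(proj) {
  path <- .manifest_path(proj$dir)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(proj$manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!file.rename(tmp, path))
    stop("cannot write manifest at ", path)
  invisible(proj)
}

#' @rdname create_project
#' @export
open_project <- function(dir) {
  path <- .manifest_path(dir)
  if (!file.exists(path))
    stop("open_project: no manifest in ", dir)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  man$origin <- if (is.null(man$origin)) NULL else as.numeric(man$origin)
  structure(list(dir = normalizePath(dir), manifest = man),
            class = "mesoconn_project")
}

#' @export
print.mesoconn_project <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<mesoconn_project> %s\n  %d file(s); um_per_px=%s; origin=%s\n",
              x$dir, length(m$files),
              if (is.null(m$um_per_px)) "unset" else format(m$um_per_px),
              if (is.null(m$origin)) "unset" else
                paste(format(m$origin), collapse = ", ")))
  for (f in m$files)
    cat(sprintf("  - %s [%s]\n", f$name,
                paste(vapply(f$manipulations, `[[`, "", "name"),
                      collapse = " -> ")))
  invisible(x)
}

#' @rdname create_project
#' @param proj a `mesoconn_project`.
#' @param um_per_px microns per pixel (> 0).
#' @export
set_project_scale <- function(proj, um_per_px) {
  if (um_per_px <= 0) stop("set_project_scale: um_per_px must be > 0")
  proj$manifest$um_per_px <- um_per_px
  .save_manifest(proj)
  proj
}

#' @rdname create_project
#' @param origin length-2 `(x_px, y_px)` bregma position (see
#'   [set_origin()] for averaging clicks).
#' @param file optional file name: set a per-stack origin instead of the
#'   global one.
#' @export
set_project_origin <- function(proj, origin, file = NULL) {
  origin <- as.numeric(origin)
  if (length(origin) != 2L) stop("set_project_origin: origin must be (x, y)")
  if (is.null(file)) {
    proj$manifest$origin <- origin
  } else {
    i <- .file_index(proj, file)
    proj$manifest$files[[i]]$origin <- origin
  }
  .save_manifest(proj)
  proj
}

#' Coordinate system of a project
#'
#' The global origin wins unless a per-stack origin is explicitly requested
#' via `file`.
#'
#' @param proj a `mesoconn_project`.
#' @param file optional file name whose per-stack origin to use.
#' @return A [coordinate_system()].
#' @export
project_cs <- function(proj, file = NULL) {
  origin <- proj$manifest$origin
  if (!is.null(file)) {
    rec <- proj$manifest$files[[.file_index(proj, file)]]
    if (!is.null(rec$origin)) origin <- as.numeric(rec$origin)
  }
  if (is.null(origin) || is.null(proj$manifest$um_per_px))
    stop("project_cs: project origin / um_per_px not set")
  coordinate_system(origin, proj$manifest$um_per_px)
}

.file_index <- function(proj, name) {
  names <- vapply(proj$manifest$files, `[[`, "", "name")
  i <- match(name, names)
  if (is.na(i)) stop("no file named '", name, "' in project")
  i
}

#' @rdname create_project
#' @export
project_files <- function(proj)
  vapply(proj$manifest$files, `[[`, "", "name")

#' Load a project file as an image stack
#'
#' @param proj a `mesoconn_project`.
#' @param name file name in the manifest.
#' @return An [image_stack()].
#' @export
project_stack <- function(proj, name) {
  rec <- proj$manifest$files[[.file_index(proj, name)]]
  load_stack(file.path(proj$dir, rec$path))
}

.append_record <- function(proj, rec) {
  proj$manifest$files[[length(proj$manifest$files) + 1L]] <- rec
  .save_manifest(proj)
  proj
}

#' Import a RAW or TIFF recording into a project
#'
#' The selected channel is converted to the native NPY representation
#' inside the project directory and registered in the manifest with an
#' `import` manipulation.
#'
#' @param proj a `mesoconn_project`.
#' @param path source file.
#' @param spec a [raw_spec()] (RAW only).
#' @param fps frame rate in Hz.
#' @param channel_index 0-based channel (TIFF only; `NULL` for grayscale).
#' @param name manifest name; defaults to the file name without extension.
#' @return The updated project.
#' @export
import_raw <- function(proj, path, spec, fps, name = NULL) {
  stack <- read_raw_stack(path, spec, fps)
  .import_stack(proj, stack, path, name,
                params = list(source = basename(path), format = "raw",
                              dtype = spec$dtype,
                              channel = spec$channel_index))
}

#' @rdname import_raw
#' @export
import_tiff <- function(proj, path, fps, channel_index = NULL, name = NULL) {
  stack <- read_tiff_stack(path, channel_index, fps)
  .import_stack(proj, stack, path, name,
                params = list(source = basename(path), format = "tiff",
                              channel = channel_index))
}

.import_stack <- function(proj, stack, path, name, params) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (name %in% project_files(proj))
    stop("import: a file named '", name, "' already exists in the project")
  out <- paste0(name, ".npy")
  persist_stack(stack, file.path(proj$dir, out))
  rec <- list(path = out, name = name, source_stack = basename(path),
              type = "import",
              manipulations = list(list(name = "import", params = params)))
  .append_record(proj, rec)
}

#' Record a derived file in the manifest
#'
#' Appends a record whose manipulation history extends the source's by
#' exactly the one step that produced it; the manifest is rewritten
#' atomically.
#'
#' @param proj a `mesoconn_project`.
#' @param in_name name of the registered input file.
#' @param step `list(name = , params = list(...))`.
#' @param out_path path of the produced file (inside the project dir).
#' @return The updated project.
#' @export
record_step <- function(proj, in_name, step, out_path) {
  i <- .file_index(proj, in_name)
  src <- proj$manifest$files[[i]]
  name <- tools::file_path_sans_ext(basename(out_path))
  rec <- list(path = basename(out_path), name = name,
              source_stack = in_name, type = step$name,
              manipulations = c(src$manipulations,
                                list(list(name = step$name,
                                          params = step$params))))
  .append_record(proj, rec)
}

#' Filter manifest records by manipulation
#'
#' @param proj a `mesoconn_project`.
#' @param manipulation step name to look for in each file's history.
#' @return List of file records, in insertion order (possibly empty).
#' @export
filter_files <- function(proj, manipulation) {
  Filter(function(f)
    manipulation %in% vapply(f$manipulations, `[[`, "", "name"),
    proj$manifest$files)
}

# --- step registry -----------------------------------------------------

.step_registry <- new.env(parent = emptyenv())

#' Register a named pipeline step
#'
#' Per-file steps map one stack to one stack; steps flagged `reduce`
#' (concatenation, evoked averaging) consume the whole current file set
#' and emit a single stack. New steps register without modifying the
#' runner.
#'
#' @param name step name used in pipeline configurations.
#' @param fn `function(stack, params, ctx)` (or `function(stacks, params,
#'   ctx)` for reduce steps) returning an [image_stack()]; `ctx` carries
#'   `project` and a per-run cache environment.
#' @param reduce whether the step combines all current files into one.
#' @return `name`, invisibly.
#' @export
register_step <- function(name, fn, reduce = FALSE) {
  assign(name, list(fn = fn, reduce = reduce), envir = .step_registry)
  invisible(name)
}

#' @rdname register_step
#' @export
registered_steps <- function() sort(ls(.step_registry))

.get_step <- function(name) {
  if (!exists(name, envir = .step_registry, inherits = FALSE))
    stop("unknown pipeline step '", name, "' (registered: ",
         paste(registered_steps(), collapse = ", "), ")")
  get(name, envir = .step_registry, inherits = FALSE)
}

.pget <- function(params, key, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) default else v
}

# reference frame for the align step, cached per run
.align_reference <- function(params, ctx) {
  key <- paste0("ref:", .pget(params, "reference_stack"),
                ":", .pget(params, "sharpen_kernel", 8),
                ":", .pget(params, "ref_start", 0),
                ":", .pget(params, "ref_end", 1))
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  rs_name <- .pget(params, "reference_stack")
  if (is.null(rs_name)) stop("align: params$reference_stack is required")
  rs <- project_stack(ctx$project, rs_name)
  rs <- unsharp_filter(rs, .pget(params, "sharpen_kernel", 8))
  ref <- build_reference(rs, .pget(params, "ref_start", 0),
                         .pget(params, "ref_end", n_frames(rs)))
  ctx$cache[[key]] <- ref
  ref
}

.as_polygons <- function(p)
  lapply(p, function(v) {
    if (is.matrix(v)) v else do.call(rbind, lapply(v, as.numeric))
  })

.register_builtin_steps <- function() {
  register_step("trim", function(stack, params, ctx)
    trim_frames(stack, .pget(params, "n_front", 0L),
                .pget(params, "n_back", 0L)))
  register_step("unsharp", function(stack, params, ctx)
    unsharp_filter(stack, .pget(params, "kernel_size", 8)))
  register_step("align", function(stack, params, ctx) {
    ref <- .align_reference(params, ctx)
    align_stack(stack, ref, .pget(params, "frame_index", 0L))$stack
  })
  register_step("crop", function(stack, params, ctx)
    polygon_mask(stack, .as_polygons(.pget(params, "polygons", list()))))
  # keep_baseline defaults TRUE in the pipeline so bandpass -> dff stays
  # well-posed (dff divides by the temporal mean, which a pure bandpass
  # would zero out)
  register_step("bandpass", function(stack, params, ctx)
    cheby_bandpass(stack, .pget(params, "low", 0.3),
                   .pget(params, "high", 3.0),
                   .pget(params, "order", 4L),
                   .pget(params, "ripple", 0.1),
                   .pget(params, "keep_baseline", TRUE)))
  register_step("dff", function(stack, params, ctx) dff(stack))
  register_step("gsr", function(stack, params, ctx) gsr(stack))
  register_step("divide", function(stack, params, ctx) {
    den_name <- .pget(params, "denominator")
    if (is.null(den_name)) stop("divide: params$denominator is required")
    divide_stacks(stack, project_stack(ctx$project, den_name))
  })
  register_step("shift-origin", function(stack, params, ctx)
    shift_to_common_origin(stack, as.numeric(.pget(params, "own_origin")),
                           as.numeric(.pget(params, "target_origin"))))
  register_step("stdev-map", function(stack, params, ctx)
    image_stack(stdev_map(stack), stack$fps))
  register_step("concat", function(stacks, params, ctx)
    concat_stacks(stacks), reduce = TRUE)
  register_step("evoked-avg", function(stacks, params, ctx)
    evoked_average(stacks, .pget(params, "truncate_to_shortest", FALSE)),
    reduce = TRUE)
}

#' Run an ordered pipeline over project files
#'
#' Every input is pushed through every step in order; each step's output is
#' persisted as NPY in the project directory and recorded in the manifest
#' with the extended manipulation history. Reduce steps (concatenation,
#' evoked averaging) fan the whole current file set into one output. The
#' first failing step aborts with the step name, input name, and cause;
#' outputs of earlier steps remain on disk. Running the same configuration
#' on the same inputs twice is bit-identical.
#'
#' @param proj a `mesoconn_project`.
#' @param config list of steps, each `list(name = , params = list(...))`
#'   (see [read_pipeline_config()]).
#' @param inputs character vector of registered file names.
#' @return `list(project = updated project, outputs = records of the final
#'   step's outputs)`.
#' @export
run_pipeline <- function(proj, config, inputs) {
  for (nm in inputs) .file_index(proj, nm)               # validate early
  for (st in config) .get_step(st$name)
  current <- inputs
  ctx <- list(project = proj, cache = new.env(parent = emptyenv()))
  for (st in config) {
    entry <- .get_step(st$name)
    params <- if (is.null(st$params)) list() else st$params
    t0 <- proc.time()[["elapsed"]]
    if (entry$reduce) {
      stacks <- lapply(current, function(nm) project_stack(proj, nm))
      out <- tryCatch(entry$fn(stacks, params, ctx), error = function(e)
        stop(sprintf("pipeline step '%s' failed on [%s]: %s", st$name,
                     paste(current, collapse = ", "), conditionMessage(e)),
             call. = FALSE))
      out_name <- paste0(st$name, "_of_", length(current))
      out_path <- file.path(proj$dir, paste0(out_name, ".npy"))
      persist_stack(out, out_path)
      proj <- record_step(proj, current[[1L]],
                          list(name = st$name,
                               params = c(params,
                                          list(n_inputs = length(current)))),
                          out_path)
      current <- out_name
    } else {
      nxt <- character(0)
      for (nm in current) {
        stack <- project_stack(proj, nm)
        out <- tryCatch(entry$fn(stack, params, ctx), error = function(e)
          stop(sprintf("pipeline step '%s' failed on '%s': %s", st$name, nm,
                       conditionMessage(e)), call. = FALSE))
        out_name <- paste0(nm, "_", gsub("-", "_", st$name))
        out_path <- file.path(proj$dir, paste0(out_name, ".npy"))
        persist_stack(out, out_path)
        proj <- record_step(proj, nm, list(name = st$name, params = params),
                            out_path)
        nxt <- c(nxt, out_name)
      }
      current <- nxt
    }
    ctx$project <- proj
    message(sprintf("[%s] %d file(s) in %.2f s", st$name, length(current),
                    proc.time()[["elapsed"]] - t0))
  }
  recs <- proj$manifest$files
  names(recs) <- vapply(recs, `[[`, "", "name")
  list(project = proj, outputs = recs[current])
}

#' Read a pipeline configuration file
#'
#' JSON or YAML (by extension); the file holds an ordered list of steps,
#' each with a `name` and an optional `params` map.
#'
#' @param path configuration file.
#' @return A list usable as `config` in [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(cfg, function(st) {
    if (is.null(st$name)) stop("read_pipeline_config: step without a name")
    list(name = st$name,
         params = if (is.null(st$params)) list() else st$params)
  })
}
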
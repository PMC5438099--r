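# small raw trial on disk + imported project, reused across tests
make_project <- function(n = 3L, nf = 60L, hw = 8L, seed = 100L) {
  dir <- tempfile("proj")
  proj <- create_project(dir)
  for (i in seq_len(n)) {
    s <- rand_stack(nf = nf, h = hw, w = hw, seed = seed + i)
    raw <- file.path(dir, sprintf("rec_%d.raw", i))
    write_raw_stack(s, raw, dtype = "float64")
    proj <- import_raw(proj, raw, raw_spec(hw, hw, 1, "float64"), fps = 30)
  }
  proj
}

test_that("project creation writes an empty manifest and validates dir", {
  dir <- tempfile("proj")
  proj <- create_project(dir)
  expect_true(file.exists(file.path(dir, "mesoconn_project.json")))
  expect_length(proj$manifest$files, 0)
  expect_null(proj$manifest$origin)
  notdir <- tempfile(); writeLines("x", notdir)
  expect_error(create_project(notdir), "not a directory")
})

test_that("a copied project folder reopens with identical contents", {
  proj <- make_project(2)
  proj <- set_project_scale(proj, 41)
  proj <- set_project_origin(proj, c(136.28, 145.06))
  copy <- tempfile("copy")
  dir.create(copy)
  file.copy(list.files(proj$dir, full.names = TRUE), copy)
  reopened <- open_project(copy)
  expect_equal(reopened$manifest$files, proj$manifest$files)
  expect_equal(reopened$manifest$origin, c(136.28, 145.06))
  expect_equal(project_stack(reopened, project_files(proj)[1])$data,
               project_stack(proj, project_files(proj)[1])$data)
})

test_that("derived records extend the source history by exactly one step", {
  proj <- make_project(1)
  nm <- project_files(proj)[1]
  s <- trim_frames(project_stack(proj, nm), 5)
  out <- file.path(proj$dir, paste0(nm, "_trim.npy"))
  persist_stack(s, out)
  proj <- record_step(proj, nm, list(name = "trim",
                                     params = list(n_front = 5)), out)
  rec <- proj$manifest$files[[2]]
  expect_equal(vapply(rec$manipulations, `[[`, "", "name"),
               c("import", "trim"))
  out2 <- file.path(proj$dir, paste0(nm, "_trim_gsr.npy"))
  persist_stack(gsr(s), out2)
  proj <- record_step(proj, rec$name, list(name = "gsr", params = list()),
                      out2)
  expect_length(proj$manifest$files[[3]]$manipulations, 3)
  expect_error(record_step(proj, "nope", list(name = "x", params = list()),
                           out2), "no file named")
})

test_that("files filter by manipulation history", {
  proj <- make_project(3)
  res <- suppressMessages(
    run_pipeline(proj, list(list(name = "dff"), list(name = "gsr")),
                 project_files(proj)[1:2]))
  proj <- res$project
  expect_length(filter_files(proj, "gsr"), 2)
  expect_length(filter_files(proj, "dff"), 4)     # dff outputs + gsr children
  expect_length(filter_files(proj, "import"), length(proj$manifest$files))
  expect_length(filter_files(proj, "nonexistent"), 0)
})

test_that("the pipeline fans per-file steps and reduces trial-combiners", {
  proj <- make_project(3, nf = 120)
  cfg <- list(list(name = "trim", params = list(n_front = 10)),
              list(name = "bandpass", params = list(low = 0.3, high = 3)),
              list(name = "dff"), list(name = "gsr"))
  res <- suppressMessages(run_pipeline(proj, cfg, project_files(proj)))
  expect_length(res$project$manifest$files, 3 + 12)  # 4 steps x 3 inputs
  hl <- vapply(res$project$manifest$files, function(f)
    length(f$manipulations), integer(1))
  expect_setequal(unique(hl), 1:5)
  expect_length(res$outputs, 3)

  res2 <- suppressMessages(run_pipeline(
    res$project, list(list(name = "dff"), list(name = "concat")),
    project_files(proj)[1:3]))
  new <- length(res2$project$manifest$files) -
    length(res$project$manifest$files)
  expect_equal(new, 4)                             # 3 dff + 1 concat
  expect_length(res2$outputs, 1)
  cc <- project_stack(res2$project, names(res2$outputs)[1])
  expect_equal(n_frames(cc), 3 * 120L)
})

test_that("an empty pipeline returns the inputs unchanged", {
  proj <- make_project(2)
  before <- length(proj$manifest$files)
  res <- suppressMessages(run_pipeline(proj, list(), project_files(proj)))
  expect_length(res$project$manifest$files, before)
  expect_equal(names(res$outputs), project_files(proj))
})

test_that("a failing step names the step, the input, and the cause", {
  proj <- make_project(1, nf = 30)
  cfg <- list(list(name = "trim", params = list(n_front = 500)))
  expect_error(suppressMessages(run_pipeline(proj, cfg,
                                             project_files(proj))),
               "step 'trim' failed on 'rec_1'")
  expect_error(suppressMessages(run_pipeline(
    proj, list(list(name = "warp9")), project_files(proj))),
    "unknown pipeline step")
})

test_that("pipeline configs load from JSON and YAML alike", {
  cfg <- list(list(name = "trim", params = list(n_front = 20)),
              list(name = "dff"))
  jp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  yp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yp)
  cj <- read_pipeline_config(jp)
  cy <- read_pipeline_config(yp)
  expect_equal(cj[[1]]$name, "trim")
  expect_equal(cj[[1]]$params$n_front, 20)
  expect_equal(cy[[2]]$name, "dff")
  expect_equal(length(cj), 2)
})

test_that("per-stack origins are stored but the global origin wins", {
  proj <- make_project(1)
  proj <- set_project_scale(proj, 41)
  proj <- set_project_origin(proj, c(100, 100))
  nm <- project_files(proj)[1]
  proj <- set_project_origin(proj, c(50, 60), file = nm)
  expect_equal(project_cs(proj)$origin, c(100, 100))
  expect_equal(project_cs(proj, file = nm)$origin, c(50, 60))
})

test_that("custom steps register and run without touching the runner", {
  register_step("halve", function(stack, params, ctx)
    image_stack(stack$data / 2, stack$fps))
  proj <- make_project(1)
  nm <- project_files(proj)[1]
  res <- suppressMessages(run_pipeline(proj, list(list(name = "halve")), nm))
  expect_equal(project_stack(res$project, names(res$outputs)[1])$data,
               project_stack(proj, nm)$data / 2)
  expect_true("halve" %in% registered_steps())
})
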
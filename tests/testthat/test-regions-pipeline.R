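test_that("region extraction returns member-cell values and drops missing", {
  g <- grid_spec(lat = c(38, 39), lon = c(-9, -8))
  field <- data.frame(cell = 1:4, lat = rep(c(38, 39), each = 2),
                      lon = rep(c(-9, -8), 2), value = c(7, 2, 3, 4))
  one <- region_mask("one", cells = 1)
  expect_equal(extract_region(field, one, g), 7)
  field$value[2] <- NA
  all4 <- region_mask("all", cells = 1:4)
  expect_message(v <- extract_region(field, all4, g), "1 missing")
  expect_equal(sort(v), c(3, 4, 7))
  expect_error(region_cells(region_mask("out", cells = 99), g),
               "does not intersect")
})

test_that("polygon and explicit-index masks select the same cells", {
  g <- grid_spec(lat = seq(36.5, 42.5, length.out = 8),
                 lon = seq(-9.5, -6.0, length.out = 8))
  poly <- region_mask("p", polygon = cbind(lon = c(-8.2, -7.3, -7.3, -8.2),
                                           lat = c(38.0, 38.0, 39.3, 39.3)))
  cells <- region_cells(poly, g)
  expect_gt(length(cells), 0)
  idx <- region_mask("i", cells = cells)
  expect_equal(region_cells(idx, g), cells)
  cc <- cell_coords(g)
  expect_true(all(cc$lon[cells] >= -8.2 & cc$lon[cells] <= -7.3 &
                    cc$lat[cells] >= 38.0 & cc$lat[cells] <= 39.3))
})

test_that("packaged GeoJSON regions load with unique ids and fruit labels", {
  path <- system.file("extdata", "demo_regions.geojson",
                      package = "chillforce")
  masks <- read_regions_geojson(path)
  expect_length(masks, 8)
  expect_equal(anyDuplicated(names(masks)), 0)
  expect_setequal(unique(vapply(masks, `[[`, "", "fruit")),
                  c("apple", "pear", "plum", "orange"))
  g <- grid_spec(lat = seq(36.5, 42.5, length.out = 8),
                 lon = seq(-9.5, -6.0, length.out = 8))
  for (m in masks) expect_gt(length(region_cells(m, g)), 0)
})

test_that("boxplot statistics respect the order-statistic chain", {
  b <- regional_boxstats(5)
  expect_equal(unlist(b[c("min", "q25", "mean", "median", "q75", "max")]),
               rep(5, 6), ignore_attr = TRUE)
  b2 <- regional_boxstats(c(1, 2, 3, 4, 5))
  expect_equal(unlist(b2[c("q25", "median", "q75", "mean")]),
               c(2, 3, 4, 3), ignore_attr = TRUE)
  for (seed in 1:5) {
    set.seed(seed)
    b3 <- regional_boxstats(rlnorm(40, 2, 1))
    expect_true(b3$min <= b3$q25 && b3$q25 <= b3$median &&
                  b3$median <= b3$q75 && b3$q75 <= b3$max)
    expect_true(b3$min <= b3$mean && b3$mean <= b3$max)
  }
  expect_error(regional_boxstats(numeric(0)), "no values")
})

test_that("YAML run configurations load with grids, scenarios and regions", {
  path <- system.file("extdata", "demo_config.yaml", package = "chillforce")
  cfg <- read_run_config(path, outdir = withr::local_tempdir(), seed = 7)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$weather$seed, 7)
  expect_equal(n_cells(cfg$weather$grid), 100)
  expect_equal(n_cells(cfg$scenario_grid), 64)
  expect_equal(cfg$scenarios, c(rcp45 = 0.02, rcp85 = 0.045))
  expect_length(cfg$regions, 8)
})

test_that("a small full run emits traceable outputs and a manifest", {
  od <- withr::local_tempdir()
  cfg <- run_config(
    weather = weather_gen_config(grid = grid_spec(c(37.2, 38.1), c(-8.6, -7.7)),
                                 bias_offset = 1, seed = 5),
    scenario_grid = grid_spec(c(37.2, 38.1), c(-8.6, -7.7)),
    n_models = 2, scenarios = c(rcp85 = 0.045), future_end = 2080,
    regions = list(south = region_mask("south", cells = 1:4, fruit = "orange")),
    outdir = od, seed = 5)
  res <- run_pipeline(cfg, quiet = TRUE)
  for (f in c("seasonal_totals.csv", "safe_indices.csv",
              "ensemble_summary.csv", "change_maps.csv",
              "regional_boxstats.csv", "regional_annual_series.csv",
              "trends.csv", "manifest.json"))
    expect_true(file.exists(file.path(od, f)), label = f)
  # every index row is traceable to scenario/model/period
  si <- read.csv(file.path(od, "safe_indices.csv"))
  expect_true(all(c("scenario", "model", "period", "variable", "cell")
                  %in% names(si)))
  expect_false(any(is.na(si$scenario) | is.na(si$period)))
  man <- jsonlite::read_json(file.path(od, "manifest.json"))
  expect_equal(man$seed, 5)
  expect_match(man$config_hash, "^[0-9a-f]{32}$")
  # ensemble sd is finite and non-negative everywhere
  es <- read.csv(file.path(od, "ensemble_summary.csv"))
  expect_true(all(es$sd >= 0))
  # stage-limited runs stop early
  od2 <- withr::local_tempdir()
  cfg2 <- cfg; cfg2$outdir <- od2
  res2 <- run_pipeline(cfg2, through = "accumulate", quiet = TRUE)
  expect_true(file.exists(file.path(od2, "seasonal_totals.csv")))
  expect_false(file.exists(file.path(od2, "trends.csv")))
})

test_that("the command-line front end runs a stage-limited pipeline", {
  cli <- system.file("cli", "chillforce", package = "chillforce")
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "weather:",
    "  grid: {lat: [38.0, 38.8, 2], lon: [-8.8, -8.0, 2]}",
    "  year_start: 2000",
    "  year_end: 2003",
    "scenario_grid: {lat: [38.0, 38.8, 2], lon: [-8.8, -8.0, 2]}",
    "n_models: 1",
    "scenarios: {rcp85: 0.045}",
    "future_end: 2005",
    "seed: 3"), cfg_path)
  od <- withr::local_tempdir()
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "correct", "--config", shQuote(cfg_path),
                   "--outdir", shQuote(od), "--log-level", "quiet"),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(od, "manifest.json")))
})
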
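small_cfg <- function() synth_config(n_cells = 4000, live_fraction = 1)
small_run_cfg <- function(seed = 1) {
  pipeline_config(target_fraction = 1, B = 400, m = 50, seed = seed)
}

test_that("run_pipeline recovers three-way phenotypes on a small panel", {
  spec <- make_panel_spec(phis = c(WT = 1, dn = 0.4, nul = 1, up = 2.5))
  sim <- simulate_panel(spec, base_config = small_cfg(), seed = 3)
  res <- suppressWarnings(
    run_pipeline(sim$manifest, small_run_cfg(seed = 3), tables = sim$tables))
  expect_identical(nrow(res$calls), 9L) # 3 mutants x 3 clients
  got <- merge(res$calls, sim$manifest[, c("sample_id", "truth_phi")])
  expect_true(all(got$category[got$truth_phi < 1] == "decreased"))
  expect_true(all(got$category[got$truth_phi > 1] == "increased"))
  # per-client counts line up with the calls table
  expect_identical(nrow(res$category_counts), 3L)
  expect_true(all(rowSums(res$category_counts[, -1]) == 3))
  # every sample, references included, has a QC row
  expect_identical(sort(res$qc$sample_id), sort(sim$manifest$sample_id))
})

test_that("a WT file re-listed as a mutant is an exact self-null", {
  spec <- make_panel_spec(clients = "TMEM97", phis = c(WT = 1, self = 1))
  spec$seed <- 55 # identical generator stream for both rows
  sim <- simulate_panel(spec, base_config = small_cfg())
  res <- suppressWarnings(
    run_pipeline(sim$manifest, small_run_cfg(), tables = sim$tables))
  expect_identical(res$calls$t_stat, 0)
  expect_identical(res$calls$p_decrease, 0.5)
  expect_identical(res$calls$category, "wt_like")
})

test_that("pipeline runs identically from files and from memory", {
  dir <- withr::local_tempdir()
  spec <- make_panel_spec(clients = "B1AR", phis = c(WT = 1, mutA = 0.5))
  sim <- simulate_panel(spec, base_config = small_cfg(), seed = 9,
                        dir = dir)
  res_mem <- suppressWarnings(
    run_pipeline(sim$manifest, small_run_cfg(), tables = sim$tables))
  res_file <- suppressWarnings(
    run_pipeline(sim$manifest, small_run_cfg()))
  expect_equal(res_file$calls, res_mem$calls, tolerance = 1e-12)
})

test_that("manifest validation catches structural problems", {
  spec <- make_panel_spec(clients = "B1AR", phis = c(WT = 1, mutA = 0.5))
  sim <- simulate_panel(spec, base_config = quick_config(n_cells = 300))
  bad <- sim$manifest
  bad$is_wt_reference <- FALSE
  expect_error(run_pipeline(bad, small_run_cfg(), tables = sim$tables),
               "WT reference")
  dup <- rbind(sim$manifest, sim$manifest[1, ])
  expect_error(run_pipeline(dup, small_run_cfg(), tables = sim$tables),
               "duplicate")
  nofile <- sim$manifest
  nofile$path <- file.path(tempdir(), "missing.tsv")
  expect_error(run_pipeline(nofile, small_run_cfg()), "not found")
})

test_that("stage errors carry the sample id", {
  spec <- make_panel_spec(clients = "B1AR", phis = c(WT = 1, mutA = 0.5))
  sim <- simulate_panel(spec, base_config = quick_config(n_cells = 300))
  tiny <- simulate_sample(quick_config(n_cells = 120), "t")
  tiny$fsc_a[1:80] <- -1 # >50% non-positive scatter
  sim$tables[[2]] <- tiny
  suppressWarnings(expect_error(
    run_pipeline(sim$manifest, small_run_cfg(), tables = sim$tables),
    sim$manifest$sample_id[2]))
})

test_that("assemble_matrix pivots calls to mutants x clients", {
  calls <- expand.grid(rescue_variant = sprintf("EMC3_N%dD", 101:149),
                       client = c("SQS378-410", "B1AR", "TMEM97"),
                       stringsAsFactors = FALSE)
  calls$category <- rep(c("decreased", "wt_like", "increased"),
                        length.out = nrow(calls))
  m <- assemble_matrix(calls)
  expect_identical(dim(m), c(49L, 4L))
  expect_identical(names(m)[1], "rescue_variant")

  one <- assemble_matrix(calls[1, ])
  expect_identical(dim(one), c(1L, 2L))

  expect_error(assemble_matrix(rbind(calls, calls[1, ])), "duplicate")

  # missing combinations are explicit
  holey <- assemble_matrix(calls[-1, ])
  expect_identical(holey[holey$rescue_variant == calls$rescue_variant[1],
                         "SQS378-410"], "missing")
})

test_that("mutation strings parse to subunit and 1-based substitutions", {
  p <- parse_mutation("EMC3_N114D+N117D")
  expect_identical(p$subunit, "EMC3")
  expect_identical(p$substitutions$position, c(114L, 117L))
  expect_identical(p$substitutions$wt_aa, c("N", "N"))
  expect_identical(p$substitutions$mut_aa, c("D", "D"))
  expect_identical(nrow(parse_mutation("WT")$substitutions), 0L)
  expect_error(parse_mutation("EMC3_N114"), "N114")
  expect_error(parse_mutation("justtext"), "parse")
})

test_that("residue attributes map mutated residues to categories", {
  calls <- data.frame(
    rescue_variant = c("EMC3_N114D+N117D", "WT", "EMC5_G21L"),
    client = "SQS378-410",
    category = c("decreased", "wt_like", "increased"),
    stringsAsFactors = FALSE)
  att <- export_residue_attributes(calls, "SQS378-410")
  expect_identical(nrow(att), 3L)
  expect_identical(att$residue, c(114L, 117L, 21L))
  expect_identical(att$category, c("decreased", "decreased", "increased"))
  expect_identical(att$color, c("gold", "gold", "white"))

  f <- withr::local_tempfile(fileext = ".tsv")
  export_residue_attributes(calls, "SQS378-410", path = f)
  back <- read.delim(f)
  expect_identical(nrow(back), 3L)

  # wild-type residue letters are checked against a reference sequence
  seqs <- c(EMC3 = paste(rep("A", 200), collapse = ""))
  expect_error(
    export_residue_attributes(calls[1, ], "SQS378-410", ref_seqs = seqs),
    "reference sequence")
  seqs_ok <- c(EMC3 = paste(c(rep("A", 113), "N", "A", "A", "N",
                              rep("A", 100)), collapse = ""))
  expect_identical(
    nrow(export_residue_attributes(calls[1, ], "SQS378-410",
                                   ref_seqs = seqs_ok)), 2L)
  expect_error(export_residue_attributes(calls, "B1AR"), "no calls")
})

test_that("benjamini-hochberg adjustment is available across the panel", {
  spec <- make_panel_spec(phis = c(WT = 1, dn = 0.4, up = 2.5))
  sim <- simulate_panel(spec, base_config = small_cfg(), seed = 13)
  cfg <- pipeline_config(target_fraction = 1, B = 300, m = 50,
                         p_adjust = "BH", seed = 13)
  res <- suppressWarnings(run_pipeline(sim$manifest, cfg,
                                       tables = sim$tables))
  expect_true(all(c("p_decrease_adj", "p_increase_adj") %in%
                    names(res$calls)))
  expect_true(all(res$calls$p_decrease_adj >= res$calls$p_decrease))
})

test_that("exports are stable and the config snapshot round-trips", {
  spec <- make_panel_spec(clients = "B1AR", phis = c(WT = 1, mutA = 0.5))
  sim <- simulate_panel(spec, base_config = small_cfg(), seed = 17)
  res <- suppressWarnings(
    run_pipeline(sim$manifest, small_run_cfg(seed = 17),
                 tables = sim$tables))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_panel(res, d1)
  export_panel(res, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  snap <- jsonlite::read_json(file.path(d1, "config.json"),
                              simplifyVector = TRUE)
  cfg2 <- do.call(pipeline_config, snap)
  res2 <- suppressWarnings(
    run_pipeline(sim$manifest, cfg2, tables = sim$tables))
  expect_equal(res2$calls, res$calls, tolerance = 1e-12)
})
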
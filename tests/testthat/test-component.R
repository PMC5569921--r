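# component framework: scaffolding, loading, definition round-trips and
# deterministic command rendering

test_that("scaffolding creates the standard layout and a loadable definition", {
  dest <- withr::local_tempdir()
  sc <- make_component_template("comp_linecount", dest)
  expect_true(dir.exists(sc$root_dir))
  expect_true(file.exists(sc$definition_file))
  expect_true(file.exists(sc$wrapper_file))
  expect_true(dir.exists(sc$seed_dir))
  expect_true(file.exists(sc$docs))
  expect_true(dir.exists(sc$tests_dir))
  comp <- load_component(sc$root_dir)
  expect_equal(comp$name, "comp_linecount")
  expect_length(comp$params, 0L)
  expect_equal(comp$requirements, list(memory = "1G", num_cpus = 1L))
  # no clobbering, no path separators
  expect_error(make_component_template("comp_linecount", dest), "clobber")
  expect_error(make_component_template("bad/name", dest), "identifier")
})

test_that("definition invariants are enforced at load time", {
  dest <- withr::local_tempdir()
  d <- file.path(dest, "broken"); dir.create(d)
  writeLines(c("name: broken",
               "seed_command: echo",
               "parallelization:",
               "  merge_strategy: concat"), file.path(d, "component.yaml"))
  expect_error(load_component(d), "split_param")
  writeLines(c("name: broken", "seed_command: echo",
               "params:",
               "  - {name: p1, role: argument}",
               "  - {name: p1, role: flag}"), file.path(d, "component.yaml"))
  expect_error(load_component(d), "p1")
  writeLines("name: broken", file.path(d, "component.yaml"))
  expect_error(load_component(d), "seed_command")
  expect_error(load_component(file.path(dest, "nowhere")), "component definition")
})

test_that("loaded definitions re-emit identically (scaffold-load-scaffold stability)", {
  fx <- local_fixture_suite()
  comp <- fx$registry$comp_interval_count
  f <- withr::local_tempfile(fileext = ".yaml")
  dir2 <- withr::local_tempdir()
  write_component_definition(comp, f)
  dir.create(file.path(dir2, "x")); file.copy(f, file.path(dir2, "x", "component.yaml"))
  comp2 <- load_component(file.path(dir2, "x"))
  attributes(comp) <- attributes(comp2) <- NULL
  expect_equal(comp, comp2)
})

test_that("command rendering is deterministic, ordered and boilerplate-aware", {
  fx <- local_fixture_suite()
  copy <- fx$registry$comp_copy
  cmd <- build_command(copy, list(in_file = "a.txt", out_file = "b.txt"))
  expect_equal(cmd, sprintf("bash %s/seed/run.sh --in_file a.txt --out_file b.txt",
                            attr(copy, "dir")))
  # boilerplate prepends and is joined so its failure aborts the task
  cmd_b <- build_command(copy, list(in_file = "a.txt", out_file = "b.txt"),
                         boilerplate = "module load samtools")
  expect_equal(cmd_b, paste("module load samtools &&", cmd))
  # purity: equal inputs, byte-equal output
  expect_identical(cmd, build_command(copy, list(in_file = "a.txt", out_file = "b.txt")))
  # missing required parameter names the component and the parameter
  expect_error(build_command(copy, list(in_file = "a.txt")), "comp_copy.*out_file")
})

test_that("flags render only when true and fan-in values expand in order", {
  fx <- local_fixture_suite()
  tg <- fx$registry$comp_textgen
  base <- list(n = 3, tag = "t", out_file = "o.txt")
  expect_false(grepl("--upper", build_command(tg, base)))
  expect_false(grepl("--upper", build_command(tg, c(base, list(upper = FALSE)))))
  expect_match(build_command(tg, c(base, list(upper = TRUE))), "--upper( |$)")
  tm <- fx$registry$comp_table_merge
  cmd <- build_command(tm, list(in_files = c("x.tsv", "y.tsv"), out_file = "z.tsv"))
  expect_match(cmd, "--in_files x.tsv y.tsv --out_file z.tsv", fixed = TRUE)
  # values with shell metacharacters are quoted
  cmd_q <- build_command(fx$registry$comp_copy,
                         list(in_file = "my file.txt", out_file = "b.txt"))
  expect_match(cmd_q, "'my file.txt'", fixed = TRUE)
})
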
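# DAG construction and the stage planner, checked against a brute-force
# longest-path-depth oracle

test_that("the two-task wiring yields a 2-node, 1-io-edge graph", {
  fx <- local_fixture_suite()
  g <- build_graph(parse_config(chain_config()), fx$registry)
  expect_setequal(g$nodes, c("__TASK_1__", "__TASK_2__"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "__TASK_1__")
  expect_equal(g$edges$to, "__TASK_2__")
  expect_equal(g$edges$kind, "io")
})

test_that("swapping a task section changes only that node of the DAG", {
  fx <- local_fixture_suite()
  # original producer: a text generator; replacement: a copier exposing the
  # same out_file parameter — the consumer's wiring is untouched
  consumer <- "
__TASK_2__:
  component: comp_linecount
  in_file: ('%s', 'out_file')
  out_file: n.txt
"
  cfg1 <- parse_config(paste0(
    "__TASK_1__: {component: comp_textgen, n: 4, out_file: x.txt}\n",
    sprintf(consumer, "__TASK_1__")))
  cfg2 <- parse_config(paste0(
    sprintf("__TASK_5__: {component: comp_copy, in_file: '%s', out_file: x.txt}\n",
            local_fixture_suite()$data$variants),
    sprintf(consumer, "__TASK_5__")))
  g1 <- build_graph(cfg1, fx$registry)
  g2 <- build_graph(cfg2, fx$registry)
  # isomorphic up to renaming the swapped node
  rename <- function(x) ifelse(x == "__TASK_5__", "__TASK_1__", x)
  expect_setequal(rename(g2$nodes), g1$nodes)
  expect_equal(data.frame(from = rename(g2$edges$from), to = rename(g2$edges$to),
                          kind = g2$edges$kind),
               g1$edges)
  # the consumer keeps its component and parameters; only its wiring target
  # follows the rename
  expect_equal(g1$payload$`__TASK_2__`$task$component_name,
               g2$payload$`__TASK_2__`$task$component_name)
  expect_equal(g2$payload$`__TASK_2__`$task$params$in_file$source_task,
               "__TASK_5__")
})

test_that("cycles are rejected with an explicit task-name path", {
  fx <- local_fixture_suite()
  cyc <- parse_config("
__TASK_A__:
  component: comp_copy
  in_file: ('__TASK_B__', 'out_file')
  out_file: a.txt
__TASK_B__:
  component: comp_copy
  in_file: ('__TASK_A__', 'out_file')
  out_file: b.txt
")
  err <- tryCatch(build_graph(cyc, fx$registry), condition = identity)
  expect_s3_class(err, "flowforge_validation_error")
  expect_match(conditionMessage(err),
               "(__TASK_A__ -> __TASK_B__ -> __TASK_A__)|(__TASK_B__ -> __TASK_A__ -> __TASK_B__)")
})

test_that("chains and joins plan into the expected stages", {
  fx <- local_fixture_suite()
  chain <- build_plan(build_graph(parse_config("
__TASK_A__: {component: comp_textgen, out_file: a.txt}
__TASK_B__: {component: comp_textgen, out_file: b.txt, forced_dependencies: [__TASK_A__]}
__TASK_C__: {component: comp_textgen, out_file: c.txt, forced_dependencies: [__TASK_B__]}
"), fx$registry))
  expect_equal(chain$stages,
               list("__TASK_A__", "__TASK_B__", "__TASK_C__"))
  join <- build_plan(build_graph(parse_config("
__TASK_C__: {component: comp_textgen, out_file: c.txt, forced_dependencies: [__TASK_A__, __TASK_B__]}
__TASK_B__: {component: comp_textgen, out_file: b.txt}
__TASK_A__: {component: comp_textgen, out_file: a.txt}
"), fx$registry))
  expect_equal(join$stages, list(c("__TASK_A__", "__TASK_B__"), "__TASK_C__"))
})

test_that("plans match the brute-force longest-path partition on random DAGs", {
  fx <- local_fixture_suite()
  withr::local_seed(2024)
  for (i in 1:60) {
    dag <- random_dag(sample(2:8, 1))
    g <- build_graph(parse_config(dag_config(dag)), fx$registry)
    plan <- build_plan(g)
    # node preservation
    expect_setequal(unlist(plan$stages), dag$nodes)
    depths <- oracle_depths(dag$nodes, dag$edges)
    for (v in dag$nodes) {
      expect_equal(stage_of_task(plan, v), unname(depths[v]) + 1L,
                   label = sprintf("stage of %s (dag %d)", v, i))
    }
    # every edge crosses stages forward; within-stage pairs are non-adjacent
    for (k in seq_len(nrow(dag$edges))) {
      expect_true(stage_of_task(plan, dag$edges$from[k]) <
                  stage_of_task(plan, dag$edges$to[k]))
    }
    expect_length(plan$stages, max(depths) + 1L)
    # lexicographic tie-break within stages: deterministic plans
    expect_true(all(vapply(plan$stages, function(s) !is.unsorted(s), logical(1))))
  }
})

test_that("forced and io edges constrain scheduling identically", {
  fx <- local_fixture_suite()
  io_cfg <- parse_config(chain_config())
  forced_cfg <- parse_config("
__TASK_1__: {component: comp_textgen, out_file: a.txt}
__TASK_2__: {component: comp_textgen, out_file: b.txt, forced_dependencies: [__TASK_1__]}
")
  p_io <- build_plan(build_graph(io_cfg, fx$registry))
  p_forced <- build_plan(build_graph(forced_cfg, fx$registry))
  expect_equal(p_io$stages, p_forced$stages)
})

test_that("graphs export to DOT and plans to JSON", {
  fx <- local_fixture_suite()
  g <- build_graph(parse_config(chain_config()), fx$registry)
  dot <- graph_to_dot(g)
  expect_match(dot[1], "^digraph")
  expect_true(any(grepl('"__TASK_1__" -> "__TASK_2__"', dot)))
  js <- jsonlite::fromJSON(plan_to_json(build_plan(g)), simplifyVector = FALSE)
  expect_equal(js, list(list("__TASK_1__"), list("__TASK_2__")))
})

test_that("descendant sets follow reachability", {
  fx <- local_fixture_suite()
  g <- build_graph(parse_config(chain_plus_branch_config()), fx$registry)
  expect_equal(descendants(g, "__TASK_A__"), c("__TASK_B__", "__TASK_C__"))
  expect_equal(descendants(g, "__TASK_D__"), character())
})
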
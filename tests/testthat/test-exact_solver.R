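test_that("solver handles the worked toy instance and trivial cases", {
  # all pairs share T2, so only singletons are feasible; g2 is largest
  res <- wmem_solve(toy_instance())
  expect_identical(res$solution$chosen, "g2")
  expect_identical(res$solution$coverage, 3L)
  expect_identical(res$solution$weight, 0.02)
  expect_same_solution(res$solution, brute_force_solve(toy_instance()))

  empty <- wmem_solve(cover_instance(list()))
  expect_identical(empty$solution$chosen, character(0))
  expect_identical(empty$solution$coverage, 0L)
  expect_identical(empty$stats$branch_leaves, 1L)

  # disjoint sets are included directly, regardless of weight sign
  disj <- wmem_solve(cover_instance(list(A = c("1", "2"), B = "3"),
                                    c(A = 5, B = -1)))
  expect_identical(disj$solution$chosen, c("A", "B"))
  expect_identical(disj$solution$coverage, 3L)
  expect_equal(disj$solution$weight, 4)
  expect_identical(disj$stats$branch_nodes, 0L)
})

test_that("path and ring components are solved optimally", {
  # path A-B-C, weights 0: brute force says {A, C}, coverage 4
  p <- path_instance()
  res <- wmem_solve(p)
  expect_same_solution(res$solution, brute_force_solve(p))
  expect_identical(res$solution$chosen, c("A", "C"))
  expect_identical(res$solution$coverage, 4L)
  expect_identical(res$stats$branch_leaves, 1L)  # handed to the deg-2 routine

  # ring A-B-C with weights 1,2,3: any single set covers 2; A is cheapest
  r <- ring_instance()
  rres <- wmem_solve(r)
  expect_same_solution(rres$solution, brute_force_solve(r))
  expect_identical(rres$solution$chosen, "A")
  expect_identical(rres$solution$weight, 1)

  single <- wmem_solve(cover_instance(list(A = "7"), c(A = 2.5)))
  expect_identical(single$solution$chosen, "A")
  expect_identical(single$solution$coverage, 1L)
})

test_that("longer paths and rings match brute force with mixed-sign weights", {
  for (s in 1:10) {
    m <- 4 + (s %% 6)
    ids <- sprintf("N%02d", 1:m)
    pinst <- instance_from_graph(
      list(nodes = ids, edges = cbind(ids[-m], ids[-1])),
      weight_range = c(-1, 1), seed = s)
    expect_same_solution(wmem_solve(pinst)$solution, brute_force_solve(pinst))
    rinst <- instance_from_graph(
      list(nodes = ids, edges = rbind(cbind(ids[-m], ids[-1]), c(ids[m], ids[1]))),
      weight_range = c(-1, 1), seed = s + 100)
    expect_same_solution(wmem_solve(rinst)$solution, brute_force_solve(rinst))
  }
})

test_that("degree-3 structures match brute force", {
  # star-with-tail: x meets a, b, c; c-d forms a tail
  star <- cover_instance(
    list(x = c("1", "2", "3", "9"), a = c("1", "10"), b = c("2", "11"),
         c = c("3", "4"), d = c("4", "5")),
    rep(0, 5))
  expect_same_solution(wmem_solve(star)$solution, brute_force_solve(star))

  # K4 with one unique shared element per edge: only singletons feasible,
  # coverage = size of the largest set
  k4 <- instance_from_graph(list(
    nodes = c("a", "b", "c", "d"),
    edges = cbind(c("a", "a", "a", "b", "b", "c"),
                  c("b", "c", "d", "c", "d", "d"))))
  res <- wmem_solve(k4)
  expect_same_solution(res$solution, brute_force_solve(k4))
  expect_identical(res$solution$coverage,
                   max(lengths(normalize_instance(k4)$sets)))
})

test_that("solver equals brute force on seeded random instances", {
  for (s in 1:150) {
    m <- 2 + (s %% 11)
    dens <- c(0.1, 0.3, 0.6)[(s %% 3) + 1]
    inst <- random_instance(m = m, n = 18, density = dens,
                            weight_range = c(-1, 1), seed = 5000 + s)
    a <- wmem_solve(inst)$solution
    b <- brute_force_solve(inst)
    expect_identical(a$coverage, b$coverage)
    expect_lt(abs(a$weight - b$weight), 1e-9)
    expect_identical(a$chosen, b$chosen)
    expect_valid_solution(inst, a)
  }
})

test_that("component decomposition is consistent with whole-instance solving", {
  for (s in 1:15) {
    inst <- random_instance(m = 10, n = 40, density = 0.08,
                            weight_range = c(-1, 1), seed = 900 + s)
    whole <- wmem_solve(inst)
    g <- build_intersection_graph(inst)
    comps <- graph_components(g)
    cov <- 0L; w <- 0; chosen <- character(0)
    for (comp in comps) {
      sub <- cover_instance(inst$sets[comp], inst$weights[comp])
      r <- wmem_solve(sub)$solution
      cov <- cov + r$coverage; chosen <- c(chosen, r$chosen)
    }
    expect_identical(whole$solution$coverage, cov)
    expect_identical(whole$solution$chosen, sort(chosen, method = "radix"))
  }
})

test_that("3-uniform coverage equals three times the maximum packing size", {
  for (s in 1:30) {
    m <- 4 + (s %% 9)
    inst <- random_uniform_instance(m = m, n = 12, set_size = 3,
                                    seed = 300 + s)
    cov <- wmem_solve(inst)$solution$coverage
    expect_identical(cov, 3L * brute_force_packing_size(inst))
  }
})

test_that("solver output and stats are deterministic across runs", {
  inst <- random_instance(m = 14, n = 25, density = 0.2, seed = 77)
  r1 <- wmem_solve(inst)
  r2 <- wmem_solve(inst)
  expect_identical(r1$solution, r2$solution)
  expect_identical(r1$stats, r2$stats)
  expect_gte(r1$stats$branch_leaves, 1L)
  expect_gte(r1$solution$coverage,
             max(lengths(normalize_instance(inst)$sets)))
})

test_that("find_branch_node_deg3 follows the minimum-degree walk", {
  # pendant path a-b-x with deg(x) = 3
  spec <- list(nodes = c("a", "b", "x", "y", "z", "w"),
               edges = cbind(c("a", "b", "x", "x", "y"),
                             c("b", "x", "y", "z", "w")))
  g <- build_intersection_graph(instance_from_graph(spec))
  expect_identical(find_branch_node_deg3(g), "x")

  # degree-1 node directly adjacent to a degree-3 node
  spec2 <- list(nodes = c("p", "q", "r", "s", "t"),
                edges = cbind(c("p", "q", "q", "r"), c("q", "r", "s", "t")))
  # degrees: p1 q3 r2 s1 t1 -> smallest-id min-degree node is p, neighbor q has deg 3
  g2 <- build_intersection_graph(instance_from_graph(spec2))
  expect_identical(find_branch_node_deg3(g2), "q")

  # 3-regular K4: smallest id
  k4 <- instance_from_graph(list(
    nodes = c("a", "b", "c", "d"),
    edges = cbind(c("a", "a", "a", "b", "b", "c"),
                  c("b", "c", "d", "c", "d", "d"))))
  expect_identical(find_branch_node_deg3(build_intersection_graph(k4)), "a")

  expect_error(find_branch_node_deg3(build_intersection_graph(path_instance())),
               "not 3")
})

test_that("component solver wrappers enforce their degree contracts", {
  tri_plus <- cover_instance(
    list(x = c("1", "2", "3", "4"), a = "1", b = "2", c = "3", d = "4"),
    rep(0, 5))  # star: x has degree 4
  expect_error(solve_component_deg2(tri_plus), "degree > 2")
  expect_error(solve_component_deg3(tri_plus), "max degree != 3")
  expect_error(solve_component_deg3(path_instance()), "max degree != 3")

  # valid calls agree with the general solver
  p <- path_instance(ids = sprintf("N%d", 1:5))
  expect_same_solution(solve_component_deg2(p)$solution,
                       wmem_solve(p)$solution)
  star <- cover_instance(
    list(x = c("1", "2", "3"), a = "1", b = "2", c = "3"), rep(0, 4))
  expect_same_solution(solve_component_deg3(star)$solution,
                       brute_force_solve(star))
})

test_that("brute force refuses oversized instances and handles forced choices", {
  inst <- random_instance(m = 21, n = 30, density = 0.2, seed = 1)
  expect_error(brute_force_solve(inst, max_m = 20), "max_m")
  dupes <- cover_instance(list(A = "1", B = "1"), c(A = 2, B = 1))
  sol <- brute_force_solve(dupes)
  expect_identical(sol$chosen, "B")
  expect_identical(sol$weight, 1)
  expect_identical(brute_force_solve(cover_instance(list()))$coverage, 0L)
})
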
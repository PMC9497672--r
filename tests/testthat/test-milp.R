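test_that("the assembled model has the expected size and guards its inputs", {
  net <- random_network(3, 1)
  model <- build_model(net, 2)
  expect_equal(model$n_constraints, 26L)  # 1+1+3 card/gate, 3 balance, 12 capacity, 3+3 sink
  expect_equal(model$n_vars, 18L)
  expect_error(build_model(net, 0), "P must be")
  expect_error(build_model(net, 4), "P must be")
  expect_error(build_model(net, 2, bounds = compute_upper_bounds(net, 3)),
               "different P")
  expect_error(build_model(net, 2, bounds = compute_upper_bounds(random_network(5, 2), 2)),
               "do not match")
})

test_that("LP export writes one line per constraint", {
  net <- random_network(3, 4)
  model <- build_model(net, 2)
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp(model, path)
  lines <- readLines(path)
  con <- grep("^ (card|gate|bal|cap|sink)", lines)
  expect_length(con, model$n_constraints)
  expect_true(any(grepl("card_y.*= 2", lines)))
  expect_true(any(grepl("^Binaries$", lines)))
})

test_that("P = 1 selects the single highest-supply feature", {
  for (seed in 1:5) {
    net <- random_network(6, seed + 10)
    res <- solve_model(build_model(net, 1), milp_config(mip_gap = 0))
    expect_equal(res$selected, unname(which.max(net$b)))
    expect_equal(res$terminal, unname(which.max(net$b)))
    expect_equal(res$objective, max(net$b), tolerance = 1e-9)
  }
})

test_that("the two-node worked example routes 0.8 bits through terminal 1", {
  net <- mi_network(matrix(c(0, 0.3, 0.3, 0), 2), b = c(0.5, 0.4))
  res <- solve_model(build_model(net, 2), milp_config(mip_gap = 0))
  expect_equal(res$selected, c(1L, 2L))
  expect_equal(res$terminal, 1L)
  expect_equal(res$objective, 0.8, tolerance = 1e-9)
  expect_equal(res$status, "optimal")

  orc <- exhaustive_oracle(net, 2)
  expect_equal(orc$objective, 0.8, tolerance = 1e-12)
  expect_equal(orc$terminal, 1L)
})

test_that("a zero-supply network has optimal objective 0", {
  net <- mi_network(matrix(c(0, 0.5, 0.5, 0), 2), b = c(0, 0))
  res <- solve_model(build_model(net, 2), milp_config(mip_gap = 0))
  expect_equal(res$objective, 0)
  expect_equal(res$status, "optimal")
})

test_that("the oracle is bounded below by the best single supply and rejects huge instances", {
  net <- random_network(7, 42)
  expect_gte(exhaustive_oracle(net, 3)$objective, max(net$b) - 1e-12)
  expect_error(exhaustive_oracle(net, 3, cap = 10), "cap")
  expect_error(exhaustive_oracle(net, 9), "P must be")
})

test_that("branch-and-bound at gap 0 reproduces the exhaustive optimum", {
  set.seed(500)
  for (rep in 1:12) {
    n <- sample(4:8, 1); P <- sample(1:min(4, n), 1)
    net <- random_network(n, rep + 600)
    orc <- exhaustive_oracle(net, P)
    res <- solve_model(build_model(net, P), milp_config(mip_gap = 0))
    expect_equal(res$objective, orc$objective, tolerance = 1e-6)
    expect_true(res$status %in% c("optimal", "gap_reached"))
    expect_lte(res$achieved_gap, 1e-9)
  }
})

test_that("objective is non-decreasing in the selection size", {
  net <- random_network(6, 77)
  objs <- vapply(1:6, function(P) exhaustive_oracle(net, P)$objective, numeric(1))
  expect_true(all(diff(objs) >= -1e-12))
})

test_that("uniform rescaling of the network rescales the objective and keeps the subset", {
  for (seed in 1:5) {
    net <- random_network(6, seed + 900)
    res <- solve_model(build_model(net, 3), milp_config(mip_gap = 0))
    for (c_scale in c(0.25, 7)) {
      scaled <- mi_network(net$U * c_scale, net$b * c_scale,
                           big_M = net$big_M * c_scale)
      res_c <- solve_model(build_model(scaled, 3), milp_config(mip_gap = 0))
      expect_equal(res_c$objective, res$objective * c_scale, tolerance = 1e-9)
      expect_equal(res_c$selected, res$selected)
      expect_equal(res_c$terminal, res$terminal)
    }
  }
})

test_that("solutions satisfy conservation and capacity, and tampering is caught", {
  net <- random_network(6, 321)
  res <- solve_model(build_model(net, 3), milp_config(mip_gap = 0))
  expect_length(validate_solution(res, net, 3), 0)

  # flow into the sink never exceeds any global cap
  expect_lte(res$objective, max(compute_upper_bounds(net, 3)$k) + 1e-9)
  expect_lte(res$objective, sum(net$b) + 1e-9)

  bad <- res
  bad$terminal <- setdiff(seq_len(6), res$selected)[1]
  expect_true(any(grepl("terminal", validate_solution(bad, net, 3))))

  # perturbing one feature-feature arc breaks balance at exactly its two ends
  perturbed <- res
  ff <- which(perturbed$flow$from != "D" & perturbed$flow$to != "D" &
                perturbed$flow$to != "T")[1]
  perturbed$flow$flow[ff] <- perturbed$flow$flow[ff] + 1e-3
  v <- validate_solution(perturbed, net, 3)
  expect_equal(sum(grepl("balance", v)), 2)
})

test_that("the gap termination contract holds against the oracle", {
  set.seed(1234)
  for (rep in 1:6) {
    n <- sample(5:8, 1); P <- sample(2:4, 1)
    net <- random_network(n, rep + 40)
    opt <- exhaustive_oracle(net, P)$objective
    for (gam in c(0.05, 0.2)) {
      res <- solve_model(build_model(net, P), milp_config(mip_gap = gam))
      expect_gte(res$objective, opt / (1 + gam) - 1e-9)
      expect_lte(res$achieved_gap, gam + 1e-9)
    }
  }
})

test_that("a time limit returns the best incumbent with status time_limit", {
  net <- random_network(14, 5150)
  res <- solve_model(build_model(net, 7),
                     milp_config(mip_gap = 0, time_limit_seconds = 0))
  expect_equal(res$status, "time_limit")
  expect_length(res$selected, 7)
  expect_length(validate_solution(res, net, 7), 0)
})

test_that("results serialize to JSON", {
  net <- random_network(4, 8)
  res <- solve_model(build_model(net, 2), milp_config(mip_gap = 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_result_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$objective_bits, res$objective, tolerance = 1e-12)
  expect_equal(back$selected, res$selected_names)
  expect_equal(back$terminal, res$terminal_name)
})
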
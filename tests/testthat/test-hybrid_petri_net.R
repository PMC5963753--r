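# continuous Petri-net engine

test_that("validate_net reports structural defects by name", {
  empty <- hybrid_petri_net(
    data.frame(name = character(0), initial = numeric(0)),
    data.frame(name = character(0), type = character(0), k = numeric(0)),
    data.frame(place = character(0), transition = character(0),
               direction = character(0), weight = numeric(0)))
  expect_length(validate_net(empty), 0L)

  bad_arc <- chain_net()
  bad_arc$arcs <- rbind(bad_arc$arcs,
                        data.frame(place = "X", transition = "t",
                                   direction = "pre", weight = 1))
  v <- validate_net(bad_arc)
  expect_length(v, 1L)
  expect_match(v, "'X'")

  dup <- chain_net()
  dup$places <- rbind(dup$places, dup$places)   # duplicates A and B
  v2 <- validate_net(dup)
  expect_length(grep("duplicate place", v2), 2L)

  mm2 <- hybrid_petri_net(
    data.frame(name = c("A", "B", "C"), initial = c(1, 1, 0)),
    data.frame(name = "t", type = "michaelis_menten", k = NA,
               Vmax = 1, Km = 1),
    data.frame(place = c("A", "B", "C"), transition = "t",
               direction = c("pre", "pre", "post"), weight = 1))
  expect_match(validate_net(mm2), "exactly one pre-place")

  orphan <- hybrid_petri_net(
    data.frame(name = "A", initial = 1),
    data.frame(name = "t", type = "mass_action", k = 1),
    data.frame(place = "A", transition = "t", direction = "post", weight = 1))
  expect_match(validate_net(orphan), "not flagged as source")
})

test_that("transition_rate evaluates the rate laws and inhibition modes", {
  net <- chain_net(k = 1)
  expect_equal(transition_rate(net, c(A = 0, B = 0), "t"), 0)
  expect_equal(transition_rate(net, c(A = 5, B = 0), "t"), 5)

  mm <- hybrid_petri_net(
    data.frame(name = c("S", "P", "I"), initial = c(1, 0, 0)),
    data.frame(name = "t", type = "michaelis_menten", k = NA, Vmax = 2, Km = 1),
    data.frame(place = c("S", "P"), transition = "t",
               direction = c("pre", "post"), weight = 1),
    data.frame(place = "I", transition = "t", threshold = 2))
  expect_equal(transition_rate(mm, c(S = 1, P = 0, I = 0), "t"), 1)
  # hard switch: zero at/above threshold
  expect_equal(transition_rate(mm, c(S = 1, P = 0, I = 2), "t"), 0)
  expect_equal(transition_rate(mm, c(S = 1, P = 0, I = 1.99), "t"), 1)
  # smooth: threshold/(threshold+m) factor, and Hill sharpening -> hard
  expect_equal(transition_rate(mm, c(S = 1, P = 0, I = 2), "t", "smooth"), 0.5)
  expect_equal(
    transition_rate(mm, c(S = 1, P = 0, I = 4), "t", "smooth",
                    inhibition_hill = 200),
    transition_rate(mm, c(S = 1, P = 0, I = 4), "t", "hard"),
    tolerance = 1e-12)
  expect_equal(
    transition_rate(mm, c(S = 1, P = 0, I = 0.5), "t", "smooth",
                    inhibition_hill = 200),
    transition_rate(mm, c(S = 1, P = 0, I = 0.5), "t", "hard"),
    tolerance = 1e-12)

  # weight acts as a mass-action exponent
  sq <- chain_net()
  sq$arcs$weight[1] <- 2
  expect_equal(transition_rate(sq, c(A = 3, B = 0), "t"), 9)
})

test_that("simulate_net matches closed forms and honours inhibition", {
  still <- hybrid_petri_net(
    data.frame(name = c("A", "B"), initial = c(2, 7)),
    data.frame(name = character(0), type = character(0), k = numeric(0)),
    data.frame(place = character(0), transition = character(0),
               direction = character(0), weight = numeric(0)))
  tr <- simulate_net(still, 5)
  expect_true(all(tr$markings[, "A"] == 2))
  expect_true(all(tr$markings[, "B"] == 7))

  # A -> B closed form at several (k, a0)
  for (p in list(c(1, 5), c(0.3, 2), c(2.5, 1))) {
    tr <- simulate_net(chain_net(k = p[1], a0 = p[2]), 1)
    expect_equal(unname(tr$markings[nrow(tr$markings), "A"]),
                 p[2] * exp(-p[1]), tolerance = 1e-6)
    expect_equal(unname(tr$markings[nrow(tr$markings), "B"]),
                 p[2] * (1 - exp(-p[1])), tolerance = 1e-6)
  }

  # permanently inhibited transition: source place stays constant
  inh <- chain_net()
  inh$places <- rbind(inh$places, data.frame(name = "C", initial = 1))
  inh$inhibitory_arcs <- data.frame(place = "C", transition = "t", threshold = 1)
  tr2 <- simulate_net(inh, 10)
  expect_true(all(tr2$markings[, "A"] == 5))

  expect_error(simulate_net(chain_net(), -1), "horizon")
  bad <- chain_net(); bad$arcs$place[1] <- "nope"
  expect_error(simulate_net(bad, 1), "invalid net")
})

test_that("conservation, non-negativity and refinement invariants hold", {
  # closed 3-cycle conserves total marking
  cyc <- hybrid_petri_net(
    data.frame(name = c("A", "B", "C"), initial = c(4, 1, 0)),
    data.frame(name = c("t1", "t2", "t3"), type = "mass_action",
               k = c(1, 0.5, 2)),
    data.frame(place = c("A", "B", "B", "C", "C", "A"),
               transition = c("t1", "t1", "t2", "t2", "t3", "t3"),
               direction = rep(c("pre", "post"), 3), weight = 1))
  tr <- simulate_net(cyc, 20)
  totals <- rowSums(tr$markings)
  expect_lt(max(abs(totals - totals[1])), 1e-6)
  expect_true(all(tr$markings >= -1e-9))

  # packaged nets: non-negativity and step-refinement stability
  for (net in list(build_untreated(), build_treated())) {
    t1 <- simulate_net(net, 50)
    expect_true(all(t1$markings >= -1e-9))
    t2 <- simulate_net(net, 50, max_step = t1$solver$max_step / 2)
    expect_lt(max(abs(t1$markings - t2$markings)), 1e-5)
  }
})

test_that("simulation is deterministic and fold_change behaves", {
  net <- build_untreated()
  a <- simulate_net(net, 10)
  b <- simulate_net(net, 10)
  expect_identical(a$markings, b$markings)

  still <- hybrid_petri_net(
    data.frame(name = "A", initial = 3),
    data.frame(name = character(0), type = character(0), k = numeric(0)),
    data.frame(place = character(0), transition = character(0),
               direction = character(0), weight = numeric(0)))
  trs <- simulate_net(still, 2)
  expect_equal(fold_change(trs, "A", "final_over_initial"), 1)
  expect_equal(fold_change(trs, "A", "peak_over_initial"), 1)

  tr <- simulate_net(chain_net(), 1)
  expect_equal(fold_change(tr, "A", "final_over_initial"), exp(-1),
               tolerance = 1e-6)
  # monotone increasing series: peak equals final
  grow <- chain_net()
  grow$places$initial[2] <- 1
  trg <- simulate_net(grow, 1)
  expect_true(all(diff(trg$markings[, "B"]) >= 0))
  expect_equal(fold_change(trg, "B", "peak_over_initial"),
               fold_change(trg, "B", "final_over_initial"))

  trz <- simulate_net(chain_net(a0 = 5), 1)   # B starts at 0
  expect_warning(fc <- fold_change(trz, "B"), "undefined")
  expect_true(is.na(fc))
  expect_error(fold_change(tr, "nope"), "unknown place")
})

test_that("net specs round-trip through JSON", {
  net <- build_treated()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_net(net, tmp)
  back <- read_net(tmp)
  expect_length(validate_net(back), 0L)
  t1 <- simulate_net(net, 5)
  t2 <- simulate_net(back, 5)
  expect_equal(t1$markings, t2$markings)
})
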
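test_that("uniform layouts have the expected geometry", {
  base <- make_uniform_layout(120, 1150, 0.69)
  expect_equal(nrow(base), 120)              # 121 nodes
  expect_equal(sum(base$length_um), 138000)
  expect_length(node_positions(base), 121)
  expect_true(all(base$category == "normal"))

  one <- make_uniform_layout(1, 575, 0.69)
  expect_equal(nrow(one), 1)
  expect_length(node_positions(one), 2)

  fine <- make_uniform_layout(240, 575, 0.69)
  expect_equal(sum(fine$length_um), 138000)
  expect_length(node_positions(fine), 241)

  expect_error(make_uniform_layout(0, 1150, 0.69))
  expect_error(make_uniform_layout(10, -5, 0.69))
  expect_error(make_uniform_layout(10, 1150, 1.2))
})

test_that("remyelination halves nodal separation and conserves length", {
  base <- make_uniform_layout(120, 1150, 0.69)

  same <- remyelinate(base, 0, seed = 7)
  expect_equal(as.data.frame(same), as.data.frame(base),
               ignore_attr = c("p", "seed"))

  full <- remyelinate(base, 1, seed = 7)
  expect_equal(nrow(full), 240)
  expect_true(all(full$length_um == 575))
  expect_true(all(full$category == "remyelinated"))
  expect_length(node_positions(full), 241)

  for (p in c(0.25, 0.5, 0.75)) {
    r <- remyelinate(base, p, seed = 11)
    expect_equal(sum(r$length_um), 138000) # length conservation
    mask <- attr(r, "mask")
    expect_equal(sum(table(r$slot) == 2), sum(mask)) # pairs are atomic
    expect_true(all(r$length_um[r$category == "remyelinated"] == 575))
  }

  thin <- remyelinate(base, 0.5, seed = 3, remyelinated_g_ratio = 0.86)
  expect_setequal(unique(thin$g_ratio[thin$category == "remyelinated"]), 0.86)
  expect_setequal(unique(thin$g_ratio[thin$category == "normal"]), 0.69)

  expect_error(remyelinate(base, 1.5, seed = 1))
  expect_error(remyelinate(base, 0.5), "seed")
  expect_error(remyelinate(full, 0.5, seed = 1), "uniform")
})

test_that("remyelination masks are deterministic per seed and match binomial moments", {
  base <- make_uniform_layout(70, 1150, 0.69)
  a <- remyelinate(base, 0.5, seed = 123)
  b <- remyelinate(base, 0.5, seed = 123)
  expect_identical(attr(a, "mask"), attr(b, "mask"))

  draws <- axon_ensemble(0.5, n_models = 10000, master_seed = 5,
                         n_internodes = 70, keep_layouts = FALSE)
  counts <- draws$n_remyelinated
  # exact binomial moments: Np = 35, sqrt(Np(1-p)) = 4.183; allow 3 MC se
  sigma <- binomial_sigma(70, 0.5)
  expect_lt(abs(mean(counts) - 35), 3 * sigma / sqrt(10000))
  expect_lt(abs(sd(counts) - sigma), 3 * sigma / sqrt(2 * 10000))
})

test_that("semi-uniform layouts have a single transition", {
  semi <- make_semi_uniform(35, 35, "long_first")
  expect_equal(nrow(semi), 35 + 70)
  expect_equal(semi$length_um[1:35], rep(1150, 35))
  expect_equal(semi$length_um[36:105], rep(575, 70))
  expect_equal(count_transitions(semi),
               tibble::tibble(n_long_to_short = 1L, n_short_to_long = 0L),
               ignore_attr = TRUE)

  mirror <- make_semi_uniform(35, 35, "short_first")
  expect_equal(count_transitions(mirror)$n_short_to_long, 1L)
  expect_equal(count_transitions(mirror)$n_long_to_short, 0L)

  tiny <- make_semi_uniform(1, 1, "long_first")
  expect_equal(nrow(tiny), 3)
  expect_equal(sum(tiny$length_um), 2300)
  expect_equal(node_positions(tiny), c(0, 1150, 1725, 2300))

  expect_error(make_semi_uniform(0, 1))
})

test_that("node positions are cumulative sums ending at the total length", {
  u <- make_uniform_layout(3, 1150, 0.69)
  expect_equal(node_positions(u), c(0, 1150, 2300, 3450))
  r <- remyelinate(make_uniform_layout(20, 1150, 0.69), 0.4, seed = 2)
  pos <- node_positions(r)
  expect_equal(pos[length(pos)], sum(r$length_um))
  expect_true(all(diff(pos) > 0))
})

test_that("electrodes resolve to the paper protocol nodes at fixed physical positions", {
  base <- make_uniform_layout(120, 1150, 0.69)
  el <- resolve_electrodes(base, default_electrodes())
  expect_equal(el$node, c(11, 31, 101))

  full <- remyelinate(base, 1)
  el2 <- resolve_electrodes(full, default_electrodes())
  expect_equal(el2$node, c(21, 61, 201))

  expect_equal(resolve_electrodes(base, electrode_set(0, c(1150, 2300)))$node[1], 1)
  expect_error(resolve_electrodes(base, electrode_set(0, c(1150, 1e9))),
               "beyond")

  # recording separation is invariant across remyelinated draws
  for (p in c(0.25, 0.5, 0.75)) {
    for (s in 1:5) {
      r <- remyelinate(base, p, seed = s)
      e <- resolve_electrodes(r, default_electrodes())
      expect_equal(e$node_um[3] - e$node_um[2], 80500)
    }
  }
})

test_that("transition counting uses original-slot granularity", {
  base <- make_uniform_layout(10, 1150, 0.69)
  expect_equal(unlist(count_transitions(base)), c(n_long_to_short = 0L,
                                                  n_short_to_long = 0L))
  # mask L,S,L,S over 4 slots: boundaries L->S, S->L, L->S => (2, 1)
  four <- make_uniform_layout(4, 1150, 0.69)
  lsls <- remyelinate_exact(four, 2, slots = c(2, 4), seed = 1)
  expect_equal(attr(lsls, "mask"), c(FALSE, TRUE, FALSE, TRUE))
  tr <- count_transitions(lsls)
  expect_equal(tr$n_long_to_short, 2L)
  expect_equal(tr$n_short_to_long, 1L)

  # alternation: counts can differ by at most one on any layout
  for (s in 1:20) {
    r <- remyelinate(make_uniform_layout(70, 1150, 0.69), 0.5, seed = s)
    tr <- count_transitions(r)
    expect_lte(abs(tr$n_long_to_short - tr$n_short_to_long), 1L)
  }
})

test_that("restricted slot window counts only span-internal transitions", {
  base <- make_uniform_layout(10, 1150, 0.69)
  r <- remyelinate_exact(base, 2, slots = c(1, 10), seed = 1, p_outside = 0)
  # short slots sit at the ends; the interior window 2..9 is uniform
  expect_equal(count_transitions(r, slots = 2:9)$n_long_to_short, 0L)
  expect_equal(count_transitions(r)$n_long_to_short, 1L)
})

test_that("binomial sigma and average internode length follow their closed forms", {
  expect_equal(binomial_sigma(70, 0.5), sqrt(17.5))
  expect_equal(round(binomial_sigma(70, 0.5), 1), 4.2)
  expect_equal(binomial_sigma(70, 0), 0)
  expect_equal(binomial_sigma(4, 0.5), 1)

  expect_equal(average_internode_length(1150, 0), 1150)
  expect_equal(average_internode_length(1150, 1), 575)
  expect_equal(average_internode_length(1150, 0.5), 1150 / 1.5)
})

test_that("ensembles are reproducible and match the exact binomial law", {
  e1 <- axon_ensemble(0, n_models = 3, master_seed = 1, n_internodes = 12)
  expect_true(all(e1$n_remyelinated == 0))
  expect_equal(as.data.frame(e1$layout[[1]]), as.data.frame(e1$layout[[3]]),
               ignore_attr = c("p", "seed"))

  e2 <- axon_ensemble(0.5, n_models = 50, master_seed = 9, n_internodes = 70)
  e3 <- axon_ensemble(0.5, n_models = 50, master_seed = 9, n_internodes = 70)
  expect_identical(e2$n_remyelinated, e3$n_remyelinated)
  expect_identical(purrr::map(e2$layout, attr, "mask"),
                   purrr::map(e3$layout, attr, "mask"))

  # fraction of draws with 31..39 remyelinated of 70 at p = 0.5; the exact
  # binomial CDF gives 0.718
  big <- axon_ensemble(0.5, n_models = 2000, master_seed = 17,
                       n_internodes = 70, keep_layouts = FALSE)
  frac <- mean(big$n_remyelinated >= 31 & big$n_remyelinated <= 39)
  exact <- pbinom(39, 70, 0.5) - pbinom(30, 70, 0.5)
  expect_lt(abs(frac - exact), 3 * sqrt(exact * (1 - exact) / 2000))
})

test_that("exact-composition remyelination fixes the span count", {
  base <- make_uniform_layout(120, 1150, 0.69)
  span <- 31:100
  for (s in 1:10) {
    r <- remyelinate_exact(base, 35, slots = span, p_outside = 0.5, seed = s)
    expect_equal(sum(attr(r, "mask")[span]), 35)
    expect_equal(sum(r$length_um), 138000)
  }
  expect_error(remyelinate_exact(base, 200, seed = 1), "exceed")
})

test_that("layout CSV serialisation round-trips bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  r <- remyelinate(make_uniform_layout(20, 1150, 0.69), 0.4, seed = 42,
                   remyelinated_g_ratio = 0.86)
  write_axon_layout(r, path)
  back <- read_axon_layout(path)
  expect_identical(as.data.frame(back), as.data.frame(r))
  expect_identical(attr(back, "mask"), attr(r, "mask"))
  expect_equal(attr(back, "p"), 0.4)
  expect_equal(attr(back, "seed"), 42L)
})
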
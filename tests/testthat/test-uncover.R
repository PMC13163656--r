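sim <- sim_chain_panel(n = 4, cytb = 15, coi = 15, subs = 3, seed = 42)
panel <- sim$panel

test_that("a single uncovering step recognizes and removes via the main system", {
  step <- uncover_step(panel, removed = "org04", reference = "org04",
                       seed = 11)
  expect_identical(step$teaching_set, c("org01", "org02", "org03"))
  expect_true("concat" %in% names(step$reports))
  expect_identical(step$removed_after, step$reports$concat$recognized)
  expect_false(step$lost_recognition && length(step$removed_after) > 0)
  expect_error(uncover_step(panel, removed = "org01", reference = "org02"),
               "must be in the removed set")
  expect_error(uncover_step(panel, removed = names(panel),
                            reference = "org04"),
               "empty teaching set")
})

test_that("a 1-organism teaching set can only yield that organism", {
  step <- uncover_step(panel, removed = c("org02", "org03", "org04"),
                       reference = "org04", seed = 13,
                       allow_subthreshold = TRUE)
  fg <- step$reports$concat$foreground
  expect_identical(if (is.na(fg)) step$removed_after else fg, "org01")
})

test_that("sub-threshold continuation picks the best organism when nothing passes", {
  step <- uncover_step(panel, removed = "org04", reference = "org04",
                       seed = 11, threshold = 1.1, allow_subthreshold = TRUE)
  expect_true(step$subthreshold_used)
  expect_identical(step$removed_after,
                   step$reports$concat$below_threshold_top)
  step2 <- uncover_step(panel, removed = "org04", reference = "org04",
                        seed = 11, threshold = 1.1,
                        allow_subthreshold = FALSE)
  expect_true(step2$lost_recognition)
  expect_length(step2$removed_after, 0L)
})

test_that("a full run terminates, never removes twice, and shrinks the teaching set", {
  tr <- run_uncovering(panel, "org04", direction = "top_down", seed = 21)
  expect_s3_class(tr, "uncover_trace")
  expect_false(anyDuplicated(tr$visited) > 0)
  expect_true(all(tr$visited %in% setdiff(names(panel), "org04")))
  sizes <- vapply(tr$steps, function(s) length(s$teaching_set), integer(1))
  productive <- !vapply(tr$steps, function(s) s$lost_recognition, logical(1))
  if (length(sizes) > 1)
    expect_true(all(diff(sizes)[productive[-length(productive)]] < 0))
  expect_identical(tr$steps[[1]]$step_label, "1A")
  expect_identical(length(tr$homolog_fraction), length(tr$foregrounds))
})

test_that("a 2-organism panel gives the trivial one-step trace both ways", {
  p2 <- organism_panel(list(
    organism_record("a", "Aus aus", "MACDEF", "MTTWYKLH"),
    organism_record("b", "Bus bus", "MACDEY", "MTTWYKLQ")),
    ref = reference_lengths(6, 8))
  top <- run_uncovering(p2, "Aus aus", direction = "top_down", seed = 5,
                        allow_subthreshold = TRUE)
  bot <- run_uncovering(p2, "Bus bus", direction = "bottom_up", seed = 6)
  expect_identical(top$visited, "Bus bus")
  expect_identical(bot$visited, "Aus aus")
  expect_identical(top$steps[[1]]$step_label, "1A")
  expect_identical(bot$steps[[1]]$step_label, "1B")
  line <- build_virtual_line(top, bot)
  expect_identical(nrow(line$line), 2L)
  expect_identical(line$line$organism, c("Aus aus", "Bus bus"))
  expect_length(line$unplaced, 0L)
})

test_that("threshold organisms are detected by the 25%/50% crossing rules", {
  fake_trace <- function(direction, orgs, fracs, switch_after = integer()) {
    structure(list(direction = direction, apex = "apex", steps = list(),
                   foregrounds = orgs, visited = orgs,
                   homolog_fraction = setNames(fracs, orgs),
                   switch_after = switch_after),
              class = "uncover_trace")
  }
  orgs <- paste0("o", 1:8)
  # monotone ladder crossing 25% between positions 6 and 7
  tr <- fake_trace("top_down", orgs,
                   c(0.9, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  marks <- detect_threshold_organisms(tr)
  expect_identical(marks$organism[marks$marker == "**"], "o6")
  # all fractions above 25% -> no marker
  tr2 <- fake_trace("top_down", orgs, seq(0.9, 0.3, length.out = 8))
  expect_identical(nrow(detect_threshold_organisms(tr2)), 0L)
  # boundary: exactly 25% counts as 'at or above'
  tr3 <- fake_trace("top_down", c("a", "b", "c"), c(0.30, 0.25, 0.10))
  m3 <- detect_threshold_organisms(tr3)
  expect_identical(m3$organism[m3$marker == "**"], "b")
  # bottom-up: last fraction <= 50% before it first exceeds 50%
  tr4 <- fake_trace("bottom_up", c("x", "y", "z", "w"),
                    c(0.1, 0.3, 0.6, 0.9))
  m4 <- detect_threshold_organisms(tr4)
  expect_identical(m4$organism[m4$marker == "***"], "y")
  # reference-switch marker
  tr5 <- fake_trace("top_down", orgs,
                    c(0.9, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
                    switch_after = 3L)
  m5 <- detect_threshold_organisms(tr5)
  expect_identical(m5$organism[m5$marker == "*"], "o3")
})

test_that("the virtual line places every organism exactly once", {
  sim8 <- sim_chain_panel(n = 6, cytb = 15, coi = 15, subs = 3, seed = 77)
  top <- run_uncovering(sim8$panel, "org06", direction = "top_down",
                        seed = 31, allow_subthreshold = TRUE)
  bot <- run_uncovering(sim8$panel, "org01", direction = "bottom_up",
                        seed = 37)
  line <- build_virtual_line(top, bot)
  placed <- c(line$line$organism,
              unlist(strsplit(line$line$backgrounds[
                nzchar(line$line$backgrounds)], ";")))
  expect_false(anyDuplicated(placed) > 0)
  expect_setequal(c(placed, line$unplaced), names(sim8$panel))
  expect_identical(line$line$organism[1], "org06")  # top apex at position 0
  expect_identical(line$line$position[1], 0L)
})

test_that("rooted-tree counts follow the double factorial exactly", {
  expect_identical(count_rooted_trees(2), "1")
  expect_identical(count_rooted_trees(3), "3")
  expect_identical(count_rooted_trees(4), "15")   # enumerable by hand
  expect_identical(count_rooted_trees(5), "105")
  # exact arbitrary-precision value for 32 taxa: 61!! (43 digits)
  n32 <- count_rooted_trees(32)
  expect_identical(nchar(n32), 43L)
  expect_equal(signif(as.numeric(n32), 4), 1.782e42)
  # cross-check small cases against a double-precision double factorial
  for (n in 2:12) {
    expect_equal(as.numeric(count_rooted_trees(n)),
                 prod(seq(1, 2 * n - 3, by = 2)))
  }
  expect_error(count_rooted_trees(1), ">= 2")
})
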
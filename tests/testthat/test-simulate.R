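test_that("root simulation is seeded, stop-free, and sized", {
  tab <- codon_table()
  r1 <- simulate_root(50, tab, seed = 4)
  r2 <- simulate_root(50, tab, seed = 4)
  r3 <- simulate_root(50, tab, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_length(r1, 50L)
  expect_false(any(r1 %in% tab$stop_codons))
  expect_true(all(nchar(r1) == 3L))
})

test_that("lineage mutation applies exactly the recorded substitutions", {
  tab <- codon_table()
  parent <- simulate_root(40, tab, seed = 6)
  mut <- mutate_lineage(parent, n_subs = 10, kappa = 3, tab, seed = 7)
  expect_identical(nrow(mut$subs), 10L)
  # replay the substitution list on the parent -> child, exactly
  nt <- strsplit(paste(parent, collapse = ""), "")[[1]]
  for (i in seq_len(nrow(mut$subs))) {
    expect_identical(nt[mut$subs$site[i]], mut$subs$from[i])
    nt[mut$subs$site[i]] <- mut$subs$to[i]
  }
  expect_identical(paste(nt, collapse = ""),
                   paste(mut$codons, collapse = ""))
  expect_false(any(mut$codons %in% tab$stop_codons))
  # typing of each recorded substitution is consistent
  for (i in seq_len(nrow(mut$subs)))
    expect_identical(mut$subs$transition[i],
                     is_transition(mut$subs$from[i], mut$subs$to[i]))
})

test_that("zero substitutions copy the parent; infinite kappa forces transitions", {
  tab <- codon_table()
  parent <- simulate_root(30, tab, seed = 8)
  none <- mutate_lineage(parent, 0, 3, tab, seed = 9)
  expect_identical(none$codons, parent)
  expect_identical(nrow(none$subs), 0L)
  all_ts <- mutate_lineage(parent, 25, Inf, tab, seed = 10)
  expect_true(all(all_ts$subs$transition))
})

test_that("panels honour the topology with non-decreasing divergence along a chain", {
  # sequences long enough that reversions do not mask the divergence trend
  sim <- generate_panel(sim_config(40, 50, "chain:5", subs_per_branch = 3,
                                   kappa = 3, seed = 12))
  expect_length(sim$panel, 5L)
  expect_identical(names(sim$panel), sprintf("org%02d", 1:5))
  parents <- vapply(sim$truth, function(t)
    if (is.null(t$parent) || is.na(t$parent)) NA_character_ else t$parent,
    character(1))
  expect_identical(unname(parents[-1]), sprintf("org%02d", 1:4))
  root_seq <- paste0(sim$panel[["org01"]]$cytb_seq,
                     sim$panel[["org01"]]$coi_seq)
  divergence <- vapply(names(sim$panel), function(org) {
    s <- paste0(sim$panel[[org]]$cytb_seq, sim$panel[[org]]$coi_seq)
    sum(strsplit(s, "")[[1]] != strsplit(root_seq, "")[[1]])
  }, numeric(1))
  expect_true(all(diff(divergence) >= 0))
  # amino-acid changes cannot exceed the nucleotide substitutions separating
  # a node from the root
  expect_true(all(divergence <= 3 * (seq_along(divergence) - 1)))
})

test_that("identical-panel degenerate config is reproducible and flagged distinct-free", {
  cfg <- sim_config(10, 10, "chain:3", subs_per_branch = 0, seed = 14)
  sim <- generate_panel(cfg)
  seqs <- vapply(sim$panel, function(r) paste0(r$cytb_seq, r$coi_seq),
                 character(1))
  expect_identical(unname(seqs[1]), unname(seqs[2]))
  expect_identical(unname(seqs[2]), unname(seqs[3]))
})

test_that("panel generation guarantees protein-distinct organisms by default", {
  # small proteins + heavy transition bias: raw draws often collapse,
  # the generator must still deliver distinct translated sequences
  for (seed in c(1, 2, 3)) {
    sim <- generate_panel(sim_config(8, 8, "chain:6", subs_per_branch = 2,
                                     kappa = 10, seed = seed))
    seqs <- vapply(sim$panel, function(r) paste0(r$cytb_seq, r$coi_seq),
                   character(1))
    expect_false(anyDuplicated(seqs) > 0)
  }
})

test_that("single-transition-per-codon pairs classify as R or # only", {
  tab <- codon_table()
  root <- simulate_root(60, tab, seed = 15)
  # apply exactly one transition in each of 12 distinct codons, rejecting
  # those that would create stops
  nt <- strsplit(paste(root, collapse = ""), "")[[1]]
  partner <- c(A = "G", G = "A", C = "U", U = "C")
  set.seed(16)
  changed <- 0L
  for (codon_idx in sample(60, 30)) {
    if (changed >= 12L) break
    pos <- (codon_idx - 1L) * 3L + sample(3, 1)
    cand <- nt
    cand[pos] <- partner[[nt[pos]]]
    new_codon <- paste(cand[(codon_idx * 3 - 2):(codon_idx * 3)],
                       collapse = "")
    if (!new_codon %in% tab$stop_codons) {
      nt <- cand
      changed <- changed + 1L
    }
  }
  mutant <- apply(matrix(nt, nrow = 3), 2, paste, collapse = "")
  aa_root <- vapply(root, function(c) tab$sense_codons[[c]], character(1))
  aa_mut <- vapply(mutant, function(c) tab$sense_codons[[c]], character(1))
  cp <- count_positions(paste(aa_root, collapse = ""),
                        paste(aa_mut, collapse = ""), tab)
  expect_identical(cp$tv, 0L)
  expect_identical(cp$other, 0L)
  expect_identical(cp$r + cp$ts, 60L)
})

test_that("recorded transition fraction tracks kappa within binomial error", {
  tab <- codon_table()
  root <- simulate_root(500, tab, seed = 17)
  for (kappa in c(1, 3)) {
    mut <- mutate_lineage(root, 1000, kappa, tab, seed = 18 + kappa)
    frac <- mean(mut$subs$transition)
    p <- kappa / (kappa + 1)
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(frac - p), 3 * se)
  }
})
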
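toy_events <- function(parent, clone, donors) {
  muts <- call_mutations(align_global(parent, clone))
  classify_clone(muts, clone, parent, donors)
}

test_that("tally_spectrum counts PM substitutions cell by cell", {
  parent <- random_dna(120, seed = 201)
  bases <- c("A", "C", "G", "T")
  pc <- strsplit(parent, "")[[1]]
  donors <- c(d1 = paste(replace(pc, 1, setdiff(bases, pc[1])[1]),
                         collapse = ""))
  # three PMs with known cells: G>A, C>T, A>C at donor-free positions
  want <- list(c("G", "A"), c("C", "T"), c("A", "C"))
  cc <- pc
  ps <- integer(0)
  p <- 10
  for (w in want) {
    while (pc[p] != w[1] || p %in% ps) p <- p + 1
    cc[p] <- w[2]
    ps <- c(ps, p)
    p <- p + 15   # keep changes isolated
  }
  clone <- paste(cc, collapse = "")
  res <- toy_events(parent, clone, donors)
  spec <- tally_spectrum(res, "PM")
  expect_identical(spec$n, 3L)
  expect_identical(spec$table["G", "A"], 1L)
  expect_identical(spec$table["C", "T"], 1L)
  expect_identical(spec$table["A", "C"], 1L)
  expect_identical(sum(diag(spec$table)), 0L)
  expect_identical(spec$at_gc[["GC"]], 2L)
  expect_identical(spec$at_gc[["AT"]], 1L)
})

test_that("no PM events give an all-zero table", {
  parent <- random_dna(100, seed = 202)
  res <- toy_events(parent, parent,
                    c(d1 = paste(rev(strsplit(parent, "")[[1]]),
                                 collapse = "")))
  spec <- tally_spectrum(res, "PM")
  expect_identical(spec$n, 0L)
  expect_true(all(spec$table == 0L))
  expect_error(gc_to_at_transition_percent(spec), "undefined")
})

test_that("transition percentages reproduce printed fractions", {
  tab <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  tab["G", "A"] <- 7L; tab["C", "T"] <- 5L   # 12 transitions at G/C
  tab["A", "C"] <- 6L; tab["T", "G"] <- 7L   # 13 others; total 25
  p <- gc_to_at_transition_percent(tab)
  expect_identical(p$numerator, 12L)
  expect_identical(p$denominator, 25L)
  expect_identical(p$percent, 48L)

  tab2 <- matrix(0L, 4, 4, dimnames = dimnames(tab))
  tab2["G", "A"] <- 2L
  tab2["A", "T"] <- 16L
  p2 <- gc_to_at_transition_percent(tab2)
  expect_identical(p2$numerator, 2L)
  expect_identical(p2$denominator, 18L)
  expect_identical(p2$percent, 11L)
})

test_that("percent rounding is half-up", {
  tab <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  tab["G", "A"] <- 1L; tab["A", "C"] <- 7L   # 1/8 = 12.5% -> 13
  expect_identical(gc_to_at_transition_percent(tab)$percent, 13L)
})

test_that("spectrum percentages sum to ~100 and match the count total", {
  parent <- random_dna(300, seed = 204)
  db <- simulate_pseudogene_db(parent, donor_sim_params(3, 0.03, 3,
                                                        seed = 20))
  sim <- simulate_clone_set(parent, db,
                            hypermut_sim_params(n_clones = 4,
                                                event_mean = 6,
                                                gc_fraction = 0,
                                                seed = 21))
  res <- classify_clone_set(parent, sim$clones, db)
  spec <- tally_spectrum(res, "PM")
  rates <- category_rates(res, 4, 300)
  expect_identical(as.integer(rates$counts[["PM"]]), spec$n)
  tt <- spectrum_table(spec)
  expect_identical(nrow(tt), 12L)
  expect_lte(abs(sum(tt$percent) - 100), 12 * 0.5)
})

test_that("a generator spectrum of pure C>T is recovered exactly", {
  parent <- random_dna(300, seed = 205)
  spectrum <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  spectrum["C", "T"] <- 1
  db <- simulate_pseudogene_db(parent, donor_sim_params(2, 0.02, 3,
                                                        seed = 22))
  sim <- simulate_clone_set(parent, db,
                            hypermut_sim_params(n_clones = 3,
                                                event_mean = 5,
                                                gc_fraction = 0,
                                                spectrum = spectrum,
                                                pm_avoid_donor = TRUE,
                                                seed = 23))
  expect_true(all(sim$truth$ref == "C" & sim$truth$alt == "T"))
  res <- classify_clone_set(parent, sim$clones, db)
  spec <- tally_spectrum(res, "PM")
  other <- sum(spec$table) - spec$table["C", "T"]
  expect_identical(other, 0L)
  expect_gt(spec$table["C", "T"], 0L)
})

test_that("category rates normalize by clones and kilobases", {
  ev <- data.frame(category = rep(c("PM", "AMB", "GC"), c(6, 2, 1)))
  r <- category_rates(ev, n_clones = 3, clone_length = 500)
  expect_equal(unname(r$per_clone["PM"]), 2)
  expect_equal(unname(r$per_kb["PM"]), 6 / 1.5)
  r0 <- category_rates(ev[0, , drop = FALSE], 3, 500)
  expect_true(all(r0$counts == 0))
})
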
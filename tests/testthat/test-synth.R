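test_that("generators are byte-deterministic under a fixed seed", {
  parent <- random_dna(200, seed = 301)
  expect_identical(random_dna(50, seed = 4), random_dna(50, seed = 4))
  p1 <- simulate_pseudogene_db(parent, donor_sim_params(5, 0.02, seed = 7))
  p2 <- simulate_pseudogene_db(parent, donor_sim_params(5, 0.02, seed = 7))
  expect_identical(p1, p2)
  hp <- hypermut_sim_params(seed = 8)
  expect_identical(simulate_clone_set(parent, p1, hp),
                   simulate_clone_set(parent, p1, hp))
  arch <- load_architecture(system.file("extdata", "pqts_synthetic.yaml",
                                        package = "igtls"))
  bp <- bypass_sim_params(c(TLS_top = 0.5, error_free = 0.5),
                          n_products = 30, seed = 9)
  expect_identical(simulate_bypass_products(arch, bp),
                   simulate_bypass_products(arch, bp))
})

test_that("generator RNG use does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_dna(100, seed = 1))
  expect_identical(runif(1), before)
})

test_that("donor constraints are enforced and verifiable by recount", {
  parent <- random_dna(300, seed = 302)
  db <- simulate_pseudogene_db(parent,
                               donor_sim_params(3, 0.02, min_pair_diffs = 3,
                                                seed = 11))
  pc <- strsplit(parent, "")[[1]]
  chars <- lapply(db, function(d) strsplit(d, "")[[1]])
  for (dc in chars) expect_gte(sum(dc != pc), 1L)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_gte(sum(chars[[i]] != chars[[j]]), 3L)
    }
  }
  expect_error(donor_sim_params(3, 0), "divergence")
  expect_error(simulate_pseudogene_db(random_dna(50, seed = 1),
                                      donor_sim_params(2, 0.05)),
               "at least 100")
})

test_that("zero event mean gives clones identical to the parent", {
  parent <- random_dna(200, seed = 303)
  db <- simulate_pseudogene_db(parent, donor_sim_params(2, 0.02, seed = 1))
  sim <- simulate_clone_set(parent, db,
                            hypermut_sim_params(event_mean = 0, seed = 2))
  expect_true(all(sim$clones == parent))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("truth events reconstruct each clone before sequencing error", {
  parent <- random_dna(400, seed = 304)
  db <- simulate_pseudogene_db(parent, donor_sim_params(4, 0.03, seed = 3))
  sim <- simulate_clone_set(parent, db,
                            hypermut_sim_params(n_clones = 5,
                                                event_mean = 7,
                                                gc_fraction = 0.3,
                                                seed = 5))
  for (id in names(sim$clones)) {
    expect_identical(apply_truth(parent, db, sim$truth, id),
                     unname(sim$clones[id]), info = id)
  }
  # with sequencing error the reconstruction differs exactly at the
  # recorded error positions
  sim_e <- simulate_clone_set(parent, db,
                              hypermut_sim_params(n_clones = 3,
                                                  event_mean = 5,
                                                  error_rate = 0.01,
                                                  seed = 6))
  for (id in names(sim_e$clones)) {
    rebuilt <- strsplit(apply_truth(parent, db, sim_e$truth, id), "")[[1]]
    got <- strsplit(sim_e$clones[[id]], "")[[1]]
    err <- sim_e$errors[sim_e$errors$clone_id == id, ]
    expect_identical(which(rebuilt != got), err$pos + 1L)
  }
})

test_that("a pure-GC simulation under identifiability is fully recovered", {
  parent <- random_dna(400, seed = 305)
  db <- simulate_pseudogene_db(parent,
                               donor_sim_params(4, 0.03, min_pair_diffs = 3,
                                                seed = 13))
  sim <- simulate_clone_set(parent, db,
                            hypermut_sim_params(n_clones = 4,
                                                event_mean = 3,
                                                gc_fraction = 1,
                                                gc_min_diffs = 2,
                                                min_flank = 10,
                                                seed = 14))
  expect_true(all(sim$truth$category == "GC"))
  expect_true(all(sim$truth$n_diffs >= 2))
  res <- classify_clone_set(parent, sim$clones, db)
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    hit <- res$events$clone_id == tr$clone_id &
      res$events$category == "GC" &
      res$events$donor_id == tr$donor_id &
      res$events$tract_start <= tr$tract_start &
      res$events$tract_end >= tr$tract_end
    expect_true(any(hit), info = paste("truth row", r))
  }
})
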
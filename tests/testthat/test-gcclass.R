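# Construct a co-linear parent/donor pair differing at chosen positions.
make_donor <- function(parent, at, alts = NULL) {
  pc <- strsplit(parent, "")[[1]]
  for (i in seq_along(at)) {
    p <- at[i]
    pc[p] <- if (is.null(alts)) {
      setdiff(c("A", "C", "G", "T"), pc[p])[1]
    } else alts[i]
  }
  paste(pc, collapse = "")
}

test_that("a donor-matching mutation yields one maximal donor string", {
  parent <- random_dna(60, seed = 101)
  donor <- make_donor(parent, 31)            # single diff at 0-based 30
  clone <- make_donor(parent, 31)            # clone copied it
  muts <- call_mutations(align_global(parent, clone))
  expect_identical(muts$pos, 30L)
  prof <- alignment_profile(align_global(parent, clone))
  dprofs <- donor_profiles(parent, c(d1 = donor))
  m <- find_donor_matches(muts[1, ], prof, dprofs, parent)
  expect_identical(nrow(m), 1L)
  # donor and clone are identical end to end, so the maximal string is
  # the whole parent
  expect_identical(m$start, 0L)
  expect_identical(m$end, 60L)
  expect_identical(m$length, 60L)
  # a length bound above the sequence length leaves no match
  m2 <- find_donor_matches(muts[1, ], prof, dprofs, parent,
                           classifier_params(min_donor_string = 61))
  expect_identical(nrow(m2), 0L)
})

test_that("a mutation matching no donor has no donor string", {
  parent <- random_dna(60, seed = 102)
  donor <- make_donor(parent, 31)
  # clone carries a different alt at the same position
  bases <- c("A", "C", "G", "T")
  p31 <- substr(parent, 31, 31)
  d31 <- substr(donor, 31, 31)
  other <- setdiff(bases, c(p31, d31))[1]
  clone <- make_donor(parent, 31, other)
  muts <- call_mutations(align_global(parent, clone))
  prof <- alignment_profile(align_global(parent, clone))
  dprofs <- donor_profiles(parent, c(d1 = donor))
  expect_identical(nrow(find_donor_matches(muts[1, ], prof, dprofs,
                                           parent)), 0L)
})

test_that("two donor diffs copied together form one GC event", {
  parent <- random_dna(80, seed = 103)
  donor <- make_donor(parent, c(31, 46))     # diffs 15 nt apart
  clone <- make_donor(parent, c(31, 46))
  muts <- call_mutations(align_global(parent, clone))
  res <- classify_clone(muts, clone, parent, c(dA = donor))
  expect_identical(nrow(res$events), 1L)
  expect_identical(res$events$category, "GC")
  expect_identical(res$events$donor_id, "dA")
  expect_identical(res$events$n_members, 2L)
  # tract covers both member positions
  expect_lte(res$events$tract_start, 30L)
  expect_gte(res$events$tract_end, 46L)

  # only one diff copied -> ambiguous
  clone1 <- make_donor(parent, 31)
  muts1 <- call_mutations(align_global(parent, clone1))
  res1 <- classify_clone(muts1, clone1, parent, c(dA = donor))
  expect_identical(res1$events$category, "AMB")
  expect_identical(res1$events$donor_id, "dA")
})

test_that("mutations matching no donor are independent PM events", {
  parent <- random_dna(80, seed = 104)
  donors <- c(dA = make_donor(parent, 11))
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(parent, "")[[1]]
  for (p in c(30, 60)) {
    avoid <- c(cc[p], strsplit(donors[["dA"]], "")[[1]][p])
    cc[p] <- setdiff(bases, avoid)[1]
  }
  clone <- paste(cc, collapse = "")
  muts <- call_mutations(align_global(parent, clone))
  res <- classify_clone(muts, clone, parent, donors)
  expect_identical(res$events$category, c("PM", "PM"))
  expect_identical(nrow(res$events), 2L)
})

test_that("empty input classifies to an empty partition", {
  parent <- random_dna(60, seed = 105)
  res <- classify_clone(call_mutations(align_global(parent, parent)),
                        parent, parent, c(d1 = make_donor(parent, 10)))
  expect_identical(nrow(res$events), 0L)
})

test_that("events always partition the called mutations", {
  set.seed(2024)
  for (k in 1:30) {
    inst <- random_instance()
    muts <- call_mutations(align_global(inst$parent, inst$clone))
    res <- classify_clone(muts, inst$clone, inst$parent, inst$donors)
    expect_identical(sum(res$events$n_members), nrow(muts))
    expect_false(anyNA(res$mutations$event_id))
    expect_identical(sort(unique(res$mutations$event_id)),
                     sort(res$events$event_id))
    # PM and AMB events are singletons; GC events have >= 2 members
    expect_true(all(res$events$n_members[res$events$category != "GC"] == 1L))
    expect_true(all(res$events$n_members[res$events$category == "GC"] >= 2L))
  }
})

test_that("classification matches the brute-force enumeration oracle", {
  set.seed(515)
  for (k in 1:60) {
    inst <- random_instance(n = sample(100:200, 1),
                            n_donors = sample(2:5, 1))
    muts <- call_mutations(align_global(inst$parent, inst$clone))
    res <- classify_clone(muts, inst$clone, inst$parent, inst$donors)
    orc <- oracle_classify(inst$parent, inst$clone, inst$donors)
    got <- stats::setNames(
      res$events$category[match(res$mutations$event_id,
                                res$events$event_id)],
      as.character(res$mutations$pos + 1L))
    expect_identical(got[names(orc$per_mutation)], orc$per_mutation,
                     info = paste("instance", k))
  }
})

test_that("raising the length bound only moves events toward PM", {
  set.seed(616)
  for (k in 1:15) {
    inst <- random_instance()
    muts <- call_mutations(align_global(inst$parent, inst$clone))
    cat_at <- function(L) {
      res <- classify_clone(muts, inst$clone, inst$parent, inst$donors,
                            classifier_params(min_donor_string = L))
      stats::setNames(
        res$events$category[match(res$mutations$event_id,
                                  res$events$event_id)],
        as.character(res$mutations$pos))
    }
    lo <- cat_at(10L); hi <- cat_at(25L)
    # every PM at L=10 is still PM at L=25
    expect_true(all(hi[names(lo)[lo == "PM"]] == "PM"))
  }
})

test_that("classification is invariant to donor file order", {
  set.seed(717)
  inst <- random_instance(n_donors = 4)
  muts <- call_mutations(align_global(inst$parent, inst$clone))
  r1 <- classify_clone(muts, inst$clone, inst$parent, inst$donors)
  r2 <- classify_clone(muts, inst$clone, inst$parent, rev(inst$donors))
  expect_identical(r1$events$category, r2$events$category)
  expect_identical(r1$events$donor_id, r2$events$donor_id)
  expect_identical(r1$mutations$event_id, r2$mutations$event_id)
})

test_that("a mutation outside the parent is a contract violation", {
  parent <- random_dna(60, seed = 106)
  muts <- data.frame(kind = "substitution", pos = 400L, ref = "A",
                     alt = "C")
  expect_error(
    classify_clone(muts, parent, parent, c(d1 = make_donor(parent, 10))),
    "outside the parent")
})
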
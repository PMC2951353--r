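pqts_arch <- function() {
  load_architecture(system.file("extdata", "pqts_synthetic.yaml",
                                package = "igtls"))
}
pqto_arch <- function() {
  load_architecture(system.file("extdata", "pqto_synthetic.yaml",
                                package = "igtls"))
}

# Edit the reference at a 0-based site interval.
edit_site <- function(ref, site, repl) {
  paste0(substr(ref, 1, site[1]), repl,
         substr(ref, site[2] + 1, nchar(ref)))
}

test_that("a marker-form product is error-free bypass", {
  arch <- pqts_arch()
  call <- classify_pqts(arch$reference, arch)
  expect_identical(call$mode, "error_free")
  expect_identical(call$site_top, "GC")
  expect_identical(call$site_bottom, "GC")
  expect_identical(call$del_len, 0L)
})

test_that("accurate TLS on either strand is decoded from the site read", {
  arch <- pqts_arch()
  # top-strand lesion: accurate AA insertion reads TT at the top site
  top <- edit_site(arch$reference, arch$top_site, "TT")
  call <- classify_pqts(top, arch)
  expect_identical(call$mode, "TLS_top")
  expect_true(call$accurate)
  expect_identical(call$base_3T, "A")
  expect_identical(call$base_5T, "A")
  # bottom-strand lesion: accurate AA insertion reads AA directly
  bottom <- edit_site(arch$reference, arch$bottom_site, "AA")
  call <- classify_pqts(bottom, arch)
  expect_identical(call$mode, "TLS_bottom")
  expect_true(call$accurate)
  expect_identical(call$base_3T, "A")
  expect_identical(call$base_5T, "A")
  # inaccurate TLS: a non-AA insertion clears the accurate flag
  call <- classify_pqts(edit_site(arch$reference, arch$top_site, "TG"),
                        arch)
  expect_identical(call$mode, "TLS_top")
  expect_false(call$accurate)
})

test_that("a deletion covering a pQTs site is deletion-associated TLS", {
  arch <- pqts_arch()
  s <- arch$top_site
  ref <- arch$reference
  # remove the site dinucleotide plus one base
  prod <- paste0(substr(ref, 1, s[1] - 1), substr(ref, s[2] + 1, nchar(ref)))
  call <- classify_pqts(prod, arch)
  expect_identical(call$mode, "TLS_top")
  expect_identical(call$site_top, "del")
  expect_identical(call$del_len, 3L)
  expect_identical(call$base_3T, "del")
  expect_identical(call$base_5T, "del")
})

test_that("non-marker at both sites is flagged other, not forced", {
  arch <- pqts_arch()
  prod <- edit_site(edit_site(arch$reference, arch$top_site, "TT"),
                    arch$bottom_site, "AA")
  expect_identical(classify_pqts(prod, arch)$mode, "other")
})

test_that("classification is invariant to read orientation", {
  arch <- pqts_arch()
  prod <- edit_site(arch$reference, arch$top_site, "TT")
  fwd <- classify_pqts(prod, arch)
  rev <- classify_pqts(revcomp(prod), arch)
  expect_identical(fwd$mode, rev$mode)
  expect_identical(fwd$base_3T, rev$base_3T)
  expect_identical(fwd$base_5T, rev$base_5T)
})

test_that("a low-identity read is unclassifiable and excluded", {
  arch <- pqts_arch()
  junk <- random_dna(100, seed = 900)
  call <- classify_pqts(junk, arch)
  expect_identical(call$mode, "unclassifiable")
  calls <- rbind(call, classify_pqts(arch$reference, arch))
  fr <- tls_fraction(calls)
  expect_identical(fr$n_classifiable, 1L)
  expect_identical(fr$n_unclassifiable, 1L)
})

test_that("pQTo products are TLS or deletion-associated, never error-free", {
  arch <- pqto_arch()
  # template TT at the site: accurate-by-template TLS
  call <- classify_pqto(arch$reference, arch)
  expect_identical(call$mode, "TLS")
  expect_true(call$accurate)
  s <- arch$top_site
  ref <- arch$reference
  # 2-nt deletion at the site: the deletion-associated class
  del2 <- paste0(substr(ref, 1, s[1]), substr(ref, s[2] + 1, nchar(ref)))
  call <- classify_pqto(del2, arch)
  expect_identical(call$mode, "deletion")
  expect_identical(call$del_len, 2L)
  # 1-nt deletion stays below the >= 2 threshold: still TLS
  del1 <- paste0(substr(ref, 1, s[1]), substr(ref, s[1] + 2, nchar(ref)))
  call <- classify_pqto(del1, arch)
  expect_identical(call$mode, "TLS")
  expect_identical(call$del_len, 1L)
  # the marker-form read cannot occur, but error_free is never emitted:
  gc_site <- edit_site(ref, s, "GC")
  expect_false(classify_pqto(gc_site, arch)$mode == "error_free")
})

test_that("mode fractions sum to 100 over classifiable reads", {
  arch <- pqts_arch()
  prods <- c(a = arch$reference,
             b = edit_site(arch$reference, arch$top_site, "TT"),
             c = edit_site(arch$reference, arch$bottom_site, "AA"),
             d = arch$reference)
  calls <- classify_products(prods, arch)
  fr <- tls_fraction(calls)
  expect_equal(sum(fr$percent), 100)
  expect_equal(fr$tls_percent, 50)
  # all error-free -> exactly 0% TLS
  fr0 <- tls_fraction(classify_products(c(x = arch$reference,
                                          y = arch$reference), arch))
  expect_identical(fr0$tls_percent, 0)
  expect_error(tls_fraction(calls[0, ]), "no classifiable")
})

test_that("incorporation profiles are per-position frequencies over TLS", {
  arch <- pqts_arch()
  prods <- c(a = edit_site(arch$reference, arch$top_site, "TT"),
             b = edit_site(arch$reference, arch$top_site, "TT"),
             c = edit_site(arch$reference, arch$top_site, "TG"),
             ef = arch$reference)
  calls <- classify_products(prods, arch)
  prof <- incorporation_profile(calls)
  expect_equal(colSums(prof), c(`3T` = 1, `5T` = 1, `+1` = 1, `+2` = 1))
  # 3'T: read TT and TG both give base T at s+1 -> inserted A... decode:
  # TT -> (A, A); TG -> (C, A): 3'T is the complement of the second base
  expect_equal(prof["A", "3T"], 2 / 3)
  expect_equal(prof["C", "3T"], 1 / 3)
  expect_equal(prof["A", "5T"], 1)
  # error-free reads never enter the profile
  expect_error(incorporation_profile(calls[calls$mode == "error_free", ]),
               "no TLS")
  # a single TLS call gives a one-hot profile
  single <- incorporation_profile(calls[1, ])
  expect_true(all(single %in% c(0, 1)))
})

test_that("synthetic bypass products are recovered mode-exactly", {
  arch <- pqts_arch()
  sim <- simulate_bypass_products(
    arch, bypass_sim_params(c(TLS_top = 0.35, TLS_bottom = 0.15,
                              error_free = 0.5),
                            n_products = 120, seed = 55))
  calls <- classify_products(sim$products, arch)
  expect_identical(calls$mode, sim$truth$mode)
  tls <- calls$mode %in% c("TLS_top", "TLS_bottom")
  expect_identical(calls$base_3T[tls], sim$truth$base_3T[tls])
  expect_identical(calls$base_5T[tls], sim$truth$base_5T[tls])

  arch2 <- pqto_arch()
  sim2 <- simulate_bypass_products(
    arch2, bypass_sim_params(c(TLS = 0.6, deletion = 0.4),
                             n_products = 80, seed = 56))
  calls2 <- classify_products(sim2$products, arch2)
  expect_identical(calls2$mode, sim2$truth$mode)
  del <- calls2$mode == "deletion"
  expect_identical(calls2$del_len[del], sim2$truth$del_len[del])
})

test_that("an all-error-free mixture reproduces the reference exactly", {
  arch <- pqts_arch()
  sim <- simulate_bypass_products(
    arch, bypass_sim_params(c(error_free = 1), n_products = 10, seed = 57))
  expect_true(all(sim$products == arch$reference))
  expect_error(
    simulate_bypass_products(
      pqto_arch(), bypass_sim_params(c(error_free = 1), n_products = 2)),
    "cannot generate")
})
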
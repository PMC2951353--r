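# Helpers shared by the bypass classifiers ---------------------------------

# Contiguous run of deleted parent positions (profile entries "") that
# intersects the 0-based half-open interval `site`; returns c(start, len)
# in 0-based coordinates, or c(NA, 0) if none.
.deletion_run <- function(prof, site) {
  idx <- (site[1L] + 1L):site[2L]
  hit <- idx[prof[idx] == ""]
  if (length(hit) == 0L) return(c(NA_integer_, 0L))
  i <- hit[1L]
  l <- i
  while (l > 1L && prof[l - 1L] == "") l <- l - 1L
  r <- i
  while (r < length(prof) && prof[r + 1L] == "") r <- r + 1L
  c(l - 1L, r - l + 1L)
}

# Base read by the product at 0-based parent coordinate `coord`:
# "del" if deleted, first base of the profile entry otherwise, NA if the
# coordinate falls outside the reference.
.read_base <- function(prof, coord) {
  if (coord < 0L || coord >= length(prof)) return(NA_character_)
  e <- prof[coord + 1L]
  if (e == "") "del" else substr(e, 1L, 1L)
}

.comp_base <- function(b) {
  if (is.na(b) || b == "del") return(b)
  chartr("ACGTN", "TGCAN", b)
}

# Bases inserted opposite the lesion, in synthesis order (3'T, 5'T, +1,
# +2).  For a top-strand lesion the nascent strand is the bottom strand:
# synthesis runs right to left in reference coordinates and the inserted
# base is the complement of the product read.  For a bottom-strand
# lesion the nascent strand is the top strand, read left to right as-is.
.incorporation_bases <- function(prof, site, strand) {
  s <- site[1L]
  if (strand == "top") {
    coords <- c(s + 1L, s, s - 1L, s - 2L)
    vapply(coords, function(c_) .comp_base(.read_base(prof, c_)),
           character(1))
  } else {
    coords <- c(s, s + 1L, s + 2L, s + 3L)
    vapply(coords, function(c_) .read_base(prof, c_), character(1))
  }
}

# A deletion's position is only defined up to the placements that give
# the same product sequence (a gap slides freely through repeats).
# Called deletions are left-normalized; for lesion-site logic the
# deletion must be judged over its whole equivalence range and then
# placed canonically: at the placement maximizing overlap with a lesion
# site (tie-break: covering the 3' T, then leftmost).  Without this, a
# deletion made at the lesion could slide off the site through an
# adjacent repeat and be missed.
.reposition_deletions <- function(pc, muts, sites) {
  n <- length(pc)
  for (r in which(muts$kind == "deletion")) {
    L <- nchar(muts$ref[r])
    p0 <- muts$pos[r]
    pmax <- p0
    while (pmax + L + 1L <= n && pc[pmax + 1L] == pc[pmax + L + 1L]) {
      pmax <- pmax + 1L
    }
    cand <- p0:pmax
    best <- p0; best_key <- c(0, 0, -p0)
    for (st in sites) {
      s <- st$site[1L]; e <- st$site[2L]
      ov <- pmin(cand + L, e) - pmax(cand, s)
      ov[ov < 0] <- 0
      covers_tp <- as.numeric(cand <= st$tp & st$tp < cand + L)
      for (i in seq_along(cand)) {
        key <- c(ov[i], covers_tp[i], -cand[i])
        if (key[1L] > best_key[1L] ||
            (key[1L] == best_key[1L] && key[2L] > best_key[2L]) ||
            (key[1L] == best_key[1L] && key[2L] == best_key[2L] &&
             key[3L] > best_key[3L])) {
          best <- cand[i]; best_key <- key
        }
      }
    }
    if (best != p0) {
      muts$pos[r] <- best
      muts$ref[r] <- paste(pc[(best + 1L):(best + L)], collapse = "")
    }
  }
  muts
}

# Site-aware product profile: mutation calls with deletions repositioned
# toward the lesion sites, collapsed to per-reference-position entries.
.bypass_profile <- function(arch, aln) {
  pc <- strsplit(arch$reference, "")[[1L]]
  sites <- list(list(site = arch$top_site, tp = arch$top_site[1L] + 1L))
  if (arch$arrangement == "staggered") {
    sites <- c(sites, list(list(site = arch$bottom_site,
                                tp = arch$bottom_site[1L])))
  }
  muts <- .reposition_deletions(pc, call_mutations(aln), sites)
  profile_from_mutations(pc, muts)
}

# A single missing base inside a lesion-site dinucleotide cannot be
# attributed to one T or the other from sequence alone; by convention it
# is scored at the 3' T (the first position synthesized past the
# lesion).  `three_prime_at` is the 0-based coordinate of the 3' T.
.normalize_site_del <- function(prof, site, three_prime_at) {
  idx <- (site[1L] + 1L):site[2L]
  del_in <- idx[prof[idx] == ""]
  if (length(del_in) != 1L) return(prof)
  p <- del_in
  run_contained <- (p == 1L || prof[p - 1L] != "") &&
    (p == length(prof) || prof[p + 1L] != "")
  tp <- three_prime_at + 1L
  if (run_contained && p != tp && tp %in% idx && nchar(prof[tp]) == 1L) {
    prof[p] <- prof[tp]
    prof[tp] <- ""
  }
  prof
}

# Orient a product read to the reference strand: align both orientations
# and keep the higher-scoring one (ties broken toward forward).
.canonicalize <- function(product, arch, aln_params) {
  fwd <- align_global(arch$reference, product, aln_params)
  rev <- align_global(arch$reference, revcomp(product), aln_params)
  if (rev$score > fwd$score) rev else fwd
}

# Fraction of identical positions outside the lesion sites (and outside
# any deletion run touching a site); low identity marks an artifactual
# read that must not enter the fractions.
.outside_identity <- function(prof, parent_chars, arch) {
  n <- length(prof)
  excl <- rep(FALSE, n)
  for (site in list(arch$top_site, arch$bottom_site)) {
    excl[(site[1L] + 1L):site[2L]] <- TRUE
    run <- .deletion_run(prof, site)
    if (run[2L] > 0L) excl[(run[1L] + 1L):(run[1L] + run[2L])] <- TRUE
  }
  keep <- which(!excl)
  if (length(keep) == 0L) return(1)
  mean(prof[keep] == parent_chars[keep])
}

.empty_call <- function(read_id, mode) {
  data.frame(read_id = read_id, mode = mode,
             site_top = NA_character_, site_bottom = NA_character_,
             base_3T = NA_character_, base_5T = NA_character_,
             base_p1 = NA_character_, base_p2 = NA_character_,
             del_len = NA_integer_, accurate = NA,
             stringsAsFactors = FALSE)
}

#' Classify one replicated product of a staggered-lesion (pQTs-like) plasmid
#'
#' The staggered construct places one T-T (6-4) photoproduct on each
#' strand, 28 nucleotides apart, each opposite a `GC` marker
#' dinucleotide.  The mode of bypass is decided from the two site
#' dinucleotides as read from the product: marker at both sites means
#' error-free bypass by template switching; a non-marker (or deleted)
#' site with marker at the other means TLS past the lesion on that
#' site's strand, with the inserted bases recorded at the 3' T, the 5' T
#' and the next two template bases; non-marker at both sites is flagged
#' `other` for manual review rather than forced into a mode.  A deletion
#' touching a site makes that site read `del`.  Reads are first oriented
#' to the reference strand; reads below `min_identity` outside the
#' lesion region are returned as `unclassifiable`.
#'
#' @param product Product DNA sequence (either orientation).
#' @param arch A [lesion_architecture()] with `arrangement = "staggered"`.
#' @param read_id Read id recorded in the call.
#' @param aln_params [align_params()] for the product-to-reference
#'   alignment.
#' @param min_identity Identity threshold outside the lesion region
#'   (default 0.9).
#' @return A one-row data frame: `read_id`, `mode` (`TLS_top`,
#'   `TLS_bottom`, `error_free`, `other`, `unclassifiable`), the two
#'   site reads, incorporation bases `base_3T`, `base_5T`, `base_p1`,
#'   `base_p2`, `del_len`, and `accurate` (inserted dinucleotide equals
#'   the accurate-insertion dinucleotide).
#' @export
classify_pqts <- function(product, arch, read_id = "read",
                          aln_params = align_params(),
                          min_identity = 0.9) {
  stopifnot(inherits(arch, "lesion_architecture"))
  if (arch$arrangement != "staggered") {
    stop("classify_pqts requires a staggered architecture", call. = FALSE)
  }
  aln <- .canonicalize(product, arch, aln_params)
  prof <- .bypass_profile(arch, aln)
  pc <- strsplit(arch$reference, "")[[1L]]
  if (.outside_identity(prof, pc, arch) < min_identity) {
    return(.empty_call(read_id, "unclassifiable"))
  }
  prof <- .normalize_site_del(prof, arch$top_site, arch$top_site[1L] + 1L)
  prof <- .normalize_site_del(prof, arch$bottom_site, arch$bottom_site[1L])
  site_read <- function(site) {
    paste(prof[(site[1L] + 1L):site[2L]], collapse = "")
  }
  top <- site_read(arch$top_site)
  bottom <- site_read(arch$bottom_site)
  top_run <- .deletion_run(prof, arch$top_site)
  bottom_run <- .deletion_run(prof, arch$bottom_site)
  top_marker <- (top == arch$marker) && top_run[2L] == 0L
  bottom_marker <- (bottom == arch$marker) && bottom_run[2L] == 0L
  call <- .empty_call(read_id, "other")
  call$site_top <- if (top_run[2L] > 0L) "del" else top
  call$site_bottom <- if (bottom_run[2L] > 0L) "del" else bottom
  call$del_len <- 0L
  if (top_marker && bottom_marker) {
    call$mode <- "error_free"
    return(call)
  }
  if (!top_marker && bottom_marker) {
    call$mode <- "TLS_top"
    bases <- .incorporation_bases(prof, arch$top_site, "top")
    call$del_len <- top_run[2L]
  } else if (top_marker && !bottom_marker) {
    call$mode <- "TLS_bottom"
    bases <- .incorporation_bases(prof, arch$bottom_site, "bottom")
    call$del_len <- bottom_run[2L]
  } else {
    call$mode <- "other"
    call$del_len <- max(top_run[2L], bottom_run[2L])
    return(call)
  }
  call$base_3T <- bases[1L]; call$base_5T <- bases[2L]
  call$base_p1 <- bases[3L]; call$base_p2 <- bases[4L]
  call$accurate <- identical(paste0(bases[1L], bases[2L]), arch$accurate)
  call
}

#' Classify one replicated product of an opposing-lesion (pQTo-like) plasmid
#'
#' In the opposing arrangement the two lesions occupy the same site on
#' opposite strands, so template switching cannot yield a replicated
#' copy: every product arises by TLS or carries a deletion across the
#' site.  A full-length site is called `TLS` with the read bases
#' recorded; a deletion of two or more nucleotides covering the site is
#' the deletion-associated class (`deletion`); a single-nucleotide
#' deletion stays `TLS` (below the >= 2 nt threshold) with the deleted
#' position recorded.  The call is never `error_free`.
#'
#' @inheritParams classify_pqts
#' @param arch A [lesion_architecture()] with `arrangement = "opposing"`.
#' @return A one-row data frame as in [classify_pqts()], with `mode`
#'   one of `TLS`, `deletion`, `unclassifiable`.  `accurate` is `TRUE`
#'   when the site reads the template `TT` (accurate insertion opposite
#'   the top-strand lesion) or the accurate dinucleotide itself
#'   (accurate insertion opposite the bottom-strand lesion).
#' @export
classify_pqto <- function(product, arch, read_id = "read",
                          aln_params = align_params(),
                          min_identity = 0.9) {
  stopifnot(inherits(arch, "lesion_architecture"))
  if (arch$arrangement != "opposing") {
    stop("classify_pqto requires an opposing architecture", call. = FALSE)
  }
  aln <- .canonicalize(product, arch, aln_params)
  prof <- .bypass_profile(arch, aln)
  pc <- strsplit(arch$reference, "")[[1L]]
  if (.outside_identity(prof, pc, arch) < min_identity) {
    return(.empty_call(read_id, "unclassifiable"))
  }
  site <- arch$top_site
  prof <- .normalize_site_del(prof, site, site[1L] + 1L)
  run <- .deletion_run(prof, site)
  call <- .empty_call(read_id, "TLS")
  site_str <- paste(prof[(site[1L] + 1L):site[2L]], collapse = "")
  call$site_top <- call$site_bottom <-
    if (run[2L] > 0L) "del" else site_str
  call$del_len <- run[2L]
  if (run[2L] >= 2L) {
    call$mode <- "deletion"
    return(call)
  }
  bases <- .incorporation_bases(prof, site, "top")
  call$base_3T <- bases[1L]; call$base_5T <- bases[2L]
  call$base_p1 <- bases[3L]; call$base_p2 <- bases[4L]
  ref_site <- paste(pc[(site[1L] + 1L):site[2L]], collapse = "")
  call$accurate <- identical(site_str, ref_site) ||
    identical(site_str, arch$accurate)
  call
}

#' Classify every product of a set against an architecture
#'
#' Routes each read to [classify_pqts()] or [classify_pqto()] according
#' to the architecture's arrangement.
#'
#' @param products Named character vector of product sequences.
#' @param arch A [lesion_architecture()].
#' @param aln_params,min_identity Passed through to the per-read
#'   classifier.
#' @return A data frame of per-read calls (one row per product).
#' @export
classify_products <- function(products, arch, aln_params = align_params(),
                              min_identity = 0.9) {
  stopifnot(!is.null(names(products)))
  fun <- if (arch$arrangement == "staggered") classify_pqts else classify_pqto
  calls <- lapply(names(products), function(id) {
    fun(products[[id]], arch, read_id = id, aln_params = aln_params,
        min_identity = min_identity)
  })
  do.call(rbind, calls)
}

#' Bypass-mode fractions over classifiable reads
#'
#' Percentages of TLS versus error-free bypass (and other classes) over
#' the classifiable reads of a call set.  TLS pools `TLS_top`,
#' `TLS_bottom` and the opposing-arrangement `TLS` mode;
#' deletion-associated TLS (a deleted site in a TLS read) is counted as
#' TLS.  The opposing-arrangement `deletion` class is reported
#' separately.  Unclassifiable reads are counted but excluded from the
#' denominators.
#'
#' @param calls Data frame of calls from [classify_products()].
#' @return A list with `n_classifiable`, `n_unclassifiable`, `counts`
#'   and `percent` (named: `TLS`, `error_free`, `deletion`, `other`),
#'   and `tls_percent`.
#' @export
tls_fraction <- function(calls) {
  classifiable <- calls[calls$mode != "unclassifiable", , drop = FALSE]
  n <- nrow(classifiable)
  if (n == 0L) {
    stop("no classifiable reads: fractions are undefined", call. = FALSE)
  }
  grp <- ifelse(classifiable$mode %in% c("TLS_top", "TLS_bottom", "TLS"),
                "TLS", classifiable$mode)
  counts <- table(factor(grp, levels = c("TLS", "error_free", "deletion",
                                         "other")))
  percent <- 100 * as.numeric(counts) / n
  names(percent) <- names(counts)
  list(n_classifiable = n,
       n_unclassifiable = sum(calls$mode == "unclassifiable"),
       counts = as.integer(counts) |> stats::setNames(names(counts)),
       percent = percent,
       tls_percent = percent[["TLS"]])
}

#' Per-position nucleotide-incorporation profile of TLS reads
#'
#' Frequencies of `A`, `C`, `G`, `T` and `del` at the four
#' incorporation positions (the 3' T and 5' T of the lesion, then the
#' next two template bases), over TLS calls only -- error-free reads
#' are excluded by construction.
#'
#' @param calls Data frame of calls from [classify_products()].
#' @return A 5x4 matrix (rows `A,C,G,T,del`; columns `3T`, `5T`, `+1`,
#'   `+2`) of frequencies; each column sums to 1 over the reads with a
#'   readable base at that position.
#' @export
incorporation_profile <- function(calls) {
  tls <- calls[calls$mode %in% c("TLS_top", "TLS_bottom", "TLS"), ,
               drop = FALSE]
  if (nrow(tls) == 0L) {
    stop("no TLS calls: the incorporation profile is undefined",
         call. = FALSE)
  }
  lv <- c("A", "C", "G", "T", "del")
  cols <- c(`3T` = "base_3T", `5T` = "base_5T", `+1` = "base_p1",
            `+2` = "base_p2")
  prof <- sapply(cols, function(cl) {
    v <- tls[[cl]]
    v <- v[!is.na(v)]
    tab <- table(factor(v, levels = lv))
    if (sum(tab) == 0L) rep(NA_real_, length(lv)) else
      as.numeric(tab) / sum(tab)
  })
  rownames(prof) <- lv
  colnames(prof) <- names(cols)
  prof
}
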
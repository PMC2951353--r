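# Run `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' @param n Length in nucleotides.
#' @param seed Optional seed (the caller's RNG state is untouched).
#' @param gc GC content (default 0.5).
#' @return A DNA string.
#' @export
random_dna <- function(n, seed = NULL, gc = 0.5) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Parameters for simulating a pseudogene donor array
#'
#' @param n_donors Number of donors.
#' @param divergence Per-donor substitution rate from the parent, in
#'   (0, 0.2].
#' @param min_pair_diffs Minimum pairwise Hamming distance between
#'   donors (default 3).
#' @param unique_diff_positions If `TRUE`, no two donors differ from the
#'   parent at the same position (default `FALSE`).  Shared differences
#'   are realistic for related pseudogenes but make event assignment
#'   genuinely ambiguous: a conversion tract's mutations can be
#'   explained by a second donor carrying the same differences.  Set
#'   this for identifiability studies where exact truth recovery is
#'   asserted.
#' @param seed RNG seed.
#' @return An object of class `"donor_sim_params"`.
#' @export
donor_sim_params <- function(n_donors, divergence, min_pair_diffs = 3L,
                             unique_diff_positions = FALSE, seed = 1L) {
  if (!(divergence > 0 && divergence <= 0.2)) {
    stop("divergence must lie in (0, 0.2]: donors must differ from the ",
         "parent but remain recognizably homologous", call. = FALSE)
  }
  stopifnot(n_donors >= 1L, min_pair_diffs >= 0L)
  structure(list(n_donors = as.integer(n_donors), divergence = divergence,
                 min_pair_diffs = as.integer(min_pair_diffs),
                 unique_diff_positions = isTRUE(unique_diff_positions),
                 seed = as.integer(seed)),
            class = "donor_sim_params")
}

#' Simulate a pseudogene donor array
#'
#' Each donor is the parent with substitutions at a `divergence`
#' fraction of positions (at least one), subject to every donor pair
#' differing at `min_pair_diffs` or more positions.  Output is
#' reproducible under the seed.
#'
#' @param parent Parent DNA string (length >= 100).
#' @param params A [donor_sim_params()] object.
#' @return Named character vector of donor sequences
#'   (`pseudoV01`, `pseudoV02`, ...).
#' @export
simulate_pseudogene_db <- function(parent, params) {
  stopifnot(inherits(params, "donor_sim_params"))
  parent <- toupper(parent)
  n <- nchar(parent)
  if (n < 100L) stop("parent must be at least 100 nt", call. = FALSE)
  pc <- strsplit(parent, "")[[1L]]
  n_diff <- max(1L, round(params$divergence * n))
  if (params$unique_diff_positions && params$n_donors * n_diff > n) {
    stop("not enough parent positions for ", params$n_donors,
         " donors with disjoint difference sites", call. = FALSE)
  }
  with_seed(params$seed, {
    donors <- character(0)
    donor_chars <- list()
    used <- integer(0)
    for (i in seq_len(params$n_donors)) {
      ok <- FALSE
      for (attempt in seq_len(500L)) {
        dc <- pc
        pool <- if (params$unique_diff_positions) setdiff(seq_len(n), used)
                else seq_len(n)
        at <- sort(sample(pool, n_diff))
        for (p in at) {
          dc[p] <- sample(setdiff(c("A", "C", "G", "T"), pc[p]), 1L)
        }
        if (all(vapply(donor_chars,
                       function(prev) sum(prev != dc) >=
                         params$min_pair_diffs, logical(1)))) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not place ", params$n_donors, " donors pairwise >= ",
             params$min_pair_diffs, " differences apart at divergence ",
             params$divergence, call. = FALSE)
      }
      donor_chars[[i]] <- dc
      used <- c(used, at)
      donors <- c(donors, paste(dc, collapse = ""))
    }
    stats::setNames(donors, sprintf("pseudoV%02d", seq_along(donors)))
  })
}

#' Parameters for simulating hypermutated clone sets
#'
#' Defaults mirror the design of the Ig V-lambda hypermutation
#' experiment: a small number of clonally expanded sequences per
#' genotype (three clones per data set), a handful of diversification
#' events per clone, a minority of gene-conversion tracts among them,
#' and AID's strong preference for G/C base pairs modeled as a simple
#' position-sampling weight.  Sequencing error defaults to zero
#' (high-fidelity amplification and Sanger reads).
#'
#' @param n_clones Number of clones (default 3).
#' @param event_mean Poisson mean of diversification events per clone
#'   (default 8).
#' @param gc_fraction Fraction of events that are gene conversions
#'   (default 0.2).
#' @param tract_mean Mean of the geometric gene-conversion tract length
#'   distribution, in nucleotides (default 25).
#' @param spectrum 4x4 ref-by-alt weight matrix for PM substitutions
#'   (diagonal ignored); default uniform over the nine off-diagonal
#'   alternatives.
#' @param gc_bias Position-sampling weight of G/C positions relative to
#'   A/T for PM events (default 4; AID hotspot proxy).
#' @param error_rate Per-base uniform substitution sequencing-error rate
#'   (default 0).
#' @param min_flank Minimum separation, in nucleotides, between event
#'   footprints and between a conversion tract and the nearest
#'   donor-parent difference outside it (default 0; set to the
#'   classifier's minimum donor string for identifiability studies).
#' @param gc_min_diffs Minimum donor-parent differences copied by a
#'   conversion tract (default 1).
#' @param pm_avoid_donor If `TRUE`, PM alternative bases are re-drawn so
#'   that no donor carries them at the mutated position (default
#'   `FALSE`).
#' @param seed RNG seed.
#' @return An object of class `"hypermut_sim_params"`.
#' @export
hypermut_sim_params <- function(n_clones = 3L, event_mean = 8,
                                gc_fraction = 0.2, tract_mean = 25,
                                spectrum = NULL, gc_bias = 4,
                                error_rate = 0, min_flank = 0L,
                                gc_min_diffs = 1L, pm_avoid_donor = FALSE,
                                seed = 1L) {
  stopifnot(n_clones >= 1L, event_mean >= 0, gc_fraction >= 0,
            gc_fraction <= 1, tract_mean >= 1, gc_bias > 0,
            error_rate >= 0, error_rate < 1)
  bases <- c("A", "C", "G", "T")
  if (is.null(spectrum)) {
    spectrum <- matrix(1, 4, 4, dimnames = list(bases, bases))
    diag(spectrum) <- 0
  }
  stopifnot(all(dim(spectrum) == 4L), all(spectrum >= 0))
  diag(spectrum) <- 0
  if (sum(spectrum) == 0) {
    stop("the PM spectrum needs at least one positive weight",
         call. = FALSE)
  }
  structure(list(n_clones = as.integer(n_clones), event_mean = event_mean,
                 gc_fraction = gc_fraction, tract_mean = tract_mean,
                 spectrum = spectrum, gc_bias = gc_bias,
                 error_rate = error_rate, min_flank = as.integer(min_flank),
                 gc_min_diffs = as.integer(gc_min_diffs),
                 pm_avoid_donor = pm_avoid_donor, seed = as.integer(seed)),
            class = "hypermut_sim_params")
}

#' Simulate a hypermutated clone set with truth labels
#'
#' Generates clones from the parent by placing non-overlapping
#' diversification events: gene-conversion events copy a contiguous
#' donor tract containing at least `gc_min_diffs` donor-parent
#' differences, point-mutation events substitute a single base at a
#' G/C-biased position with an alternative drawn from the spectrum.
#' Uniform sequencing errors, if requested, are applied last and
#' recorded separately from the event truth.  Applying the truth events
#' to the parent reconstructs every clone exactly (before sequencing
#' error).
#'
#' @param parent Parent DNA string.
#' @param donors Named character vector of donor sequences (same length
#'   as the parent; e.g. from [simulate_pseudogene_db()]).
#' @param params A [hypermut_sim_params()] object.
#' @return A list of class `"hypermut_sim"`: `clones` (named character
#'   vector), `truth` (data frame: `clone_id`, `category`, `pos`,
#'   `tract_start`, `tract_end`, `donor_id`, `ref`, `alt`, `n_diffs`),
#'   and `errors` (data frame of applied sequencing errors).
#' @export
simulate_clone_set <- function(parent, donors, params) {
  stopifnot(inherits(params, "hypermut_sim_params"))
  parent <- toupper(parent)
  pc <- strsplit(parent, "")[[1L]]
  n <- length(pc)
  donor_chars <- lapply(donors, function(d) {
    d <- toupper(d)
    if (nchar(d) != n) {
      stop("simulate_clone_set requires donors co-linear with the parent",
           call. = FALSE)
    }
    strsplit(d, "")[[1L]]
  })
  bases <- c("A", "C", "G", "T")
  # PM positions: G/C hotspot bias times the spectrum's total weight for
  # the reference base there, so a ref base with zero spectrum weight is
  # never mutated (e.g. a pure C>T spectrum only mutates C positions)
  pos_weight <- ifelse(pc %in% c("G", "C"), params$gc_bias, 1) *
    rowSums(params$spectrum)[pc]
  flank <- params$min_flank
  with_seed(params$seed, {
    clones <- character(0)
    truth <- NULL
    errors <- NULL
    claim <- function(occ, from, to) {
      lo <- max(1L, from - flank); hi <- min(n, to + flank)
      occ[lo:hi] <- TRUE
      occ
    }
    # Draw one clone; NULL if the drawn events cannot all be placed
    # under the spacing constraints (the caller then redraws the clone,
    # so event counts are conditioned on fitting the locus).
    draw_clone <- function(clone_id) {
      cc <- pc
      occupied <- rep(FALSE, n)   # footprints padded by the flank
      truth <- NULL
      n_ev <- stats::rpois(1L, params$event_mean)
      for (e in seq_len(n_ev)) {
        is_gc <- length(donor_chars) > 0L &&
          stats::runif(1L) < params$gc_fraction
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          if (is_gc) {
            di <- sample.int(length(donor_chars), 1L)
            dc <- donor_chars[[di]]
            # anchor the tract on a run of donor-parent differences so
            # that it copies at least gc_min_diffs of them
            g <- max(1L, params$gc_min_diffs)
            all_diffs <- which(dc != pc)
            if (length(all_diffs) < g) next
            j <- sample.int(length(all_diffs) - g + 1L, 1L)
            span <- all_diffs[j + g - 1L] - all_diffs[j] + 1L
            len <- max(span, stats::rgeom(1L, 1 / params$tract_mean) + 1L)
            if (len > n) next
            offset <- sample.int(len - span + 1L, 1L) - 1L
            start <- all_diffs[j] - offset
            start <- max(1L, min(start, n - len + 1L))
            tract <- start:(start + len - 1L)
            diffs <- tract[dc[tract] != pc[tract]]
            if (length(diffs) < g) next
            if (any(occupied[tract])) next
            if (flank > 0L) {
              outside <- which(dc != pc)
              outside <- outside[outside < start | outside > max(tract)]
              if (any(abs(outside - start) < flank |
                      abs(outside - max(tract)) < flank)) next
            }
            cc[tract] <- dc[tract]
            occupied <- claim(occupied, start, max(tract))
            truth <- rbind(truth, data.frame(
              clone_id = clone_id, category = "GC", pos = NA_integer_,
              tract_start = start - 1L, tract_end = max(tract),
              donor_id = names(donors)[di], ref = NA_character_,
              alt = NA_character_, n_diffs = length(diffs)))
            placed <- TRUE; break
          } else {
            p <- sample.int(n, 1L, prob = pos_weight)
            if (occupied[p]) next
            w <- params$spectrum[pc[p], ]
            alt <- sample(bases, 1L, prob = w)
            if (params$pm_avoid_donor) {
              allowed <- bases[w > 0]
              allowed <- allowed[vapply(allowed, function(b) {
                !any(vapply(donor_chars, function(dc) dc[p] == b,
                            logical(1)))
              }, logical(1))]
              if (length(allowed) == 0L) next
              alt <- sample(allowed, 1L,
                            prob = params$spectrum[pc[p], allowed])
            }
            cc[p] <- alt
            occupied <- claim(occupied, p, p)
            truth <- rbind(truth, data.frame(
              clone_id = clone_id, category = "PM", pos = p - 1L,
              tract_start = NA_integer_, tract_end = NA_integer_,
              donor_id = NA_character_, ref = pc[p], alt = alt,
              n_diffs = 1L))
            placed <- TRUE; break
          }
        }
        if (!placed) return(NULL)
      }
      list(seq = paste(cc, collapse = ""), truth = truth)
    }
    for (ci in seq_len(params$n_clones)) {
      clone_id <- sprintf("clone%02d", ci)
      drawn <- NULL
      for (try_c in seq_len(50L)) {
        drawn <- draw_clone(clone_id)
        if (!is.null(drawn)) break
      }
      if (is.null(drawn)) {
        stop("could not place the simulated events of ", clone_id,
             " within the locus; relax min_flank / gc_min_diffs, ",
             "shorten tracts, or lower event_mean", call. = FALSE)
      }
      cc <- strsplit(drawn$seq, NULL)[[1L]]
      if (!is.null(drawn$truth)) truth <- rbind(truth, drawn$truth)
      # sequencing error, applied last and recorded separately
      if (params$error_rate > 0) {
        hit <- which(stats::runif(n) < params$error_rate)
        for (p in hit) {
          new <- sample(setdiff(bases, cc[p]), 1L)
          errors <- rbind(errors, data.frame(
            clone_id = clone_id, pos = p - 1L, ref = cc[p], alt = new))
          cc[p] <- new
        }
      }
      clones <- c(clones, stats::setNames(paste(cc, collapse = ""),
                                          clone_id))
    }
    empty_truth <- data.frame(clone_id = character(0),
                              category = character(0), pos = integer(0),
                              tract_start = integer(0),
                              tract_end = integer(0),
                              donor_id = character(0), ref = character(0),
                              alt = character(0), n_diffs = integer(0))
    structure(list(clones = clones,
                   truth = if (is.null(truth)) empty_truth else truth,
                   errors = if (is.null(errors)) {
                     data.frame(clone_id = character(0), pos = integer(0),
                                ref = character(0), alt = character(0))
                   } else errors),
              class = "hypermut_sim")
  })
}

#' Reconstruct a simulated clone from the parent and its truth events
#'
#' @param parent Parent DNA string.
#' @param donors Named donor vector used in the simulation.
#' @param truth Truth table from [simulate_clone_set()].
#' @param clone_id Which clone to reconstruct.
#' @return The clone sequence before sequencing error.
#' @export
apply_truth <- function(parent, donors, truth, clone_id) {
  pc <- strsplit(toupper(parent), "")[[1L]]
  tr <- truth[truth$clone_id == clone_id, , drop = FALSE]
  for (r in seq_len(nrow(tr))) {
    if (tr$category[r] == "GC") {
      dc <- strsplit(toupper(donors[[tr$donor_id[r]]]), "")[[1L]]
      idx <- (tr$tract_start[r] + 1L):tr$tract_end[r]
      pc[idx] <- dc[idx]
    } else {
      pc[tr$pos[r] + 1L] <- tr$alt[r]
    }
  }
  paste(pc, collapse = "")
}

#' Parameters for simulating lesion-plasmid replication products
#'
#' @param mixture Named weights over generating modes.  Staggered
#'   (pQTs-like) architectures use `TLS_top`, `TLS_bottom`,
#'   `error_free`, `other`; opposing (pQTo-like) architectures use
#'   `TLS` and `deletion` (never `error_free`: template switching is
#'   impossible by construction).
#' @param incorporation 5x2 preference matrix (rows `A,C,G,T,del`,
#'   columns the 3' T and 5' T positions) for bases inserted opposite
#'   the lesion; default 90% accurate `A` with a small admixture of the
#'   other bases, and deletion mass confined to the 3' T -- the position
#'   where within-site deletions are scored by convention, since a
#'   single missing base inside the lesion dinucleotide cannot be
#'   attributed to one T or the other from sequence alone.
#' @param del_lengths Integer support of the deletion-length
#'   distribution for the opposing-arrangement deletion class (default
#'   2:6, uniform).
#' @param del_weights Weights over `del_lengths`.
#' @param n_products Number of products.
#' @param error_rate Per-base uniform substitution sequencing-error
#'   rate (default 0).
#' @param seed RNG seed.
#' @return An object of class `"bypass_sim_params"`.
#' @export
bypass_sim_params <- function(mixture, incorporation = NULL,
                              del_lengths = 2:6, del_weights = NULL,
                              n_products = 100L, error_rate = 0,
                              seed = 1L) {
  stopifnot(!is.null(names(mixture)), all(mixture >= 0), sum(mixture) > 0)
  mixture <- mixture / sum(mixture)
  lv <- c("A", "C", "G", "T", "del")
  if (is.null(incorporation)) {
    incorporation <- matrix(c(0.90, 0.02, 0.02, 0.02, 0.04,
                              0.94, 0.02, 0.02, 0.02, 0.00), nrow = 5L,
                            ncol = 2L, dimnames = list(lv, c("3T", "5T")))
  }
  stopifnot(nrow(incorporation) == 5L, ncol(incorporation) == 2L,
            all(incorporation >= 0))
  rownames(incorporation) <- lv
  if (is.null(del_weights)) del_weights <- rep(1, length(del_lengths))
  stopifnot(length(del_weights) == length(del_lengths),
            all(del_lengths >= 1L))
  structure(list(mixture = mixture, incorporation = incorporation,
                 del_lengths = as.integer(del_lengths),
                 del_weights = del_weights,
                 n_products = as.integer(n_products),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "bypass_sim_params")
}

#' Simulate replicated lesion-plasmid products with truth labels
#'
#' Error-free products carry the marker at both sites; TLS products
#' carry drawn bases (or single-base deletions) opposite the lesion on
#' the generating strand and the marker at the other site; opposing
#' deletion products remove the drawn number of nucleotides covering
#' the site.  Draws whose site read would coincide with the marker are
#' rejected and re-drawn so that generating modes remain identifiable.
#' Sequencing error is applied last.
#'
#' @param arch A [lesion_architecture()].
#' @param params A [bypass_sim_params()] object.
#' @return A list of class `"bypass_sim"`: `products` (named character
#'   vector) and `truth` (data frame: `read_id`, `mode`, `base_3T`,
#'   `base_5T`, `del_len`).
#' @export
simulate_bypass_products <- function(arch, params) {
  stopifnot(inherits(arch, "lesion_architecture"),
            inherits(params, "bypass_sim_params"))
  modes <- names(params$mixture)
  if (arch$arrangement == "opposing" && "error_free" %in%
      modes[params$mixture > 0]) {
    stop("opposing arrangement cannot generate error_free products",
         call. = FALSE)
  }
  pc <- strsplit(arch$reference, "")[[1L]]
  n <- length(pc)
  lv <- c("A", "C", "G", "T", "del")
  comp <- function(b) if (b == "del") "del" else chartr("ACGT", "TGCA", b)
  with_seed(params$seed, {
    products <- character(params$n_products)
    ids <- sprintf("read%04d", seq_len(params$n_products))
    truth <- data.frame(read_id = ids,
                        mode = sample(modes, params$n_products,
                                      replace = TRUE,
                                      prob = params$mixture),
                        base_3T = NA_character_, base_5T = NA_character_,
                        del_len = 0L, stringsAsFactors = FALSE)
    draw_insert <- function() {
      c(sample(lv, 1L, prob = params$incorporation[, 1L]),
        sample(lv, 1L, prob = params$incorporation[, 2L]))
    }
    for (i in seq_len(params$n_products)) {
      cc <- pc
      mode <- truth$mode[i]
      if (mode == "error_free") {
        # marker-form reference as-is
      } else if (mode %in% c("TLS_top", "TLS_bottom", "TLS")) {
        site <- if (mode == "TLS_bottom") arch$bottom_site else
          arch$top_site
        s <- site[1L]
        repeat {
          ins <- draw_insert()   # (3'T, 5'T) inserted bases
          if (mode == "TLS_bottom") {
            # bottom-strand lesion: nascent top strand reads the inserts
            # directly, 3'T at the site start
            read <- c(ins[1L], ins[2L])
            read_at <- c(s + 1L, s + 2L)
          } else {
            # top-strand lesion: product reads the complement, 3'T at s+1
            read <- c(comp(ins[2L]), comp(ins[1L]))
            read_at <- c(s + 1L, s + 2L)
          }
          # a draw deleting both site bases is indistinguishable from the
          # opposing-arrangement deletion class; redraw it there
          if (mode == "TLS" && all(ins == "del")) next
          site_str <- paste(ifelse(read == "del", "", read), collapse = "")
          if (site_str != arch$marker) break
        }
        keep <- read != "del"
        cc[read_at] <- ifelse(keep, read, NA)
        cc <- cc[!(seq_along(cc) %in% read_at[!keep])]
        truth$base_3T[i] <- ins[1L]; truth$base_5T[i] <- ins[2L]
        truth$del_len[i] <- sum(!keep)
      } else if (mode == "deletion") {
        len <- params$del_lengths[sample.int(length(params$del_lengths), 1L,
                                             prob = params$del_weights)]
        site <- arch$top_site
        # deletion run covering the whole site
        offset <- if (len > 2L) sample.int(len - 1L, 1L) - 1L else 0L
        start <- max(1L, site[1L] + 1L - offset)
        end <- min(n, start + len - 1L)
        cc <- cc[-(start:end)]
        truth$del_len[i] <- end - start + 1L
      } else if (mode == "other") {
        for (site in list(arch$top_site, arch$bottom_site)) {
          repeat {
            rd <- c(sample(c("A", "C", "G", "T"), 1L),
                    sample(c("A", "C", "G", "T"), 1L))
            if (paste(rd, collapse = "") != arch$marker) break
          }
          cc[(site[1L] + 1L):site[2L]] <- rd
        }
      } else {
        stop("unknown generating mode '", mode, "'", call. = FALSE)
      }
      cc <- cc[!is.na(cc)]
      if (params$error_rate > 0) {
        hit <- which(stats::runif(length(cc)) < params$error_rate)
        for (p in hit) {
          cc[p] <- sample(setdiff(c("A", "C", "G", "T"), cc[p]), 1L)
        }
      }
      products[i] <- paste(cc, collapse = "")
    }
    structure(list(products = stats::setNames(products, ids),
                   truth = truth),
              class = "bypass_sim")
  })
}
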
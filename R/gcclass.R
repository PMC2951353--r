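#' Parameters for the PM / GC / Amb event classifier
#'
#' The classifier assigns every called mutation of a clone to exactly
#' one diversification event: a non-templated point mutation (PM), a
#' long-tract gene conversion from a pseudogene donor (GC), or an
#' ambiguous single change (Amb).  The decisive quantity is the donor
#' string: a contiguous exact match between clone and donor that covers
#' the mutated position.  A mutation with no donor string of at least
#' `min_donor_string` nucleotides in any donor is PM; a mutation with
#' such a string whose donor also explains at least one further mutation
#' of the same clone seeds a single GC event collecting all mutations
#' that donor explains; a mutation with a qualifying string but no
#' co-explained partner is Amb.
#'
#' @param min_donor_string Minimum donor-string length in nucleotides
#'   (default 10, i.e. strictly more than 9 bp).
#' @param search_revcomp Also search donors in reverse-complement
#'   orientation (default `FALSE`).
#' @param tie_break Donor tie-break policy; the single supported policy
#'   picks the donor explaining the most mutations, then the longest
#'   donor string, then the lexicographically smallest donor id, making
#'   classification independent of donor file order.
#' @return An object of class `"classifier_params"`.
#' @export
classifier_params <- function(min_donor_string = 10L,
                              search_revcomp = FALSE,
                              tie_break = "longest-then-lexicographic-id") {
  min_donor_string <- as.integer(min_donor_string)
  stopifnot(min_donor_string >= 2L, is.logical(search_revcomp))
  tie_break <- match.arg(tie_break)
  structure(list(min_donor_string = min_donor_string,
                 search_revcomp = search_revcomp, tie_break = tie_break),
            class = "classifier_params")
}

# Align every donor to the parent once and collapse to per-parent-position
# profiles; homology between donor and parent positions is read through
# this alignment, so donors of unequal length are handled uniformly.
donor_profiles <- function(parent, donors, params = classifier_params(),
                           aln_params = align_params()) {
  stopifnot(length(donors) >= 1L, !is.null(names(donors)))
  if (anyDuplicated(names(donors))) {
    stop("donor ids must be unique", call. = FALSE)
  }
  ids <- names(donors)
  profs <- list()
  for (i in seq_along(donors)) {
    profs[[ids[i]]] <- alignment_profile(
      align_global(parent, donors[[i]], aln_params))
    if (params$search_revcomp) {
      profs[[paste0(ids[i], ":rc")]] <- alignment_profile(
        align_global(parent, revcomp(donors[[i]]), aln_params))
    }
  }
  profs
}

# Footprint of a mutation on the parent profile: the positions (1-based
# profile indices) whose profile entries encode the change.
.mut_footprint <- function(mut) {
  switch(mut$kind,
         substitution = mut$pos + 1L,
         deletion = (mut$pos + 1L):(mut$pos + nchar(mut$ref)),
         insertion = max(mut$pos, 1L))
}

# Does a donor profile explain a mutation, i.e. does the donor carry the
# clone's state over the mutation's footprint?
.explains <- function(donor_prof, clone_prof, mut) {
  fp <- .mut_footprint(mut)
  all(donor_prof[fp] == clone_prof[fp])
}

#' Find qualifying donor strings for one mutation
#'
#' For each donor, computes the maximal contiguous interval of parent
#' positions over which clone and donor are identical and which covers
#' the mutation, and keeps it if its nucleotide length reaches
#' `params$min_donor_string` and the donor actually carries the mutant
#' base(s).  Matched length is counted in clone nucleotides over the
#' interval (so deletions shorten and insertions lengthen the string).
#'
#' @param mut One row (as a list or one-row data frame) of a mutation
#'   table from [call_mutations()].
#' @param clone_prof Clone profile from [alignment_profile()].
#' @param donor_profs Named list of donor profiles from
#'   `donor_profiles()`.
#' @param parent Parent DNA string.
#' @param params A [classifier_params()] object.
#' @return Data frame with columns `donor_id`, `start`, `end` (0-based
#'   half-open parent interval), `length` (nucleotides matched), sorted
#'   by decreasing length then donor order.
#' @export
find_donor_matches <- function(mut, clone_prof, donor_profs, parent,
                               params = classifier_params()) {
  mut <- as.list(mut)
  n <- length(clone_prof)
  fp <- .mut_footprint(mut)
  if (any(fp < 1L) || any(fp > n)) {
    stop("mutation position outside parent", call. = FALSE)
  }
  res <- data.frame(donor_id = character(0), start = integer(0),
                    end = integer(0), length = integer(0))
  for (d in names(donor_profs)) {
    dp <- donor_profs[[d]]
    if (!.explains(dp, clone_prof, mut)) next
    l <- min(fp); r <- max(fp)
    while (l > 1L && dp[l - 1L] == clone_prof[l - 1L]) l <- l - 1L
    while (r < n && dp[r + 1L] == clone_prof[r + 1L]) r <- r + 1L
    len <- sum(nchar(clone_prof[l:r]))
    if (len >= params$min_donor_string) {
      res <- rbind(res, data.frame(donor_id = d, start = l - 1L, end = r,
                                   length = len))
    }
  }
  res[order(-res$length, seq_len(nrow(res))), , drop = FALSE]
}

#' Classify a clone's mutations into PM / GC / Amb events
#'
#' Implements the three-category rule.  Mutations are visited in parent
#' order; each unassigned mutation is looked up in the donor database
#' with [find_donor_matches()].  No qualifying donor string: the
#' mutation is a non-templated point mutation (PM).  A qualifying donor
#' that also explains at least one further unassigned mutation of the
#' clone: all mutations that donor explains are collected into one
#' long-tract gene conversion (GC) event.  A qualifying donor with no
#' co-explained partner: the mutation is ambiguous (Amb) -- it could
#' have been templated or not.  The output events partition the input
#' mutations.
#'
#' When several donors qualify, the donor explaining the most mutations
#' wins, then the longest donor string, then the lexicographically
#' smallest donor id; all qualifying donors are recorded for audit.
#'
#' The reported GC tract is the minimal parent interval covering the
#' member mutations, extended outward while clone, donor and parent all
#' agree (the maximal credible tract); this affects reporting only,
#' never category counts.
#'
#' @param muts Mutation table from [call_mutations()] (the clone's full
#'   call set).
#' @param clone Clone DNA sequence (or a precomputed profile via
#'   `clone_prof`).
#' @param parent Parent DNA string.
#' @param donors Named character vector of donor sequences (or a
#'   precomputed named list of profiles via `donor_profs`).
#' @param params A [classifier_params()] object.
#' @param aln_params An [align_params()] object used for clone and donor
#'   alignment.
#' @param clone_prof,donor_profs Optional precomputed profiles.
#' @return A list of class `"clone_events"`: `events` (data frame with
#'   `event_id`, `category`, `donor_id`, `tract_start`, `tract_end`,
#'   `n_members`), `mutations` (input table plus `event_id`), and
#'   `audit` (qualifying donors per seed mutation).
#' @export
classify_clone <- function(muts, clone = NULL, parent, donors = NULL,
                           params = classifier_params(),
                           aln_params = align_params(),
                           clone_prof = NULL, donor_profs = NULL) {
  if (is.null(clone_prof)) {
    clone_prof <- alignment_profile(align_global(parent, clone, aln_params))
  }
  if (is.null(donor_profs)) {
    donor_profs <- donor_profiles(parent, donors, params, aln_params)
  }
  n_mut <- nrow(muts)
  empty_events <- data.frame(event_id = integer(0), category = character(0),
                             donor_id = character(0),
                             tract_start = integer(0), tract_end = integer(0),
                             n_members = integer(0))
  if (n_mut == 0L) {
    muts$event_id <- integer(0)
    return(structure(list(events = empty_events, mutations = muts,
                          audit = list()), class = "clone_events"))
  }
  max_fp <- max(unlist(lapply(seq_len(n_mut),
                              function(r) .mut_footprint(as.list(muts[r, ])))))
  if (max_fp > length(clone_prof)) {
    stop("mutation references a position outside the parent", call. = FALSE)
  }
  ord <- order(muts$pos)
  assigned <- rep(NA_integer_, n_mut)
  events <- empty_events
  audit <- list()
  next_event <- 1L
  pc <- strsplit(toupper(parent), "")[[1L]]
  for (r in ord) {
    if (!is.na(assigned[r])) next
    mut <- as.list(muts[r, ])
    matches <- find_donor_matches(mut, clone_prof, donor_profs, parent,
                                  params)
    if (nrow(matches) == 0L) {
      assigned[r] <- next_event
      events <- rbind(events, data.frame(
        event_id = next_event, category = "PM", donor_id = NA_character_,
        tract_start = NA_integer_, tract_end = NA_integer_, n_members = 1L))
      next_event <- next_event + 1L
      next
    }
    audit[[as.character(r)]] <- matches
    # how many unassigned mutations does each qualifying donor explain?
    cand <- matches
    cand$n_explained <- vapply(cand$donor_id, function(d) {
      sum(vapply(seq_len(n_mut), function(j) {
        is.na(assigned[j]) &&
          .explains(donor_profs[[d]], clone_prof, as.list(muts[j, ]))
      }, logical(1)))
    }, integer(1))
    cand <- cand[order(-cand$n_explained, -cand$length, cand$donor_id), ,
                 drop = FALSE]
    best <- cand[1L, ]
    if (best$n_explained >= 2L) {
      members <- which(vapply(seq_len(n_mut), function(j) {
        is.na(assigned[j]) &&
          .explains(donor_profs[[best$donor_id]], clone_prof,
                    as.list(muts[j, ]))
      }, logical(1)))
      assigned[members] <- next_event
      fps <- unlist(lapply(members,
                           function(j) .mut_footprint(as.list(muts[j, ]))))
      l <- min(fps); rr <- max(fps)
      dp <- donor_profs[[best$donor_id]]
      while (l > 1L && dp[l - 1L] == clone_prof[l - 1L] &&
             clone_prof[l - 1L] == pc[l - 1L]) l <- l - 1L
      while (rr < length(pc) && dp[rr + 1L] == clone_prof[rr + 1L] &&
             clone_prof[rr + 1L] == pc[rr + 1L]) rr <- rr + 1L
      events <- rbind(events, data.frame(
        event_id = next_event, category = "GC", donor_id = best$donor_id,
        tract_start = l - 1L, tract_end = rr,
        n_members = length(members)))
    } else {
      assigned[r] <- next_event
      events <- rbind(events, data.frame(
        event_id = next_event, category = "AMB", donor_id = best$donor_id,
        tract_start = NA_integer_, tract_end = NA_integer_, n_members = 1L))
    }
    next_event <- next_event + 1L
  }
  muts$event_id <- assigned
  rownames(events) <- NULL
  structure(list(events = events, mutations = muts, audit = audit),
            class = "clone_events")
}

#' @export
print.clone_events <- function(x, ...) {
  tab <- table(factor(x$events$category, levels = c("PM", "GC", "AMB")))
  cat("Clone classification: ", nrow(x$mutations), " mutation(s) in ",
      nrow(x$events), " event(s) [PM ", tab[["PM"]], ", GC ", tab[["GC"]],
      ", Amb ", tab[["AMB"]], "]\n", sep = "")
  invisible(x)
}

#' Classify every clone of a clone set
#'
#' Driver composing [call_clone_mutations()] and [classify_clone()] over
#' a set of sequenced clones.  Clones flagged as too divergent are
#' excluded from classification and reported as such.
#'
#' @inheritParams classify_clone
#' @param clones Named character vector of clone sequences.
#' @param max_divergence Passed to [call_clone_mutations()].
#' @return A list of class `"cloneset_events"`: `events` (combined data
#'   frame with a `clone_id` column), `per_clone` (list of
#'   `"clone_events"`), `excluded` (character vector of excluded clone
#'   ids).
#' @export
classify_clone_set <- function(parent, clones, donors,
                               params = classifier_params(),
                               aln_params = align_params(),
                               max_divergence = 0.1) {
  calls <- call_clone_mutations(parent, clones, aln_params, max_divergence)
  donor_profs <- donor_profiles(parent, donors, params, aln_params)
  per_clone <- list()
  events <- NULL
  excluded <- character(0)
  for (id in names(calls)) {
    if (calls[[id]]$excluded) {
      excluded <- c(excluded, id)
      next
    }
    clone_prof <- alignment_profile(calls[[id]]$alignment)
    cl <- classify_clone(calls[[id]]$mutations, parent = parent,
                         params = params, aln_params = aln_params,
                         clone_prof = clone_prof, donor_profs = donor_profs)
    per_clone[[id]] <- cl
    if (nrow(cl$events)) {
      ev <- cbind(clone_id = id, cl$events)
      events <- if (is.null(events)) ev else rbind(events, ev)
    }
  }
  if (is.null(events)) {
    events <- data.frame(clone_id = character(0), event_id = integer(0),
                         category = character(0), donor_id = character(0),
                         tract_start = integer(0), tract_end = integer(0),
                         n_members = integer(0))
  }
  structure(list(events = events, per_clone = per_clone,
                 excluded = excluded),
            class = "cloneset_events")
}

#' @export
print.cloneset_events <- function(x, ...) {
  tab <- table(factor(x$events$category, levels = c("PM", "GC", "AMB")))
  cat("Clone-set classification: ", length(x$per_clone), " clone(s), ",
      nrow(x$events), " event(s) [PM ", tab[["PM"]], ", GC ", tab[["GC"]],
      ", Amb ", tab[["AMB"]], "]", sep = "")
  if (length(x$excluded)) {
    cat("; excluded: ", paste(x$excluded, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
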
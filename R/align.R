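#' Alignment parameters for clone-to-parent global alignment
#'
#' Defaults (match +1, mismatch -2, gap open -6, gap extend -1) are
#' chosen so that in near-identical V segments an isolated substitution
#' is preferred over a pair of compensating indels.  A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open Gap-opening penalty (<= 0), charged once per gap.
#' @param gap_extend Gap-extension penalty (<= 0), charged per gap column.
#' @return An object of class `"align_params"`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = -6,
                         gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

# Substitution matrix over A/C/G/T/N: N scores 0 against everything so
# that uncallable bases neither attract nor repel the alignment.
.sub_matrix <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Global (end-to-end) alignment of a clone against the parent
#'
#' Needleman-Wunsch global alignment with affine gaps, computed with
#' `Biostrings::pairwiseAlignment()`.  The result is a pair of gapped
#' strings of equal length with no gap-against-gap column.
#'
#' @param parent Parent (reference) DNA string.
#' @param clone Clone (query) DNA string.
#' @param params An [align_params()] object.
#' @return A list of class `"pairwise_alignment"` with elements
#'   `parent` and `clone` (gapped strings) and `score`.
#' @export
align_global <- function(parent, clone, params = align_params()) {
  parent <- toupper(parent); clone <- toupper(clone)
  if (!nzchar(parent) || !nzchar(clone)) {
    stop("align_global requires non-empty sequences", call. = FALSE)
  }
  check_dna(parent, "parent"); check_dna(clone, "clone")
  aln <- Biostrings::pairwiseAlignment(
    pattern = clone, subject = parent, type = "global",
    substitutionMatrix = .sub_matrix(params),
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend
  )
  structure(list(parent = as.character(Biostrings::alignedSubject(aln)),
                 clone = as.character(Biostrings::alignedPattern(aln)),
                 score = Biostrings::score(aln)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat("  parent: ", x$parent, "\n  clone:  ", x$clone, "\n", sep = "")
  invisible(x)
}

#' Call mutations from a clone-to-parent alignment
#'
#' Walks the alignment columns and emits one row per sequence change:
#' substitutions per mismatch column, and indels with adjacent gap
#' columns merged into a single event.  Positions are 0-based on the
#' parent; an insertion at position `p` sits immediately before parent
#' base `p`.  Columns containing `N` in either sequence are uncallable
#' and skipped.  Indels are left-normalized against the parent (shifted
#' to the smallest equivalent position, stopping at any other called
#' mutation) so tract searches are reproducible across equivalent
#' alignment optima.
#'
#' @param alignment A `"pairwise_alignment"` from [align_global()].
#' @return A data frame with columns `kind` (`"substitution"`,
#'   `"insertion"`, `"deletion"`), `pos` (0-based parent position),
#'   `ref`, `alt`.
#' @export
call_mutations <- function(alignment) {
  p <- strsplit(alignment$parent, "")[[1L]]
  q <- strsplit(alignment$clone, "")[[1L]]
  stopifnot(length(p) == length(q))
  if (any(p == "-" & q == "-")) {
    stop("alignment contains a gap-against-gap column", call. = FALSE)
  }
  kind <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0)
  i <- 0L  # parent coordinate of the current column's parent base
  k <- 1L
  ncol <- length(p)
  while (k <= ncol) {
    if (p[k] != "-" && q[k] != "-") {
      if (p[k] != q[k] && p[k] != "N" && q[k] != "N") {
        kind <- c(kind, "substitution"); pos <- c(pos, i)
        ref <- c(ref, p[k]); alt <- c(alt, q[k])
      }
      i <- i + 1L; k <- k + 1L
    } else if (q[k] == "-") {           # deletion from the clone
      start <- i; del <- character(0)
      while (k <= ncol && q[k] == "-" && p[k] != "-") {
        del <- c(del, p[k]); i <- i + 1L; k <- k + 1L
      }
      if (!any(del == "N")) {
        kind <- c(kind, "deletion"); pos <- c(pos, start)
        ref <- c(ref, paste(del, collapse = "")); alt <- c(alt, "")
      }
    } else {                            # insertion into the clone
      ins <- character(0)
      while (k <= ncol && p[k] == "-") {
        ins <- c(ins, q[k]); k <- k + 1L
      }
      if (!any(ins == "N")) {
        kind <- c(kind, "insertion"); pos <- c(pos, i)
        ref <- c(ref, ""); alt <- c(alt, paste(ins, collapse = ""))
      }
    }
  }
  muts <- data.frame(kind = kind, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  left_normalize(muts, gsub("-", "", alignment$parent))
}

# Shift indels to their left-most equivalent parent position, without
# crossing another called mutation, so equivalent alignment optima give
# identical calls.
left_normalize <- function(muts, parent) {
  if (nrow(muts) == 0L) return(muts)
  pc <- strsplit(parent, "")[[1L]]
  ord <- order(muts$pos, match(muts$kind,
                               c("insertion", "substitution", "deletion")))
  muts <- muts[ord, , drop = FALSE]
  # end coordinate of each mutation's footprint on the parent
  foot_end <- function(row) {
    switch(row$kind,
           substitution = row$pos + 1L,
           deletion = row$pos + nchar(row$ref),
           insertion = row$pos)
  }
  for (r in seq_len(nrow(muts))) {
    if (muts$kind[r] == "substitution") next
    bound <- 0L
    if (r > 1L) {
      prev_ends <- vapply(seq_len(r - 1L),
                          function(j) foot_end(muts[j, ]), integer(1))
      bound <- max(0L, prev_ends)
    }
    if (muts$kind[r] == "deletion") {
      p0 <- muts$pos[r]; L <- nchar(muts$ref[r])
      while (p0 > bound && pc[p0] == pc[p0 + L]) p0 <- p0 - 1L
      muts$pos[r] <- p0
      muts$ref[r] <- paste(pc[(p0 + 1L):(p0 + L)], collapse = "")
    } else {                            # insertion
      p0 <- muts$pos[r]; s <- strsplit(muts$alt[r], "")[[1L]]
      L <- length(s)
      while (p0 > bound && s[L] == pc[p0]) {
        s <- c(pc[p0], s[-L]); p0 <- p0 - 1L
      }
      muts$pos[r] <- p0; muts$alt[r] <- paste(s, collapse = "")
    }
  }
  muts <- muts[order(muts$pos,
                     match(muts$kind,
                           c("insertion", "substitution", "deletion"))), ,
               drop = FALSE]
  rownames(muts) <- NULL
  muts
}

#' Reconstruct a clone from the parent plus called mutations
#'
#' Applies a mutation table from [call_mutations()] to the parent.  This
#' is the round-trip guarantee of the caller: the result equals the
#' clone the alignment was computed from.
#'
#' @param parent Parent DNA string.
#' @param muts Mutation data frame (`kind`, `pos`, `ref`, `alt`).
#' @return The reconstructed clone sequence.
#' @export
apply_mutations <- function(parent, muts) {
  pc <- strsplit(toupper(parent), "")[[1L]]
  n <- length(pc)
  sub_at <- ins_at <- del_at <- list()
  for (r in seq_len(nrow(muts))) {
    key <- as.character(muts$pos[r])
    switch(muts$kind[r],
           substitution = { sub_at[[key]] <- muts$alt[r] },
           insertion = { ins_at[[key]] <- paste0(
             if (is.null(ins_at[[key]])) "" else ins_at[[key]],
             muts$alt[r]) },
           deletion = { del_at[[key]] <- nchar(muts$ref[r]) })
  }
  out <- character(0)
  i <- 0L
  while (i < n) {
    key <- as.character(i)
    if (!is.null(ins_at[[key]])) out <- c(out, ins_at[[key]])
    if (!is.null(del_at[[key]])) {
      i <- i + del_at[[key]]
    } else if (!is.null(sub_at[[key]])) {
      out <- c(out, sub_at[[key]]); i <- i + 1L
    } else {
      out <- c(out, pc[i + 1L]); i <- i + 1L
    }
  }
  if (!is.null(ins_at[[as.character(n)]])) {
    out <- c(out, ins_at[[as.character(n)]])
  }
  paste(out, collapse = "")
}

#' Per-parent-position profile of an aligned sequence
#'
#' Collapses a clone-to-parent (or donor-to-parent) alignment into a
#' character vector with one entry per parent position: the base the
#' query carries there (`""` if deleted), with any insertion appended to
#' the entry of the preceding parent position.  Two sequences match over
#' a parent interval exactly when their profiles are equal on it, which
#' is the representation the donor-string search works in.
#'
#' @param alignment A `"pairwise_alignment"` (query vs parent).
#' @return Character vector of length `nchar(parent)`.
#' @export
alignment_profile <- function(alignment) {
  p <- strsplit(alignment$parent, "")[[1L]]
  q <- strsplit(alignment$clone, "")[[1L]]
  n <- sum(p != "-")
  prof <- character(n)
  i <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") {
      i <- i + 1L
      prof[i] <- if (q[k] == "-") "" else q[k]
    } else {
      # insertion: attach to the previous parent position (or the first)
      j <- max(i, 1L)
      prof[j] <- paste0(prof[j], q[k])
    }
  }
  prof
}

#' Canonical per-parent-position profile via left-normalized calls
#'
#' Like [alignment_profile()], but rebuilt from the left-normalized
#' mutation calls of [call_mutations()], so that indel placement is
#' canonical: equivalent alignment optima (a gap slid through a
#' homopolymer, a deletion next to a compatible mismatch) always give
#' the same profile.  Used by the bypass classifiers, where a
#' reproducible deletion position relative to the lesion sites matters.
#'
#' @param parent Parent (reference) DNA string.
#' @param alignment A `"pairwise_alignment"` (query vs parent).
#' @return Character vector of length `nchar(parent)`.
#' @export
canonical_profile <- function(parent, alignment) {
  profile_from_mutations(strsplit(toupper(parent), "")[[1L]],
                         call_mutations(alignment))
}

# Build a per-parent-position profile from a mutation table (parent
# given as a character vector).  Substitutions first, then deletions,
# then insertions, so indels take precedence at contested positions.
profile_from_mutations <- function(pc, muts) {
  prof <- pc
  for (k in c("substitution", "deletion", "insertion")) {
    for (r in which(muts$kind == k)) {
      switch(k,
             substitution = { prof[muts$pos[r] + 1L] <- muts$alt[r] },
             deletion = {
               prof[(muts$pos[r] + 1L):
                      (muts$pos[r] + nchar(muts$ref[r]))] <- ""
             },
             insertion = {
               j <- max(muts$pos[r], 1L)
               prof[j] <- paste0(prof[j], muts$alt[r])
             })
    }
  }
  prof
}

#' Align a set of clones and call their mutations
#'
#' Driver used by the Ig V classification pipeline: aligns every clone
#' end-to-end against the parent, calls mutations, and flags clones
#' whose divergence (mutated parent positions / parent length) exceeds
#' `max_divergence` -- such clones are likely mis-tracked sequences and
#' are excluded from classification by default.
#'
#' @param parent Parent DNA string.
#' @param clones Named character vector of clone sequences.
#' @param params An [align_params()] object.
#' @param max_divergence Divergence threshold above which a clone is
#'   flagged (default 0.1).
#' @return A list with one element per clone: `mutations` (data frame),
#'   `alignment`, `excluded` (logical), `divergence`.
#' @export
call_clone_mutations <- function(parent, clones, params = align_params(),
                                 max_divergence = 0.1) {
  stopifnot(length(clones) == 0L || !is.null(names(clones)))
  out <- vector("list", length(clones))
  names(out) <- names(clones)
  for (i in seq_along(clones)) {
    aln <- align_global(parent, clones[[i]], params)
    muts <- call_mutations(aln)
    footprint <- sum(ifelse(muts$kind == "deletion", nchar(muts$ref), 1L))
    divergence <- footprint / nchar(parent)
    out[[i]] <- list(mutations = muts, alignment = aln,
                     divergence = divergence,
                     excluded = divergence > max_divergence)
  }
  out
}
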
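#' Tally a nucleotide-substitution spectrum from classified events
#'
#' Counts single-base substitutions belonging to events of the requested
#' category into a 4x4 ref-by-alt table (diagonal structurally zero).
#' Strands are not pooled: G>A and C>T occupy separate cells; pooled
#' G/C-pair and A/T-pair totals are reported alongside.  Indels never
#' enter the spectrum.
#'
#' @param x A `"clone_events"` or `"cloneset_events"` object.
#' @param category Event category to tally (default `"PM"`).
#' @return An object of class `"mutation_spectrum"`: a list with
#'   `table` (4x4 integer matrix), `n` (total substitutions counted),
#'   `at_gc` (counts at G/C and at A/T parent bases), and `category`.
#' @export
tally_spectrum <- function(x, category = "PM") {
  bases <- c("A", "C", "G", "T")
  tab <- matrix(0L, 4L, 4L, dimnames = list(ref = bases, alt = bases))
  per_clone <- if (inherits(x, "cloneset_events")) x$per_clone else list(x)
  for (cl in per_clone) {
    muts <- cl$mutations
    if (nrow(muts) == 0L) next
    ev_cat <- stats::setNames(cl$events$category, cl$events$event_id)
    keep <- muts$kind == "substitution" &
      !is.na(muts$event_id) &
      ev_cat[as.character(muts$event_id)] == category
    for (r in which(keep)) {
      tab[muts$ref[r], muts$alt[r]] <- tab[muts$ref[r], muts$alt[r]] + 1L
    }
  }
  structure(list(table = tab, n = sum(tab),
                 at_gc = c(GC = sum(tab[c("G", "C"), ]),
                           AT = sum(tab[c("A", "T"), ])),
                 category = category),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Substitution spectrum (", x$category, ", n = ", x$n, "; at G/C ",
      x$at_gc[["GC"]], ", at A/T ", x$at_gc[["AT"]], ")\n", sep = "")
  print(x$table)
  invisible(x)
}

# Round half away from zero, the convention used for printed percentages.
round_half_up <- function(x, digits = 0L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Proportion of transitions at G/C pairs in a spectrum
#'
#' The numerator counts G>A plus C>T substitutions (the transition at a
#' G/C pair read on either strand); the denominator is the total number
#' of substitutions in the spectrum.  The percentage is rounded half-up
#' to an integer, matching the printed `48%` / `11%` style, and the raw
#' fraction is always returned with it.
#'
#' @param spectrum A `"mutation_spectrum"`, or a 4x4 ref-by-alt count
#'   matrix with `A,C,G,T` dimnames.
#' @return A list with `numerator`, `denominator`, `percent`.
#' @export
gc_to_at_transition_percent <- function(spectrum) {
  tab <- if (inherits(spectrum, "mutation_spectrum")) spectrum$table
         else spectrum
  stopifnot(is.matrix(tab), all(dim(tab) == 4L))
  num <- tab["G", "A"] + tab["C", "T"]
  den <- sum(tab)
  if (den == 0L) {
    stop("empty spectrum: the transition proportion is undefined",
         call. = FALSE)
  }
  list(numerator = as.integer(num), denominator = as.integer(den),
       percent = as.integer(round_half_up(100 * num / den)))
}

#' Event-category rates for a clone set
#'
#' Summarizes classified events into per-category counts and rates: PM
#' and Amb are counted per mutation (each such event has exactly one
#' member), GC per conversion tract (one count per event, however many
#' mutations it carries).  Rates are normalized per clone and per kb of
#' sequenced clone length.
#'
#' @param x A `"cloneset_events"` object (or a data frame of events with
#'   a `category` column).
#' @param n_clones Number of clones sequenced (>= 1).
#' @param clone_length Sequenced length per clone, in nucleotides.
#' @return An object of class `"category_rates"`: counts, per-clone
#'   rates and per-kb rates for PM, Amb and GC, plus the denominators.
#' @export
category_rates <- function(x, n_clones, clone_length) {
  stopifnot(n_clones >= 1L, clone_length >= 1L)
  events <- if (is.data.frame(x)) x else x$events
  counts <- c(PM = sum(events$category == "PM"),
              AMB = sum(events$category == "AMB"),
              GC = sum(events$category == "GC"))
  per_clone <- counts / n_clones
  per_kb <- counts / (n_clones * clone_length / 1000)
  structure(list(counts = counts, per_clone = per_clone, per_kb = per_kb,
                 n_clones = as.integer(n_clones),
                 clone_length = as.integer(clone_length)),
            class = "category_rates")
}

#' @export
print.category_rates <- function(x, ...) {
  cat("Event rates over ", x$n_clones, " clone(s) x ", x$clone_length,
      " nt:\n", sep = "")
  df <- data.frame(count = x$counts,
                   per_clone = round(x$per_clone, 3),
                   per_kb = round(x$per_kb, 4))
  print(df)
  invisible(x)
}

#' Spectrum as a tidy table of cells and percentages
#'
#' @param spectrum A `"mutation_spectrum"`.
#' @return Data frame with `ref`, `alt`, `count`, `percent` (of the
#'   spectrum total; `NA` when the spectrum is empty).
#' @export
spectrum_table <- function(spectrum) {
  tab <- spectrum$table
  bases <- rownames(tab)
  rows <- expand.grid(alt = bases, ref = bases,
                      stringsAsFactors = FALSE)[, c("ref", "alt")]
  rows <- rows[rows$ref != rows$alt, ]
  rows$count <- mapply(function(r, a) tab[r, a], rows$ref, rows$alt)
  rows$percent <- if (spectrum$n > 0) {
    round_half_up(100 * rows$count / spectrum$n)
  } else NA_real_
  rownames(rows) <- NULL
  rows
}
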
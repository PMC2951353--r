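#' Lesion-plasmid architecture
#'
#' Describes the geometry of a site-specific T-T (6-4) photoproduct
#' construct.  Two arrangements are supported.  In the *staggered*
#' arrangement (a pQTs-like construct) the top and bottom strands each
#' carry one T-T lesion; the two lesion sites are disjoint, separated by
#' a fixed spacer (28 intervening nucleotides in the original construct),
#' and each lesion is placed opposite a marker dinucleotide (`GC`) on the
#' undamaged strand.  A replicated copy therefore reads the marker at a
#' site bypassed error-free (template switching to the undamaged nascent
#' strand) and something else -- most commonly `TT`, i.e. accurate `AA`
#' insertion -- at a site bypassed by translesion synthesis.  In the
#' *opposing* arrangement (pQTo-like) the two lesions occupy the same
#' site on opposite strands, so template switching cannot produce a
#' replicated copy and every product arises by TLS or by deletion across
#' the site.
#'
#' All coordinates are 0-based half-open on the reference (marker-form)
#' top strand.
#'
#' @param id Architecture id.
#' @param arrangement `"staggered"` or `"opposing"`.
#' @param reference Marker-form reference sequence (top strand).
#' @param top_site Integer length-2 vector `c(start, end)`: the top-strand
#'   lesion site (the product dinucleotide read opposite the top-strand
#'   T-T lesion).
#' @param bottom_site As `top_site`, for the bottom-strand lesion.
#' @param marker Marker dinucleotide read on error-free bypass
#'   (default `"GC"`).
#' @param accurate Dinucleotide inserted by accurate TLS (default `"AA"`).
#' @return An object of class `"lesion_architecture"`.
#' @export
lesion_architecture <- function(id, arrangement, reference, top_site,
                                bottom_site, marker = "GC",
                                accurate = "AA") {
  arrangement <- match.arg(arrangement, c("staggered", "opposing"))
  reference <- toupper(reference)
  check_dna(reference, what = "architecture reference")
  top_site <- as.integer(top_site)
  bottom_site <- as.integer(bottom_site)
  stopifnot(length(top_site) == 2L, length(bottom_site) == 2L)
  n <- nchar(reference)
  for (site in list(top_site, bottom_site)) {
    if (site[1L] < 0L || site[2L] > n || site[2L] <= site[1L]) {
      stop("lesion site [", site[1L], ", ", site[2L],
           ") outside reference of length ", n, call. = FALSE)
    }
  }
  if (nchar(marker) != 2L || nchar(accurate) != 2L) {
    stop("marker and accurate-insertion dinucleotides must have length 2",
         call. = FALSE)
  }
  spacer <- NA_integer_
  if (arrangement == "staggered") {
    if (max(top_site[1L], bottom_site[1L]) <
        min(top_site[2L], bottom_site[2L])) {
      stop("staggered arrangement requires disjoint lesion sites",
           call. = FALSE)
    }
    spacer <- if (top_site[2L] <= bottom_site[1L]) {
      bottom_site[1L] - top_site[2L]
    } else {
      top_site[1L] - bottom_site[2L]
    }
  } else {
    if (!identical(top_site, bottom_site)) {
      stop("opposing arrangement requires the two lesion sites to coincide",
           call. = FALSE)
    }
  }
  structure(
    list(id = as.character(id), arrangement = arrangement,
         reference = reference, top_site = top_site,
         bottom_site = bottom_site, marker = toupper(marker),
         accurate = toupper(accurate), spacer = spacer),
    class = "lesion_architecture"
  )
}

#' @export
print.lesion_architecture <- function(x, ...) {
  cat("Lesion-plasmid architecture '", x$id, "' (", x$arrangement, ")\n",
      sep = "")
  cat("  reference: ", nchar(x$reference), " nt; marker ", x$marker,
      "; accurate insertion ", x$accurate, "\n", sep = "")
  cat("  top site [", x$top_site[1L], ",", x$top_site[2L],
      "), bottom site [", x$bottom_site[1L], ",", x$bottom_site[2L], ")",
      sep = "")
  if (x$arrangement == "staggered") cat("; spacer ", x$spacer, " nt", sep = "")
  cat("\n")
  invisible(x)
}

#' Load a lesion-plasmid architecture from a YAML config
#'
#' The config is a flat key/value file with fields `id`, `arrangement`
#' (`staggered` or `opposing`), `reference` (marker-form top-strand
#' sequence), `top_site` and `bottom_site` (each `[start, end)`,
#' 0-based), and optionally `marker` and `accurate`.  The geometry is
#' validated on load: sites must lie inside the reference, be disjoint
#' under `staggered` (the derived spacer is recorded) and coincide under
#' `opposing`.
#'
#' @param path Path to a YAML config file.
#' @return A [lesion_architecture()] object.
#' @export
load_architecture <- function(path) {
  if (!file.exists(path)) {
    stop("architecture config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  required <- c("id", "arrangement", "reference", "top_site", "bottom_site")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("architecture config ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lesion_architecture(
    id = cfg$id, arrangement = cfg$arrangement, reference = cfg$reference,
    top_site = unlist(cfg$top_site), bottom_site = unlist(cfg$bottom_site),
    marker = if (is.null(cfg$marker)) "GC" else cfg$marker,
    accurate = if (is.null(cfg$accurate)) "AA" else cfg$accurate
  )
}
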
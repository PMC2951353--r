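#' Run the Ig V classification pipeline on FASTA inputs
#'
#' Composes mutation calling, PM/GC/Amb classification and spectrum /
#' rate summaries over FASTA files, writing the report tables to an
#' output directory: `mutations.tsv` (per-clone calls), `events.tsv`
#' (classified events), `spectrum.tsv` (12 substitution cells plus
#' pooled pair classes, counts beside percentages), `rates.tsv`
#' (per-category counts and rates) and `summary.json`.
#'
#' @param parent_fa FASTA with the single parental V segment.
#' @param donors_fa FASTA with the pseudogene donor array.
#' @param clones_fa FASTA with the sequenced clone segments.
#' @param out_dir Output directory (created if missing).
#' @param params A [classifier_params()].
#' @param aln_params An [align_params()].
#' @param max_divergence Clone-exclusion threshold (see
#'   [call_clone_mutations()]).
#' @return The `"cloneset_events"` object, invisibly.
#' @export
run_classify_igv <- function(parent_fa, donors_fa, clones_fa, out_dir,
                             params = classifier_params(),
                             aln_params = align_params(),
                             max_divergence = 0.1) {
  parent <- read_fasta(parent_fa)
  if (length(parent) != 1L) {
    stop("parent FASTA must contain exactly one record", call. = FALSE)
  }
  donors <- read_fasta(donors_fa)
  if (length(donors) < 1L) {
    stop("donor FASTA must contain at least one record", call. = FALSE)
  }
  clones <- read_fasta(clones_fa)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- classify_clone_set(parent[[1L]], clones, donors, params,
                            aln_params, max_divergence)
  prov <- provenance_block(
    inputs = list(parent = basename(parent_fa),
                  donors = basename(donors_fa),
                  clones = basename(clones_fa)),
    params = list(min_donor_string = params$min_donor_string,
                  search_revcomp = params$search_revcomp,
                  max_divergence = max_divergence))
  muts <- NULL
  for (id in names(res$per_clone)) {
    m <- res$per_clone[[id]]$mutations
    if (nrow(m)) muts <- rbind(muts, cbind(clone_id = id, m))
  }
  if (is.null(muts)) {
    muts <- data.frame(clone_id = character(0), kind = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), event_id = integer(0))
  }
  muts$pos_1based <- muts$pos + 1L
  write_report(muts, file.path(out_dir, "mutations.tsv"), "tsv", prov)
  ev <- res$events
  ev$tract_start_1based <- ev$tract_start + 1L
  write_report(ev, file.path(out_dir, "events.tsv"), "tsv", prov)
  spec <- tally_spectrum(res, "PM")
  write_report(spectrum_table(spec), file.path(out_dir, "spectrum.tsv"),
               "tsv", prov)
  n_clones <- max(1L, length(res$per_clone))
  rates <- category_rates(res, n_clones, nchar(parent[[1L]]))
  rates_df <- data.frame(category = names(rates$counts),
                         count = as.integer(rates$counts),
                         per_clone = rates$per_clone,
                         per_kb = rates$per_kb)
  write_report(rates_df, file.path(out_dir, "rates.tsv"), "tsv", prov)
  summary <- list(provenance = prov,
                  n_clones = length(res$per_clone),
                  excluded = res$excluded,
                  category_totals = as.list(rates$counts),
                  pm_substitutions = spec$n)
  if (spec$n > 0) {
    summary$gc_to_at_transition <- gc_to_at_transition_percent(spec)
  }
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "summary.json"))
  invisible(res)
}

#' Run the lesion-bypass classification pipeline on FASTA inputs
#'
#' Classifies every replicated product against the architecture and
#' writes `calls.tsv` (per-read calls), `fractions.tsv` (bypass-mode
#' percentages) and, when any TLS read exists, `incorporation.tsv`
#' (per-position nucleotide frequencies).
#'
#' @param products_fa FASTA of replicated product reads.
#' @param arch_config Architecture YAML config (see
#'   [load_architecture()]).
#' @param out_dir Output directory.
#' @param aln_params,min_identity Passed to [classify_products()].
#' @return The per-read call data frame, invisibly.
#' @export
run_classify_bypass <- function(products_fa, arch_config, out_dir,
                                aln_params = align_params(),
                                min_identity = 0.9) {
  arch <- load_architecture(arch_config)
  products <- read_fasta(products_fa)
  if (length(products) == 0L) {
    stop("product FASTA is empty", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- classify_products(products, arch, aln_params, min_identity)
  prov <- provenance_block(
    inputs = list(products = basename(products_fa),
                  architecture = arch$id),
    params = list(arrangement = arch$arrangement,
                  min_identity = min_identity))
  write_report(calls, file.path(out_dir, "calls.tsv"), "tsv", prov)
  fr <- tls_fraction(calls)
  fr_df <- data.frame(mode = names(fr$counts),
                      count = as.integer(fr$counts),
                      percent = as.numeric(fr$percent))
  write_report(fr_df, file.path(out_dir, "fractions.tsv"), "tsv", prov)
  if (any(calls$mode %in% c("TLS_top", "TLS_bottom", "TLS"))) {
    prof <- incorporation_profile(calls)
    prof_df <- data.frame(base = rownames(prof), as.data.frame(prof),
                          check.names = FALSE)
    write_report(prof_df, file.path(out_dir, "incorporation.tsv"), "tsv",
                 prov)
  }
  invisible(calls)
}

#' Poisson aberration rates from a counts table
#'
#' Reads a TSV mirroring the aberration-scoring table (columns `label`,
#' `n_cells`, `chromatid_gaps`, `chromatid_breaks`, `isochromatid_gaps`,
#' `isochromatid_breaks`), computes the per-cell Poisson rate and SE for
#' each row and writes `aberration_rates.tsv` with the total presented
#' as in the source table (`x (mean+/-SE)` at two decimals) beside the
#' full-precision values.
#'
#' @param counts_tsv Input TSV path.
#' @param out_dir Output directory.
#' @return Data frame of rate rows, invisibly.
#' @export
run_aberration_stats <- function(counts_tsv, out_dir) {
  if (!file.exists(counts_tsv)) {
    stop("counts table not found: ", counts_tsv, call. = FALSE)
  }
  df <- utils::read.delim(counts_tsv, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("label", "n_cells", "chromatid_gaps", "chromatid_breaks",
            "isochromatid_gaps", "isochromatid_breaks")
  if (nrow(df) == 0L || !all(need %in% names(df))) {
    stop("counts table must be non-empty with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    ac <- aberration_count(df$n_cells[i], df$chromatid_gaps[i],
                           df$chromatid_breaks[i], df$isochromatid_gaps[i],
                           df$isochromatid_breaks[i], label = df$label[i])
    r <- poisson_rate(ac)
    data.frame(label = df$label[i], n_cells = r$n, x = r$x,
               mean = r$mean, se = r$se,
               printed = sprintf("%g (%.2f±%.2f)", r$x, r$mean_2dp,
                                 r$se_2dp))
  }))
  write_report(rows, file.path(out_dir, "aberration_rates.tsv"), "tsv",
               provenance_block(inputs = list(counts = basename(counts_tsv))))
  invisible(rows)
}

#' Mann-Whitney comparison and induced-SCE subtraction for SCE samples
#'
#' Reads a TSV of per-cell SCE counts (columns `condition`, `count`),
#' runs the two-sided Mann-Whitney U test for every pair of conditions,
#' and, when `treated` / `control` condition names are given, the
#' induced-SCE subtraction.  Writes `sce_tests.tsv` (and
#' `sce_induced.tsv` if requested).
#'
#' @param sce_tsv Input TSV path.
#' @param out_dir Output directory.
#' @param treated,control Optional condition labels for the induced-SCE
#'   subtraction.
#' @return List with `tests` (data frame) and optional `induced`.
#' @export
run_sce_stats <- function(sce_tsv, out_dir, treated = NULL,
                          control = NULL) {
  if (!file.exists(sce_tsv)) {
    stop("SCE table not found: ", sce_tsv, call. = FALSE)
  }
  df <- utils::read.delim(sce_tsv, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !all(c("condition", "count") %in% names(df))) {
    stop("SCE table must be non-empty with columns condition, count",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- unique(df$condition)
  tests <- NULL
  if (length(conds) >= 2L) {
    for (i in seq_len(length(conds) - 1L)) {
      for (j in (i + 1L):length(conds)) {
        a <- df$count[df$condition == conds[i]]
        b <- df$count[df$condition == conds[j]]
        mw <- mann_whitney(a, b)
        tests <- rbind(tests, data.frame(
          a = conds[i], b = conds[j], n_a = length(a), n_b = length(b),
          mean_a = mean(a), mean_b = mean(b), U = mw$U, p = mw$p,
          method = mw$method))
      }
    }
  }
  if (is.null(tests)) {
    tests <- data.frame(a = character(0), b = character(0),
                        n_a = integer(0), n_b = integer(0),
                        mean_a = numeric(0), mean_b = numeric(0),
                        U = numeric(0), p = numeric(0),
                        method = character(0))
  }
  prov <- provenance_block(inputs = list(sce = basename(sce_tsv)))
  write_report(tests, file.path(out_dir, "sce_tests.tsv"), "tsv", prov)
  out <- list(tests = tests)
  if (!is.null(treated) && !is.null(control)) {
    ind <- induced_sce(df$count[df$condition == treated],
                       df$count[df$condition == control])
    ind_df <- data.frame(treated = treated, control = control,
                         induced_mean = ind$mean, induced_se = ind$se)
    write_report(ind_df, file.path(out_dir, "sce_induced.tsv"), "tsv",
                 prov)
    out$induced <- ind
  }
  invisible(out)
}

#' Generate a complete synthetic data set on disk
#'
#' One-stop generator used by the command-line `simulate` subcommand
#' and by `make-fixtures`: writes a parent FASTA, a simulated donor
#' array, a simulated clone set with truth labels, and (if an
#' architecture config is supplied) simulated bypass products with
#' truth.  Identical configuration and seed give byte-identical files.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param parent_length Parent length in nucleotides (default 400).
#' @param donor_params A [donor_sim_params()] (seed is overridden by
#'   `seed + 1`).
#' @param hypermut_params A [hypermut_sim_params()] (seed overridden by
#'   `seed + 2`).
#' @param arch Optional [lesion_architecture()].
#' @param bypass_params Optional [bypass_sim_params()] (seed overridden
#'   by `seed + 3`).
#' @return Named list of generated objects, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, parent_length = 400L,
                         donor_params = donor_sim_params(5L, 0.03),
                         hypermut_params = hypermut_sim_params(),
                         arch = NULL, bypass_params = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parent <- random_dna(parent_length, seed = seed)
  write_fasta(stats::setNames(parent, "parentV"),
              file.path(out_dir, "parent.fasta"))
  donor_params$seed <- seed + 1L
  donors <- simulate_pseudogene_db(parent, donor_params)
  write_fasta(donors, file.path(out_dir, "donors.fasta"))
  hypermut_params$seed <- seed + 2L
  sim <- simulate_clone_set(parent, donors, hypermut_params)
  write_fasta(sim$clones, file.path(out_dir, "clones.fasta"))
  write_report(sim$truth, file.path(out_dir, "clone_truth.tsv"), "tsv",
               provenance_block(params = list(seed = seed)))
  out <- list(parent = parent, donors = donors, clones = sim)
  if (!is.null(arch) && !is.null(bypass_params)) {
    bypass_params$seed <- seed + 3L
    bp <- simulate_bypass_products(arch, bypass_params)
    write_fasta(bp$products, file.path(out_dir, "products.fasta"))
    write_report(bp$truth, file.path(out_dir, "product_truth.tsv"), "tsv",
                 provenance_block(params = list(seed = seed)))
    out$products <- bp
  }
  invisible(out)
}
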
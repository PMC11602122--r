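# File readers/writers and the umbrella pipeline.

#' Read plasmid sequences from FASTA
#'
#' Record id is the first whitespace-delimited token of the header;
#' sequences are upper-cased; GC is computed over A/C/G/T positions only.
#' Topology is declared here (FASTA headers are not standardized), the same
#' for all records.
#'
#' @param path FASTA file.
#' @param topology `"circular"` (default for plasmids) or `"linear"`.
#' @return Tibble of plasmid records in file order (see [plasmid_record()]).
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s) in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  empty <- which(BiocGenerics::width(set) == 0L)
  if (length(empty) > 0L) {
    stop("empty record(s) in FASTA: ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_rows(purrr::map(seq_along(set), function(i) {
    plasmid_record(ids[i], as.character(set[[i]]), topology)
  }))
}

#' Write plasmid records to FASTA
#'
#' @param plasmids Tibble of plasmid records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(plasmids, path) {
  set <- Biostrings::DNAStringSet(plasmids$sequence)
  names(set) <- plasmids$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a mating-assay table
#'
#' Tab-separated with a header row; see [transfer_efficiency()] for the
#' required columns.
#'
#' @param path TSV file.
#' @return Tibble of assay rows.
#' @export
read_assays <- function(path) {
  if (!file.exists(path)) stop("assay table not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("colonies_T", "colonies_D", "colonies_R",
                "dilution_T", "dilution_D", "dilution_R",
                "plated_volume", "time_h")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("assay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Run the full analysis pipeline
#'
#' Composes the stages scan -> expect -> efficiency -> summarize -> fit on
#' files, writing every stage output as TSV plus a JSON run report with the
#' package version, seed, options in effect, md5 hashes of the outputs and
#' headline summaries (overall median/mean RE, per-RM-type site medians,
#' site-number regression terms when the design permits the fit).
#'
#' @param config A list with elements `fasta`, `enzymes`, `assays` (input
#'   paths), `outdir`, and options `topology` ("circular"), `duplex`
#'   ("auto"), `ambiguity` ("lenient"), `control` ("none"),
#'   `include_censored` (TRUE), `seed` (optional).
#' @return The run report (list), invisibly written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(topology = "circular", duplex = "auto",
                   ambiguity = "lenient", control = "none",
                   include_censored = TRUE, seed = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("fasta", "enzymes", "assays")) {
    if (is.null(config[[f]])) {
      stop("config is missing required path '", f, "'", call. = FALSE)
    }
    if (!file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]], call. = FALSE)
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  plasmids <- stage("read", read_fasta(config$fasta, config$topology))
  enzymes <- stage("read", parse_enzyme_table(config$enzymes))
  assays <- stage("read", read_assays(config$assays))

  sites <- stage("scan", site_table(plasmids, enzymes,
                                    duplex = config$duplex,
                                    ambiguity = config$ambiguity))
  expectations <- stage("expect", expectation_table(plasmids, enzymes,
                                                    duplex = config$duplex))
  gamma_tbl <- stage("efficiency", transfer_efficiency(assays))
  re_tbl <- stage("efficiency",
                  restriction_efficiency(gamma_tbl, control = config$control))
  re_summary <- stage("summarize",
                      summarize_re(re_tbl, .data$plasmid_id, .data$rm_system,
                                   include_censored = config$include_censored))
  overall <- stage("summarize",
                   summarize_re(re_tbl,
                                include_censored = config$include_censored))

  fit_terms <- NULL
  fit_note <- NULL
  model_data <- stage("fit", prepare_re_dataset(re_tbl, sites))
  fit_try <- tryCatch({
    f <- if (length(unique(model_data$rm_system)) > 1L) {
      log10_re ~ rm_system * log10_nsites + rm_system * plasmid_id
    } else {
      log10_re ~ log10_nsites
    }
    fit_re_model(model_data, f, allow_aliased = TRUE)
  }, error = function(e) e)
  if (inherits(fit_try, "error")) {
    fit_note <- conditionMessage(fit_try)
  } else {
    at <- fit_try$anova
    fit_terms <- lapply(rownames(at), function(tn) {
      list(term = tn, df = at[tn, "Df"], F = at[tn, "F value"],
           p = at[tn, "Pr(>F)"])
    })
  }

  paths <- list(
    sites = file.path(config$outdir, "sites.tsv"),
    expectations = file.path(config$outdir, "expectations.tsv"),
    gamma = file.path(config$outdir, "gamma.tsv"),
    re = file.path(config$outdir, "re.tsv"),
    re_summary = file.path(config$outdir, "re_summary.tsv")
  )
  readr::write_tsv(sites, paths$sites)
  readr::write_tsv(expectations, paths$expectations)
  readr::write_tsv(gamma_tbl, paths$gamma)
  readr::write_tsv(re_tbl, paths$re)
  readr::write_tsv(re_summary, paths$re_summary)

  report <- list(
    package = "rmconj",
    version = as.character(utils::packageVersion("rmconj")),
    seed = config$seed,
    options = config[c("topology", "duplex", "ambiguity", "control",
                       "include_censored")],
    inputs = config[c("fasta", "enzymes", "assays")],
    output_hashes = as.list(tools::md5sum(unlist(paths))),
    headline = list(
      n_plasmids = nrow(plasmids),
      n_enzymes = nrow(enzymes),
      n_re_estimates = nrow(re_tbl),
      median_re = overall$median_re,
      mean_re = overall$mean_re,
      geo_mean_re = overall$geo_mean_re,
      censored_frac = overall$censored_frac,
      site_type_medians = purrr::transpose(site_type_medians(sites)),
      fit_terms = fit_terms,
      fit_note = fit_note
    )
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
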
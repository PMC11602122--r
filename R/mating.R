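# Transfer-efficiency and restriction-efficiency estimation from
# colony-count mating assays.

#' Cell density from a plate count
#'
#' Standard plate-count conversion: colonies x dilution factor / plated
#' volume, giving cells/ml.
#'
#' @param colonies Non-negative colony count.
#' @param dilution Dilution factor of the counted plate (>= 1; 1 = undiluted).
#' @param plated_volume Plated volume in ml (> 0).
#' @return Density in cells/ml (0 when no colonies were seen).
#' @examples
#' plate_density(40, 1e4, 0.01) # 4e7 cells/ml
#' @export
plate_density <- function(colonies, dilution, plated_volume) {
  if (any(plated_volume <= 0)) stop("plated_volume must be > 0", call. = FALSE)
  if (any(colonies < 0)) stop("colony counts must be >= 0", call. = FALSE)
  if (any(dilution < 1)) stop("dilution factors must be >= 1", call. = FALSE)
  colonies * dilution / plated_volume
}

#' Transfer efficiency from mating-assay counts
#'
#' Computes the end-point conjugation transfer efficiency
#' gamma (ml/cell/h) = T / (D * R * t), where T, D and R are the cell
#' densities (cells/ml) of transconjugants, donors and recipients and t the
#' mating time in hours. When no transconjugant colony was observed, a
#' detection-threshold (censored) value is computed by assuming 0.5 colonies
#' on the lowest-dilution plate actually screened: for zero-count assays
#' `dilution_T` and `plated_volume` must therefore describe that plate.
#'
#' @param assays Tibble with one row per assay and columns `colonies_T`,
#'   `colonies_D`, `colonies_R`, `dilution_T`, `dilution_D`, `dilution_R`,
#'   `plated_volume`, `time_h` (any further columns, e.g. `plasmid_id`,
#'   `rm_system`, `replicate`, are carried through).
#' @param detection_colonies Colony count substituted when `colonies_T == 0`
#'   (default 0.5).
#' @return The input tibble with added columns `dens_T`, `dens_D`, `dens_R`
#'   (cells/ml), `gamma` (ml/cell/h) and `censored` (TRUE when gamma is an
#'   upper-bound detection threshold).
#' @examples
#' a <- tibble::tibble(colonies_T = 40, colonies_D = 100, colonies_R = 100,
#'                     dilution_T = 1e3, dilution_D = 1e6, dilution_R = 1e6,
#'                     plated_volume = 1, time_h = 4)
#' transfer_efficiency(a)$gamma # 1e-12
#' @export
transfer_efficiency <- function(assays, detection_colonies = 0.5) {
  required <- c("colonies_T", "colonies_D", "colonies_R",
                "dilution_T", "dilution_D", "dilution_R",
                "plated_volume", "time_h")
  missing_cols <- setdiff(required, names(assays))
  if (length(missing_cols) > 0L) {
    stop("assay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(assays$time_h <= 0)) stop("time_h must be > 0", call. = FALSE)
  if (any(assays$colonies_D == 0 | assays$colonies_R == 0)) {
    stop("zero donor or recipient count: assay invalid (density undefined)",
         call. = FALSE)
  }
  dens_D <- plate_density(assays$colonies_D, assays$dilution_D, assays$plated_volume)
  dens_R <- plate_density(assays$colonies_R, assays$dilution_R, assays$plated_volume)
  censored <- assays$colonies_T == 0
  eff_T <- ifelse(censored, detection_colonies, assays$colonies_T)
  dens_T <- eff_T * assays$dilution_T / assays$plated_volume
  gamma <- dens_T / (dens_D * dens_R * assays$time_h)
  dplyr::mutate(assays,
    dens_T = dens_T, dens_D = dens_D, dens_R = dens_R,
    gamma = gamma, censored = censored
  )
}

#' Restriction efficiency from paired transfer estimates
#'
#' For each plasmid (and any extra grouping columns) pairs replicates of the
#' RM-carrying arm with replicates of the RM-free control arm by sorted
#' replicate index and computes the fold restriction
#' `re_fold = gamma_RM- / gamma_RM+` (> 1 means the RM system impedes
#' transfer). The raw ratio gamma_RM+/gamma_RM- is retained as `raw_ratio`.
#' Unpaired extra replicates in either arm are dropped with a warning; a
#' pair is censored when either member is.
#'
#' @param estimates Output of [transfer_efficiency()] with columns
#'   `rm_system`, `replicate`, `gamma`, `censored` plus grouping columns.
#' @param control Label of the RM-free arm in `rm_system` (default "none").
#' @param group_cols Columns defining an experimental unit (default
#'   `"plasmid_id"`); e.g. add `"mutant"` or `"experiment"` when present.
#' @return Tibble with one row per pair: grouping columns, `rm_system`,
#'   `replicate` (of the RM+ member), `gamma_plus`, `gamma_minus`,
#'   `re_fold`, `raw_ratio`, `censored`.
#' @export
restriction_efficiency <- function(estimates, control = "none",
                                   group_cols = "plasmid_id") {
  required <- c("rm_system", "replicate", "gamma", "censored", group_cols)
  missing_cols <- setdiff(required, names(estimates))
  if (length(missing_cols) > 0L) {
    stop("estimate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  groups <- dplyr::distinct(estimates[, group_cols, drop = FALSE])
  out <- purrr::map(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(estimates))
    for (col in group_cols) sel <- sel & estimates[[col]] == groups[[col]][g]
    block <- estimates[sel, ]
    minus <- dplyr::arrange(block[block$rm_system == control, ], .data$replicate)
    if (nrow(minus) == 0L) {
      stop("no control ('", control, "') replicates for group ",
           paste(unlist(groups[g, ]), collapse = "/"), call. = FALSE)
    }
    arms <- setdiff(unique(block$rm_system), control)
    purrr::map(arms, function(arm) {
      plus <- dplyr::arrange(block[block$rm_system == arm, ], .data$replicate)
      if (nrow(plus) == 0L) return(NULL)
      n <- min(nrow(plus), nrow(minus))
      if (nrow(plus) != nrow(minus)) {
        warning(sprintf(
          "unequal replicate numbers for %s (%s): %d RM+ vs %d RM- ; extras dropped",
          paste(unlist(groups[g, ]), collapse = "/"), arm, nrow(plus), nrow(minus)
        ), call. = FALSE)
      }
      dplyr::bind_cols(
        groups[rep(g, n), , drop = FALSE],
        tibble::tibble(
          rm_system = arm,
          replicate = plus$replicate[seq_len(n)],
          gamma_plus = plus$gamma[seq_len(n)],
          gamma_minus = minus$gamma[seq_len(n)],
          re_fold = minus$gamma[seq_len(n)] / plus$gamma[seq_len(n)],
          raw_ratio = plus$gamma[seq_len(n)] / minus$gamma[seq_len(n)],
          censored = plus$censored[seq_len(n)] | minus$censored[seq_len(n)]
        )
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

#' Geometric mean
#'
#' @param x Positive values.
#' @return exp(mean(log(x))).
#' @export
geometric_mean <- function(x) exp(mean(log(x)))

#' Summarize restriction-efficiency estimates
#'
#' Per-group geometric mean (the scale on which fold ratios average
#' naturally), median and arithmetic mean of `re_fold`, with replicate count
#' and censored fraction.
#'
#' @param re Output of [restriction_efficiency()].
#' @param ... Grouping columns (tidy-select), e.g. `plasmid_id, rm_system`.
#'   With no grouping a single overall row is returned.
#' @param include_censored Keep detection-threshold pairs (default TRUE,
#'   treating thresholds as values, as when summarizing a complete assay
#'   grid); FALSE drops them first.
#' @return Tibble of group keys plus `n`, `geo_mean_re`, `median_re`,
#'   `mean_re`, `censored_frac`.
#' @export
summarize_re <- function(re, ..., include_censored = TRUE) {
  if (!include_censored) re <- dplyr::filter(re, !.data$censored)
  if (nrow(re) == 0L) stop("no estimates to summarize", call. = FALSE)
  re |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      geo_mean_re = geometric_mean(.data$re_fold),
      median_re = stats::median(.data$re_fold),
      mean_re = mean(.data$re_fold),
      censored_frac = mean(.data$censored),
      .groups = "drop"
    )
}
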
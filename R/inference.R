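# Linear models on log10 restriction efficiency and multiple-comparison
# contrasts for plasmid mutants.

#' Assemble the regression table of RE against site numbers
#'
#' Joins per-replicate restriction-efficiency estimates with the site-count
#' table and applies the transformations used throughout: log10 of the RE
#' fold value, and log10 of the site count after replacing zero counts by
#' 0.5 (a zero cannot be log-transformed; the half-count offset keeps those
#' plasmid x RM combinations in the model).
#'
#' @param re Output of [restriction_efficiency()] (columns `plasmid_id`,
#'   `rm_system`, `re_fold`, ...).
#' @param sites Output of [site_table()] (columns `plasmid_id`,
#'   `enzyme_name`, `n_sites`, `rm_type`).
#' @param zero_offset Value substituted for zero site counts before the log
#'   (default 0.5).
#' @return The RE tibble with added columns `n_sites`, `rm_type`,
#'   `log10_re`, `log10_nsites`.
#' @export
prepare_re_dataset <- function(re, sites, zero_offset = 0.5) {
  stopifnot(all(c("plasmid_id", "rm_system", "re_fold") %in% names(re)))
  stopifnot(all(c("plasmid_id", "enzyme_name", "n_sites") %in% names(sites)))
  key <- sites[, c("plasmid_id", "enzyme_name", "n_sites",
                   intersect("rm_type", names(sites)))]
  joined <- dplyr::left_join(
    re, key, by = c(plasmid_id = "plasmid_id", rm_system = "enzyme_name")
  )
  if (anyNA(joined$n_sites)) {
    bad <- unique(paste0(joined$plasmid_id, " x ", joined$rm_system)[is.na(joined$n_sites)])
    stop("no site counts for combination(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  dplyr::mutate(joined,
    log10_re = log10(.data$re_fold),
    log10_nsites = log10(ifelse(.data$n_sites == 0, zero_offset, .data$n_sites))
  )
}

#' Fit a linear model on log10 restriction efficiency
#'
#' Ordinary least squares with sequential (type-I) sums of squares for the
#' per-term F tests, the construction behind `anova(lm(...))`; term order is
#' therefore meaningful and follows the supplied formula. The design must be
#' full rank after factor encoding.
#'
#' @param data A model table from [prepare_re_dataset()] (or any data frame).
#' @param formula Model formula, e.g.
#'   `log10_re ~ rm_system * log10_nsites + rm_system * plasmid_id`.
#' @param allow_aliased By default a rank-deficient design is an error that
#'   names the aliased coefficients. Set TRUE to let aliased columns be
#'   dropped the way `lm()` does; this is needed for the saturated
#'   site-number model above, where `log10_nsites` is a function of the
#'   plasmid x RM cell and some interaction columns are necessarily
#'   redundant.
#' @return An object of class `re_fit`: a list with the fitted `lm` object
#'   (`model`), the sequential ANOVA table (`anova`), `coefficients`, fitted
#'   values and residuals.
#' @export
fit_re_model <- function(data, formula, allow_aliased = FALSE) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit)) && !allow_aliased) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (stats::df.residual(fit) <= 0) {
    stop("no residual degrees of freedom (n <= model df)", call. = FALSE)
  }
  structure(
    list(
      model = fit,
      formula = formula,
      anova = stats::anova(fit),
      coefficients = stats::coef(fit),
      fitted = stats::fitted(fit),
      residuals = stats::residuals(fit)
    ),
    class = "re_fit"
  )
}

#' @export
print.re_fit <- function(x, ...) {
  cat("Linear model on log10(RE):",
      deparse(x$formula), "\n\nSequential (type-I) ANOVA:\n")
  print(x$anova)
  invisible(x)
}

#' Bonferroni adjustment with explicit test count
#'
#' `min(1, m * p)`, with the test family size m stated explicitly (for the
#' mutant screen: number of RM systems x number of mutants tested, which can
#' exceed the number of p-values actually computed).
#'
#' @param p Raw p-value(s).
#' @param m Family size.
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m) pmin(1, p * m)

#' Mutant vs wild-type restriction-efficiency contrasts
#'
#' Implements the two-stage screen for mutant effects: first a gate model
#' `log10_re ~ [experiment +] mutant * rm_system` is fitted and the
#' mutant:RM interaction tested (sequential F); only when that interaction
#' is significant at `gate_alpha` are per-cell contrasts emitted. Each
#' contrast compares one mutant to the wild type within one RM system by an
#' unpaired two-sided t-test on log10 RE (Welch by default), reporting the
#' geometric-mean fold change and a Bonferroni-adjusted p with family size
#' m = (number of RM systems) x (number of mutants tested). Cells with
#' fewer than 2 replicates yield an NA contrast.
#'
#' @param data Tibble with columns `log10_re`, `rm_system` and a mutant
#'   identity column.
#' @param wild_type Level of `mutant_col` identifying the wild type.
#' @param mutant_col Name of the mutant identity column (default "mutant").
#' @param experiment_col Optional name of a blocking factor added as an
#'   additive term in the gate model (e.g. "experiment").
#' @param var_equal FALSE (default) for Welch's t-test; TRUE for the
#'   pooled-variance test.
#' @param gate_alpha Significance level of the interaction gate (default 0.05).
#' @return A list with `gate` (interaction F, df and p, and whether the gate
#'   passed) and `contrasts` (tibble with `rm_system`, `mutant`, `n_wt`,
#'   `n_mut`, `fold_change`, `t`, `df`, `p`, `p_adj`; empty when the gate
#'   fails).
#' @export
mutant_contrasts <- function(data, wild_type = "WT", mutant_col = "mutant",
                             experiment_col = NULL, var_equal = FALSE,
                             gate_alpha = 0.05) {
  stopifnot(all(c("log10_re", "rm_system", mutant_col) %in% names(data)))
  data$..mutant <- factor(data[[mutant_col]])
  data$..rm <- factor(data$rm_system)
  if (!wild_type %in% levels(data$..mutant)) {
    stop("wild-type level '", wild_type, "' not found in ", mutant_col,
         call. = FALSE)
  }
  data$..mutant <- stats::relevel(data$..mutant, ref = wild_type)
  gate_formula <- if (is.null(experiment_col)) {
    log10_re ~ ..mutant * ..rm
  } else {
    data$..exp <- factor(data[[experiment_col]])
    log10_re ~ ..exp + ..mutant * ..rm
  }
  gate_fit <- stats::lm(gate_formula, data = data)
  atab <- stats::anova(gate_fit)
  irow <- grep("\\.\\.mutant:\\.\\.rm", rownames(atab))
  gate <- list(
    F = atab$`F value`[irow],
    df = c(atab$Df[irow], stats::df.residual(gate_fit)),
    p = atab$`Pr(>F)`[irow],
    passed = atab$`Pr(>F)`[irow] < gate_alpha
  )
  mutants <- setdiff(levels(data$..mutant), wild_type)
  rms <- levels(data$..rm)
  m <- length(rms) * length(mutants)
  contrasts <- tibble::tibble(
    rm_system = character(), mutant = character(),
    n_wt = integer(), n_mut = integer(), fold_change = numeric(),
    t = numeric(), df = numeric(), p = numeric(), p_adj = numeric()
  )
  if (gate$passed) {
    rows <- list()
    for (rm in rms) {
      wt_vals <- data$log10_re[data$..rm == rm & data$..mutant == wild_type]
      for (mu in mutants) {
        mu_vals <- data$log10_re[data$..rm == rm & data$..mutant == mu]
        if (length(wt_vals) < 2L || length(mu_vals) < 2L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            rm_system = rm, mutant = mu,
            n_wt = length(wt_vals), n_mut = length(mu_vals),
            fold_change = NA_real_, t = NA_real_, df = NA_real_,
            p = NA_real_, p_adj = NA_real_
          )
          next
        }
        diff_means <- mean(mu_vals) - mean(wt_vals)
        df0 <- length(mu_vals) + length(wt_vals) - 2
        tt <- if (stats::sd(mu_vals) == 0 && stats::sd(wt_vals) == 0) {
          # degenerate zero-variance limit of the t-test
          if (diff_means == 0) {
            list(statistic = 0, parameter = df0, p.value = 1)
          } else {
            list(statistic = sign(diff_means) * Inf, parameter = df0, p.value = 0)
          }
        } else {
          stats::t.test(mu_vals, wt_vals, var.equal = var_equal)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rm_system = rm, mutant = mu,
          n_wt = length(wt_vals), n_mut = length(mu_vals),
          fold_change = 10^diff_means,
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value,
          p_adj = bonferroni_adjust(tt$p.value, m)
        )
      }
    }
    contrasts <- dplyr::bind_rows(rows)
  }
  list(gate = gate, contrasts = contrasts, m = m)
}
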
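# Synthetic plasmid sequences and simulated mating experiments with known
# ground truth.

# Sample a concrete base for each position of a degenerate motif, weighting
# within each allowed set by the background composition.
realize_motif <- function(motif, probs) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  vapply(chars, function(ch) {
    allowed <- IUPAC_SETS[[ch]]
    if (length(allowed) == 1L) return(allowed)
    w <- probs[allowed]
    sample(allowed, 1L, prob = w / sum(w))
  }, "")
}

#' Generate a random plasmid sequence with controlled site counts
#'
#' Draws i.i.d. bases at a target GC content, scrubs every spontaneous
#' duplex occurrence of the planted and forbidden motifs by local
#' resampling, then inserts exactly the requested number of copies of each
#' planted motif at random non-overlapping positions. The result is verified
#' with the package's own duplex scanner; generation is retried (bounded)
#' if planting creates spurious junction matches.
#'
#' @param length Sequence length in bases.
#' @param gc Target GC fraction (default 0.5).
#' @param planted Named integer vector of site counts, names are IUPAC
#'   motifs, e.g. `c(GAATTC = 5)`. Counts of 0 only forbid the motif.
#' @param forbid Character vector of additional motifs scrubbed from the
#'   sequence (duplex: both orientations removed).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param id Plasmid id for the returned record.
#' @param seed Optional integer seed (sets the RNG).
#' @param max_tries Bound on regeneration attempts (default 100).
#' @return A [plasmid_record()] tibble row.
#' @export
generate_sequence <- function(length, gc = 0.5, planted = NULL,
                              forbid = character(),
                              topology = c("circular", "linear"),
                              id = "synthetic", seed = NULL, max_tries = 100L) {
  topology <- match.arg(topology)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(planted)) planted <- integer(0)
  if (length(planted) > 0L) {
    stopifnot(!is.null(names(planted)), all(planted >= 0))
    names(planted) <- vapply(names(planted), validate_motif, "")
  }
  forbid <- vapply(forbid, validate_motif, "", USE.NAMES = FALSE)
  plant_total <- if (length(planted) > 0L) {
    sum(nchar(names(planted)) * planted)
  } else 0L
  if (length < max(plant_total, 1L)) {
    stop("sequence length too short for the requested planted sites",
         call. = FALSE)
  }
  probs <- composition_model(gc)$probs
  bases <- names(probs)
  # duplex scrubbing: remove both orientations of every controlled motif
  avoid <- unique(c(names(planted), forbid))
  avoid <- unique(c(avoid, vapply(avoid, reverse_complement, "")))

  for (attempt in seq_len(max_tries)) {
    chars <- sample(bases, length, replace = TRUE, prob = probs)
    # scrub spontaneous occurrences by local resampling
    clean <- length(avoid) == 0L
    for (round in seq_len(200L)) {
      if (clean) break
      seq_str <- paste(chars, collapse = "")
      dirty <- FALSE
      for (m in avoid) {
        hits <- scan_strand(seq_str, m, topology)
        if (length(hits) > 0L) {
          dirty <- TRUE
          k <- nchar(m)
          for (h in hits) {
            idx <- ((h - 1L + 0:(k - 1L)) %% length) + 1L
            chars[idx] <- sample(bases, k, replace = TRUE, prob = probs)
          }
          seq_str <- paste(chars, collapse = "")
        }
      }
      clean <- !dirty
    }
    if (!clean) next
    # plant motifs at random non-overlapping (non-wrapping) positions
    occupied <- integer(0)
    plant_ok <- TRUE
    for (m in names(planted)) {
      k <- nchar(m)
      n_copies <- planted[[m]]
      if (n_copies == 0L) next
      for (cp in seq_len(n_copies)) {
        placed <- FALSE
        for (draw in seq_len(1000L)) {
          s <- sample.int(length - k + 1L, 1L)
          win <- s:(s + k - 1L)
          if (!any(win %in% occupied)) {
            chars[win] <- realize_motif(m, probs)
            occupied <- c(occupied, win)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          plant_ok <- FALSE
          break
        }
      }
      if (!plant_ok) break
    }
    if (!plant_ok) next
    rec <- plasmid_record(id, paste(chars, collapse = ""), topology)
    # verify with the duplex scanner
    ok <- TRUE
    for (m in names(planted)) {
      got <- count_sites(rec, list(name = m, recognition = m))$n_sites
      if (got != planted[[m]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      for (m in forbid) {
        if (m %in% names(planted)) next
        if (count_sites(rec, list(name = m, recognition = m))$n_sites > 0L) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(rec)
  }
  stop("could not generate a sequence with the requested site counts in ",
       max_tries, " attempts", call. = FALSE)
}

# Choose the plate a microbiologist would count from a dilution series:
# the least-diluted plate with <= 300 colonies; if every plate is crowded,
# the most-diluted one; if no colonies anywhere, the least-diluted plate
# (which defines the detection limit).
pick_plate <- function(counts, dilutions) {
  ord <- order(dilutions)
  counts <- counts[ord]
  dilutions <- dilutions[ord]
  countable <- which(counts > 0 & counts <= 300)
  if (length(countable) > 0L) {
    i <- countable[1L]
  } else if (any(counts > 300)) {
    i <- length(counts)
  } else {
    i <- 1L
  }
  list(colonies = counts[i], dilution = dilutions[i])
}

#' Simulate replicate mating assays with Poisson plating noise
#'
#' The expected transconjugant density after mating is
#' `true_gamma * D * R * t * p_escape^n_sites` (multiplicative per-site
#' escape from restriction, independent between sites); donor and recipient
#' densities stay constant, matching the end-point estimator's assumptions.
#' Every plate of the serial dilution receives a Poisson-distributed colony
#' count with mean density x plated_volume / dilution, and the counted
#' plate is chosen as in practice (least-diluted plate with at most 300
#' colonies). Zero transconjugant counts are recorded at the lowest
#' dilution, where the detection-threshold rule applies.
#'
#' @param true_gamma True transfer efficiency (ml/cell/h).
#' @param donor_density,recipient_density Cell densities (cells/ml).
#' @param time_h Mating time in hours.
#' @param n_replicates Number of replicate assays.
#' @param p_escape Per-site probability of escaping restriction in (0, 1].
#' @param n_sites Number of recognition sites on the plasmid.
#' @param dilution_series Dilution factors plated (default `10^(0:7)`).
#' @param plated_volume Plated volume per spot, ml.
#' @param plasmid_id,rm_system Labels carried into the assay rows.
#' @param replicates Optional explicit replicate indices (default
#'   `1:n_replicates`).
#' @param seed Optional integer seed.
#' @return Tibble of mating-assay rows suitable for
#'   [transfer_efficiency()].
#' @export
simulate_assay <- function(true_gamma, donor_density = 1e9,
                           recipient_density = 1e9, time_h = 4,
                           n_replicates = 4, p_escape = 1, n_sites = 0,
                           dilution_series = 10^(0:7), plated_volume = 0.1,
                           plasmid_id = "plasmid", rm_system = "none",
                           replicates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(true_gamma > 0, donor_density > 0, recipient_density > 0,
            time_h > 0, p_escape > 0, p_escape <= 1, n_sites >= 0)
  if (is.null(replicates)) replicates <- seq_len(n_replicates)
  t_dens <- true_gamma * donor_density * recipient_density * time_h *
    p_escape^n_sites
  rows <- purrr::map(replicates, function(r) {
    draw <- function(dens) {
      counts <- stats::rpois(length(dilution_series),
                             dens * plated_volume / dilution_series)
      pick_plate(counts, dilution_series)
    }
    pT <- draw(t_dens)
    pD <- draw(donor_density)
    pR <- draw(recipient_density)
    tibble::tibble(
      assay_id = paste(plasmid_id, rm_system, r, sep = "_"),
      plasmid_id = plasmid_id,
      rm_system = rm_system,
      replicate = r,
      colonies_T = pT$colonies, dilution_T = pT$dilution,
      colonies_D = pD$colonies, dilution_D = pD$dilution,
      colonies_R = pR$colonies, dilution_R = pR$dilution,
      plated_volume = plated_volume,
      time_h = time_h
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a complete restriction-vs-conjugation study
#'
#' Generates plasmid sequences with planted recognition-site counts, the
#' corresponding site table, and mating assays toward an RM-free control
#' recipient plus one recipient per RM system. Under the default per-site
#' escape model the ground-truth restriction efficiency of a plasmid with n
#' sites is `p_escape^-n`, so `log10(RE) = n * (-log10 p_escape)`: the slope
#' of log10(RE) on n is known exactly and recoverable by regression. The
#' alternative `link = "log_sites"` makes log10(RE) linear in log10(n)
#' (zero counts replaced by 0.5), the empirical form used when regressing
#' on log-transformed site numbers.
#'
#' @param plasmid_specs Tibble with columns `id`, `length`, `gc` and either
#'   `n_sites` (single-enzyme studies) or a `sites` list-column of named
#'   vectors (enzyme name -> planted count).
#' @param enzymes Enzyme tibble ([parse_enzyme_table()]); rows used define
#'   the RM+ arms.
#' @param p_escape Per-site escape probability, scalar or named per enzyme.
#' @param true_gamma,donor_density,recipient_density,time_h,n_replicates
#'   Passed to [simulate_assay()].
#' @param dilution_series,plated_volume Passed to [simulate_assay()].
#' @param link `"per_site"` (default) or `"log_sites"`, see Details.
#' @param sequences Generate actual sequences (default TRUE); FALSE skips
#'   sequence synthesis and fabricates the site table directly from the
#'   specs, for fast simulation studies of the downstream statistics.
#' @param seed Optional integer seed governing all randomness.
#' @param outdir Optional directory; when given, writes `plasmids.fa`,
#'   `enzymes.tsv`, `assays.tsv`, `sites.tsv` and `truth.json`.
#' @return List with `plasmids` (tibble of records, or NULL), `sites`,
#'   `assays`, `truth` (list of all ground-truth parameters) and `paths`
#'   (when `outdir` was given).
#' @export
simulate_study <- function(plasmid_specs, enzymes, p_escape = 0.5,
                           true_gamma = 1e-11, donor_density = 1e9,
                           recipient_density = 1e9, time_h = 4,
                           n_replicates = 4, dilution_series = 10^(0:7),
                           plated_volume = 0.1,
                           link = c("per_site", "log_sites"),
                           sequences = TRUE, seed = NULL, outdir = NULL) {
  link <- match.arg(link)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(plasmid_specs) > 0L, nrow(enzymes) > 0L)
  if (!"sites" %in% names(plasmid_specs)) {
    if (!"n_sites" %in% names(plasmid_specs) || nrow(enzymes) != 1L) {
      stop("plasmid_specs needs a `sites` list-column, or an `n_sites` ",
           "column with a single enzyme", call. = FALSE)
    }
    plasmid_specs$sites <- purrr::map(plasmid_specs$n_sites, function(n) {
      stats::setNames(n, enzymes$name[1L])
    })
  }
  esc <- if (length(p_escape) == 1L && is.null(names(p_escape))) {
    stats::setNames(rep(p_escape, nrow(enzymes)), enzymes$name)
  } else {
    stopifnot(all(enzymes$name %in% names(p_escape)))
    p_escape[enzymes$name]
  }

  plasmids <- NULL
  if (sequences) {
    plasmids <- dplyr::bind_rows(purrr::map(seq_len(nrow(plasmid_specs)),
      function(i) {
        spec <- plasmid_specs[i, ]
        sites_i <- spec$sites[[1L]]
        motifs <- stats::setNames(
          as.integer(sites_i),
          enzymes$recognition[match(names(sites_i), enzymes$name)]
        )
        generate_sequence(spec$length, spec$gc, planted = motifs,
                          id = spec$id)
      }))
    sites <- site_table(plasmids, enzymes)
  } else {
    sites <- dplyr::bind_rows(purrr::map(seq_len(nrow(plasmid_specs)),
      function(i) {
        spec <- plasmid_specs[i, ]
        sites_i <- spec$sites[[1L]]
        tibble::tibble(
          plasmid_id = spec$id,
          enzyme_name = names(sites_i),
          rm_type = enzymes$rm_type[match(names(sites_i), enzymes$name)],
          n_sites = as.integer(sites_i),
          forward = NA_integer_, reverse = NA_integer_,
          length = spec$length, gc = spec$gc
        )
      }))
  }

  escape_multiplier <- function(enzyme_name, n) {
    pe <- esc[[enzyme_name]]
    if (link == "per_site") {
      pe^n
    } else {
      pe^log10(ifelse(n == 0, 0.5, n))
    }
  }

  assays <- dplyr::bind_rows(purrr::map(seq_len(nrow(plasmid_specs)),
    function(i) {
      spec <- plasmid_specs[i, ]
      sites_i <- spec$sites[[1L]]
      arms <- list(simulate_assay(
        true_gamma, donor_density, recipient_density, time_h, n_replicates,
        p_escape = 1, n_sites = 0,
        dilution_series = dilution_series, plated_volume = plated_volume,
        plasmid_id = spec$id, rm_system = "none"
      ))
      for (enz in names(sites_i)) {
        n <- sites_i[[enz]]
        mult <- escape_multiplier(enz, n)
        arms[[length(arms) + 1L]] <- simulate_assay(
          true_gamma * mult, donor_density, recipient_density, time_h,
          n_replicates, p_escape = 1, n_sites = 0,
          dilution_series = dilution_series, plated_volume = plated_volume,
          plasmid_id = spec$id, rm_system = enz
        )
      }
      dplyr::bind_rows(arms)
    }))

  truth <- list(
    true_gamma = true_gamma,
    p_escape = as.list(esc),
    link = link,
    slope_per_site = as.list(-log10(esc)),
    donor_density = donor_density,
    recipient_density = recipient_density,
    time_h = time_h,
    n_replicates = n_replicates,
    n_sites = stats::setNames(plasmid_specs$sites, plasmid_specs$id)
  )

  out <- list(plasmids = plasmids, sites = sites, assays = assays,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      enzymes = file.path(outdir, "enzymes.tsv"),
      assays = file.path(outdir, "assays.tsv"),
      sites = file.path(outdir, "sites.tsv"),
      truth = file.path(outdir, "truth.json")
    )
    if (!is.null(plasmids)) {
      paths$fasta <- file.path(outdir, "plasmids.fa")
      write_fasta(plasmids, paths$fasta)
    }
    enz_out <- enzymes
    names(enz_out)[names(enz_out) == "rm_type"] <- "type"
    readr::write_tsv(enz_out, paths$enzymes)
    readr::write_tsv(out$assays, paths$assays)
    readr::write_tsv(out$sites, paths$sites)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
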
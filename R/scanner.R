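# Recognition-site scanning on circular and linear replicons.

#' Construct a plasmid record
#'
#' @param id Plasmid identifier.
#' @param sequence DNA string; upper-cased on input. Bases outside A/C/G/T
#'   are allowed (IUPAC ambiguity codes) but are handled according to the
#'   scanner's `ambiguity` mode.
#' @param topology `"circular"` (default for plasmids) or `"linear"`.
#' @return A one-row tibble with columns `id`, `sequence`, `topology`,
#'   `length` and `gc` (GC fraction computed over A/C/G/T positions only).
#' @export
plasmid_record <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf("plasmid '%s': non-IUPAC character(s) at position(s) %s",
                 id, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  gc <- if (length(acgt) > 0L) mean(acgt %in% c("G", "C")) else NA_real_
  tibble::tibble(
    id = as.character(id),
    sequence = sequence,
    topology = topology,
    length = nchar(sequence),
    gc = gc
  )
}

#' Scan one strand for a degenerate motif
#'
#' Finds every (possibly overlapping) match of an IUPAC motif on the given
#' strand of a sequence. For circular topology the scan wraps across the
#' origin: the first `|motif| - 1` bases are appended before matching and
#' start positions are reported modulo the sequence length.
#'
#' @param seq DNA sequence (single string).
#' @param motif IUPAC motif.
#' @param topology `"circular"` or `"linear"`.
#' @param ambiguity `"lenient"` (default): ambiguity codes in the sequence
#'   match any compatible base (base sets must intersect); `"strict"`: any
#'   non-A/C/G/T base in the sequence is an error listing its positions.
#' @return Sorted integer vector of 1-based match start positions (in
#'   1..length(seq) for circular topology).
#' @export
scan_strand <- function(seq, motif,
                        topology = c("circular", "linear"),
                        ambiguity = c("lenient", "strict")) {
  topology <- match.arg(topology)
  ambiguity <- match.arg(ambiguity)
  motif <- validate_motif(motif)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("seq must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (ambiguity == "strict") {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad) > 0L) {
      stop(sprintf("ambiguous base(s) in sequence at position(s) %s",
                   paste(utils::head(bad, 20L), collapse = ", ")),
           call. = FALSE)
    }
  }
  k <- nchar(motif)
  L <- nchar(seq)
  if (k > L) return(integer(0))
  subject <- if (topology == "circular" && k > 1L) {
    paste0(seq, substr(seq, 1L, k - 1L))
  } else {
    seq
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(subject),
    fixed = FALSE
  )
  starts <- BiocGenerics::start(hits)
  if (topology == "circular") {
    starts <- (starts - 1L) %% L + 1L
  }
  sort(unique(as.integer(starts)))
}

#' Count duplex recognition sites on a plasmid
#'
#' Duplex convention: a degenerate-palindromic motif is counted on the
#' forward strand only (its reverse-strand matches coincide with forward
#' matches at the same duplex position); an asymmetric motif is counted on
#' both strands, as forward matches of the motif plus forward matches of its
#' reverse complement.
#'
#' @param plasmid A one-row plasmid record ([plasmid_record()]) or any list
#'   with `id`, `sequence` and `topology`.
#' @param enzyme A one-row enzyme table ([parse_enzyme_table()]) or list with
#'   `name` and `recognition` (optionally `rm_type`).
#' @param duplex `"auto"` (palindromy rule above, default), `"both"` (force
#'   two-strand counting) or `"forward"` (forward strand only).
#' @param ambiguity Passed to [scan_strand()].
#' @return A one-row tibble: `plasmid_id`, `enzyme_name`, `rm_type`,
#'   `n_sites`, `forward`, `reverse`.
#' @export
count_sites <- function(plasmid, enzyme,
                        duplex = c("auto", "both", "forward"),
                        ambiguity = c("lenient", "strict")) {
  duplex <- match.arg(duplex)
  ambiguity <- match.arg(ambiguity)
  motif <- validate_motif(enzyme$recognition[[1L]])
  topology <- plasmid$topology[[1L]]
  seq <- plasmid$sequence[[1L]]
  fwd <- scan_strand(seq, motif, topology, ambiguity)
  palindromic <- is_degenerate_palindrome(motif)
  count_reverse <- switch(duplex,
    auto = !palindromic,
    both = TRUE,
    forward = FALSE
  )
  rev_hits <- if (count_reverse) {
    scan_strand(seq, reverse_complement(motif), topology, ambiguity)
  } else {
    integer(0)
  }
  tibble::tibble(
    plasmid_id = plasmid$id[[1L]],
    enzyme_name = enzyme$name[[1L]],
    rm_type = if (!is.null(enzyme$rm_type)) enzyme$rm_type[[1L]] else NA_character_,
    n_sites = length(fwd) + length(rev_hits),
    forward = length(fwd),
    reverse = length(rev_hits)
  )
}

#' Site-count table for plasmids x enzymes
#'
#' One row per plasmid x enzyme combination (zero counts retained), with
#' plasmid length and GC carried along for downstream null models.
#'
#' @param plasmids Tibble of plasmid records (e.g. from [read_fasta()]).
#' @param enzymes Enzyme tibble from [parse_enzyme_table()].
#' @inheritParams count_sites
#' @return Tibble with columns `plasmid_id`, `enzyme_name`, `rm_type`,
#'   `n_sites`, `forward`, `reverse`, `length`, `gc`.
#' @export
site_table <- function(plasmids, enzymes,
                       duplex = c("auto", "both", "forward"),
                       ambiguity = c("lenient", "strict")) {
  duplex <- match.arg(duplex)
  ambiguity <- match.arg(ambiguity)
  stopifnot(nrow(plasmids) > 0L, nrow(enzymes) > 0L)
  rows <- purrr::map(seq_len(nrow(plasmids)), function(i) {
    p <- plasmids[i, ]
    counts <- purrr::map(seq_len(nrow(enzymes)), function(j) {
      count_sites(p, enzymes[j, ], duplex = duplex, ambiguity = ambiguity)
    })
    dplyr::mutate(dplyr::bind_rows(counts), length = p$length, gc = p$gc)
  })
  dplyr::bind_rows(rows)
}

#' Per-RM-type median site counts
#'
#' Pools all plasmid x system counts within each mechanistic type and takes
#' the median, the summary used to compare how densely Type I, II and III
#' sites occur on plasmids.
#'
#' @param sites A table from [site_table()].
#' @return Tibble with columns `rm_type`, `n`, `median_sites`.
#' @export
site_type_medians <- function(sites) {
  sites |>
    dplyr::group_by(.data$rm_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_sites = stats::median(.data$n_sites),
      .groups = "drop"
    )
}
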
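# Expected recognition-site counts under compositional null models and
# site-avoidance statistics.

# Match probability of a degenerate motif under a first-order Markov chain.
# `trans` is a 4x4 row-stochastic matrix over A/C/G/T; `init` the marginal
# base frequencies. Ambiguity sets are handled by propagating a probability
# vector restricted to the allowed bases at each position.
markov1_motif_probability <- function(motif, trans, init) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  v <- init
  allowed <- bases %in% IUPAC_SETS[[chars[1L]]]
  v[!allowed] <- 0
  for (ch in chars[-1L]) {
    v <- as.numeric(v %*% trans)
    names(v) <- bases
    allowed <- bases %in% IUPAC_SETS[[ch]]
    v[!allowed] <- 0
  }
  sum(v)
}

# Estimate dinucleotide transition probabilities from a sequence (circular
# topology includes the wrap-around dinucleotide). Pseudocount 1 avoids
# zero rows on short sequences.
estimate_markov1 <- function(seq, topology = "circular") {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  chars <- chars[chars %in% bases]
  n <- length(chars)
  if (n < 2L) stop("sequence too short for a first-order model", call. = FALSE)
  from <- chars
  to <- c(chars[-1L], chars[1L])
  if (topology != "circular") {
    from <- from[-n]
    to <- to[-n]
  }
  counts <- table(factor(from, bases), factor(to, bases)) + 1
  trans <- sweep(unclass(counts), 1L, rowSums(counts), "/")
  init <- as.numeric(table(factor(chars, bases)) / n)
  names(init) <- bases
  list(trans = trans, init = init)
}

#' Expected recognition-site count from size and composition
#'
#' Number of scanned positions times the motif match probability under a
#' null model built from the plasmid's own composition, matching the
#' scanner's conventions: positions = L for circular topology or
#' L - |motif| + 1 for linear; the expectation is doubled for asymmetric
#' motifs (both strands counted) and not for degenerate palindromes.
#'
#' @param plasmid A plasmid record ([plasmid_record()]).
#' @param enzyme A one-row enzyme table or list with `name`, `recognition`.
#' @param model Optional [composition_model()]; defaults to one built from
#'   the plasmid's GC content.
#' @param order Null-model order: `0` (GC-only, default) or `1` (dinucleotide
#'   Markov chain estimated from the plasmid sequence).
#' @return Expected site count (non-negative real; 0 with a warning when the
#'   motif is longer than the sequence).
#' @export
expected_count <- function(plasmid, enzyme, model = NULL, order = 0) {
  motif <- validate_motif(enzyme$recognition[[1L]])
  k <- nchar(motif)
  L <- plasmid$length[[1L]]
  topology <- plasmid$topology[[1L]]
  if (k > L) {
    warning("motif longer than sequence; expected count is 0")
    return(0)
  }
  positions <- if (topology == "circular") L else L - k + 1L
  p <- if (order == 0) {
    if (is.null(model)) model <- composition_model(plasmid$gc[[1L]])
    motif_probability(motif, model)
  } else if (order == 1) {
    m1 <- estimate_markov1(plasmid$sequence[[1L]], topology)
    markov1_motif_probability(motif, m1$trans, m1$init)
  } else {
    stop("order must be 0 or 1", call. = FALSE)
  }
  strands <- if (is_degenerate_palindrome(motif)) 1 else 2
  positions * p * strands
}

#' Site-avoidance statistics
#'
#' Quantifies under-representation of recognition sites relative to a
#' compositional expectation: the avoidance ratio observed/expected and the
#' lower-tail Poisson probability P(X <= observed | mean = expected). The
#' Poisson approximation ignores overlap clumping of self-overlapping motifs
#' and is adequate for the 5-15 nt sites considered here.
#'
#' @param observed Non-negative integer site count(s).
#' @param expected Expected count(s) from [expected_count()].
#' @return Tibble with columns `observed`, `expected`, `ratio`,
#'   `p_lower`. When `expected` is 0 the ratio is undefined and reported as
#'   `NA`.
#' @examples
#' avoidance(1, 7) # ratio 1/7, p_lower = exp(-7) * 8
#' @export
avoidance <- function(observed, expected) {
  stopifnot(all(observed >= 0), all(expected >= 0))
  tibble::tibble(
    observed = observed,
    expected = expected,
    ratio = ifelse(expected > 0, observed / expected, NA_real_),
    p_lower = ifelse(expected > 0, stats::ppois(observed, expected), NA_real_)
  )
}

#' Observed vs expected site counts for plasmids x enzymes
#'
#' Combines [site_table()] and [expected_count()] into one avoidance table.
#'
#' @inheritParams site_table
#' @param order Null-model order passed to [expected_count()].
#' @return Tibble with columns `plasmid_id`, `enzyme_name`, `rm_type`,
#'   `observed`, `expected`, `ratio`, `p_lower`.
#' @export
expectation_table <- function(plasmids, enzymes, order = 0,
                              duplex = c("auto", "both", "forward")) {
  duplex <- match.arg(duplex)
  sites <- site_table(plasmids, enzymes, duplex = duplex)
  exp_vals <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    p <- plasmids[plasmids$id == sites$plasmid_id[i], ]
    e <- enzymes[enzymes$name == sites$enzyme_name[i], ]
    expected_count(p, e, order = order)
  })
  dplyr::bind_cols(
    sites[, c("plasmid_id", "enzyme_name", "rm_type")],
    avoidance(sites$n_sites, exp_vals)
  )
}
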